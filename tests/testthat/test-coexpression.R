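test_that("pairwise correlations match a first-principles oracle and basic identities", {
  m <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4), C = c(-1, -2, -3, -4),
             D = c(1, 2, 3, 100))
  colnames(m) <- paste0("s", 1:4)
  expr <- expression_matrix(m, stats::setNames(rep("x", 4), colnames(m)))
  r <- pairwise_correlations(expr, "x")
  expect_equal(r["A", "B"], 1.0)
  expect_equal(r["A", "C"], -1.0)
  expect_equal(r["A", "D"], oracle_pearson(c(1, 2, 3, 4), c(1, 2, 3, 100)),
               tolerance = 1e-12)
  expect_true(is.na(r["A", "A"]))
  expect_equal(unclass(r)[upper.tri(r)], t(unclass(r))[upper.tri(r)])

  set.seed(7)
  expr2 <- toy_expr(n_genes = 6, n1 = 5, n2 = 5)
  r2 <- pairwise_correlations(expr2, "disease")
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(r2[i, j],
                 oracle_pearson(expr2$values[i, 1:5], expr2$values[j, 1:5]),
                 tolerance = 1e-12)
})

test_that("too few samples and zero-variance genes are handled explicitly", {
  m <- rbind(A = c(1, 2, 3, 4), B = c(5, 5, 5, 5), C = c(2, 1, 4, 3))
  colnames(m) <- paste0("s", 1:4)
  expr <- expression_matrix(m, stats::setNames(c("x", "x", "x", "y"),
                                               colnames(m)))
  expect_error(pairwise_correlations(expr, "y"), "at least 3")
  expect_warning(r <- pairwise_correlations(expr, "x"), "zero-variance")
  expect_true(all(is.na(r["B", ])))
  expect_false(is.na(r["A", "C"]))
})

test_that("link retention follows the cutoff rule in both modes", {
  # absolute: a link strong in either condition is kept with both r values
  g <- c("AHR", "TLE4", "U", "V")
  m1 <- matrix(NA_real_, 4, 4, dimnames = list(g, g))
  m1["AHR", "TLE4"] <- m1["TLE4", "AHR"] <- 0.94
  m1["U", "V"] <- m1["V", "U"] <- 0.5
  m2 <- m1
  m2["AHR", "TLE4"] <- m2["TLE4", "AHR"] <- 0.14
  m2["U", "V"] <- m2["V", "U"] <- -0.5
  c1 <- structure(m1, condition = "disease", method = "pearson",
                  class = "cor_map")
  c2 <- structure(m2, condition = "control", method = "pearson",
                  class = "cor_map")
  net <- build_network_pair(c1, c2, link_cutoff("absolute", 0.8))
  expect_identical(nrow(net$links), 1L)
  expect_equal(net$links$gene_a, "AHR")
  expect_equal(net$links[, c("r1", "r2")],
               data.frame(r1 = 0.94, r2 = 0.14))

  # quantile: top-q fraction of pairs by max |r|, brute-force enumerated
  g <- c("a", "b", "c", "d")
  mq <- matrix(NA_real_, 4, 4, dimnames = list(g, g))  # 4-pair universe
  mq["a", "b"] <- mq["b", "a"] <- 0.1
  mq["a", "c"] <- mq["c", "a"] <- 0.3
  mq["a", "d"] <- mq["d", "a"] <- 0.7
  mq["b", "c"] <- mq["c", "b"] <- 0.9
  cq <- structure(mq, condition = "x", method = "pearson", class = "cor_map")
  cq2 <- structure(mq * 0.5, condition = "y", method = "pearson",
                   class = "cor_map")
  diag(cq2) <- NA
  netq <- build_network_pair(cq, cq2, link_cutoff("quantile", 0.5))
  kept <- netq$links
  expect_setequal(kept$r1, c(0.7, 0.9))

  expect_error(build_network_pair(c1, c2, link_cutoff("absolute", 0.99)),
               "no links retained")
})

test_that("network pairs share topology, canonical order and bounded coefficients", {
  expr <- toy_expr(n_genes = 30, seed = 11)
  c1 <- pairwise_correlations(expr, "disease")
  c2 <- pairwise_correlations(expr, "control")
  net <- build_network_pair(c1, c2, link_cutoff("quantile", 0.05))
  l <- net$links
  expect_true(all(l$gene_a < l$gene_b))
  expect_false(anyDuplicated(paste(l$gene_a, l$gene_b)) > 0)
  expect_true(all(abs(l$r1) <= 1 & abs(l$r2) <= 1))
  expect_false(anyNA(l$r1) || anyNA(l$r2))

  # symmetry: swapping condition roles swaps (r1, r2) and nothing else
  net_rev <- build_network_pair(c2, c1, link_cutoff("quantile", 0.05))
  expect_equal(net_rev$links$gene_a, l$gene_a)
  expect_equal(net_rev$links$r1, l$r2)
  expect_equal(net_rev$links$r2, l$r1)
  swapped <- swap_conditions(net)
  expect_equal(swapped$links, net_rev$links)
  expect_equal(swapped$conditions, rev(net$conditions))
})

test_that("neighbor vectors align pairwise in canonical neighbor order", {
  net <- toy_net(gene_a = c("HUB", "HUB", "C", "HUB"),
                 gene_b = c("B", "A", "HUB", "D"),
                 r1 = c(0.9, 0.8, 0.7, -0.6),
                 r2 = c(0.1, -0.2, 0.3, 0.6))
  nv <- neighbor_vectors(net, "HUB")
  expect_equal(nv$neighbors, c("A", "B", "C", "D"))
  expect_equal(nv$x, c(0.8, 0.9, 0.7, -0.6))
  expect_equal(nv$y, c(-0.2, 0.1, 0.3, 0.6))

  single <- neighbor_vectors(net, "A")
  expect_equal(single$x, 0.8)
  expect_equal(single$y, -0.2)

  none <- neighbor_vectors(net, "ZZ")
  expect_length(none$neighbors, 0)
  expect_length(none$x, 0)
})
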