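test_that("reversal typing flags sign switches and only sign switches", {
  expect_identical(reversal_type(0.94, 0.14), 0L)
  expect_identical(reversal_type(-0.60, 0.97), 1L)
  expect_identical(reversal_type(-0.71, 0.97), 1L)
  expect_identical(reversal_type(0.0, 0.5), 0L)   # zero product: no switch
  expect_identical(reversal_type(-0.3, -0.9), 0L)
  # symmetric under swapping the two conditions
  set.seed(8)
  r1 <- runif(50, -1, 1)
  r2 <- runif(50, -1, 1)
  expect_identical(reversal_type(r1, r2), reversal_type(r2, r1))
  expect_error(reversal_type(1.2, 0.5), "\\[-1, 1\\]")
})

test_that("limit-fold-change selection ranks within bins and skips unchanged links", {
  # single bin, delta 0.5, fold changes 10, 5, 2, 1 -> exactly the top two
  net <- toy_net(gene_a = c("a", "b", "c", "d"),
                 gene_b = c("e", "f", "g", "h"),
                 r1 = c(1.0, 0.05, 0.9, 0.9),
                 r2 = c(0.1, 0.25, 0.45, 0.9))
  d <- lfc_select_dcls(net, delta = 0.5, n_bins = 1)
  fc <- pmax(abs(d$r1), abs(d$r2)) / (pmin(abs(d$r1), abs(d$r2)) + 1e-8)
  expect_setequal(round(fc[d$is_dcl]), c(10, 5))

  # identical coefficients in both conditions: nothing is differential
  net0 <- toy_net(gene_a = c("a", "b"), gene_b = c("c", "d"),
                  r1 = c(0.9, 0.85), r2 = c(0.9, 0.85))
  expect_warning(d0 <- lfc_select_dcls(net0, delta = 0.5), "no links")
  expect_false(any(d0$is_dcl))

  # an opposite-sign link is ranked by |r1 - r2| and keeps its type
  net1 <- toy_net(gene_a = c("JUN", "x"), gene_b = c("CHURC1", "y"),
                  r1 = c(0.51, -0.95), r2 = c(-0.95, -0.90))
  d1 <- lfc_select_dcls(net1, delta = 0.5, n_bins = 1)
  row <- d1[d1$gene_a == "CHURC1", ]
  expect_true(row$is_dcl)
  expect_identical(row$type, 1L)

  # strong reversals (both |r| at link strength) bypass the ranking
  netsw <- toy_net(gene_a = rep("h", 4), gene_b = c("p", "q", "r", "s"),
                   r1 = c(0.9, 0.88, 0.92, 0.91),
                   r2 = c(-0.85, -0.9, -0.88, -0.87))
  dsw <- lfc_select_dcls(netsw, delta = 0.1, n_bins = 1)
  expect_true(all(dsw$is_dcl))
  expect_true(all(dsw$bin == 0L))
})

test_that("per-gene DCL bookkeeping conserves counts", {
  set.seed(12)
  g <- sprintf("g%02d", 1:12)
  pairs <- t(combn(g, 2))
  pick <- sample(nrow(pairs), 30)
  d <- toy_dcls(pairs[pick, 1], pairs[pick, 2],
                runif(30, -1, 1), runif(30, -1, 1),
                is_dcl = runif(30) < 0.4)
  cnt <- dce_counts(d)
  expect_identical(cnt$N, 30L)
  expect_identical(cnt$K, sum(d$is_dcl))
  expect_identical(sum(cnt$genes$k_i), 2L * cnt$K)
  expect_true(all(cnt$genes$k_i <= cnt$genes$n_i))
  expect_identical(sum(cnt$genes$n_i), 2L * cnt$N)
})

test_that("binomial enrichment matches exhaustive summation and boundary cases", {
  expect_identical(binomial_enrichment(5, 0, 3, 10), 1)
  expect_equal(binomial_enrichment(2, 1, 1, 2), 0.75, tolerance = 1e-12)
  expect_equal(binomial_enrichment(3, 3, 1, 10), 1e-3, tolerance = 1e-12)
  for (n in c(1, 4, 7)) for (k in 0:n) for (q in c(0.05, 0.5, 0.95))
    expect_equal(binomial_enrichment(n, k, round(q * 100), 100),
                 oracle_binom_tail(n, k, q), tolerance = 1e-10)
  # non-increasing in k at fixed (n, K, N)
  p <- binomial_enrichment(rep(8, 9), 0:8, 25, 100)
  expect_true(all(diff(p) <= 0))
  expect_error(binomial_enrichment(3, 4, 1, 10), "k_i")
  expect_error(binomial_enrichment(3, 1, 11, 10), "K")
})

test_that("DCe DCG calls agree with an exhaustive-summation oracle", {
  d <- toy_dcls(gene_a = c("hub", "hub", "hub", "a", "b"),
                gene_b = c("t1", "t2", "t3", "b", "c"),
                r1 = c(0.9, 0.9, 0.9, 0.8, 0.85),
                r2 = c(-0.9, -0.9, -0.9, 0.8, 0.2),
                is_dcl = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  cnt <- dce_counts(d)
  called <- call_dce_dcgs(cnt, 0.05)
  manual <- character(0)
  for (i in seq_len(nrow(cnt$genes))) {
    gi <- cnt$genes[i, ]
    if (oracle_binom_tail(gi$n_i, gi$k_i, cnt$K / cnt$N) <= 0.05)
      manual <- c(manual, gi$gene)
  }
  expect_setequal(called, manual)
  # k_i = 0 genes are never called below threshold 1
  expect_false(any(c("a", "b", "c") %in% call_dce_dcgs(cnt, 0.999)))
  # a hub whose links are all DCLs at low background rate is always called
  expect_lte(binomial_enrichment(8, 8, 5, 100), 0.05)
  expect_equal(binomial_enrichment(8, 8, 5, 100), 0.05^8, tolerance = 1e-12)
})
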