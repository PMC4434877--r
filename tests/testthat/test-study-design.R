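test_that("individual-effect exclusion is a set difference and is idempotent", {
  expect_equal(exclude_shared(c("A", "B", "C"), c("B", "D")), c("A", "C"))
  expect_length(exclude_shared(c("A", "B"), c("A", "B")), 0)
  a <- c("FOSB", "PATZ1", "TFAP4")
  b <- c("EGR1", "IRF1", "MYOD1", "SOX5", "TFAP4")
  once <- exclude_shared(a, b)
  expect_equal(once, c("FOSB", "PATZ1"))
  expect_equal(exclude_shared(once, b), once)

  # DRL tables are matched on (tf, target) identity, not on correlations
  d1 <- data.frame(tf = c("P", "P", "Q"), target = c("t1", "t2", "t3"),
                   r1 = c(0.9, 0.8, 0.7), stringsAsFactors = FALSE)
  d2 <- data.frame(tf = "P", target = "t2", r1 = -0.5,
                   stringsAsFactors = FALSE)
  kept <- exclude_shared(d1, d2)
  expect_equal(paste(kept$tf, kept$target), c("P t1", "Q t3"))
  expect_equal(exclude_shared(kept, d2), kept)
})

test_that("key overlap keeps DRLs whose TF is a DRG, and key DRGs are their TFs", {
  set.seed(41)
  drls <- data.frame(tf = sample(LETTERS[1:8], 20, TRUE),
                     target = sprintf("t%02d", 1:20),
                     stringsAsFactors = FALSE)
  drgs <- c("A", "C", "E", "G", "Z")
  k <- key_overlap(drgs, drls)
  manual <- drls[drls$tf %in% drgs, ]
  expect_equal(nrow(k$key_drls), nrow(manual))
  expect_setequal(paste(k$key_drls$tf, k$key_drls$target),
                  paste(manual$tf, manual$target))
  expect_setequal(k$key_drgs, unique(manual$tf))
  expect_true(all(k$key_drgs %in% drgs))

  none <- key_overlap(character(0), drls)
  expect_length(none$key_drgs, 0)
  expect_identical(nrow(none$key_drls), 0L)
})

test_that("deterministic pipeline stages are invariant to sample order", {
  sim <- simulate_dc_data(simulation_config(
    n_genes = 40, n_tf_hubs = 2, targets_per_hub = 5,
    reversal_fraction = 1, shift_fraction = 0,
    samples_per_group = c(pre = 6, control = 6), seed = 17))
  shuffled <- sim$expr
  set.seed(1)
  o <- sample(ncol(shuffled$values))
  shuffled <- expression_matrix(shuffled$values[, o],
                                shuffled$conditions[o])
  stages <- function(e) {
    c1 <- pairwise_correlations(e, "pre")
    c2 <- pairwise_correlations(e, "control")
    net <- build_network_pair(c1, c2)
    d <- suppressWarnings(lfc_select_dcls(net))
    list(links = net$links, dcls = d, dce = dce_counts(d)$genes)
  }
  expect_equal(stages(shuffled), stages(sim$expr))
})

test_that("a full arm recovers a planted regulator and flags no effect when there is none", {
  sim <- simulate_dc_data(simulation_config(
    n_genes = 80, n_tf_hubs = 2, targets_per_hub = 8,
    reversal_fraction = 1, shift_fraction = 0, seed = 23))
  cfg <- dc_config(seed = 23, n_permutations = 200)
  arm <- run_study_arm(sim$expr,
                       c(pre = "pre", post = "post", control = "control"),
                       sim$truth$library, cfg, label = "planted")
  expect_true(all(sim$truth$dcg_genes %in% arm$summary$key_drgs))
  expect_true(all(arm$summary$key_drgs %in% arm$summary$disease_drgs))
  expect_setequal(unique(arm$summary$key_drls$tf), arm$summary$key_drgs)

  # identical seed, identical outcome end to end
  arm2 <- run_study_arm(sim$expr,
                        c(pre = "pre", post = "post", control = "control"),
                        sim$truth$library, cfg, label = "planted")
  expect_identical(arm$summary, arm2$summary)

  expect_error(
    run_study_arm(sim$expr, c(pre = "pre", post = "post"),
                  sim$truth$library, cfg),
    "control")
  expect_error(
    run_study_arm(sim$expr, c(pre = "pre", post = "post", control = "ctrl"),
                  sim$truth$library, cfg),
    "'ctrl'")
})

test_that("a contrast-free arm (all labels aliasing one pool) reports nothing", {
  sim <- simulate_dc_data(simulation_config(
    n_genes = 40, n_tf_hubs = 1, targets_per_hub = 5,
    reversal_fraction = 0, shift_fraction = 0,
    samples_per_group = c(control = 8), altered_groups = character(0),
    seed = 3))
  arm <- suppressWarnings(run_study_arm(
    sim$expr, c(pre = "control", post = "control", control = "control"),
    sim$truth$library, dc_config(seed = 3, n_permutations = 50)))
  for (r in arm$reports) {
    expect_length(r$true_dcgs, 0)
    expect_identical(nrow(r$true_dcls), 0L)
    expect_length(r$drgs, 0)
  }
  expect_length(arm$summary$key_drgs, 0)
})

test_that("identically drawn pre and post groups yield no treatment effect", {
  # pre and post share the correlation structure; an empty pre-vs-post
  # report is the expected outcome in nearly every replicate
  empty <- 0L
  for (s in 1:8) {
    sim <- simulate_dc_data(simulation_config(
      n_genes = 80, n_tf_hubs = 2, targets_per_hub = 5,
      reversal_fraction = 0, shift_fraction = 0, seed = s))
    rep <- run_comparison(sim$expr, "pre", "post", sim$truth$library,
                          dc_config(seed = s, n_permutations = 100))
    empty <- empty +
      (length(rep$drgs) == 0L && nrow(rep$drls) == 0L)
  }
  expect_gte(empty, 7L)
})
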