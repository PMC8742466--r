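test_that("stock scenarios reproduce the benchmark design table", {
  dims <- data.frame(p_a = c(2, 4, 8, 16), act = c(1, 2, 4, 8),
                     tot = c(4, 8, 16, 32), p = c(80, 160, 320, 640),
                     n = c(100, 200, 400, 800))
  for (s in 1:4) {
    scn <- simulation_scenario(s)
    expect_equal(scn$p_a, dims$p_a[s])
    expect_equal(scn$n_groups_active, dims$act[s])
    expect_equal(scn$n_groups_total, dims$tot[s])
    expect_equal(scn$p, dims$p[s])
    expect_equal(scn$n_total, dims$n[s])
    expect_equal(scn$p / scn$n_total, 0.8)  # constant p/n ratio
  }
})

test_that("simulated datasets carry the planted effect pattern", {
  scn <- simulation_scenario(1)
  sim <- simulate_dataset(scn, seed = 3)
  expect_equal(sim$data$p, 80)
  expect_equal(sim$data$K, 2)
  expect_equal(unname(sim$data$n), c(50, 50))
  expect_equal(sim$groups$G, 4)
  expect_true(all(sim$groups$sizes == 20))

  # 2 active variables in group 1; magnitudes all 0.8
  active <- which(rowSums(sim$true_B != 0) > 0)
  expect_equal(active, 1:2)
  expect_true(all(abs(sim$true_B[active, ]) == 0.8))
  # study 1 all positive; study 2 alternates starting +
  expect_true(all(sim$true_B[active, 1] == 0.8))
  expect_equal(sim$true_B[active, 2], c(0.8, -0.8))

  # determinism
  sim2 <- simulate_dataset(scn, seed = 3)
  expect_identical(sim$data$X, sim2$data$X)
  expect_identical(sim$data$y, sim2$data$y)

  # scenario 2: alternation continues across groups in the active index order
  simb <- simulate_dataset(simulation_scenario(2), seed = 4)
  act2 <- which(rowSums(simb$true_B != 0) > 0)
  expect_equal(act2, c(1:4, 21:24))
  expect_equal(simb$true_B[act2, 2], 0.8 * rep(c(1, -1), 4))

  # genotype mode draws standardised dosages with three levels
  scng <- simulation_scenario(1, covariate_mode = "genotype")
  simg <- simulate_dataset(scng, seed = 5)
  expect_lte(length(unique(as.numeric(simg$data$X[[1]]))), 3)
})

test_that("metrics match hand evaluations and the independent confusion oracle", {
  scn <- simulation_scenario(1)
  sim <- simulate_dataset(scn, seed = 7)

  # perfect recovery
  m <- compute_metrics(sim$true_B, sim$true_B, sim$groups, "variable")
  expect_equal(c(m$tpr, m$tnr, m$mcc), c(1, 1, 1))
  expect_equal(c(m$l1_error, m$l2_error), c(0, 0))

  # all-null estimate: closed-form l2 anchor sqrt(4 * 0.8^2) = 1.6
  m0 <- compute_metrics(matrix(0, 80, 2), sim$true_B, sim$groups, "variable")
  expect_equal(m0$tpr, 0)
  expect_equal(m0$tnr, 1)
  expect_equal(m0$l2_error, 1.6)
  expect_equal(m0$l1_error, 4 * 0.8)

  g0 <- compute_metrics(matrix(0, 80, 2), sim$true_B, sim$groups, "group")
  expect_equal(g0$tp + g0$fn, 1)  # one active group in scenario 1
  expect_equal(g0$tn + g0$fp, 3)

  # random selection vectors against an independent confusion implementation
  set.seed(1)
  truth <- rowSums(sim$true_B != 0) > 0
  for (i in 1:200) {
    called <- sample(80, sample(0:30, 1))
    m <- compute_metrics(list(variables = called, groups = integer(0)),
                         sim$true_B, sim$groups, "variable")
    ref <- ref_confusion_metrics(truth, seq_len(80) %in% called)
    expect_equal(m$tpr, ref$tpr)
    expect_equal(m$tnr, ref$tnr)
    expect_equal(m$mcc, ref$mcc)
  }

  # the fixed confusion table TP=8 FP=2 TN=88 FN=2
  mcc_ref <- (8 * 88 - 2 * 2) / sqrt(10) / sqrt(10) / sqrt(90) / sqrt(90)
  truth2 <- rep(c(TRUE, FALSE), c(10, 90))
  called2 <- c(rep(TRUE, 8), FALSE, FALSE, rep(TRUE, 2), rep(FALSE, 88))
  ref2 <- ref_confusion_metrics(truth2, called2)
  expect_equal(ref2$mcc, mcc_ref)
})

test_that("a small benchmark run is deterministic and well-formed", {
  scn <- simulation_scenario(NULL, K = 2, group_size = 5, p_a = 2,
                             n_groups_active = 1, n_groups_total = 2,
                             n_total = 80)
  r1 <- run_scenario(scn, methods = c("SMT", "SGST"), protocol = "selection",
                     n_replicates = 2, n_bootstrap = 5, seed = 3,
                     n_lambda = 6, n_folds = 4)
  r2 <- run_scenario(scn, methods = c("SMT", "SGST"), protocol = "selection",
                     n_replicates = 2, n_bootstrap = 5, seed = 3,
                     n_lambda = 6, n_folds = 4)
  expect_identical(r1$results, r2$results)
  expect_setequal(unique(r1$results$level), c("variable", "group"))
  expect_equal(nrow(r1$results), 2 * 2 * 2)  # reps x methods x levels
  expect_true(all(r1$results$tnr >= 0 & r1$results$tnr <= 1, na.rm = TRUE))

  r3 <- run_scenario(scn, methods = "SMT", protocol = "reconstruction",
                     n_replicates = 2, seed = 3, n_lambda = 6)
  expect_true(all(is.finite(r3$results$l2_error)))
  expect_true(all(r3$results$l2_error >= 0))

  out <- tempfile(); on.exit(unlink(out, recursive = TRUE))
  paths <- write_sim_result(r3, out)
  expect_true(all(file.exists(paths)))
})
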