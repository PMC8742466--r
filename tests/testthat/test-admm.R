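test_that("block soft-threshold kills small blocks and shrinks large ones", {
  expect_equal(block_soft_threshold(c(1, 2), 5), c(0, 0))       # zero branch
  expect_equal(block_soft_threshold(c(3, 4), 2.5), c(1.5, 2))   # shrink by half
  A <- matrix(rnorm(6), 3, 2)
  expect_equal(block_soft_threshold(A, 0), A)                   # identity at 0
  expect_equal(sqrt(sum(block_soft_threshold(A, 0.7)^2)),
               max(sqrt(sum(A^2)) - 0.7, 0))
  expect_error(block_soft_threshold(A, -1), "nonnegative")
})

test_that("z_update implements the exact prox of the composite penalty", {
  # lambda = 0: prox of the zero function is the identity
  inst <- rand_instance(10, p = 6, K = 2, n = 20, G = 2)
  B <- matrix(rnorm(12), 6, 2); U <- matrix(rnorm(12), 6, 2)
  expect_equal(z_update(B, U, inst$groups, penalty_config(0, 0.5)), B + U)

  # single group, alpha = 0, ||B+U||_F below the group threshold -> exact zero
  g1 <- group_structure(rep(1, 4))
  cfg <- penalty_config(lambda = 10, alpha = 0, rho = 1)
  V_small <- matrix(0.1, 4, 2)
  expect_true(all(z_update(V_small, V_small * 0, g1, cfg) == 0))

  # random instances against the Douglas-Rachford oracle
  for (s in 1:12) {
    set.seed(200 + s)
    p <- sample(4:8, 1); K <- sample(1:3, 1); G <- sample(1:3, 1)
    groups <- group_structure(sort(sample(seq_len(G), p, replace = TRUE)))
    V <- matrix(rnorm(p * K, sd = 2), p, K)
    lam <- runif(1, 0.2, 2); al <- runif(1)
    rho <- runif(1, 0.5, 2)
    cfg <- penalty_config(lam, al, rho = rho)
    Z <- z_update(V, V * 0, groups, cfg)
    Z_oracle <- oracle_prox_dr(V, groups,
                               t_row = rep(al * lam / rho, p),
                               t_grp = sqrt(groups$sizes) *
                                 (1 - al) * lam / rho)
    expect_lt(max(abs(Z - Z_oracle)), 1e-6)
  }

  # the worked 4x2 example: one group of 4, lambda1 = lambda2 = 0.3, rho = 1
  set.seed(99)
  V <- matrix(rnorm(8), 4, 2)
  g4 <- group_structure(rep(1, 4))
  cfg <- penalty_config(lambda = 0.6, alpha = 0.5, rho = 1,
                        group_weights = 1)  # unit group weight
  Z <- z_update(V, V * 0, g4, cfg)
  Z_oracle <- oracle_prox_dr(V, g4, t_row = rep(0.3, 4), t_grp = 0.3)
  expect_lt(max(abs(Z - Z_oracle)), 1e-6)
})

test_that("b_update solves the anchored ridge-logistic sub-problem", {
  inst <- rand_instance(11, p = 5, K = 2, n = 40)
  Z <- matrix(0, 5, 2); U <- matrix(0, 5, 2)

  # proximal point: enormous rho pins B at the anchor Z - U = 0
  B_inf <- b_update(inst$data, Z, U, rho = 1e8)
  expect_lt(max(abs(B_inf)), 1e-6)

  # tiny rho on well-posed data: B approaches the per-study MLE
  B_mle <- b_update(inst$data, Z, U, rho = 1e-6)
  mle <- vapply(1:2, function(k)
    ref_glm_coef(inst$data$X[[k]], inst$data$y[[k]]), numeric(5))
  expect_lt(max(abs(B_mle - mle)), 1e-3)

  # sub-objective gradient vanishes at the returned point
  rho <- 1.3
  Zr <- matrix(rnorm(10), 5, 2); Ur <- matrix(rnorm(10), 5, 2)
  B <- b_update(inst$data, Zr, Ur, rho, tol = 1e-9)
  grad <- likelihood_gradient(inst$data, B) + rho * (B - Zr + Ur)
  expect_lt(max(abs(grad)), 1e-8)

  # agrees with the generic smooth-convex minimiser
  fn <- function(par) {
    B <- matrix(par, 5, 2)
    neg_log_likelihood(inst$data, B) + rho / 2 * sum((B - Zr + Ur)^2)
  }
  opt <- stats::optim(rep(0, 10), fn, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(sqrt(sum((B - matrix(opt$par, 5, 2))^2)), 1e-5)
})

test_that("admm_fit recovers the per-study MLE at lambda = 0", {
  inst <- rand_instance(12, p = 5, K = 2, n = 60)
  cfg <- penalty_config(0, 0.5, tol_primal = 1e-7, tol_dual = 1e-7,
                        max_iter = 5000)
  fit <- admm_fit(inst$data, inst$groups, cfg)
  mle <- vapply(1:2, function(k)
    ref_glm_coef(inst$data$X[[k]], inst$data$y[[k]]), numeric(5))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$coefficients - mle)), 1e-4)
})

test_that("lambda_max brackets the all-zero solution in every penalty regime", {
  for (s in 1:6) {
    inst <- rand_instance(20 + s, p = 6, K = 2, n = 30, G = 2)
    al <- c(0, 0.35, 1)[(s %% 3) + 1]
    lmax <- lambda_max(inst$data, inst$groups, al)
    above <- admm_fit(inst$data, inst$groups, penalty_config(1.01 * lmax, al))
    below <- admm_fit(inst$data, inst$groups, penalty_config(0.5 * lmax, al))
    expect_true(all(above$coefficients == 0))
    expect_gt(length(below$selected_variables), 0)
  }

  # alpha = 0, single group: closed form ||g||_F / sqrt(p)
  inst <- rand_instance(30, p = 4, K = 2, n = 25, G = 1)
  g <- likelihood_gradient(inst$data, matrix(0, 4, 2))
  expect_equal(lambda_max(inst$data, inst$groups, 0),
               sqrt(sum(g^2)) / sqrt(4))
})

test_that("ADMM objective matches the smoothed convex oracle on random instances", {
  for (s in 1:8) {
    inst <- rand_instance(40 + s, p = sample(4:8, 1), K = sample(1:3, 1),
                          n = 30, G = 2)
    al <- runif(1)
    lmax <- lambda_max(inst$data, inst$groups, al)
    lam <- runif(1, 0.05, 0.6) * lmax
    cfg <- penalty_config(lam, al, tol_primal = 1e-7, tol_dual = 1e-7,
                          max_iter = 10000)
    fit <- admm_fit(inst$data, inst$groups, cfg)
    orc <- oracle_objective_min(inst$data, inst$groups, cfg)
    expect_true(fit$converged)
    expect_lt(abs(fit$objective_value - orc$value) / abs(orc$value), 1e-5)
  }
})

test_that("fits satisfy the KKT conditions and the residual criteria", {
  for (s in 1:4) {
    inst <- rand_instance(60 + s, p = 8, K = 2, n = 40, G = 3)
    al <- c(0, 0.5, 1, 0.25)[s]
    lmax <- lambda_max(inst$data, inst$groups, al)
    cfg <- penalty_config(0.3 * lmax, al, tol_primal = 1e-7, tol_dual = 1e-7,
                          max_iter = 10000)
    fit <- admm_fit(inst$data, inst$groups, cfg)
    expect_true(fit$converged)
    expect_lt(pleiosgl:::kkt_residual(inst$data, inst$groups, cfg,
                                      fit$coefficients), 1e-3)
    expect_true(all(fit$trace$primal >= 0), all(fit$trace$dual >= 0))
  }
})

test_that("alpha = 0 produces group-aligned sparsity; selection is read from Z", {
  inst <- rand_instance(70, p = 8, K = 2, n = 40, G = 4)
  lmax <- lambda_max(inst$data, inst$groups, 0)
  fit <- admm_fit(inst$data, inst$groups, penalty_config(0.4 * lmax, 0))
  Z <- fit$coefficients
  for (g in seq_len(inst$groups$G)) {
    blk <- Z[inst$groups$groups[[g]], , drop = FALSE]
    expect_true(all(blk == 0) || all(rowSums(blk^2) > 0))
  }
  # every selected variable's group is selected
  expect_true(all(inst$groups$index[fit$selected_variables] %in%
                    fit$selected_groups))
  # exact zeros, no epsilon noise
  expect_true(all(Z[Z != 0 & abs(Z) < 1e-14] == 0))
})

test_that("permuting variables and the group map permutes the solution", {
  inst <- rand_instance(71, p = 6, K = 2, n = 35, G = 2)
  lmax <- lambda_max(inst$data, inst$groups, 0.5)
  cfg <- penalty_config(0.3 * lmax, 0.5, tol_primal = 1e-6, tol_dual = 1e-6)
  fit <- admm_fit(inst$data, inst$groups, cfg)
  perm <- c(4, 1, 6, 2, 5, 3)
  data_p <- multistudy_dataset(lapply(inst$data$X, function(m) m[, perm]),
                               inst$data$y,
                               variable_ids = inst$data$variable_ids[perm])
  groups_p <- group_structure(inst$groups$group_ids[inst$groups$index][perm])
  fit_p <- admm_fit(data_p, groups_p, cfg)
  expect_equal(unname(fit_p$coefficients), unname(fit$coefficients[perm, ]),
               tolerance = 1e-5)
})

test_that("selection counts shrink as lambda grows along a warm-started path", {
  inst <- rand_instance(72, p = 10, K = 2, n = 60, G = 2)
  lmax <- lambda_max(inst$data, inst$groups, 1)
  lams <- exp(seq(log(lmax), log(0.05 * lmax), length.out = 12))
  fits <- pleiosgl:::admm_path(inst$data, inst$groups, lams, 1)
  counts <- vapply(fits, function(f) length(f$selected_variables), integer(1))
  # strict monotonicity is not guaranteed; assert the endpoints' ordering
  # (the first fit sits exactly at lambda_max, a boundary case)
  expect_lte(counts[1], 1L)
  expect_lt(counts[1], counts[length(counts)])
})

test_that("the unpenalised intercept matches glm and survives heavy penalisation", {
  set.seed(80)
  n <- 80; p <- 4
  X <- lapply(1:2, function(k) matrix(rnorm(n * p), n, p))
  b <- c(0.8, -0.6, 0, 0)
  y <- lapply(1:2, function(k) {
    rbinom(n, 1, plogis(-0.7 + X[[k]] %*% b))   # shifted class balance
  })
  data <- multistudy_dataset(X, y)
  groups <- group_structure(rep(1:2, each = 2))

  cfg <- penalty_config(0, 0.5, tol_primal = 1e-7, tol_dual = 1e-7,
                        max_iter = 5000, intercept = TRUE)
  fit <- admm_fit(data, groups, cfg)
  for (k in 1:2) {
    ref <- suppressWarnings(glm(y[[k]] ~ X[[k]], family = binomial()))
    expect_lt(abs(fit$intercept[k] - coef(ref)[1]), 1e-4)
    expect_lt(max(abs(fit$coefficients[, k] - coef(ref)[-1])), 1e-4)
  }

  # at lambda >= lambda_max (intercept-adjusted) the slopes vanish but the
  # intercept stays at the intercept-only MLE
  lmax <- lambda_max(data, groups, 1, intercept = TRUE)
  cfg2 <- penalty_config(1.05 * lmax, 1, tol_primal = 1e-6,
                         tol_dual = 1e-6, intercept = TRUE)
  fit2 <- admm_fit(data, groups, cfg2)
  expect_true(all(fit2$coefficients == 0))
  for (k in 1:2)
    expect_lt(abs(fit2$intercept[k] - qlogis(mean(y[[k]]))), 1e-3)

  # held-out deviance accounts for the intercept
  expect_equal(held_out_deviance(fit2, data),
               2 * sum(vapply(1:2, function(k)
                 -sum(dbinom(y[[k]], 1, mean(y[[k]]), log = TRUE)),
                 numeric(1))) / (2 * n),
               tolerance = 1e-5)
})
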