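# run expr with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stratified cross-validation folds for a multi-study dataset
#'
#' Folds are drawn within each study independently and stratified by
#' case/control label, so every training split retains both classes in every
#' study. Deterministic given `seed`.
#'
#' @param data a [multistudy_dataset()].
#' @param n_folds number of folds (>= 2, at most the smallest study size).
#' @param seed integer seed.
#' @return A list of K integer vectors of fold labels (1..n_folds).
#' @export
make_folds <- function(data, n_folds, seed) {
  stopifnot(n_folds >= 2L, n_folds <= min(data$n))
  for (k in seq_len(data$K)) {
    if (sum(data$y[[k]] == 1) < 2L || sum(data$y[[k]] == 0) < 2L)
      stop("study ", k, " is too small to stratify: need >= 2 cases and ",
           ">= 2 controls")
  }
  with_local_seed(seed, {
    lapply(seq_len(data$K), function(k) {
      y <- data$y[[k]]
      fold <- integer(length(y))
      for (cls in c(0, 1)) {
        idx <- which(y == cls)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(sample.int(n_folds), length(idx))
      }
      fold
    })
  })
}

#' Held-out deviance of a fit
#'
#' Mean per-observation deviance on held-out samples: twice the joint
#' negative log-likelihood at the fitted coefficients, divided by the total
#' held-out sample count.
#'
#' @param fit an `sgmt_fit` or a p x K coefficient matrix.
#' @param held_out a [multistudy_dataset()] of held-out samples.
#' @return Nonnegative number (equal to `2*log(2)` for the all-zero model).
#' @export
held_out_deviance <- function(fit, held_out) {
  B <- if (inherits(fit, "sgmt_fit")) fit$coefficients else fit
  if (inherits(fit, "sgmt_fit") && !is.null(fit$intercept)) {
    Xs <- lapply(held_out$X, function(m) cbind(m, 1))
    return(2 * cpp_nll(Xs, held_out$y, rbind(B, fit$intercept)) /
             sum(held_out$n))
  }
  2 * neg_log_likelihood(held_out, B) / sum(held_out$n)
}

#' Cross-validation grid
#'
#' @param alphas mixing parameters to scan (in [0, 1]).
#' @param n_lambda number of penalty levels per path.
#' @param lambda_min_ratio smallest lambda as a fraction of `lambda_max`.
#' @param n_folds folds per repeat.
#' @param n_repeats CV repetitions.
#' @param seed integer seed driving the fold draws.
#' @return An object of class `cv_grid`.
#' @export
cv_grid <- function(alphas = c(0, 0.25, 0.5, 0.75, 1), n_lambda = 30L,
                    lambda_min_ratio = 0.01, n_folds = 5L, n_repeats = 1L,
                    seed = 1L) {
  stopifnot(all(alphas >= 0 & alphas <= 1), n_lambda >= 1L,
            lambda_min_ratio > 0, lambda_min_ratio <= 1,
            n_folds >= 2L, n_repeats >= 1L)
  structure(list(alphas = alphas, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "cv_grid")
}

#' Tune (alpha, lambda) by repeated stratified cross-validation
#'
#' For every `alpha` in the grid, a decreasing lambda path (log-spaced from
#' `lambda_max` down to `lambda_min_ratio * lambda_max`) is fitted on each
#' training split with warm starts, and the held-out deviance recorded.
#' Reports the minimum-deviance selection and the one-standard-error
#' selection (the largest lambda, at the minimising alpha, whose mean
#' deviance is within one standard error of the minimum;
#' `SE = SD / sqrt(n_folds * n_repeats)`).
#'
#' @param data a [multistudy_dataset()].
#' @param groups a [group_structure()].
#' @param grid a [cv_grid()].
#' @param cfg_base optional [penalty_config()] template carrying solver
#'   controls and weights; its `lambda`/`alpha` are overwritten.
#' @return An object of class `sgmt_cv`: `mean_deviance` and `sd_deviance`
#'   (alpha x lambda matrices), `lambdas` (per alpha), `best_min` and
#'   `best_1se` (lists with `alpha`, `lambda`, indices), `fold_assignments`.
#' @export
cross_validate <- function(data, groups, grid, cfg_base = NULL) {
  stopifnot(inherits(grid, "cv_grid"))
  if (is.null(cfg_base)) cfg_base <- penalty_config(lambda = 1, alpha = 0)
  nA <- length(grid$alphas)
  nL <- grid$n_lambda
  lam_mat <- matrix(NA_real_, nA, nL)
  dev_arr <- array(NA_real_, c(nA, nL, grid$n_folds * grid$n_repeats))
  conv_arr <- array(TRUE, c(nA, nL, grid$n_folds * grid$n_repeats))
  folds_all <- vector("list", grid$n_repeats)

  for (a in seq_len(nA)) {
    alpha <- grid$alphas[a]
    lmax <- lambda_max(data, groups, alpha,
                       group_weights = cfg_base$group_weights,
                       row_weights = cfg_base$row_weights,
                       intercept = isTRUE(cfg_base$intercept))
    lam_mat[a, ] <- if (nL == 1L) lmax else
      exp(seq(log(lmax), log(lmax * grid$lambda_min_ratio), length.out = nL))
    slot <- 0L
    for (r in seq_len(grid$n_repeats)) {
      folds <- make_folds(data, grid$n_folds, seed = grid$seed + r - 1L)
      folds_all[[r]] <- folds
      for (f in seq_len(grid$n_folds)) {
        slot <- slot + 1L
        train_idx <- lapply(folds, function(fl) which(fl != f))
        test_idx <- lapply(folds, function(fl) which(fl == f))
        train <- subset_multistudy(data, train_idx)
        test <- subset_multistudy(data, test_idx)
        fits <- admm_path(train, groups, lam_mat[a, ], alpha, cfg_base)
        for (i in seq_len(nL)) {
          dev_arr[a, i, slot] <- held_out_deviance(fits[[i]], test)
          conv_arr[a, i, slot] <- fits[[i]]$converged
        }
      }
      slot <- (r) * grid$n_folds   # keep slot aligned across alphas
    }
  }

  mean_dev <- apply(dev_arr, c(1, 2), mean)
  sd_dev <- apply(dev_arr, c(1, 2), stats::sd)
  cell_ok <- apply(conv_arr, c(1, 2), all)
  mean_for_min <- mean_dev
  mean_for_min[!cell_ok] <- Inf   # non-convergent cells excluded from argmin
  if (all(!is.finite(mean_for_min)))
    stop("no cross-validation cell converged")
  best <- which(mean_for_min == min(mean_for_min), arr.ind = TRUE)[1L, ]
  a_min <- best[[1L]]; l_min <- best[[2L]]
  se_min <- sd_dev[a_min, l_min] / sqrt(grid$n_folds * grid$n_repeats)
  # largest lambda (smallest index; lambdas decreasing) at the same alpha
  ok <- which(mean_for_min[a_min, ] <= mean_for_min[a_min, l_min] + se_min)
  l_1se <- min(ok)
  structure(
    list(mean_deviance = mean_dev, sd_deviance = sd_dev,
         lambdas = lam_mat, alphas = grid$alphas, converged_cell = cell_ok,
         best_min = list(alpha = grid$alphas[a_min],
                         lambda = lam_mat[a_min, l_min],
                         alpha_index = a_min, lambda_index = l_min),
         best_1se = list(alpha = grid$alphas[a_min],
                         lambda = lam_mat[a_min, l_1se],
                         alpha_index = a_min, lambda_index = l_1se),
         se_min = se_min, grid = grid, fold_assignments = folds_all),
    class = "sgmt_cv")
}

#' @export
print.sgmt_cv <- function(x, ...) {
  cat("Cross-validation over", length(x$alphas), "alpha value(s) x",
      ncol(x$lambdas), "lambda value(s)\n")
  cat(sprintf("  min rule: alpha = %.3g, lambda = %.4g (mean deviance %.4f)\n",
              x$best_min$alpha, x$best_min$lambda,
              x$mean_deviance[x$best_min$alpha_index,
                              x$best_min$lambda_index]))
  cat(sprintf("  1se rule: alpha = %.3g, lambda = %.4g\n",
              x$best_1se$alpha, x$best_1se$lambda))
  invisible(x)
}
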