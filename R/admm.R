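#' Block soft-thresholding operator
#'
#' The shrink-or-kill map
#' \deqn{S_t(A) = 0 \text{ if } \|A\|_F \le t, \quad
#'   \frac{\|A\|_F - t}{\|A\|_F} A \text{ otherwise},}
#' the proximal operator of \eqn{t\,\|\cdot\|_F}. The output Frobenius norm
#' is exactly `max(norm(A) - t, 0)`; thresholded blocks are exact zeros.
#'
#' @param A numeric vector or matrix block.
#' @param t nonnegative threshold.
#' @return Same shape as `A`.
#' @export
block_soft_threshold <- function(A, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("threshold t must be a single nonnegative number")
  nrm <- sqrt(sum(A^2))
  if (nrm <= t) return(A * 0)
  if (t == 0) return(A)
  A * ((nrm - t) / nrm)
}

#' ADMM B-update: ridge-logistic fit towards an anchor
#'
#' Solves the strictly convex smooth sub-problem
#' \eqn{\mathrm{argmin}_B \; \ell(B) + (\rho/2)\|B - Z + U\|_F^2},
#' which separates into K independent l2-regularised logistic regressions.
#' Each is solved by damped Newton steps with backtracking line search; the
#' Hessian factorisation is refreshed lazily and held in Woodbury form when
#' n_k < p.
#'
#' @param data a [multistudy_dataset()].
#' @param Z,U p x K matrices (ADMM copy and scaled dual).
#' @param rho positive augmented-Lagrangian parameter.
#' @param B_init optional warm start.
#' @param tol gradient-norm tolerance of the sub-problem.
#' @param max_inner inner iteration cap; if hit, the best iterate is
#'   returned and a warning raised.
#' @return p x K matrix minimising the sub-objective.
#' @export
b_update <- function(data, Z, U, rho, B_init = NULL, tol = 1e-8,
                     max_inner = 1000L) {
  stopifnot(rho > 0)
  Z <- check_B(Z, data); U <- check_B(U, data)
  B <- if (is.null(B_init)) matrix(0, data$p, data$K) else check_B(B_init, data)
  hit <- FALSE
  for (k in seq_len(data$K)) {
    res <- cpp_logistic_prox(data$X[[k]], data$y[[k]], a = Z[, k] - U[, k],
                             rho = rho, b0 = B[, k], tol = tol,
                             maxit = max_inner)
    if (res$hit_cap) hit <- TRUE
    B[, k] <- res$b
  }
  if (hit) warning("inner solver hit its iteration cap; best iterate returned")
  B
}

#' ADMM Z-update: proximal operator of the composite penalty
#'
#' Applies the proximal operator of
#' \eqn{(\lambda_1/\rho)\|\cdot\|_{G_{2,1}} +
#'  (\lambda_2/\rho)\|\cdot\|_{l_{2,1}}} to `V = B + U` by sequential block
#' soft-thresholding: each variable row j is thresholded at
#' \eqn{\kappa_j \lambda_2 / \rho} first, then each group block at
#' \eqn{\gamma_g \lambda_1 / \rho}. Because the rows are nested inside the
#' groups, this composition is the exact proximal operator of the sum.
#'
#' @param B,U p x K matrices.
#' @param groups a [group_structure()].
#' @param cfg a [penalty_config()].
#' @return p x K matrix with exact zeros in thresholded rows/blocks.
#' @export
z_update <- function(B, U, groups, cfg) {
  B <- check_B(B, groups = groups); U <- check_B(U, groups = groups)
  w <- resolve_weights(cfg, groups)
  ls <- lambda_split(cfg)
  cpp_prox_sgl(B + U, groups$index - 1L,
               w$kappa * ls$lambda2 / cfg$rho,
               w$gamma * ls$lambda1 / cfg$rho)
}

#' Fit the penalised multi-study model by ADMM
#'
#' Minimises the penalised joint negative log-likelihood by scaled-form
#' ADMM: B-update (smooth ridge-logistic sub-problem), Z-update (sequential
#' sparse-group proximal operator), dual update `U <- U + B - Z`, iterated
#' until the primal residual `||B - Z||_F` and dual residual
#' `rho * ||Z_t - Z_{t-1}||_F` both fall below their tolerances (relative to
#' a `sqrt(p*K)` scaling and the iterate norms) or `max_iter` is reached.
#'
#' @param data a [multistudy_dataset()].
#' @param groups a [group_structure()].
#' @param cfg a [penalty_config()].
#' @param B_init optional p x K warm start (also used for Z and U when
#'   `Z_init`/`U_init` are not given).
#' @param Z_init,U_init optional warm starts for the ADMM copies.
#' @details With `cfg$intercept = TRUE` each study gains an unpenalised
#'   intercept: the design is augmented with a constant column whose row of
#'   `B` is never thresholded; the fitted intercepts are returned in the
#'   `intercept` field and the coefficient matrix stays p x K.
#' @return An object of class `sgmt_fit`: `coefficients` (the exactly sparse
#'   Z), `dense_B`, `selected_variables`, `selected_groups`,
#'   `objective_value` (objective at Z), `converged`, `iterations`,
#'   `primal_residual`, `dual_residual`, `trace`, plus the inputs' metadata.
#'   Selection is always read off Z, never the dense B.
#' @export
admm_fit <- function(data, groups, cfg, B_init = NULL, Z_init = NULL,
                     U_init = NULL) {
  stopifnot(inherits(data, "multistudy_dataset"),
            inherits(groups, "group_structure"),
            inherits(cfg, "penalty_config"))
  if (groups$p != data$p) stop("group structure does not match the data")
  for (k in seq_len(data$K)) {
    if (data$n[k] > 1L && length(data$constant_columns[[k]]))
      warning("constant column(s) in the design of study ", k)
  }
  w <- resolve_weights(cfg, groups)
  ls <- lambda_split(cfg)
  B0 <- if (is.null(B_init)) matrix(0, data$p, data$K) else check_B(B_init, data)
  Z0 <- if (is.null(Z_init)) B0 else check_B(Z_init, data)
  U0 <- if (is.null(U_init)) matrix(0, data$p, data$K) else check_B(U_init, data)

  use_int <- isTRUE(cfg$intercept)
  Xs <- data$X
  grp0 <- groups$index - 1L
  thr_row <- w$kappa * ls$lambda2
  thr_grp <- w$gamma * ls$lambda1
  if (use_int) {
    # augment each design with a constant column; its row of B sits in its
    # own group and both of its thresholds are zero (never shrunk)
    Xs <- lapply(Xs, function(m) cbind(m, 1))
    grp0 <- c(grp0, groups$G)
    thr_row <- c(thr_row, 0)
    thr_grp <- c(thr_grp, 0)
    pad <- function(m) rbind(m, 0)
    B0 <- pad(B0); Z0 <- pad(Z0); U0 <- pad(U0)
  }

  res <- cpp_admm(Xs, data$y, grp0,
                  thr_row_base = thr_row, thr_grp_base = thr_grp,
                  rho = cfg$rho, tol_primal = cfg$tol_primal,
                  tol_dual = cfg$tol_dual, max_iter = cfg$max_iter,
                  B = B0, Z = Z0, U = U0, adapt_rho = cfg$adapt_rho,
                  inner_tol_floor = 1e-6, inner_maxit = 500L)

  Z <- res$Z
  intercepts <- NULL
  if (use_int) {
    intercepts <- stats::setNames(Z[data$p + 1L, ], data$study_ids)
    Z <- Z[seq_len(data$p), , drop = FALSE]
    res$B <- res$B[seq_len(data$p), , drop = FALSE]
  }
  dimnames(Z) <- list(data$variable_ids, data$study_ids)
  sel_var <- which(rowSums(Z != 0) > 0)
  sel_grp <- sort(unique(groups$index[sel_var]))
  structure(
    list(coefficients = Z, dense_B = res$B, U = res$U,
         intercept = intercepts,
         selected_variables = sel_var, selected_groups = sel_grp,
         objective_value = if (use_int)
           cpp_nll(Xs, data$y, rbind(Z, intercepts)) +
             penalty_value(Z, groups, cfg)
         else objective(data, Z, groups, cfg),
         converged = isTRUE(res$converged),
         iterations = res$iterations,
         primal_residual = res$primal_residual,
         dual_residual = res$dual_residual,
         rho_final = res$rho,
         trace = data.frame(iteration = seq_along(res$trace_primal),
                            primal = res$trace_primal,
                            dual = res$trace_dual,
                            rho = res$trace_rho),
         cfg = cfg, variable_ids = data$variable_ids,
         group_ids = groups$group_ids, group_index = groups$index),
    class = "sgmt_fit")
}

#' @export
print.sgmt_fit <- function(x, ...) {
  cat("Sparse group multi-task fit (lambda = ", signif(x$cfg$lambda, 4),
      ", alpha = ", x$cfg$alpha, ")\n", sep = "")
  cat("  selected: ", length(x$selected_variables), " variables in ",
      length(x$selected_groups), " groups\n", sep = "")
  cat("  objective ", signif(x$objective_value, 6), "; ",
      if (x$converged) "converged" else "NOT converged", " in ",
      x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Smallest penalty level with an all-zero solution
#'
#' Computes the smallest `lambda` at which `B = 0` is optimal, from the
#' likelihood gradient at zero via the dual-norm (subgradient) condition of
#' the composite penalty. For `alpha = 1` this is
#' \eqn{\max_j \|g_{j\cdot}\|_2/\kappa_j}; for `alpha = 0`,
#' \eqn{\max_g \|g_{(\pi_g,\cdot)}\|_F/\gamma_g}; for intermediate `alpha`
#' the per-group zero condition
#' \eqn{\|S_{\lambda\alpha\kappa}(g_{(\pi_g,\cdot)})\|_F \le
#'  \lambda(1-\alpha)\gamma_g} is solved by bisection.
#'
#' @param data a [multistudy_dataset()].
#' @param groups a [group_structure()].
#' @param alpha mixing parameter in [0, 1].
#' @param group_weights,row_weights optional weights (defaults as in
#'   [penalty_config()]).
#' @param intercept logical; when TRUE the gradient is taken at the
#'   intercept-only MLE of each study instead of at zero.
#' @return A single nonnegative number.
#' @export
lambda_max <- function(data, groups, alpha, group_weights = NULL,
                       row_weights = NULL, intercept = FALSE) {
  stopifnot(alpha >= 0, alpha <= 1)
  cfg0 <- penalty_config(lambda = 0, alpha = alpha,
                         group_weights = group_weights,
                         row_weights = row_weights)
  w <- resolve_weights(cfg0, groups)
  g <- if (intercept) {
    # slope gradient at the intercept-only MLE: sigma(b0_k) = mean(y_k)
    vapply(seq_len(data$K), function(k)
      crossprod(data$X[[k]], mean(data$y[[k]]) - data$y[[k]])[, 1L],
      numeric(data$p))
  } else {
    likelihood_gradient(data, matrix(0, data$p, data$K))
  }
  g <- matrix(g, data$p, data$K)
  row_norm <- sqrt(rowSums(g^2))
  if (alpha >= 1) return(max(row_norm / w$kappa))
  grp_norm <- sqrt(as.numeric(rowsum(rowSums(g^2), groups$index)))
  if (alpha <= 0) return(max(grp_norm / w$gamma))
  # zero condition for group g at level lam:
  #   || row-shrink(g_g, lam*alpha*kappa) ||_F <= lam*(1-alpha)*gamma_g
  crit_group <- function(gset, gidx) {
    rn <- row_norm[gset]
    kap <- w$kappa[gset]
    f <- function(lam) {
      shr <- pmax(rn - lam * alpha * kap, 0)
      sqrt(sum(shr^2)) - lam * (1 - alpha) * w$gamma[gidx]
    }
    hi <- max(rn / (alpha * kap))      # rows all shrink to zero here
    if (f(hi) <= 0) {
      lo <- 0
      for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (f(mid) <= 0) hi <- mid else lo <- mid
        if (hi - lo < 1e-12 * max(1, hi)) break
      }
    }
    hi
  }
  max(vapply(seq_len(groups$G),
             function(g_) crit_group(groups$groups[[g_]], g_), numeric(1)))
}

# Fit a decreasing lambda path with warm starts. Returns list of sgmt_fit.
# lambdas must be sorted decreasing.
admm_path <- function(data, groups, lambdas, alpha, cfg_base = NULL) {
  if (is.null(cfg_base)) cfg_base <- penalty_config(lambda = 1, alpha = alpha)
  if (is.unsorted(rev(lambdas))) stop("lambdas must be sorted decreasing")
  fits <- vector("list", length(lambdas))
  B <- Z <- U <- NULL
  for (i in seq_along(lambdas)) {
    cfg <- cfg_base
    cfg$lambda <- lambdas[i]
    cfg$alpha <- alpha
    fits[[i]] <- admm_fit(data, groups, cfg, B_init = B, Z_init = Z,
                          U_init = U)
    B <- fits[[i]]$dense_B
    Z <- fits[[i]]$coefficients
    U <- fits[[i]]$U
  }
  fits
}

# KKT residual of the penalised objective at an (exactly sparse) Z.
# Returns the maximum violation across rows/groups; used by tests.
kkt_residual <- function(data, groups, cfg, Z) {
  w <- resolve_weights(cfg, groups)
  ls <- lambda_split(cfg)
  g <- likelihood_gradient(data, Z)
  viol <- 0
  for (gi in seq_len(groups$G)) {
    set <- groups$groups[[gi]]
    Gg <- g[set, , drop = FALSE]
    Zg <- Z[set, , drop = FALSE]
    t_g <- ls$lambda1 * w$gamma[gi]
    t_r <- ls$lambda2 * w$kappa[set]
    if (all(Zg == 0)) {
      # need -g_g in the subdifferential: || row-shrink(g_g, t_r) ||_F <= t_g
      shr <- pmax(sqrt(rowSums(Gg^2)) - t_r, 0)
      viol <- max(viol, sqrt(sum(shr^2)) - t_g)
    } else {
      ng <- sqrt(sum(Zg^2))
      for (j in seq_along(set)) {
        zj <- Zg[j, ]
        gj <- Gg[j, ]
        if (any(zj != 0)) {
          r <- gj + t_g * zj / ng + t_r[j] * zj / sqrt(sum(zj^2))
          viol <- max(viol, sqrt(sum(r^2)))
        } else {
          r <- gj + t_g * zj / ng   # zj = 0 contributes nothing from group term
          viol <- max(viol, max(sqrt(sum(r^2)) - t_r[j], 0))
        }
      }
    }
  }
  viol
}
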