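#' Joint negative log-likelihood over the K studies
#'
#' Evaluates the combined negative log-likelihood
#' \deqn{\ell(B) = -\sum_k \sum_i \left( y_{ik} x_{ik}^T \beta_{\cdot k}
#'   - \log(1 + e^{x_{ik}^T \beta_{\cdot k}}) \right)}
#' of the K independent logistic regressions at the coefficient matrix `B`.
#' The studies are independent, so the value is exactly additive over them.
#'
#' @param data a [multistudy_dataset()].
#' @param B numeric p x K coefficient matrix (variable j, study k).
#' @return A single nonnegative number.
#' @details `log(1 + exp(z))` is computed with the standard overflow-safe
#'   branch (`z + log1p(exp(-z))` for positive `z`).
#' @export
neg_log_likelihood <- function(data, B) {
  B <- check_B(B, data)
  cpp_nll(data$X, data$y, B)
}

#' Gradient of the joint negative log-likelihood
#'
#' Column k of the returned p x K matrix is
#' \eqn{X_k^T (\sigma(X_k \beta_{\cdot k}) - y_k)} with \eqn{\sigma} the
#' logistic function.
#'
#' @inheritParams neg_log_likelihood
#' @return p x K numeric matrix.
#' @export
likelihood_gradient <- function(data, B) {
  B <- check_B(B, data)
  cpp_nll_grad(data$X, data$y, B)
}

#' Composite sparse-group penalty
#'
#' Evaluates
#' \deqn{\lambda(1-\alpha) \sum_g \gamma_g \sqrt{\sum_{i \in \pi_g} \sum_k
#'   \beta_{ik}^2} + \lambda \alpha \sum_i \kappa_i \sqrt{\sum_k
#'   \beta_{ik}^2}.}
#' With default weights (\eqn{\gamma_g = \sqrt{n_g}}, \eqn{\kappa_i = 1})
#' this is \eqn{\lambda(1-\alpha)\|B\|_{G_{2,1}} + \lambda\alpha
#' \|B\|_{l_{2,1}}}. Positively homogeneous of degree one in `B`.
#'
#' @param B numeric p x K coefficient matrix.
#' @param groups a [group_structure()].
#' @param cfg a [penalty_config()].
#' @return A single nonnegative number.
#' @export
penalty_value <- function(B, groups, cfg) {
  B <- check_B(B, groups = groups)
  w <- resolve_weights(cfg, groups)
  ls <- lambda_split(cfg)
  row_ss <- rowSums(B^2)
  grp_ss <- as.numeric(rowsum(row_ss, groups$index))
  ls$lambda1 * sum(w$gamma * sqrt(grp_ss)) +
    ls$lambda2 * sum(w$kappa * sqrt(row_ss))
}

#' Penalised objective
#'
#' `neg_log_likelihood(data, B) + penalty_value(B, groups, cfg)`; convex
#' in `B`.
#'
#' @inheritParams penalty_value
#' @param data a [multistudy_dataset()].
#' @return A single number.
#' @export
objective <- function(data, B, groups, cfg) {
  neg_log_likelihood(data, B) + penalty_value(B, groups, cfg)
}

#' Adaptive penalty weights from ridge-logistic pilot fits
#'
#' Computes data-driven penalty weights in the spirit of the adaptive lasso:
#' \eqn{\gamma_g = 1/\sqrt{\sum_{i \in \pi_g} \sum_k \hat\beta_{ik}^2}} and
#' \eqn{\kappa_i = 1/\sqrt{\sum_k \hat\beta_{ik}^2}}, where \eqn{\hat\beta}
#' are per-study pilot estimates.  Because the model is logistic and p may
#' exceed n_k, the pilots are ridge-penalised logistic fits (ridge
#' `ridge * n_k`), which reduce toward the MLE when it exists and remain
#' finite under separation. Pilot norms of exactly zero are floored at
#' `floor` before inversion so every returned weight is finite and positive.
#'
#' @param data a [multistudy_dataset()].
#' @param groups a [group_structure()].
#' @param ridge small positive ridge multiplier (scaled by n_k); default 1e-3.
#' @param floor lower bound applied to pilot norms before inversion.
#' @return A list with `group_weights` (length G), `row_weights` (length p)
#'   and the pilot coefficient matrix `pilot`.
#' @export
adaptive_weights <- function(data, groups, ridge = 1e-3, floor = 1e-8) {
  stopifnot(ridge > 0, floor > 0)
  pilot <- matrix(0, data$p, data$K)
  for (k in seq_len(data$K)) {
    fit <- cpp_logistic_prox(data$X[[k]], data$y[[k]],
                             a = rep(0, data$p),
                             rho = ridge * data$n[[k]],
                             b0 = rep(0, data$p),
                             tol = 1e-8, maxit = 500L)
    pilot[, k] <- fit$b
  }
  row_norm <- pmax(sqrt(rowSums(pilot^2)), floor)
  grp_norm <- pmax(sqrt(as.numeric(rowsum(rowSums(pilot^2), groups$index))),
                   floor)
  list(group_weights = 1 / grp_norm, row_weights = 1 / row_norm,
       pilot = pilot)
}
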