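#' Assemble a multi-study case-control dataset
#'
#' Bundles the design matrices and binary phenotype vectors of K independent
#' case-control studies that share one variable panel (the same p variables,
#' in the same order, in every study).
#'
#' @param X list of K numeric matrices, each n_k x p (dosages or covariates).
#' @param y list of K binary (0/1) response vectors, lengths n_k.
#' @param variable_ids character vector of p variable identifiers; defaults to
#'   the column names of the first design, or `V1..Vp`.
#' @param study_ids character vector of K study identifiers.
#' @return An object of class `multistudy_dataset` with elements `X`, `y`,
#'   `variable_ids`, `study_ids`, `p`, `K`, `n`.
#' @details Each study must contain at least one case and one control;
#'   otherwise the per-study likelihood sub-problems degenerate and an error
#'   is raised rather than silently accepting the data.
#' @export
multistudy_dataset <- function(X, y, variable_ids = NULL, study_ids = NULL) {
  if (!is.list(X)) X <- list(X)
  if (!is.list(y)) y <- list(y)
  K <- length(X)
  if (K < 1L || length(y) != K)
    stop("need the same number of design matrices and response vectors (K >= 1)")
  X <- lapply(X, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  p <- ncol(X[[1L]])
  for (k in seq_len(K)) {
    if (ncol(X[[k]]) != p)
      stop("all studies must share the same variable panel: study ", k,
           " has ", ncol(X[[k]]), " columns, expected ", p)
    if (!all(is.finite(X[[k]])))
      stop("non-finite entries in the design matrix of study ", k)
    yk <- as.numeric(y[[k]])
    if (length(yk) != nrow(X[[k]]))
      stop("response length does not match the design rows in study ", k)
    if (!all(yk %in% c(0, 1)))
      stop("responses must be coded 0/1 (study ", k, ")")
    if (sum(yk == 1) == 0L || sum(yk == 0) == 0L)
      stop("study ", k, " has a single response class; the logistic MLE ",
           "sub-problems are degenerate")
    y[[k]] <- yk
  }
  if (is.null(variable_ids)) {
    variable_ids <- colnames(X[[1L]])
    if (is.null(variable_ids)) variable_ids <- paste0("V", seq_len(p))
  }
  if (length(variable_ids) != p) stop("variable_ids must have length p")
  if (is.null(study_ids)) study_ids <- paste0("study", seq_len(K))
  if (length(study_ids) != K) stop("study_ids must have length K")
  const_cols <- lapply(X, function(m) {
    v <- colMeans(m * m) - colMeans(m)^2   # per-column variance (biased)
    which(v <= 0)
  })
  structure(
    list(X = X, y = y, variable_ids = as.character(variable_ids),
         study_ids = as.character(study_ids), p = p, K = K,
         n = vapply(X, nrow, integer(1)), constant_columns = const_cols),
    class = "multistudy_dataset")
}

#' @export
print.multistudy_dataset <- function(x, ...) {
  cat("Multi-study case-control dataset\n")
  cat("  studies:  ", x$K, " (", paste(x$study_ids, collapse = ", "), ")\n",
      sep = "")
  cat("  variables:", x$p, "\n")
  cat("  samples:  ", paste(x$n, collapse = " + "), "=", sum(x$n), "\n")
  invisible(x)
}

#' Define the group structure over the variable panel
#'
#' Partitions the p variables into G disjoint groups (genes or pathways).
#' Overlapping groups are not supported by the method and raise an error.
#'
#' @param groups either a vector of length p giving a group label per
#'   variable, or a list of G integer index vectors over `1:p`.
#' @param p number of variables (required when `groups` is a list).
#' @param group_ids optional G group labels.
#' @return An object of class `group_structure` with elements `index`
#'   (integer group number per variable), `groups` (list of index sets),
#'   `sizes`, `group_ids`, `G`, `p`.
#' @export
group_structure <- function(groups, p = NULL, group_ids = NULL) {
  if (is.list(groups)) {
    if (is.null(p)) stop("p is required when groups are given as index sets")
    idx <- rep(NA_integer_, p)
    for (g in seq_along(groups)) {
      ig <- as.integer(groups[[g]])
      if (any(ig < 1L | ig > p)) stop("group index out of range in group ", g)
      if (any(!is.na(idx[ig])) || anyDuplicated(ig))
        stop("groups overlap: variable assigned to more than one group")
      idx[ig] <- g
    }
    if (anyNA(idx))
      stop("groups do not cover all variables: the groups must partition 1..p")
    if (is.null(group_ids)) group_ids <- paste0("G", seq_along(groups))
  } else {
    if (!is.null(p) && length(groups) != p)
      stop("group label vector must have length p")
    f <- factor(groups, levels = unique(groups))
    idx <- as.integer(f)
    if (is.null(group_ids)) group_ids <- as.character(levels(f))
    p <- length(idx)
  }
  G <- max(idx)
  sets <- split(seq_len(p), idx)
  names(sets) <- NULL
  sizes <- lengths(sets)
  if (any(sizes < 1L)) stop("empty group")
  if (length(group_ids) != G) stop("group_ids must have length G")
  structure(
    list(index = idx, groups = sets, sizes = as.integer(sizes),
         group_ids = as.character(group_ids), G = G, p = p),
    class = "group_structure")
}

#' @export
print.group_structure <- function(x, ...) {
  cat("Group structure: ", x$p, " variables in ", x$G, " groups (sizes ",
      paste(range(x$sizes), collapse = "-"), ")\n", sep = "")
  invisible(x)
}

#' Penalty and solver configuration
#'
#' Collects the composite penalty parameters and the ADMM solver controls.
#' The two penalty components are always derived from (`lambda`, `alpha`):
#' the group (G2,1) component has weight `lambda * (1 - alpha)` and the
#' variable-level (l2,1) component has weight `lambda * alpha`.
#'
#' @param lambda overall penalty level, >= 0.
#' @param alpha mixing parameter in [0, 1]; 0 gives the pure group penalty
#'   (GMT), 1 the pure variable-level penalty (SMT), intermediate values the
#'   sparse-group compromise (SGMT).
#' @param group_weights optional positive weights per group; default
#'   `sqrt(n_g)`. Replaced entirely in adaptive mode.
#' @param row_weights optional positive weights per variable; default 1.
#' @param adaptive logical flag recording whether the weights are adaptive
#'   (data-driven); informational, weights themselves are passed explicitly.
#' @param rho ADMM augmented-Lagrangian parameter, > 0.
#' @param tol_primal,tol_dual relative convergence tolerances (scaled by
#'   `sqrt(p*K)` and the iterate norms).
#' @param max_iter ADMM iteration cap.
#' @param adapt_rho logical; rescale rho by a factor 2 when one residual
#'   exceeds 10x the other (on by default; balances the residuals and cuts
#'   the iteration count when the problem scale is far from rho = 1).
#' @param intercept logical; add an unpenalised per-study intercept column
#'   (off by default: the joint model and the simulation benchmark carry no
#'   intercept).
#' @return An object of class `penalty_config`.
#' @export
penalty_config <- function(lambda, alpha,
                           group_weights = NULL, row_weights = NULL,
                           adaptive = FALSE, rho = 1,
                           tol_primal = 1e-4, tol_dual = 1e-4,
                           max_iter = 2000L, adapt_rho = TRUE,
                           intercept = FALSE) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0,
            is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            rho > 0, tol_primal > 0, tol_dual > 0, max_iter >= 1L)
  if (!is.null(group_weights) && any(group_weights <= 0))
    stop("group weights must be strictly positive")
  if (!is.null(row_weights) && any(row_weights <= 0))
    stop("row weights must be strictly positive")
  structure(
    list(lambda = lambda, alpha = alpha,
         group_weights = group_weights, row_weights = row_weights,
         adaptive = isTRUE(adaptive), rho = rho,
         tol_primal = tol_primal, tol_dual = tol_dual,
         max_iter = as.integer(max_iter), adapt_rho = isTRUE(adapt_rho),
         intercept = isTRUE(intercept)),
    class = "penalty_config")
}

# resolve weights against a group structure (defaults: gamma_g = sqrt(n_g),
# kappa_i = 1)
resolve_weights <- function(cfg, groups) {
  gw <- cfg$group_weights
  rw <- cfg$row_weights
  if (is.null(gw)) gw <- sqrt(groups$sizes)
  if (is.null(rw)) rw <- rep(1, groups$p)
  if (length(gw) != groups$G) stop("group_weights must have length G")
  if (length(rw) != groups$p) stop("row_weights must have length p")
  list(gamma = as.numeric(gw), kappa = as.numeric(rw))
}

# lambda1 = (1-alpha)*lambda weights the group norm; lambda2 = alpha*lambda
# the row norm. Derived, never stored.
lambda_split <- function(cfg) {
  list(lambda1 = (1 - cfg$alpha) * cfg$lambda,
       lambda2 = cfg$alpha * cfg$lambda)
}

check_B <- function(B, data = NULL, groups = NULL) {
  B <- as.matrix(B)
  if (!all(is.finite(B))) stop("coefficient matrix has non-finite entries")
  if (!is.null(data) && (nrow(B) != data$p || ncol(B) != data$K))
    stop("coefficient matrix must be p x K (", data$p, " x ", data$K, ")")
  if (!is.null(groups) && nrow(B) != groups$p)
    stop("coefficient matrix rows do not match the group structure")
  B
}

# restrict a multistudy_dataset to given row indices per study
subset_multistudy <- function(data, idx) {
  multistudy_dataset(
    X = lapply(seq_len(data$K), function(k) data$X[[k]][idx[[k]], , drop = FALSE]),
    y = lapply(seq_len(data$K), function(k) data$y[[k]][idx[[k]]]),
    variable_ids = data$variable_ids, study_ids = data$study_ids)
}
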