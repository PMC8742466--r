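# default resampler: within-study with replacement, preserving n_k and the
# case/control counts (stratified), so no resample collapses to one class
stratified_resample <- function(data) {
  lapply(seq_len(data$K), function(k) {
    y <- data$y[[k]]
    idx <- integer(length(y))
    for (cls in c(0, 1)) {
      pos <- which(y == cls)
      idx[pos] <- pos[sample.int(length(pos), length(pos), replace = TRUE)]
    }
    idx
  })
}

#' Bootstrap selection frequencies at fixed tuning parameters
#'
#' Refits the model on `M` bootstrap resamples (drawn with replacement
#' within each study, preserving each study's size and case/control counts)
#' at the tuning parameters chosen on the original data, and tabulates how
#' often each variable and each group is selected. Non-convergent resample
#' fits are excluded from both numerator and denominator (reported in
#' `n_effective`). Deterministic given `seed`.
#'
#' @param data a [multistudy_dataset()].
#' @param groups a [group_structure()].
#' @param cfg_fixed a [penalty_config()] carrying the (alpha, lambda) chosen
#'   on the full data.
#' @param M number of bootstrap resamples (>= 1).
#' @param seed integer seed.
#' @param resampler resampling function `function(data) -> list of index
#'   vectors`; the default is the stratified within-study resampler. Exposed
#'   so deterministic resamplers can be injected (e.g. in tests).
#' @param warm_start optional `sgmt_fit` on the full data used to warm-start
#'   the resample fits (and reported as `full_fit_selection`); computed if
#'   missing.
#' @return An object of class `sgmt_bootstrap`: `M`, `n_effective`,
#'   `variable_freq`, `group_freq`, `full_fit_selection` (list with
#'   `variables`, `groups`), `seed`.
#' @export
bootstrap_frequencies <- function(data, groups, cfg_fixed, M, seed,
                                  resampler = stratified_resample,
                                  warm_start = NULL) {
  stopifnot(M >= 1L)
  full_fit <- if (is.null(warm_start)) admm_fit(data, groups, cfg_fixed)
              else warm_start
  var_count <- numeric(data$p)
  grp_count <- numeric(groups$G)
  n_ok <- 0L
  with_local_seed(seed, {
    for (m in seq_len(M)) {
      idx <- resampler(data)
      boot <- subset_multistudy(data, idx)
      fit <- admm_fit(boot, groups, cfg_fixed,
                      B_init = full_fit$dense_B,
                      Z_init = full_fit$coefficients)
      if (!fit$converged) next
      n_ok <- n_ok + 1L
      var_count[fit$selected_variables] <- var_count[fit$selected_variables] + 1
      grp_count[fit$selected_groups] <- grp_count[fit$selected_groups] + 1
    }
  })
  if (n_ok == 0L) stop("no bootstrap fit converged")
  if (n_ok < M)
    warning(M - n_ok, " bootstrap fit(s) did not converge and were excluded")
  structure(
    list(M = M, n_effective = n_ok,
         variable_freq = stats::setNames(var_count / n_ok, data$variable_ids),
         group_freq = stats::setNames(grp_count / n_ok, groups$group_ids),
         full_fit_selection = list(variables = full_fit$selected_variables,
                                   groups = full_fit$selected_groups),
         full_fit = full_fit, seed = seed,
         variable_ids = data$variable_ids, group_ids = groups$group_ids,
         group_index = groups$index),
    class = "sgmt_bootstrap")
}

#' @export
print.sgmt_bootstrap <- function(x, ...) {
  cat("Bootstrap stability summary over", x$n_effective, "of", x$M,
      "resamples\n")
  cat("  full-data fit selected", length(x$full_fit_selection$variables),
      "variables in", length(x$full_fit_selection$groups), "groups\n")
  cat("  variables at frequency 1:", sum(x$variable_freq >= 1), "\n")
  invisible(x)
}

#' Strict bootstrap selection rule
#'
#' Returns exactly the variables and groups selected on every bootstrap
#' resample (frequency 1). A conservative rule suited to simulation
#' benchmarks; note the returned sets are not intersected with the
#' full-data selection.
#'
#' @param summary an `sgmt_bootstrap`.
#' @return List with integer vectors `variables` and `groups`.
#' @export
select_strict <- function(summary) {
  stopifnot(inherits(summary, "sgmt_bootstrap"))
  list(variables = which(summary$variable_freq >= 1),
       groups = which(summary$group_freq >= 1))
}

#' Application bootstrap selection rule
#'
#' Keeps the full-data-selected items whose bootstrap selection frequency is
#' strictly higher than that of every item NOT selected on the full data.
#' The threshold is computed separately for variables and for groups.
#'
#' @param summary an `sgmt_bootstrap`.
#' @return List with integer vectors `variables` and `groups` and the two
#'   thresholds `tau_variables`, `tau_groups`.
#' @export
select_application <- function(summary) {
  stopifnot(inherits(summary, "sgmt_bootstrap"))
  pick <- function(freq, selected) {
    if (length(selected) == 0L)
      return(list(keep = integer(0), tau = NA_real_))
    non_sel <- setdiff(seq_along(freq), selected)
    tau <- if (length(non_sel)) max(freq[non_sel]) else 0
    list(keep = selected[freq[selected] > tau], tau = tau)
  }
  v <- pick(summary$variable_freq, summary$full_fit_selection$variables)
  g <- pick(summary$group_freq, summary$full_fit_selection$groups)
  if (length(summary$full_fit_selection$variables) == 0L)
    warning("full-data fit selected nothing; returning empty selection")
  list(variables = unname(v$keep), groups = unname(g$keep),
       tau_variables = v$tau, tau_groups = g$tau)
}

#' Write the bootstrap frequency table
#'
#' TSV with one row per variable: `variable_id`, `group_id`, `frequency`,
#' `selected_full_fit`, `selected_strict`, `selected_application`.
#'
#' @param summary an `sgmt_bootstrap`.
#' @param path output file path.
#' @return The table, invisibly.
#' @export
write_frequency_table <- function(summary, path) {
  strict <- select_strict(summary)
  app <- select_application(summary)
  tab <- data.frame(
    variable_id = summary$variable_ids,
    group_id = summary$group_ids[summary$group_index],
    frequency = as.numeric(summary$variable_freq),
    selected_full_fit = seq_along(summary$variable_freq) %in%
      summary$full_fit_selection$variables,
    selected_strict = seq_along(summary$variable_freq) %in% strict$variables,
    selected_application = seq_along(summary$variable_freq) %in% app$variables)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
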