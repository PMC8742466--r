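#' Define a simulation scenario
#'
#' The benchmark design: K studies share a variable panel partitioned into
#' equally sized groups; a fixed fraction of groups is active and the first
#' `p_a` variables of each active group carry effects of magnitude
#' `effect_size` (all positive in study 1, alternating sign in study 2
#' across the ordered active variables). The four stock scenarios scale
#' `p_a`, the number of groups and the sample size together so that the
#' ratio p/n stays 0.8:
#'
#' | scenario | p_a | active/total groups | p   | n   |
#' |----------|-----|---------------------|-----|-----|
#' | 1        | 2   | 1/4                 | 80  | 100 |
#' | 2        | 4   | 2/8                 | 160 | 200 |
#' | 3        | 8   | 4/16                | 320 | 400 |
#' | 4        | 16  | 8/32                | 640 | 800 |
#'
#' @param scenario_id 1, 2, 3 or 4; or NULL when all fields are given.
#' @param K number of studies (observations split equally), default 2.
#' @param group_size variables per group, default 20.
#' @param p_a active variables per active group.
#' @param n_groups_active,n_groups_total group counts.
#' @param n_total total observations across studies.
#' @param effect_size magnitude of every active effect, default 0.8.
#' @param covariate_mode `"gaussian"` (i.i.d. standard normal, default) or
#'   `"genotype"` (standardised Binomial(2, `maf`) dosages).
#' @param maf minor allele frequency for genotype mode.
#' @return An object of class `sim_scenario`.
#' @export
simulation_scenario <- function(scenario_id = NULL, K = 2L, group_size = 20L,
                                p_a = NULL, n_groups_active = NULL,
                                n_groups_total = NULL, n_total = NULL,
                                effect_size = 0.8,
                                covariate_mode = c("gaussian", "genotype"),
                                maf = 0.3) {
  covariate_mode <- match.arg(covariate_mode)
  if (!is.null(scenario_id)) {
    stopifnot(scenario_id %in% 1:4)
    s <- as.integer(scenario_id)
    if (is.null(p_a)) p_a <- c(2L, 4L, 8L, 16L)[s]
    if (is.null(n_groups_active)) n_groups_active <- c(1L, 2L, 4L, 8L)[s]
    if (is.null(n_groups_total)) n_groups_total <- c(4L, 8L, 16L, 32L)[s]
    if (is.null(n_total)) n_total <- c(100L, 200L, 400L, 800L)[s]
  }
  stopifnot(!is.null(p_a), !is.null(n_groups_active), !is.null(n_groups_total),
            !is.null(n_total), p_a >= 1L, p_a <= group_size,
            n_groups_active >= 1L, n_groups_active <= n_groups_total,
            K >= 1L, n_total >= K, effect_size > 0)
  structure(
    list(scenario_id = scenario_id, K = as.integer(K),
         group_size = as.integer(group_size), p_a = as.integer(p_a),
         n_groups_active = as.integer(n_groups_active),
         n_groups_total = as.integer(n_groups_total),
         p = as.integer(group_size * n_groups_total),
         n_total = as.integer(n_total), effect_size = effect_size,
         covariate_mode = covariate_mode, maf = maf),
    class = "sim_scenario")
}

# the true p x K coefficient matrix of a scenario: study 1 all positive,
# study 2 alternating (+,-,+,...) over the ordered active variables; any
# further studies copy study 1
true_coefficients <- function(scn) {
  B <- matrix(0, scn$p, scn$K)
  active <- unlist(lapply(seq_len(scn$n_groups_active), function(g)
    (g - 1L) * scn$group_size + seq_len(scn$p_a)))
  B[active, ] <- scn$effect_size
  if (scn$K >= 2L) {
    signs <- rep_len(c(1, -1), length(active))
    B[active, 2L] <- scn$effect_size * signs
  }
  B
}

#' Simulate one multi-study dataset from a scenario
#'
#' Designs are drawn i.i.d. per `covariate_mode`; responses are Bernoulli
#' with success probability `sigmoid(x' beta_k)` (no intercept). The first
#' `p_a` variables of each of the first `n_groups_active` groups are active.
#'
#' @param scn a [simulation_scenario()].
#' @param seed integer seed; same seed, same dataset.
#' @return List with `data` (a [multistudy_dataset()]), `groups`
#'   (a [group_structure()]) and `true_B` (p x K matrix).
#' @export
simulate_dataset <- function(scn, seed) {
  stopifnot(inherits(scn, "sim_scenario"))
  true_B <- true_coefficients(scn)
  n_k <- rep(scn$n_total %/% scn$K, scn$K)
  n_k[seq_len(scn$n_total %% scn$K)] <- n_k[seq_len(scn$n_total %% scn$K)] + 1L
  with_local_seed(seed, {
    draws <- lapply(seq_len(scn$K), function(k) {
      repeat {
        X <- if (scn$covariate_mode == "gaussian") {
          matrix(stats::rnorm(n_k[k] * scn$p), n_k[k], scn$p)
        } else {
          g <- matrix(stats::rbinom(n_k[k] * scn$p, 2L, scn$maf), n_k[k],
                      scn$p)
          (g - 2 * scn$maf) / sqrt(2 * scn$maf * (1 - scn$maf))
        }
        pr <- 1 / (1 + exp(-(X %*% true_B[, k])))
        y <- stats::rbinom(n_k[k], 1L, pr)
        if (any(y == 0) && any(y == 1)) return(list(X = X, y = y))
      }
    })
    data <- multistudy_dataset(
      X = lapply(draws, `[[`, "X"), y = lapply(draws, `[[`, "y"),
      variable_ids = sprintf("snp%04d", seq_len(scn$p)))
    groups <- group_structure(rep(sprintf("gene%02d",
                                          seq_len(scn$n_groups_total)),
                                  each = scn$group_size))
    list(data = data, groups = groups, true_B = true_B)
  })
}

#' Selection and reconstruction metrics against the truth
#'
#' At variable level a variable is positive iff its true coefficient row is
#' nonzero and called positive iff selected; at group level a group is
#' positive iff it contains at least one true-active variable and called
#' positive iff selected. Reports TPR, TNR, the Matthews correlation
#' coefficient (0 by convention when its denominator vanishes, flagged via
#' `mcc_defined`), and — when an estimate matrix is supplied — the l1 error
#' \eqn{\sum_{i,k} |\beta_{ik} - \hat\beta_{ik}|} and l2 error
#' \eqn{\sqrt{\sum_{i,k} (\beta_{ik} - \hat\beta_{ik})^2}}.
#'
#' @param estimate a p x K coefficient matrix, an `sgmt_fit`, or a list with
#'   `variables`/`groups` integer selection sets.
#' @param true_B the true p x K coefficient matrix.
#' @param groups a [group_structure()].
#' @param level `"variable"` or `"group"`.
#' @return A one-row data.frame: `level`, `tp`, `fp`, `tn`, `fn`, `tpr`,
#'   `tnr`, `mcc`, `mcc_defined`, `l1_error`, `l2_error` (errors NA for
#'   selection-set input).
#' @export
compute_metrics <- function(estimate, true_B, groups,
                            level = c("variable", "group")) {
  level <- match.arg(level)
  p <- nrow(true_B)
  l1 <- l2 <- NA_real_
  if (inherits(estimate, "sgmt_fit")) {
    sel_var <- estimate$selected_variables
    sel_grp <- estimate$selected_groups
    l1 <- sum(abs(true_B - estimate$coefficients))
    l2 <- sqrt(sum((true_B - estimate$coefficients)^2))
  } else if (is.matrix(estimate)) {
    sel_var <- which(rowSums(estimate != 0) > 0)
    sel_grp <- sort(unique(groups$index[sel_var]))
    l1 <- sum(abs(true_B - estimate))
    l2 <- sqrt(sum((true_B - estimate)^2))
  } else {
    sel_var <- estimate$variables
    sel_grp <- estimate$groups
  }
  true_var <- which(rowSums(true_B != 0) > 0)
  if (level == "variable") {
    pos <- seq_len(p) %in% true_var
    called <- seq_len(p) %in% sel_var
  } else {
    true_grp <- sort(unique(groups$index[true_var]))
    pos <- seq_len(groups$G) %in% true_grp
    called <- seq_len(groups$G) %in% sel_grp
  }
  tp <- sum(pos & called); fp <- sum(!pos & called)
  tn <- sum(!pos & !called); fn <- sum(pos & !called)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc_defined <- denom > 0
  mcc <- if (mcc_defined) (tp * tn - fp * fn) / denom else 0
  data.frame(level = level, tp = tp, fp = fp, tn = tn, fn = fn,
             tpr = tpr, tnr = tnr, mcc = mcc, mcc_defined = mcc_defined,
             l1_error = l1, l2_error = l2)
}

# fit one method on one simulated dataset under one protocol; returns a list
# with selection sets (bootstrap-based for "selection") and coefficient matrix
fit_method_once <- function(sim, method, protocol, n_bootstrap, seed,
                            alphas_sgmt = c(0, 0.25, 0.5, 0.75, 1),
                            n_lambda = 30L, n_folds = NULL,
                            cfg_base = NULL, sgst_combine = "intersection") {
  if (is.null(n_folds)) n_folds <- if (protocol == "reconstruction") 10L else 5L
  if (is.null(cfg_base)) cfg_base <- penalty_config(lambda = 1, alpha = 0)
  single_task <- identical(method, "SGST")
  alphas <- switch(method, SMT = 1, GMT = 0, SGST = 0, SGMT = alphas_sgmt)

  run_one <- function(data, groups) {
    grid <- cv_grid(alphas = alphas, n_lambda = n_lambda, n_folds = n_folds,
                    seed = seed)
    cv <- cross_validate(data, groups, grid, cfg_base)
    cfg <- cfg_base
    cfg$alpha <- cv$best_1se$alpha
    cfg$lambda <- cv$best_1se$lambda
    fit <- admm_fit(data, groups, cfg)
    out <- list(fit = fit, cfg = cfg,
                selection = list(variables = fit$selected_variables,
                                 groups = fit$selected_groups))
    if (protocol == "selection") {
      bs <- bootstrap_frequencies(data, groups, cfg, M = n_bootstrap,
                                  seed = seed + 7L, warm_start = fit)
      out$selection <- select_strict(bs)
    }
    out
  }

  if (!single_task) {
    res <- run_one(sim$data, sim$groups)
    list(selection = res$selection, B_hat = res$fit$coefficients,
         cfg = res$cfg)
  } else {
    # per-study group-lasso fits; a variable or group counts as a
    # pleiotropic call when detected in every study ("intersection", the
    # convention under which a single-task method genuinely claims a shared
    # signal) or in any study ("union", more favourable to the baseline)
    combine <- match.arg(sgst_combine, c("intersection", "union"))
    sel_var <- sel_grp <- NULL
    B_hat <- matrix(0, sim$data$p, sim$data$K)
    for (k in seq_len(sim$data$K)) {
      dk <- multistudy_dataset(X = sim$data$X[k], y = sim$data$y[k],
                               variable_ids = sim$data$variable_ids,
                               study_ids = sim$data$study_ids[k])
      res <- run_one(dk, sim$groups)
      merge <- if (combine == "union") union else intersect
      sel_var <- if (is.null(sel_var)) res$selection$variables
                 else merge(sel_var, res$selection$variables)
      sel_grp <- if (is.null(sel_grp)) res$selection$groups
                 else merge(sel_grp, res$selection$groups)
      B_hat[, k] <- res$fit$coefficients[, 1L]
    }
    list(selection = list(variables = sort(sel_var), groups = sort(sel_grp)),
         B_hat = B_hat, cfg = NULL)
  }
}

#' Run the simulation benchmark for one scenario
#'
#' Per replicate: simulate a dataset, tune each method by cross-validation
#' with the one-standard-error rule, and score it. Under the `"selection"`
#' protocol (selection benchmark) tuning uses 5-fold CV and the selection
#' sets come from the strict bootstrap rule over `n_bootstrap` resamples;
#' under `"reconstruction"` (reconstruction benchmark) tuning uses 10-fold CV and
#' the fitted coefficients are scored directly. Methods: `"SMT"` (alpha=1), `"GMT"` (alpha=0), `"SGMT"` (alpha
#' tuned over a grid), `"SGST"` (per-study single-task group lasso,
#' selections combined across studies per `sgst_combine`).
#'
#' @param scn a [simulation_scenario()].
#' @param methods character vector from `c("SMT","GMT","SGMT","SGST")`.
#' @param protocol `"selection"` or `"reconstruction"`.
#' @param n_replicates number of simulated datasets.
#' @param n_bootstrap bootstrap resamples per replicate (selection only).
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param alphas_sgmt alpha grid for SGMT tuning.
#' @param n_lambda lambda path length.
#' @param n_folds CV folds (defaults: 5 for selection, 10 for reconstruction).
#' @param cfg_base optional [penalty_config()] template (solver controls).
#' @param sgst_combine how SGST's per-study selections merge into one
#'   pleiotropy call: `"intersection"` (default: detected in every study) or
#'   `"union"` (detected in any study).
#' @return An object of class `sim_result`: `results` (one row per
#'   replicate x method x level) and `summary` (mean and SD per metric).
#' @export
run_scenario <- function(scn, methods = c("SMT", "GMT", "SGMT", "SGST"),
                         protocol = c("selection", "reconstruction"),
                         n_replicates = 10L, n_bootstrap = 100L, seed = 1L,
                         alphas_sgmt = c(0, 0.25, 0.5, 0.75, 1),
                         n_lambda = 30L, n_folds = NULL, cfg_base = NULL,
                         sgst_combine = "intersection") {
  protocol <- match.arg(protocol)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    sim <- simulate_dataset(scn, seed = seed + r)
    for (m in methods) {
      res <- tryCatch(
        fit_method_once(sim, m, protocol, n_bootstrap, seed = seed + r,
                        alphas_sgmt = alphas_sgmt, n_lambda = n_lambda,
                        n_folds = n_folds, cfg_base = cfg_base,
                        sgst_combine = sgst_combine),
        error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1L
        warning("replicate ", r, " method ", m, " failed: ",
                conditionMessage(res))
        next
      }
      for (lev in c("variable", "group")) {
        met <- if (protocol == "selection")
          compute_metrics(res$selection, sim$true_B, sim$groups, lev)
        else
          compute_metrics(res$B_hat, sim$true_B, sim$groups, lev)
        if (protocol == "reconstruction") {
          # reconstruction errors come from the coefficients in either case
          met$l1_error <- sum(abs(sim$true_B - res$B_hat))
          met$l2_error <- sqrt(sum((sim$true_B - res$B_hat)^2))
        }
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(replicate = r, method = m), met)
      }
    }
  }
  results <- do.call(rbind, rows)
  metric_cols <- c("tpr", "tnr", "mcc", "l1_error", "l2_error")
  summ <- do.call(rbind, lapply(split(
    results, list(results$method, results$level), drop = TRUE),
    function(d) {
      out <- data.frame(method = d$method[1L], level = d$level[1L],
                        n_replicates = nrow(d))
      for (mc in metric_cols) {
        out[[paste0(mc, "_mean")]] <- mean(d[[mc]], na.rm = TRUE)
        out[[paste0(mc, "_sd")]] <- stats::sd(d[[mc]], na.rm = TRUE)
      }
      out
    }))
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ, scenario = scn,
                 protocol = protocol, seed = seed, n_failed = n_failed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulation benchmark (", x$protocol, " protocol, ",
      max(x$results$replicate), " replicates)\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write simulation results as tidy TSVs
#'
#' @param res a `sim_result`.
#' @param out_dir output directory (created if missing).
#' @return Paths of the two files, invisibly.
#' @export
write_sim_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(out_dir, "replicates.tsv")
  p2 <- file.path(out_dir, "summary.tsv")
  utils::write.table(res$results, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$summary, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
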