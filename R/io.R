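# columns tolerated (and stripped) from PLINK .raw style dosage exports
PLINK_META_COLS <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")

read_tsv_file <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a multi-study dataset and group map from TSV files
#'
#' Each genotype file holds one sample per row with a header of variable
#' IDs (PLINK `.raw`-style leading columns FID/IID/PAT/MAT/SEX/PHENOTYPE are
#' tolerated and stripped); each phenotype file is a two-column TSV
#' (`sample_id`, `label` in 0/1); the group map is a three-column TSV
#' (`variable_id`, `gene_id`, `pathway_id`). Variables are aligned across
#' studies and the group map by ID: the intersection is taken, the column
#' order of the first study kept, and dropped IDs reported in a warning.
#' A variable mapped to more than one group is a hard error — the method
#' requires non-overlapping groups.
#'
#' @param genotype_paths character vector of K genotype TSV paths.
#' @param phenotype_paths character vector of K phenotype TSV paths.
#' @param group_map_path path of the group-map TSV.
#' @param grouping `"gene"` or `"pathway"`: which column defines the groups.
#' @param study_ids optional K study labels (default: file base names).
#' @return List with `data` (a [multistudy_dataset()]) and `groups`
#'   (a [group_structure()]).
#' @export
read_multistudy <- function(genotype_paths, phenotype_paths, group_map_path,
                            grouping = c("gene", "pathway"),
                            study_ids = NULL) {
  grouping <- match.arg(grouping)
  K <- length(genotype_paths)
  stopifnot(K >= 1L, length(phenotype_paths) == K)
  for (f in c(genotype_paths, phenotype_paths, group_map_path))
    if (!file.exists(f)) stop("file not found: ", f)

  geno <- lapply(genotype_paths, function(p) {
    d <- read_tsv_file(p)
    d[, setdiff(names(d), PLINK_META_COLS), drop = FALSE]
  })
  pheno <- lapply(phenotype_paths, function(p) {
    d <- read_tsv_file(p)
    if (ncol(d) < 2L) stop("phenotype file needs columns sample_id, label: ", p)
    if (!all(d[[2L]] %in% c(0, 1)))
      stop("non-binary phenotype in ", p)
    d
  })
  gmap <- read_tsv_file(group_map_path)
  if (ncol(gmap) < 3L)
    stop("group map needs columns variable_id, gene_id, pathway_id")
  names(gmap)[1:3] <- c("variable_id", "gene_id", "pathway_id")
  if (anyDuplicated(gmap$variable_id))
    stop("variable assigned to more than one group in the group map; ",
         "the method requires non-overlapping groups")

  ids <- colnames(geno[[1L]])
  for (k in seq_len(K)) ids <- ids[ids %in% colnames(geno[[k]])]
  ids <- ids[ids %in% gmap$variable_id]
  dropped <- setdiff(unique(c(unlist(lapply(geno, colnames)),
                              gmap$variable_id)), ids)
  if (length(dropped))
    warning("dropped ", length(dropped), " variable(s) absent from some ",
            "input: ", paste(utils::head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "")
  if (length(ids) == 0L) stop("no variable shared by all inputs")

  X <- lapply(geno, function(d) as.matrix(d[, ids, drop = FALSE]))
  y <- lapply(pheno, function(d) as.numeric(d[[2L]]))
  if (is.null(study_ids))
    study_ids <- tools::file_path_sans_ext(basename(genotype_paths))
  data <- multistudy_dataset(X, y, variable_ids = ids, study_ids = study_ids)
  gm <- gmap[match(ids, gmap$variable_id), ]
  gcol <- if (grouping == "gene") gm$gene_id else gm$pathway_id
  list(data = data, groups = group_structure(gcol))
}

#' Write a dataset back to TSV files (round-trips with [read_multistudy()])
#'
#' @param data a [multistudy_dataset()].
#' @param groups a [group_structure()] (written as the gene column; the
#'   pathway column is a single catch-all unless `pathway_ids` is given).
#' @param out_dir output directory, created if missing.
#' @param pathway_ids optional per-variable pathway labels.
#' @return Named list of written paths, invisibly.
#' @export
write_multistudy <- function(data, groups, out_dir, pathway_ids = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gpaths <- file.path(out_dir, paste0(data$study_ids, "_genotypes.tsv"))
  ppaths <- file.path(out_dir, paste0(data$study_ids, "_phenotypes.tsv"))
  for (k in seq_len(data$K)) {
    gm <- as.data.frame(data$X[[k]])
    names(gm) <- data$variable_ids
    utils::write.table(gm, gpaths[k], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = sprintf("%s_s%04d", data$study_ids[k],
                                     seq_len(data$n[k])),
                 label = data$y[[k]]),
      ppaths[k], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (is.null(pathway_ids)) pathway_ids <- rep("all", data$p)
  mpath <- file.path(out_dir, "group_map.tsv")
  utils::write.table(
    data.frame(variable_id = data$variable_ids,
               gene_id = groups$group_ids[groups$index],
               pathway_id = pathway_ids),
    mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(genotypes = gpaths, phenotypes = ppaths, group_map = mpath))
}

#' Write a fit to disk
#'
#' Writes `coefficients.tsv` (variable_id, group_id, study_id, beta),
#' `selection.tsv` (variable_id, group_id, selection flags) and
#' `run_metadata.json` (penalty settings, seed, convergence summary,
#' package version). Byte-stable given identical inputs.
#'
#' @param result an `sgmt_fit`.
#' @param out_dir output directory, created if missing.
#' @param seed optional seed to record in the metadata.
#' @return Named list of written paths, invisibly.
#' @export
write_fit <- function(result, out_dir, seed = NA_integer_) {
  stopifnot(inherits(result, "sgmt_fit"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  Z <- result$coefficients
  p <- nrow(Z); K <- ncol(Z)
  coef_tab <- data.frame(
    variable_id = rep(result$variable_ids, K),
    group_id = rep(result$group_ids[result$group_index], K),
    study_id = rep(colnames(Z), each = p),
    beta = as.numeric(Z))
  sel_tab <- data.frame(
    variable_id = result$variable_ids,
    group_id = result$group_ids[result$group_index],
    selected = seq_len(p) %in% result$selected_variables)
  meta <- list(
    package = "pleiosgl",
    version = as.character(utils::packageVersion("pleiosgl")),
    seed = seed,
    lambda = result$cfg$lambda, alpha = result$cfg$alpha,
    rho = result$cfg$rho, adaptive = result$cfg$adaptive,
    tol_primal = result$cfg$tol_primal, tol_dual = result$cfg$tol_dual,
    max_iter = result$cfg$max_iter,
    converged = result$converged, iterations = result$iterations,
    primal_residual = result$primal_residual,
    dual_residual = result$dual_residual,
    objective_value = result$objective_value,
    n_selected_variables = length(result$selected_variables),
    n_selected_groups = length(result$selected_groups))
  cpath <- file.path(out_dir, "coefficients.tsv")
  spath <- file.path(out_dir, "selection.tsv")
  jpath <- file.path(out_dir, "run_metadata.json")
  utils::write.table(coef_tab, cpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sel_tab, spath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(meta, jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(coefficients = cpath, selection = spath, metadata = jpath))
}
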