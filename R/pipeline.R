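## The per-gene and per-dataset analysis workflow: log-transform, species
## means and standard errors, tip excision for missing species, relative fit
## (AIC over BM/OU/EB), and absolute fit (adequacy of the best model only).

#' Log-transform normalized expression values
#'
#' `log(value + offset)`, natural log. Expression is modelled on the log
#' scale; the pseudo-count keeps zeros finite.
#'
#' @param values Numeric values, linear scale, >= 0 (NAs pass through).
#' @param offset Pseudo-count added before the log (default 1).
#' @return Log-scale values.
#' @export
log_transform <- function(values, offset = 1) {
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  if (any(values + offset <= 0, na.rm = TRUE))
    stop("offset too small: log of a non-positive value")
  log(values + offset)
}

#' Construct a replicate-level expression matrix
#'
#' @param values Numeric matrix, genes x samples, linear scale (>= 0;
#'   `NA` marks a missing measurement). Needs row and column names.
#' @param samples Data frame with columns `sample` (matching the matrix
#'   columns), `species`, and optionally `replicate` and `tissue`.
#' @return An `"expression_matrix"` list with `values` and `samples`.
#' @export
expression_matrix <- function(values, samples) {
  values <- as.matrix(values)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      is.null(colnames(values)))
    stop("values needs gene rownames and sample colnames")
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  samples <- as.data.frame(samples)
  need <- c("sample", "species")
  if (!all(need %in% names(samples)))
    stop("samples needs columns: ", paste(need, collapse = ", "))
  if (!"tissue" %in% names(samples)) samples$tissue <- "all"
  miss <- setdiff(colnames(values), samples$sample)
  if (length(miss)) stop("samples sheet missing: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample)) stop("duplicate sample ids")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' Read an expression matrix and its sample sidecar from delimited text
#'
#' The matrix file holds gene ids in the first column and one column per
#' sample; the sidecar maps `sample` to `species` (and optionally
#' `replicate`, `tissue`). Tab- or comma-delimited, autodetected from the
#' file extension (`.csv` = comma).
#'
#' @param matrix_file Path to the expression matrix.
#' @param sidecar_file Path to the sample-metadata table.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(matrix_file, sidecar_file) {
  sep_of <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  m <- utils::read.delim(matrix_file, sep = sep_of(matrix_file),
                         check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(m[, -1L, drop = FALSE])
  rownames(vals) <- as.character(m[[1L]])
  sc <- utils::read.delim(sidecar_file, sep = sep_of(sidecar_file),
                          stringsAsFactors = FALSE)
  expression_matrix(vals, sc)
}

#' Per-species trait summary for one gene
#'
#' Log-transforms the gene's replicate measurements and summarises them per
#' species: the mean, and the standard error of the mean (`sd / sqrt(m)`)
#' for species with `m >= 2` replicates. Species with a single replicate
#' get `se = 0` and are flagged; species with no data are omitted.
#'
#' @param em An [expression_matrix()].
#' @param gene Gene id (rowname).
#' @param tissue Tissue to restrict to (default: all samples).
#' @param offset Pseudo-count for [log_transform()].
#' @return A [trait_vector()] with attribute `"singletons"` naming species
#'   summarised from a single replicate.
#' @export
species_summary <- function(em, gene, tissue = NULL, offset = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!gene %in% rownames(em$values)) stop("gene not found: ", gene)
  sel <- if (is.null(tissue)) rep(TRUE, nrow(em$samples))
         else em$samples$tissue == tissue
  if (!any(sel)) stop("no samples for tissue ", tissue)
  v <- log_transform(em$values[gene, sel], offset)
  sp <- em$samples$species[sel]
  ok <- !is.na(v)
  v <- v[ok]; sp <- sp[ok]
  if (length(v) == 0L) stop("no data for gene ", gene)
  means <- tapply(v, sp, mean)
  m <- tapply(v, sp, length)
  sds <- tapply(v, sp, stats::sd)        # NA for singletons
  se <- ifelse(m >= 2L, sds / sqrt(m), 0)
  tv <- trait_vector(as.numeric(means), se = as.numeric(se),
                     species = names(means))
  attr(tv, "singletons") <- names(means)[m == 1L]
  tv
}

#' Analysis configuration
#'
#' @param models Candidate models to fit.
#' @param min_taxa Minimum species with data per gene (default 4); genes
#'   below are reported as skipped.
#' @param n_sim Adequacy bootstrap replicates.
#' @param cutoff Adequacy rejection cutoff.
#' @param offset Log-transform pseudo-count.
#' @param seed Master seed; per-gene seeds are derived by a stable hash.
#' @return An `"adequacy_config"` list.
#' @export
adequacy_config <- function(models = c("BM", "OU", "EB"), min_taxa = 4,
                            n_sim = 1000, cutoff = 0.05, offset = 1,
                            seed = 1) {
  stopifnot(min_taxa >= 4, n_sim >= 2, cutoff > 0, cutoff < 1)
  structure(list(models = models, min_taxa = min_taxa, n_sim = n_sim,
                 cutoff = cutoff, offset = offset, seed = seed),
            class = "adequacy_config")
}

## Deterministic per-gene seed below 2^31: a 32-bit-style mixing hash of the
## master seed and the gene/tissue key.
derive_seed <- function(master, key) {
  M <- 2147483647
  h <- as.numeric(master) %% M
  for (ch in utf8ToInt(paste0(key))) h <- (h * 31 + ch) %% M
  as.integer((h * 48271) %% M)
}

#' Fit, select, and adequacy-test one gene
#'
#' Prunes the tree to the species with data (tip excision), fits the
#' candidate models, selects the best by AIC, and assesses the adequacy of
#' the best fit only.
#'
#' @param tree Species tree (`"phylo"`).
#' @param trait A [trait_vector()] holding the species with data.
#' @param config An [adequacy_config()].
#' @param gene Gene id used in the report.
#' @param tissue Tissue label used in the report.
#' @param seed Seed for the adequacy bootstrap (default: derived from
#'   `config$seed` and `gene`/`tissue`).
#' @return A `"gene_report"`: `gene`, `tissue`, `n_species_used`, `status`
#'   (`"ok"`, `"skipped_few_taxa"` or `"fit_failed"`), `fits`,
#'   `best_model`, `adequacy`.
#' @export
run_gene <- function(tree, trait, config = adequacy_config(), gene = "gene",
                     tissue = "all", seed = NULL) {
  tree <- validate_tree(tree)
  trait <- as_trait_vector(trait)
  keep <- intersect(tree$tip.label, trait$species)
  rep0 <- function(status, fits = NULL, best = NULL, adequacy = NULL)
    structure(list(gene = gene, tissue = tissue,
                   n_species_used = length(keep), status = status,
                   fits = fits, best_model = best, adequacy = adequacy),
              class = "gene_report")
  if (length(keep) < config$min_taxa) return(rep0("skipped_few_taxa"))
  tg <- prune_tips(tree, keep)
  idx <- match(keep, trait$species)
  tg_trait <- trait_vector(trait$values[idx], se = trait$se[idx],
                           species = keep)
  fits <- fit_all_models(tg, tg_trait, config$models)
  best <- tryCatch(suppressWarnings(select_best(fits)),
                   error = function(e) NULL)
  if (is.null(best)) return(rep0("fit_failed", fits = fits))
  if (is.null(seed)) seed <- derive_seed(config$seed, paste0(gene, ":", tissue))
  adq <- tryCatch(
    assess_adequacy(tg, tg_trait, best, n_sim = config$n_sim, seed = seed,
                    cutoff = config$cutoff),
    error = function(e) NULL)
  if (is.null(adq)) return(rep0("fit_failed", fits = fits, best = best$model))
  rep0("ok", fits = fits, best = best$model, adequacy = adq)
}

#' Run the full workflow over an expression dataset
#'
#' Analyses every gene x tissue combination independently: species summary,
#' tip excision, model fitting, AIC selection, and adequacy of the best
#' model. Fully deterministic given the master seed (per-gene seeds come
#' from a stable hash of the gene/tissue key).
#'
#' @param tree Species tree whose tips cover the dataset's species.
#' @param em An [expression_matrix()].
#' @param config An [adequacy_config()].
#' @return A `"dataset_report"` list:
#' \describe{
#'   \item{reports}{wide data frame, one row per gene x tissue: status,
#'     `n_species_used`, `best_model`, AIC weights, per-statistic p-values,
#'     `adequate_all`.}
#'   \item{stats}{tidy long data frame, one row per gene x tissue x
#'     statistic: `observed`, `p_value`, `flag`.}
#'   \item{summary}{list with `n_total`, `n_ok`, `n_skipped`,
#'     `n_fit_failed`, `prop_best` (share of ok genes best-fit by each
#'     model), `prop_fail_by_stat`, `prop_adequate_all`, and
#'     `prop_ou_and_adequate`.}
#' }
#' @export
run_dataset <- function(tree, em, config = adequacy_config()) {
  stopifnot(inherits(em, "expression_matrix"))
  tree <- validate_tree(tree)
  bad <- setdiff(unique(em$samples$species), tree$tip.label)
  if (length(bad))
    stop("species absent from the tree: ", paste(bad, collapse = ", "))

  genes <- rownames(em$values)
  tissues <- unique(em$samples$tissue)
  combos <- expand.grid(gene = genes, tissue = tissues,
                        stringsAsFactors = FALSE)

  rep_rows <- vector("list", nrow(combos))
  stat_rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    g <- combos$gene[i]; ti <- combos$tissue[i]
    tv <- tryCatch(species_summary(em, g, tissue = ti,
                                   offset = config$offset),
                   error = function(e) NULL)
    gr <- if (is.null(tv))
      structure(list(gene = g, tissue = ti, n_species_used = 0L,
                     status = "skipped_few_taxa", fits = NULL,
                     best_model = NULL, adequacy = NULL),
                class = "gene_report")
    else run_gene(tree, tv, config, gene = g, tissue = ti)

    w <- setNames(rep(NA_real_, length(config$models)), config$models)
    if (!is.null(gr$fits)) {
      wi <- vapply(gr$fits, function(f) f$aic_weight, numeric(1))
      w[names(wi)] <- wi
    }
    pv <- setNames(rep(NA_real_, length(STAT_NAMES)), STAT_NAMES)
    adequate_all <- NA
    if (gr$status == "ok") {
      pv[] <- gr$adequacy$p_values[STAT_NAMES]
      fl <- gr$adequacy$flags[STAT_NAMES]
      adequate_all <- !any(fl == "fail", na.rm = TRUE)
      stat_rows[[i]] <- data.frame(
        gene = g, tissue = ti, statistic = STAT_NAMES,
        observed = as.numeric(gr$adequacy$observed[STAT_NAMES]),
        p_value = as.numeric(pv), flag = as.character(fl),
        stringsAsFactors = FALSE, row.names = NULL)
    }
    rep_rows[[i]] <- data.frame(
      gene = g, tissue = ti, status = gr$status,
      n_species_used = gr$n_species_used,
      best_model = if (is.null(gr$best_model)) NA_character_ else gr$best_model,
      t(w), t(pv), adequate_all = adequate_all,
      stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE)
  }
  reports <- do.call(rbind, rep_rows)
  if (is.null(reports)) {
    reports <- data.frame(gene = character(), tissue = character(),
                          status = character(), n_species_used = integer(),
                          best_model = character(),
                          adequate_all = logical(),
                          stringsAsFactors = FALSE)
    for (m in config$models) reports[[paste0("w_", m)]] <- numeric()
    for (s in STAT_NAMES) reports[[paste0("p_", s)]] <- numeric()
  } else {
    names(reports)[match(config$models, names(reports))] <-
      paste0("w_", config$models)
    names(reports)[match(STAT_NAMES, names(reports))] <-
      paste0("p_", STAT_NAMES)
  }
  stats <- do.call(rbind, stat_rows)
  if (is.null(stats))
    stats <- data.frame(gene = character(), tissue = character(),
                        statistic = character(), observed = numeric(),
                        p_value = numeric(), flag = character(),
                        stringsAsFactors = FALSE)

  ok <- reports$status == "ok"
  n_ok <- sum(ok)
  prop_best <- setNames(rep(0, length(config$models)), config$models)
  if (n_ok > 0) {
    tab <- table(factor(reports$best_model[ok], levels = config$models))
    prop_best[] <- as.numeric(tab) / n_ok
  }
  prop_fail <- setNames(rep(NA_real_, length(STAT_NAMES)), STAT_NAMES)
  prop_adq <- NA_real_
  prop_ou_adq <- NA_real_
  if (n_ok > 0) {
    for (s in STAT_NAMES) {
      p <- reports[[paste0("p_", s)]][ok]
      prop_fail[s] <- mean(p < config$cutoff, na.rm = TRUE)
    }
    prop_adq <- mean(reports$adequate_all[ok])
    prop_ou_adq <- mean(reports$best_model[ok] == "OU" &
                          reports$adequate_all[ok])
  }
  structure(list(
    reports = reports, stats = stats,
    summary = list(n_total = nrow(reports), n_ok = n_ok,
                   n_skipped = sum(reports$status == "skipped_few_taxa"),
                   n_fit_failed = sum(reports$status == "fit_failed"),
                   prop_best = prop_best, prop_fail_by_stat = prop_fail,
                   prop_adequate_all = prop_adq,
                   prop_ou_and_adequate = prop_ou_adq),
    config = config), class = "dataset_report")
}
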