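# Experiment drivers: ingest refolded predictions, and run the mutagenesis,
# scRMSD-correction and oracle benchmarks end-to-end on synthetic or
# ingested data. All randomness is explicitly seeded; re-running a driver
# with the same inputs gives identical tables.

SCRMSD_VARIANTS <- c("naive_mean", "naive_median", "corrected_mean",
                     "corrected_median", "iterative")

scrmsd_by_variant <- function(mobile, target, variant, mad_factor = 1.5,
                              max_iter = 10L) {
  switch(variant,
    naive_mean = scrmsd(mobile, target, "mean"),
    naive_median = scrmsd(mobile, target, "median"),
    corrected_mean = corrected_scrmsd(mobile, target, mad_factor,
                                      "mean")$scrmsd,
    corrected_median = corrected_scrmsd(mobile, target, mad_factor,
                                        "median")$scrmsd,
    iterative = iterative_outlier_superpose(mobile, target, mad_factor,
                                            max_iter, "median")$scrmsd,
    stopf("unknown scRMSD variant: %s", variant))
}

#' Ingest a directory of refolded predictions
#'
#' Pairs prediction files named `<target_id>__<design_id>.pdb` with target
#' files `<target_id>.pdb` and builds a [design_records] table: mean pLDDT
#' from the prediction B-factors, scRMSD by the configured variant.
#' Predictions without a matching target are reported with a warning, not
#' fatally. An optional metrics CSV (columns `design_id`, `plddt_mean`)
#' overrides the ingested confidence; every design it names must exist.
#'
#' @param predictions_dir directory of prediction PDB files.
#' @param targets_dir directory of target PDB files.
#' @param metrics_csv optional CSV path overriding pLDDT.
#' @param scrmsd_variant one of `"naive_mean"`, `"naive_median"`,
#'   `"corrected_mean"`, `"corrected_median"`, `"iterative"`.
#' @param plddt_min,scrmsd_max thresholds for the designability verdict.
#' @return a [design_records] data.frame.
#' @export
ingest_predictions <- function(predictions_dir, targets_dir,
                               metrics_csv = NULL,
                               scrmsd_variant = "naive_mean",
                               plddt_min = 70, scrmsd_max = 2.0) {
  files <- list.files(predictions_dir, pattern = "\\.pdb$", full.names = TRUE)
  if (length(files) == 0L) stopf("no PDB files in %s", predictions_dir)
  base <- sub("\\.pdb$", "", basename(files))
  ok_name <- grepl("__", base, fixed = TRUE)
  if (any(!ok_name))
    warnf("skipping %d file(s) not matching <target>__<design>.pdb",
          sum(!ok_name))
  files <- files[ok_name]; base <- base[ok_name]
  if (length(files) == 0L) stopf("no files match <target>__<design>.pdb")
  target_id <- sub("__.*$", "", base)
  design_id <- sub("^.*?__", "", base)

  overrides <- NULL
  if (!is.null(metrics_csv)) {
    overrides <- utils::read.csv(metrics_csv, stringsAsFactors = FALSE)
    absent <- setdiff(overrides$design_id, design_id)
    if (length(absent))
      stopf("metrics CSV names design(s) absent from the directory: %s",
            paste(absent, collapse = ", "))
  }

  rows <- list()
  for (i in seq_along(files)) {
    tpath <- file.path(targets_dir, paste0(target_id[i], ".pdb"))
    if (!file.exists(tpath)) {
      warnf("no target '%s' for prediction '%s'; skipped",
            target_id[i], basename(files[i]))
      next
    }
    pred <- read_chain(files[i])
    targ <- read_chain(tpath)
    pl <- mean_plddt(pred)
    if (!is.null(overrides) && design_id[i] %in% overrides$design_id)
      pl <- overrides$plddt_mean[match(design_id[i], overrides$design_id)]
    sc_naive <- scrmsd(pred, targ, "mean")
    sc_corr <- corrected_scrmsd(pred, targ)$scrmsd
    rows[[length(rows) + 1L]] <- data.frame(
      design_id = design_id[i], target_id = target_id[i], plddt_mean = pl,
      scrmsd_naive = sc_naive, scrmsd_corrected = sc_corr,
      length = chain_length(pred), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stopf("no prediction could be paired with a target")
  df <- do.call(rbind, rows)
  use_corr <- scrmsd_variant %in% c("corrected_mean", "corrected_median",
                                    "iterative")
  design_records(df$design_id, df$target_id, df$plddt_mean, df$scrmsd_naive,
                 df$scrmsd_corrected, df$length, plddt_min, scrmsd_max,
                 use_corrected = use_corr)
}

#' Default metric degradation model for the mutagenesis experiment
#'
#' A stand-in for a folding oracle that penalizes mutation load: mean pLDDT
#' falls and scRMSD rises linearly with the mutated fraction, with Gaussian
#' design-to-design scatter.
#'
#' @param plddt_base,plddt_slope,plddt_sd pLDDT at fraction 0, change per
#'   unit fraction, and scatter.
#' @param scrmsd_base,scrmsd_slope,scrmsd_sd same for scRMSD (A).
#' @return a list of class `metric_model`.
#' @export
metric_model <- function(plddt_base = 92, plddt_slope = -45, plddt_sd = 4,
                         scrmsd_base = 0.8, scrmsd_slope = 5,
                         scrmsd_sd = 0.4) {
  structure(list(plddt_base = plddt_base, plddt_slope = plddt_slope,
                 plddt_sd = plddt_sd, scrmsd_base = scrmsd_base,
                 scrmsd_slope = scrmsd_slope, scrmsd_sd = scrmsd_sd),
            class = "metric_model")
}

simulate_mutant_metrics <- function(fraction, n, model, seed) {
  with_seed(seed, {
    plddt <- pmin(100, pmax(0, stats::rnorm(
      n, model$plddt_base + model$plddt_slope * fraction, model$plddt_sd)))
    sc <- pmax(0, stats::rnorm(
      n, model$scrmsd_base + model$scrmsd_slope * fraction, model$scrmsd_sd))
  })
  data.frame(plddt_mean = plddt, scrmsd = sc)
}

#' Designability-versus-mutation-fraction experiment
#'
#' Generates a randomized mutant panel from the parents, obtains per-mutant
#' refolding metrics (from the supplied `metrics` table for ingested runs,
#' or from the [metric_model()] simulator), and reports the designable
#' fraction per mutation fraction at every pLDDT threshold.
#'
#' @param parents named character vector of parent sequences.
#' @param fractions mutation fractions (default 0.1-0.6 step 0.1).
#' @param replicates mutants per parent and fraction (default 64).
#' @param master_seed integer seed for panel and simulator.
#' @param metrics optional data.frame with columns `parent_id`, `fraction`,
#'   `replicate`, `plddt_mean`, `scrmsd` (ingested real metrics); when
#'   `NULL`, metrics are simulated from `model`.
#' @param model a [metric_model()].
#' @param plddt_thresholds pLDDT thresholds (default 70, 80, 85).
#' @param scrmsd_max scRMSD threshold (default 2.0 A).
#' @return list with `panel` (the mutant panel), `metrics` (per-mutant
#'   table) and `summary` (fraction x threshold designability table).
#' @export
run_mutagenesis_experiment <- function(parents,
                                       fractions = seq(0.1, 0.6, by = 0.1),
                                       replicates = 64L, master_seed = 1L,
                                       metrics = NULL, model = metric_model(),
                                       plddt_thresholds = c(70, 80, 85),
                                       scrmsd_max = 2.0) {
  panel <- generate_mutant_panel(parents, fractions, replicates, master_seed)
  if (is.null(metrics)) {
    metrics <- do.call(rbind, lapply(panel, function(s) {
      m <- simulate_mutant_metrics(
        s$fraction, length(s$replicates), model,
        derive_seed(master_seed, "metrics", s$parent_id, s$fraction))
      cbind(data.frame(parent_id = s$parent_id, fraction = s$fraction,
                       replicate = seq_along(s$replicates)), m)
    }))
  } else {
    need <- c("parent_id", "fraction", "replicate", "plddt_mean", "scrmsd")
    miss <- setdiff(need, names(metrics))
    if (length(miss))
      stopf("metrics table missing column(s): %s", paste(miss, collapse = ", "))
  }
  summary <- do.call(rbind, lapply(sort(unique(metrics$fraction)), function(f) {
    sel <- metrics[metrics$fraction == f, , drop = FALSE]
    do.call(rbind, lapply(plddt_thresholds, function(p) {
      data.frame(fraction = f, plddt_min = p, scrmsd_max = scrmsd_max,
                 designability = mean(is_designable(sel$plddt_mean, sel$scrmsd,
                                                    p, scrmsd_max)),
                 n = nrow(sel))
    }))
  }))
  rownames(summary) <- NULL
  list(panel = panel, metrics = metrics, summary = summary)
}

#' Compare scRMSD variants on identical target/prediction pairs
#'
#' Computes every requested scRMSD variant for each pair, plus the
#' designability fraction per variant under shared thresholds — the
#' comparison showing how outlier-corrected median scRMSD rescues
#' designability on structures with flexible tails while leaving tail-free
#' sets essentially unchanged.
#'
#' @param pairs list of `list(target =, prediction =)` pairs
#'   ([chain_structure]s); predictions must carry pLDDT.
#' @param variants subset of `naive_mean`, `naive_median`, `corrected_mean`,
#'   `corrected_median`, `iterative`.
#' @param plddt_min,scrmsd_max designability thresholds.
#' @param mad_factor,max_iter outlier-rejection parameters.
#' @return list with `per_design` (long data.frame: pair, variant, plddt,
#'   scrmsd, designable) and `summary` (per-variant designability).
#' @export
run_correction_benchmark <- function(pairs, variants = SCRMSD_VARIANTS,
                                     plddt_min = 70, scrmsd_max = 2.0,
                                     mad_factor = 1.5, max_iter = 10L) {
  if (length(pairs) == 0L) stopf("no pairs supplied")
  bad <- setdiff(variants, SCRMSD_VARIANTS)
  if (length(bad)) stopf("unknown variant(s): %s", paste(bad, collapse = ", "))
  per <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    pl <- mean_plddt(pr$prediction)
    do.call(rbind, lapply(variants, function(v) {
      sc <- scrmsd_by_variant(pr$prediction, pr$target, v, mad_factor,
                              max_iter)
      data.frame(pair = i, variant = v, plddt_mean = pl, scrmsd = sc,
                 designable = is_designable(pl, sc, plddt_min, scrmsd_max),
                 stringsAsFactors = FALSE)
    }))
  }))
  summary <- do.call(rbind, lapply(variants, function(v) {
    sel <- per[per$variant == v, , drop = FALSE]
    data.frame(variant = v, designability = mean(sel$designable),
               mean_scrmsd = mean(sel$scrmsd), n = nrow(sel),
               stringsAsFactors = FALSE)
  }))
  list(per_design = per, summary = summary)
}

#' Metric-versus-outcome benchmark (AUCs, grids, optima)
#'
#' For every dataset in the outcome table: AUC of pLDDT (higher is better)
#' and scRMSD (lower is better) as predictors of experimental success, the
#' full precision/F1 threshold grid, the precision- and F1-optimal cells,
#' and the confusion matrix at the F1 optimum. Single-class datasets skip
#' the AUCs with a warning; the grid is still computed.
#'
#' @param table outcome table (columns `design_id`, `plddt_mean`, `scrmsd`,
#'   `outcome`, optional `dataset`).
#' @param plddt_axis,scrmsd_axis grid axes (defaults 50-100 step 5 and
#'   0-5 step 0.5).
#' @return named list (one entry per dataset) of lists with `auc_plddt`,
#'   `auc_scrmsd`, `grid`, `optimum_precision`, `optimum_f1`,
#'   `confusion_f1`.
#' @export
run_oracle_benchmark <- function(table, plddt_axis = seq(50, 100, by = 5),
                                 scrmsd_axis = seq(0, 5, by = 0.5)) {
  if (NROW(table) == 0L) stopf("empty outcome table")
  if (is.null(table$dataset)) table$dataset <- "all"
  out <- lapply(split(table, table$dataset), function(sub) {
    auc_p <- auc_s <- NA_real_
    if (length(unique(sub$outcome)) == 2L) {
      auc_p <- roc_auc(sub$plddt_mean, sub$outcome, higher_is_better = TRUE)
      auc_s <- roc_auc(sub$scrmsd, sub$outcome, higher_is_better = FALSE)
    } else {
      warnf("dataset '%s' has a single outcome class; AUC skipped",
            sub$dataset[1])
    }
    grid <- threshold_grid_sweep(sub, plddt_axis, scrmsd_axis)
    opt_f1 <- select_optimum(grid, "f1")
    list(auc_plddt = auc_p, auc_scrmsd = auc_s, grid = grid,
         optimum_precision = select_optimum(grid, "precision"),
         optimum_f1 = opt_f1,
         confusion_f1 = unlist(opt_f1[1, c("tp", "fp", "fn", "tn")]))
  })
  out
}

#' Write a reproducibility manifest for an experiment run
#'
#' Records the configuration, seeds, package version and input digests as
#' JSON so a run can be re-executed and byte-compared.
#'
#' @param path output JSON path.
#' @param config named list echoed verbatim.
#' @param inputs optional character vector of input file paths (md5 digests
#'   are recorded).
#' @export
write_run_manifest <- function(path, config, inputs = character(0)) {
  manifest <- list(
    package = "refoldr",
    version = as.character(utils::packageVersion("refoldr")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = config,
    input_digests = if (length(inputs))
      stats::setNames(as.list(tools::md5sum(inputs)), basename(inputs))
    else list())
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
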