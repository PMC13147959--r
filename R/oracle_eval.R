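#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC computed as the Mann-Whitney probability that a positive scores above
#' a negative, with half credit for ties — exactly the trapezoidal ROC area
#' with tie grouping, and exactly order-independent. For metrics where lower
#' is better (scRMSD) set `higher_is_better = FALSE`.
#'
#' @param scores numeric scores.
#' @param labels binary outcome labels (0/1 or logical).
#' @param higher_is_better score orientation (default `TRUE`).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, higher_is_better = TRUE) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both outcome classes must be present")
  if (!higher_is_better) scores <- -scores
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts for an inclusive (pLDDT, scRMSD) threshold pair
#'
#' Predicted positive iff `plddt >= plddt_min & scrmsd <= scrmsd_max`,
#' matching [is_designable()].
#' @keywords internal
confusion_at <- function(plddt, scrmsd, outcome, plddt_min, scrmsd_max) {
  pred <- plddt >= plddt_min & scrmsd <= scrmsd_max
  c(tp = sum(pred & outcome == 1L), fp = sum(pred & outcome == 0L),
    fn = sum(!pred & outcome == 1L), tn = sum(!pred & outcome == 0L))
}

#' Precision/recall/F1 sweep over a designability threshold grid
#'
#' Evaluates the designability predicate (pLDDT >= p AND scRMSD <= r,
#' inclusive) as a classifier of experimental success for every cell of a
#' threshold grid — by default pLDDT 50 to 100 in steps of 5 and scRMSD 0 to
#' 5 A in steps of 0.5 (121 cells). Precision is reported as 0 (and flagged
#' via `defined = FALSE`) in cells with no predicted positives; F1 is 0
#' where precision + recall is 0.
#'
#' @param table data.frame with columns `plddt_mean`, `scrmsd` and binary
#'   `outcome` (an outcome table).
#' @param plddt_axis,scrmsd_axis threshold axes.
#' @return object of class `threshold_grid`: data.frame with one row per
#'   cell (`plddt_min`, `scrmsd_max`, `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`, `f1`, `defined`).
#' @export
threshold_grid_sweep <- function(table, plddt_axis = seq(50, 100, by = 5),
                                 scrmsd_axis = seq(0, 5, by = 0.5)) {
  if (NROW(table) == 0L) stopf("empty outcome table")
  if (length(plddt_axis) == 0L || length(scrmsd_axis) == 0L)
    stopf("empty threshold axis")
  need <- c("plddt_mean", "scrmsd", "outcome")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(table$outcome %in% c(0L, 1L))) stopf("outcome must be binary")
  cells <- expand.grid(plddt_min = plddt_axis, scrmsd_max = scrmsd_axis,
                       KEEP.OUT.ATTRS = FALSE)
  res <- t(apply(cells, 1L, function(cell)
    confusion_at(table$plddt_mean, table$scrmsd, table$outcome,
                 cell[["plddt_min"]], cell[["scrmsd_max"]])))
  grid <- cbind(cells, as.data.frame(res))
  npred <- grid$tp + grid$fp
  grid$precision <- ifelse(npred > 0, grid$tp / pmax(npred, 1), 0)
  grid$recall <- ifelse(grid$tp + grid$fn > 0,
                        grid$tp / pmax(grid$tp + grid$fn, 1), 0)
  pr <- grid$precision + grid$recall
  grid$f1 <- ifelse(pr > 0, 2 * grid$precision * grid$recall / pmax(pr, 1), 0)
  grid$defined <- npred > 0
  class(grid) <- c("threshold_grid", "data.frame")
  grid
}

#' Most stringent optimal cell of a threshold grid
#'
#' Selects the cell maximizing the criterion; ties at the maximum are
#' resolved by the most stringent thresholds — highest pLDDT threshold
#' first, then lowest scRMSD threshold. When no cell has any predicted
#' positive the result carries `flagged = TRUE`.
#'
#' @param grid a [threshold_grid_sweep()] result.
#' @param criterion `"f1"` (default) or `"precision"`.
#' @return single-row data.frame of the optimal cell with attribute
#'   `flagged`.
#' @export
select_optimum <- function(grid, criterion = c("f1", "precision")) {
  criterion <- match.arg(criterion)
  flagged <- !any(grid$defined)
  val <- grid[[criterion]]
  best <- val == max(val)
  # stringency: highest pLDDT threshold, then lowest scRMSD threshold
  ord <- order(-grid$plddt_min, grid$scrmsd_max)
  ord_best <- ord[best[ord]][1]
  out <- grid[ord_best, , drop = FALSE]
  attr(out, "flagged") <- flagged
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities, over all
#' tables with the observed margins, of tables no more probable than the
#' observed one (relative tie tolerance 1e-12).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stopf("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stopf("counts must be non-negative integers")
  n <- sum(table)
  if (n == 0L) stopf("empty table")
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1])
  a_obs <- table[1, 1]
  a_range <- max(0L, r1 + c1 - n):min(r1, c1)
  p <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(a_obs, c1, n - c1, r1)
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Length-distribution-matched control subset
#'
#' Bins the case lengths into `n_bins` equal-width bins over the cases'
#' length range and samples, per bin, `k` times the case count from the pool
#' (without replacement), with `k` the largest integer feasible in every
#' non-empty bin — producing a control set whose length histogram is
#' proportional to the cases'. Deterministic given `rng_seed`.
#'
#' @param cases,pool data.frames with a `length` column.
#' @param n_bins number of equal-width bins (default 10).
#' @param rng_seed integer seed.
#' @return subset of `pool` rows.
#' @export
matched_subset_by_length <- function(cases, pool, n_bins = 10, rng_seed = 1L) {
  if (NROW(cases) == 0L || NROW(pool) == 0L) stopf("cases and pool required")
  lo <- min(cases$length); hi <- max(cases$length)
  width <- (hi - lo) / n_bins
  bin_of <- function(len) {
    b <- if (width > 0) floor((len - lo) / width) else rep(0, length(len))
    pmin(pmax(b, 0), n_bins - 1)
  }
  cb <- bin_of(cases$length)
  pb <- bin_of(pool$length)
  pb[pool$length < lo | pool$length > hi] <- -1L
  case_counts <- tabulate(cb + 1L, nbins = n_bins)
  pool_counts <- vapply(seq_len(n_bins) - 1L, function(b) sum(pb == b),
                        integer(1))
  active <- which(case_counts > 0L)
  if (any(pool_counts[active] == 0L))
    stopf("pool has no entries in case length bin(s): %s",
          paste(active[pool_counts[active] == 0L], collapse = ", "))
  k <- min(pool_counts[active] %/% case_counts[active])
  if (k < 1L) stopf("pool too small to match the case distribution")
  with_seed(rng_seed, {
    picked <- unlist(lapply(active - 1L, function(b) {
      cand <- which(pb == b)
      take <- k * case_counts[b + 1L]
      if (length(cand) == take) cand else sample(cand, take)
    }))
    pool[sort(picked), , drop = FALSE]
  })
}

#' Read/write outcome tables as CSV
#'
#' Columns: design_id, plddt_mean, scrmsd, outcome (0/1), dataset.
#'
#' @param table outcome data.frame.
#' @param path CSV path.
#' @export
write_outcome_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcome_table
#' @export
read_outcome_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("design_id", "plddt_mean", "scrmsd", "outcome")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(df$outcome %in% c(0L, 1L))) stopf("outcome must be binary")
  df
}
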