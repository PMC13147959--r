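#' Mean pLDDT of a chain
#'
#' Arithmetic mean of the per-residue confidence over the full chain length.
#'
#' @param s a [chain_structure] with `plddt` present.
#' @return mean pLDDT on the 0-100 scale.
#' @export
mean_plddt <- function(s) {
  stopifnot(inherits(s, "chain_structure"))
  if (is.null(s$plddt) || length(s$plddt) == 0L)
    stopf("structure carries no pLDDT values")
  mean(s$plddt)
}

#' Designability verdict for one design
#'
#' A refolded design is designable when its mean pLDDT is at least
#' `plddt_min` *and* its scRMSD to the target is at most `scrmsd_max`
#' (both comparisons inclusive). Defaults are the conventional pLDDT >= 70
#' and scRMSD <= 2.0 Angstrom.
#'
#' @param plddt_mean mean pLDDT (0-100).
#' @param scrmsd self-consistency RMSD in Angstrom (any variant).
#' @param plddt_min,scrmsd_max thresholds.
#' @return logical vector (vectorized over the metric arguments).
#' @export
is_designable <- function(plddt_mean, scrmsd, plddt_min = 70,
                          scrmsd_max = 2.0) {
  if (any(!is.finite(plddt_mean)) || any(!is.finite(scrmsd)))
    stopf("metrics must be finite")
  if (any(scrmsd < 0)) stopf("scrmsd must be non-negative")
  plddt_mean >= plddt_min & scrmsd <= scrmsd_max
}

#' Build a table of design records
#'
#' The canonical per-design metric table used by the summary and benchmark
#' functions: one row per design with its mean pLDDT, naive and (optionally)
#' corrected scRMSD, length and a designability verdict under the stated
#' thresholds.
#'
#' @param design_id,target_id character vectors.
#' @param plddt_mean mean pLDDT per design (0-100).
#' @param scrmsd_naive plain scRMSD per design (Angstrom).
#' @param scrmsd_corrected optional corrected scRMSD (Angstrom).
#' @param length residue counts.
#' @param plddt_min,scrmsd_max thresholds used for the `designable` column.
#' @param use_corrected if `TRUE` the verdict uses `scrmsd_corrected`.
#' @return a data.frame of class `design_records`.
#' @export
design_records <- function(design_id, target_id, plddt_mean, scrmsd_naive,
                           scrmsd_corrected = NA_real_, length,
                           plddt_min = 70, scrmsd_max = 2.0,
                           use_corrected = FALSE) {
  sc <- if (use_corrected) scrmsd_corrected else scrmsd_naive
  if (use_corrected && any(is.na(scrmsd_corrected)))
    stopf("use_corrected = TRUE but scrmsd_corrected has missing values")
  df <- data.frame(design_id = as.character(design_id),
                   target_id = as.character(target_id),
                   plddt_mean = plddt_mean, scrmsd_naive = scrmsd_naive,
                   scrmsd_corrected = scrmsd_corrected, length = length,
                   designable = is_designable(plddt_mean, sc, plddt_min,
                                              scrmsd_max),
                   stringsAsFactors = FALSE)
  attr(df, "thresholds_used") <- c(plddt_min = plddt_min,
                                   scrmsd_max = scrmsd_max)
  attr(df, "scrmsd_variant") <- if (use_corrected) "corrected" else "naive"
  class(df) <- c("design_records", "data.frame")
  df
}

#' Best-of-N design selection
#'
#' Among several candidate designs for the same target, select the one with
#' the lowest naive scRMSD to the target backbone (ties broken by earliest
#' position).
#'
#' @param candidates a `design_records` data.frame (or any data.frame with
#'   `target_id` and `scrmsd_naive` columns).
#' @return the selected row (single-row data.frame).
#' @export
select_best_design <- function(candidates) {
  if (NROW(candidates) == 0L) stopf("empty candidate list")
  if (length(unique(candidates$target_id)) != 1L)
    stopf("candidates mix multiple targets")
  candidates[which.min(candidates$scrmsd_naive), , drop = FALSE]
}

#' Fraction of designable designs
#'
#' @param records a `design_records` data.frame.
#' @param plddt_min,scrmsd_max thresholds applied uniformly.
#' @param scrmsd_col metric column to threshold (default `"scrmsd_naive"`).
#' @return fraction in [0, 1].
#' @export
designability_fraction <- function(records, plddt_min = 70, scrmsd_max = 2.0,
                                   scrmsd_col = "scrmsd_naive") {
  if (NROW(records) == 0L) stopf("empty record list")
  mean(is_designable(records$plddt_mean, records[[scrmsd_col]],
                     plddt_min, scrmsd_max))
}

#' Length-binned designability summary
#'
#' Bins designs by length into half-open bins `[lo, lo + width)` and reports
#' per-bin mean designability, mean pLDDT, mean scRMSD and the design count.
#' Empty bins are omitted.
#'
#' @param records a `design_records` data.frame.
#' @param bin_width bin width in residues (default 25).
#' @param scrmsd_col metric column to summarize.
#' @return data.frame with columns `bin_lo`, `bin_hi`, `designability`,
#'   `mean_plddt`, `mean_scrmsd`, `n`.
#' @export
length_binned_summary <- function(records, bin_width = 25,
                                  scrmsd_col = "scrmsd_naive") {
  if (!is.numeric(bin_width) || bin_width <= 0) stopf("bin_width must be > 0")
  if (NROW(records) == 0L) stopf("empty record list")
  lo <- floor(records$length / bin_width) * bin_width
  out <- do.call(rbind, lapply(sort(unique(lo)), function(b) {
    sel <- records[lo == b, , drop = FALSE]
    data.frame(bin_lo = b, bin_hi = b + bin_width,
               designability = mean(sel$designable),
               mean_plddt = mean(sel$plddt_mean),
               mean_scrmsd = mean(sel[[scrmsd_col]]),
               n = nrow(sel))
  }))
  rownames(out) <- NULL
  out
}

#' Class-balanced uniform-length subset
#'
#' Partitions the length range `[lo, hi)` into `n_bins` equal-width bins and
#' draws the same number of designs from every bin (the minimum available
#' count over bins), uniformly without replacement, so the selected set has a
#' flat length distribution. Deterministic given `rng_seed`.
#'
#' @param records a `design_records` data.frame.
#' @param lo,hi length range (half-open, residues).
#' @param n_bins number of equal-width bins.
#' @param rng_seed integer seed.
#' @return the selected subset (rows of `records`).
#' @export
uniform_length_subset <- function(records, lo = 60, hi = 300, n_bins = 15,
                                  rng_seed = 1L) {
  if (lo >= hi) stopf("lo must be < hi")
  if (!is_count(n_bins) || n_bins < 1) stopf("n_bins must be >= 1")
  width <- (hi - lo) / n_bins
  inb <- records$length >= lo & records$length < hi
  bin <- floor((records$length[inb] - lo) / width)
  bin[bin >= n_bins] <- n_bins - 1
  counts <- tabulate(bin + 1L, nbins = n_bins)
  if (any(counts == 0L))
    stopf("empty length bin(s): %s",
          paste(which(counts == 0L), collapse = ", "))
  k <- min(counts)
  idx_all <- which(inb)
  with_seed(rng_seed, {
    picked <- unlist(lapply(seq_len(n_bins) - 1L, function(b) {
      cand <- idx_all[bin == b]
      if (length(cand) == 1L) cand else sample(cand, k)
    }))
    records[sort(picked), , drop = FALSE]
  })
}

#' Truncate a full-length model to a deposited reference sequence
#'
#' Full-length predicted models (e.g. AlphaFold Database entries) often span
#' flexible regions absent from the deposited experimental structure. This
#' slices the full-length chain down to the contiguous residue range whose
#' sequence matches `reference_seq` exactly (coordinates and pLDDT sliced
#' accordingly). The match must be unique.
#'
#' @param full a [chain_structure] (the full-length model).
#' @param reference_seq one-letter sequence of the deposited construct.
#' @param max_mismatch maximum tolerated mismatches in a sliding-window
#'   match; default 0 (exact substring matching).
#' @return the truncated [chain_structure].
#' @seealso [truncation_eligible()]
#' @export
truncate_to_reference <- function(full, reference_seq, max_mismatch = 0L) {
  stopifnot(inherits(full, "chain_structure"))
  Lf <- chain_length(full); Lr <- nchar(reference_seq)
  if (Lr > Lf) stopf("reference longer than full-length model")
  if (Lr == 0L) stopf("empty reference sequence")
  if (max_mismatch == 0L) {
    m <- gregexpr(reference_seq, full$sequence, fixed = TRUE)[[1]]
    starts <- if (m[1] == -1L) integer(0) else as.integer(m)
  } else {
    fc <- seq_chars(full$sequence); rc <- seq_chars(reference_seq)
    starts <- Filter(function(st) {
      sum(fc[st:(st + Lr - 1L)] != rc) <= max_mismatch
    }, seq_len(Lf - Lr + 1L))
    starts <- as.integer(starts)
  }
  if (length(starts) == 0L) stopf("reference not found in full-length sequence")
  if (length(starts) > 1L)
    stopf("reference matches %d positions (ambiguous)", length(starts))
  chain_slice(full, starts, starts + Lr - 1L)
}

#' Eligibility of a full/deposited pair for the truncation analysis
#'
#' A pair enters the truncation comparison when the full-length model exceeds
#' the deposited length by more than `min_extra` and fewer than `max_extra`
#' residues (strict on both sides).
#'
#' @param full_length,reference_length residue counts.
#' @param min_extra,max_extra bounds on the length difference (defaults 5
#'   and 50).
#' @return logical (vectorized).
#' @export
truncation_eligible <- function(full_length, reference_length,
                                min_extra = 5, max_extra = 50) {
  d <- full_length - reference_length
  d > min_extra & d < max_extra
}

#' Read/write design-record tables as CSV
#'
#' Columns: design_id, target_id, plddt_mean, scrmsd_naive, scrmsd_corrected,
#' length, designable.
#'
#' @param records a `design_records` data.frame.
#' @param path CSV file path.
#' @export
write_design_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_records
#' @export
read_design_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("design_id", "target_id", "plddt_mean", "scrmsd_naive", "length",
            "designable")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  class(df) <- c("design_records", "data.frame")
  df
}
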