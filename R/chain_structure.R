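#' Single-chain protein structure container
#'
#' Holds one protein chain as used throughout the refolding pipeline: the
#' one-letter sequence, ordered C-alpha coordinates (Angstrom), optional
#' backbone N/C/O coordinates (required only for secondary-structure
#' assignment), optional per-residue confidence (pLDDT, 0-100 scale) and the
#' author residue numbering as metadata. Internally residues are indexed
#' 0-based and contiguously by array position; author numbering is never used
#' by any algorithm.
#'
#' @param id chain identifier (free text).
#' @param sequence one-letter amino-acid string (may contain X).
#' @param ca_coords numeric matrix, one row per residue, columns x/y/z in
#'   Angstrom.
#' @param backbone_coords optional named list with matrices `n`, `c`, `o`
#'   (same dimensions as `ca_coords`).
#' @param plddt optional numeric vector of per-residue confidence in [0, 100].
#' @param residue_numbers optional character vector of author residue
#'   identifiers (insertion codes kept); defaults to 1..L.
#' @return an object of class `chain_structure`.
#' @examples
#' s <- chain_structure("toy", "GAV", matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0),
#'                      ncol = 3, byrow = TRUE), plddt = c(90, 85, 70))
#' chain_length(s)
#' @export
chain_structure <- function(id, sequence, ca_coords, backbone_coords = NULL,
                            plddt = NULL, residue_numbers = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stopf("sequence must be a single string")
  L <- nchar(sequence)
  ca_coords <- as_coord_matrix(ca_coords, "ca_coords")
  if (nrow(ca_coords) != L)
    stopf("sequence length (%d) != number of CA coordinates (%d)",
          L, nrow(ca_coords))
  if (!all(is.finite(ca_coords))) stopf("non-finite CA coordinates")
  if (!is.null(backbone_coords)) {
    if (!all(c("n", "c", "o") %in% names(backbone_coords)))
      stopf("backbone_coords must contain matrices 'n', 'c', 'o'")
    backbone_coords <- lapply(backbone_coords[c("n", "c", "o")],
                              as_coord_matrix, what = "backbone_coords")
    for (m in backbone_coords) {
      if (nrow(m) != L) stopf("backbone coordinate count != sequence length")
      if (!all(is.finite(m))) stopf("non-finite backbone coordinates")
    }
  }
  if (!is.null(plddt)) {
    plddt <- as.numeric(plddt)
    if (length(plddt) != L) stopf("plddt length != sequence length")
    if (!all(is.finite(plddt)) || any(plddt < 0 | plddt > 100))
      stopf("plddt values must be finite and in [0, 100]")
  }
  if (is.null(residue_numbers)) residue_numbers <- as.character(seq_len(L))
  if (length(residue_numbers) != L)
    stopf("residue_numbers length != sequence length")
  structure(list(id = id, sequence = sequence,
                 residue_numbers = as.character(residue_numbers),
                 ca_coords = ca_coords, backbone_coords = backbone_coords,
                 plddt = plddt),
            class = "chain_structure")
}

as_coord_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stopf("%s must have 3 columns (x, y, z)", what)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> id=%s  %d residues\n", x$id, chain_length(x)))
  cat("  sequence: ",
      if (chain_length(x) > 50) paste0(substr(x$sequence, 1, 50), "...")
      else x$sequence, "\n", sep = "")
  cat(sprintf("  backbone atoms: %s;  pLDDT: %s\n",
              if (is.null(x$backbone_coords)) "CA only" else "N/CA/C/O",
              if (is.null(x$plddt)) "absent"
              else sprintf("mean %.1f", mean(x$plddt))))
  invisible(x)
}

#' Number of residues in a chain
#' @param s a `chain_structure`.
#' @return integer residue count.
#' @export
chain_length <- function(s) nrow(s$ca_coords)

#' Slice a chain to a contiguous residue range
#'
#' @param s a `chain_structure`.
#' @param from,to 1-based residue positions (inclusive).
#' @return a `chain_structure` covering positions `from..to`.
#' @export
chain_slice <- function(s, from, to) {
  L <- chain_length(s)
  if (from < 1 || to > L || from > to) stopf("invalid slice [%d, %d]", from, to)
  idx <- from:to
  chain_structure(
    id = s$id, sequence = substr(s$sequence, from, to),
    ca_coords = s$ca_coords[idx, , drop = FALSE],
    backbone_coords = if (!is.null(s$backbone_coords))
      lapply(s$backbone_coords, function(m) m[idx, , drop = FALSE]),
    plddt = if (!is.null(s$plddt)) s$plddt[idx],
    residue_numbers = s$residue_numbers[idx])
}

# Warn (not error) when CA-CA spacing is outside the physical range for an
# intact chain; ingest of real files must degrade gracefully.
check_ca_spacing <- function(s, lo = 2.8, hi = 4.2) {
  if (chain_length(s) < 2) return(invisible(TRUE))
  d <- sqrt(rowSums((s$ca_coords[-1, , drop = FALSE] -
                     s$ca_coords[-chain_length(s), , drop = FALSE])^2))
  bad <- which(d < lo | d > hi)
  if (length(bad))
    warnf("%d consecutive CA-CA distances outside [%.1f, %.1f] Angstrom",
          length(bad), lo, hi)
  invisible(length(bad) == 0L)
}
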