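#' Read one chain from a PDB file
#'
#' Parses ATOM records of a PDB file (via bio3d) and normalizes the selected
#' chain into a [chain_structure]: one C-alpha per residue in file order,
#' backbone N/C/O kept when every residue carries them, and optionally the
#' C-alpha B-factor column interpreted as pLDDT. HETATM records are skipped,
#' alternate locations are resolved by first occurrence and insertion codes
#' are preserved in the author residue numbers.
#'
#' Confidence scale auto-detection: predicted models write pLDDT either on the
#' 0-100 scale (AlphaFold2 convention) or 0-1 (ESMFold convention). If every
#' ingested value is <= 1 the values are multiplied by 100, so thresholds such
#' as 70 always refer to the 0-100 scale.
#'
#' @param path PDB file path.
#' @param chain chain identifier; `NULL` (default) takes the first chain in
#'   the file.
#' @param plddt_from_bfactor if `TRUE` (default) populate `plddt` from the
#'   C-alpha B-factor column.
#' @return a [chain_structure].
#' @seealso [write_chain()]
#' @export
read_chain <- function(path, chain = NULL, plddt_from_bfactor = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stopf("no ATOM records in %s", path)
  at$chain[is.na(at$chain)] <- ""
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stopf("chain not found: '%s' in %s", chain, path)
  at$insert[is.na(at$insert)] <- ""
  # altLoc: first occurrence per (residue, atom name) wins
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  at <- at[!duplicated(key), , drop = FALSE]
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stopf("non-numeric coordinate fields in %s", path)

  res_key <- paste(at$resno, at$insert, sep = "|")
  res_order <- unique(res_key)
  ca <- at[at$elety == "CA", , drop = FALSE]
  miss <- setdiff(res_order, paste(ca$resno, ca$insert, sep = "|"))
  if (length(miss))
    stopf("residue with no CA atom in chain '%s' (%s)", chain,
          paste(utils::head(miss, 3), collapse = ", "))
  ca <- ca[match(res_order, paste(ca$resno, ca$insert, sep = "|")), ,
           drop = FALSE]

  seq1 <- AA3_TO_1[ca$resid]
  seq1[is.na(seq1)] <- "X"
  atom_mat <- function(name) {
    sub <- at[at$elety == name, , drop = FALSE]
    idx <- match(res_order, paste(sub$resno, sub$insert, sep = "|"))
    if (anyNA(idx)) return(NULL)
    as.matrix(sub[idx, c("x", "y", "z")])
  }
  backbone <- NULL
  n_m <- atom_mat("N"); c_m <- atom_mat("C"); o_m <- atom_mat("O")
  if (!is.null(n_m) && !is.null(c_m) && !is.null(o_m))
    backbone <- list(n = n_m, c = c_m, o = o_m)

  plddt <- NULL
  if (isTRUE(plddt_from_bfactor)) {
    b <- ca$b
    if (all(is.finite(b))) {
      if (all(b <= 1.0)) b <- b * 100  # ESMFold-style 0-1 scale
      if (all(b >= 0 & b <= 100)) plddt <- b
    }
  }
  s <- chain_structure(
    id = sub("\\.pdb$", "", basename(path)), sequence = paste(seq1, collapse = ""),
    ca_coords = as.matrix(ca[, c("x", "y", "z")]), backbone_coords = backbone,
    plddt = plddt, residue_numbers = paste0(ca$resno, trimws(ca$insert)))
  check_ca_spacing(s)
  s
}

#' Write a chain to a PDB file
#'
#' Emits standard ATOM records (N/CA/C/O when backbone coordinates are
#' present, CA only otherwise) with 1-based serial numbers. Per-residue
#' confidence is written to the B-factor column with two decimals.
#'
#' @param s a [chain_structure].
#' @param path output file path.
#' @param chain chain identifier to write (single character), default "A".
#' @return `path`, invisibly.
#' @export
write_chain <- function(s, path, chain = "A") {
  stopifnot(inherits(s, "chain_structure"))
  L <- chain_length(s)
  if (L == 0L) stopf("empty structure")
  aa3 <- AA1_TO_3[seq_chars(s$sequence)]
  aa3[is.na(aa3)] <- "UNK"
  b <- s$plddt %||% rep(0, L)
  if (is.null(s$backbone_coords)) {
    elety <- rep("CA", L)
    resno <- seq_len(L)
    xyz <- as.vector(t(s$ca_coords))
    resid <- aa3
    bb <- b
  } else {
    # atom order N, CA, C, O within each residue
    elety <- rep(c("N", "CA", "C", "O"), L)
    resno <- rep(seq_len(L), each = 4L)
    coords <- matrix(0, 4L * L, 3L)
    coords[seq(1, 4 * L, by = 4), ] <- s$backbone_coords$n
    coords[seq(2, 4 * L, by = 4), ] <- s$ca_coords
    coords[seq(3, 4 * L, by = 4), ] <- s$backbone_coords$c
    coords[seq(4, 4 * L, by = 4), ] <- s$backbone_coords$o
    xyz <- as.vector(t(coords))
    resid <- rep(aa3, each = 4L)
    bb <- rep(b, each = 4L)
  }
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", length(elety)),
                   resno = resno, resid = resid, eleno = seq_along(elety),
                   elety = elety, chain = rep(chain, length(elety)),
                   o = rep(1, length(elety)), b = round(bb, 2))
  invisible(path)
}

validate_aa_string <- function(seq, id, allow_gap = FALSE) {
  ok <- c(AA1, "X", if (allow_gap) "-")
  bad <- setdiff(unique(seq_chars(seq)), ok)
  if (length(bad))
    stopf("record '%s' contains non-amino-acid symbol(s): %s", id,
          paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Read/write amino-acid FASTA
#'
#' `read_fasta()` returns a named character vector of sequences in file
#' order; `write_fasta()` writes one with 60-column wrapping. Both reject
#' duplicate identifiers and symbols outside the 20 standard amino acids
#' plus X.
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stopf("duplicate FASTA id: %s", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  for (i in seq_along(seqs)) validate_aa_string(seqs[[i]], ids[[i]])
  seqs
}

#' @param records named character vector (names are FASTA ids).
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  if (length(records) == 0L) stopf("no records to write")
  if (is.null(names(records)) || any(names(records) == ""))
    stopf("all records must be named")
  if (anyDuplicated(names(records)))
    stopf("duplicate FASTA id: %s", names(records)[duplicated(names(records))][1])
  for (i in seq_along(records))
    validate_aa_string(records[[i]], names(records)[[i]])
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
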