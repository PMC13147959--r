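#' Randomly mutate a fixed fraction of residues
#'
#' Simulates a "badly designed" sequence: `k = round(fraction * L)` distinct
#' positions (at least one when `fraction > 0`) are chosen uniformly without
#' replacement and each is substituted by a residue drawn uniformly from the
#' 19 standard amino acids other than the parent residue, so the realized
#' mutation load is exactly `k`, not merely expected.
#'
#' @param parent parent sequence over the 20 standard amino acids.
#' @param fraction fraction of residues to mutate, in [0, 1].
#' @param seed integer seed (the function is deterministic given it).
#' @return list with `mutant` (sequence) and `positions` (sorted 1-based
#'   mutated positions).
#' @export
mutate_sequence <- function(parent, fraction, seed) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stopf("fraction must be in [0, 1]")
  validate_aa_string(parent, "parent")
  if (grepl("X", parent, fixed = TRUE))
    stopf("parent contains non-standard residue X")
  L <- nchar(parent)
  if (L == 0L) stopf("empty parent sequence")
  k <- if (fraction == 0) 0L else max(1L, as.integer(round(fraction * L)))
  if (k == 0L) return(list(mutant = parent, positions = integer(0)))
  chars <- seq_chars(parent)
  with_seed(seed, {
    pos <- sort(sample.int(L, k))
    for (p in pos) {
      alt <- AA1[AA1 != chars[p]]
      chars[p] <- alt[sample.int(19L, 1L)]
    }
  })
  list(mutant = paste(chars, collapse = ""), positions = pos)
}

#' Generate a randomized mutagenesis panel
#'
#' One mutant set per (parent, fraction) pair with `replicates` independent
#' mutants each; per-replicate seeds are derived deterministically from
#' `(master_seed, parent_id, fraction, replicate)`, so the panel is
#' bit-reproducible. The default study layout — 50 parents, fractions 10-60%
#' in steps of 10%, 64 replicates — yields 19,200 sequences.
#'
#' @param parents named character vector of parent sequences (names are ids).
#' @param fractions numeric vector of mutation fractions.
#' @param replicates mutants per (parent, fraction).
#' @param master_seed integer master seed.
#' @return list of `mutant_set` objects, each with `parent_id`, `parent_seq`,
#'   `fraction`, `seed`, and `replicates` (list of
#'   `list(mutant, positions)`).
#' @export
generate_mutant_panel <- function(parents, fractions = seq(0.1, 0.6, by = 0.1),
                                  replicates = 64L, master_seed = 1L) {
  if (length(parents) == 0L || length(fractions) == 0L)
    stopf("parents and fractions must be non-empty")
  if (is.null(names(parents)) || anyDuplicated(names(parents)))
    stopf("parents must carry unique ids")
  if (!is_count(replicates) || replicates < 1) stopf("replicates must be >= 1")
  sets <- vector("list", length(parents) * length(fractions))
  i <- 0L
  for (pid in names(parents)) {
    for (f in fractions) {
      reps <- lapply(seq_len(replicates), function(r)
        mutate_sequence(parents[[pid]], f,
                        derive_seed(master_seed, pid, f, r)))
      i <- i + 1L
      sets[[i]] <- structure(
        list(parent_id = pid, parent_seq = parents[[pid]], fraction = f,
             seed = master_seed, replicates = reps),
        class = "mutant_set")
    }
  }
  sets
}

#' Total number of sequences in a panel
#' @param panel output of [generate_mutant_panel()].
#' @return integer count.
#' @export
panel_size <- function(panel) {
  sum(vapply(panel, function(s) length(s$replicates), integer(1)))
}

#' Write a panel as FASTA plus a manifest CSV
#'
#' FASTA ids are `<parent_id>_f<percent>_r<replicate>`; the manifest lists
#' parent_id, fraction, replicate and the mutated positions as
#' semicolon-separated 1-based indices.
#'
#' @param panel output of [generate_mutant_panel()].
#' @param fasta_path,manifest_path output files.
#' @export
write_mutant_panel <- function(panel, fasta_path, manifest_path) {
  recs <- character(0); man <- list()
  for (s in panel) {
    for (r in seq_along(s$replicates)) {
      id <- sprintf("%s_f%02d_r%03d", s$parent_id, round(100 * s$fraction), r)
      recs[[id]] <- s$replicates[[r]]$mutant
      man[[length(man) + 1L]] <- data.frame(
        id = id, parent_id = s$parent_id, fraction = s$fraction,
        replicate = r,
        mutated_positions = paste(s$replicates[[r]]$positions, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  write_fasta(recs, fasta_path)
  utils::write.csv(do.call(rbind, man), manifest_path, row.names = FALSE)
  invisible(list(fasta = fasta_path, manifest = manifest_path))
}

#' Pairwise sequence identity
#'
#' Ungapped mode (default) requires equal lengths and reports the fraction of
#' matching positions. Gapped mode accepts aligned rows and computes identity
#' only over columns where both rows are non-gap.
#'
#' @param a,b sequences (aligned rows in gapped mode, `-` as gap).
#' @param gapped compare only mutually non-gap columns.
#' @return identity fraction in [0, 1] (`NaN` when no comparable columns).
#' @export
sequence_identity <- function(a, b, gapped = FALSE) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb)) stopf("sequence length mismatch")
  if (gapped) {
    keep <- ca != "-" & cb != "-"
    ca <- ca[keep]; cb <- cb[keep]
  }
  if (length(ca) == 0L) return(NaN)
  mean(ca == cb)
}
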