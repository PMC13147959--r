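# 3-state secondary-structure assignment from backbone geometry.
#
# Backbone hydrogen bonds are detected with the Kabsch-Sander electrostatic
# model after placing the amide hydrogen from the preceding residue's C=O
# direction; alpha-helix comes from two consecutive i->i+4 turns, strand from
# parallel/antiparallel bridge patterns, everything else is coil. 3_10/pi
# helices collapse into coil, isolated beta bridges into strand, matching the
# simplified helix/strand/coil view used for composition summaries.

KS_COUPLING <- 0.084 * 332   # kcal/mol * Angstrom, Kabsch-Sander constant
HBOND_ENERGY_CUTOFF <- -0.5  # kcal/mol
NH_BOND_LENGTH <- 1.01       # Angstrom
CHAIN_BREAK_CA_DIST <- 4.5   # Angstrom

#' Assign 3-state secondary structure (H/E/C)
#'
#' Simplified DSSP on backbone geometry. Amide hydrogens are inferred on each
#' N opposite the preceding residue's C=O (1.01 A bond); a backbone hydrogen
#' bond CO(i)...HN(j) is declared when the Kabsch-Sander energy
#' `0.084 * 332 * (1/dON + 1/dCH - 1/dOH - 1/dCN)` is below -0.5 kcal/mol.
#' Two consecutive i->i+4 turns mark an alpha-helix (minimum run of 4);
#' parallel/antiparallel bridge patterns mark strands; all else is coil.
#' Chains are split at C-alpha breaks (> 4.5 A) before assignment, and
#' chains shorter than 5 residues are entirely coil.
#'
#' @param s a [chain_structure] with backbone (N/C/O) coordinates.
#' @return an object of class `secstruct`: list with `states` (character
#'   vector over H/E/C) and `source` (the chain id).
#' @export
assign_secondary_structure <- function(s) {
  stopifnot(inherits(s, "chain_structure"))
  if (is.null(s$backbone_coords))
    stopf("backbone N/C/O coordinates required for secondary structure")
  L <- chain_length(s)
  states <- rep("C", L)
  if (L >= 5L) {
    ca <- s$ca_coords
    n_xyz <- s$backbone_coords$n
    c_xyz <- s$backbone_coords$c
    o_xyz <- s$backbone_coords$o

    dca <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-L, , drop = FALSE])^2))
    seg <- cumsum(c(1L, as.integer(dca > CHAIN_BREAK_CA_DIST)))

    # amide H on N_j, anti-parallel to C(j-1)=O(j-1); absent at segment starts
    h_xyz <- matrix(NA_real_, L, 3L)
    for (j in 2:L) {
      if (seg[j] != seg[j - 1L]) next
      # DSSP convention: N-H anti-parallel to the preceding C=O
      dir <- c_xyz[j - 1L, ] - o_xyz[j - 1L, ]
      dir <- dir / sqrt(sum(dir^2))
      h_xyz[j, ] <- n_xyz[j, ] + NH_BOND_LENGTH * dir
    }

    hbond <- hbond_map(c_xyz, o_xyz, n_xyz, h_xyz)

    # alpha helix: two consecutive 4-turns
    turn4 <- rep(FALSE, L)
    for (i in seq_len(L - 4L))
      if (seg[i] == seg[i + 4L] && hbond[i, i + 4L]) turn4[i] <- TRUE
    for (i in which(turn4[-1] & turn4[-L])) {
      # turn4 at i and i+1 (index into original): residues i+1 .. i+4 helical
      states[(i + 1L):(i + 4L)] <- "H"
    }

    # beta bridges (parallel or antiparallel), |i - j| >= 3
    is_e <- rep(FALSE, L)
    for (i in 2:(L - 1L)) {
      for (j in seq_len(L)) {
        if (abs(i - j) < 3L || j < 2L || j > L - 1L) next
        par <- (hbond[i - 1L, j] && hbond[j, i + 1L]) ||
               (hbond[j - 1L, i] && hbond[i, j + 1L])
        anti <- (hbond[i, j] && hbond[j, i]) ||
                (hbond[i - 1L, j + 1L] && hbond[j - 1L, i + 1L])
        if (par || anti) { is_e[i] <- TRUE; is_e[j] <- TRUE }
      }
    }
    states[is_e & states != "H"] <- "E"
  }
  structure(list(states = states, source = s$id), class = "secstruct")
}

# Kabsch-Sander H-bond energy map: entry [i, j] is TRUE when CO(i) accepts
# from NH(j). Donors without an inferred H (segment starts) never bond.
hbond_map <- function(c_xyz, o_xyz, n_xyz, h_xyz) {
  L <- nrow(c_xyz)
  hb <- matrix(FALSE, L, L)
  donors <- which(!is.na(h_xyz[, 1]))
  for (j in donors) {
    dON <- sqrt(colSums((t(o_xyz) - n_xyz[j, ])^2))
    dCH <- sqrt(colSums((t(c_xyz) - h_xyz[j, ])^2))
    dOH <- sqrt(colSums((t(o_xyz) - h_xyz[j, ])^2))
    dCN <- sqrt(colSums((t(c_xyz) - n_xyz[j, ])^2))
    e <- KS_COUPLING * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
    e[abs(j - seq_len(L)) < 2L] <- 0      # self and sequence-adjacent
    e[pmin(dON, dCH, dOH, dCN) < 0.5] <- 0  # clash guard
    hb[, j] <- e < HBOND_ENERGY_CUTOFF
  }
  hb
}

#' @export
print.secstruct <- function(x, ...) {
  comp <- ss_composition(x)
  cat(sprintf("<secstruct> %d residues  H %.1f%%  E %.1f%%  C %.1f%%\n",
              length(x$states), comp["helix"], comp["strand"], comp["coil"]))
  invisible(x)
}

#' Secondary-structure composition
#'
#' @param ss a `secstruct` object (or plain character vector of H/E/C
#'   states).
#' @return named numeric vector `c(helix, strand, coil)` in percent, summing
#'   to 100.
#' @export
ss_composition <- function(ss) {
  states <- if (inherits(ss, "secstruct")) ss$states else
    if (is.character(ss) && length(ss) == 1L) seq_chars(ss) else ss
  if (length(states) == 0L) stopf("empty secondary-structure string")
  c(helix = 100 * mean(states == "H"),
    strand = 100 * mean(states == "E"),
    coil = 100 * mean(states == "C"))
}

#' Filter structures by helical content
#'
#' Retains the structures whose helix percentage lies in `[lo, hi]`
#' (inclusive) — the curation rule used to avoid a parent set dominated by
#' small helical bundles.
#'
#' @param structures list of [chain_structure] objects with backbone atoms.
#' @param lo,hi helix-content bounds in percent (defaults 30 and 60).
#' @return the retained sublist.
#' @export
helix_content_filter <- function(structures, lo = 30, hi = 60) {
  if (lo > hi) stopf("lo must be <= hi")
  keep <- vapply(structures, function(s) {
    h <- ss_composition(assign_secondary_structure(s))["helix"]
    h >= lo && h <= hi
  }, logical(1))
  structures[keep]
}
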