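# Synthetic stand-ins for folding-model outputs: ideal backbones built from
# dihedrals, "predicted" models with a noisy rigid core and divergent tails,
# Gaussian region-wise confidence profiles, controlled-diversity MSAs, and
# logistic binary outcomes. These give every pipeline stage a desk-scale,
# fully seeded test bed.

# ideal backbone geometry (Angstrom / degrees, standard trans-peptide values)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
ANG_N_CA_C <- 111.2
ANG_CA_C_N <- 116.2
ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.8
PHI_PSI <- list(H = c(-57, -47), E = c(-119, 113))

# Natural-extension reference frame: place D from A-B-C with bond C-D = r,
# angle B-C-D = theta, torsion A-B-C-D = chi (degrees).
nerf_place <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cbind(bc, pracma_cross(n, bc), n)
  d2 <- r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c + as.numeric(m %*% d2)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

STATE_AA <- c(H = "A", E = "V", C = "G")

#' Build an ideal backbone from a secondary-structure layout
#'
#' Constructs N/CA/C/O coordinates segment by segment from ideal dihedrals
#' (helix phi/psi = -57/-47, strand -119/113, coil drawn from a broad seeded
#' distribution) with standard bond lengths and angles, giving consecutive
#' CA-CA distances of ~3.8 A. The sequence is a per-state homopolymer code
#' (A for helix, V for strand, G for coil) — composition, not chemistry,
#' is what downstream consumers read.
#'
#' @param ss_layout data.frame with columns `state` (H/E/C) and `length`
#'   (residues).
#' @param seed integer seed (used for coil dihedrals).
#' @param id chain id for the result.
#' @param compact if `TRUE`, coil dihedrals are chosen greedily (from the
#'   same broad distribution) to steer the chain back toward its running
#'   centroid, emulating the compactness of a folded domain instead of an
#'   extended snake of secondary-structure elements. A chain built from
#'   independent coil dihedrals has the radius of gyration of a stiff
#'   random chain, several-fold larger than a folded domain of the same
#'   length; steered linkers restore domain-like extent while keeping all
#'   bond geometry ideal. Steering can also be restricted to part of the
#'   chain via `steer_mask`.
#' @param steer_mask optional logical per-residue vector limiting which coil
#'   residues are steered (default: all of them when `compact = TRUE`).
#' @return a [chain_structure] with backbone coordinates.
#' @examples
#' helix <- make_ideal_backbone(data.frame(state = "H", length = 20), seed = 1)
#' @export
make_ideal_backbone <- function(ss_layout, seed = 1L, id = "synthetic",
                                compact = FALSE, steer_mask = NULL) {
  if (NROW(ss_layout) == 0L) stopf("empty secondary-structure layout")
  states <- rep(as.character(ss_layout$state), times = ss_layout$length)
  L <- length(states)
  if (L < 2L) stopf("layout must cover at least 2 residues")
  if (!all(states %in% c("H", "E", "C"))) stopf("states must be H, E or C")
  if (is.null(steer_mask)) steer_mask <- rep(isTRUE(compact), L)
  if (length(steer_mask) != L) stopf("steer_mask length != layout length")
  steer_mask <- steer_mask & states == "C"

  n_xyz <- matrix(0, L, 3); ca_xyz <- matrix(0, L, 3)
  c_xyz <- matrix(0, L, 3); o_xyz <- matrix(0, L, 3)
  with_seed(seed, {
    phi <- numeric(L); psi <- numeric(L)
    for (i in seq_len(L)) {
      if (states[i] %in% names(PHI_PSI)) {
        phi[i] <- PHI_PSI[[states[i]]][1]
        psi[i] <- PHI_PSI[[states[i]]][2]
      } else {                       # broad coil distribution
        phi[i] <- stats::runif(1, -150, -60)
        psi[i] <- stats::runif(1, -70, 150)
      }
    }
    n_xyz[1, ] <- c(0, 0, 0)
    ca_xyz[1, ] <- c(BOND_N_CA, 0, 0)
    th <- (180 - ANG_N_CA_C) * pi / 180
    c_xyz[1, ] <- ca_xyz[1, ] + BOND_CA_C * c(cos(th), sin(th), 0)
    for (i in 2:L) {
      if (steer_mask[i - 1L]) {
        # greedy fold-back: among candidate psi draws, take the one whose
        # next CA lands closest to the centroid of the chain built so far
        cand <- stats::runif(12L, -70, 150)
        ctr <- colMeans(ca_xyz[seq_len(i - 1L), , drop = FALSE])
        best <- Inf
        for (ps in cand) {
          n_try <- nerf_place(n_xyz[i - 1, ], ca_xyz[i - 1, ], c_xyz[i - 1, ],
                              BOND_C_N, ANG_CA_C_N, ps)
          ca_try <- nerf_place(ca_xyz[i - 1, ], c_xyz[i - 1, ], n_try,
                               BOND_N_CA, ANG_C_N_CA, 180)
          d <- sum((ca_try - ctr)^2)
          if (d < best) { best <- d; psi[i - 1L] <- ps }
        }
      }
      n_xyz[i, ] <- nerf_place(n_xyz[i - 1, ], ca_xyz[i - 1, ], c_xyz[i - 1, ],
                               BOND_C_N, ANG_CA_C_N, psi[i - 1])
      ca_xyz[i, ] <- nerf_place(ca_xyz[i - 1, ], c_xyz[i - 1, ], n_xyz[i, ],
                                BOND_N_CA, ANG_C_N_CA, 180)
      c_xyz[i, ] <- nerf_place(c_xyz[i - 1, ], n_xyz[i, ], ca_xyz[i, ],
                               BOND_CA_C, ANG_N_CA_C, phi[i])
    }
    for (i in seq_len(L))
      o_xyz[i, ] <- nerf_place(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ],
                               BOND_C_O, ANG_CA_C_O, psi[i] + 180)
  })

  chain_structure(id = id, sequence = paste(STATE_AA[states], collapse = ""),
                  ca_coords = ca_xyz,
                  backbone_coords = list(n = n_xyz, c = c_xyz, o = o_xyz))
}

#' Specification of a synthetic target/prediction pair
#'
#' Describes a target with a rigid core flanked by flexible terminal tails,
#' and how its simulated "prediction" deviates from it: isotropic Gaussian
#' noise on the core, tails re-posed either rigidly about a hinge or as a
#' random walk, and region-wise Gaussian pLDDT. Defaults describe the
#' canonical tail-inflation scenario: an 80-residue mixed core with 0.5 A
#' coordinate noise and a 20-residue C-terminal tail hinged by 90 degrees,
#' confident core (pLDDT ~90) and low-confidence tail (~40).
#'
#' @param core_length rigid-core residues (>= 10).
#' @param tail_n,tail_c N-/C-terminal tail residues.
#' @param ss_layout optional core layout (data.frame state/length); default
#'   is a mixed helix/strand/coil layout filling `core_length`. Tails are
#'   always coil.
#' @param core_noise_sigma per-coordinate Gaussian noise sd (A).
#' @param tail_mode `"none"`, `"hinge"` or `"walk"`.
#' @param hinge_angle tail hinge rotation (degrees).
#' @param plddt_core,plddt_tail,plddt_sd region means and sd of the
#'   simulated confidence profile.
#' @param seed integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(core_length = 80L, tail_n = 0L, tail_c = 20L,
                           ss_layout = NULL, core_noise_sigma = 0.5,
                           tail_mode = c("hinge", "none", "walk"),
                           hinge_angle = 90, plddt_core = 90,
                           plddt_tail = 40, plddt_sd = 3, seed = 1L) {
  tail_mode <- match.arg(tail_mode)
  if (core_length < 2L) stopf("core_length must be >= 2")
  if (tail_n < 0L || tail_c < 0L) stopf("tail lengths must be >= 0")
  if (core_noise_sigma < 0) stopf("core_noise_sigma must be >= 0")
  if (any(c(plddt_core, plddt_tail) < 0 | c(plddt_core, plddt_tail) > 100))
    stopf("pLDDT means must lie in [0, 100]")
  if (is.null(ss_layout)) ss_layout <- default_core_layout(core_length)
  if (sum(ss_layout$length) != core_length)
    stopf("ss_layout covers %d residues, core_length is %d",
          sum(ss_layout$length), core_length)
  structure(list(core_length = as.integer(core_length),
                 tail_n = as.integer(tail_n), tail_c = as.integer(tail_c),
                 ss_layout = ss_layout, core_noise_sigma = core_noise_sigma,
                 tail_mode = tail_mode, hinge_angle = hinge_angle,
                 plddt_core = plddt_core, plddt_tail = plddt_tail,
                 plddt_sd = plddt_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# mixed alpha/beta core: repeat (H10 C5 E5 C5) — typical element/loop
# lengths in small globular domains — and trim to length
default_core_layout <- function(core_length) {
  unit <- data.frame(state = c("H", "C", "E", "C"), length = c(10, 5, 5, 5))
  reps <- ceiling(core_length / sum(unit$length))
  lay <- unit[rep(seq_len(4), reps), ]
  cum <- cumsum(lay$length)
  keep <- cum <= core_length
  lay <- lay[keep, , drop = FALSE]
  rem <- core_length - sum(lay$length)
  if (rem > 0) lay <- rbind(lay, data.frame(state = "C", length = rem))
  rownames(lay) <- NULL
  lay
}

#' Build the target structure described by a synthetic spec
#'
#' Core layout plus coil tails, built by [make_ideal_backbone()] with
#' compact steering of all coil residues: core linkers fold the secondary
#' structure elements into a domain-like arrangement, and tail coils adopt
#' collapsed conformations whose end-to-end extent follows the scaling of
#' real disordered segments (roughly 10-16 Angstrom for a 20-mer) rather
#' than the rod-like reach of stiff, independently drawn dihedrals.
#'
#' @param spec a [synthetic_spec].
#' @return a [chain_structure].
#' @export
make_target <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lay <- spec$ss_layout
  if (spec$tail_n > 0)
    lay <- rbind(data.frame(state = "C", length = spec$tail_n), lay)
  if (spec$tail_c > 0)
    lay <- rbind(lay, data.frame(state = "C", length = spec$tail_c))
  make_ideal_backbone(lay, seed = spec$seed, id = "target", compact = TRUE)
}

rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

#' Simulate a predicted model of a synthetic target
#'
#' Applies isotropic Gaussian displacement (sd `core_noise_sigma` per
#' coordinate, per residue) to the whole chain, then re-poses the tail
#' residues: `"hinge"` rotates each tail rigidly about its junction with the
#' core by `hinge_angle` around a random axis (a terminal region captured in
#' a different, but internally ordered, conformation); `"walk"` rebuilds the
#' tail as a 3.8 A/step random walk (disordered terminus). Per-residue pLDDT
#' is drawn Normal(core/tail mean, sd), clipped to [0, 100]. Deterministic
#' given `spec$seed`.
#'
#' @param target the [chain_structure] returned by [make_target()] (lengths
#'   must match the spec).
#' @param spec a [synthetic_spec].
#' @param seed RNG seed for the perturbation; defaults to `spec$seed + 1` so
#'   a spec yields one deterministic pair, but can be varied to draw many
#'   independent predictions of the same target.
#' @return a CA-trace [chain_structure] with `plddt` set.
#' @export
simulate_prediction <- function(target, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(target, "chain_structure"),
            inherits(spec, "synthetic_spec"))
  L <- chain_length(target)
  if (L != spec$core_length + spec$tail_n + spec$tail_c)
    stopf("target length %d does not match spec (%d core + %d + %d tails)",
          L, spec$core_length, spec$tail_n, spec$tail_c)
  ca <- target$ca_coords
  with_seed(seed, {
    ca <- ca + matrix(stats::rnorm(L * 3, 0, spec$core_noise_sigma), L, 3)
    n_idx <- if (spec$tail_n > 0) seq_len(spec$tail_n) else integer(0)
    c_idx <- if (spec$tail_c > 0) (L - spec$tail_c + 1L):L else integer(0)
    if (spec$tail_mode == "hinge") {
      for (side in list(list(idx = n_idx, pivot = spec$tail_n + 1L),
                        list(idx = c_idx, pivot = L - spec$tail_c))) {
        if (length(side$idx) == 0L) next
        axis <- stats::rnorm(3)
        rot <- rotation_about_axis(axis, spec$hinge_angle)
        pv <- ca[side$pivot, ]
        ca[side$idx, ] <- sweep(sweep(ca[side$idx, , drop = FALSE], 2, pv) %*%
                                  t(rot), 2, pv, FUN = "+")
      }
    } else if (spec$tail_mode == "walk") {
      for (side in list(list(idx = n_idx, pivot = spec$tail_n + 1L,
                             dir = -1L),
                        list(idx = c_idx, pivot = L - spec$tail_c,
                             dir = 1L))) {
        if (length(side$idx) == 0L) next
        pos <- ca[side$pivot, ]
        ord <- if (side$dir > 0) side$idx else rev(side$idx)
        for (i in ord) {
          step <- stats::rnorm(3)
          pos <- pos + 3.8 * step / sqrt(sum(step^2))
          ca[i, ] <- pos
        }
      }
    }
    region_tail <- c(n_idx, c_idx)
    plddt <- stats::rnorm(L, spec$plddt_core, spec$plddt_sd)
    if (length(region_tail))
      plddt[region_tail] <- stats::rnorm(length(region_tail), spec$plddt_tail,
                                         spec$plddt_sd)
    plddt <- pmin(100, pmax(0, plddt))
  })
  chain_structure(id = paste0(target$id, "_pred"), sequence = target$sequence,
                  ca_coords = ca, plddt = plddt,
                  residue_numbers = target$residue_numbers)
}

#' Generate a target/prediction pair in one call
#'
#' @param spec a [synthetic_spec].
#' @return list with elements `target` and `prediction`.
#' @export
synthetic_pair <- function(spec) {
  target <- make_target(spec)
  list(target = target, prediction = simulate_prediction(target, spec))
}

#' Simulate an MSA of controlled depth and diversity
#'
#' Each homolog row is the query with `Binomial(L, divergence)` substitutions
#' (uniform over the 19 other residues) and `Binomial(L, gap_rate)` gap
#' positions, independently per row. Deterministic given `seed`.
#'
#' @param query ungapped query sequence.
#' @param depth number of homolog rows (>= 0).
#' @param divergence expected substituted fraction per row, in [0, 1).
#' @param gap_rate expected gap fraction per row, in [0, 1).
#' @param seed integer seed.
#' @return an [msa].
#' @export
simulate_msa <- function(query, depth, divergence = 0.2, gap_rate = 0.05,
                         seed = 1L) {
  validate_aa_string(query, "query")
  if (depth < 0) stopf("depth must be >= 0")
  if (divergence < 0 || divergence >= 1 || gap_rate < 0 || gap_rate >= 1)
    stopf("divergence and gap_rate must lie in [0, 1)")
  L <- nchar(query)
  qc <- seq_chars(query)
  rows <- character(0)
  if (depth > 0) with_seed(seed, {
    rows <- vapply(seq_len(depth), function(r) {
      ch <- qc
      nsub <- stats::rbinom(1, L, divergence)
      if (nsub > 0) {
        pos <- sample.int(L, nsub)
        for (p in pos) {
          alt <- AA1[AA1 != ch[p]]
          ch[p] <- alt[sample.int(length(alt), 1L)]
        }
      }
      ngap <- stats::rbinom(1, L, gap_rate)
      if (ngap > 0) ch[sample.int(L, ngap)] <- "-"
      paste(ch, collapse = "")
    }, character(1))
  })
  msa(query, rows = rows, source = "simulated")
}

#' Logistic outcome model for simulated experimental labels
#'
#' @param intercept,beta_plddt,beta_scrmsd coefficients of the linear
#'   predictor `intercept + beta_plddt * pLDDT + beta_scrmsd * scRMSD`.
#' @param seed integer seed.
#' @return an object of class `outcome_model`.
#' @export
outcome_model <- function(intercept = 0, beta_plddt = 0, beta_scrmsd = 0,
                          seed = 1L) {
  structure(list(intercept = intercept, beta_plddt = beta_plddt,
                 beta_scrmsd = beta_scrmsd, seed = as.integer(seed)),
            class = "outcome_model")
}

#' Simulate binary experimental outcomes for design records
#'
#' Success probability is `plogis(intercept + beta_plddt * pLDDT +
#' beta_scrmsd * scRMSD)`; labels are independent Bernoulli draws,
#' deterministic given the model seed.
#'
#' @param records a `design_records` data.frame (columns `plddt_mean` and a
#'   scRMSD column).
#' @param model an [outcome_model].
#' @param scrmsd_col metric column used in the linear predictor.
#' @param dataset dataset tag for the resulting table.
#' @return outcome table data.frame (design_id, plddt_mean, scrmsd, outcome,
#'   dataset).
#' @export
simulate_outcomes <- function(records, model, scrmsd_col = "scrmsd_naive",
                              dataset = "synthetic") {
  stopifnot(inherits(model, "outcome_model"))
  eta <- model$intercept + model$beta_plddt * records$plddt_mean +
    model$beta_scrmsd * records[[scrmsd_col]]
  if (any(!is.finite(eta))) stopf("non-finite linear predictor")
  p <- stats::plogis(eta)
  out <- with_seed(model$seed, stats::rbinom(length(p), 1L, p))
  data.frame(design_id = records$design_id, plddt_mean = records$plddt_mean,
             scrmsd = records[[scrmsd_col]], outcome = out,
             dataset = dataset, stringsAsFactors = FALSE)
}
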