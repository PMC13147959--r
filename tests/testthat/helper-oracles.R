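# Independent oracles used across test files. Each deliberately avoids the
# code path it checks.

# Optimal-superposition RMSD by numerical minimization over a rotation
# parameterized by a unit quaternion (translation handled by centering).
quaternion_rmsd_oracle <- function(mobile, target, n_starts = 6) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(target, 2, colMeans(target))
  rot_from_quat <- function(v) {
    v <- v / sqrt(sum(v^2))
    a <- v[1]; b <- v[2]; c <- v[3]; d <- v[4]
    rbind(
      c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
      c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
      c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
  }
  obj <- function(v) {
    moved <- p %*% t(rot_from_quat(v))
    sqrt(mean(rowSums((moved - q)^2)))
  }
  best <- Inf
  starts <- rbind(c(1, 0, 0, 0), matrix(rnorm(4 * (n_starts - 1)),
                                        n_starts - 1, 4))
  for (k in seq_len(nrow(starts))) {
    fit <- optim(starts[k, ], obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))
    best <- min(best, fit$value)
  }
  best
}

# Mann-Whitney AUC by explicit iteration over all positive-negative pairs.
pair_counting_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (s in pos) total <- total + sum(s > neg) + 0.5 * sum(s == neg)
  total / (length(pos) * length(neg))
}

# Two-sided Fisher p by exhaustive enumeration with choose() arithmetic.
fisher_enumeration_oracle <- function(tab) {
  n <- sum(tab); r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- sapply(a_range, function(a)
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1))
  p_obs <- probs[a_range == tab[1, 1]]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Per-row weights by direct pairwise identity enumeration.
neff_weights_oracle <- function(rows, threshold) {
  n <- length(rows)
  split_rows <- lapply(rows, function(s) strsplit(s, "")[[1]])
  w <- numeric(n)
  for (i in seq_len(n)) {
    cnt <- 0
    for (j in seq_len(n)) {
      a <- split_rows[[i]]; b <- split_rows[[j]]
      keep <- a != "-" & b != "-"
      ident <- if (any(keep)) mean(a[keep] == b[keep]) else 0
      if (ident >= threshold) cnt <- cnt + 1
    }
    w[i] <- 1 / cnt
  }
  w
}

random_rigid_motion <- function() {
  # uniform-ish random rotation from QR of a Gaussian matrix, det corrected
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  list(rotation = r, translation = rnorm(3, sd = 10))
}

apply_rigid <- function(x, motion) {
  x %*% t(motion$rotation) + rep(1, nrow(x)) %o% motion$translation
}

# Explicit tailed pair: compact random core blob (identical in both frames)
# plus a tail laid out on an arc at fixed radius around the hinge in the
# xy-plane; the mobile frame carries the tail rotated 90 degrees about the
# z-axis through the hinge, so every tail residue deviates by exactly
# radius * sqrt(2) while the core is untouched.
make_hinged_pair <- function(n_core = 80, n_tail = 20, seed = 1,
                             radius = 10) {
  set.seed(seed)
  core <- matrix(rnorm(n_core * 3, sd = 8), n_core, 3)
  hinge <- core[n_core, ]
  theta <- 3.8 / radius * seq_len(n_tail)
  tail_t <- cbind(hinge[1] + radius * cos(theta),
                  hinge[2] + radius * sin(theta),
                  hinge[3])
  rot_z <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  tail_m <- sweep(sweep(tail_t, 2, hinge) %*% t(rot_z), 2, hinge, FUN = "+")
  list(target = rbind(core, tail_t), mobile = rbind(core, tail_m),
       tail_idx = n_core + seq_len(n_tail))
}

random_aa_seq <- function(L) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), L, replace = TRUE),
        collapse = "")
}
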