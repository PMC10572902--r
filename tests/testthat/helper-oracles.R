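# Independent oracles and small fixture builders used across the suite.

# second, independently coded torsion routine: project the outer bonds onto
# the plane perpendicular to the central bond and take the signed angle
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p1 - p2; b2 <- p3 - p2; b3 <- p4 - p3
  u2 <- b2 / sqrt(sum(b2^2))
  v1 <- b1 - sum(b1 * u2) * u2
  v2 <- b3 - sum(b3 * u2) * u2
  ang <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
  tri <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  s <- sign(sum(u2 * tri))
  deg <- ang * 180 / pi * ifelse(s == 0, 1, s)
  ((deg + 180) %% 360) - 180
}

rot_from_euler <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
  rz(a) %*% ry(b) %*% rz(c)
}

# brute-force minimum RMSD over proper rotations (translation optimal at
# matched centroids), multi-start Nelder-Mead
oracle_min_rmsd <- function(mobile, reference, n_starts = 25) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  f <- function(th) {
    r <- rot_from_euler(th[1], th[2], th[3])
    sqrt(mean(rowSums((p %*% t(r) - q)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    th0 <- stats::runif(3, -pi, pi)
    o <- stats::optim(th0, f, control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# brute-force maximum TM-score over rotations + translations: multi-start
# quasi-Newton ascent followed by a Nelder-Mead polish
oracle_max_tm <- function(mobile, reference, l_target = nrow(reference),
                          n_starts = 60) {
  d0 <- max(1.24 * max(l_target - 15, 0)^(1 / 3) - 1.8, 0.5)
  f <- function(par) {
    r <- rot_from_euler(par[1], par[2], par[3])
    moved <- mobile %*% t(r) + matrix(par[4:6], nrow(mobile), 3, byrow = TRUE)
    d <- sqrt(rowSums((moved - reference)^2))
    -sum(1 / (1 + (d / d0)^2)) / l_target
  }
  best <- Inf
  shift0 <- colMeans(reference) - colMeans(mobile)
  for (s in seq_len(n_starts)) {
    par0 <- c(stats::runif(3, -pi, pi), shift0 + stats::rnorm(3, 0, 1))
    o <- try(stats::optim(par0, f, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14)),
             silent = TRUE)
    if (!inherits(o, "try-error")) best <- min(best, o$value)
    par1 <- if (inherits(o, "try-error")) par0 else o$par
    o2 <- stats::optim(par1, f, control = list(maxit = 5000, reltol = 1e-15))
    best <- min(best, o2$value)
  }
  -best
}

# random plausible backbone: an ensemble built from random dihedrals
random_trace <- function(L, seed = 1) {
  set.seed(seed)
  build_backbone(data.frame(phi = c(NA, runif(L - 1, -180, 180)),
                            psi = c(runif(L - 1, -180, 180), NA)))
}

# apply a rigid motion to every frame of an ensemble
rigid_move_ensemble <- function(ens, rot, shift) {
  for (fr in seq_len(n_frames(ens))) {
    for (ai in 1:3) {
      xyz <- matrix(ens$xyz[fr, , ai, ], ncol = 3)
      ens$xyz[fr, , ai, ] <- xyz %*% t(rot) +
        matrix(shift, nrow(xyz), 3, byrow = TRUE)
    }
  }
  ens
}

# one-position profile vector concentrated on `letter`
point_profile <- function(letter) {
  f <- stats::setNames(rep(0, 16), PB_LETTERS)
  f[letter] <- 1
  f
}
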