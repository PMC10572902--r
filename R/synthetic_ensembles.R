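# Synthetic conformational ensembles with prescribed per-position Protein
# Block statistics. Each frame samples one PB letter per position; every
# 5-residue window centred on a sampled letter proposes the prototype's
# eight dihedrals for the residues it covers; overlapping proposals are
# averaged on the circle, wrapped-Gaussian noise is added, and Cartesian
# backbone coordinates are rebuilt by internal-coordinate (NeRF) chain
# construction with standard covalent geometry (N-CA 1.458 A, CA-C 1.525 A,
# C-N 1.329 A, omega = 180 deg). No physics is attempted: the generator
# reproduces PB occupancy statistics and backbone geometry, not
# thermodynamics, sterics or side chains.

.geom <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
              a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
              omega = 180)

#' Two-PB (or k-PB) profile with a prescribed Neq
#'
#' Inverts the Neq formula: finds the mixture `(p, (1-p)/(k-1), ...)` over
#' the given support whose Neq equals `target`, by bisection on the dominant
#' mass to 1e-9. With the default two-letter support this solves
#' `exp(-p ln p - (1-p) ln(1-p)) = target` for targets in [1, 2]; larger
#' targets need a larger support (up to all 16 letters for targets near 16).
#'
#' @param target desired Neq, in `[1, length(support)]`.
#' @param dominant PB letter carrying the largest mass.
#' @param alternate second support letter (two-PB case).
#' @param support optional character vector of support letters (first =
#'   dominant); overrides `dominant`/`alternate`.
#' @return named length-16 frequency vector summing to 1.
#' @export
profile_for_neq <- function(target, dominant = "d", alternate = "e",
                            support = NULL) {
  if (is.null(support)) support <- c(dominant, alternate)
  support <- unique(support)
  stopifnot(all(support %in% PB_LETTERS), length(support) >= 2)
  k <- length(support)
  if (target < 1 - 1e-12 || target > k + 1e-12) {
    stop("target Neq ", target, " unattainable with support size ", k)
  }
  target <- min(max(target, 1), k)
  mix <- function(p) {
    f <- rep((1 - p) / (k - 1), k); f[1] <- p
    f
  }
  # Neq is monotone decreasing in the dominant mass p on [1/k, 1]
  lo <- 1 / k; hi <- 1
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (neq(.embed_profile(mix(mid), support)) > target) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  .embed_profile(mix((lo + hi) / 2), support)
}

.embed_profile <- function(f, support) {
  out <- stats::setNames(rep(0, 16), PB_LETTERS)
  out[support] <- f
  out
}

#' Sample a PB matrix from per-position profiles
#'
#' Independent draws per frame and position.
#'
#' @param profiles L x 16 matrix of per-position PB frequencies (rows sum
#'   to 1), columns in alphabet order a..p; a named length-16 vector is
#'   recycled over `n_positions`.
#' @param n_frames number of frames.
#' @param seed RNG seed (optional; sampling uses the current RNG state if
#'   omitted).
#' @param n_positions used only when `profiles` is a single profile vector.
#' @return frames x positions PB character matrix (class `pb_matrix`).
#' @export
sample_pb_matrix <- function(profiles, n_frames, seed = NULL,
                             n_positions = NULL) {
  profiles <- .as_profile_matrix(profiles, n_positions)
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(stats::runif(n_frames * nrow(profiles)), n_frames)
  .letters_from_u(profiles, u)
}

.as_profile_matrix <- function(profiles, n_positions = NULL) {
  if (!is.matrix(profiles)) {
    stopifnot(length(profiles) == 16)
    profiles <- matrix(profiles, max(1, n_positions %||% 1), 16, byrow = TRUE)
  }
  stopifnot(ncol(profiles) == 16,
            all(abs(rowSums(profiles) - 1) < 1e-8), all(profiles >= 0))
  colnames(profiles) <- PB_LETTERS
  profiles
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# inverse-CDF letters from a uniform matrix (frames x positions)
.letters_from_u <- function(profiles, u) {
  L <- nrow(profiles)
  stopifnot(ncol(u) == L)
  m <- matrix(NA_character_, nrow(u), L,
              dimnames = list(NULL, as.character(seq_len(L))))
  for (j in seq_len(L)) {
    cdf <- cumsum(profiles[j, ])
    m[, j] <- PB_LETTERS[findInterval(u[, j], cdf, left.open = TRUE) + 1L]
  }
  structure(m, class = c("pb_matrix", class(m)))
}

#' Rebuild backbone coordinates from phi/psi dihedrals
#'
#' Internal-coordinate (NeRF) chain construction with standard covalent
#' geometry and trans peptide bonds (omega = 180 deg). Recomputing dihedrals
#' from the built coordinates reproduces the inputs to numerical precision.
#'
#' @param dihedrals data.frame with `phi`, `psi` columns in degrees (phi of
#'   residue 1 and psi of the last residue are ignored).
#' @return backbone trace: list of L x 3 matrices `n`, `ca`, `c`.
#' @export
build_backbone <- function(dihedrals) {
  xyz <- .build_frames(matrix(dihedrals$phi, 1), matrix(dihedrals$psi, 1))
  L <- length(dihedrals$phi)
  list(n  = matrix(xyz[1, , 1, ], L, 3),
       ca = matrix(xyz[1, , 2, ], L, 3),
       c  = matrix(xyz[1, , 3, ], L, 3),
       bfactor = rep(NA_real_, L))
}

# frames-vectorised NeRF: phi, psi are F x L matrices -> [F, L, 3, 3] array
.build_frames <- function(phi, psi) {
  f <- nrow(phi); L <- ncol(phi)
  stopifnot(L >= 2, identical(dim(phi), dim(psi)))
  g <- .geom
  xyz <- array(NA_real_, c(f, L, 3, 3))
  n  <- matrix(rep(c(0, 0, 0), each = f), f, 3)
  ca <- matrix(rep(c(g$b_n_ca, 0, 0), each = f), f, 3)
  ang <- g$a_n_ca_c * pi / 180
  c_ <- ca + g$b_ca_c * matrix(rep(c(-cos(ang), sin(ang), 0), each = f), f, 3)
  xyz[, 1, 1, ] <- n; xyz[, 1, 2, ] <- ca; xyz[, 1, 3, ] <- c_
  for (i in 2:L) {
    n2  <- place_atom(n, ca, c_, g$b_c_n, g$a_ca_c_n, psi[, i - 1])
    ca2 <- place_atom(ca, c_, n2, g$b_n_ca, g$a_c_n_ca, rep(g$omega, f))
    c2  <- place_atom(c_, n2, ca2, g$b_ca_c, g$a_n_ca_c, phi[, i])
    xyz[, i, 1, ] <- n2; xyz[, i, 2, ] <- ca2; xyz[, i, 3, ] <- c2
    n <- n2; ca <- ca2; c_ <- c2
  }
  xyz
}

# per-residue phi/psi (F x L matrices) from sampled letters (F x L) by
# circular averaging of the prototype-window proposals that cover each angle
.angles_from_letters <- function(letters_m, prototypes = pb_reference_table()) {
  f <- nrow(letters_m); L <- ncol(letters_m)
  idx <- matrix(match(letters_m, rownames(prototypes)), f, L)
  # angle slot s of the window centred at w proposes:
  #   phi(j): (w = j+1, s2) (w = j, s4) (w = j-1, s6) (w = j-2, s8)
  #   psi(j): (w = j+2, s1) (w = j+1, s3) (w = j, s5) (w = j-1, s7)
  gather <- function(slots, shifts) {
    s_sin <- s_cos <- cnt <- matrix(0, f, L)
    for (k in seq_along(slots)) {
      w <- seq_len(L) + shifts[k]
      ok <- which(w >= 1 & w <= L)
      a <- matrix(prototypes[cbind(as.vector(idx[, w[ok]]), slots[k])],
                  f, length(ok)) * pi / 180
      s_sin[, ok] <- s_sin[, ok] + sin(a)
      s_cos[, ok] <- s_cos[, ok] + cos(a)
      cnt[, ok] <- cnt[, ok] + 1
    }
    out <- atan2(s_sin, s_cos) * 180 / pi
    out[cnt == 0] <- NA_real_
    wrap_angle(out)
  }
  list(phi = gather(c(2L, 4L, 6L, 8L), c(1L, 0L, -1L, -2L)),
       psi = gather(c(1L, 3L, 5L, 7L), c(2L, 1L, 0L, -1L)))
}

#' Generate a synthetic ensemble with prescribed PB statistics
#'
#' @param profiles L x 16 per-position PB frequency matrix (see
#'   [profile_for_neq()], [vhh_template_profiles()]).
#' @param n_frames frames to generate (the case study mirrors 1 microsecond
#'   of dynamics saved every 100 ps, i.e. 10,000 frames per system).
#' @param noise wrapped-Gaussian dihedral noise, standard deviation in
#'   degrees, added independently to every phi/psi.
#' @param seed RNG seed for reproducibility.
#' @param aa residue one-letter codes (default poly-alanine).
#' @param letters_m optional pre-sampled frames x positions PB letter
#'   matrix; overrides sampling from `profiles`.
#' @return an [ensemble] with extra fields `true_letters` (the sampled PB
#'   states) and `true_profiles`.
#' @export
make_ensemble <- function(profiles, n_frames = 100L, noise = 5, seed = NULL,
                          aa = NULL, letters_m = NULL) {
  profiles <- .as_profile_matrix(profiles)
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(profiles)
  if (is.null(letters_m)) {
    u <- matrix(stats::runif(n_frames * L), n_frames)
    letters_m <- .letters_from_u(profiles, u)
  } else {
    n_frames <- nrow(letters_m)
  }
  ang <- .angles_from_letters(letters_m)
  if (noise > 0) {
    ang$phi <- wrap_angle(ang$phi + matrix(stats::rnorm(n_frames * L, 0, noise),
                                           n_frames))
    ang$psi <- wrap_angle(ang$psi + matrix(stats::rnorm(n_frames * L, 0, noise),
                                           n_frames))
  }
  xyz <- .build_frames(ang$phi, ang$psi)
  ens <- ensemble(xyz, aa %||% rep("A", L), frame_spacing_ps = 100)
  ens$true_letters <- letters_m
  ens$true_profiles <- profiles
  ens
}

#' Generate a matched pair of ensembles with localized profile differences
#'
#' The two systems share PB-state draws (inverse-CDF coupling on common
#' uniforms), so they are identical wherever their profiles agree. At the
#' override window the second system redraws its states; by default the
#' overridden positions switch coherently per frame (one uniform per frame
#' for the whole window), emulating a loop that changes conformation as a
#' unit.
#'
#' @param profiles base L x 16 profile matrix (system 1).
#' @param overrides list of overrides, each a list with `positions` (integer
#'   vector) and `profile` (length-16 vector, or |positions| x 16 matrix
#'   giving one profile per overridden position), plus optional
#'   `coherent = TRUE`.
#' @param n_frames,noise,seed,aa as in [make_ensemble()].
#' @param coords set `FALSE` to skip coordinate building and return the
#'   sampled PB matrices only (fast path for statistical checks).
#' @return list with elements `first`, `second` (ensembles, or `pb_matrix`
#'   objects when `coords = FALSE`), `profiles_first`, `profiles_second` and
#'   `analytic_delta_pb` (per-position L1 distance of the two profile sets).
#' @export
make_pair <- function(profiles, overrides = list(), n_frames = 100L,
                      noise = 5, seed = NULL, aa = NULL, coords = TRUE) {
  p1 <- .as_profile_matrix(profiles)
  L <- nrow(p1)
  p2 <- p1
  for (ov in overrides) {
    stopifnot(all(ov$positions >= 1), all(ov$positions <= L))
    prof <- ov$profile
    if (!is.matrix(prof)) {
      prof <- matrix(prof, length(ov$positions), 16, byrow = TRUE)
    }
    p2[ov$positions, ] <- .as_profile_matrix(prof)
  }
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(stats::runif(n_frames * L), n_frames)
  s1 <- .letters_from_u(p1, u)
  u2 <- u
  for (ov in overrides) {
    coherent <- ov$coherent %||% TRUE
    if (coherent) {
      u2[, ov$positions] <- stats::runif(n_frames)
    } else {
      u2[, ov$positions] <- stats::runif(n_frames * length(ov$positions))
    }
  }
  s2 <- .letters_from_u(p2, u2)
  out <- list(profiles_first = p1, profiles_second = p2,
              analytic_delta_pb = rowSums(abs(p1 - p2)))
  if (coords) {
    noise1 <- noise2 <- NULL
    if (noise > 0) {
      # shared noise: the two systems differ only through their PB states
      noise1 <- matrix(stats::rnorm(n_frames * L, 0, noise), n_frames)
      noise2 <- matrix(stats::rnorm(n_frames * L, 0, noise), n_frames)
    }
    build <- function(lm) {
      ang <- .angles_from_letters(lm)
      if (!is.null(noise1)) {
        ang$phi <- wrap_angle(ang$phi + noise1)
        ang$psi <- wrap_angle(ang$psi + noise2)
      }
      ens <- ensemble(.build_frames(ang$phi, ang$psi), aa %||% rep("A", L),
                      frame_spacing_ps = 100)
      ens$true_letters <- lm
      ens
    }
    out$first <- build(s1)
    out$second <- build(s2)
  } else {
    out$first <- s1
    out$second <- s2
  }
  out
}

#' RMSF profile of the VHH-like template
#'
#' Per-position target root-mean-square fluctuations (Angstrom) emulating
#' the canonical VHH layout: frayed termini, the FR2 loop as the most
#' mobile region (about 2 Angstrom), a mobile central FR3 loop, CDR1/CDR2
#' around 1 Angstrom, CDR3 slightly below, and beta-strands near 0.5.
#'
#' @return numeric vector of 121 target RMSF values in Angstrom.
#' @export
vhh_template_rmsf <- function() {
  r <- rep(0.5, 121)
  r[1:3] <- c(2.5, 1.8, 1.2)           # N-terminal fraying
  r[26:30] <- 1.0                      # CDR1
  r[35:41] <- c(1.2, 1.6, 2.0, 2.2, 2.0, 1.6, 1.2)  # FR2 loop
  r[49:56] <- 1.0                      # CDR2
  r[57:60] <- 0.9                      # beginning of FR3
  r[69:75] <- c(0.9, 1.2, 1.6, 1.6, 1.4, 1.1, 0.8)  # central FR3 loop
  r[94:109] <- 0.8                     # CDR3
  r[119:121] <- c(1.2, 1.8, 2.5)       # C-terminal fraying
  r
}

#' Ensemble with a prescribed per-residue RMSF profile
#'
#' Frames are a fixed base conformation plus isotropic Gaussian jitter with
#' per-residue standard deviation `target_rmsf / sqrt(3)` on every backbone
#' coordinate, so the raw (unsuperposed) per-residue CA RMSF converges to
#' the target. This is the controllable-RMSF counterpart of
#' [make_ensemble()], which controls PB statistics instead: dihedral-space
#' generation leaves global Cartesian fluctuations uncontrolled (a local
#' angle change levers the whole downstream chain), so RMSF studies use
#' this generator.
#'
#' @param target_rmsf numeric vector of per-residue RMSF targets (Angstrom).
#' @param n_frames frames to generate.
#' @param seed RNG seed.
#' @param base optional backbone trace (list with L x 3 `n`, `ca`, `c`);
#'   defaults to an extended-strand chain of matching length.
#' @param aa residue codes (default poly-alanine).
#' @return an [ensemble] with extra field `target_rmsf`.
#' @export
make_rmsf_ensemble <- function(target_rmsf, n_frames = 100L, seed = NULL,
                               base = NULL, aa = NULL) {
  L <- length(target_rmsf)
  stopifnot(all(target_rmsf >= 0), n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(base)) {
    base <- build_backbone(data.frame(phi = c(NA, rep(-120, L - 1)),
                                      psi = c(rep(130, L - 1), NA)))
  }
  s <- target_rmsf / sqrt(3)
  xyz <- array(NA_real_, c(n_frames, L, 3, 3))
  for (ai in 1:3) {
    base_m <- base[[c("n", "ca", "c")[ai]]]
    xyz[, , ai, ] <- rep(base_m, each = n_frames) +
      stats::rnorm(n_frames * L * 3) * rep(s, each = n_frames)
  }
  ens <- ensemble(xyz, aa %||% rep("A", L))
  ens$target_rmsf <- target_rmsf
  ens
}

#' Five-residue ensemble realising one PB prototype window
#'
#' Builds frames of a 5-residue backbone whose eight dihedrals are exactly
#' the prototype window of the given PB letter (plus optional
#' wrapped-Gaussian noise), so the single complete window — centred on
#' residue 3 — re-encodes to that letter. This is the exact zero-noise
#' round trip through [build_backbone()] and [encode_ensemble()]: a
#' homogeneous run of most PB letters is geometrically self-contradictory
#' (overlapping windows impose conflicting angles on shared residues), so
#' per-window construction is the faithful recovery statement.
#'
#' @param letter a PB letter a..p.
#' @param n_frames frames to build.
#' @param noise wrapped-Gaussian dihedral noise (degrees).
#' @param seed RNG seed.
#' @return an [ensemble] of 5 residues.
#' @export
prototype_window_ensemble <- function(letter, n_frames = 1L, noise = 0,
                                      seed = NULL) {
  stopifnot(letter %in% PB_LETTERS)
  if (!is.null(seed)) set.seed(seed)
  th <- pb_reference_table()[letter, ]
  phi <- matrix(rep(c(0, th[2], th[4], th[6], th[8]), each = n_frames),
                n_frames, 5)
  psi <- matrix(rep(c(th[1], th[3], th[5], th[7], 0), each = n_frames),
                n_frames, 5)
  if (noise > 0) {
    phi <- wrap_angle(phi + matrix(stats::rnorm(5 * n_frames, 0, noise),
                                   n_frames))
    psi <- wrap_angle(psi + matrix(stats::rnorm(5 * n_frames, 0, noise),
                                   n_frames))
  }
  ensemble(.build_frames(phi, psi), rep("A", 5))
}

#' A VHH-like synthetic 121-residue sequence
#'
#' Synthetic stand-in for a camelid single-domain sequence: the residues at
#' every position touched by the built-in humanization mutation sets carry
#' the documented wild-type amino acid; all other positions are filler. It
#' is not a natural sequence.
#'
#' @return character vector of 121 one-letter codes.
#' @export
vhh_synthetic_sequence <- function() {
  s <- rep(c("G", "S", "T", "V", "L", "A", "Y", "S", "G", "T"), length.out = 121)
  fixed <- c("5" = "Q", "11" = "S", "14" = "A", "23" = "S", "34" = "F",
             "41" = "E", "42" = "R", "44" = "G", "69" = "Q", "76" = "V",
             "84" = "K", "85" = "P", "90" = "M", "95" = "A", "116" = "E")
  s[as.integer(names(fixed))] <- fixed
  s
}

# per-region mean Neq of the VHH flexibility layout the template encodes
.vhh_region_mean_neq <- c(FR1 = 1.20, CDR1 = 1.45, FR2 = 1.04, CDR2 = 1.27,
                          FR3 = 1.24, CDR3 = 1.52, FR4 = 1.09)

#' Default VHH-like per-position PB profile template
#'
#' A 121-position profile matrix emulating the flexibility layout of a VHH
#' domain: framework beta-strands locally rigid (Neq 1), loops mildly
#' variable, CDRs on average more variable than frameworks, a CDR1 loop
#' carrying the dfbdcfb motif at positions 23-29, a kbfkipm motif in CDR3
#' (102-108), and three strong peaks (positions 62 and 72 in FR3, 97 in
#' CDR3, the only positions above Neq 3). Per-region mean Neq is allocated
#' exactly: fixed peak values plus shoulder positions whose excesses are
#' scaled so each region of [default_region_map()] attains the layout means
#' FR1 1.20, CDR1 1.45, FR2 1.04, CDR2 1.27, FR3 1.24, CDR3 1.52, FR4 1.09.
#'
#' @return 121 x 16 profile matrix with attributes `target_neq` and
#'   `dominant` (the per-position template PB letters).
#' @export
vhh_template_profiles <- function() {
  L <- 121L
  dom <- rep("d", L)
  # loop motifs over an extended-strand scaffold
  dom[1:2]    <- "c"                                    # N-terminal cap
  dom[23:29]  <- strsplit("dfbdcfb", "")[[1]]           # CDR1 loop
  dom[36:40]  <- c("e", "h", "i", "a", "c")             # FR2 loop
  dom[50:55]  <- c("e", "h", "j", "a", "c", "d")        # CDR2 loop
  dom[60:64]  <- c("g", "o", "p", "a", "c")             # FR3 unusual loop at 62
  dom[70:74]  <- c("e", "h", "i", "a", "c")             # FR3 loop at 72
  dom[80:84]  <- c("f", "k", "b", "c", "d")
  dom[95:99]  <- c("k", "l", "o", "p", "a")             # CDR3 loop at 97
  dom[102:108] <- c("k", "b", "f", "k", "i", "p", "m")  # CDR3 tail motif
  dom[119:121] <- c("m", "n", "o")                      # C-terminal helix turn

  # Neq above the rigid baseline: fixed peaks, plus shoulders rescaled per
  # region so every region mean lands exactly on the layout value
  fixed <- c("61" = 1.05, "62" = 2.5, "63" = 1.05,      # FR3 peak at 62
             "71" = 1.02, "72" = 2.2,                   # FR3 peak at 72
             "96" = 1.10, "97" = 2.4, "98" = 1.2,       # CDR3 peak at 97
             "106" = 1.05)
  shoulders <- list(
    FR1  = c("3" = 0.40, "8" = 0.10, "10" = 0.15, "14" = 0.30, "15" = 0.45,
             "16" = 0.25, "17" = 0.10, "20" = 0.15, "21" = 0.30, "22" = 0.45,
             "23" = 0.70, "24" = 0.85, "25" = 0.80),
    CDR1 = c("26" = 0.60, "27" = 0.50, "28" = 0.50, "29" = 0.40, "30" = 0.25),
    FR2  = c("33" = 0.05, "36" = 0.20, "37" = 0.25, "38" = 0.12, "39" = 0.10),
    CDR2 = c("50" = 0.30, "51" = 0.50, "52" = 0.46, "53" = 0.40, "54" = 0.30,
             "55" = 0.20),
    FR3  = c("60" = 0.40, "64" = 0.35, "70" = 0.30, "73" = 0.45, "74" = 0.20,
             "81" = 0.30, "82" = 0.35, "83" = 0.20),
    CDR3 = c("95" = 0.20, "99" = 0.70, "100" = 0.22, "102" = 0.50,
             "103" = 0.60, "107" = 0.50, "109" = 0.30),
    FR4  = c("119" = 0.30, "120" = 0.40, "121" = 0.38))

  target <- rep(1.0, L)
  target[as.integer(names(fixed))] <- target[as.integer(names(fixed))] + fixed
  regions <- default_region_map()
  for (r in seq_len(nrow(regions))) {
    span <- regions$start[r]:regions$end[r]
    budget <- .vhh_region_mean_neq[[regions$name[r]]] * length(span) -
      sum(target[span])
    sh <- shoulders[[regions$name[r]]]
    target[as.integer(names(sh))] <- target[as.integer(names(sh))] +
      sh * budget / sum(sh)
  }

  # alternate (second-support) letter: the next PB letter, except in the
  # CDR1 loop where alternates are fixed to stay disjoint from the
  # humanized e/d/j/d motif used in paired-system studies
  alt <- PB_LETTERS[match(dom, PB_LETTERS) %% 16 + 1]
  alt[23:29] <- c("c", "g", "c", "e", "b", "g", "c")

  prof <- matrix(0, L, 16, dimnames = list(NULL, PB_LETTERS))
  for (i in seq_len(L)) {
    if (target[i] <= 2) {
      prof[i, ] <- profile_for_neq(target[i], dom[i], alt[i])
    } else {
      sup <- unique(c(dom[i], alt[i], PB_LETTERS))[1:ceiling(target[i] + 1)]
      prof[i, ] <- profile_for_neq(target[i], support = sup)
    }
  }
  attr(prof, "target_neq") <- target
  attr(prof, "dominant") <- dom
  prof
}
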