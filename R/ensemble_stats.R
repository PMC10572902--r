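# Per-position flexibility and comparison statistics over Protein Block
# matrices and coordinate ensembles.
#
# Neq = exp(-sum_x f_x ln f_x) is the exponential of the Shannon entropy of
# a position's PB frequency profile: 1 means one block only (local
# rigidity), 16 a uniform spread over the whole alphabet. Delta-PB is the L1
# distance between two profiles (0 identical, 2 disjoint); Delta-PB / 2 is
# the fraction of occurrences that differ (total-variation distance).

#' Per-position Protein Block frequency profiles
#'
#' Frequencies are taken over assigned (non-Z) frames only; a position with
#' zero assigned frames (e.g. the two positions at each terminus) gets an
#' all-`NA` row.
#'
#' @param matrix_pb frames x positions PB character matrix (see
#'   [encode_ensemble()]).
#' @return positions x 16 numeric matrix of frequencies `f_x`, columns a..p,
#'   with attribute `n_assigned` (assigned-frame count per position); class
#'   `pb_profile`.
#' @export
pb_profiles <- function(matrix_pb) {
  m <- unclass(matrix_pb)
  stopifnot(is.matrix(m), nrow(m) >= 1)
  L <- ncol(m)
  counts <- vapply(seq_len(L), function(j) {
    tabulate(match(m[, j], PB_LETTERS), nbins = 16L)
  }, numeric(16))
  counts <- t(counts)                      # L x 16
  n_assigned <- rowSums(counts)
  freq <- counts / ifelse(n_assigned > 0, n_assigned, NA_real_)
  dimnames(freq) <- list(as.character(seq_len(L)), PB_LETTERS)
  structure(freq, n_assigned = as.integer(n_assigned),
            class = c("pb_profile", "matrix", "array"))
}

.profile_rows <- function(profile) {
  if (is.matrix(profile)) unclass(profile) else matrix(profile, nrow = 1)
}

#' Equivalent number of Protein Blocks (Neq)
#'
#' `exp(-sum f_x ln f_x)` with the `0 * ln 0 = 0` convention; 1 for a
#' single-block profile, 16 for the uniform profile. Undefined (all-`NA`)
#' profiles propagate `NA`, never a silent 1.
#'
#' @param profile a length-16 frequency vector or a positions x 16 profile
#'   matrix (see [pb_profiles()]).
#' @return numeric vector of Neq values in `[1, 16]` (or `NA`).
#' @export
neq <- function(profile) {
  p <- .profile_rows(profile)
  stopifnot(ncol(p) == 16)
  h <- -rowSums(ifelse(p > 0, p * log(p), 0))
  out <- exp(h)
  out[rowSums(is.na(p)) > 0] <- NA_real_
  unname(out)
}

#' Delta-PB: L1 distance between two PB profiles
#'
#' `sum_x |f_x^1 - f_x^2|`, in `[0, 2]`; `delta_pb / 2` is the fraction of
#' PB occurrences that differ between the two systems.
#'
#' @param first,second length-16 frequency vectors, or profile matrices of
#'   equal dimensions (compared row by row).
#' @return numeric vector of Delta-PB values; `NA` where either profile is
#'   undefined.
#' @export
delta_pb <- function(first, second) {
  a <- .profile_rows(first); b <- .profile_rows(second)
  stopifnot(ncol(a) == 16, identical(dim(a), dim(b)))
  unname(rowSums(abs(a - b)))
}

#' Per-position |Neq difference| between two systems
#'
#' @param first,second numeric Neq series of equal length.
#' @return numeric vector of absolute differences.
#' @export
delta_neq <- function(first, second) {
  if (length(first) != length(second)) stop("series lengths differ")
  abs(first - second)
}

# mean structure of the CA trace after superposing all frames on `ref_ca`
.superposed_ca <- function(x, ref_ca) {
  f <- n_frames(x); L <- n_residues(x)
  out <- array(NA_real_, c(f, L, 3))
  for (fr in seq_len(f)) {
    ca <- matrix(x$xyz[fr, , 2, ], L, 3)
    out[fr, , ] <- kabsch_superpose(ca, ref_ca)$coords
  }
  out
}

#' Root mean square fluctuation of CA atoms
#'
#' Every frame is least-squares superposed onto the ensemble-average
#' structure (average taken after a first superposition onto frame 1, then
#' re-superposed once onto that average) before fluctuations about the mean
#' CA position are measured.
#'
#' @param x an [ensemble] with at least 2 frames (a single frame yields all
#'   zeros with a warning).
#' @param superpose set `FALSE` to measure fluctuations in the raw frame
#'   coordinates.
#' @return numeric vector of per-residue RMSF in Angstrom.
#' @export
rmsf <- function(x, superpose = TRUE) {
  stopifnot(inherits(x, "ensemble"))
  f <- n_frames(x); L <- n_residues(x)
  if (f < 2) {
    warning("single-frame ensemble: RMSF is identically zero")
    return(rep(0, L))
  }
  if (superpose) {
    ref <- matrix(x$xyz[1, , 2, ], L, 3)
    avg <- apply(.superposed_ca(x, ref), c(2, 3), mean)
    ca <- .superposed_ca(x, avg)
  } else {
    ca <- array(x$xyz[, , 2, ], c(f, L, 3))
  }
  mu <- apply(ca, c(2, 3), mean)
  dev2 <- (ca - rep(mu, each = f))^2
  sqrt(colMeans(dev2[, , 1] + dev2[, , 2] + dev2[, , 3]))
}

#' CA RMSD of every frame against a reference frame
#'
#' @param x an [ensemble].
#' @param reference index of the reference frame (default the first, the
#'   usual convention for trajectory drift plots).
#' @return numeric vector of per-frame RMSD in Angstrom after Kabsch
#'   superposition.
#' @export
rmsd_timeseries <- function(x, reference = 1L) {
  stopifnot(inherits(x, "ensemble"))
  L <- n_residues(x)
  ref <- matrix(x$xyz[reference, , 2, ], L, 3)
  vapply(seq_len(n_frames(x)), function(fr) {
    kabsch_superpose(matrix(x$xyz[fr, , 2, ], L, 3), ref)$rmsd
  }, numeric(1))
}

#' Correlation between two per-position series
#'
#' Pearson by default (Spearman available); optionally drops a fixed number
#' of positions at each terminus, where fraying dominates both B-factors and
#' RMSF.
#'
#' @param a,b numeric series of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @param exclude_extremities drop `n_excluded` positions at each end first.
#' @param n_excluded how many positions to drop per end (default 3).
#' @return the correlation coefficient; `NA` with a warning if either series
#'   has zero variance.
#' @export
correlate <- function(a, b, method = c("pearson", "spearman"),
                      exclude_extremities = FALSE, n_excluded = 3L) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("series lengths differ")
  if (exclude_extremities) {
    keep <- (n_excluded + 1):(length(a) - n_excluded)
    if (length(keep) < 3) stop("fewer than 3 positions left after exclusion")
    a <- a[keep]; b <- b[keep]
  }
  ok <- stats::complete.cases(a, b)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a[ok], b[ok], method = method)
}

#' Per-region means of a per-position series
#'
#' @param series numeric per-position values (`NA` positions excluded).
#' @param regions a [region_map()] whose length matches the series.
#' @return data.frame with columns `region`, `mean`, `n`.
#' @export
region_summary <- function(series, regions) {
  if (length(series) != regions$end[nrow(regions)]) {
    stop("series length does not match region map")
  }
  reg <- region_of(seq_along(series), regions)
  reg <- factor(reg, levels = regions$name)
  data.frame(region = regions$name,
             mean = as.numeric(tapply(series, reg, mean, na.rm = TRUE)),
             n = as.integer(tapply(!is.na(series), reg, sum)))
}

#' Flexibility class of an Neq value
#'
#' The conventional reading of Neq: 1 is total local rigidity, values below
#' 2 low flexibility, 4 the classical threshold for a flexible position.
#'
#' @param x numeric Neq values (must be >= 1).
#' @return factor with levels rigid, low, intermediate, flexible; `NA` in,
#'   `NA` out.
#' @export
classify_flexibility <- function(x) {
  if (any(x < 1 - 1e-6, na.rm = TRUE)) stop("Neq below 1")
  cls <- ifelse(abs(x - 1) <= 1e-6, "rigid",
         ifelse(x < 2, "low",
         ifelse(x <= 4, "intermediate", "flexible")))
  factor(cls, levels = c("rigid", "low", "intermediate", "flexible"))
}

#' Information-content PB logo stacks
#'
#' WebLogo-style column stacks over the 16-letter PB alphabet: the column
#' information content is `R = log2(16) - H` bits (H the Shannon entropy of
#' the column profile, in bits; no small-sample correction) and each letter
#' is drawn with height `f_x * R`, stacked by ascending frequency.
#'
#' @param matrix_pb frames x positions PB matrix.
#' @param positions positions (columns) to include.
#' @return list, one element per position: list with `position`, `R`
#'   (bits) and `letters` (data.frame letter/frequency/height, ascending
#'   frequency, zero-frequency letters dropped). Undefined columns give an
#'   empty stack with `R = NA`.
#' @export
pb_logo <- function(matrix_pb, positions = seq_len(ncol(matrix_pb))) {
  stopifnot(all(positions >= 1), all(positions <= ncol(matrix_pb)))
  prof <- pb_profiles(matrix_pb)
  lapply(positions, function(p) {
    f <- unclass(prof)[p, ]
    if (anyNA(f)) {
      return(list(position = p, R = NA_real_,
                  letters = data.frame(letter = character(0),
                                       frequency = numeric(0),
                                       height = numeric(0))))
    }
    h_bits <- -sum(ifelse(f > 0, f * log2(f), 0))
    r <- log2(16) - h_bits
    keep <- which(f > 0)
    ord <- keep[order(f[keep])]
    list(position = p, R = r,
         letters = data.frame(letter = PB_LETTERS[ord],
                              frequency = unname(f[ord]),
                              height = unname(f[ord] * r)))
  })
}
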