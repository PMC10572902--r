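# Low-level backbone geometry: angle wrapping, torsions, internal-coordinate
# atom placement. All routines are row-vectorised: coordinate arguments are
# n x 3 matrices and angle arguments length-n vectors, so per-frame work on
# whole ensembles stays in vectorised code.

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  w <- x %% 360
  out <- ifelse(w > 180, w - 360, w)
  # keep NA, map -0 to 0
  out + 0
}

# circular mean of angles in degrees, NA-tolerant; x is a vector or a matrix
# whose rows are averaged
circular_mean <- function(x) {
  if (is.matrix(x)) {
    r <- x * pi / 180
    s <- rowMeans(sin(r), na.rm = TRUE)
    c_ <- rowMeans(cos(r), na.rm = TRUE)
    out <- atan2(s, c_) * 180 / pi
    out[!is.finite(s) | !is.finite(c_)] <- NA_real_
    wrap_angle(out)
  } else {
    circular_mean(matrix(x, nrow = 1))[1]
  }
}

# row-wise cross product of n x 3 matrices
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norm <- function(a) sqrt(rowSums(a * a))

normalize_rows <- function(a) a / row_norm(a)

#' Torsion angle of four points
#'
#' Standard IUPAC sign convention; inputs are n x 3 matrices (or length-3
#' vectors) of Cartesian coordinates, output is in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 coordinates of the four atoms defining the torsion.
#' @return numeric vector of torsion angles in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross_rows(b1, b2)
  n2 <- cross_rows(b2, b3)
  m1 <- cross_rows(n1, normalize_rows(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  wrap_angle(atan2(-y, x) * 180 / pi)
}

# NeRF placement: given three placed atoms A-B-C (n x 3 each), place D with
# |C-D| = bond, angle(B,C,D) = angle_deg and torsion(A,B,C,D) = torsion_deg.
place_atom <- function(a, b, c_, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- normalize_rows(c_ - b)
  n <- normalize_rows(cross_rows(b - a, bc))
  m <- cross_rows(n, bc)
  d2 <- cbind(-bond * cos(ang),
              bond * sin(ang) * cos(tor),
              bond * sin(ang) * sin(tor))
  c_ + d2[, 1] * bc + d2[, 2] * m + d2[, 3] * n
}

# random proper rotation matrix (uniform via QR of Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
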