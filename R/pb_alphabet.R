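# The 16-letter Protein Blocks (PB) structural alphabet. Each block is a
# prototype of the local backbone conformation of five consecutive residues,
# described by eight dihedral angles
#   psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1), psi(i+1), phi(i+2)
# centred on residue i. Block m is the alpha-helix core prototype and block d
# the central beta-strand prototype; a-c are strand N-caps, e-f strand C-caps,
# g-j coil, k-l helix N-caps and n-p helix C-caps.

#' PB letters a..p
#' @export
PB_LETTERS <- letters[1:16]

#' Unassignable marker used where a full dihedral window is not defined
#' @export
PB_UNDEF <- "Z"

.pb_angle_names <- c("psi_m2", "phi_m1", "psi_m1", "phi", "psi",
                     "phi_p1", "psi_p1", "phi_p2")

.pb_reference <- matrix(c(
   41.14,   75.53,  13.92,  -99.80, 131.88,  -96.27, 122.08,  -99.68,  # a
  108.24,  -90.12, 119.54,  -92.21, -18.06, -128.93, 147.04,  -99.90,  # b
  -11.61, -105.66,  94.81, -106.09, 133.56, -106.93, 135.97, -100.63,  # c
  141.98, -112.79, 132.20, -114.79, 140.11, -111.05, 139.54, -103.16,  # d
  133.25, -112.37, 137.64, -108.13, 133.00,  -87.30, 120.54,   77.40,  # e
  116.40, -105.53, 129.32,  -96.68, 140.72,  -74.19, -26.65,  -94.51,  # f
    0.40,  -81.83,   4.91, -100.59,  85.50,  -71.65, 130.78,   84.98,  # g
  119.14, -102.58, 130.83,  -67.91, 121.55,   76.25,  -2.95,  -90.88,  # h
  130.68,  -56.92, 119.26,   77.85,  10.42,  -99.43, 141.40,  -98.01,  # i
  114.32, -121.47, 118.14,   82.88,-150.05,  -83.81,  23.35,  -85.82,  # j
  117.16,  -95.41, 140.40,  -59.35, -29.23,  -72.39, -25.08,  -76.16,  # k
  139.20,  -55.96, -32.70,  -68.51, -26.09,  -74.44, -22.60,  -71.74,  # l
  -39.62,  -64.73, -39.52,  -65.54, -38.88,  -66.89, -37.76,  -70.19,  # m
  -35.34,  -65.03, -38.12,  -66.34, -29.51,  -89.10,  -2.91,   77.90,  # n
  -45.29,  -67.44, -27.72,  -87.27,   5.13,   77.49,  30.71,  -93.23,  # o
  -27.09,  -86.14,   0.30,   59.85,  21.51,  -96.30, 132.67,  -92.91   # p
), nrow = 16, byrow = TRUE,
  dimnames = list(letters[1:16], .pb_angle_names))

#' Protein Block reference dihedral prototypes
#'
#' Returns the canonical table of the 16 PB prototypes: one row per block
#' (labels a..p), eight columns holding the reference dihedral angles in
#' degrees in window order psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i),
#' phi(i+1), psi(i+1), phi(i+2).
#'
#' @return a 16 x 8 numeric matrix with row names a..p.
#' @examples
#' tab <- pb_reference_table()
#' tab["m", c("phi", "psi")]  # alpha-helical core
#' @export
pb_reference_table <- function() .pb_reference

# wrapped squared angular dissimilarity between window matrix (n x 8) and
# every prototype; returns n x 16 matrix of sums of squared wrapped diffs
.pb_dissimilarity <- function(windows, prototypes = pb_reference_table()) {
  n <- nrow(windows)
  d <- matrix(NA_real_, n, nrow(prototypes),
              dimnames = list(NULL, rownames(prototypes)))
  for (k in seq_len(nrow(prototypes))) {
    diff <- wrap_angle(sweep(windows, 2, prototypes[k, ], "-"))
    d[, k] <- rowSums(diff * diff)
  }
  d
}

#' Assign a Protein Block to one dihedral window
#'
#' The window is the 8-vector of dihedrals around the central residue; the
#' assigned block minimises the sum of squared wrapped angular differences to
#' the prototype (the RMSDA criterion), ties broken alphabetically. Any
#' undefined (NA) angle makes the window unassignable and yields `"Z"`.
#'
#' @param window numeric vector of 8 dihedrals in degrees.
#' @param prototypes prototype table as from [pb_reference_table()].
#' @return single character: a PB letter or `"Z"`.
#' @export
assign_window <- function(window, prototypes = pb_reference_table()) {
  stopifnot(length(window) == 8L)
  assign_windows(matrix(window, nrow = 1), prototypes)
}

# vectorised assignment over an n x 8 window matrix -> character vector
assign_windows <- function(windows, prototypes = pb_reference_table()) {
  out <- rep(PB_UNDEF, nrow(windows))
  ok <- rowSums(is.na(windows)) == 0L
  if (any(ok)) {
    d <- .pb_dissimilarity(windows[ok, , drop = FALSE], prototypes)
    # max.col on negated distances; ties.method "first" = alphabetical order
    out[ok] <- rownames(prototypes)[max.col(-d, ties.method = "first")]
  }
  out
}

# build the n_defined x 8 window matrix for positions 3..L-2 from per-residue
# phi/psi vectors (or frame x L matrices stacked row-wise)
.pb_windows <- function(phi, psi) {
  L <- length(phi)
  if (L < 5) return(matrix(numeric(0), 0, 8))
  i <- 3:(L - 2)
  cbind(psi[i - 2], phi[i - 1], psi[i - 1], phi[i], psi[i],
        phi[i + 1], psi[i + 1], phi[i + 2])
}

#' Encode an ensemble into a Protein Block matrix
#'
#' Computes backbone phi/psi for every frame and assigns one PB letter per
#' residue per frame. The first two and last two positions of every frame are
#' `"Z"` (their 5-residue window is incomplete), as is any position whose
#' window contains an undefined dihedral (e.g. a missing backbone atom).
#'
#' @param ensemble an [ensemble] object.
#' @param prototypes prototype table as from [pb_reference_table()].
#' @return a frames x positions character matrix (class `pb_matrix`) over
#'   the alphabet a..p plus `"Z"`.
#' @export
encode_ensemble <- function(ensemble, prototypes = pb_reference_table()) {
  stopifnot(inherits(ensemble, "ensemble"))
  dih <- ensemble_dihedrals(ensemble)
  n_frames <- nrow(dih$phi)
  L <- ncol(dih$phi)
  m <- matrix(PB_UNDEF, n_frames, L,
              dimnames = list(NULL, as.character(seq_len(L))))
  if (L >= 5) {
    # stack windows of all frames: block f occupies rows (f-1)*(L-4)+1 ...
    win <- do.call(rbind, lapply(seq_len(n_frames), function(f) {
      .pb_windows(dih$phi[f, ], dih$psi[f, ])
    }))
    lab <- assign_windows(win, prototypes)
    m[, 3:(L - 2)] <- matrix(lab, n_frames, L - 4, byrow = TRUE)
    n_undef <- sum(lab == PB_UNDEF)
    if (n_undef > 0) {
      message("encode_ensemble: ", n_undef,
              " interior window(s) unassignable (missing dihedrals)")
    }
  }
  structure(m, class = c("pb_matrix", class(m)))
}

#' Write / read a PB matrix as plain text
#'
#' One PB string per line, frame order preserved.
#'
#' @param x a PB matrix (frames x positions character matrix).
#' @param path file path.
#' @return `read_pb_matrix` returns the frames x positions character matrix.
#' @export
write_pb_matrix <- function(x, path) {
  writeLines(apply(unclass(x), 1, paste0, collapse = ""), path)
  invisible(path)
}

#' @rdname write_pb_matrix
#' @export
read_pb_matrix <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) >= 1, length(unique(nchar(lines))) == 1)
  m <- do.call(rbind, strsplit(lines, ""))
  dimnames(m) <- list(NULL, as.character(seq_len(ncol(m))))
  structure(m, class = c("pb_matrix", class(m)))
}
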