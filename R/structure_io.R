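# Conformational-ensemble container and structure I/O. Ensembles are stored
# as a backbone-only coordinate array [frame, residue, atom(N,CA,C), xyz] in
# Angstrom; multi-model PDB is the interchange format (bio3d does the
# parsing/formatting). Superposition and TM-score are implemented here.

.bb_atoms <- c("N", "CA", "C")

#' Conformational ensemble of one chain
#'
#' Container for an ordered set of conformations (frames) of the same chain.
#' Only backbone N/CA/C atoms are kept; that is all the downstream Protein
#' Block and flexibility statistics need.
#'
#' @param xyz numeric array `[n_frames, L, 3, 3]`: frame, residue, atom in
#'   order N/CA/C, Cartesian coordinate in Angstrom. `NA` marks a missing
#'   backbone atom.
#' @param aa character vector of L one-letter residue codes.
#' @param bfactor numeric vector of L CA B-factors (Angstrom^2), optional.
#' @param resno_orig original residue numbering (metadata); internally
#'   positions are always sequential 1..L.
#' @param frame_spacing_ps frame spacing metadata in picoseconds.
#' @param chain chain identifier.
#' @return an object of class `ensemble`.
#' @export
ensemble <- function(xyz, aa, bfactor = NULL, resno_orig = NULL,
                     frame_spacing_ps = NA_real_, chain = "A") {
  stopifnot(is.array(xyz), length(dim(xyz)) == 4L,
            dim(xyz)[3] == 3L, dim(xyz)[4] == 3L,
            dim(xyz)[1] >= 1L)
  L <- dim(xyz)[2]
  stopifnot(length(aa) == L)
  if (any(is.infinite(xyz))) stop("non-finite coordinates")
  if (is.null(bfactor)) bfactor <- rep(NA_real_, L)
  if (is.null(resno_orig)) resno_orig <- seq_len(L)
  structure(list(xyz = xyz, aa = aa, bfactor = bfactor,
                 resno_orig = as.integer(resno_orig),
                 frame_spacing_ps = frame_spacing_ps, chain = chain),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d frame(s), %d residues, chain %s\n",
              n_frames(x), n_residues(x), x$chain))
  invisible(x)
}

#' Number of frames / residues of an ensemble
#' @param x an `ensemble`.
#' @export
n_frames <- function(x) dim(x$xyz)[1]

#' @rdname n_frames
#' @export
n_residues <- function(x) dim(x$xyz)[2]

#' Extract the backbone trace of one frame
#'
#' @param x an `ensemble`.
#' @param frame frame index.
#' @return list with L x 3 matrices `n`, `ca`, `c` plus `bfactor`. A warning
#'   is raised if any consecutive CA-CA virtual bond falls outside the
#'   2.0-5.0 Angstrom sanity window.
#' @export
backbone_trace <- function(x, frame = 1L) {
  stopifnot(inherits(x, "ensemble"), frame >= 1, frame <= n_frames(x))
  L <- n_residues(x)
  tr <- list(n  = matrix(x$xyz[frame, , 1, ], L, 3),
             ca = matrix(x$xyz[frame, , 2, ], L, 3),
             c  = matrix(x$xyz[frame, , 3, ], L, 3),
             bfactor = x$bfactor)
  if (L >= 2) {
    d <- row_norm(tr$ca[-1, , drop = FALSE] - tr$ca[-L, , drop = FALSE])
    bad <- which(is.finite(d) & (d < 2 | d > 5))
    if (length(bad)) {
      warning("CA-CA virtual bond outside 2-5 A at ", length(bad),
              " position(s)")
    }
  }
  tr
}

#' Backbone phi/psi dihedrals of one conformation
#'
#' phi(i) is the torsion C(i-1)-N(i)-CA(i)-C(i) and psi(i) the torsion
#' N(i)-CA(i)-C(i)-N(i+1); phi of the first and psi of the last residue are
#' undefined (`NA`), as is any angle touching a missing atom.
#'
#' @param trace a backbone trace as from [backbone_trace()] (list with L x 3
#'   matrices `n`, `ca`, `c`).
#' @return data.frame with columns `phi`, `psi` in degrees, one row per
#'   residue.
#' @export
compute_dihedrals <- function(trace) {
  n <- trace$n; ca <- trace$ca; c_ <- trace$c
  L <- nrow(ca)
  stopifnot(L >= 3)
  phi <- psi <- rep(NA_real_, L)
  i <- 2:L
  phi[i] <- dihedral_angle(c_[i - 1, , drop = FALSE], n[i, , drop = FALSE],
                           ca[i, , drop = FALSE], c_[i, , drop = FALSE])
  j <- 1:(L - 1)
  psi[j] <- dihedral_angle(n[j, , drop = FALSE], ca[j, , drop = FALSE],
                           c_[j, , drop = FALSE], n[j + 1, , drop = FALSE])
  data.frame(phi = phi, psi = psi)
}

# per-frame dihedrals for a whole ensemble, vectorised across frames;
# returns list(phi, psi) of n_frames x L matrices
ensemble_dihedrals <- function(x) {
  stopifnot(inherits(x, "ensemble"))
  f <- n_frames(x); L <- n_residues(x)
  slab <- function(pos, atom) {
    # (f * |pos|) x 3 matrix, frame index fastest
    matrix(x$xyz[, pos, atom, , drop = FALSE], f * length(pos), 3)
  }
  phi <- psi <- matrix(NA_real_, f, L)
  if (L >= 2) {
    i <- 2:L
    v <- dihedral_angle(slab(i - 1, 3), slab(i, 1), slab(i, 2), slab(i, 3))
    phi[, i] <- matrix(v, f, length(i))
    j <- 1:(L - 1)
    v <- dihedral_angle(slab(j, 1), slab(j, 2), slab(j, 3), slab(j + 1, 1))
    psi[, j] <- matrix(v, f, length(j))
  }
  list(phi = phi, psi = psi)
}

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation mapping `mobile` onto
#' `reference` in the least-squares sense; reflections are disallowed.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, in one-to-one
#'   correspondence.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom) and `coords` (the transformed mobile set). The
#'   transform is `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (nrow(mobile) < 3) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm); q <- sweep(reference, 2, cr)
  if (svd(p)$d[2] < 1e-8 * max(1, svd(p)$d[1])) {
    stop("degenerate (collinear) point set")
  }
  s <- svd(crossprod(p, q))        # H = t(p) %*% q = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- p %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - q)^2)))
  list(rotation = rot, translation = as.numeric(cr - rot %*% cm),
       rmsd = rmsd, coords = sweep(fitted, 2, cr, "+"))
}

# TM score of a fixed set of inter-CA distances
.tm_from_d <- function(d, l_target, d0) sum(1 / (1 + (d / d0)^2)) / l_target

# weighted Kabsch fit (w >= 0); returns function applying the transform
.kabsch_weighted <- function(mobile, reference, w) {
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  p <- sweep(mobile, 2, cm); q <- sweep(reference, 2, cr)
  s <- svd(crossprod(p * w, q))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  shift <- as.numeric(cr - rot %*% cm)
  function(x) x %*% t(rot) + matrix(shift, nrow(x), 3, byrow = TRUE)
}

#' TM-score of two aligned equal-length CA sets
#'
#' Template-modelling score, `(1/L_target) * sum 1/(1+(d_i/d0)^2)` with
#' `d0 = 1.24 (L_target-15)^(1/3) - 1.8` (clamped at 0.5 Angstrom),
#' maximised over superpositions found by iterative fragment seeding:
#' every contiguous fragment of a ladder of lengths seeds a superposition
#' that is refined by re-superposing on the close-residue subset until the
#' subset is stable.
#'
#' @param mobile,reference n x 3 aligned CA coordinate matrices.
#' @param l_target normalisation length; defaults to the reference length.
#' @return the TM-score, a number in (0, 1].
#' @export
tm_score <- function(mobile, reference, l_target = nrow(reference)) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(reference)
  stopifnot(nrow(mobile) == n)
  if (l_target < 3) stop("l_target must be >= 3")
  d0 <- max(1.24 * max(l_target - 15, 0)^(1 / 3) - 1.8, 0.5)

  score_from_subset <- function(idx) {
    best <- 0
    for (iter in 1:20) {
      fit <- tryCatch(
        kabsch_superpose(mobile[idx, , drop = FALSE],
                         reference[idx, , drop = FALSE]),
        error = function(e) NULL)
      if (is.null(fit)) return(best)
      moved <- mobile %*% t(fit$rotation) +
        matrix(fit$translation, n, 3, byrow = TRUE)
      d <- row_norm(moved - reference)
      best <- max(best, .tm_from_d(d, l_target, d0))
      d_cut <- d0
      repeat {
        new_idx <- which(d < d_cut)
        if (length(new_idx) >= 4 || d_cut > max(d)) break
        d_cut <- d_cut + 0.5
      }
      if (length(new_idx) < 3 || identical(new_idx, idx)) break
      idx <- new_idx
    }
    # polish: iteratively reweighted superposition ascending the TM objective
    d <- tryCatch({
      fit <- kabsch_superpose(mobile[idx, , drop = FALSE],
                              reference[idx, , drop = FALSE])
      moved <- mobile %*% t(fit$rotation) +
        matrix(fit$translation, n, 3, byrow = TRUE)
      row_norm(moved - reference)
    }, error = function(e) NULL)
    if (is.null(d)) return(best)
    for (iter in 1:100) {
      w <- (1 / (1 + (d / d0)^2))^2
      moved <- .kabsch_weighted(mobile, reference, w)(mobile)
      d_new <- row_norm(moved - reference)
      sc <- .tm_from_d(d_new, l_target, d0)
      improved <- sc > best + 1e-12
      best <- max(best, sc)
      d <- d_new
      if (!improved && iter > 2) break
    }
    best
  }

  lens <- unique(pmax(4, floor(n / c(1, 2, 4))))
  lens <- lens[lens <= n]
  best <- 0
  for (len in lens) {
    for (start in seq(1, n - len + 1)) {
      best <- max(best, score_from_subset(start:(start + len - 1)))
    }
  }
  min(best, 1)
}

#' Read a (multi-model) PDB file as an ensemble
#'
#' Each MODEL record becomes one frame; single-model files yield a 1-frame
#' ensemble. Residues are renumbered sequentially from 1 (original numbering
#' kept as metadata). Where alternate locations are present the
#' highest-occupancy conformer is kept; insertion codes are rejected. A
#' residue missing a backbone atom is kept with `NA` coordinates and flagged
#' with a warning, never silently dropped.
#'
#' @param path PDB file.
#' @param models `"all"` or an integer vector of model indices.
#' @param chain chain to read (default: first chain in the file).
#' @return an [ensemble].
#' @export
read_ensemble <- function(path, models = "all", chain = NULL) {
  raw <- readLines(path)
  starts <- grep("^MODEL", raw)
  if (length(starts) > 1) {
    ends <- grep("^ENDMDL", raw)
    if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL records")
    counts <- mapply(function(s, e) sum(grepl("^(ATOM|HETATM)", raw[s:e])),
                     starts, ends)
    if (length(unique(counts)) != 1) {
      stop("inconsistent atom counts across MODEL blocks")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atom <- pdb$atom
  atom$row <- seq_len(nrow(atom))
  atom <- atom[atom$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- atom$chain[1]
  atom <- atom[atom$chain %in% chain, , drop = FALSE]
  if (any(!is.na(atom$insert))) stop("insertion codes are not supported")
  atom <- atom[atom$elety %in% .bb_atoms, , drop = FALSE]
  # highest-occupancy altloc per (resno, atom name)
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  atom <- atom[order(atom$resno, match(atom$elety, .bb_atoms), -occ), ]
  atom <- atom[!duplicated(atom[, c("resno", "elety")]), ]
  atom <- atom[order(atom$row), ]

  resno <- unique(atom$resno)
  L <- length(resno)
  if (L < 1) stop("no protein residues found")
  xyz_all <- pdb$xyz
  if (!is.matrix(xyz_all)) xyz_all <- matrix(xyz_all, nrow = 1)
  nf_all <- nrow(xyz_all)
  sel <- if (identical(models, "all")) seq_len(nf_all) else as.integer(models)
  if (any(sel < 1 | sel > nf_all)) stop("model selector out of range")

  xyz <- array(NA_real_, c(length(sel), L, 3, 3))
  aa <- rep(NA_character_, L); bf <- rep(NA_real_, L)
  missing_atoms <- 0L
  for (ri in seq_len(L)) {
    rows <- atom[atom$resno == resno[ri], , drop = FALSE]
    aa[ri] <- bio3d::aa321(rows$resid[1])
    for (ai in 1:3) {
      hit <- rows[rows$elety == .bb_atoms[ai], , drop = FALSE]
      if (nrow(hit) == 1) {
        cols <- (hit$row - 1) * 3 + 1:3
        xyz[, ri, ai, ] <- xyz_all[sel, cols, drop = FALSE]
        if (ai == 2) bf[ri] <- hit$b
      } else {
        missing_atoms <- missing_atoms + 1L
      }
    }
  }
  if (missing_atoms > 0) {
    warning(missing_atoms, " missing backbone atom(s); affected dihedral ",
            "windows will be unassignable")
  }
  ensemble(xyz, aa, bfactor = bf, resno_orig = resno, chain = chain[1])
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param x an [ensemble].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ensemble <- function(x, path) {
  stopifnot(inherits(x, "ensemble"))
  f <- n_frames(x); L <- n_residues(x)
  # frames x (3 * natoms) coordinate matrix in atom order N,CA,C per residue
  natoms <- 3L * L
  xyz <- matrix(NA_real_, f, 3L * natoms)
  for (ri in seq_len(L)) {
    for (ai in 1:3) {
      cols <- ((ri - 1L) * 3L + ai - 1L) * 3L + 1:3
      xyz[, cols] <- matrix(x$xyz[, ri, ai, ], f, 3)
    }
  }
  aa3 <- bio3d::aa123(x$aa)
  b <- ifelse(is.na(x$bfactor), 0, x$bfactor)
  bio3d::write.pdb(file = path, xyz = xyz,
                   elety = rep(.bb_atoms, L),
                   resno = rep(seq_len(L), each = 3),
                   resid = rep(aa3, each = 3),
                   chain = rep(x$chain, natoms),
                   o = rep(1, natoms), b = rep(b, each = 3))
  invisible(path)
}

#' Read the first sequence of a FASTA file as a one-letter vector
#'
#' @param path FASTA file.
#' @return character vector of one-letter residue codes.
#' @export
read_sequence <- function(path) {
  fa <- bio3d::read.fasta(path)
  toupper(as.character(fa$ali[1, fa$ali[1, ] != "-"]))
}
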