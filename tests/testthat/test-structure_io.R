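test_that("torsion angles match an independent vector-algebra oracle", {
  set.seed(11)
  for (rep in 1:5) {
    tr <- random_trace(6, seed = rep)
    d <- compute_dihedrals(tr)
    for (i in 2:6) {
      expect_equal(d$phi[i],
                   oracle_dihedral(tr$c[i - 1, ], tr$n[i, ], tr$ca[i, ],
                                   tr$c[i, ]),
                   tolerance = 1e-6)
    }
    for (i in 1:5) {
      expect_equal(d$psi[i],
                   oracle_dihedral(tr$n[i, ], tr$ca[i, ], tr$c[i, ],
                                   tr$n[i + 1, ]),
                   tolerance = 1e-6)
    }
  }
})

test_that("planar trans arrangement gives 180 deg and mirroring negates torsions", {
  p <- rbind(c(-1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0))
  expect_equal(abs(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])), 180)

  tr <- random_trace(6, seed = 3)
  d <- compute_dihedrals(tr)
  mir <- lapply(tr[c("n", "ca", "c")], function(m) {
    m[, 1] <- -m[, 1]; m
  })
  dm <- compute_dihedrals(mir)
  # mirror image: every defined angle is negated (up to the 180 == -180 wrap)
  expect_equal(wrap_angle(dm$phi[-1] + d$phi[-1]), rep(0, 5), tolerance = 1e-9)
  expect_equal(wrap_angle(dm$psi[-6] + d$psi[-6]), rep(0, 5), tolerance = 1e-9)
})

test_that("dihedrals are invariant under rigid motion of the trace", {
  tr <- random_trace(8, seed = 5)
  set.seed(6)
  r <- pbflex:::random_rotation()
  shift <- c(10, -4, 2.5)
  tr2 <- lapply(tr[c("n", "ca", "c")], function(m) {
    m %*% t(r) + matrix(shift, nrow(m), 3, byrow = TRUE)
  })
  expect_equal(compute_dihedrals(tr2), compute_dihedrals(tr),
               tolerance = 1e-6)
})

test_that("Kabsch superposition is exact on congruent sets and matches a brute-force oracle", {
  set.seed(21)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-12)

  r <- pbflex:::random_rotation()
  moved <- x %*% t(r) + matrix(c(3, -1, 7), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(moved, x)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  y <- x + matrix(rnorm(30, 0, 0.4), 10, 3)
  fit2 <- kabsch_superpose(x, y)
  expect_equal(fit2$rmsd, oracle_min_rmsd(x, y), tolerance = 1e-6)
  # rmsd symmetric in its arguments
  expect_equal(fit2$rmsd, kabsch_superpose(y, x)$rmsd, tolerance = 1e-9)
})

test_that("Kabsch agrees with bio3d on a random pair", {
  set.seed(8)
  x <- matrix(rnorm(45), 15, 3)
  y <- x + matrix(rnorm(45, 0, 0.3), 15, 3)
  expect_equal(kabsch_superpose(x, y)$rmsd,
               bio3d::rmsd(as.vector(t(x)), as.vector(t(y)), fit = TRUE),
               tolerance = 1e-4)
})

test_that("degenerate superposition inputs are rejected", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)), "3 points")
})

test_that("TM-score: identity gives 1 and toy pairs match a brute-force oracle", {
  set.seed(31)
  x <- random_trace(20, seed = 31)$ca
  expect_equal(tm_score(x, x), 1, tolerance = 1e-9)

  y <- x + matrix(rnorm(60, 0, 0.8), 20, 3)
  set.seed(32)
  expect_equal(tm_score(y, x), oracle_max_tm(y, x), tolerance = 1e-3)

  # one displaced half: fragment seeding must still find the best fit
  z <- x
  z[11:20, ] <- z[11:20, ] %*% t(rot_from_euler(0.6, 0.2, -0.4)) + 5
  set.seed(33)
  expect_equal(tm_score(z, x), oracle_max_tm(z, x, n_starts = 80),
               tolerance = 1e-3)

  expect_error(tm_score(x[1:2, ], x[1:2, ]), "l_target|3")
})

test_that("PDB round trip preserves frames, sequence, B-factors and coordinates", {
  set.seed(41)
  L <- 7
  xyz <- array(NA_real_, c(3, L, 3, 3))
  for (fr in 1:3) {
    tr <- random_trace(L, seed = 40 + fr)
    xyz[fr, , 1, ] <- tr$n; xyz[fr, , 2, ] <- tr$ca; xyz[fr, , 3, ] <- tr$c
  }
  aa <- c("Q", "V", "K", "L", "A", "G", "S")
  ens <- ensemble(xyz, aa, bfactor = seq(10, 70, by = 10))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, f)
  back <- read_ensemble(f)
  expect_equal(n_frames(back), 3)
  expect_equal(back$aa, aa)
  expect_equal(back$bfactor, ens$bfactor)
  expect_equal(back$xyz, ens$xyz, tolerance = 1e-3)

  # write -> read -> write is byte-stable at PDB precision
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(back, f2)
  expect_identical(readLines(f), readLines(f2))

  expect_equal(n_frames(read_ensemble(f, models = c(1, 3))), 2)
  expect_error(read_ensemble(f, models = 9), "out of range")
})

test_that("malformed ensembles are rejected or flagged, never silently dropped", {
  # two models with different residue counts
  line <- function(no, elety, resno, x) {
    sprintf("ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00 10.00",
            no, elety, resno, x, 0, 0)
  }
  bad <- c("MODEL        1",
           line(1, "N", 1, 0), line(2, "CA", 1, 1.4), line(3, "C", 1, 2.4),
           "ENDMDL", "MODEL        2",
           line(1, "N", 1, 0), line(2, "CA", 1, 1.4), line(3, "C", 1, 2.4),
           line(4, "N", 2, 3.6),
           "ENDMDL", "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, f)
  expect_error(suppressWarnings(read_ensemble(f)))

  # missing backbone atom -> warning, residue kept with NA
  one <- c(line(1, "N", 1, 0), line(2, "CA", 1, 1.4), line(3, "C", 1, 2.4),
           line(4, "N", 2, 3.6), line(5, "CA", 2, 4.9),
           line(6, "N", 3, 6.0), line(7, "CA", 3, 7.2), line(8, "C", 3, 8.0),
           "END")
  writeLines(one, f)
  expect_warning(ens <- read_ensemble(f), "missing backbone")
  expect_equal(n_residues(ens), 3)
  expect_true(all(is.na(ens$xyz[1, 2, 3, ])))

  # insertion codes rejected
  ins <- sprintf(
    "ATOM  %5d  %-3s ALA A%4d%s   %8.3f%8.3f%8.3f  1.00 10.00",
    4L, "N", 1L, "A", 3.6, 0, 0)
  writeLines(c(one[1:3], ins, one[5:9]), f)
  expect_error(read_ensemble(f), "insertion")
})
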