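test_that("profile_for_neq inverts the Neq formula by bisection", {
  expect_equal(unname(profile_for_neq(1, "d", "m")[c("d", "m")]), c(1, 0))
  expect_equal(unname(profile_for_neq(2, "d", "m")[c("d", "m")]), c(0.5, 0.5))
  f <- profile_for_neq(1.5, "d", "m")
  expect_equal(neq(f), 1.5, tolerance = 1e-6)
  # general k-block solver
  g <- profile_for_neq(3.4, support = c("d", "e", "k", "o", "a"))
  expect_equal(neq(g), 3.4, tolerance = 1e-6)
  expect_equal(sum(g), 1, tolerance = 1e-12)
  expect_error(profile_for_neq(2.5, "d", "m"), "unattainable")
})

test_that("PB-state sampling is reproducible and concentrates on its target", {
  prof <- matrix(rep(point_profile("d"), each = 3), 3, 16)
  m <- sample_pb_matrix(prof, 100, seed = 5)
  expect_true(all(m == "d"))
  expect_identical(sample_pb_matrix(prof, 50, seed = 9),
                   sample_pb_matrix(prof, 50, seed = 9))

  half <- (point_profile("d") + point_profile("m")) / 2
  m2 <- sample_pb_matrix(half, 10000, seed = 6, n_positions = 1)
  expect_equal(neq(pb_profiles(m2))[1], 2, tolerance = 0.05)
})

test_that("backbone reconstruction round-trips its dihedrals", {
  set.seed(61)
  for (rep in 1:4) {
    L <- 10
    d <- data.frame(phi = c(NA, runif(L - 1, -180, 180)),
                    psi = c(runif(L - 1, -180, 180), NA))
    tr <- build_backbone(d)
    d2 <- compute_dihedrals(tr)
    expect_lt(max(abs(wrap_angle(d2$phi - d$phi)), na.rm = TRUE), 1e-4)
    expect_lt(max(abs(wrap_angle(d2$psi - d$psi)), na.rm = TRUE), 1e-4)
  }
})

test_that("helical dihedrals give ~3.8 A CA-CA virtual bonds", {
  L <- 12
  tr <- build_backbone(data.frame(phi = c(NA, rep(-65, L - 1)),
                                  psi = c(rep(-40, L - 1), NA)))
  d <- sqrt(rowSums((tr$ca[-1, ] - tr$ca[-L, ])^2))
  expect_true(all(abs(d - 3.8) < 0.15))
})

test_that("each prototype window re-encodes to its own letter", {
  for (l in PB_LETTERS) {
    pm <- encode_ensemble(prototype_window_ensemble(l))
    expect_identical(unname(pm[1, 3]), l)
  }
  # wide assignment basins: 5 deg noise keeps >= 99% recovery
  for (l in c("a", "d", "g", "m", "p")) {
    pm <- encode_ensemble(prototype_window_ensemble(l, n_frames = 200,
                                                    noise = 5, seed = 71))
    expect_gte(mean(pm[, 3] == l), 0.99)
  }
})

test_that("homogeneous strand/helix ensembles re-encode their letter exactly", {
  for (l in c("d", "m")) {
    prof <- matrix(rep(point_profile(l), each = 15), 15, 16)
    ens <- make_ensemble(prof, n_frames = 5, noise = 0, seed = 81)
    pm <- encode_ensemble(ens)
    expect_true(all(pm[, 3:13] == l))
  }
})

test_that("generated ensembles are deterministic down to the PDB bytes", {
  prof <- vhh_template_profiles()[1:20, ]
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(make_ensemble(prof, n_frames = 2, noise = 5, seed = 3), f1)
  write_ensemble(make_ensemble(prof, n_frames = 2, noise = 5, seed = 3), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("Neq parameter recovery on the target grid at 10,000 frames", {
  targets <- c(1, 1.5, 2, 3, 4)
  prof <- do.call(rbind, lapply(targets, function(t) {
    if (t <= 2) profile_for_neq(t, "d", "e") else
      profile_for_neq(t, support = c("d", "e", "k", "m", "o"))
  }))
  m <- sample_pb_matrix(prof, 10000, seed = 23)
  expect_true(all(abs(neq(pb_profiles(m)) - targets) <= 0.05))
})

test_that("paired ensembles realise their analytic delta-PB", {
  prof <- matrix(rep(point_profile("d"), each = 30), 30, 16)
  base <- make_pair(prof, n_frames = 10000, seed = 25, coords = FALSE)
  dpb0 <- delta_pb(pb_profiles(base$first), pb_profiles(base$second))
  expect_lte(max(dpb0), 0.05)

  shift <- 0.375 * point_profile("d") + 0.625 * point_profile("m")
  quarter <- 0.75 * point_profile("d") + 0.25 * point_profile("m")
  pair <- make_pair(prof,
                    overrides = list(list(positions = 10:12, profile = shift),
                                     list(positions = 20, profile = quarter)),
                    n_frames = 10000, seed = 26, coords = FALSE)
  expect_equal(unname(pair$analytic_delta_pb[c(10, 11, 12, 20)]),
               c(1.25, 1.25, 1.25, 0.5))
  dpb <- delta_pb(pb_profiles(pair$first), pb_profiles(pair$second))
  expect_true(all(abs(dpb[10:12] - 1.25) <= 0.1))
  expect_lte(abs(dpb[20] - 0.5), 0.1)
  expect_true(all(dpb[setdiff(1:30, c(10:12, 20))] < 0.05))
})

test_that("RMSF-controlled ensembles converge to their target profile", {
  target <- c(0.5, 1, 2, 0.8, 1.5, 0.5, 0.5, 2.5)
  ens <- make_rmsf_ensemble(target, n_frames = 3000, seed = 33)
  r <- rmsf(ens, superpose = FALSE)
  expect_true(all(abs(r - target) / target < 0.05))
  expect_equal(length(vhh_template_rmsf()), 121)
  expect_true(all(vhh_template_rmsf() >= 0.5))
})

test_that("the VHH template matches its documented flexibility layout", {
  prof <- vhh_template_profiles()
  expect_equal(nrow(prof), 121)
  expect_equal(rowSums(prof), rep(1, 121), tolerance = 1e-9)
  target <- attr(prof, "target_neq")
  expect_equal(neq(prof), target, tolerance = 1e-6)
  # CDR1 carries the canonical dfbdcfb loop motif
  expect_identical(paste(attr(prof, "dominant")[23:29], collapse = ""),
                   "dfbdcfb")
  # per-region mean Neq lands exactly on the documented layout values
  sm <- region_summary(neq(prof), default_region_map())
  expect_equal(sm$mean, c(1.20, 1.45, 1.04, 1.27, 1.24, 1.52, 1.09),
               tolerance = 1e-6)
  cdr <- grepl("CDR", sm$region)
  expect_gt(mean(sm$mean[cdr]), mean(sm$mean[!cdr]))
  # the only positions above the Neq-3 flexibility shoulder are 62, 72, 97
  expect_identical(which(neq(prof) > 3), c(62L, 72L, 97L))
})
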