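make_pb_matrix <- function(cols) {
  m <- do.call(cbind, cols)
  colnames(m) <- as.character(seq_len(ncol(m)))
  structure(m, class = c("pb_matrix", class(m)))
}

test_that("profiles count frequencies over assigned frames only", {
  m <- make_pb_matrix(list(rep("d", 10),
                           c(rep("d", 5), rep("m", 5)),
                           c("d", "d", "d", "Z", "Z", "Z", "Z", "Z", "Z", "Z")))
  pr <- pb_profiles(m)
  expect_equal(unname(pr[1, "d"]), 1)
  expect_equal(unname(pr[2, c("d", "m")]), c(0.5, 0.5))
  expect_equal(unname(pr[3, "d"]), 1)
  expect_equal(attr(pr, "n_assigned"), c(10L, 10L, 3L))
  expect_equal(rowSums(pr), c(1, 1, 1), ignore_attr = TRUE)

  all_z <- pb_profiles(make_pb_matrix(list(rep("Z", 4))))
  expect_true(all(is.na(all_z[1, ])))
  expect_true(is.na(neq(all_z)[1]))
})

test_that("Neq spans 1 (single block) to 16 (uniform)", {
  expect_equal(neq(point_profile("d")), 1)
  expect_equal(neq(rep(1 / 16, 16)), 16)
  expect_equal(neq(c(0.5, 0.5, rep(0, 14))), 2)

  # property: bounds hold and extremes are achieved only at the extremes
  set.seed(77)
  for (rep in 1:50) {
    f <- rexp(16); f <- f / sum(f)
    v <- neq(f)
    expect_gte(v, 1)
    expect_lte(v, 16 + 1e-12)
    expect_gt(v, 1 + 1e-9)
    expect_lt(v, 16 - 1e-9)
  }
})

test_that("delta-PB is the L1 profile distance with its documented anchors", {
  d <- point_profile("d"); m <- point_profile("m")
  expect_equal(delta_pb(d, d), 0)
  expect_equal(delta_pb(d, m), 2)
  quarter <- 0.75 * d + 0.25 * m
  expect_equal(delta_pb(d, quarter), 0.5)
  shifted <- 0.375 * d + 0.625 * m
  expect_equal(delta_pb(d, shifted), 1.25)

  set.seed(78)
  for (rep in 1:25) {
    f <- rexp(16); f <- f / sum(f)
    g <- rexp(16); g <- g / sum(g)
    h <- rexp(16); h <- h / sum(h)
    expect_equal(delta_pb(f, g), delta_pb(g, f))
    expect_lte(delta_pb(f, h), delta_pb(f, g) + delta_pb(g, h) + 1e-12)
    # delta-PB / 2 is the total-variation distance
    expect_equal(delta_pb(f, g) / 2, sum(pmax(f - g, 0)), tolerance = 1e-12)
  }
})

test_that("delta-Neq is the absolute per-position difference", {
  expect_equal(delta_neq(c(2, 3), c(3.5, 3)), c(1.5, 0))
  expect_equal(delta_neq(c(2, 3), c(3.5, 1)), delta_neq(c(3.5, 1), c(2, 3)))
  expect_error(delta_neq(1:3, 1:4), "length")
})

test_that("Neq of two-block mixtures is never below the pure components", {
  # numeric grid over two-PB mixtures
  for (p in seq(0.5, 1, by = 0.025)) {
    f <- c(p, 1 - p, rep(0, 14))
    expect_gte(neq(f), 1)
  }
})

test_that("RMSF handles degenerate and closed-form cases", {
  tr <- random_trace(6, seed = 91)
  xyz <- array(NA_real_, c(2, 6, 3, 3))
  for (fr in 1:2) {
    xyz[fr, , 1, ] <- tr$n; xyz[fr, , 2, ] <- tr$ca; xyz[fr, , 3, ] <- tr$c
  }
  ens <- ensemble(xyz, rep("A", 6))
  expect_equal(rmsf(ens), rep(0, 6), tolerance = 1e-12)
  expect_warning(r1 <- rmsf(ensemble(xyz[1, , , , drop = FALSE], rep("A", 6))),
                 "single")
  expect_equal(r1, rep(0, 6))

  # one CA alternating between two points 1 A apart, superposition disabled
  xyz[2, 3, 2, ] <- xyz[1, 3, 2, ] + c(1, 0, 0)
  ens2 <- ensemble(xyz, rep("A", 6))
  expect_equal(rmsf(ens2, superpose = FALSE)[3], 0.5)
  expect_equal(rmsf(ens2, superpose = FALSE)[-3], rep(0, 5))
})

test_that("RMSF is invariant under a global rigid motion of all frames", {
  prof <- matrix(rep(point_profile("d"), each = 12), 12, 16)
  ens <- make_ensemble(prof, n_frames = 20, noise = 8, seed = 17)
  set.seed(18)
  moved <- rigid_move_ensemble(ens, pbflex:::random_rotation(), c(-2, 9, 4))
  expect_equal(rmsf(moved), rmsf(ens), tolerance = 1e-9)
})

test_that("RMSD time series is zero for the reference and rigid copies", {
  prof <- matrix(rep(point_profile("m"), each = 10), 10, 16)
  ens <- make_ensemble(prof, n_frames = 3, noise = 6, seed = 19)
  ens$xyz[2, , , ] <- ens$xyz[1, , , ]
  set.seed(20)
  r <- pbflex:::random_rotation()
  for (ai in 1:3) {
    ens$xyz[2, , ai, ] <- matrix(ens$xyz[2, , ai, ], ncol = 3) %*% t(r) + 5
  }
  ts <- rmsd_timeseries(ens)
  expect_equal(ts[1], 0, tolerance = 1e-12)
  expect_equal(ts[2], 0, tolerance = 1e-9)
  # third frame: matches the brute-force superposition oracle
  ca1 <- matrix(ens$xyz[1, , 2, ], ncol = 3)
  ca3 <- matrix(ens$xyz[3, , 2, ], ncol = 3)
  set.seed(21)
  expect_equal(ts[3], oracle_min_rmsd(ca3, ca1), tolerance = 1e-6)
})

test_that("correlation matches the textbook formula and honours exclusions", {
  set.seed(31)
  a <- rnorm(121); b <- 0.3 * a + rnorm(121)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlate(a, b), manual, tolerance = 1e-12)
  expect_equal(correlate(a, a), 1)
  expect_equal(correlate(a, -a), -1)
  expect_equal(correlate(a, b, exclude_extremities = TRUE, n_excluded = 3),
               cor(a[4:118], b[4:118]), tolerance = 1e-12)
  expect_warning(v <- correlate(rep(1, 10), rnorm(10)), "variance")
  expect_true(is.na(v))
})

test_that("region summaries average per segment with NA exclusion", {
  rm_ <- default_region_map()
  s <- rep(1, 121)
  expect_equal(region_summary(s, rm_)$mean, rep(1, 7))
  expect_equal(region_summary(seq_len(121), rm_)$mean[1], 13)  # mean of 1..25
  s2 <- rep(1, 121)
  cdr <- region_of(1:121, rm_) %in% c("CDR1", "CDR2", "CDR3")
  s2[cdr] <- 2
  sm <- region_summary(s2, rm_)
  cdr <- sm$region %in% c("CDR1", "CDR2", "CDR3")
  expect_gt(min(sm$mean[cdr]), max(sm$mean[!cdr]))
})

test_that("flexibility classes follow the 1 / 2 / 4 thresholds", {
  expect_identical(as.character(classify_flexibility(c(1, 1.9, 2.5, 4, 4.5))),
                   c("rigid", "low", "intermediate", "intermediate", "flexible"))
  expect_error(classify_flexibility(0.8), "below 1")
})

test_that("logo stacks carry information content in bits", {
  single <- make_pb_matrix(list(rep("d", 8)))
  lg <- pb_logo(single, 1)[[1]]
  expect_equal(lg$R, 4)
  expect_identical(lg$letters$letter, "d")
  expect_equal(lg$letters$height, 4)

  uni <- make_pb_matrix(list(rep(PB_LETTERS, 2)))
  lg2 <- pb_logo(uni, 1)[[1]]
  expect_equal(lg2$R, 0)
  expect_equal(sum(lg2$letters$height), 0)

  half <- make_pb_matrix(list(c(rep("d", 5), rep("m", 5))))
  lg3 <- pb_logo(half, 1)[[1]]
  expect_equal(lg3$R, 3)
  expect_equal(lg3$letters$height, c(1.5, 1.5))
  # sum of letter heights equals the column information content
  expect_equal(sum(lg3$letters$height), lg3$R)

  undef <- make_pb_matrix(list(rep("Z", 3)))
  expect_equal(nrow(pb_logo(undef, 1)[[1]]$letters), 0)
})
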