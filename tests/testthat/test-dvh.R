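test_that("differential DVH constructor enforces its invariants", {
  expect_error(dvh_differential(numeric(0), numeric(0)), "empty")
  expect_error(dvh_differential(c(1, 2), c(0.5, 0.4), bin_width = 1),
               "not a normalized")
  expect_error(dvh_differential(c(1, 1.9), c(0.5, 0.5), bin_width = 1),
               "uniform grid")
  expect_error(dvh_differential(c(-1, 0), c(0.5, 0.5), bin_width = 1),
               "non-negative")
  expect_error(dvh_differential(c(1, 2), c(0.7, -0.3), bin_width = 1),
               "non-negative")
  # small deviations are renormalized with a warning
  expect_warning(d <- dvh_differential(c(1, 2), c(0.5, 0.5003), bin_width = 1),
                 "renormaliz")
  expect_equal(sum(d$volume_fraction), 1, tolerance = 1e-12)
})

test_that("cumulative DVH constructor enforces monotonicity and V(0) = 1", {
  expect_error(dvh_cumulative(c(0, 10, 20), c(1, 0.4, 0.6)), "monotone")
  expect_error(dvh_cumulative(c(0, 10), c(0.8, 0.2)), "equal 1 at zero")
  expect_silent(dvh_cumulative(c(0, 10, 20), c(1, 0.5, 0)))
})

test_that("differential to cumulative handles point masses", {
  # all volume at 10 Gy: full volume below the bin, none above
  d <- mass_ddvh(10, 1)
  cd <- as_cumulative(d)
  expect_equal(volume_at_dose(cd, 5), 1)
  expect_equal(volume_at_dose(cd, 9.975), 1)
  expect_equal(volume_at_dose(cd, 10.025), 0)
  # half at 0.025 Gy, half at 20.025 Gy: plateau of 0.5 between the bins
  d2 <- mass_ddvh(c(0.025, 20.025), c(0.5, 0.5))
  cd2 <- as_cumulative(d2)
  expect_equal(volume_at_dose(cd2, 10), 0.5)
  expect_equal(volume_at_dose(cd2, 20.0), 0.5)
  expect_equal(volume_at_dose(cd2, 20.06), 0)
})

test_that("cumulative to differential localizes steps and spreads ramps", {
  # step at 25 Gy -> a single mass in the bin containing 25 Gy
  step <- dvh_cumulative(c(0, 25, 25.05), c(1, 1, 0))
  d <- as_differential(step, 0.05)
  expect_equal(sum(d$volume_fraction), 1, tolerance = 1e-9)
  hot <- which(d$volume_fraction > 1e-9)
  expect_length(hot, 1L)
  expect_lt(abs(d$bin_center[hot] - 25.025), 1e-9)
  # linear ramp (0,1)-(50,0) -> 1000 equal masses of 1e-3
  d2 <- as_differential(linear_cdvh(50), 0.05)
  expect_length(d2$volume_fraction, 1000L)
  expect_equal(d2$volume_fraction, rep(1e-3, 1000), tolerance = 1e-9)
})

test_that("differential/cumulative round trip is the identity on the grid", {
  set.seed(42)
  for (n_bins in c(1, 7, 200)) {
    d <- rand_ddvh(n_bins)
    back <- as_differential(as_cumulative(d), d$bin_width)
    expect_equal(back$bin_center, d$bin_center, tolerance = 1e-9)
    expect_equal(back$volume_fraction, d$volume_fraction, tolerance = 1e-9)
  }
})

test_that("mean dose is the volume-weighted bin sum", {
  expect_equal(mean_dose(mass_ddvh(10, 1)), 10)
  expect_equal(mean_dose(mass_ddvh(c(10, 30), c(0.5, 0.5))), 20)
  set.seed(7)
  d <- rand_ddvh(150)
  oracle <- 0
  for (i in seq_along(d$bin_center))
    oracle <- oracle + d$bin_center[i] * d$volume_fraction[i]
  expect_equal(mean_dose(d), oracle, tolerance = 1e-12)
})

test_that("volume_at_dose interpolates the cumulative curve", {
  step <- dvh_cumulative(c(0, 25, 25.05), c(1, 1, 0))
  expect_equal(volume_at_dose(step, 20), 1)
  expect_equal(volume_at_dose(linear_cdvh(50), 25), 0.5)
  expect_equal(volume_at_dose(linear_cdvh(50), 0), 1)
  expect_equal(volume_at_dose(linear_cdvh(50), 60), 0)   # above grid
  expect_error(volume_at_dose(linear_cdvh(50), -1), "non-negative")
})

test_that("relative-dose coverage metrics follow the prescription", {
  # target entirely above 95% of 50 Gy -> full coverage
  target <- dvh_cumulative(c(0, 47.6, 49, 50), c(1, 1, 0.5, 0))
  expect_equal(volume_at_relative_dose(target, 95, 50), 1)
  # nothing above 105% of 50 Gy
  expect_equal(volume_at_relative_dose(target, 105, 50), 0)
  expect_equal(volume_at_relative_dose(linear_cdvh(50), 93, 50), 0.07,
               tolerance = 1e-12)
})

test_that("dose_at_volume finds the near-maximum dose", {
  # linear tail from (40 Gy, 10%) to (50 Gy, 0): the hottest 2% starts at 48
  cd <- dvh_cumulative(c(0, 40, 50), c(1, 0.10, 0))
  expect_equal(dose_at_volume(cd, 0.02), 48, tolerance = 1e-12)
  # uniform-dose organ: D2% equals the uniform dose
  expect_equal(dose_at_volume(dvh_cumulative(c(0, 30), c(1, 1)), 0.02), 30)
  # the full volume receives at least 0 Gy
  expect_equal(dose_at_volume(linear_cdvh(50), 1), 0)
  # nearest-bin mode returns a grid dose
  cd5 <- dvh_cumulative(seq(0, 50, by = 10), c(1, 0.6, 0.3, 0.1, 0.02, 0))
  expect_equal(dose_at_volume(cd5, 0.02, interp = "nearest"), 40)
  expect_equal(dose_at_volume(cd5, 0.05, interp = "linear"),
               30 + 10 * (0.1 - 0.05) / (0.1 - 0.02), tolerance = 1e-12)
})

test_that("metric properties hold on random DVHs", {
  set.seed(11)
  for (rep in 1:20) {
    d <- rand_ddvh(100)
    cd <- as_cumulative(d)
    # V(D) non-increasing in the threshold
    th <- sort(stats::runif(25, 0, 6))
    expect_true(all(diff(volume_at_dose(cd, th)) <= 1e-12))
    # scaling doses by k > 1 scales the mean and never shrinks V(D)
    k <- 1 + stats::runif(1, 0.1, 2)
    ds <- dvh_differential(d$bin_center * k, d$volume_fraction,
                           bin_width = d$bin_width * k)
    expect_equal(mean_dose(ds), k * mean_dose(d), tolerance = 1e-9)
    expect_true(all(volume_at_dose(as_cumulative(ds), th) >=
                      volume_at_dose(cd, th) - 1e-12))
  }
  # dose_at_volume inverts volume_at_dose on a strictly decreasing curve
  cd <- linear_cdvh(50)
  for (vf in seq(0.05, 0.95, by = 0.1))
    expect_equal(volume_at_dose(cd, dose_at_volume(cd, vf)), vf,
                 tolerance = 1e-9)
  # dose_at_volume non-increasing in the volume fraction
  dv <- vapply(seq(0.05, 0.95, by = 0.1), dose_at_volume, numeric(1),
               cdvh = cd)
  expect_true(all(diff(dv) <= 1e-12))
})
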