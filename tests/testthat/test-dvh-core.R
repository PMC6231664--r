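test_that("cumulative_dvh validates its invariants with diagnostics", {
  expect_s3_class(cumulative_dvh("S", c(0, 40, 80), c(1, 0.5, 0), 100),
                  "cumulative_dvh")
  expect_error(cumulative_dvh("S", c(0, 40, 40), c(1, 0.5, 0), 100),
               "not strictly increasing at index 3")
  expect_error(cumulative_dvh("S", c(0, 40, 80), c(1, 0.4, 0.5), 100),
               "increases at index 3")
  expect_error(cumulative_dvh("S", c(5, 40), c(1, 0), 100), "start at 0")
  expect_error(cumulative_dvh("S", c(0, 40), c(0.9, 0), 100), "start at 1")
  expect_error(cumulative_dvh("S", c(0, 40), c(1, 0), -1), "positive")
  expect_error(cumulative_dvh("S", c(0, NA), c(1, 0), 10), "NA")
})

test_that("cumulative -> differential conserves mass and bins correctly", {
  # all mass between 78 and 80
  cd <- cumulative_dvh("S", c(0, 78, 80), c(1, 1, 0), 50)
  dd <- cumulative_to_differential(cd, bin_width = 2)
  expect_equal(sum(dd$fractional_volumes), 1, tolerance = 1e-12)
  expect_equal(dd$fractional_volumes[dd$bin_centers == 79], 1)

  # hand-derived bin differencing: 1.0, 0.6, 0.0 at 0/10/20, width 10
  cd2 <- cumulative_dvh("S", c(0, 10, 20), c(1, 0.6, 0), 50)
  dd2 <- cumulative_to_differential(cd2, bin_width = 10)
  expect_equal(dd2$bin_centers, c(5, 15))
  expect_equal(dd2$fractional_volumes, c(0.4, 0.6), tolerance = 1e-12)

  # residual volume above the curve end lands in the terminal bin
  cd3 <- cumulative_dvh("S", c(0, 10), c(1, 0.3), 50)
  dd3 <- cumulative_to_differential(cd3, bin_width = 5)
  expect_equal(sum(dd3$fractional_volumes), 1, tolerance = 1e-12)
  expect_equal(dd3$fractional_volumes[2], 0.35 + 0.3, tolerance = 1e-12)

  expect_error(cumulative_to_differential(cd, bin_width = 0), "positive")
})

test_that("differential -> cumulative is the tail-sum staircase", {
  dd <- differential_dvh("S", 78, 1)
  cd <- differential_to_cumulative(dd)
  expect_equal(volume_at_dose(cd, 50), 1)
  expect_equal(volume_at_dose(cd, 78), 1)       # center >= d convention
  expect_equal(volume_at_dose(cd, 78.5), 0)

  dd2 <- differential_dvh("S", c(60, 80), c(0.5, 0.5))
  cd2 <- differential_to_cumulative(dd2)
  expect_equal(volume_at_dose(cd2, 50), 1)      # bin edge below both centers
  expect_equal(volume_at_dose(cd2, 70), 0.5)    # edge between centers
  expect_equal(volume_at_dose(cd2, 85), 0)      # edge above both
  expect_equal(cd2$fraction[1], 1)

  expect_error(differential_dvh("S", numeric(0), numeric(0)), "at least one")
  expect_error(differential_dvh("S", c(60, 80), c(1.2, -0.2)),
               "non-negative")
})

test_that("conversion round trip reproduces the cumulative at bin edges", {
  set.seed(42)
  for (rep in 1:25) {
    cd <- random_cdvh(n_pts = sample(10:80, 1))
    bw <- sample(c(0.1, 0.5, 1, 2), 1)
    dd <- cumulative_to_differential(cd, bw)
    expect_equal(sum(dd$fractional_volumes), 1, tolerance = 1e-9)
    back <- differential_to_cumulative(dd, cd$total_volume)
    edges <- seq(0, by = bw, length.out = length(dd$bin_centers) + 1L)
    # interior edges; the terminal bin absorbs residual mass by design
    for (e in edges[edges <= max(cd$dose) & edges < max(edges)]) {
      expect_equal(volume_at_dose(back, e), volume_at_dose(cd, e),
                   tolerance = 1e-9)
    }
  }
})

test_that("dose_at_volume interpolates, honors ties and the D_min convention", {
  cd <- cumulative_dvh("S", c(0, 70, 80), c(1, 1, 0), 100)
  expect_equal(dose_at_volume(cd, 0.5), 75)
  expect_equal(dose_at_volume(cd, 0.02), 79.8)
  expect_equal(dose_at_volume(cd, 1), 70)   # highest dose still covering all

  u <- uniform_cdvh(78)
  expect_equal(dose_at_volume(u, 0.02), 78, tolerance = 1e-6)
  expect_equal(dose_at_volume(u, 0.5), 78, tolerance = 1e-6)
  expect_equal(dose_at_volume(u, 0.98), 78, tolerance = 1e-6)

  # flat segment at 0.5: tie resolves to the lowest dose
  cd2 <- cumulative_dvh("S", c(0, 10, 20, 30), c(1, 0.5, 0.5, 0), 100)
  expect_equal(dose_at_volume(cd2, 0.5), 10)

  expect_error(dose_at_volume(cd, 0), "in \\(0, 1\\]")
  expect_error(dose_at_volume(cd, 1.2), "in \\(0, 1\\]")
})

test_that("volume_at_dose interpolates and vanishes above the support", {
  cd <- cumulative_dvh("S", c(0, 70, 80), c(1, 1, 0), 100)
  expect_equal(volume_at_dose(cd, 74.1), 0.59)
  expect_equal(v_x_percent(cd, 95, 78), 59)
  expect_equal(v_x_percent(uniform_cdvh(78), 95, 78), 100)
  expect_equal(volume_at_dose(cd, 200), 0)
  expect_error(volume_at_dose(cd, -1), "non-negative")
})

test_that("dose_at_volume and volume_at_dose invert each other on strict segments", {
  cd <- cumulative_dvh("S", c(0, 60, 70, 80), c(1, 0.9, 0.4, 0), 100)
  for (fr in c(0.85, 0.6, 0.41, 0.2)) {
    expect_equal(volume_at_dose(cd, dose_at_volume(cd, fr)), fr,
                 tolerance = 1e-12)
  }
  for (d in c(62, 66, 71, 79)) {
    expect_equal(dose_at_volume(cd, volume_at_dose(cd, d)), d,
                 tolerance = 1e-12)
  }
})

test_that("dvh_summary matches hand results and orders its statistics", {
  u <- uniform_cdvh(78)
  s <- dvh_summary(u)
  expect_equal(s$min, 78)
  expect_equal(s$max, 78, tolerance = 1e-6)
  expect_equal(s$mean, 78, tolerance = 1e-6)
  expect_equal(s$median, 78, tolerance = 1e-6)

  # point masses 0.5/0.5 at 60 and 80 Gy: mean is 70; the median of the
  # tail-sum staircase under the ties-to-lowest-dose convention is the lower
  # mass point (any value in [60, 80] is a valid median of this distribution)
  dd <- differential_dvh("S", c(60, 80), c(0.5, 0.5))
  s2 <- dvh_summary(differential_to_cumulative(dd))
  expect_equal(s2$mean, 70, tolerance = 1e-6)
  expect_equal(s2$median, 60, tolerance = 1e-6)

  expect_error(dvh_summary(cumulative_dvh("S", 0, 1, 10)), "degenerate")

  set.seed(7)
  for (rep in 1:20) {
    s3 <- dvh_summary(random_cdvh())
    expect_lte(s3$min, s3$median)
    expect_lte(s3$median, s3$max)
    expect_lte(s3$min, s3$mean)
    expect_lte(s3$mean, s3$max)
  }
})
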