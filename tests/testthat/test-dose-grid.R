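make_ramp_grid <- function(n = c(9, 7, 5), spacing = c(2, 2, 2),
                           origin = c(0, 0, 0), slope = 0.5) {
  # dose = slope * x (mm), constant in y/z
  x <- origin[1] + (seq_len(n[1]) - 1) * spacing[1]
  vals <- array(rep(slope * x, times = n[2] * n[3]), dim = n)
  dose_grid(vals, origin, spacing)
}

test_that("grid containers validate their frames", {
  expect_error(dose_grid(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(dose_grid(array(-1, c(2, 2, 2))), ">= 0")
  expect_error(dose_grid(matrix(1, 2, 2)), "3D")
  expect_error(structure_mask(array(2, c(2, 2, 2))), "binary")
})

test_that("resampling identities: same frame, constants, linear ramps", {
  g <- make_ramp_grid()
  same <- resample_to_frame(g, grid_frame(g$origin, g$spacing, dim(g$values)))
  expect_equal(same$values, g$values, tolerance = 1e-12)

  const <- dose_grid(array(3.7, c(5, 5, 5)), c(0, 0, 0), c(4, 4, 4))
  fine <- resample_to_frame(const, grid_frame(c(2, 2, 2), c(1, 1, 1),
                                              c(9, 9, 9)))
  expect_true(all(abs(fine$values - 3.7) < 1e-12))

  # trilinear is exact on a linear field: midpoint offsets recover slope*x
  g2 <- make_ramp_grid(slope = 0.5, spacing = c(2, 2, 2))
  mid <- resample_to_frame(g2, grid_frame(c(1, 1, 1), c(2, 2, 2), c(7, 5, 3)))
  x_mid <- 1 + (seq_len(7) - 1) * 2
  expect_equal(mid$values[, 3, 2], 0.5 * x_mid, tolerance = 1e-12)

  # voxels outside the source support come back missing, not zero
  wide <- resample_to_frame(g2, grid_frame(c(-6, 0, 0), c(2, 2, 2), c(4, 3, 3)))
  expect_true(all(is.na(wide$values[1:2, , ])))
  expect_true(all(!is.na(wide$values[4, , ])))

  expect_error(resample_to_frame(g2, grid_frame(c(1000, 0, 0), c(1, 1, 1),
                                                c(3, 3, 3))),
               "overlap")
})

test_that("subtraction: zero self-difference, constants, anticommutativity", {
  g <- make_ramp_grid()
  z <- subtract_grids(g, g)
  expect_true(all(z$values == 0))

  a <- dose_grid(array(1.0, c(3, 3, 3)))
  b <- dose_grid(array(0.4, c(3, 3, 3)))
  expect_true(all(abs(subtract_grids(a, b)$values - 0.6) < 1e-12))
  expect_equal(subtract_grids(a, b)$values, -subtract_grids(b, a)$values)

  shifted <- dose_grid(array(1, c(3, 3, 3)), origin = c(0.5, 0, 0))
  expect_error(subtract_grids(a, shifted), "resample")
  ok <- subtract_grids(a, shifted, resample = TRUE)
  expect_equal(dim(ok$values), c(3L, 3L, 3L))
})

test_that("dvh_from_grid agrees with brute-force voxel counting", {
  # 10 masked voxels with doses 1..10 Gy
  vals <- array(0, c(5, 2, 1))
  vals[] <- 1:10
  g <- dose_grid(vals, spacing = c(10, 10, 10))
  m <- structure_mask(array(TRUE, c(5, 2, 1)), spacing = c(10, 10, 10))
  cd <- dvh_from_grid(g, m, bin_width = 0.5)
  expect_equal(volume_at_dose(cd, 5.5), 0.5)
  expect_equal(cd$total_volume, 10 * 1000 / 1000)  # 10 voxels of 1 cm^3

  # uniform dose: step DVH
  gu <- dose_grid(array(78, c(4, 4, 4)))
  mu <- structure_mask(array(TRUE, c(4, 4, 4)))
  cdu <- dvh_from_grid(gu, mu)
  expect_equal(volume_at_dose(cdu, 77.9), 1)
  expect_equal(volume_at_dose(cdu, 78.2), 0)

  # every bin edge agrees with a direct >= count; mean within half a bin
  set.seed(5)
  vals2 <- array(runif(6 * 5 * 4, 0, 80), c(6, 5, 4))
  mask2 <- array(runif(6 * 5 * 4) < 0.4, c(6, 5, 4))
  g2 <- dose_grid(vals2, spacing = c(2.5, 2.5, 2.5))
  m2 <- structure_mask(mask2, spacing = c(2.5, 2.5, 2.5))
  bw <- 1
  cd2 <- dvh_from_grid(g2, m2, bin_width = bw, structure_name = "R")
  doses <- vals2[mask2]
  for (e in seq(0, 80, by = 7)) {
    expect_equal(volume_at_dose(cd2, e), mean(doses >= e), tolerance = 1e-9)
  }
  expect_lt(abs(dvh_summary(cd2)$mean - mean(doses)), bw / 2)

  expect_error(dvh_from_grid(g2, structure_mask(array(FALSE, c(6, 5, 4)),
                                                spacing = c(2.5, 2.5, 2.5))),
               "empty mask")
})

test_that("masked_difference_stats summarizes signed differences", {
  z <- subtract_grids(make_ramp_grid(), make_ramp_grid())
  m <- structure_mask(array(TRUE, dim(z$values)), z$origin, z$spacing)
  s <- masked_difference_stats(z, m)
  expect_equal(c(s$mean, s$min, s$max), c(0, 0, 0))
  expect_equal(s$exceedance$frac_abs_above, c(0, 0, 0))

  a <- dose_grid(array(1.0, c(4, 4, 4)))
  b <- dose_grid(array(0.4, c(4, 4, 4)))
  s2 <- masked_difference_stats(subtract_grids(a, b),
                                structure_mask(array(TRUE, c(4, 4, 4))))
  expect_equal(c(s2$mean, s2$min, s2$max), c(0.6, 0.6, 0.6))

  # half at +1, half at -1
  vals <- array(rep(c(1, 0), each = 32), c(4, 4, 4))
  d <- subtract_grids(dose_grid(vals), dose_grid(1 - vals))
  s3 <- masked_difference_stats(d, structure_mask(array(TRUE, c(4, 4, 4))))
  expect_equal(s3$mean, 0)
  expect_equal(s3$exceedance$frac_abs_above[s3$exceedance$threshold == 0.5], 1)

  # missing voxels are excluded and reported
  dv <- d
  dv$values[1:8] <- NA
  s4 <- masked_difference_stats(dv, structure_mask(array(TRUE, c(4, 4, 4))))
  expect_equal(s4$excluded_fraction, 8 / 64)
  expect_equal(s4$n, 56)
})

test_that("round-trip resample (fine then back) stays within reconstruction error", {
  # smooth band-limited field
  n <- c(12, 12, 12)
  x <- seq(0, 1, length.out = n[1])
  f <- outer(outer(sin(pi * x), cos(pi * x / 2)), rep(1, n[3]))
  g <- dose_grid(10 + 5 * array(f, n), spacing = c(4, 4, 4))
  fine <- resample_to_frame(g, grid_frame(g$origin, c(2, 2, 2), c(23, 23, 23)))
  back <- resample_to_frame(fine, grid_frame(g$origin, c(4, 4, 4), n))
  interior <- back$values[3:10, 3:10, 3:10] - g$values[3:10, 3:10, 3:10]
  expect_lt(max(abs(interior)), 0.05)  # trilinear reconstruction bound
})

test_that("grid text format round-trips bit-exactly", {
  set.seed(8)
  g <- dose_grid(array(runif(3 * 4 * 5, 0, 80), c(3, 4, 5)),
                 origin = c(-1.25, 3.5, 0), spacing = c(2.5, 2, 1.5))
  path <- tempfile(fileext = ".grid")
  write_dose_grid(g, path)
  back <- read_dose_grid(path)
  expect_identical(back$values, g$values)
  expect_identical(back$origin, g$origin)
  expect_identical(back$spacing, g$spacing)

  m <- structure_mask(array(runif(24) < 0.5, c(2, 3, 4)), spacing = c(1, 2, 3))
  path2 <- tempfile(fileext = ".grid")
  write_dose_grid(m, path2)
  back2 <- read_dose_grid(path2)
  expect_identical(back2$values, m$values)
  expect_s3_class(back2, "structure_mask")
  unlink(c(path, path2))
})
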