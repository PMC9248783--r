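test_that("smoothing reproduces polynomials in its fit space and respects flags", {
  grid <- seq(65, 75, by = 0.1)
  quad <- 3 - 0.2 * grid + 0.01 * grid^2
  d <- melt_tbl(list(w = quad), grid)
  expect_equal(smooth_rfu(d)$rfu, quad, tolerance = 1e-9)
  const <- melt_tbl(list(w = rep(7, length(grid))), grid)
  expect_equal(smooth_rfu(const)$rfu, rep(7, length(grid)))
  noisy <- melt_tbl(list(w = quad + rnorm(length(grid))), grid)
  expect_identical(smooth_rfu(noisy, enabled = FALSE), noisy)

  irregular <- melt_tbl(list(w = c(1, 2, 3, 4, 5, 6, 7)),
                        c(65, 65.1, 65.2, 65.35, 65.4, 65.5, 65.6))
  expect_error(smooth_rfu(irregular), "regrid")
  expect_error(smooth_rfu(d, window = 6), "odd")
  expect_error(smooth_rfu(d[1:30, ], window = 51), "larger than")
})

test_that("negative derivative uses central differences inside, one-sided at ends", {
  d <- melt_tbl(list(w = c(100, 90, 70)), c(65.0, 65.1, 65.2))
  mc <- melt_curves(d, smooth = FALSE)
  expect_equal(mc$dneg, c(100, 150, 200))  # -(90-100)/0.1, -(70-100)/0.2, -(70-90)/0.1

  grid <- seq(65, 70, by = 0.1)
  lin <- melt_tbl(list(w = 500 - 4 * grid), grid)
  expect_equal(melt_curves(lin, smooth = FALSE)$dneg, rep(4, length(grid)))

  const <- melt_tbl(list(w = rep(3, length(grid))), grid)
  expect_equal(melt_curves(const, smooth = FALSE)$dneg, rep(0, length(grid)))

  expect_error(melt_curves(melt_tbl(list(w = c(1, 2)), c(65, 66)),
                           smooth = FALSE), "3 points")
})

test_that("trapezoidal integral of -dF/dT recovers the fluorescence drop", {
  grid <- ramp_grid()
  f <- logistic_f(grid, 78.4, width = 0.8)
  mc <- melt_curves(melt_tbl(list(w = f), grid), smooth = FALSE)
  integral <- sum(diff(grid) * (head(mc$dneg, -1) + tail(mc$dneg, -1)) / 2)
  expect_equal(integral, f[[1L]] - f[[length(f)]], tolerance = 1e-3)
})

test_that("Tm calling finds the peak, refines it, and flags boundary maxima", {
  grid <- ramp_grid()
  for (tm in c(78.3, 72.07, 81.55)) {
    for (width in c(0.3, 0.6, 1.2)) {
      mc <- melt_curves(melt_tbl(list(w = logistic_f(grid, tm, width)), grid))
      called <- call_tm(mc)
      expect_false(called$no_peak)
      expect_lt(abs(called$tm - tm), 0.05)
    }
  }
  # monotone increasing dneg -> boundary maximum -> no_peak
  rising <- curves_tbl(list(w = seq(0, 1, length.out = 11)), 65:75)
  called <- call_tm(rising)
  expect_true(called$no_peak)
  expect_true(is.na(called$tm))
  # symmetric triangular peak on a grid point -> exactly that temperature
  tri <- curves_tbl(list(w = c(0, 1, 2, 1, 0)), c(70, 71, 72, 73, 74))
  expect_equal(call_tm(tri)$tm, 72)
})

test_that("replicate averaging is a pointwise mean with grid checks", {
  grid <- c(70, 71)
  cv <- curves_tbl(list(r1 = c(0, 2), r2 = c(2, 0), solo = c(5, 5)), grid)
  cv$replicate_group <- c("g", "g", "g", "g", "solo", "solo")
  avg <- average_replicates(cv)
  expect_equal(unique(avg$sample_id), c("g", "solo"))
  expect_equal(avg$dneg[avg$sample_id == "g"], c(1, 1))
  expect_equal(avg$dneg[avg$sample_id == "solo"], c(5, 5))

  plate <- simulate_melt_plate(setNames(72 + 0.9 * (0:2), c("a", "b", "c")),
                               replicates = c(5L), seed = 2L)
  cv5 <- melt_curves(plate$data)
  avg5 <- average_replicates(cv5)
  expect_equal(length(unique(avg5$sample_id)), 3L)
  five <- cv5[cv5$replicate_group == "a", ]
  expect_equal(avg5$dneg[avg5$sample_id == "a"],
               colMeans(matrix(five$dneg, nrow = 5, byrow = TRUE)))

  mismatch <- dplyr::bind_rows(
    tibble::tibble(sample_id = "x", replicate_group = "g",
                   temperature = c(70, 71), dneg = c(1, 2)),
    tibble::tibble(sample_id = "y", replicate_group = "g",
                   temperature = c(70, 71.5), dneg = c(1, 2)))
  expect_error(average_replicates(mismatch), "g")
})

test_that("difference curves subtract each curve from the reference mean", {
  cv <- curves_tbl(list(a = c(2, 4), b = c(0, 0), c = c(1, 2)), c(70, 71))
  dd <- difference_curves(cv)
  expect_equal(dd$delta[dd$sample_id == "a"], c(-1, -2))
  expect_equal(dd$delta[dd$sample_id == "b"], c(1, 2))
  expect_equal(dd$delta[dd$sample_id == "c"], c(0, 0))
  sums <- tapply(dd$delta, dd$temperature, sum)
  expect_equal(as.numeric(sums), c(0, 0))

  one <- difference_curves(curves_tbl(list(a = c(1, 2)), c(70, 71)))
  expect_equal(one$delta, c(0, 0))

  # curves outside the reference set are differenced against the same mean
  dd2 <- difference_curves(cv, reference = c("a", "b"))
  expect_equal(dd2$delta[dd2$sample_id == "c"], c(0, 0))
  expect_equal(dd2$delta[dd2$sample_id == "a"], c(-1, -2))
})

test_that("pipeline is offset-invariant and scale-equivariant", {
  grid <- ramp_grid()
  plate <- simulate_melt_plate(c(a = 74, b = 78), replicates = 2L, seed = 5L)
  base_curves <- melt_curves(plate$data)
  base_diffs <- difference_curves(base_curves)

  shifted <- dplyr::mutate(plate$data, rfu = rfu + 123)
  expect_equal(melt_curves(shifted)$dneg, base_curves$dneg, tolerance = 1e-9)

  scaled <- dplyr::mutate(plate$data, rfu = rfu * 3.5)
  expect_equal(melt_curves(scaled)$dneg, 3.5 * base_curves$dneg,
               tolerance = 1e-9)
  expect_equal(difference_curves(melt_curves(scaled))$delta,
               3.5 * base_diffs$delta, tolerance = 1e-9)
})

test_that("regridding is linear interpolation and refuses extrapolation", {
  grid <- seq(65, 70, by = 0.5)
  lin <- melt_tbl(list(w = 10 - 2 * grid), grid)
  same <- regrid_curves(lin, grid)
  expect_equal(same$rfu, lin$rfu)
  target <- seq(65.1, 69.9, by = 0.2)
  rg <- regrid_curves(lin, target)
  expect_equal(rg$rfu, 10 - 2 * target, tolerance = 1e-12)
  expect_error(regrid_curves(lin, seq(64, 70, 0.5)), "extrapolation")
})

test_that("normalized-fluorescence mode rescales between melt baselines", {
  grid <- ramp_grid()
  d <- melt_tbl(list(w = logistic_f(grid, 78, b0 = 5, b1 = 0)), grid)
  nn <- normalize_fluorescence(d)
  expect_lt(abs(max(nn$rfu_norm) - 100), 1.0)
  expect_lt(abs(min(nn$rfu_norm)), 1.0)
  expect_equal(nn$rfu_norm[which.min(abs(nn$temperature - 78))], 50,
               tolerance = 1)
})
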