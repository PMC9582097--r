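test_that("image-count rule: smallest n with n*floor(side/pitch)^2 >= min_pixels", {
  expect_equal(required_image_count(0.085, 50, 4e6), 12)
  expect_lt(11 * 588^2, 4e6)
  expect_gte(12 * 588^2, 4e6)
  expect_equal(required_image_count(0.1, 51.2, 262144), 1)
  expect_equal(required_image_count(0.1, 51.2, 0), 1)
  expect_error(required_image_count(0.1, 20), "256")
})

test_that("ROI tiling: 128-px steps, fully contained ROIs only", {
  expect_equal(tile_rois(matrix(0, 256, 256))$m, 1)
  t9 <- tile_rois(matrix(0, 512, 512))
  expect_equal(t9$m, 9)
  expect_equal(tile_rois(matrix(0, 588, 588))$m, 9)
  expect_equal(t9$step, 128)
  # every ROI inside the region
  expect_true(all(t9$origins >= 0))
  expect_true(all(t9$origins + 256 <= 512))
  expect_error(tile_rois(matrix(0, 200, 300)), "smaller")
})

test_that("detrend: mean zeroes a constant, poly2 absorbs a planar ramp", {
  expect_equal(detrend(matrix(7, 20, 20), "mean"), matrix(0, 20, 20))
  expect_identical(detrend(matrix(7, 20, 20), "none"), matrix(7, 20, 20))
  x <- matrix(rep(1:30, each = 20), 20, 30)
  y <- matrix(rep(1:20, times = 30), 20, 30)
  ramp <- 5 + 0.3 * x - 0.7 * y
  expect_lt(max(abs(detrend(ramp, "poly2"))), 1e-9 * max(abs(ramp)))
  quad <- 1 + x + y + 0.01 * x^2 - 0.02 * x * y + 0.03 * y^2
  expect_lt(max(abs(detrend(quad, "poly2"))), 1e-8 * max(abs(quad)))
  expect_error(detrend(ramp, "median"), "method")
})

test_that("fast-transform periodogram equals the literal double sum on small grids", {
  set.seed(12)
  for (n in c(4L, 8L, 16L)) {
    reg <- matrix(rnorm(4 * n * n), 2 * n, 2 * n)
    w <- nps_2d(reg, dx = 0.085, dy = 0.1, roi_size = n)
    wo <- nps_2d_bruteforce(reg, dx = 0.085, dy = 0.1, n = n)
    expect_lt(max(abs(w$w - wo)) / max(wo), 1e-12)
    expect_equal(w$m_total, tile_rois(reg, n)$m)
  }
})

test_that("white-noise NPS sits at sigma^2*dx*dy and satisfies Parseval", {
  set.seed(3)
  sigma <- 2.5
  regs <- lapply(1:6, function(i) matrix(rnorm(512^2, sd = sigma), 512, 512))
  w <- nps_2d(regs, dx = 0.1, dy = 0.1)
  expect_gte(w$m_total, 50) # 6 images x 9 overlapping ROIs
  off <- w$w; off[1, 1] <- NA
  expect_rel_equal(mean(off, na.rm = TRUE), sigma^2 * 0.1 * 0.1, 0.05)
  # Parseval: sum of bins * df_u * df_v = mean per-ROI mean square
  msq <- mean(vapply(regs, function(r) {
    t <- tile_rois(r)
    mean(vapply(seq_len(t$m), function(i)
      mean(r[t$origins[i, 1] + 1:256, t$origins[i, 2] + 1:256]^2), 0))
  }, 0))
  expect_rel_equal(sum(w$w) * w$df_u * w$df_v, msq, 1e-6)
  expect_true(all(w$w >= 0))
})

test_that("white-noise stack reaches M >= 50 ROIs with x/y isotropy", {
  set.seed(21)
  regs <- lapply(1:7, function(i) matrix(rnorm(512^2), 512, 512))
  w <- nps_2d(regs, dx = 0.085, dy = 0.085)
  expect_gte(w$m_total, 50)
  sx <- nps_1d(w, "x"); sy <- nps_1d(w, "y")
  expect_equal(mean(sx$values), mean(sy$values), tolerance = 0.02)
  expect_rel_equal(mean(sx$values), 0.085^2, 0.05)
})

test_that("mean subtraction changes only the zero-frequency bin", {
  set.seed(8)
  reg <- matrix(rnorm(512^2, mean = 100), 512, 512)
  w_none <- nps_2d(detrend(reg, "none"), 0.085, 0.085)
  w_mean <- nps_2d(detrend(reg, "mean"), 0.085, 0.085)
  d <- abs(w_none$w - w_mean$w)
  d[1, 1] <- 0 # the zero bin is the one allowed to differ
  expect_lt(max(d), 1e-6 * max(w_mean$w[-1]))
})

test_that("poly2 detrending recovers the trend-free NPS of a corrupted flat field", {
  m_clean <- detector_model(seed = 14, gain = 1, offset = 0, quantize = FALSE)
  m_trend <- detector_model(seed = 14, gain = 1, offset = 0, quantize = FALSE,
                            trend = list(type = "quad",
                                         coef = c(1, 2e-3, -1e-3, 2e-4, 1e-4, 3e-4)))
  q <- 5e4
  f_clean <- gen_flat_field(m_clean, q, shape = c(512, 512))$pixels
  f_trend <- gen_flat_field(m_trend, q, shape = c(512, 512))$pixels
  w_clean <- nps_2d(detrend(f_clean, "mean"), 0.085, 0.085)
  w_poly <- nps_2d(detrend(f_trend, "poly2"), 0.085, 0.085)
  s_clean <- nps_1d(w_clean, "x")$values
  s_poly <- nps_1d(w_poly, "x")$values
  # Poisson white level tracks the mean fluence; the trend raises that mean,
  # so the detrended spectrum must sit at the trended image's own mean level
  expect_lt(abs(mean(s_clean) / q - 1), 0.05)
  expect_lt(abs(mean(s_poly) / mean(f_trend) - 1), 0.05)
  # and the trend structure itself (low-frequency power) is gone: the first
  # spectral bins stay at the white level instead of blowing up
  expect_lt(max(s_poly[1:5]) / mean(s_poly), 3)
})

test_that("axis exclusion: a spectrum living only on the axis averages to zero", {
  w <- nps_2d(matrix(0, 256, 256), 0.1, 0.1)
  w$w[] <- 0
  w$w[1, ] <- 99 # v = 0 axis line
  s <- nps_1d(w, "x")
  expect_true(all(s$values == 0))
  w$w[] <- 3.5 # constant spectrum averages to itself
  s2 <- nps_1d(w, "x")
  expect_true(all(s2$values == 3.5))
  expect_equal(s2$n_lines_averaged, 14)
  expect_equal(length(s2$freqs), 128)
  expect_equal(max(s2$freqs), 1 / (2 * 0.1))
  expect_true(all(diff(s2$freqs) > 0))
})

test_that("NNPS algebra: scaling laws and the Poisson 1/Q law", {
  w <- nps_2d(matrix(0, 256, 256), 0.1, 0.1)
  w$w[] <- 4
  s <- nps_1d(w, "x")
  expect_true(all(nnps(s, mean_linearized = 2)$values == 1))
  expect_equal(nnps(s, mean_linearized = 4)$values,
               nnps(s, mean_linearized = 2)$values / 4)
  expect_error(nnps(s, mean_linearized = 0), "positive")
  # ideal Poisson flat field at fluence Q: NNPS ~= 1/Q
  m <- detector_model(seed = 6, gain = 1, offset = 0, quantize = FALSE)
  q <- 2e5
  regs <- lapply(1:3, function(i)
    gen_flat_field(m, q, shape = c(512, 512), seed = 6 + i)$pixels)
  mean_lin <- mean(vapply(regs, mean, 0))
  w2 <- nps_2d(lapply(regs, detrend, method = "mean"), 0.085, 0.085,
               mean_linearized = mean_lin)
  nn <- nnps(nps_1d(w2, "x"))
  expect_rel_equal(mean(nn$values), 1 / q, 0.05)
})
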