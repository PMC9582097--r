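test_that("inverse-square geometry factor matches direct arithmetic", {
  expect_equal(geometry_correction_factor(
    list(d_source_detector = 700, d_source_chamber = 700)), 1)
  expect_equal(geometry_correction_factor(
    list(d_source_detector = 1300, d_source_chamber = 650)), 0.25)
  expect_equal(geometry_correction_factor(
    list(d_source_detector = 660, d_source_chamber = 650)), (650 / 660)^2)
  expect_error(geometry_correction_factor(
    list(d_source_detector = -1, d_source_chamber = 650)), "positive")
})

test_that("geometry factor is monotone in detector distance and scale invariant", {
  set.seed(5)
  for (i in 1:25) {
    d_ch <- runif(1, 400, 700)
    d1 <- d_ch + runif(1, 0, 100)
    d2 <- d1 + runif(1, 1, 100)
    f1 <- geometry_correction_factor(list(d_source_detector = d1, d_source_chamber = d_ch))
    f2 <- geometry_correction_factor(list(d_source_detector = d2, d_source_chamber = d_ch))
    expect_lt(f2, f1)
    s <- runif(1, 0.1, 10)
    expect_equal(geometry_correction_factor(
      list(d_source_detector = s * d1, d_source_chamber = s * d_ch)), f1)
  }
})

test_that("noise-free linear calibration is recovered exactly with R^2 = 1", {
  geom <- list(d_source_detector = 660, d_source_chamber = 650)
  fac <- geometry_correction_factor(geom)
  beam <- beam_quality("W/Rh", 30, 6179)
  kerma <- c(10, 20, 40, 80, 160)
  pts <- data.frame(kerma_measured = kerma, mean_pv = 12.5 * kerma * fac + 33.25)
  fit <- fit_conversion(pts, beam, geom)
  expect_equal(fit$slope_pv_per_ugy, 12.5, tolerance = 1e-10)
  expect_equal(fit$intercept_pv, 33.25, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(fit$compliant)
  expect_equal(fit$slope_pv_per_fluence, 12.5 / 6179, tolerance = 1e-10)
})

test_that("a badly perturbed point yields compliant = FALSE with a warning, not an error", {
  geom <- list(d_source_detector = 660, d_source_chamber = 660)
  beam <- beam_quality("W/Rh", 30, 6179)
  pts <- data.frame(kerma_measured = c(10, 20, 40, 80),
                    mean_pv = c(100, 200, 4000, 800))
  expect_warning(fit <- fit_conversion(pts, beam, geom), "0.99")
  expect_false(fit$compliant)
  expect_lt(fit$r_squared, 0.99)
  expect_error(linearize(matrix(100, 4, 4), fit), "compliant")
  expect_silent(linearize(matrix(100, 4, 4), fit, allow_noncompliant = TRUE))
})

test_that("fit requires >= 3 points with kerma variance", {
  geom <- list(d_source_detector = 660, d_source_chamber = 660)
  beam <- beam_quality("W/Rh", 30, 6179)
  expect_error(fit_conversion(data.frame(kerma_measured = c(1, 2), mean_pv = c(1, 2)),
                              beam, geom), "3")
  expect_error(fit_conversion(data.frame(kerma_measured = c(2, 2, 2), mean_pv = 1:3),
                              beam, geom), "variance")
})

test_that("fluence basis: 1 uGy at W/Rh 30 kV corresponds to Q = 6179 mm^-2", {
  beam <- lookup_snr_in2("W/Rh", 30)
  geom <- list(d_source_detector = 660, d_source_chamber = 660)
  kerma <- c(0.5, 1, 2, 4)
  pts <- data.frame(kerma_measured = kerma, mean_pv = 10 * kerma + 5)
  fit <- fit_conversion(pts, beam, geom)
  # linearizing the pixel value seen at KAD = 1 uGy must give Q = 6179 mm^-2
  q <- linearize(matrix(10 * 1 + 5, 2, 2), fit)
  expect_equal(q[1, 1], 6179, tolerance = 1e-9)
})

test_that("linearize inverts the forward conversion over random affine parameters", {
  set.seed(17)
  geom <- list(d_source_detector = 700, d_source_chamber = 650)
  fac <- geometry_correction_factor(geom)
  for (i in 1:25) {
    slope <- runif(1, 0.5, 50)
    intercept <- runif(1, -100, 500)
    snr2 <- runif(1, 3000, 9000)
    beam <- beam_quality("x", 30, snr2)
    kerma <- sort(runif(5, 1, 200))
    pts <- data.frame(kerma_measured = kerma, mean_pv = slope * kerma * fac + intercept)
    fit <- fit_conversion(pts, beam, geom)
    pv <- matrix(runif(16, intercept, intercept + slope * 200), 4, 4)
    q <- linearize(pv, fit)
    pv_back <- q * fit$slope_pv_per_fluence + fit$intercept_pv
    expect_equal(pv_back, pv, tolerance = 1e-9)
    # pv at the intercept maps to zero fluence
    expect_equal(linearize(matrix(intercept, 1, 1), fit)[1, 1], 0,
                 tolerance = 1e-8)
  }
})

test_that("SNR_in^2 lookup rejects unknown beam qualities instead of interpolating", {
  expect_error(lookup_snr_in2("Mo/Mo", 28), "Mo/Mo")
  expect_error(lookup_snr_in2("W/Rh", 31), "31")
})

test_that("flat image linearized mean equals the fluence predicted by the fit", {
  m <- detector_model(seed = 4, noise = "none", quantize = FALSE)
  beam <- beam_quality("W/Rh", 30, 6179)
  geom <- list(d_source_detector = 660, d_source_chamber = 660)
  series <- gen_calibration_series(m, c(10, 20, 40), 6179, shape = c(32, 32))
  pts <- data.frame(
    kerma_measured = vapply(series, `[[`, 0, "kerma"),
    mean_pv = vapply(series, function(s) mean(s$image$pixels), 0))
  fit <- fit_conversion(pts, beam, geom)
  img <- gen_flat_small(m, fluence = 123456, shape = c(32, 32))
  expect_equal(mean(linearize(img, fit)), 123456, tolerance = 1e-8)
})
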