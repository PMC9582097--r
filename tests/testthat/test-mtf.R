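# Noise-free generator model shared by the geometric checks.
edge_model <- function(sigma = 0.05, ...)
  detector_model(psf_sigma = sigma, noise = "none", quantize = FALSE, ...)

test_that("edge angle and centre are recovered from a synthetic 2-degree edge", {
  m <- edge_model()
  img <- gen_edge_image(m, 2.0, 3e5, 3e4, shape = c(420, 300))
  e <- find_edge(img$pixels, m$dx, m$dy)
  expect_lt(abs(e$angle_deg - 2.0), 0.05)
  expect_equal(e$orientation, "x")
  expect_equal(e$polarity, 1)
  # edge runs through the image centre
  expect_lt(abs(e$center["col"] - 150.5), 1)
})

test_that("degenerate edges are rejected: no edge, or angle at the 0-degree boundary", {
  expect_error(find_edge(matrix(100, 100, 100), 0.1, 0.1), "step")
  # a perfectly vertical edge: tan(alpha) = 0, oversampling impossible
  px <- cbind(matrix(10, 100, 50), matrix(1000, 100, 50))
  expect_warning(e <- find_edge(px, 0.1, 0.1, orientation = "vertical"),
                 "angle")
  expect_error(build_esf(px, e, 0.1, 0.1), "oversampling|sections|steep")
})

test_that("ESF sub-pixel grid follows N = round(1/tan(alpha))", {
  m <- edge_model()
  a <- atan(1 / 10) * 180 / pi # 1/tan = 10 exactly
  img <- gen_edge_image(m, a, 3e5, 3e4, shape = c(420, 300))
  e <- find_edge(img$pixels, m$dx, m$dy)
  esf <- build_esf(img$pixels, e, m$dx, m$dy)
  expect_equal(esf$n, 10)
  expect_equal(esf$h, m$dx / 10)
  expect_gte(length(esf$values), 2 * esf$n)
  expect_equal(diff(esf$positions), rep(esf$h, length(esf$positions) - 1))
})

test_that("noise-free ESF spans the full step amplitude and matches the erf profile", {
  m <- edge_model(sigma = 0.05)
  img <- gen_edge_image(m, 2.5, 3e5, 3e4, shape = c(840, 300))
  e <- find_edge(img$pixels, m$dx, m$dy)
  esf <- build_esf(img$pixels, e, m$dx, m$dy)
  gain_a <- m$gain * (3e5 - 3e4)
  expect_equal(diff(range(esf$values)), gain_a, tolerance = 0.005)
  expect_gte(esf$n_sections, 20)
  # aperture-convolved analytic profile, allowing a sub-bin registration shift
  base <- m$gain * 3e4 + m$offset
  prof <- function(x, x0) {
    z <- (x - x0)
    s <- m$psf_sigma
    base + gain_a * (s / m$dx) *
      ((function(u) u * pnorm(u) + dnorm(u))((z + m$dx / 2) / s) -
       (function(u) u * pnorm(u) + dnorm(u))((z - m$dx / 2) / s))
  }
  shifts <- seq(-esf$h, esf$h, length.out = 41)
  dev <- vapply(shifts, function(s0)
    max(abs(esf$values - prof(esf$positions, s0))), 0)
  expect_lt(min(dev) / gain_a, 0.01)
})

test_that("LSF central difference is exact for ramps and constants", {
  esf <- list(positions = (1:50) * 0.01, values = 3 + 0.7 * (1:50) * 0.01,
              h = 0.01, angle_deg = 2, direction = "x", dx = 0.1,
              n = 10, n_sections = 5)
  lsf <- lsf_from_esf(esf)
  expect_equal(lsf$values, rep(0.7, 48), tolerance = 1e-12)
  esf$values <- rep(5, 50)
  expect_equal(lsf_from_esf(esf)$values, rep(0, 48))
  esf$values <- esf$values[1:2]
  expect_error(lsf_from_esf(esf), "3")
})

test_that("Gaussian-PSF edge: LSF width and MTF match the closed forms", {
  m <- edge_model(sigma = 0.06)
  img <- gen_edge_image(m, 2.5, 3e5, 3e4, shape = c(840, 300))
  gt <- attr(img, "ground_truth")
  e <- find_edge(img$pixels, m$dx, m$dy)
  lsf <- lsf_from_esf(build_esf(img$pixels, e, m$dx, m$dy))
  # effective sigma recovered from the second moment of the LSF
  wts <- pmax(lsf$values, 0)
  mu <- sum(lsf$positions * wts) / sum(wts)
  sd_emp <- sqrt(sum((lsf$positions - mu)^2 * wts) / sum(wts))
  sd_expected <- sqrt(0.06^2 + m$dx^2 / 12 + lsf$h^2 / 6) # psf + aperture + kernel
  expect_equal(sd_emp, sd_expected, tolerance = 0.01)
  mtf <- slanted_edge_mtf(img$pixels, m$dx, m$dy)
  expect_lt(max(abs(mtf$values - gt$mtf(mtf$freqs))), 0.02)
})

test_that("MTF normalization: exactly 1 at zero frequency for varied inputs", {
  for (sg in c(0, 0.04, 0.08)) {
    m <- edge_model(sigma = sg)
    img <- gen_edge_image(m, 3, 2e5, 2e4, shape = c(420, 300))
    mtf <- slanted_edge_mtf(img$pixels, m$dx, m$dy)
    expect_identical(mtf$values[1], 1)
    expect_lte(max(mtf$freqs), 1 / (2 * m$dx) + 1e-12)
  }
})

test_that("perfectly sharp edge reproduces the pixel-aperture sinc", {
  m <- edge_model(sigma = 0)
  img <- gen_edge_image(m, 2.5, 3e5, 3e4, shape = c(420, 300))
  mtf <- slanted_edge_mtf(img$pixels, m$dx, m$dy)
  ap <- abs(sin(pi * mtf$freqs * m$dx) / (pi * mtf$freqs * m$dx))
  ap[1] <- 1
  expect_lt(max(abs(mtf$values - ap)), 0.02)
})

test_that("presampling MTF is invariant to the edge angle over 1.5-4 degrees", {
  m <- edge_model(sigma = 0.05)
  curves <- lapply(c(1.5, 2.3, 3.1, 4.0), function(a) {
    img <- gen_edge_image(m, a, 3e5, 3e4, shape = c(840, 300))
    mtf <- slanted_edge_mtf(img$pixels, m$dx, m$dy)
    expect_lt(abs(attr(mtf, "edge")$angle_deg - a), 0.05)
    mtf$values
  })
  for (i in 2:4)
    expect_lt(max(abs(curves[[i]] - curves[[1]])), 0.02)
})

test_that("MTF of Gaussian-PSF edges is monotone non-increasing after rebinning", {
  m <- edge_model(sigma = 0.07)
  img <- gen_edge_image(m, 2.5, 3e5, 3e4, shape = c(840, 300))
  mtf <- slanted_edge_mtf(img$pixels, m$dx, m$dy)
  expect_true(all(diff(mtf$values) <= 1e-6))
})

test_that("MTF is invariant to edge polarity", {
  m <- edge_model(sigma = 0.05)
  img <- gen_edge_image(m, 2.5, 3e5, 3e4, shape = c(420, 300))
  flipped <- img$pixels[, ncol(img$pixels):1]
  m1 <- slanted_edge_mtf(img$pixels, m$dx, m$dy)
  m2 <- slanted_edge_mtf(flipped, m$dx, m$dy)
  expect_equal(attr(m2, "edge")$polarity, -1)
  expect_lt(max(abs(m1$values - m2$values)), 0.01)
})

test_that("rebinning: identity on matching grids, mean-preserving on constants", {
  fine <- structure(list(freqs = (0:128) * (1 / (256 * 0.1)),
                         values = rep(0.5, 129), direction = "x",
                         angle_used = 2, fine = TRUE, h = 0.01, dx = 0.1,
                         n_lines = 100), class = "mtf_curve")
  out <- rebin_mtf(fine, fine$freqs, nyquist = 5)
  expect_equal(out$values[-1], rep(0.5, 128))
  expect_equal(out$values[1], 1) # forced normalization at f = 0
  gauss <- fine
  gauss$values <- exp(-2 * pi^2 * 0.05^2 * fine$freqs^2)
  out2 <- rebin_mtf(gauss, fine$freqs, nyquist = 5)
  expect_equal(out2$values[-1], gauss$values[-1], tolerance = 1e-12)
  short <- fine
  short$freqs <- short$freqs[1:10]; short$values <- short$values[1:10]
  expect_error(rebin_mtf(short, fine$freqs, nyquist = 5), "Nyquist")
})

test_that("edge orientation sets the MTF direction label (two-image protocol)", {
  m <- edge_model()
  iv <- gen_edge_image(m, 2.5, 3e5, 3e4, shape = c(420, 300), orientation = "vertical")
  ih <- gen_edge_image(m, 2.5, 3e5, 3e4, shape = c(300, 420), orientation = "horizontal")
  expect_equal(slanted_edge_mtf(iv$pixels, m$dx, m$dy)$direction, "x")
  expect_equal(slanted_edge_mtf(ih$pixels, m$dx, m$dy)$direction, "y")
})
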