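# Synthetic detector forward model: generates the flat-field, slanted-edge
# and calibration images the measurement chain consumes, with exact known
# ground truth (STP slope/intercept, presampling MTF, noise power) so every
# stage can be validated without any real acquisition.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Synthetic detector model
#'
#' Forward model of an ideal(izable) flat-panel detector: pixel pitch, affine
#' signal transfer (`pv = offset + gain * fluence`), optional Gaussian PSF,
#' a choice of noise models, and an optional multiplicative large-scale
#' trend. The same seed always yields bit-identical images.
#'
#' @param dx,dy Pixel pitch, mm (default 0.085, a typical mammography panel).
#' @param gain Pixel value per unit fluence (PV mm^2).
#' @param offset Pixel value at zero fluence.
#' @param psf_sigma Gaussian PSF width, mm; 0 means aperture-only blur.
#' @param noise `"poisson"` (quantum-limited), `"none"`, or
#'   `list(type = "gaussian", sd = <PV>)`.
#' @param trend `"none"`, `list(type = "plane", a, b, c)` (multiplicative
#'   fluence factor `a + b*x + c*y`, x/y in mm from the image centre), or
#'   `list(type = "quad", coef = c(a, bx, by, bxx, bxy, byy))`.
#' @param seed Base RNG seed; generator calls derive from it.
#' @param quantize Round pixel values to integers (real detectors do);
#'   disable for analytic zero-noise checks.
#' @param aperture Integrate the edge profile over the pixel aperture
#'   (default TRUE, real sampling). With `FALSE` the profile is point-sampled
#'   at pixel centres: the ground-truth MTF then has no sinc factor, which
#'   makes the aperture-free ideal detector (DQE = 1 at all frequencies)
#'   constructible.
#' @return A `detector_model` list.
#' @export
detector_model <- function(dx = 0.085, dy = 0.085, gain = 0.04, offset = 50,
                           psf_sigma = 0, noise = "poisson", trend = "none",
                           seed = 1L, quantize = TRUE, aperture = TRUE) {
  if (gain <= 0) stop("gain must be positive")
  if (psf_sigma < 0) stop("psf_sigma must be non-negative")
  if (is.character(noise)) noise <- list(type = match.arg(noise, c("poisson", "none")))
  if (is.character(trend)) trend <- list(type = match.arg(trend, c("none")))
  structure(list(dx = dx, dy = dy, gain = gain, offset = offset,
                 psf_sigma = psf_sigma, noise = noise, trend = trend,
                 seed = as.integer(seed), quantize = quantize,
                 aperture = aperture),
            class = "detector_model")
}

.trend_factor <- function(model, nr, nc) {
  tr <- model$trend
  if (tr$type == "none") return(1)
  x <- ((seq_len(nc) - (nc + 1) / 2)) * model$dx
  y <- ((seq_len(nr) - (nr + 1) / 2)) * model$dy
  X <- matrix(rep(x, each = nr), nr, nc)
  Y <- matrix(rep(y, times = nc), nr, nc)
  if (tr$type == "plane") return(tr$a + tr$b * X + tr$c * Y)
  if (tr$type == "quad") {
    cf <- tr$coef
    return(cf[1] + cf[2] * X + cf[3] * Y + cf[4] * X^2 + cf[5] * X * Y + cf[6] * Y^2)
  }
  stop("unknown trend type: ", tr$type)
}

.apply_noise_and_digitize <- function(model, fluence_map, nr, nc) {
  g <- model$gain; a_px <- model$dx * model$dy
  nt <- model$noise$type
  pv <- if (nt == "poisson") {
    counts <- stats::rpois(nr * nc, lambda = as.vector(fluence_map) * a_px)
    model$offset + g * matrix(counts, nr, nc) / a_px
  } else if (nt == "gaussian") {
    model$offset + g * fluence_map +
      matrix(stats::rnorm(nr * nc, sd = model$noise$sd), nr, nc)
  } else {
    model$offset + g * fluence_map
  }
  pv[pv < 0] <- 0
  if (model$quantize) {
    if (any(pv > 65535.5)) stop("synthetic pixel values exceed 16-bit range")
    pv <- matrix(as.integer(round(pv)), nr, nc)
  }
  pv
}

#' Generate a synthetic flat-field image
#'
#' Pixel mean is `offset + gain * fluence * trend(x, y)`; Poisson noise is
#' realized as quanta counts `n ~ Pois(fluence * dx * dy)` per pixel with
#' `pv = offset + gain * n/(dx*dy)`, so that after linearization the image is
#' an ideal Poisson fluence field.
#'
#' @param model A [detector_model()].
#' @param fluence Input photon fluence, mm^-2.
#' @param shape Image dimensions `c(rows, cols)`; below 256 a warning is
#'   issued since such images cannot feed the NPS stage.
#' @param kvp,mas,kerma_ugy Exposure metadata recorded in the image.
#' @param seed RNG seed for this image; defaults to the model seed.
#' @return A [detector_image()].
#' @export
gen_flat_field <- function(model, fluence, shape = c(620L, 620L),
                           kvp = 30, mas = 12.5, kerma_ugy = NA_real_,
                           seed = model$seed) {
  stopifnot(inherits(model, "detector_model"))
  if (fluence <= 0) stop("fluence must be positive")
  nr <- shape[1L]; nc <- shape[2L]
  if (nr < 256L || nc < 256L)
    warning("flat field smaller than 256 px per side cannot hold one NPS ROI")
  fluence_map <- fluence * .trend_factor(model, nr, nc)
  if (length(fluence_map) == 1L) fluence_map <- matrix(fluence_map, nr, nc)
  px <- .with_seed(seed, .apply_noise_and_digitize(model, fluence_map, nr, nc))
  img <- detector_image(px, model$dx, model$dy, kvp = kvp, mas = mas,
                        anode_filter = "W/Rh")
  attr(img, "ground_truth") <- list(fluence = fluence, gain = model$gain,
                                    offset = model$offset,
                                    kerma_ugy = kerma_ugy)
  img
}

# integral of the standard normal CDF: \int Phi(z) dz = z*Phi(z) + phi(z)
.int_phi <- function(z) z * stats::pnorm(z) + stats::dnorm(z)

#' Generate a synthetic slanted-edge image
#'
#' An ideal straight step through the image centre at `angle_deg` to the
#' pixel column direction, convolved with the model's Gaussian PSF and
#' integrated analytically over the pixel aperture (difference of error
#' functions; never supersampled), then passed through gain/offset and the
#' noise model. The exact ground-truth presampling MTF,
#' `exp(-2 pi^2 sigma^2 f^2) * |sinc(pi f dx)|`, is attached as attribute
#' `"ground_truth"`.
#'
#' @param model A [detector_model()].
#' @param angle_deg Edge angle, degrees, in (0.5, 10).
#' @param fluence_high,fluence_low Fluence on the bright / dark side, mm^-2.
#' @param shape Image dimensions `c(rows, cols)`.
#' @param orientation `"vertical"` (edge along columns; measures MTF in x)
#'   or `"horizontal"`.
#' @param kvp,mas Exposure metadata.
#' @param seed RNG seed for this image.
#' @return A [detector_image()] with attribute `"ground_truth"` holding
#'   `angle_deg`, `sigma`, `mtf` (a function of frequency in mm^-1) and the
#'   sampling pitch along the measured axis.
#' @export
gen_edge_image <- function(model, angle_deg, fluence_high, fluence_low,
                           shape = c(420L, 300L),
                           orientation = c("vertical", "horizontal"),
                           kvp = 30, mas = 12.5, seed = model$seed) {
  stopifnot(inherits(model, "detector_model"))
  orientation <- match.arg(orientation)
  if (angle_deg <= 0.5 || angle_deg >= 10)
    stop("edge angle must lie in (0.5, 10) degrees")
  if (fluence_high == fluence_low)
    stop("degenerate edge: fluence_high equals fluence_low")
  # generate in the vertical-edge frame; transpose afterwards if horizontal
  dx <- if (orientation == "vertical") model$dx else model$dy
  dy <- if (orientation == "vertical") model$dy else model$dx
  nr <- shape[1L]; nc <- shape[2L]
  if (orientation == "horizontal") { nr <- shape[2L]; nc <- shape[1L] }

  xc <- (seq_len(nc) - 0.5) * dx
  yc <- (seq_len(nr) - 0.5) * dy
  tan_a <- tan(angle_deg * pi / 180)
  edge_x <- mean(xc) + tan_a * (yc - mean(yc)) # edge position per row
  dxm <- outer(-edge_x, xc, `+`)               # x distance pixel centre -> edge
  sigma <- model$psf_sigma
  frac <- if (model$aperture) {
    if (sigma > 0)
      (sigma / dx) * (.int_phi((dxm + dx / 2) / sigma) -
                        .int_phi((dxm - dx / 2) / sigma))
    else pmin(pmax((dxm + dx / 2) / dx, 0), 1)
  } else {
    if (sigma > 0) stats::pnorm(dxm / sigma)
    else (dxm > 0) + 0.5 * (dxm == 0)
  }
  fluence_map <- fluence_low + (fluence_high - fluence_low) * frac
  px <- .with_seed(seed, .apply_noise_and_digitize(model, fluence_map, nr, nc))
  if (orientation == "horizontal") px <- t(px)
  img <- detector_image(px, model$dx, model$dy, kvp = kvp, mas = mas,
                        anode_filter = "W/Rh")
  pitch <- if (orientation == "vertical") model$dx else model$dy
  attr(img, "ground_truth") <- list(
    angle_deg = angle_deg, sigma = sigma, pitch = pitch,
    direction = if (orientation == "vertical") "x" else "y",
    mtf = local({
      has_ap <- model$aperture
      function(f) {
        ap <- if (has_ap)
          ifelse(f == 0, 1, abs(sin(pi * f * pitch) / (pi * f * pitch)))
        else 1
        exp(-2 * pi^2 * sigma^2 * f^2) * ap
      }
    }))
  img
}

#' Generate a synthetic STP calibration series
#'
#' One image per air-kerma value with mean pixel value
#' `offset + gain * snr_in2 * kerma` (the fluence of a Poisson field at that
#' kerma), so the ground-truth conversion is `slope = gain * snr_in2` PV/uGy
#' and `intercept = offset`.
#'
#' @param model A [detector_model()].
#' @param kerma_list Air kerma values at the detector, uGy (>= 3).
#' @param snr_in2 Squared input SNR per unit kerma, 1/(mm^2 uGy).
#' @param shape Image dimensions (small images suffice for a mean).
#' @return List with one element per kerma: `list(kerma, mas, image)`;
#'   attribute `"ground_truth"` holds `slope_pv_per_ugy` and `intercept_pv`.
#' @export
gen_calibration_series <- function(model, kerma_list, snr_in2,
                                   shape = c(280L, 280L)) {
  stopifnot(inherits(model, "detector_model"))
  if (length(kerma_list) < 3L) stop("at least 3 kerma values are required")
  series <- lapply(seq_along(kerma_list), function(i) {
    k <- kerma_list[i]
    img <- if (k > 0)
      suppressWarnings( # calibration images need no NPS-sized area
        gen_flat_field(model, fluence = snr_in2 * k, shape = shape,
                       mas = k, kerma_ugy = k, seed = model$seed + 1000L + i))
    else {
      px <- matrix(if (model$quantize) as.integer(round(model$offset)) else model$offset,
                   shape[1L], shape[2L])
      detector_image(px, model$dx, model$dy, kvp = 30, mas = 0,
                     anode_filter = "W/Rh")
    }
    list(kerma = k, mas = k, image = img)
  })
  attr(series, "ground_truth") <- list(
    slope_pv_per_ugy = model$gain * snr_in2, intercept_pv = model$offset)
  series
}

#' Write a complete synthetic DQE study to disk
#'
#' Generates and writes (raw fixture format) everything one acquisition
#' session provides: an STP calibration series, `n_flat` flat fields at the
#' working kerma, and two slanted-edge images (one per direction), plus the
#' calibration table as CSV. The returned list is a ready-made
#' [run_pipeline()] configuration.
#'
#' @param dir Output directory (created if absent).
#' @param model A [detector_model()]; the default mirrors the validation
#'   conditions used throughout the package (0.085 mm pitch, W/Rh 30 kV).
#' @param kad Working air kerma at the detector, uGy.
#' @param snr_in2 Squared input SNR per unit kerma.
#' @param n_flat Number of flat-field images (default 12, the count the
#'   4-million-pixel rule demands at 0.085 mm pitch and a 50 mm region).
#' @param region_mm NPS analysis region side, mm.
#' @param edge_angle_deg Slanted-edge angle, degrees.
#' @param edge_shape Edge image dimensions.
#' @param flat_shape Flat-field image dimensions.
#' @param cal_kerma Calibration kerma values, uGy.
#' @return A configuration list for [run_pipeline()].
#' @export
gen_dqe_study <- function(dir, model = detector_model(), kad = 50,
                          snr_in2 = 6179, n_flat = 12L, region_mm = 50,
                          edge_angle_deg = 2.5, edge_shape = c(840L, 300L),
                          flat_shape = c(620L, 620L),
                          cal_kerma = kad * c(0.25, 0.5, 1, 1.5, 2)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  q_work <- snr_in2 * kad

  series <- gen_calibration_series(model, cal_kerma, snr_in2)
  stp_paths <- character(length(series))
  for (i in seq_along(series)) {
    stp_paths[i] <- file.path(dir, sprintf("stp_%02d", i))
    write_raw_image(series[[i]]$image, stp_paths[i])
  }
  cal_path <- file.path(dir, "calibration.csv")
  utils::write.csv(data.frame(mas = vapply(series, `[[`, 0, "mas"),
                              kerma_ugy = vapply(series, `[[`, 0, "kerma")),
                   cal_path, row.names = FALSE)

  flat_paths <- character(n_flat)
  for (i in seq_len(n_flat)) {
    img <- gen_flat_field(model, q_work, shape = flat_shape,
                          kerma_ugy = kad, seed = model$seed + i)
    flat_paths[i] <- file.path(dir, sprintf("flat_%02d", i))
    write_raw_image(img, flat_paths[i])
  }

  ex <- gen_edge_image(model, edge_angle_deg, fluence_high = q_work,
                       fluence_low = q_work / 10, shape = edge_shape,
                       orientation = "vertical", seed = model$seed + 501L)
  ey <- gen_edge_image(model, edge_angle_deg, fluence_high = q_work,
                       fluence_low = q_work / 10,
                       shape = edge_shape[c(2L, 1L)], # long axis along columns
                       orientation = "horizontal", seed = model$seed + 502L)
  edge_x_path <- file.path(dir, "edge_x")
  edge_y_path <- file.path(dir, "edge_y")
  write_raw_image(ex, edge_x_path)
  write_raw_image(ey, edge_y_path)

  list(flat_paths = flat_paths, edge_x_path = edge_x_path,
       edge_y_path = edge_y_path, stp_paths = stp_paths,
       calibration_file = cal_path,
       beam = beam_quality("W/Rh", 30, snr_in2),
       geometry = list(d_source_detector = 660, d_source_chamber = 660),
       region_mm = region_mm, trend = "mean",
       kerma_accuracy = 0, dist_err_detector = 0, dist_err_chamber = 0,
       out_dir = dir,
       ground_truth = list(kad = kad, fluence = q_work,
                           mtf = attr(ex, "ground_truth")$mtf,
                           edge_angle_deg = edge_angle_deg))
}
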