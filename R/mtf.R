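#' Locate a slanted edge and estimate its angle
#'
#' For every line perpendicular to the nominal edge direction the sub-pixel
#' edge crossing is taken as the centroid of the absolute discrete gradient
#' (restricted to a window around the gradient peak); a straight line is then
#' fitted to the crossings by least squares. The angle is reported between
#' the edge and the pixel column (vertical edge, x-direction MTF) or row
#' (horizontal edge, y-direction MTF).
#'
#' @param image Numeric matrix, the linearized edge image, containing exactly
#'   one approximately straight intensity step.
#' @param dx,dy Pixel spacing, mm.
#' @param orientation `"auto"` (default), `"vertical"` (edge roughly parallel
#'   to columns, measures MTF in x) or `"horizontal"`.
#' @return An `edge_geometry`: `angle_deg`, `slope` and `intercept` of the
#'   fitted crossing line (working-frame pixel coordinates,
#'   `col = intercept + slope * row`), `center` (row, col; 1-based, working
#'   frame), `orientation` (`"x"` or `"y"`), `polarity` (+1 bright side at
#'   larger column), `transposed` (TRUE when the image was worked on
#'   transposed), `n_lines` used.
#' @export
find_edge <- function(image, dx, dy,
                      orientation = c("auto", "vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  if (orientation == "auto") {
    step_x <- abs(mean(image[, ncol(image)]) - mean(image[, 1L]))
    step_y <- abs(mean(image[nrow(image), ]) - mean(image[1L, ]))
    orientation <- if (step_x >= step_y) "vertical" else "horizontal"
  }
  transposed <- orientation == "horizontal"
  if (transposed) {
    image <- t(image)
    tmp <- dx; dx <- dy; dy <- tmp
  }
  nr <- nrow(image); nc <- ncol(image)
  if (nc < 8L || nr < 8L) stop("edge image too small for edge detection")

  crossings <- rep(NA_real_, nr)
  scale_ref <- max(abs(image)) + .Machine$double.eps
  for (i in seq_len(nr)) {
    p <- image[i, ]
    k <- min(5L, nc %/% 4L)
    amp <- abs(mean(p[(nc - k + 1L):nc]) - mean(p[seq_len(k)]))
    noise <- stats::sd(diff(p[seq_len(max(k, 3L))])) / sqrt(2)
    if (!is.finite(amp) || amp <= max(3 * noise, 1e-8 * scale_ref, na.rm = TRUE))
      next
    g <- abs(diff(p))
    jmax <- which.max(g)
    win <- max(1L, jmax - 10L):min(length(g), jmax + 10L)
    gw <- g[win]
    if (sum(gw) == 0) next
    crossings[i] <- sum((win + 0.5) * gw) / sum(gw)
  }
  ok <- is.finite(crossings)
  if (mean(!ok) > 0.10 || sum(ok) < 4L)
    stop("edge detection error: no clean intensity step found on more than 10% of lines")
  rows <- which(ok)
  fit <- stats::lm.fit(cbind(1, rows), crossings[ok])
  intercept <- unname(fit$coefficients[1L])
  slope <- unname(fit$coefficients[2L])
  tan_alpha <- abs(slope) * dx / dy
  angle_deg <- atan(tan_alpha) * 180 / pi
  if (angle_deg <= 0.5 || angle_deg >= 45)
    warning(sprintf(
      "edge angle %.3f deg outside (0.5, 45): sub-pixel oversampling unreliable",
      angle_deg))
  row_c <- mean(range(rows))
  col_c <- intercept + slope * row_c
  right <- image[rows, pmin(nc, ceiling(crossings[ok]) + 5L)]
  left <- image[rows, pmax(1L, floor(crossings[ok]) - 5L)]
  polarity <- if (mean(right) >= mean(left)) 1 else -1
  structure(list(angle_deg = angle_deg, slope = slope, intercept = intercept,
                 center = c(row = row_c, col = col_c),
                 orientation = if (transposed) "y" else "x",
                 polarity = polarity, transposed = transposed,
                 n_lines = sum(ok)),
            class = "edge_geometry")
}

#' Build the oversampled edge spread function
#'
#' The calculation window is split into consecutive sections of
#' `N = round(1/tan(alpha))` pixel lines. Within each section every sample is
#' assigned a sub-pixel bin by its perpendicular distance to the fitted edge
#' (bin width `h = dx/N`); per-section ESFs are then averaged bin-wise. Edges
#' with dark-to-bright polarity are flipped so the ESF always ascends.
#'
#' @param image Numeric matrix, the linearized edge image (same one passed to
#'   [find_edge()]).
#' @param edge An `edge_geometry` from [find_edge()].
#' @param dx,dy Pixel spacing of the image, mm.
#' @param window_px Half-width of the calculation window across the edge, in
#'   pixels (default 20); all full sections along the edge are used.
#' @return An `oversampled_esf`: `positions` (mm along the edge normal,
#'   strictly increasing, uniform spacing `h`), `values`, `h`, `n` (lines per
#'   section), `n_sections`, `angle_deg`, `direction`, `dx` (detector
#'   sampling pitch along the measured axis).
#' @export
build_esf <- function(image, edge, dx, dy, window_px = 20L) {
  stopifnot(inherits(edge, "edge_geometry"))
  if (edge$transposed) {
    image <- t(image)
    tmp <- dx; dx <- dy; dy <- tmp
  }
  tan_alpha <- tan(edge$angle_deg * pi / 180)
  if (tan_alpha <= 0 || 1 / tan_alpha > nrow(image))
    stop("edge angle too close to 0 degrees: sub-pixel oversampling impossible")
  N <- as.integer(round(1 / tan_alpha))
  if (N < 2L) stop("edge too steep for sub-pixel oversampling (need round(1/tan(alpha)) >= 2)")
  h <- dx / N
  cos_alpha <- cos(edge$angle_deg * pi / 180)
  nr <- nrow(image); nc <- ncol(image)

  n_sections <- nr %/% N
  if (n_sections < 2L)
    stop(sprintf("calculation window holds %d complete sections of %d lines; at least 2 required",
                 n_sections, N))
  rows <- seq_len(n_sections * N)
  edge_col <- edge$intercept + edge$slope * rows
  c_lo <- max(1L, floor(min(edge_col)) - as.integer(window_px))
  c_hi <- min(nc, ceiling(max(edge_col)) + as.integer(window_px))
  if (c_hi - c_lo < 4L) stop("calculation window too narrow across the edge")
  cols <- c_lo:c_hi

  # perpendicular distance of each sample to the fitted edge, in mm
  d <- outer(edge_col, cols, function(ec, cc) (cc - ec) * dx * cos_alpha)
  bin <- matrix(as.integer(round(d / h)), nrow = length(rows))
  section <- rep(seq_len(n_sections), each = N)

  b_lo <- max(tapply(apply(bin, 1L, min), section, max))
  b_hi <- min(tapply(apply(bin, 1L, max), section, min))
  if (b_hi - b_lo + 1L < 2L * N)
    stop("oversampled ESF support too short; widen the calculation window")
  nbins <- b_hi - b_lo + 1L

  vals <- image[rows, cols, drop = FALSE]
  keep <- bin >= b_lo & bin <= b_hi
  sec_vec <- rep(section, times = length(cols))
  grp <- (bin[keep] - b_lo) * n_sections + sec_vec[keep]
  sums <- rowsum(vals[keep], grp)
  cnts <- rowsum(rep(1, sum(keep)), grp)
  per_section <- matrix(NA_real_, n_sections, nbins)
  per_section[as.integer(rownames(sums))] <- sums / cnts
  esf <- colMeans(per_section, na.rm = TRUE)
  if (anyNA(esf)) { # bins empty in every section: fill by linear interpolation
    known <- which(!is.na(esf))
    esf <- stats::approx(known, esf[known], xout = seq_along(esf), rule = 2)$y
  }
  positions <- (b_lo:b_hi) * h
  if (edge$polarity < 0) {
    esf <- rev(esf)
    positions <- -rev(positions)
  }
  structure(list(positions = positions, values = esf, h = h, n = N,
                 n_sections = n_sections, angle_deg = edge$angle_deg,
                 direction = edge$orientation, dx = dx),
            class = "oversampled_esf")
}

#' Differentiate the ESF to the line spread function
#'
#' Central-difference convolution with the kernel (-0.5, 0, +0.5) over the
#' sub-pixel spacing `h`; the two end samples are dropped. The result is a
#' derivative per unit length (mm^-1 scale).
#'
#' @param esf An `oversampled_esf` (or list with `positions`, `values`, `h`).
#' @return List with `positions`, `values`, `h` (and ESF metadata carried
#'   through), class `lsf_samples`.
#' @export
lsf_from_esf <- function(esf) {
  v <- esf$values
  n <- length(v)
  if (n < 3L) stop("at least 3 ESF samples are required to differentiate")
  lsf <- (v[3L:n] - v[1L:(n - 2L)]) * 0.5 / esf$h
  structure(list(positions = esf$positions[2L:(n - 1L)], values = lsf,
                 h = esf$h, angle_deg = esf$angle_deg,
                 direction = esf$direction, dx = esf$dx,
                 n = esf$n, n_sections = esf$n_sections),
            class = "lsf_samples")
}

.taper_lsf <- function(v, rel = 1e-3, run = 10L) {
  peak <- max(abs(v))
  if (peak == 0) return(v)
  small <- abs(v) < rel * peak
  ipk <- which.max(abs(v))
  runlen <- 0L
  for (i in seq(ipk, length(v))) {
    runlen <- if (small[i]) runlen + 1L else 0L
    if (runlen >= run) { v[i:length(v)] <- 0; break }
  }
  runlen <- 0L
  for (i in seq(ipk, 1L)) {
    runlen <- if (small[i]) runlen + 1L else 0L
    if (runlen >= run) { v[1L:i] <- 0; break }
  }
  v
}

#' Presampling MTF from the line spread function
#'
#' Magnitude of the discrete Fourier transform of the LSF, normalized to its
#' zero-frequency value. The frequency axis is built from the sub-pixel
#' spacing `h` and multiplied by `cos(alpha)` to refer frequencies to the
#' detector axis; each value is divided by the central-difference kernel
#' response `sin(2 pi f h)/(2 pi f h)` (finite-element differentiation
#' correction, with the analytic limit 1 at f = 0). LSF samples in the flat
#' tails (|LSF| below 0.1% of the peak for 10 consecutive samples) are zeroed
#' before the transform unless `taper = FALSE`.
#'
#' @param lsf An `lsf_samples` object.
#' @param taper Zero the noise tails of the LSF before transforming
#'   (default TRUE).
#' @param df_max Upper bound on the fine-grid frequency spacing, mm^-1: the
#'   LSF is zero-padded to the next power of two giving at least this
#'   resolution, so that every NPS-grid bin receives samples when rebinned
#'   (default 0.01).
#' @return An `mtf_curve` on the fine frequency grid: `freqs` (mm^-1,
#'   starting at 0), `values` (1 at zero frequency), `direction`,
#'   `angle_used`, `fine = TRUE`, plus `h`, `n_lines` for the uncertainty
#'   budget.
#' @export
mtf_from_lsf <- function(lsf, taper = TRUE, df_max = 0.01) {
  v <- lsf$values
  if (taper) v <- .taper_lsf(v)
  if (sum(v) == 0) stop("LSF sums to zero: cannot normalize the MTF")
  L <- max(length(v), 2^ceiling(log2(1 / (df_max * lsf$h))))
  v <- c(v, rep(0, L - length(v)))
  mag <- Mod(stats::fft(v))
  mag <- mag / mag[1L]
  half <- L %/% 2L
  j <- 0:half
  f_raw <- j / (L * lsf$h)
  arg <- 2 * pi * f_raw * lsf$h
  resp <- ifelse(arg == 0, 1, sin(arg) / arg)
  keep <- abs(resp) > 0.1 # beyond lies far past the detector Nyquist
  vals <- (mag[j + 1L] / abs(resp))[keep]
  cos_alpha <- cos(lsf$angle_deg * pi / 180)
  structure(list(freqs = f_raw[keep] * cos_alpha, values = vals,
                 direction = lsf$direction, angle_used = lsf$angle_deg,
                 fine = TRUE, h = lsf$h, dx = lsf$dx,
                 n_lines = lsf$n * lsf$n_sections),
            class = "mtf_curve")
}

#' Rebin a fine-grid MTF onto the NPS frequency grid
#'
#' Each target frequency receives the mean of the fine-grid values whose
#' frequency lies within half a target-grid spacing (lower edge closed,
#' upper edge open); the output is truncated at the detector Nyquist
#' frequency and the zero-frequency value is forced to 1.
#'
#' @param curve A fine-grid `mtf_curve`.
#' @param target_freqs Target frequency grid, mm^-1, uniformly spaced,
#'   starting at 0 (e.g. `(0:128)/(256*dx)`).
#' @param nyquist Truncation frequency, mm^-1; default `1/(2*dx)` of the
#'   curve's detector pitch.
#' @return An `mtf_curve` on the target grid (`fine = FALSE`).
#' @export
rebin_mtf <- function(curve, target_freqs, nyquist = NULL) {
  stopifnot(inherits(curve, "mtf_curve"))
  if (is.null(nyquist)) nyquist <- 1 / (2 * curve$dx)
  target_freqs <- target_freqs[target_freqs <= nyquist + 1e-12]
  dfreq <- diff(target_freqs[1:2])
  if (max(curve$freqs) < max(target_freqs) - dfreq / 2)
    stop("fine MTF grid does not extend to the Nyquist frequency")
  vals <- vapply(target_freqs, function(ft) {
    inbin <- curve$freqs >= ft - dfreq / 2 & curve$freqs < ft + dfreq / 2
    if (!any(inbin))
      stop(sprintf("no fine-grid MTF samples fall in the bin at %.4f mm^-1", ft))
    mean(curve$values[inbin])
  }, 0)
  if (target_freqs[1L] == 0) vals[1L] <- 1
  structure(list(freqs = target_freqs, values = vals,
                 direction = curve$direction, angle_used = curve$angle_used,
                 fine = FALSE, dx = curve$dx, n_lines = curve$n_lines),
            class = "mtf_curve")
}

#' Full slanted-edge presampling MTF
#'
#' Convenience wrapper: [find_edge()], [build_esf()], [lsf_from_esf()],
#' [mtf_from_lsf()], then [rebin_mtf()] onto the NPS grid
#' `(0:(roi_size/2))/(roi_size*pitch)` truncated at Nyquist.
#'
#' @param image Numeric matrix, linearized edge image.
#' @param dx,dy Pixel spacing, mm.
#' @param roi_size NPS ROI size defining the target grid (default 256).
#' @param window_px Calculation-window half-width across the edge, pixels.
#' @param taper Zero LSF noise tails before the transform.
#' @param orientation Passed to [find_edge()].
#' @return An `mtf_curve` on the NPS grid, with the `edge_geometry` attached
#'   as attribute `"edge"`.
#' @export
slanted_edge_mtf <- function(image, dx, dy, roi_size = 256L, window_px = 20L,
                             taper = TRUE, orientation = "auto") {
  edge <- find_edge(image, dx, dy, orientation = orientation)
  esf <- build_esf(image, edge, dx, dy, window_px = window_px)
  fine <- mtf_from_lsf(lsf_from_esf(esf), taper = taper)
  pitch <- if (edge$orientation == "x") dx else dy
  df <- 1 / (roi_size * pitch) # same float ops as the NPS grid
  grid <- (0:(roi_size %/% 2L)) * df
  out <- rebin_mtf(fine, grid, nyquist = 1 / (2 * pitch))
  attr(out, "edge") <- edge
  out
}
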