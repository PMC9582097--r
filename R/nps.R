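#' Number of flat-field images needed for the 4-million-pixel rule
#'
#' The noise analysis must cover at least `min_pixels` independent pixels.
#' Each image contributes the unique pixels of its analysis region,
#' `floor(region_side/pitch)^2`, regardless of ROI overlap.
#'
#' @param pixel_pitch Pixel pitch, mm.
#' @param region_side Side of the square analysis area, mm (>= 256 * pitch).
#' @param min_pixels Required pixel count; default 4e6.
#' @return Smallest integer n with `n * floor(region_side/pitch)^2 >= min_pixels`
#'   (at least 1).
#' @export
required_image_count <- function(pixel_pitch, region_side, min_pixels = 4e6) {
  if (pixel_pitch <= 0) stop("pixel pitch must be positive")
  side_px <- floor(region_side / pixel_pitch)
  if (side_px < 256)
    stop(sprintf("analysis region of %g mm holds only %d px at %g mm pitch; at least 256 needed",
                 region_side, side_px, pixel_pitch))
  max(1L, as.integer(ceiling(min_pixels / side_px^2)))
}

#' Tile an analysis region into 256 x 256 ROIs with half-ROI overlap
#'
#' ROI origins step by `roi_size/2` starting at the region origin; only fully
#' contained ROIs are kept, so any leftover margin stays at the far edge.
#'
#' @param region An `analysis_region` (or bare matrix).
#' @param roi_size ROI side in pixels (default 256; reducible for testing
#'   against the literal periodogram sum on small grids).
#' @return A `roi_tiling`: `roi_size`, `step`, integer matrix `origins`
#'   (0-based row/col offsets into the region), `m` (ROIs in this region).
#' @export
tile_rois <- function(region, roi_size = 256L) {
  px <- if (is.matrix(region)) region else region$pixels
  roi_size <- as.integer(roi_size)
  step <- roi_size %/% 2L
  nr <- nrow(px); nc <- ncol(px)
  if (nr < roi_size || nc < roi_size)
    stop(sprintf("region %d x %d is smaller than one %d x %d ROI",
                 nr, nc, roi_size, roi_size))
  rows <- seq(0L, nr - roi_size, by = step)
  cols <- seq(0L, nc - roi_size, by = step)
  origins <- as.matrix(expand.grid(row = rows, col = cols))
  structure(list(roi_size = roi_size, step = step,
                 origins = origins, m = nrow(origins)),
            class = "roi_tiling")
}

#' Remove the large-scale trend from a linearized flat-field region
#'
#' @param region Numeric matrix (linearized analysis region).
#' @param method `"none"`, `"mean"` (subtract the global mean of the region;
#'   the default choice elsewhere in the pipeline), or `"poly2"`
#'   (least-squares 2-D polynomial of total degree 2, six coefficients,
#'   fitted once over the full region and subtracted).
#' @return Matrix of the same shape with the fitted trend `S` subtracted.
#' @export
detrend <- function(region, method = c("mean", "none", "poly2")) {
  if (length(method) == 1L && !method %in% c("none", "mean", "poly2"))
    stop("unknown trend removal method: ", method)
  method <- match.arg(method)
  if (method == "none") return(region)
  if (method == "mean") return(region - mean(region))
  nr <- nrow(region); nc <- ncol(region)
  # centred, scaled coordinates keep the normal equations well conditioned
  y <- rep((seq_len(nr) - (nr + 1) / 2) / nr, times = nc)
  x <- rep((seq_len(nc) - (nc + 1) / 2) / nc, each = nr)
  X <- cbind(1, x, y, x * x, x * y, y * y)
  beta <- stats::lm.fit(X, as.vector(region))$coefficients
  region - matrix(X %*% beta, nrow = nr, ncol = nc)
}

#' Two-dimensional noise power spectrum by overlapping-ROI periodogram averaging
#'
#' Computes `W(u_n, v_k) = dx*dy/(M*N*N) * sum_m |DFT2(ROI_m)|^2` over all
#' ROIs of all supplied regions (each region already linearized and
#' detrended). The DFT is the plain unnormalized discrete Fourier transform,
#' evaluated with a fast transform; the result is mathematically identical to
#' the literal double sum.
#'
#' @param regions A single numeric matrix or list of matrices (linearized,
#'   detrended analysis regions, one per flat-field image).
#' @param dx,dy Pixel spacing, mm.
#' @param roi_size ROI side in pixels (default 256).
#' @return A `noise_spectrum_2d`: `w` (`roi_size` x `roi_size`, rows index
#'   the y-frequency v, columns the x-frequency u, zero frequency at [1,1]),
#'   `df_u = 1/(roi_size*dx)`, `df_v = 1/(roi_size*dy)`, `m_total`,
#'   `mean_linearized` (mean of the *pre-detrend* data if supplied via
#'   `mean_linearized`, else of the data given), `dx`, `dy`.
#' @param mean_linearized Optional mean of the linearized (pre-detrend) data
#'   over all analyzed ROIs, for NNPS; defaults to the mean of `regions`.
#' @export
nps_2d <- function(regions, dx, dy, roi_size = 256L, mean_linearized = NULL) {
  if (is.matrix(regions)) regions <- list(regions)
  if (dx <= 0 || dy <= 0) stop("pixel spacings must be positive")
  roi_size <- as.integer(roi_size)
  acc <- matrix(0, roi_size, roi_size)
  m_total <- 0L
  if (is.null(mean_linearized))
    mean_linearized <- mean(vapply(regions, mean, 0))
  for (reg in regions) {
    tiling <- tile_rois(reg, roi_size)
    for (i in seq_len(tiling$m)) {
      r0 <- tiling$origins[i, 1L]; c0 <- tiling$origins[i, 2L]
      roi <- reg[(r0 + 1L):(r0 + roi_size), (c0 + 1L):(c0 + roi_size)]
      acc <- acc + Mod(stats::fft(roi))^2
    }
    m_total <- m_total + tiling$m
  }
  w <- (dx * dy) / (m_total * roi_size^2) * acc
  structure(list(w = w, df_u = 1 / (roi_size * dx), df_v = 1 / (roi_size * dy),
                 m_total = m_total, mean_linearized = mean_linearized,
                 dx = dx, dy = dy, roi_size = roi_size),
            class = "noise_spectrum_2d")
}

#' One-dimensional directional NPS from the 2-D spectrum
#'
#' For the x direction, the value at each frequency `u_n = n/(roi_size*dx)`
#' is the average of the 2-D spectrum over the 14 lines `v_k`,
#' `k in {+-1, ..., +-7}`, nearest the u axis — the axis itself (k = 0) is
#' excluded. Symmetric for y. Frequencies run n = 1..Nyquist; the
#' zero-frequency average is reported separately in `zero_value` because its
#' magnitude is a pure artifact of the detrending convention.
#'
#' @param w2d A `noise_spectrum_2d`.
#' @param direction `"x"` or `"y"`.
#' @param n_lines Number of off-axis lines averaged (default 14).
#' @return A `spectrum_1d`: `freqs` (mm^-1, strictly increasing, up to
#'   Nyquist), `values`, `direction`, `n_lines_averaged`, `zero_value`,
#'   `m_total`, `mean_linearized`.
#' @export
nps_1d <- function(w2d, direction = c("x", "y"), n_lines = 14L) {
  stopifnot(inherits(w2d, "noise_spectrum_2d"))
  direction <- match.arg(direction)
  n <- w2d$roi_size
  half <- n %/% 2L
  k <- as.integer(n_lines) %/% 2L
  lines_idx <- c(1L + seq_len(k), n + 1L - seq_len(k)) # +-1..+-k on the periodic grid
  if (direction == "x") {
    vals <- colMeans(w2d$w[lines_idx, 1L:(half + 1L), drop = FALSE])
    df <- w2d$df_u
  } else {
    vals <- rowMeans(w2d$w[1L:(half + 1L), lines_idx, drop = FALSE])
    df <- w2d$df_v
  }
  structure(list(freqs = seq_len(half) * df, values = vals[-1L],
                 direction = direction, n_lines_averaged = 2L * k,
                 zero_value = vals[1L], m_total = w2d$m_total,
                 mean_linearized = w2d$mean_linearized),
            class = "spectrum_1d")
}

#' Normalized noise power spectrum
#'
#' Divides an NPS by the squared mean of the linearized signal, yielding the
#' NNPS in mm^2. For an ideal Poisson flat field at fluence Q the NNPS is
#' 1/Q at all frequencies.
#'
#' @param spec A `spectrum_1d` of NPS values.
#' @param mean_linearized Mean linearized signal (fluence, mm^-2); defaults
#'   to the value recorded in `spec`.
#' @return A `spectrum_1d` of NNPS values.
#' @export
nnps <- function(spec, mean_linearized = spec$mean_linearized) {
  stopifnot(inherits(spec, "spectrum_1d"))
  if (is.null(mean_linearized) || !is.finite(mean_linearized) ||
      mean_linearized <= 0)
    stop("mean linearized signal must be positive to normalize the NPS")
  out <- spec
  out$values <- spec$values / mean_linearized^2
  out$zero_value <- spec$zero_value / mean_linearized^2
  out
}
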