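#' Input noise power spectrum of the X-ray quantum field
#'
#' For a Poisson quantum field the input noise power is frequency
#' independent: `W_in = SNR_in^2 * KAD`, numerically equal to the photon
#' fluence at the detector (mm^-2).
#'
#' @param snr_in2 Squared input SNR per unit kerma, 1/(mm^2 uGy), or a
#'   `beam_quality`.
#' @param kad Air kerma at the detector, uGy.
#' @return An `input_spectrum`: `w_in` (mm^-2), `kad`, `snr_in2`.
#' @export
w_in <- function(snr_in2, kad) {
  if (inherits(snr_in2, "beam_quality")) snr_in2 <- snr_in2$snr_in2
  if (!is.numeric(snr_in2) || snr_in2 <= 0) stop("snr_in2 must be positive")
  if (!is.numeric(kad) || kad <= 0) stop("air kerma at detector must be positive")
  structure(list(w_in = snr_in2 * kad, kad = kad, snr_in2 = snr_in2),
            class = "input_spectrum")
}

#' Frequency-dependent detective quantum efficiency
#'
#' `DQE(f) = MTF(f)^2 * W_in / W_out(f)`. The MTF and NPS must already live
#' on the identical frequency grid (the NPS grid); no resampling happens
#' here.
#'
#' @param mtf An `mtf_curve` rebinned to the NPS grid.
#' @param win An `input_spectrum` (or a bare positive number, W_in in mm^-2).
#' @param nps A `spectrum_1d` of NPS values (mm^-2 basis for linearized
#'   input).
#' @return List of class `dqe_curve`: `freqs`, `values`, `direction`.
#' @export
dqe_curve <- function(mtf, win, nps) {
  stopifnot(inherits(mtf, "mtf_curve"), inherits(nps, "spectrum_1d"))
  wi <- if (inherits(win, "input_spectrum")) win$w_in else win
  if (!is.numeric(wi) || wi <= 0) stop("W_in must be positive")
  mtf_f <- mtf$freqs; mtf_v <- mtf$values
  if (length(mtf_f) == length(nps$freqs) + 1L && mtf_f[1L] == 0) {
    mtf_f <- mtf_f[-1L]; mtf_v <- mtf_v[-1L] # drop the forced MTF(0)=1 point
  }
  if (length(mtf_f) != length(nps$freqs) ||
      max(abs(mtf_f - nps$freqs)) > 1e-9)
    stop("MTF and NPS frequency grids differ; rebin the MTF to the NPS grid first")
  bad <- which(nps$values <= 0)
  if (length(bad))
    stop("NPS is zero at frequency bin ", bad[1L],
         " (", format(nps$freqs[bad[1L]]), " mm^-1); DQE undefined there")
  structure(list(freqs = nps$freqs, values = mtf_v^2 * wi / nps$values,
                 direction = nps$direction),
            class = "dqe_curve")
}

#' Bin a DQE curve to multiples of 0.5 lp/mm
#'
#' The value at `q * 0.5` mm^-1 is the mean of the raw values whose frequency
#' lies in `[q*0.5 - 0.25, q*0.5 + 0.25)`; the binned grid stops at the
#' Nyquist frequency.
#'
#' @param dqe A `dqe_curve` (or list with `freqs`, `values`).
#' @param nyquist Nyquist frequency, mm^-1; default `max(dqe$freqs)`.
#' @return List with `freqs` (multiples of 0.5) and `values`.
#' @export
bin_dqe <- function(dqe, nyquist = max(dqe$freqs)) {
  f <- dqe$freqs; v <- dqe$values
  if (min(diff(f)) >= 0.5)
    stop("raw frequency grid is too coarse to bin at 0.5 lp/mm")
  centers <- seq(0.5, by = 0.5, length.out = floor(nyquist / 0.5 + 1e-9))
  vals <- vapply(centers, function(cf) {
    inbin <- f >= cf - 0.25 & f < cf + 0.25
    if (!any(inbin))
      stop(sprintf("no raw DQE samples fall in the 0.5 lp/mm bin at %.2f mm^-1", cf))
    mean(v[inbin])
  }, 0)
  list(freqs = centers, values = vals)
}

#' Relative uncertainty of the NPS estimate
#'
#' `u_NPS = 1 / sqrt(M * rows * bins)`: `M` overlapping ROIs, `rows`
#' off-axis lines averaged per frequency (14 in the standard scheme), and
#' `bins` raw frequency samples averaged into each reported value.
#'
#' @param m_total Total number of ROIs across all images.
#' @param rows Lines averaged per frequency; default 14.
#' @param bin_count Raw samples per reported frequency bin; default 1.
#' @return Relative (fractional) standard uncertainty.
#' @export
u_nps <- function(m_total, rows = 14, bin_count = 1) {
  if (any(c(m_total, rows, bin_count) <= 0))
    stop("all u_NPS arguments must be positive")
  1 / sqrt(m_total * rows * bin_count)
}

#' Heuristic relative uncertainty of the slanted-edge MTF
#'
#' The edge-angle choice fixes how many pixel lines enter the calculation
#' window; the MTF uncertainty shrinks with that information as
#' `u_MTF = c / sqrt(n_lines)`. The default constant `c = 0.4` gives about
#' 2% for a typical 400-line window. This is a declared heuristic scale, not
#' a first-principles estimator; adjust `c` to a locally validated value if
#' available.
#'
#' @param n_lines Pixel lines used in the MTF calculation window.
#' @param c Scale constant (default 0.4).
#' @return Relative standard uncertainty.
#' @export
u_mtf_heuristic <- function(n_lines, c = 0.4) {
  if (n_lines <= 0) stop("n_lines must be positive")
  c / sqrt(n_lines)
}

#' Combined relative DQE uncertainty (GUM root-sum-square)
#'
#' `u_DQE = sqrt((2*u_MTF)^2 + u_Win^2 + u_NPS^2)` — the MTF term is doubled
#' because DQE depends on MTF squared. The middle term is the user-supplied
#' input-spectrum uncertainty: the kerma-meter relative accuracy and the
#' relative distance errors combined in quadrature (the inverse-square law
#' doubles each distance term).
#'
#' @param u_mtf Relative MTF uncertainty.
#' @param u_win Relative input-spectrum (W_in) uncertainty; alternatively
#'   supply `kerma_accuracy` and distance errors.
#' @param u_nps Relative NPS uncertainty.
#' @param kerma_accuracy,dist_err_detector,dist_err_chamber Optional
#'   components used to build `u_win` when it is `NULL`: relative kerma-meter
#'   accuracy and relative errors of the focus-detector / focus-chamber
#'   distances.
#' @return An `uncertainty_budget`: `u_mtf`, `u_win`, `u_nps`, `u_dqe`, all
#'   relative.
#' @export
u_dqe <- function(u_mtf, u_nps, u_win = NULL, kerma_accuracy = 0,
                  dist_err_detector = 0, dist_err_chamber = 0) {
  if (is.null(u_win))
    u_win <- sqrt(kerma_accuracy^2 + (2 * dist_err_detector)^2 +
                    (2 * dist_err_chamber)^2)
  comps <- c(u_mtf = u_mtf, u_win = u_win, u_nps = u_nps)
  if (any(comps < 0)) stop("uncertainty components must be non-negative")
  structure(list(u_mtf = u_mtf, u_win = u_win, u_nps = u_nps,
                 u_dqe = sqrt((2 * u_mtf)^2 + u_win^2 + u_nps^2)),
            class = "uncertainty_budget")
}
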