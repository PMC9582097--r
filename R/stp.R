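#' Inverse-square geometry correction factor
#'
#' The air-kerma meter usually sits on the support table rather than at the
#' detector entrance. The kerma at the detector (KAD) is then obtained from
#' the measured kerma by the inverse-square distance law:
#' `KAD = kerma_measured * (d_source_chamber / d_source_detector)^2`.
#'
#' @param geom List with `d_source_detector` and `d_source_chamber`,
#'   focus-to-detector and focus-to-kerma-meter distances in mm.
#' @return Dimensionless correction factor in (0, 1].
#' @export
geometry_correction_factor <- function(geom) {
  d_det <- geom$d_source_detector
  d_cham <- geom$d_source_chamber
  if (!is.numeric(d_det) || !is.numeric(d_cham) || d_det <= 0 || d_cham <= 0)
    stop("geometry distances must be positive")
  if (d_cham > d_det)
    stop("kerma meter cannot be farther from the focus than the detector")
  (d_cham / d_det)^2
}

#' Look up SNR_in^2 for a beam quality
#'
#' Returns the squared input signal-to-noise ratio per unit air kerma
#' (1/(mm^2 uGy)) for an anode/filter + kVp combination, from a plain-text
#' table. The shipped table carries the standard tabulated value for W/Rh at
#' 30 kV; values for other beam qualities must be added by the user (no
#' interpolation is ever performed).
#'
#' @param anode_filter Label such as `"W/Rh"`.
#' @param kvp Tube voltage, kV.
#' @param table_path Path to a tab-separated table with columns
#'   `anode_filter`, `kvp`, `snr_in2`; defaults to the table shipped with the
#'   package.
#' @return A `beam_quality` list: `anode_filter`, `kvp`, `snr_in2`.
#' @export
lookup_snr_in2 <- function(anode_filter, kvp, table_path = NULL) {
  if (is.null(table_path))
    table_path <- system.file("extdata", "snr_in2_table.tsv",
                              package = "dqemam", mustWork = TRUE)
  tab <- utils::read.delim(table_path, comment.char = "#",
                           stringsAsFactors = FALSE)
  hit <- tab$anode_filter == anode_filter & tab$kvp == kvp
  if (sum(hit) == 0L)
    stop(sprintf(
      "no SNR_in^2 entry for %s at %g kV; add it to the table or pass beam_quality() explicitly",
      anode_filter, kvp))
  if (sum(hit) > 1L)
    stop("duplicate SNR_in^2 entries for ", anode_filter, " at ", kvp, " kV")
  beam_quality(anode_filter, kvp, tab$snr_in2[hit])
}

#' Construct a beam quality descriptor
#'
#' @param anode_filter Anode/filter label.
#' @param kvp Tube voltage, kV.
#' @param snr_in2 Squared input SNR per unit kerma, 1/(mm^2 uGy).
#' @return A `beam_quality` list.
#' @export
beam_quality <- function(anode_filter, kvp, snr_in2) {
  if (!is.numeric(snr_in2) || snr_in2 <= 0) stop("snr_in2 must be positive")
  structure(list(anode_filter = anode_filter, kvp = kvp,
                 snr_in2 = as.numeric(snr_in2)),
            class = "beam_quality")
}

#' Fit the signal transfer property (conversion function)
#'
#' Ordinary least squares of mean pixel value on geometry-corrected air kerma
#' at the detector (KAD). Compliance requires R^2 >= 0.99; a non-compliant
#' fit is returned with `compliant = FALSE` and a warning so the data can be
#' inspected. The kerma-basis slope is rescaled to a photon-fluence basis
#' through `Q = snr_in2 * KAD`, which defines the inverse conversion used by
#' [linearize()].
#'
#' @param points Data frame (or list of lists) with columns `kerma_measured`
#'   (uGy at the meter) and `mean_pv` (mean pixel value of the matching
#'   image over the analysis region); an optional `mas` column is carried
#'   through for reporting.
#' @param beam A [beam_quality()].
#' @param geom Geometry list for [geometry_correction_factor()].
#' @return A `conversion_fit`: `slope_pv_per_ugy`, `intercept_pv`,
#'   `r_squared`, `slope_pv_per_fluence`, `compliant`, `kad` (the corrected
#'   kerma values used), `snr_in2`.
#' @export
fit_conversion <- function(points, beam, geom) {
  stopifnot(inherits(beam, "beam_quality"))
  if (!is.data.frame(points)) points <- do.call(rbind.data.frame, points)
  if (nrow(points) < 3L)
    stop("at least 3 calibration points are required")
  factor <- geometry_correction_factor(geom)
  kad <- points$kerma_measured * factor
  if (length(unique(kad)) < 2L || stats::var(kad) == 0)
    stop("calibration kerma values have zero variance; cannot fit STP")
  fit <- stats::lm(mean_pv ~ kad, data = data.frame(kad = kad,
                                                    mean_pv = points$mean_pv))
  ss_tot <- sum((points$mean_pv - mean(points$mean_pv))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  compliant <- is.finite(r2) && r2 >= 0.99
  if (!compliant)
    warning(sprintf("STP fit R^2 = %.5f < 0.99: not compliant; inspect the calibration data",
                    r2))
  structure(
    list(slope_pv_per_ugy = slope, intercept_pv = intercept, r_squared = r2,
         slope_pv_per_fluence = slope / beam$snr_in2,
         compliant = compliant, kad = kad, snr_in2 = beam$snr_in2,
         geometry_factor = factor),
    class = "conversion_fit")
}

#' @export
print.conversion_fit <- function(x, ...) {
  cat(sprintf(
    "<conversion_fit> pv = %.6g * KAD[uGy] + %.6g, R^2 = %.6f (%s)\n",
    x$slope_pv_per_ugy, x$intercept_pv, x$r_squared,
    if (x$compliant) "compliant" else "NOT compliant"))
  cat(sprintf("  fluence basis: pv = %.6g * Q[mm^-2] + %.6g\n",
              x$slope_pv_per_fluence, x$intercept_pv))
  invisible(x)
}

#' Linearize an image to photon-fluence units
#'
#' Applies the inverse conversion function
#' `Q(pv) = (pv - intercept) / slope_pv_per_fluence`, mapping raw pixel
#' values to input photon fluence (mm^-2). The mapping is affine and
#' order-preserving.
#'
#' @param image A [detector_image()], an `analysis_region`, or a bare matrix.
#' @param fit A `conversion_fit` from [fit_conversion()].
#' @param allow_noncompliant Set `TRUE` to linearize with a fit whose
#'   R^2 < 0.99 anyway.
#' @return Numeric matrix in fluence units, mm^-2.
#' @export
linearize <- function(image, fit, allow_noncompliant = FALSE) {
  stopifnot(inherits(fit, "conversion_fit"))
  if (!fit$compliant && !allow_noncompliant)
    stop("conversion fit is not compliant (R^2 < 0.99); pass allow_noncompliant = TRUE to override")
  if (fit$slope_pv_per_fluence == 0) stop("conversion slope is zero; cannot invert")
  px <- if (is.matrix(image)) image else image$pixels
  (px - fit$intercept_pv) / fit$slope_pv_per_fluence
}
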