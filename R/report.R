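#' Run the full DQE measurement chain
#'
#' Drives STP -> linearization -> NPS/NNPS -> MTF -> DQE on a configuration
#' of image files, and writes the CSV report. Stages are ordered and each
#' missing input produces an error naming the stage it starves.
#'
#' Configuration fields:
#' \describe{
#'   \item{flat_paths}{character vector of flat-field image paths (NPS).}
#'   \item{edge_x_path, edge_y_path}{slanted-edge images for the x and y
#'     directions.}
#'   \item{stp_paths}{optional STP image paths, one per calibration row; if
#'     absent the calibration file must carry a `mean_pv` column.}
#'   \item{calibration_file}{CSV with columns `mas`, `kerma_ugy` (and
#'     optionally `mean_pv`).}
#'   \item{beam}{a [beam_quality()], or set `anode_filter` + `kvp` to use the
#'     shipped SNR_in^2 table.}
#'   \item{geometry}{list with `d_source_detector`, `d_source_chamber`, mm.}
#'   \item{region_mm}{analysis region side, mm (default 50).}
#'   \item{trend}{trend removal: `"mean"` (default), `"none"`, `"poly2"`.}
#'   \item{kerma_ugy}{optional measured kerma (at the meter) of the
#'     flat-field exposure; when absent, KAD is derived from the mean flat
#'     pixel value through the inverse conversion function.}
#'   \item{kerma_accuracy, dist_err_detector, dist_err_chamber}{relative
#'     uncertainties feeding the W_in term of the budget.}
#'   \item{u_mtf_scale}{constant of [u_mtf_heuristic()] (default 0.4).}
#'   \item{out_dir}{directory for the CSV report (default: no file).}
#'   \item{allow_noncompliant}{linearize even when R^2 < 0.99.}
#' }
#'
#' @param config Configuration list as above (e.g. from [gen_dqe_study()]).
#' @return A `dqe_result` (invisibly written to
#'   `file.path(out_dir, "dqe_report.csv")` when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  need <- function(field, stage) {
    if (is.null(config[[field]]) || length(config[[field]]) == 0L)
      stop(sprintf("%s stage is missing its input: config$%s is absent",
                   stage, field))
    config[[field]]
  }
  cfg_or <- function(field, default)
    if (is.null(config[[field]])) default else config[[field]]

  # --- STP stage -----------------------------------------------------------
  cal_file <- need("calibration_file", "STP")
  geom <- need("geometry", "STP")
  beam <- if (!is.null(config$beam)) config$beam
          else lookup_snr_in2(need("anode_filter", "STP"), need("kvp", "STP"))
  cal <- utils::read.csv(cal_file)
  if (!all(c("mas", "kerma_ugy") %in% names(cal)))
    stop("STP stage: calibration file must have columns mas, kerma_ugy")
  region_mm <- cfg_or("region_mm", 50)
  if (is.null(cal$mean_pv)) {
    stp_paths <- need("stp_paths", "STP")
    if (length(stp_paths) != nrow(cal))
      stop("STP stage: number of STP images differs from calibration rows")
    cal$mean_pv <- vapply(stp_paths, function(p) {
      img <- read_image(p)
      mean(extract_analysis_region(img, min(region_mm,
        nrow(img$pixels) * img$dy, ncol(img$pixels) * img$dx))$pixels)
    }, 0)
  }
  points <- data.frame(mas = cal$mas, kerma_measured = cal$kerma_ugy,
                       mean_pv = cal$mean_pv)
  fit <- fit_conversion(points, beam, geom)

  # --- NPS stage -----------------------------------------------------------
  flat_paths <- need("flat_paths", "NPS")
  trend <- cfg_or("trend", "mean")
  allow_nc <- isTRUE(config$allow_noncompliant)
  flats <- lapply(flat_paths, read_image)
  dx <- flats[[1L]]$dx; dy <- flats[[1L]]$dy
  for (f in flats)
    if (abs(f$dx - dx) > 1e-12 || abs(f$dy - dy) > 1e-12)
      stop("NPS stage: flat-field images have inconsistent pixel spacings")
  lin_regions <- lapply(flats, function(f)
    linearize(extract_analysis_region(f, region_mm), fit,
              allow_noncompliant = allow_nc))
  mean_lin <- mean(vapply(lin_regions, mean, 0))
  detrended <- lapply(lin_regions, detrend, method = trend)
  w2d <- nps_2d(detrended, dx, dy, mean_linearized = mean_lin)
  nps_x <- nps_1d(w2d, "x"); nps_y <- nps_1d(w2d, "y")
  nnps_x <- nnps(nps_x); nnps_y <- nnps(nps_y)

  # --- MTF stage -----------------------------------------------------------
  edge_x <- read_image(need("edge_x_path", "MTF"))
  edge_y <- read_image(need("edge_y_path", "MTF"))
  mtf_x <- slanted_edge_mtf(linearize(edge_x$pixels, fit, allow_nc),
                            edge_x$dx, edge_x$dy, orientation = "vertical")
  mtf_y <- slanted_edge_mtf(linearize(edge_y$pixels, fit, allow_nc),
                            edge_y$dx, edge_y$dy, orientation = "horizontal")

  # --- DQE stage -----------------------------------------------------------
  kad <- if (!is.null(config$kerma_ugy))
    config$kerma_ugy * geometry_correction_factor(geom)
  else # inverse conversion: mean pv of the flats -> kerma at detector
    mean_lin / beam$snr_in2
  win <- w_in(beam, kad)
  dqe_x <- dqe_curve(mtf_x, win, nps_x)
  dqe_y <- dqe_curve(mtf_y, win, nps_y)
  nyq_x <- 1 / (2 * dx); nyq_y <- 1 / (2 * dy)
  binned_x <- bin_dqe(dqe_x, nyquist = nyq_x)
  binned_y <- bin_dqe(dqe_y, nyquist = nyq_y)

  bin_count_x <- max(1, round(0.5 / w2d$df_u))
  bin_count_y <- max(1, round(0.5 / w2d$df_v))
  u_scale <- cfg_or("u_mtf_scale", 0.4)
  budget <- function(mtf, bin_count) u_dqe(
    u_mtf = u_mtf_heuristic(mtf$n_lines, u_scale),
    u_nps = u_nps(w2d$m_total, nps_x$n_lines_averaged, bin_count),
    kerma_accuracy = cfg_or("kerma_accuracy", 0),
    dist_err_detector = cfg_or("dist_err_detector", 0),
    dist_err_chamber = cfg_or("dist_err_chamber", 0))

  result <- structure(list(
    freqs = nps_x$freqs, fit = fit,
    nps_x = nps_x, nps_y = nps_y, nnps_x = nnps_x, nnps_y = nnps_y,
    mtf_x = mtf_x, mtf_y = mtf_y, dqe_x = dqe_x, dqe_y = dqe_y,
    binned = list(freqs = binned_x$freqs, dqe_x = binned_x$values,
                  dqe_y = binned_y$values[seq_along(binned_x$freqs)]),
    budget_x = budget(mtf_x, bin_count_x),
    budget_y = budget(mtf_y, bin_count_y),
    meta = list(kvp = flats[[1L]]$kvp, mas = flats[[1L]]$mas, kad = kad,
                anode_filter = beam$anode_filter, snr_in2 = beam$snr_in2,
                m_total = w2d$m_total, trend = trend,
                dx = dx, dy = dy, r_squared = fit$r_squared,
                edge_angle_x = mtf_x$angle_used,
                edge_angle_y = mtf_y$angle_used)),
    class = "dqe_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dqe_csv(result, file.path(config$out_dir, "dqe_report.csv"))
  }
  result
}

#' @export
print.dqe_result <- function(x, ...) {
  cat(sprintf("<dqe_result> %s %g kV, KAD %.4g uGy, M = %d ROIs, trend '%s'\n",
              x$meta$anode_filter, x$meta$kvp, x$meta$kad, x$meta$m_total,
              x$meta$trend))
  cat(sprintf("  STP R^2 = %.6f; u_DQEX = %.3f, u_DQEY = %.3f\n",
              x$meta$r_squared, x$budget_x$u_dqe, x$budget_y$u_dqe))
  b <- x$binned
  cat("  binned DQE (lp/mm: x / y):\n")
  for (i in seq_along(b$freqs))
    cat(sprintf("    %4.1f: %.4f / %.4f\n", b$freqs[i], b$dqe_x[i], b$dqe_y[i]))
  invisible(x)
}

.fmt <- function(x) sprintf("%.12g", x)

#' Write the CSV report of a pipeline run
#'
#' Schema: `#`-prefixed metadata lines (key,value), a main block with one row
#' per NPS-grid frequency (`freq_mm^-1, nps_x, nps_y, nnps_x, nnps_y, mtf_x,
#' mtf_y, dqe_x, dqe_y`), then the binned block (`binned_freq_mm^-1,
#' dqe_x_binned, dqe_y_binned`) appended with its own header. Deterministic:
#' identical results produce byte-identical files.
#'
#' @param result A `dqe_result` from [run_pipeline()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dqe_csv <- function(result, path) {
  stopifnot(inherits(result, "dqe_result"))
  m <- result$meta
  meta_lines <- c(
    sprintf("# kvp,%s", .fmt(m$kvp)),
    sprintf("# mas,%s", .fmt(m$mas)),
    sprintf("# kad_ugy,%s", .fmt(m$kad)),
    sprintf("# anode_filter,%s", m$anode_filter),
    sprintf("# snr_in2,%s", .fmt(m$snr_in2)),
    sprintf("# m_rois,%d", m$m_total),
    sprintf("# trend,%s", m$trend),
    sprintf("# stp_r_squared,%s", .fmt(m$r_squared)),
    sprintf("# edge_angle_x_deg,%s", .fmt(m$edge_angle_x)),
    sprintf("# edge_angle_y_deg,%s", .fmt(m$edge_angle_y)),
    sprintf("# u_DQEX,%s", .fmt(result$budget_x$u_dqe)),
    sprintf("# u_DQEY,%s", .fmt(result$budget_y$u_dqe)),
    sprintf("# u_Wout,%s", .fmt(result$budget_x$u_win)))
  mtf_vx <- result$mtf_x$values[-1L] # drop the forced MTF(0)=1 point
  mtf_vy <- result$mtf_y$values[-1L]
  main <- paste(
    .fmt(result$freqs), .fmt(result$nps_x$values), .fmt(result$nps_y$values),
    .fmt(result$nnps_x$values), .fmt(result$nnps_y$values),
    .fmt(mtf_vx), .fmt(mtf_vy),
    .fmt(result$dqe_x$values), .fmt(result$dqe_y$values), sep = ",")
  b <- result$binned
  binned <- paste(.fmt(b$freqs), .fmt(b$dqe_x), .fmt(b$dqe_y), sep = ",")
  writeLines(c(meta_lines,
               "freq_mm^-1,nps_x,nps_y,nnps_x,nnps_y,mtf_x,mtf_y,dqe_x,dqe_y",
               main,
               "binned_freq_mm^-1,dqe_x_binned,dqe_y_binned",
               binned),
             path)
  invisible(path)
}

#' Check the supplied flat-field count against the 4-million-pixel rule
#'
#' @param config A [run_pipeline()] configuration (needs `flat_paths`, and
#'   `region_mm`; pixel pitch is read from the first flat field).
#' @param min_pixels Required pixel count (default 4e6).
#' @return List `required`, `supplied`, `pass`; also printed.
#' @export
check_image_count <- function(config, min_pixels = 4e6) {
  flat_paths <- config$flat_paths
  if (is.null(flat_paths) || length(flat_paths) == 0L)
    stop("image-count check needs config$flat_paths")
  img <- read_image(flat_paths[1L])
  region_mm <- if (is.null(config$region_mm)) 50 else config$region_mm
  req <- required_image_count(img$dx, region_mm, min_pixels)
  res <- list(required = req, supplied = length(flat_paths),
              pass = length(flat_paths) >= req)
  cat(sprintf("required images: %d, supplied: %d -> %s\n",
              res$required, res$supplied, if (res$pass) "pass" else "FAIL"))
  invisible(res)
}
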