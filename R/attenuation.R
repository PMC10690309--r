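#' Region-of-interest specification for attenuation estimation
#'
#' The attenuation coefficient is fitted inside a fixed rectangular window:
#' by default 200 A-scans wide by 250 depth pixels, laterally centered, with
#' the depth window starting a fixed offset below the detected
#' instrument-surface band ("top middle" placement, where most tissue signal
#' lives).
#'
#' @param width_px Lateral extent in A-scans (default 200).
#' @param depth_px Axial extent in pixels (default 250).
#' @param lateral_anchor Placement rule; only `"center"` is implemented.
#' @param depth_offset_px Depth offset of the window start below the detected
#'   surface band (default 10 px).
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(width_px = 200L, depth_px = 250L,
                     lateral_anchor = "center", depth_offset_px = 10L) {
  stopifnot(width_px >= 1, depth_px >= 2, depth_offset_px >= 0)
  lateral_anchor <- match.arg(lateral_anchor, "center")
  structure(list(width_px = as.integer(width_px),
                 depth_px = as.integer(depth_px),
                 lateral_anchor = lateral_anchor,
                 depth_offset_px = as.integer(depth_offset_px)),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> %d x %d px, %s, depth offset %d px below surface\n",
              x$width_px, x$depth_px, x$lateral_anchor, x$depth_offset_px))
  invisible(x)
}

#' Locate the instrument-surface band in a B-scan
#'
#' The GRIN-lens surface shows up as a bright line in the top rows of every
#' scan. Its depth index is taken as the argmax of the laterally averaged
#' intensity profile restricted to the top 10 percent of rows.
#'
#' @param scan A `bscan` or a depth x lateral intensity matrix.
#' @return Depth row index (1-based). A completely flat all-zero image
#'   returns 1 with a warning.
#' @export
locate_surface <- function(scan) {
  x <- if (inherits(scan, "bscan")) scan$pixels else scan
  stopifnot(is.matrix(x), nrow(x) >= 1, ncol(x) >= 1)
  if (all(x == 0)) {
    warning("flat all-zero image: surface defaulted to row 1")
    return(1L)
  }
  n_top <- max(1L, floor(0.1 * nrow(x)))
  prof <- rowMeans(x[seq_len(n_top), , drop = FALSE])
  which.max(prof)
}

#' Attenuation coefficient of a single A-scan
#'
#' Fits ordinary least squares of the natural-log intensity against physical
#' depth (mm) over a fixed window and returns \eqn{\mu = -slope / 2} in
#' mm^-1, the Beer-Lambert decay rate of \eqn{I(z) = I_0 e^{-2\mu z}}.
#' Nonpositive pixels cannot enter the log fit and are dropped; if fewer than
#' `min_frac` of the window pixels remain the column is declared
#' not-computable (`NA`) rather than imputed — this is exactly the failure
#' mode of signal-free pelvis scans.
#'
#' @param column Numeric depth intensity profile (one image column).
#' @param window_start First depth index (1-based) of the fitting window.
#' @param window_len Window length in pixels (default 250).
#' @param axial_pitch_mm Physical depth per pixel, mm.
#' @param min_frac Minimum fraction of window pixels that must be positive
#'   for the slope to count (default 0.5).
#' @param method Slope estimator: `"ols"` (ordinary least squares, the
#'   default and the contract) or `"theil-sen"` (median of pairwise slopes,
#'   robust to sparse bright inclusions).
#' @return Attenuation coefficient in mm^-1, or `NA_real_` when
#'   not-computable.
#' @examples
#' z <- 0:249 * 0.002
#' ascan_mu(100 * exp(-2 * 2 * z), 1, 250, 0.002)  # 2 mm^-1
#' @export
ascan_mu <- function(column, window_start, window_len = 250L,
                     axial_pitch_mm = 0.002, min_frac = 0.5,
                     method = c("ols", "theil-sen")) {
  method <- match.arg(method)
  if (axial_pitch_mm <= 0) stop("invalid geometry: 'axial_pitch_mm' must be > 0")
  n <- length(column)
  if (window_start < 1 || window_start + window_len - 1 > n)
    stop("fitting window outside the depth profile")
  seg <- column[window_start:(window_start + window_len - 1L)]
  keep <- is.finite(seg) & seg > 0
  if (sum(keep) < min_frac * window_len || sum(keep) < 2L)
    return(NA_real_)
  z <- (seq_len(window_len) - 1) * axial_pitch_mm
  y <- log(seg[keep]); zk <- z[keep]
  slope <- if (method == "ols") {
    stats::cov(zk, y) / stats::var(zk)
  } else {
    dz <- outer(zk, zk, "-"); dy <- outer(y, y, "-")
    stats::median(dy[lower.tri(dy)] / dz[lower.tri(dz)])
  }
  -slope / 2
}

#' Per-image attenuation coefficient over an ROI
#'
#' Resolves the ROI (laterally centered window of `roi$width_px` A-scans;
#' depth window of `roi$depth_px` pixels starting `roi$depth_offset_px` below
#' the detected instrument surface), computes [ascan_mu()] for every column,
#' and averages the computable columns into one attenuation coefficient per
#' image. The image-level estimate is declared invalid when fewer than
#' `min_col_frac` of the columns are computable — signal-free (pelvis) scans
#' are routed to abstention this way, never to a numeric value.
#'
#' @param scan A `bscan`.
#' @param roi A [roi_spec()].
#' @param min_px_frac Per-column validity threshold passed to [ascan_mu()].
#' @param min_col_frac Minimum fraction of computable columns for the image
#'   mean to be valid (default 0.5).
#' @param method Per-column slope estimator, as in [ascan_mu()]; the OLS
#'   path is vectorised across columns.
#' @return Object of class `attenuation_estimate`: list with `mu_image`
#'   (mm^-1, `NA` when invalid), `mu_columns`, `n_valid_columns`, `valid`,
#'   `roi`, `surface_row`, `window_start`.
#' @export
image_mu <- function(scan, roi = roi_spec(), min_px_frac = 0.5,
                     min_col_frac = 0.5, method = c("ols", "theil-sen")) {
  method <- match.arg(method)
  stopifnot(inherits(scan, "bscan"), inherits(roi, "roi_spec"))
  px <- scan$pixels
  depth <- nrow(px); width <- ncol(px)
  if (roi$width_px > width || roi$depth_px > depth)
    stop("ROI larger than image")

  col0 <- floor((width - roi$width_px) / 2) + 1L
  cols <- col0:(col0 + roi$width_px - 1L)
  surface <- suppressWarnings(locate_surface(scan))
  w0 <- surface + roi$depth_offset_px
  if (w0 + roi$depth_px - 1L > depth)
    stop("ROI depth window exceeds image depth")
  rows <- w0:(w0 + roi$depth_px - 1L)

  sub <- px[rows, cols, drop = FALSE]
  if (method == "theil-sen") {
    mu_cols <- apply(sub, 2, ascan_mu, window_start = 1L,
                     window_len = roi$depth_px,
                     axial_pitch_mm = scan$axial_pitch_mm,
                     min_frac = min_px_frac, method = "theil-sen")
    computable <- !is.na(mu_cols)
    n_valid <- sum(computable)
    valid <- n_valid >= min_col_frac * roi$width_px
    return(structure(
      list(mu_image = if (valid) mean(mu_cols[computable]) else NA_real_,
           mu_columns = mu_cols, n_valid_columns = n_valid, valid = valid,
           roi = roi, surface_row = surface, window_start = w0),
      class = "attenuation_estimate"))
  }
  y <- suppressWarnings(log(sub))
  ok <- is.finite(y)                     # nonpositive pixels dropped
  y[!ok] <- 0
  z <- (seq_len(roi$depth_px) - 1) * scan$axial_pitch_mm

  # vectorised per-column OLS with column-specific missingness
  nk  <- colSums(ok)
  sz  <- colSums(z * ok)
  szz <- colSums(z^2 * ok)
  sy  <- colSums(y * ok)
  szy <- colSums(z * y * ok)
  denom <- nk * szz - sz^2
  slope <- ifelse(denom > 0, (nk * szy - sz * sy) / denom, NA_real_)
  mu_cols <- -slope / 2
  computable <- nk >= min_px_frac * roi$depth_px & nk >= 2 & !is.na(mu_cols)
  mu_cols[!computable] <- NA_real_

  n_valid <- sum(computable)
  valid <- n_valid >= min_col_frac * roi$width_px
  structure(
    list(mu_image = if (valid) mean(mu_cols[computable]) else NA_real_,
         mu_columns = mu_cols,
         n_valid_columns = n_valid,
         valid = valid,
         roi = roi,
         surface_row = surface,
         window_start = w0),
    class = "attenuation_estimate")
}

#' @export
print.attenuation_estimate <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<attenuation_estimate> mu = %.4f mm^-1 (%d/%d columns)\n",
                x$mu_image, x$n_valid_columns, x$roi$width_px))
  else
    cat(sprintf("<attenuation_estimate> not computable (%d/%d columns)\n",
                x$n_valid_columns, x$roi$width_px))
  invisible(x)
}

#' Per-image attenuation table for a whole dataset
#'
#' Runs [image_mu()] over every scan of a [generate_phantom_dataset()]
#' result and returns the per-image attenuation table that the classifier
#' and the cross-testing harness consume.
#'
#' @param dataset A `phantom_dataset`.
#' @param roi A [roi_spec()].
#' @param ... Passed to [image_mu()].
#' @return data.frame with columns `scan_id`, `subject_id`, `label`, `mu`,
#'   `n_valid_columns`, `valid`.
#' @export
dataset_mu <- function(dataset, roi = roi_spec(), ...) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  est <- lapply(dataset$scans, image_mu, roi = roi, ...)
  data.frame(
    scan_id = dataset$manifest$scan_id,
    subject_id = dataset$manifest$subject_id,
    label = dataset$manifest$label,
    mu = vapply(est, `[[`, numeric(1), "mu_image"),
    n_valid_columns = vapply(est, `[[`, integer(1), "n_valid_columns"),
    valid = vapply(est, `[[`, logical(1), "valid"),
    stringsAsFactors = FALSE)
}
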