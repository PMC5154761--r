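# Membrane-bound fluorescence sampling along the contour and joint
# intensity statistics between channels (or against speed).

#' Sample membrane fluorescence along a contour
#'
#' For each contour point, intensities are bilinearly sampled at a fixed
#' number of positions along the inward+outward normal segment of length
#' `band_width_um` centred on the point, and averaged. The band statistic is
#' the mean (robust to single-pixel noise); sampling is deterministic.
#' Samples falling outside the image are clamped to the border and the
#' profile is flagged as clipped.
#'
#' @param img image matrix (one channel).
#' @param contour a [extract_contour()] result.
#' @param band_width_um band length along the normal; must be at least one
#'   pixel. The default (1.6) fully encloses a diffraction-scale membrane
#'   rim with margin on both sides, which makes the band mean insensitive
#'   to sub-pixel contour placement error.
#' @param cyto_mean optional cytosol mean of the same channel; when given,
#'   normalized intensities (`raw / cyto_mean`) are included.
#' @param n_samples number of samples along the normal segment (default:
#'   one per half pixel, at least 7).
#' @return Object of class `membrane_profile`: list with `raw`,
#'   `normalized` (or NULL), `arc_um`, `band_width_um`, `clipped` flag,
#'   `n_points`, `arc_spacing_um`.
#' @export
sample_membrane <- function(img, contour, band_width_um = 1.6,
                            cyto_mean = NULL, n_samples = NULL) {
  px <- contour$pixel_size_um
  if (band_width_um <= 0) {
    mp_stop("band_width_um must be positive", "invalid_parameter")
  }
  if (band_width_um < px) {
    mp_stop("band_width_um must be at least one pixel", "invalid_parameter")
  }
  if (is.null(n_samples)) {
    n_samples <- max(7L, 2L * ceiling(band_width_um / px) + 1L)
  }
  nrm <- contour_normals(contour)
  offsets <- seq(-band_width_um / 2, band_width_um / 2,
                 length.out = n_samples)
  n <- contour$n_points
  raw <- numeric(n)
  clipped <- FALSE
  # positions in pixel units: x_px = x_um / px (pixel centre of col c at c)
  px_x <- contour$points[, 1] / px
  px_y <- contour$points[, 2] / px
  for (k in seq_along(offsets)) {
    sx <- px_x + offsets[k] * nrm[, 1] / px
    sy <- px_y + offsets[k] * nrm[, 2] / px
    if (any(sx < 1 | sx > ncol(img) | sy < 1 | sy > nrow(img))) {
      clipped <- TRUE
    }
    raw <- raw + bilinear_sample(img, sx, sy)
  }
  raw <- raw / n_samples
  if (clipped) mp_warn("sampling band clipped at the image border", "clipped")
  structure(list(
    raw = raw,
    normalized = if (!is.null(cyto_mean)) raw / cyto_mean else NULL,
    cyto_mean = cyto_mean,
    arc_um = (seq_len(n) - 1) * contour$arc_spacing_um,
    band_width_um = band_width_um,
    clipped = clipped,
    n_points = n,
    arc_spacing_um = contour$arc_spacing_um),
    class = "membrane_profile")
}

#' @export
print.membrane_profile <- function(x, ...) {
  cat(sprintf("<membrane_profile> %d points, band %.3g um, raw mean %.4g%s\n",
              x$n_points, x$band_width_um, mean(x$raw),
              if (x$clipped) " (clipped)" else ""))
  invisible(x)
}

#' Joint 2D histogram and correlation of two per-point quantities
#'
#' Pools two equal-length vectors (e.g. membrane intensities of two
#' channels across all points, frames and cells) into a 2D histogram and
#' reports Pearson and Spearman correlations. A constant input vector makes
#' the correlation undefined; this is flagged, not silently zeroed.
#'
#' @param a,b numeric vectors of equal length (>= 3). `NA` pairs dropped.
#' @param bins number of bins per axis (scalar or length 2).
#' @return Object of class `joint_histogram`: list with `counts` (matrix),
#'   `a_breaks`, `b_breaks`, `pearson_r`, `spearman_rho`, `n_points`,
#'   `undefined` flag.
#' @examples
#' jh <- joint_histogram(1:10, (1:10)^2)
#' jh$pearson_r
#' @export
joint_histogram <- function(a, b, bins = 32) {
  if (length(a) != length(b)) mp_stop("a and b differ in length", "invalid_parameter")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) mp_stop("need at least 3 paired points", "invalid_parameter")
  if (length(bins) == 1) bins <- c(bins, bins)
  undefined <- stats::sd(a) == 0 || stats::sd(b) == 0
  pear <- if (undefined) NA_real_ else stats::cor(a, b)
  spear <- if (undefined) NA_real_ else
    stats::cor(a, b, method = "spearman")
  pad <- function(x, k) {
    r <- range(x)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = k + 1)
  }
  ab <- pad(a, bins[1]); bb <- pad(b, bins[2])
  ia <- pmin(findInterval(a, ab, rightmost.closed = TRUE), bins[1])
  ib <- pmin(findInterval(b, bb, rightmost.closed = TRUE), bins[2])
  counts <- matrix(0L, bins[1], bins[2])
  for (i in seq_along(ia)) counts[ia[i], ib[i]] <- counts[ia[i], ib[i]] + 1L
  structure(list(counts = counts, a_breaks = ab, b_breaks = bb,
                 pearson_r = pear, spearman_rho = spear,
                 n_points = length(a), undefined = undefined),
            class = "joint_histogram")
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("<joint_histogram> n=%d, Pearson r=%s, Spearman rho=%s%s\n",
              x$n_points, format(x$pearson_r, digits = 3),
              format(x$spearman_rho, digits = 3),
              if (x$undefined) " (undefined: constant input)" else ""))
  invisible(x)
}

#' Write a membrane profile set as long-format CSV
#'
#' @param profiles nested list: `profiles[[frame]][[channel]]` of
#'   `membrane_profile`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- list()
  for (f in seq_along(profiles)) {
    for (ch in names(profiles[[f]])) {
      p <- profiles[[f]][[ch]]
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, point_index = seq_len(p$n_points), channel = ch,
        raw = p$raw,
        normalized = if (is.null(p$normalized)) NA_real_ else p$normalized)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
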