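# Cell segmentation, sub-pixel contour extraction with equal-arclength
# resampling, and cytosol statistics.

#' Segment the cell in one frame
#'
#' Gaussian-smooths the image, thresholds it (Otsu by default), keeps the
#' largest connected component and fills interior holes.
#'
#' @param img image matrix `[row, col]`.
#' @param pixel_size_um pixel size.
#' @param smooth_sigma_um Gaussian smoothing sigma before thresholding.
#' @param threshold_method `"otsu_clipped"` (default: Otsu computed on
#'   intensities winsorized at the 95th percentile, so that the small but
#'   very bright patch class cannot capture the threshold and the
#'   background/cytosol bimodality decides it), `"otsu"` (plain), or a
#'   numeric threshold value.
#' @param min_area_px minimum component area; smaller cells raise
#'   `mp_error_no_cell`.
#' @return An object of class `cell_mask`: list with `mask` (logical
#'   matrix), `area_px`, `pixel_size_um`, `threshold`.
#' @examples
#' img <- matrix(0, 64, 64)
#' img[outer(1:64, 1:64, function(r, c) (r - 32)^2 + (c - 32)^2 < 20^2)] <- 100
#' m <- segment_cell(img, pixel_size_um = 0.1)
#' m$area_px
#' @export
segment_cell <- function(img, pixel_size_um,
                         smooth_sigma_um = 0.05,
                         threshold_method = "otsu_clipped",
                         min_area_px = 100) {
  if (length(img) == 0) mp_stop("empty image", "no_cell")
  sigma_px <- smooth_sigma_um / pixel_size_um
  sm <- if (sigma_px > 0.05) EBImage::gblur(img, sigma = sigma_px) else img
  otsu_of <- function(x) {
    rng <- range(x)
    if (diff(rng) <= 0) mp_stop("flat image: no cell found", "no_cell")
    EBImage::otsu(EBImage::Image((x - rng[1]) / diff(rng)),
                  range = c(0, 1)) * diff(rng) + rng[1]
  }
  thr <- if (identical(threshold_method, "otsu_clipped")) {
    otsu_of(pmin(sm, stats::quantile(sm, 0.95)))
  } else if (identical(threshold_method, "otsu")) {
    otsu_of(sm)
  } else {
    as.numeric(threshold_method)
  }
  bin <- sm > thr
  if (!any(bin)) mp_stop("no pixels above threshold", "no_cell")
  lab <- EBImage::bwlabel(bin)
  tab <- tabulate(lab[lab > 0])
  if (!length(tab) || max(tab) < min_area_px) {
    mp_stop(sprintf("no component with >= %d px", min_area_px), "no_cell")
  }
  keep <- which.max(tab)
  mask <- lab == keep
  mask <- EBImage::fillHull(mask)
  mask <- matrix(as.logical(mask), nrow(img), ncol(img))
  structure(list(mask = mask, area_px = sum(mask),
                 pixel_size_um = pixel_size_um, threshold = thr),
            class = "cell_mask")
}

#' Extract a sub-pixel, equal-arclength cell contour
#'
#' The binary mask is lightly Gaussian-smoothed and its 0.5 iso-contour is
#' traced with linear interpolation (marching-squares style via
#' `grDevices::contourLines`), then resampled to `n_points` points of equal
#' arclength, oriented counter-clockwise (positive shoelace area in the
#' x-right / y-down pixel frame), with the index origin at the point nearest
#' the ray from the centroid along +x.
#'
#' @param mask a [segment_cell()] result (or a logical matrix plus
#'   `pixel_size_um`).
#' @param n_points number of contour points (default 100).
#' @param pixel_size_um required if `mask` is a bare matrix.
#' @param smooth_sigma_px smoothing applied to the binary mask before
#'   iso-contouring.
#' @return Object of class `cell_contour`: list with `points` (n x 2 matrix
#'   of x, y in micrometres), `centroid_um`, `arc_spacing_um`,
#'   `perimeter_um`, `area_um2` (shoelace), `n_points`.
#' @export
extract_contour <- function(mask, n_points = 100, pixel_size_um = NULL,
                            smooth_sigma_px = 1) {
  if (inherits(mask, "cell_mask")) {
    px <- mask$pixel_size_um
    m <- mask$mask
  } else {
    if (is.null(pixel_size_um)) {
      mp_stop("pixel_size_um required for a bare mask", "invalid_config")
    }
    px <- pixel_size_um
    m <- mask
  }
  if (sum(boundary_pixels(m)) < 8) {
    mp_stop("degenerate boundary (< 8 boundary pixels)", "contour")
  }
  sm <- EBImage::gblur(m * 1.0, sigma = smooth_sigma_px)
  # z[i, j] lives at x = i (row), y = j (col)
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = sm, levels = 0.5)
  if (!length(cl)) mp_stop("no iso-contour found", "contour")
  lens <- vapply(cl, function(c) length(c$x), numeric(1))
  cc <- cl[[which.max(lens)]]
  # contourLines x = row coordinate, y = col coordinate; convert to
  # x_um = col * px, y_um = row * px
  xy <- cbind(x = cc$y * px, y = cc$x * px)
  # drop duplicated closing point if present
  if (nrow(xy) > 1 && all(abs(xy[1, ] - xy[nrow(xy), ]) < 1e-12)) {
    xy <- xy[-nrow(xy), , drop = FALSE]
  }
  if (nrow(xy) < 8) mp_stop("degenerate iso-contour", "contour")
  pts <- resample_closed_curve(xy, n_points)
  orient_contour(pts, px)
}

# uniform arclength resampling of a closed polyline (n x 2)
resample_closed_curve <- function(xy, n_points) {
  closed <- rbind(xy, xy[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n_points + 1)[seq_len(n_points)]
  cbind(stats::approx(s, closed[, 1], xout = target)$y,
        stats::approx(s, closed[, 2], xout = target)$y)
}

# fix orientation (positive shoelace = counter-clockwise in the pixel
# frame), set index origin to the point nearest the +x ray from the
# centroid, and package the contour object
orient_contour <- function(pts, px) {
  area <- shoelace_area(pts[, 1], pts[, 2])
  if (area < 0) {
    pts <- pts[c(1, nrow(pts):2), , drop = FALSE]
    area <- -area
  }
  centroid <- colMeans(pts)
  th <- wrap_angle(atan2(pts[, 2] - centroid[2], pts[, 1] - centroid[1]))
  origin <- which.min(pmin(th, 2 * pi - th))
  if (origin > 1) pts <- pts[c(origin:nrow(pts), 1:(origin - 1)), ,
                             drop = FALSE]
  seg <- sqrt(diff(rbind(pts, pts[1, ])[, 1])^2 +
                diff(rbind(pts, pts[1, ])[, 2])^2)
  structure(list(points = pts, centroid_um = centroid,
                 arc_spacing_um = mean(seg), perimeter_um = sum(seg),
                 area_um2 = area, n_points = nrow(pts),
                 pixel_size_um = px),
            class = "cell_contour")
}

#' @export
print.cell_contour <- function(x, ...) {
  cat(sprintf("<cell_contour> %d points, perimeter %.3g um, area %.3g um^2\n",
              x$n_points, x$perimeter_um, x$area_um2))
  invisible(x)
}

# 4-connected boundary pixels of a logical mask
boundary_pixels <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-nr, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -nc, drop = FALSE])
  m & !(up & dn & lf & rt)
}

#' Outward normals of a contour
#'
#' Central-difference tangents; outward = tangent rotated so that, for a
#' counter-clockwise contour, normals point away from the centroid.
#'
#' @param contour a `cell_contour`.
#' @return n x 2 matrix of unit normal vectors.
#' @export
contour_normals <- function(contour) {
  p <- contour$points
  n <- nrow(p)
  nxt <- p[c(2:n, 1), , drop = FALSE]
  prv <- p[c(n, 1:(n - 1)), , drop = FALSE]
  tg <- nxt - prv
  len <- sqrt(rowSums(tg^2))
  tg <- tg / len
  cbind(tg[, 2], -tg[, 1])
}

#' Cytosol intensity statistics inside an eroded cell mask
#'
#' Erodes the mask by `erosion_margin_um` (a disc structuring element) to
#' exclude the membrane band, then computes the mean and SD of the image
#' over the remaining interior pixels. These statistics define the patch
#' threshold (cytosol mean + k SD) and the normalization reference.
#'
#' @param img image matrix (one channel).
#' @param mask a `cell_mask` (or logical matrix).
#' @param erosion_margin_um erosion depth; must leave a non-empty interior.
#' @param pixel_size_um required when `mask` is a bare matrix.
#' @return Object of class `cytosol_stats`: list with `mean`, `sd`,
#'   `n_pixels`, `erosion_margin_um`.
#' @export
cytosol_stats <- function(img, mask, erosion_margin_um = 1.0,
                          pixel_size_um = NULL) {
  if (inherits(mask, "cell_mask")) {
    px <- mask$pixel_size_um
    m <- mask$mask
  } else {
    if (is.null(pixel_size_um)) {
      mp_stop("pixel_size_um required for a bare mask", "invalid_config")
    }
    px <- pixel_size_um
    m <- mask
  }
  r_px <- max(1L, round(erosion_margin_um / px))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  er <- EBImage::erode(m * 1.0, brush) > 0.5
  if (!any(er)) {
    mp_stop("erosion margin empties the mask", "margin_too_large")
  }
  v <- img[er]
  structure(list(mean = mean(v), sd = stats::sd(v), n_pixels = length(v),
                 erosion_margin_um = erosion_margin_um),
            class = "cytosol_stats")
}

#' Write contours to CSV (frame, index, x_um, y_um)
#'
#' @param contours list of `cell_contour` (one per frame).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- do.call(rbind, lapply(seq_along(contours), function(f) {
    p <- contours[[f]]$points
    data.frame(frame = f, index = seq_len(nrow(p)),
               x_um = p[, 1], y_um = p[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
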