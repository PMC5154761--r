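# Circular patch calling by the cytosol mean + k SD rule, centre/edge
# quantification of a second channel, size statistics and group tests.

#' Call membrane patches on a circular intensity profile
#'
#' Patches are maximal circular runs of contour points whose raw membrane
#' intensity is strictly greater than `cyto$mean + k_sd * cyto$sd`
#' (points exactly at the threshold are excluded). Runs wrapping the index
#' origin are merged into a single interval; runs shorter than
#' `min_patch_points` are discarded. A profile entirely above threshold
#' yields the single full-circle interval.
#'
#' Intervals are half-open `[start_idx, end_idx)` on the circle (1-based);
#' the centre index is the circular midpoint, ties resolved to the lower
#' index.
#'
#' @param profile a [sample_membrane()] result for the calling channel.
#' @param cyto a [cytosol_stats()] result for the same frame and channel.
#' @param k_sd threshold multiple of the cytosol SD (default 1).
#' @param min_patch_points minimum run length in points (default 3).
#' @param threshold explicit raw-intensity threshold overriding the
#'   mean + k_sd * SD rule. The rule presumes shot noise in the cytosol; on
#'   a noiseless synthetic render the cytosol SD collapses to zero and the
#'   rule degenerates, so such analyses must supply a threshold directly.
#' @return Object of class `patch_call`: list with `intervals` (data frame:
#'   `start_idx`, `end_idx`, `center_idx`, `n_points`, `arc_length_um`,
#'   `mean_norm_intensity`, `peak_norm_intensity`), `threshold`, `k_sd`,
#'   `n_profile_points`, `arc_spacing_um`, `full_circle` flag.
#' @examples
#' ct <- list(points = cbind(cos(seq(0, 2 * pi, length.out = 101)[-101]),
#'                           sin(seq(0, 2 * pi, length.out = 101)[-101])),
#'            centroid_um = c(0, 0), arc_spacing_um = 2 * pi / 100,
#'            n_points = 100, pixel_size_um = 0.1)
#' @export
call_patches <- function(profile, cyto, k_sd = 1, min_patch_points = 3,
                         threshold = NULL) {
  n <- profile$n_points
  if (n < 8) mp_stop("profile too coarse (< 8 points)", "profile_too_coarse")
  thr <- if (!is.null(threshold)) threshold else cyto$mean + k_sd * cyto$sd
  above <- profile$raw > thr
  norm <- profile$raw / cyto$mean
  spacing <- profile$arc_spacing_um

  empty <- data.frame(start_idx = integer(0), end_idx = integer(0),
                      center_idx = integer(0), n_points = integer(0),
                      arc_length_um = numeric(0),
                      mean_norm_intensity = numeric(0),
                      peak_norm_intensity = numeric(0))
  make <- function(intervals, full = FALSE) {
    structure(list(intervals = intervals, threshold = thr, k_sd = k_sd,
                   n_profile_points = n, arc_spacing_um = spacing,
                   full_circle = full),
              class = "patch_call")
  }

  if (!any(above)) return(make(empty))
  if (all(above)) {
    iv <- data.frame(start_idx = 1L, end_idx = 1L, center_idx = circ_center(1L, 1L, n),
                     n_points = n, arc_length_um = n * spacing,
                     mean_norm_intensity = mean(norm),
                     peak_norm_intensity = max(norm))
    return(make(iv, full = TRUE))
  }

  # rotate so position 1 is below threshold, find runs, rotate back
  shift <- which(!above)[1] - 1L
  rot <- above[((seq_len(n) - 1L + shift) %% n) + 1L]
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  ivs <- lapply(runs, function(k) {
    s <- ((starts[k] - 1L + shift) %% n) + 1L
    len <- r$lengths[k]
    if (len < min_patch_points) return(NULL)
    e <- ((s - 1L + len) %% n) + 1L
    idx <- circ_indices(s, e, n)
    data.frame(start_idx = s, end_idx = e,
               center_idx = circ_center(s, e, n),
               n_points = len, arc_length_um = len * spacing,
               mean_norm_intensity = mean(norm[idx]),
               peak_norm_intensity = max(norm[idx]))
  })
  ivs <- ivs[!vapply(ivs, is.null, logical(1))]
  iv <- if (length(ivs)) do.call(rbind, ivs) else empty
  if (nrow(iv)) iv <- iv[order(iv$start_idx), , drop = FALSE]
  rownames(iv) <- NULL
  make(iv)
}

#' @export
print.patch_call <- function(x, ...) {
  cat(sprintf("<patch_call> %d patch(es) of %d points (threshold %.4g = cytosol mean + %.3g SD)\n",
              nrow(x$intervals), x$n_profile_points, x$threshold, x$k_sd))
  invisible(x)
}

#' Indices covered by every called patch
#' @param call a `patch_call`.
#' @return sorted integer vector of contour indices inside any patch.
#' @export
patch_index_set <- function(call) {
  n <- call$n_profile_points
  iv <- call$intervals
  sort(unique(unlist(lapply(seq_len(nrow(iv)), function(i)
    circ_indices(iv$start_idx[i], iv$end_idx[i], n)))))
}

#' Measure a second channel at patch centres and edges
#'
#' For each called patch (of at least 3 points), reads the measurement
#' channel's membrane profile at the patch centre and at its two edges, in
#' units of the measurement channel's cytosol mean. The edge value averages,
#' for each boundary, the boundary point just inside the interval and its
#' immediate neighbour just outside (`edge_mode = "inside_outside_mean"`,
#' the default) or the inside boundary point alone (`"inside"`).
#'
#' This is the paper's configuration when calling on a PIP3 reporter and
#' measuring a SCAR reporter: the ring flanks the patch, so edges light up
#' while the centre stays at cytosolic background.
#'
#' @param call a [call_patches()] result (any channel).
#' @param measurement_profile a [sample_membrane()] result for the channel
#'   to quantify (same frame and contour).
#' @param cyto [cytosol_stats()] of the measurement channel.
#' @param edge_mode see above.
#' @return Data frame with one row per measured patch: `patch`, `I_center`,
#'   `I_edge`, `I_cytosol` (== 1 in normalized units), `n_points`. Patches
#'   of fewer than 3 points are skipped with a warning.
#' @export
measure_center_edge <- function(call, measurement_profile, cyto,
                                edge_mode = c("inside_outside_mean",
                                              "inside")) {
  edge_mode <- match.arg(edge_mode)
  n <- call$n_profile_points
  if (measurement_profile$n_points != n) {
    mp_stop("profile and call have different point counts", "invalid_parameter")
  }
  norm <- measurement_profile$raw / cyto$mean
  iv <- call$intervals
  skipped <- 0L
  rows <- lapply(seq_len(nrow(iv)), function(i) {
    if (iv$n_points[i] < 3) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    s <- iv$start_idx[i]
    e_in <- ((iv$end_idx[i] - 2L) %% n) + 1L   # last point inside
    s_out <- ((s - 2L) %% n) + 1L              # neighbour before start
    e_out <- iv$end_idx[i]                      # neighbour after end
    edge_val <- switch(edge_mode,
      inside_outside_mean = mean(c((norm[s] + norm[s_out]) / 2,
                                   (norm[e_in] + norm[e_out]) / 2)),
      inside = mean(c(norm[s], norm[e_in])))
    data.frame(patch = i, I_center = norm[iv$center_idx[i]],
               I_edge = edge_val, I_cytosol = 1,
               n_points = iv$n_points[i])
  })
  if (skipped > 0) {
    mp_warn(sprintf("%d patch(es) of < 3 points skipped", skipped),
            "patch_too_small")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) do.call(rbind, rows) else
    data.frame(patch = integer(0), I_center = numeric(0),
               I_edge = numeric(0), I_cytosol = numeric(0),
               n_points = integer(0))
}

#' Patch size distribution summary
#'
#' @param calls a `patch_call` or list of them (e.g. one per frame).
#' @return Object of class `patch_size_stats`: list with `sizes_um`
#'   (per-patch arc lengths), `mean`, `sd`, `n`.
#' @export
patch_size_stats <- function(calls) {
  if (inherits(calls, "patch_call")) calls <- list(calls)
  sizes <- unlist(lapply(calls, function(c) c$intervals$arc_length_um))
  if (!length(sizes)) mp_stop("no patches in any call", "empty_distribution")
  structure(list(sizes_um = sizes, mean = mean(sizes),
                 sd = stats::sd(sizes), n = length(sizes)),
            class = "patch_size_stats")
}

#' @export
print.patch_size_stats <- function(x, ...) {
  cat(sprintf("<patch_size_stats> n=%d, mean %.3g um, sd %.3g um\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Two-tailed t-test between two groups of measurements
#'
#' Paired (the paper's centre/edge comparisons) or Welch unpaired (group
#' comparisons such as patch sizes between strains). Identical paired
#' groups — zero variance of the differences — are reported as statistic 0,
#' p = 1 rather than an error.
#'
#' @param sizes_a,sizes_b numeric vectors (n >= 2 each; equal length when
#'   paired).
#' @param paired logical.
#' @return List with `statistic`, `p_value`, `test_name`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `effect_size` (Cohen's d, pooled SD).
#' @examples
#' compare_groups(rnorm(10, 1), rnorm(10, 2), paired = FALSE)$p_value
#' @export
compare_groups <- function(sizes_a, sizes_b, paired = FALSE) {
  if (length(sizes_a) < 2 || length(sizes_b) < 2) {
    mp_stop("need at least 2 observations per group", "insufficient_data")
  }
  if (paired && length(sizes_a) != length(sizes_b)) {
    mp_stop("paired comparison requires equal group sizes",
            "insufficient_data")
  }
  degenerate <- if (paired) stats::sd(sizes_a - sizes_b) == 0 else
    (stats::sd(sizes_a) == 0 && stats::sd(sizes_b) == 0 &&
       mean(sizes_a) == mean(sizes_b))
  if (degenerate) {
    stat <- 0; p <- 1
  } else {
    tt <- stats::t.test(sizes_a, sizes_b, paired = paired,
                        var.equal = FALSE, alternative = "two.sided")
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  sp <- sqrt((stats::var(sizes_a) + stats::var(sizes_b)) / 2)
  list(statistic = stat, p_value = p,
       test_name = if (paired) "paired two-tailed t-test" else
         "Welch two-tailed t-test",
       n_a = length(sizes_a), n_b = length(sizes_b),
       mean_a = mean(sizes_a), mean_b = mean(sizes_b),
       effect_size = if (sp > 0) (mean(sizes_a) - mean(sizes_b)) / sp else 0)
}

#' Write patch calls to CSV
#'
#' @param calls list of `patch_call`, one per frame.
#' @param path CSV path.
#' @param channel channel label to record.
#' @return `path`, invisibly.
#' @export
write_calls_csv <- function(calls, path, channel = "patch") {
  rows <- do.call(rbind, lapply(seq_along(calls), function(f) {
    iv <- calls[[f]]$intervals
    if (nrow(iv) == 0) return(NULL)
    cbind(data.frame(frame = f, channel = channel), iv,
          threshold = calls[[f]]$threshold)
  }))
  if (is.null(rows)) {
    rows <- data.frame(frame = integer(0), channel = character(0))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
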