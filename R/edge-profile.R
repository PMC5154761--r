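# Intensity profiles across patch boundaries along the membrane arc,
# their average, and 10-90% boundary sharpness.

#' Extract membrane intensity profiles across patch boundaries
#'
#' For each boundary of each called patch, samples `2*half_width_points + 1`
#' consecutive membrane profile values centred on the boundary point, along
#' the membrane arc, and orients each profile so the patch interior comes
#' first (left) and the exterior last. Boundaries whose sampling window
#' would enter another patch are skipped and counted.
#'
#' The per-edge sharpness `d90_10_um` is the arc distance between the
#' points where the profile crosses 90% and 10% of the interior-to-exterior
#' contrast (plateaus estimated from the mean of the 3 innermost and 3
#' outermost samples; crossings linearly interpolated; the result is
#' clamped below at one sample spacing, the resolution of the measurement).
#'
#' @param profile a [sample_membrane()] result (channel to measure,
#'   normally the patch/calling channel).
#' @param call the [call_patches()] result on the same contour.
#' @param half_width_points half-width of the sampling window in contour
#'   points.
#' @return Object of class `edge_profile_set`: list with `profiles` (matrix,
#'   one row per usable edge, interior to exterior), `d90_10_um` (per edge),
#'   `sample_spacing_um`, `n_skipped`, `edge_info` (patch, side).
#' @export
extract_edge_profiles <- function(profile, call, half_width_points = 8) {
  n <- call$n_profile_points
  iv <- call$intervals
  if (nrow(iv) == 0 || call$full_circle) {
    mp_stop("no usable patch edges", "empty_profile_set")
  }
  vals <- if (!is.null(profile$normalized)) profile$normalized else
    profile$raw
  inside_any <- logical(n)
  inside_by_patch <- vector("list", nrow(iv))
  for (i in seq_len(nrow(iv))) {
    idx <- circ_indices(iv$start_idx[i], iv$end_idx[i], n)
    inside_by_patch[[i]] <- idx
    inside_any[idx] <- TRUE
  }
  h <- half_width_points
  rows <- list(); info <- list(); skipped <- 0L
  for (i in seq_len(nrow(iv))) {
    own <- inside_by_patch[[i]]
    other <- inside_any
    other[own] <- FALSE
    for (side in c("start", "end")) {
      centre <- if (side == "start") iv$start_idx[i] else
        ((iv$end_idx[i] - 2L) %% n) + 1L
      win <- ((centre - 1L + (-h:h)) %% n) + 1L
      if (any(other[win])) {
        skipped <- skipped + 1L
        next
      }
      v <- vals[win]
      # orient interior -> exterior: interior lies at increasing indices
      # for a start edge, so flip it
      if (side == "start") v <- rev(v)
      rows[[length(rows) + 1L]] <- v
      info[[length(info) + 1L]] <- data.frame(patch = i, side = side)
    }
  }
  if (!length(rows)) mp_stop("no usable patch edges", "empty_profile_set")
  profs <- do.call(rbind, rows)
  spacing <- call$arc_spacing_um
  d <- apply(profs, 1, edge_d90_10, spacing = spacing)
  structure(list(profiles = profs, d90_10_um = d,
                 sample_spacing_um = spacing, n_skipped = skipped,
                 edge_info = do.call(rbind, info)),
            class = "edge_profile_set")
}

# 10-90% falling-edge width of one interior->exterior profile.
# The 90% crossing is taken at the LAST sample still at or above the 90%
# level (robust to noise dips on the interior plateau) and the 10% crossing
# at the first sample at or below the 10% level beyond it; both are
# linearly interpolated. The result is clamped below at one sample spacing,
# the resolution of the measurement.
edge_d90_10 <- function(v, spacing) {
  m <- length(v)
  hi <- mean(v[1:min(3, m)])
  lo <- mean(v[max(1, m - 2):m])
  if (hi <= lo) return(NA_real_)
  l90 <- lo + 0.9 * (hi - lo)
  l10 <- lo + 0.1 * (hi - lo)
  above <- which(v >= l90)
  above <- above[above < m]
  if (!length(above)) return(NA_real_)
  i90 <- above[length(above)]
  x90 <- if (v[i90 + 1] >= l90 || v[i90] == v[i90 + 1]) i90 else
    i90 + (v[i90] - l90) / (v[i90] - v[i90 + 1])
  below <- which(v <= l10)
  below <- below[below > i90]
  if (!length(below)) return(NA_real_)
  i10 <- below[1]
  x10 <- if (v[i10 - 1] <= l10 || v[i10 - 1] == v[i10]) i10 else
    (i10 - 1) + (v[i10 - 1] - l10) / (v[i10 - 1] - v[i10])
  max((x10 - x90) * spacing, spacing)
}

#' @export
print.edge_profile_set <- function(x, ...) {
  cat(sprintf("<edge_profile_set> %d edge(s), %d skipped, mean d90-10 %.3g um\n",
              nrow(x$profiles), x$n_skipped,
              mean(x$d90_10_um, na.rm = TRUE)))
  invisible(x)
}

#' Average edge profiles pointwise
#'
#' Profiles are already aligned on their called boundary index (no
#' re-registration) and share the interior-to-exterior orientation, so
#' averaging commutes with the orientation flips applied during extraction.
#'
#' @param set an [extract_edge_profiles()] result.
#' @return List with `mean` (pointwise mean profile), `sd` (pointwise SD,
#'   0 for a single profile), `n_profiles`, `sample_spacing_um`,
#'   `mean_d90_10_um`.
#' @export
average_profiles <- function(set) {
  if (nrow(set$profiles) < 1) mp_stop("empty profile set", "empty_profile_set")
  m <- colMeans(set$profiles)
  s <- if (nrow(set$profiles) > 1) apply(set$profiles, 2, stats::sd) else
    rep(0, ncol(set$profiles))
  list(mean = m, sd = s, n_profiles = nrow(set$profiles),
       sample_spacing_um = set$sample_spacing_um,
       mean_d90_10_um = mean(set$d90_10_um, na.rm = TRUE))
}

#' Write edge profiles and sharpness to CSV
#' @param set an `edge_profile_set`.
#' @param profile_path,sharpness_path output CSV paths (NULL to skip).
#' @return invisibly, a list of the written paths.
#' @export
write_edge_profiles_csv <- function(set, profile_path = NULL,
                                    sharpness_path = NULL) {
  if (!is.null(profile_path)) {
    utils::write.table(set$profiles, profile_path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(sharpness_path)) {
    utils::write.csv(cbind(set$edge_info, d90_10_um = set$d90_10_um),
                     sharpness_path, row.names = FALSE)
  }
  invisible(list(profile_path, sharpness_path))
}
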