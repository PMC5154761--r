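# Frame-to-frame contour correspondence, signed normal membrane speed,
# membrane / edge-line kymographs, and patch lineage tracking with origin
# classification (de novo vs split).

#' Register two consecutive contours
#'
#' Finds the global circular index offset minimising the summed squared
#' point-to-point distance; each point's displacement is then the vector to
#' its offset-mapped partner on the next contour. This deliberately simple
#' correspondence preserves rigid motions exactly (a pure translation maps
#' every point by the translation vector), and its normal projection — the
#' quantity the speed analysis consumes — agrees with the analytic normal
#' velocity field for affine motions at modest inter-frame displacement
#' (below about two arc spacings). It is not a full electrostatic contour
#' mapping.
#'
#' @param c_t,c_next `cell_contour`s of frames t and t+1 (equal point
#'   counts).
#' @return Object of class `contour_correspondence`: list with `offset`
#'   (circular index offset: point i of frame t corresponds to point
#'   `i + offset` of frame t+1), `displacement_um` (n x 2 matrix of
#'   point-to-mapped-point displacement vectors), `mapped_index`.
#' @export
register_contours <- function(c_t, c_next) {
  n <- c_t$n_points
  if (n != c_next$n_points) {
    mp_stop("contours must have equal point counts", "invalid_parameter")
  }
  jump <- sqrt(sum((c_t$centroid_um - c_next$centroid_um)^2))
  mean_radius <- c_t$perimeter_um / (2 * pi)
  if (jump > mean_radius) {
    mp_stop("centroid jump exceeds the cell radius: tracking lost",
            "tracking_lost")
  }
  p1 <- c_t$points
  p2 <- c_next$points
  ss <- vapply(0:(n - 1), function(m) {
    idx <- ((seq_len(n) - 1 + m) %% n) + 1
    sum((p1 - p2[idx, , drop = FALSE])^2)
  }, numeric(1))
  offset <- which.min(ss) - 1L
  mapped <- ((seq_len(n) - 1 + offset) %% n) + 1
  disp <- p2[mapped, , drop = FALSE] - p1
  structure(list(offset = offset, displacement_um = disp,
                 mapped_index = mapped),
            class = "contour_correspondence")
}

#' Signed local membrane speed from a correspondence
#'
#' Speed at point i is the refined displacement projected on the outward
#' normal of frame t's contour, divided by the frame interval: positive for
#' protrusion, negative for retraction. Speeds are computed forward
#' (t to t+1) and assigned to frame t.
#'
#' @param corr a [register_contours()] result.
#' @param c_t the frame-t contour used in the registration.
#' @param frame_interval_s frame interval.
#' @return Numeric vector of speeds (um/s), one per contour point.
#' @export
local_speed <- function(corr, c_t, frame_interval_s) {
  nrm <- contour_normals(c_t)
  (corr$displacement_um[, 1] * nrm[, 1] +
     corr$displacement_um[, 2] * nrm[, 2]) / frame_interval_s
}

#' Per-point speed map across a movie
#'
#' Registers consecutive contours and stacks per-point signed normal
#' speeds.
#'
#' @param contours list of `cell_contour` (one per frame).
#' @param frame_interval_s frame interval.
#' @return List with `speed` (matrix points x (frames-1)),
#'   `correspondences` (list of [register_contours()] results).
#' @export
compute_speed_map <- function(contours, frame_interval_s) {
  nf <- length(contours)
  if (nf < 2) mp_stop("need at least 2 frames", "invalid_parameter")
  corrs <- vector("list", nf - 1)
  sp <- matrix(0, contours[[1]]$n_points, nf - 1)
  for (t in seq_len(nf - 1)) {
    corrs[[t]] <- register_contours(contours[[t]], contours[[t + 1]])
    sp[, t] <- local_speed(corrs[[t]], contours[[t]], frame_interval_s)
  }
  list(speed = sp, correspondences = corrs)
}

#' Pooled speed-versus-intensity joint histogram
#'
#' Pools per-point signed membrane speed against the normalized membrane
#' intensity of the chosen channel over all frame pairs, mirroring the
#' positive correlation between local expansion and actin-nucleator
#' recruitment.
#'
#' @param speed_map a [compute_speed_map()] result.
#' @param profiles nested list `profiles[[frame]][[channel]]` of
#'   [sample_membrane()] results with normalization.
#' @param channel channel name.
#' @param bins histogram bins.
#' @return A [joint_histogram()]; `undefined` is set when the cell does not
#'   move at all.
#' @export
speed_intensity_analysis <- function(speed_map, profiles, channel,
                                     bins = 32) {
  nf1 <- ncol(speed_map$speed)
  sp <- as.vector(speed_map$speed)
  intens <- unlist(lapply(seq_len(nf1), function(t) {
    p <- profiles[[t]][[channel]]
    if (is.null(p$normalized)) p$raw else p$normalized
  }))
  joint_histogram(sp, intens, bins = bins)
}

#' Membrane kymograph aligned by contour correspondence
#'
#' Column t holds the membrane profile of frame t with rows index-aligned
#' by composing the global circular offsets of the correspondences, so a
#' material membrane point stays on (approximately) one row. Alignment only
#' permutes rows, so each column's sum equals the corresponding profile's
#' sum.
#'
#' @param profiles nested list `profiles[[frame]][[channel]]`.
#' @param correspondences list of [register_contours()] results
#'   (length frames - 1); NULL for no alignment (identity offsets).
#' @param channel channel name.
#' @param use normalized (`"normalized"`, default) or `"raw"` values.
#' @return Object of class `kymograph`: list with `matrix`
#'   (points x frames), `offsets` (cumulative row offset per frame),
#'   `axis` description.
#' @export
build_membrane_kymograph <- function(profiles, correspondences = NULL,
                                     channel,
                                     use = c("normalized", "raw")) {
  use <- match.arg(use)
  nf <- length(profiles)
  if (nf < 2) mp_stop("need at least 2 frames", "invalid_parameter")
  n <- profiles[[1]][[channel]]$n_points
  offsets <- integer(nf)
  if (!is.null(correspondences)) {
    for (t in 2:nf) {
      offsets[t] <- (offsets[t - 1] + correspondences[[t - 1]]$offset) %% n
    }
  }
  mat <- matrix(0, n, nf)
  for (t in seq_len(nf)) {
    p <- profiles[[t]][[channel]]
    v <- if (use == "normalized" && !is.null(p$normalized)) p$normalized else
      p$raw
    idx <- ((seq_len(n) - 1 + offsets[t]) %% n) + 1
    mat[, t] <- v[idx]
  }
  structure(list(matrix = mat, offsets = offsets,
                 axis = "rows: membrane points (frame-1 indexing); cols: frames",
                 channel = channel),
            class = "kymograph")
}

#' Edge-line kymograph through a tracked patch edge
#'
#' For each frame, intensity is sampled by bilinear interpolation along a
#' line of length `line_length_um` through the tracked edge point, directed
#' inward (into the cytosol); columns are concatenated over frames. A
#' closure frame, when given, is stored as an annotation. Lines leaving the
#' image are clamped at the border and flagged.
#'
#' @param stack a `frame_stack`.
#' @param channel channel name or index.
#' @param points_um matrix (frames x 2) of the tracked edge point (x, y).
#' @param dirs_um matrix (frames x 2) of unit inward directions.
#' @param frames frame indices to use (default all rows).
#' @param line_length_um line length.
#' @param step_um sampling step along the line (default half a pixel).
#' @param closure_frame optional annotated closure frame (column index
#'   within `frames`).
#' @return Object of class `kymograph` with `matrix`
#'   (line samples x frames), `step_um`, `closure_frame`, `clipped`.
#' @export
build_edge_kymograph <- function(stack, channel, points_um, dirs_um,
                                 frames = seq_len(nrow(points_um)),
                                 line_length_um, step_um = NULL,
                                 closure_frame = NULL) {
  px <- attr(stack, "pixel_size_um")
  if (is.null(step_um)) step_um <- px / 2
  s <- seq(0, line_length_um, by = step_um)
  mat <- matrix(0, length(s), length(frames))
  clipped <- FALSE
  for (k in seq_along(frames)) {
    f <- frames[k]
    img <- stack_frame(stack, f, channel)
    xs <- (points_um[k, 1] + s * dirs_um[k, 1]) / px
    ys <- (points_um[k, 2] + s * dirs_um[k, 2]) / px
    if (any(xs < 1 | xs > ncol(img) | ys < 1 | ys > nrow(img))) {
      clipped <- TRUE
    }
    mat[, k] <- bilinear_sample(img, xs, ys)
  }
  if (clipped) mp_warn("edge line clipped at the image border", "clipped")
  structure(list(matrix = mat, step_um = step_um,
                 closure_frame = closure_frame, clipped = clipped,
                 axis = "rows: distance along line (membrane -> cytosol); cols: frames"),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d x %d (%s)\n", nrow(x$matrix), ncol(x$matrix),
              x$axis))
  invisible(x)
}

#' Track called patches across frames and classify origins
#'
#' Links per-frame patch calls into lineages by greedy interval overlap
#' after aligning indices with the contour correspondences' circular
#' offsets. A new interval overlapping a live track that already has a
#' (larger-overlap) continuation is classified as a split daughter of that
#' track; an interval with no overlap starts a de-novo track. A track
#' missing for more than `gap_tolerance` consecutive frames is closed;
#' tracks alive at the end of the movie are censored.
#'
#' @param calls list of [call_patches()] results, one per frame.
#' @param correspondences list of [register_contours()] results
#'   (length frames - 1), or NULL for a static cell.
#' @param gap_tolerance frames a track may go uncalled and still continue.
#' @param min_overlap minimum shared indices to link (default 1).
#' @return Object of class `patch_tracks`: list with `tracks` (list of
#'   lineage records: `id`, `origin`, `parent`, `frames`, `intervals`
#'   (per-frame index sets), `end`), `summary` (list with `n_tracks`,
#'   `n_split`, `n_de_novo`, `split_fraction`).
#' @export
track_patches <- function(calls, correspondences = NULL, gap_tolerance = 1,
                          min_overlap = 1) {
  nf <- length(calls)
  if (nf == 0) {
    return(structure(list(tracks = list(),
                          summary = list(n_tracks = 0L, n_split = 0L,
                                         n_de_novo = 0L,
                                         split_fraction = NA_real_)),
                     class = "patch_tracks"))
  }
  n <- calls[[1]]$n_profile_points
  offs <- integer(nf)
  if (!is.null(correspondences)) {
    for (t in 2:nf) {
      offs[t] <- (offs[t - 1] + correspondences[[t - 1]]$offset) %% n
    }
  }
  # work in frame-1 ("material") index coordinates
  to_material <- function(idx, t) ((idx - 1 - offs[t]) %% n) + 1

  tracks <- list()
  active <- integer(0)  # indices into tracks
  next_id <- 1L
  for (t in seq_len(nf)) {
    iv <- calls[[t]]$intervals
    sets <- lapply(seq_len(nrow(iv)), function(i)
      to_material(circ_indices(iv$start_idx[i], iv$end_idx[i], n), t))
    unmatched <- seq_along(sets)
    # overlaps between active tracks' last sets and the new sets
    if (length(active) && length(sets)) {
      ov <- matrix(0L, length(active), length(sets))
      for (ai in seq_along(active)) {
        last_set <- tracks[[active[ai]]]$last_set
        for (si in seq_along(sets)) {
          ov[ai, si] <- length(intersect(last_set, sets[[si]]))
        }
      }
      # greedy assignment by descending overlap
      taken_a <- logical(length(active))
      taken_s <- logical(length(sets))
      repeat {
        m <- which.max(ov)
        if (!length(m) || ov[m] < min_overlap) break
        ai <- (m - 1) %% nrow(ov) + 1
        si <- (m - 1) %/% nrow(ov) + 1
        tid <- active[ai]
        tracks[[tid]]$frames <- c(tracks[[tid]]$frames, t)
        tracks[[tid]]$intervals[[length(tracks[[tid]]$intervals) + 1L]] <-
          sets[[si]]
        tracks[[tid]]$call_rows <- c(tracks[[tid]]$call_rows, si)
        tracks[[tid]]$last_set <- sets[[si]]
        tracks[[tid]]$missing <- 0L
        taken_a[ai] <- TRUE
        taken_s[si] <- TRUE
        ov[ai, ] <- -1L
        ov[, si] <- -1L
      }
      unmatched <- which(!taken_s)
      # unmatched active tracks accumulate missing frames
      for (ai in which(!taken_a)) {
        tid <- active[ai]
        tracks[[tid]]$missing <- tracks[[tid]]$missing + 1L
      }
    } else if (length(active)) {
      for (tid in active) tracks[[tid]]$missing <- tracks[[tid]]$missing + 1L
    }
    # retire tracks that have been gone too long
    if (length(active)) {
      drop <- vapply(active, function(tid)
        tracks[[tid]]$missing > gap_tolerance, logical(1))
      for (tid in active[drop]) tracks[[tid]]$end <- "closed"
      active <- active[!drop]
    }
    # new tracks from unmatched intervals; a track already present in the
    # first frame has an unobservable origin (no preceding frame) and is
    # labelled "initial", excluded from the split fraction
    for (si in unmatched) {
      parent <- NA_integer_
      origin <- if (t == 1L) "initial" else "de_novo"
      # overlap with the previous interval of a track that is still live
      # (matched in this frame) marks a split; a track that just vanished
      # cannot be a parent — its freed membrane hosts de-novo events.
      # The parent interval is dilated by two indices on each side: called
      # boundaries sit up to a point inside the true patch and the nascent
      # split gap itself spans a point or two, so a daughter carved at the
      # parent's edge may be separated from the parent's called interval
      # by up to two indices. Unrelated patches are kept much further
      # apart than this by the geometry of patch placement.
      for (tid in active) {
        prev_set <- tracks[[tid]]$prev_set
        if (is.null(prev_set) || tracks[[tid]]$missing != 0L) next
        # include the parent's current interval too: a parent that grew
        # this frame can carve the daughter beyond its previous extent
        par_set <- unique(c(prev_set, tracks[[tid]]$last_set))
        dil <- unique(c(par_set,
                        ((par_set - 2L) %% n) + 1L,
                        ((par_set - 3L) %% n) + 1L,
                        (par_set %% n) + 1L,
                        ((par_set + 1L) %% n) + 1L))
        if (length(intersect(dil, sets[[si]])) >= min_overlap) {
          origin <- "split"
          parent <- tracks[[tid]]$id
          break
        }
      }
      iv_row <- iv[si, ]
      tracks[[length(tracks) + 1L]] <-
        list(id = next_id, origin = origin, parent = parent,
             frames = t, intervals = list(sets[[si]]),
             call_rows = si,
             first_interval_raw = circ_indices(iv_row$start_idx,
                                               iv_row$end_idx, n),
             last_set = sets[[si]], prev_set = NULL, missing = 0L,
             end = "censored")
      active <- c(active, length(tracks))
      next_id <- next_id + 1L
    }
    # remember this frame's sets as "previous" for split detection
    for (tid in active) tracks[[tid]]$prev_set <- tracks[[tid]]$last_set
  }
  for (tid in seq_along(tracks)) {
    tracks[[tid]]$last_set <- NULL
    tracks[[tid]]$prev_set <- NULL
    tracks[[tid]]$missing <- NULL
  }
  origins <- vapply(tracks, `[[`, character(1), "origin")
  n_split <- sum(origins == "split")
  n_dn <- sum(origins == "de_novo")
  structure(list(
    tracks = tracks,
    summary = list(n_tracks = length(tracks), n_split = n_split,
                   n_de_novo = n_dn, n_initial = sum(origins == "initial"),
                   split_fraction = if (n_split + n_dn > 0)
                     n_split / (n_split + n_dn) else NA_real_)),
    class = "patch_tracks")
}

#' @export
print.patch_tracks <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<patch_tracks> %d track(s): %d split, %d de novo (split fraction %s)\n",
              s$n_tracks, s$n_split, s$n_de_novo,
              format(s$split_fraction, digits = 3)))
  invisible(x)
}

#' Compare recovered patch tracks with generator ground truth
#'
#' Matches each truth lineage to the recovered track whose first interval
#' overlaps the truth patch's contour indices near the truth birth frame,
#' then compares origin labels. Truth lineages born within `censor_tail`
#' frames of the movie end are excluded: a split daughter needs a few
#' frames for its gap to become resolvable, and a de-novo patch is born
#' below calling resolution, so origins of events at the very end of a
#' movie are unobservable (the same censoring applies to visual scoring of
#' real movies).
#'
#' @param tracks a [track_patches()] result.
#' @param truth the generator `ground_truth`.
#' @param contours per-frame `cell_contour` list.
#' @param birth_window allowed |recovered - truth| birth frame difference.
#' @param censor_tail truth births in the last `censor_tail` frames are
#'   excluded from scoring.
#' @return List with `table` (per scored truth lineage: truth origin,
#'   recovered origin, matched flag), `n_scored`, `n_matched`,
#'   `n_correct`, `recovered_split_fraction`, `truth_split_fraction`.
#' @export
evaluate_origin_recovery <- function(tracks, truth, contours,
                                     birth_window = 6, censor_tail = 6) {
  nf <- length(truth$frames)
  lin <- truth$lineages
  # score only origins observable in the window: born after frame 1 (a
  # frame-1 birth cannot be distinguished from a pre-existing patch) and
  # early enough for the patch to become resolvable before the movie ends
  scored <- lin[lin$origin %in% c("de_novo", "split") &
                  lin$birth_frame > 1 &
                  lin$birth_frame <= nf - censor_tail, , drop = FALSE]
  # candidate (truth lineage, track) pairs scored by first-interval overlap,
  # then assigned greedily so each track matches at most one truth lineage
  cands <- list()
  for (i in seq_len(nrow(scored))) {
    lid <- scored$lineage_id[i]
    bf <- scored$birth_frame[i]
    for (k in seq_along(tracks$tracks)) {
      tr <- tracks$tracks[[k]]
      f0 <- tr$frames[1]
      if (f0 < bf || f0 - bf > birth_window) next
      pat <- truth$frames[[min(f0, nf)]]$patches
      if (!any(pat$lineage_id == lid)) next
      tp <- truth_point_indices(truth, f0, contours[[f0]])
      tset <- tp[[as.character(lid)]]
      first_raw <- if (!is.null(tr$first_interval_raw))
        tr$first_interval_raw else tr$intervals[[1]]
      ov_own <- length(intersect(first_raw, tset))
      # a split divides the parent in two and the linker attributes the
      # parent's old track to the larger-overlap part, so the new track
      # may cover either side of the division; overlap through the
      # parent's indices is kept as a fallback score
      ov_par <- 0L
      pid <- scored$parent_id[i]
      if (!is.na(pid) && any(pat$lineage_id == pid)) {
        ov_par <- length(intersect(first_raw, tp[[as.character(pid)]]))
      }
      if (ov_own > 0 || ov_par > 0) {
        cands[[length(cands) + 1L]] <-
          data.frame(row = i, track = k, ov_own = ov_own, ov_par = ov_par)
      }
    }
  }
  match_track <- rep(NA_integer_, nrow(scored))
  if (length(cands)) {
    cd <- do.call(rbind, cands)
    used <- logical(length(tracks$tracks))
    greedy <- function(cd_sub, score) {
      cd_sub <- cd_sub[order(-score), , drop = FALSE]
      for (j in seq_len(nrow(cd_sub))) {
        if (is.na(match_track[cd_sub$row[j]]) && !used[cd_sub$track[j]]) {
          match_track[cd_sub$row[j]] <<- cd_sub$track[j]
          used[cd_sub$track[j]] <<- TRUE
        }
      }
    }
    # pass 1: direct overlap with the daughter's own indices
    own <- cd[cd$ov_own > 0, , drop = FALSE]
    if (nrow(own)) greedy(own, own$ov_own)
    # pass 2: unmatched split daughters may own the parent-side track
    par <- cd[cd$ov_par > 0, , drop = FALSE]
    if (nrow(par)) greedy(par, par$ov_par)
  }
  tab <- data.frame(
    lineage_id = scored$lineage_id,
    truth_origin = scored$origin,
    recovered_origin = vapply(match_track, function(k)
      if (is.na(k)) NA_character_ else tracks$tracks[[k]]$origin,
      character(1)),
    matched = !is.na(match_track),
    track_id = vapply(match_track, function(k)
      if (is.na(k)) NA_integer_ else tracks$tracks[[k]]$id, integer(1)))
  n_matched <- sum(tab$matched)
  n_correct <- sum(tab$matched & tab$truth_origin == tab$recovered_origin)
  list(table = tab, n_scored = nrow(tab), n_matched = n_matched,
       n_correct = n_correct,
       recovered_split_fraction = tracks$summary$split_fraction,
       truth_split_fraction =
         if (nrow(tab)) mean(tab$truth_origin == "split") else NA_real_)
}
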