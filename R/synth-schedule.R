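# Ground-truth patch schedule: births (de novo / split), growth, closure,
# and cell motion, all on the angular parameterization of the membrane.

# schedule constants (radians / frames); widths below optical scale at birth
.sched <- list(
  w0           = 3 * pi / 180,   # de-novo birth width (sub-resolution)
  growth_frames = 3,             # frames to reach target width
  min_target   = 10 * pi / 180,  # floor for sampled target widths
  min_gap      = 18 * pi / 180,  # enforced clearance when growing
  birth_margin = 28 * pi / 180,  # clearance for a de novo birth: min_gap +
                                 # min_target, so a newborn can always grow
                                 # to a resolvable width
  daughter_lo  = 0.30,           # daughter fraction of parent width
  daughter_hi  = 0.40,
  gap0         = 2 * pi / 180,   # parent/daughter gap at the split instant
  gap_max      = 14 * pi / 180,  # final gap after widening
  gap_rate     = 3 * pi / 180,   # gap widening per frame
  min_split_width = 40 * pi / 180, # parents narrower than this cannot split
  split_maturity = 4L            # min parent age (frames) before splitting
)

#' Generate a ground-truth patch schedule
#'
#' Simulates the birth, growth, splitting and closure of membrane patches on
#' a moving star-convex cell, frame by frame, under the given configuration.
#' Births are Poisson with rate `patch_birth_rate`; each birth is a split of
#' a live parent with probability `split_probability` (when an eligible
#' parent exists), otherwise de novo. A split carves a daughter subinterval
#' off one end of the parent and the gap between the two widens over the
#' following frames. De-novo patches appear at sub-resolution width and grow
#' to a normally distributed target width over a few frames. Lifetimes are
#' geometric with the configured mean; a patch still alive at the end of the
#' movie is censored rather than closed.
#'
#' The result is deterministic given `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return An object of class `ground_truth`: a list with elements
#'   `frames` (per frame: `centroid_um`, `radius_um`, `protrusion_phase`,
#'   and `patches`, a data frame with columns `lineage_id`, `theta_start`,
#'   `theta_end`, `width`, `origin`), `events` (data frame of birth and
#'   closure events with origins and parent ids), `lineages` (one row per
#'   lineage: birth/last frame, origin, parent, closed flag) and `config`.
#' @examples
#' gt <- make_patch_schedule(synth_config(n_frames = 10, seed = 2))
#' gt$lineages
#' @export
make_patch_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  cfg <- validate_synth_config(cfg)
  if (cfg$n_frames < 1 || cfg$patch_birth_rate < 0) {
    mp_stop("n_frames must be >= 1 and patch_birth_rate >= 0", "invalid_config")
  }
  with_seed(mp_substream(cfg$seed, "schedule"), make_schedule_impl(cfg))
}

make_schedule_impl <- function(cfg) {
  s <- .sched
  n <- cfg$n_frames
  # burn-in: run the birth/death process to steady state before frame 1 so
  # the movie opens on a cell already carrying patches (as a real recording
  # would); patches alive at frame 1 are labelled "pre_existing" since
  # their birth precedes the observation window
  burnin <- if (cfg$patch_birth_rate > 0) {
    min(120L, 2L * ceiling(cfg$patch_lifetime_frames_mean))
  } else 0L
  # live patch state
  live <- list()   # each: id, start, width, target, rate, birth, death, origin, parent
  intents <- list()  # queued birth intents (origin fixed at creation)
  next_id <- 1L
  events <- list()
  lineages <- list()
  frames <- vector("list", n)

  c0 <- cfg$image_size_px[c(2, 1)] * cfg$pixel_size_um / 2  # (x, y) um
  drift <- cfg$drift_speed_um_s * cfg$frame_interval_s *
    c(cos(cfg$drift_direction_rad), sin(cfg$drift_direction_rad))

  sample_target <- function() {
    max(s$min_target,
        (cfg$patch_width_deg_mean +
           cfg$patch_width_deg_sd * stats::rnorm(1)) * pi / 180)
  }
  # minimum lifetime of 4 frames (a cup that lives a single frame could
  # never be resolved by any observer); geometric tail preserves the mean
  sample_lifetime <- function() {
    p <- 1 / max(1, cfg$patch_lifetime_frames_mean - 3)
    4L + stats::rgeom(1, min(1, p))
  }

  # angular gap from end of interval a to start of interval b (ccw)
  gap_ccw <- function(end_a, start_b) wrap_angle(start_b - end_a)

  # membrane vacated by a closed patch is refractory for a few frames:
  # births there would be indistinguishable from a continuation of the
  # closed patch (for the tracker and for a human scorer alike)
  recent <- list()  # each: start, width, expiry
  overlaps_recent <- function(start, width, f) {
    for (rc in recent) {
      if (rc$expiry < f) next
      # circular interval overlap test
      d1 <- wrap_angle(start - rc$start)
      d2 <- wrap_angle(rc$start - start)
      if (d1 < rc$width || d2 < width) return(TRUE)
    }
    FALSE
  }

  for (f in seq.int(1L - burnin, n)) {
    # --- entering the observation window: relabel survivors ----------------
    if (f == 1L && burnin > 0 && length(live)) {
      for (i in seq_along(live)) {
        live[[i]]$origin <- "pre_existing"
        lineages[[live[[i]]$id]]$origin <- "pre_existing"
        lineages[[live[[i]]$id]]$birth_frame <- 1L
      }
    }
    # --- close patches whose lifetime has expired (death frame < f) ---------
    if (length(live)) {
      dead <- vapply(live, function(p) p$death < f, logical(1))
      for (p in live[dead]) {
        if (p$death >= 1L) {
          events[[length(events) + 1L]] <-
            data.frame(event = "closure", frame = p$death, lineage_id = p$id,
                       parent_id = NA_integer_, origin = p$origin)
        }
        lineages[[p$id]]$last_frame <- p$death
        lineages[[p$id]]$closed <- TRUE
        recent[[length(recent) + 1L]] <-
          list(start = p$start, width = p$width, expiry = f + 3L)
      }
      live <- live[!dead]
      recent <- Filter(function(rc) rc$expiry >= f, recent)
    }

    # --- grow / shrink toward targets, clamped to keep neighbours clear -----
    if (length(live)) {
      ord <- order(vapply(live, function(p) wrap_angle(p$start + p$width / 2),
                          numeric(1)))
      live <- live[ord]
      m <- length(live)
      for (i in seq_len(m)) {
        p <- live[[i]]
        delta <- p$target - p$width
        if (abs(delta) <= 1e-12 && !is.null(p$next_target) &&
            !is.na(p$next_target)) {
          # shrink phase done (split gap open): switch to regrowth
          live[[i]]$target <- p$next_target
          live[[i]]$rate <- max(s$gap_rate,
                                abs(p$next_target - p$width) /
                                  s$growth_frames)
          live[[i]]$next_target <- NA_real_
          p <- live[[i]]
          delta <- p$target - p$width
        }
        if (abs(delta) > 1e-12) {
          step <- sign(delta) * min(abs(delta), p$rate)
          if (step > 0) {
            # grow each side independently up to its own clearance; recently
            # vacated membrane counts as an obstacle too, so a growing patch
            # cannot invade it while it is refractory
            gap_rec_n <- gap_rec_p <- 2 * pi
            for (rc in recent) {
              if (rc$expiry < f) next
              gap_rec_n <- min(gap_rec_n,
                               gap_ccw(p$start + p$width, rc$start))
              gap_rec_p <- min(gap_rec_p,
                               gap_ccw(rc$start + rc$width, p$start))
            }
            if (m > 1) {
              nxt <- live[[if (i == m) 1L else i + 1L]]
              prv <- live[[if (i == 1L) m else i - 1L]]
              gap_n <- min(gap_ccw(p$start + p$width, nxt$start),
                           gap_rec_n + s$min_gap)
              gap_p <- min(gap_ccw(prv$start + prv$width, p$start),
                           gap_rec_p + s$min_gap)
              grow_ccw <- min(step / 2, max(0, gap_n - s$min_gap))
              grow_cw <- min(step / 2, max(0, gap_p - s$min_gap))
              # redistribute blocked growth to the free side
              spare <- step - grow_ccw - grow_cw
              grow_ccw <- min(grow_ccw + spare,
                              max(0, gap_n - s$min_gap))
              grow_cw <- min(grow_cw + max(0, step - grow_ccw - grow_cw),
                             max(0, gap_p - s$min_gap))
            } else {
              grow_ccw <- min(step / 2, gap_rec_n)
              grow_cw <- min(step / 2, gap_rec_p)
            }
            live[[i]]$start <- wrap_angle(p$start - grow_cw)
            live[[i]]$width <- p$width + grow_cw + grow_ccw
          } else if (!is.null(p$next_target) && !is.na(p$next_target)) {
            # split-parent shrink phase: retreat from the daughter side
            # (ccw end) only, so the split gap widens at the full rate
            live[[i]]$width <- p$width + step
          } else {
            live[[i]]$start <- wrap_angle(p$start - step / 2)
            live[[i]]$width <- p$width + step
          }
        }
      }
    }

    # --- births -------------------------------------------------------------
    # Each Poisson birth event creates an INTENT whose origin (split vs de
    # novo) is fixed by a coin flip at creation. An intent that cannot be
    # realized this frame (no eligible parent, no free membrane, refractory
    # target) stays queued and is retried on following frames, so the
    # realized origin fractions converge to split_probability regardless
    # of how often either type is transiently infeasible. Intents older
    # than 80 frames are abandoned (rare).
    realize_split <- function() {
      eligible <- which(vapply(live, function(p)
        p$width >= s$min_split_width && f >= p$birth + s$split_maturity &&
          p$death >= f + 5L &&  # a closing cup does not fragment
          (is.null(p$next_target) || is.na(p$next_target)),
        logical(1)))
      if (!length(eligible)) return(FALSE)
      # try eligible parents in random order; a parent whose carved
      # daughter would land on refractory membrane is passed over
      ord_el <- if (length(eligible) == 1) eligible else sample(eligible)
      frac <- stats::runif(1, s$daughter_lo, s$daughter_hi)
      pi_idx <- NA_integer_
      for (cand_idx in ord_el) {
        cand <- live[[cand_idx]]
        if (!overlaps_recent(wrap_angle(cand$start + cand$width -
                                          frac * cand$width),
                             frac * cand$width, f)) {
          pi_idx <- cand_idx
          break
        }
      }
      if (is.na(pi_idx)) return(FALSE)
      par <- live[[pi_idx]]
      dw <- frac * par$width
      # daughter occupies the counter-clockwise end of the parent interval;
      # the parent first shrinks away until the gap reaches gap_max, then
      # regrows toward a fresh sampled target (the daughter grows away
      # from the parent: the clearance clamp blocks the narrow split gap)
      d_start <- wrap_angle(par$start + par$width - dw)
      live[[pi_idx]]$width <<- par$width - dw - s$gap0
      live[[pi_idx]]$target <<- max(s$min_target,
                                    par$width - dw - s$gap_max)
      live[[pi_idx]]$rate <<- s$gap_rate
      live[[pi_idx]]$next_target <<- sample_target()
      d_target <- max(dw, sample_target())
      live[[length(live) + 1L]] <<-
        list(id = next_id, start = d_start, width = dw, target = d_target,
             rate = max(s$gap_rate, (d_target - dw) / s$growth_frames),
             birth = f, death = f + sample_lifetime() - 1L,
             origin = "split", parent = par$id, next_target = NA_real_)
      if (f >= 1L) {
        events[[length(events) + 1L]] <<-
          data.frame(event = "birth", frame = f, lineage_id = next_id,
                     parent_id = par$id, origin = "split")
      }
      lineages[[next_id]] <<- list(lineage_id = next_id, birth_frame = f,
                                   last_frame = NA_integer_,
                                   origin = "split", parent_id = par$id,
                                   closed = FALSE)
      next_id <<- next_id + 1L
      TRUE
    }
    realize_de_novo <- function() {
      half <- s$w0 / 2 + s$birth_margin
      placed <- FALSE
      for (try in 1:25) {
        cand <- stats::runif(1, 0, 2 * pi)
        clear <- TRUE
        for (p in live) {
          # distance from candidate centre to interval [start, start+width]
          d <- wrap_angle(cand - p$start)
          if (d < p$width + half || d > 2 * pi - half) {
            clear <- FALSE
            break
          }
        }
        if (clear && overlaps_recent(wrap_angle(cand - half), 2 * half, f)) {
          clear <- FALSE
        }
        if (clear) {
          placed <- TRUE
          break
        }
      }
      if (!placed) return(FALSE)
      target <- sample_target()
      live[[length(live) + 1L]] <<-
        list(id = next_id, start = wrap_angle(cand - s$w0 / 2),
             width = s$w0, target = target,
             rate = (target - s$w0) / s$growth_frames, birth = f,
             death = f + sample_lifetime() - 1L,
             origin = "de_novo", parent = NA_integer_,
             next_target = NA_real_)
      if (f >= 1L) {
        events[[length(events) + 1L]] <<-
          data.frame(event = "birth", frame = f, lineage_id = next_id,
                     parent_id = NA_integer_, origin = "de_novo")
      }
      lineages[[next_id]] <<- list(lineage_id = next_id, birth_frame = f,
                                   last_frame = NA_integer_,
                                   origin = "de_novo",
                                   parent_id = NA_integer_, closed = FALSE)
      next_id <<- next_id + 1L
      TRUE
    }
    n_births <- stats::rpois(1, cfg$patch_birth_rate)
    for (b in seq_len(n_births)) {
      intents[[length(intents) + 1L]] <-
        list(split = stats::runif(1) < cfg$split_probability, age = 0L)
    }
    if (length(intents)) {
      still <- list()
      for (it in intents) {
        done <- if (it$split) realize_split() else realize_de_novo()
        if (!done && it$age < 80L) {
          it$age <- it$age + 1L
          still[[length(still) + 1L]] <- it
        }
      }
      intents <- still
    }

    # --- record frame -------------------------------------------------------
    if (f < 1L) next
    pat <- if (length(live)) {
      data.frame(
        lineage_id = vapply(live, `[[`, integer(1), "id"),
        theta_start = vapply(live, function(p) wrap_angle(p$start), numeric(1)),
        theta_end = vapply(live, function(p) wrap_angle(p$start + p$width),
                           numeric(1)),
        width = vapply(live, `[[`, numeric(1), "width"),
        origin = vapply(live, `[[`, character(1), "origin")
      )
    } else {
      data.frame(lineage_id = integer(0), theta_start = numeric(0),
                 theta_end = numeric(0), width = numeric(0),
                 origin = character(0))
    }
    frames[[f]] <- list(
      centroid_um = c0 + (f - 1) * drift,
      radius_um = cfg$cell_radius_um +
        (f - 1) * cfg$radius_growth_um_s * cfg$frame_interval_s,
      protrusion_phase = 0.15 * (f - 1),
      patches = pat
    )
  }

  # censor survivors
  for (p in live) {
    lineages[[p$id]]$last_frame <- n
  }
  # drop lineages that never reached the observation window
  lineages <- Filter(function(l) !is.null(l) &&
                       (is.na(l$last_frame) || l$last_frame >= 1L),
                     lineages)
  lin <- if (length(lineages)) {
    do.call(rbind, lapply(lineages, function(l)
      data.frame(lineage_id = l$lineage_id, birth_frame = l$birth_frame,
                 last_frame = l$last_frame, origin = l$origin,
                 parent_id = l$parent_id, closed = l$closed)))
  } else {
    data.frame(lineage_id = integer(0), birth_frame = integer(0),
               last_frame = integer(0), origin = character(0),
               parent_id = integer(0), closed = logical(0))
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(event = character(0), frame = integer(0),
               lineage_id = integer(0), parent_id = integer(0),
               origin = character(0))
  structure(list(frames = frames, events = ev, lineages = lin, config = cfg),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  %d frames, %d lineages (%d split, %d de novo), %d closures\n",
              length(x$frames), nrow(x$lineages),
              sum(x$lineages$origin == "split"),
              sum(x$lineages$origin == "de_novo"),
              sum(x$lineages$closed)))
  invisible(x)
}

#' Realized fraction of split-origin births in a schedule
#' @param truth a `ground_truth`.
#' @return numeric fraction, or `NA` if there were no births.
#' @export
split_fraction_truth <- function(truth) {
  b <- truth$events[truth$events$event == "birth", ]
  if (nrow(b) == 0) return(NA_real_)
  mean(b$origin == "split")
}

#' Evaluate the cell radius function r(theta) for one frame
#'
#' @param truth a `ground_truth`.
#' @param frame frame index (1-based).
#' @param theta vector of angles (radians, ccw from +x at the centroid).
#' @return vector of radii in micrometres.
#' @export
truth_radius <- function(truth, frame, theta) {
  cfg <- truth$config
  fr <- truth$frames[[frame]]
  r <- rep(fr$radius_um, length(theta))
  if (cfg$protrusion_amp_um > 0) {
    if (cfg$protrusion_mode == "independent") {
      r <- r + cfg$protrusion_amp_um *
        cos(cfg$protrusion_freq * theta - fr$protrusion_phase)
    } else {
      # raised-cosine bump under each patch, scaled by its current width
      pat <- fr$patches
      for (i in seq_len(nrow(pat))) {
        w <- pat$width[i]
        amp <- cfg$protrusion_amp_um * min(1, w / (40 * pi / 180))
        rel <- wrap_angle(theta - pat$theta_start[i])
        inside <- rel < w
        r[inside] <- r[inside] +
          amp * 0.5 * (1 - cos(2 * pi * rel[inside] / w))
      }
    }
  }
  r
}

#' Rasterize ground-truth intervals into per-frame patch calls
#'
#' Converts the truth schedule's angular intervals into [call_patches()]-
#' style objects on an N-point circular grid (point i at angle
#' `(i-1) * 2*pi / n_points`), bypassing rendering and measurement. This is
#' the noise-free limit of the measurement chain and serves to exercise
#' tracking and origin classification at scale.
#'
#' @param truth a `ground_truth`.
#' @param n_points grid size (default 100).
#' @param min_patch_points intervals covering fewer grid points are
#'   dropped, as the calling stage would drop them.
#' @return List of `patch_call` objects, one per frame.
#' @export
truth_to_calls <- function(truth, n_points = 100, min_patch_points = 3) {
  theta_grid <- (seq_len(n_points) - 1) * 2 * pi / n_points
  spacing <- 2 * pi * truth$frames[[1]]$radius_um / n_points
  lapply(seq_along(truth$frames), function(f) {
    pat <- truth$frames[[f]]$patches
    ivs <- list()
    for (i in seq_len(nrow(pat))) {
      idx <- which(angle_in_arc(theta_grid, pat$theta_start[i],
                                pat$width[i]))
      if (length(idx) < min_patch_points) next
      # contiguous circular run: locate the start within the set
      if (length(idx) == n_points) {
        s <- 1L
      } else {
        gaps <- which(diff(idx) > 1)
        s <- if (length(gaps)) idx[gaps[1] + 1L] else idx[1]
      }
      e <- ((s - 1L + length(idx)) %% n_points) + 1L
      ivs[[length(ivs) + 1L]] <-
        data.frame(start_idx = s, end_idx = e,
                   center_idx = circ_center(s, e, n_points),
                   n_points = length(idx),
                   arc_length_um = length(idx) * spacing,
                   mean_norm_intensity = NA_real_,
                   peak_norm_intensity = NA_real_)
    }
    iv <- if (length(ivs)) do.call(rbind, ivs) else
      data.frame(start_idx = integer(0), end_idx = integer(0),
                 center_idx = integer(0), n_points = integer(0),
                 arc_length_um = numeric(0),
                 mean_norm_intensity = numeric(0),
                 peak_norm_intensity = numeric(0))
    structure(list(intervals = iv, threshold = NA_real_, k_sd = NA_real_,
                   n_profile_points = n_points, arc_spacing_um = spacing,
                   full_circle = FALSE),
              class = "patch_call")
  })
}

#' Map truth patch intervals of one frame to contour point indices
#'
#' Uses the angular position of each contour point around the contour
#' centroid to decide membership in each truth interval.
#'
#' @param truth a `ground_truth`.
#' @param frame frame index.
#' @param contour a [extract_contour()] result (or any list with `points`
#'   and `centroid_um`).
#' @return A list with one integer index vector per truth patch
#'   (named by lineage id), plus attribute `"all"` giving their union.
#' @export
truth_point_indices <- function(truth, frame, contour) {
  pat <- truth$frames[[frame]]$patches
  th <- wrap_angle(atan2(contour$points[, 2] - contour$centroid_um[2],
                         contour$points[, 1] - contour$centroid_um[1]))
  out <- lapply(seq_len(nrow(pat)), function(i) {
    which(angle_in_arc(th, pat$theta_start[i], pat$width[i]))
  })
  names(out) <- as.character(pat$lineage_id)
  attr(out, "all") <- sort(unique(unlist(out)))
  out
}
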