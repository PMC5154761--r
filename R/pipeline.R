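# End-to-end orchestration: segment -> contour -> profile -> call ->
# measure -> dynamics -> report, plus condition comparison.

#' Pipeline configuration
#'
#' Collects every stage parameter. In generate mode (`synth` given) the
#' movie and ground truth come from [make_cell_movie()]; otherwise
#' `input_movie` must point to a TIFF readable by [read_movie_tiff()].
#'
#' @param synth a [synth_config()] for generate mode, or NULL.
#' @param input_movie path to an input movie TIFF (ignored in generate
#'   mode).
#' @param patch_channel,ring_channel channel roles (names in the stack).
#' @param n_points contour points per frame.
#' @param band_width_um membrane sampling band.
#' @param k_sd patch threshold multiple of the cytosol SD.
#' @param min_patch_points minimum patch run length.
#' @param erosion_margin_um cytosol erosion margin.
#' @param half_width_points edge-profile window half width.
#' @param line_length_um edge-line kymograph length.
#' @param gap_tolerance track linking gap tolerance (frames).
#' @param smooth_sigma_um segmentation smoothing.
#' @param min_area_px minimum cell area.
#' @param call_threshold_fold optional fixed calling threshold as a
#'   multiple of the cytosol mean, replacing the mean + k_sd * SD rule
#'   (needed for noiseless renders, where the cytosol SD collapses to 0).
#' @param seed master seed (generate mode inherits it into `synth`).
#' @param out_dir output directory for artifact files, or NULL to skip
#'   writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            input_movie = NULL,
                            patch_channel = "patch",
                            ring_channel = "ring",
                            n_points = 100,
                            band_width_um = 1.6,
                            k_sd = 1,
                            min_patch_points = 3,
                            erosion_margin_um = 1.0,
                            half_width_points = 8,
                            line_length_um = 3,
                            gap_tolerance = 1,
                            smooth_sigma_um = 0.05,
                            min_area_px = 500,
                            call_threshold_fold = NULL,
                            seed = NULL,
                            out_dir = NULL) {
  if (!is.null(synth) && !is.null(seed)) synth$seed <- as.integer(seed)
  if (identical(patch_channel, ring_channel)) {
    mp_stop("patch_channel and ring_channel must differ", "invalid_config")
  }
  cfg <- list(synth = synth, input_movie = input_movie,
              patch_channel = patch_channel, ring_channel = ring_channel,
              n_points = n_points, band_width_um = band_width_um,
              k_sd = k_sd, min_patch_points = min_patch_points,
              erosion_margin_um = erosion_margin_um,
              half_width_points = half_width_points,
              line_length_um = line_length_um,
              gap_tolerance = gap_tolerance,
              smooth_sigma_um = smooth_sigma_um,
              min_area_px = min_area_px,
              call_threshold_fold = call_threshold_fold,
              seed = if (is.null(seed)) {
                if (!is.null(synth)) synth$seed else 1L
              } else {
                as.integer(seed)
              },
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes segmentation, contour extraction, cytosol statistics, membrane
#' profiling (both channel roles), patch calling on the patch channel,
#' centre/edge measurement of the ring channel (one observation per patch
#' lineage, at its median-width frame), patch size statistics, channel
#' correlation, contour registration, local speed, speed-versus-ring
#' correlation, a membrane kymograph, and patch lineage tracking, then
#' assembles a statistics report. Identical configuration and seed give a
#' byte-identical report.
#'
#' @param cfg a [pipeline_config()].
#' @return Object of class `pipeline_report` (see details in the fields):
#'   tables of per-stage results plus provenance (`config_hash`, `seed`,
#'   package `version`), the underlying per-frame objects in
#'   `$stages`, and the ground truth in `$truth` (generate mode only).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage_errors <- list()

  # --- input ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$synth)) {
    mv <- make_cell_movie(cfg$synth)
    stack <- mv$stack
    truth <- mv$truth
  } else {
    if (is.null(cfg$input_movie) || !file.exists(cfg$input_movie)) {
      mp_stop("input movie not readable and no generate mode configured",
              "invalid_config")
    }
    stack <- read_movie_tiff(cfg$input_movie)
  }
  chn <- attr(stack, "channel_names")
  for (role in c(cfg$patch_channel, cfg$ring_channel)) {
    if (!(role %in% chn)) {
      mp_stop(sprintf("channel role '%s' not present in the movie", role),
              "invalid_config")
    }
  }
  nf <- dim(stack)[4]
  px <- attr(stack, "pixel_size_um")
  dt <- attr(stack, "frame_interval_s")

  # --- segmentation, contours, cytosol stats, profiles ---------------------
  contours <- vector("list", nf)
  cyto <- vector("list", nf)
  profiles <- vector("list", nf)
  n_failed <- 0L
  for (f in seq_len(nf)) {
    ok <- tryCatch({
      img_patch <- stack_frame(stack, f, cfg$patch_channel)
      mask <- segment_cell(img_patch, px,
                           smooth_sigma_um = cfg$smooth_sigma_um,
                           min_area_px = cfg$min_area_px)
      ct <- extract_contour(mask, n_points = cfg$n_points)
      cs <- lapply(chn, function(ch)
        cytosol_stats(stack_frame(stack, f, ch), mask,
                      erosion_margin_um = cfg$erosion_margin_um))
      names(cs) <- chn
      pr <- lapply(chn, function(ch)
        sample_membrane(stack_frame(stack, f, ch), ct,
                        band_width_um = cfg$band_width_um,
                        cyto_mean = cs[[ch]]$mean))
      names(pr) <- chn
      contours[[f]] <- ct
      cyto[[f]] <- cs
      profiles[[f]] <- pr
      TRUE
    }, mp_error = function(e) {
      stage_errors[[length(stage_errors) + 1L]] <<-
        list(stage = "segmentation", frame = f, message = conditionMessage(e))
      FALSE
    })
    if (!ok) n_failed <- n_failed + 1L
  }
  if (n_failed > nf / 2) {
    mp_stop(sprintf("segmentation failed on %d of %d frames", n_failed, nf),
            "pipeline")
  }
  good <- which(!vapply(contours, is.null, logical(1)))
  contours <- contours[good]
  cyto <- cyto[good]
  profiles <- profiles[good]
  nf <- length(good)

  # --- patch calling -------------------------------------------------------
  calls <- lapply(seq_len(nf), function(f)
    call_patches(profiles[[f]][[cfg$patch_channel]],
                 cyto[[f]][[cfg$patch_channel]],
                 k_sd = cfg$k_sd, min_patch_points = cfg$min_patch_points,
                 threshold = if (is.null(cfg$call_threshold_fold)) NULL else
                   cfg$call_threshold_fold *
                     cyto[[f]][[cfg$patch_channel]]$mean))
  n_patches_per_frame <- vapply(calls, function(c) nrow(c$intervals),
                                numeric(1))

  # --- dynamics ------------------------------------------------------------
  speed_map <- NULL
  tracks <- NULL
  if (nf >= 2) {
    speed_map <- tryCatch(compute_speed_map(contours, dt),
                          mp_error = function(e) {
                            stage_errors[[length(stage_errors) + 1L]] <<-
                              list(stage = "dynamics",
                                   message = conditionMessage(e))
                            NULL
                          })
    tracks <- track_patches(calls,
                            if (is.null(speed_map)) NULL else
                              speed_map$correspondences,
                            gap_tolerance = cfg$gap_tolerance)
  }

  # --- centre/edge: one observation per lineage at its widest frame --------
  ce <- pipeline_center_edge(tracks, calls, profiles, cyto,
                             cfg$ring_channel, nf)

  # --- sizes, correlations -------------------------------------------------
  sizes <- tryCatch(patch_size_stats(calls),
                    mp_error = function(e) NULL)
  norm_patch <- unlist(lapply(profiles, function(p)
    p[[cfg$patch_channel]]$normalized))
  norm_ring <- unlist(lapply(profiles, function(p)
    p[[cfg$ring_channel]]$normalized))
  chan_hist <- tryCatch(joint_histogram(norm_patch, norm_ring),
                        mp_error = function(e) NULL)
  speed_hist <- if (!is.null(speed_map)) {
    tryCatch(speed_intensity_analysis(speed_map, profiles,
                                      cfg$ring_channel),
             mp_error = function(e) NULL)
  }
  kymo <- if (nf >= 2) {
    build_membrane_kymograph(profiles,
                             if (is.null(speed_map)) NULL else
                               speed_map$correspondences,
                             channel = cfg$patch_channel)
  }

  # --- tests ---------------------------------------------------------------
  edge_test <- center_test <- NULL
  if (!is.null(ce) && nrow(ce) >= 3) {
    edge_test <- compare_groups(ce$I_edge, ce$I_cytosol, paired = TRUE)
    center_test <- compare_groups(ce$I_center, ce$I_cytosol, paired = TRUE)
  }

  report <- structure(list(
    n_frames = nf,
    n_frames_failed = n_failed,
    threshold_rule = sprintf("cytosol mean + %g*SD", cfg$k_sd),
    patch_counts = list(per_frame = n_patches_per_frame,
                        mean_per_frame = mean(n_patches_per_frame)),
    patch_sizes = if (!is.null(sizes)) {
      list(sizes_um = sizes$sizes_um, mean = sizes$mean, sd = sizes$sd,
           n = sizes$n)
    } else {
      list(sizes_um = numeric(0), mean = NA_real_, sd = NA_real_, n = 0L)
    },
    patch_intensity = list(
      mean_norm = if (!is.null(sizes)) {
        mean(unlist(lapply(calls, function(c)
          c$intervals$mean_norm_intensity)))
      } else NA_real_),
    center_edge = list(
      n = if (is.null(ce)) 0L else nrow(ce),
      edge_mean = if (is.null(ce) || !nrow(ce)) NA_real_ else mean(ce$I_edge),
      edge_sd = if (is.null(ce) || !nrow(ce)) NA_real_ else stats::sd(ce$I_edge),
      center_mean = if (is.null(ce) || !nrow(ce)) NA_real_ else
        mean(ce$I_center),
      center_sd = if (is.null(ce) || !nrow(ce)) NA_real_ else
        stats::sd(ce$I_center),
      edge_vs_cytosol_p = if (is.null(edge_test)) NA_real_ else
        edge_test$p_value,
      center_vs_cytosol_p = if (is.null(center_test)) NA_real_ else
        center_test$p_value,
      test = "paired two-tailed t-test"),
    correlations = list(
      patch_vs_ring_r = if (is.null(chan_hist)) NA_real_ else
        chan_hist$pearson_r,
      speed_vs_ring_r = if (is.null(speed_hist)) NA_real_ else
        speed_hist$pearson_r,
      speed_undefined = if (is.null(speed_hist)) TRUE else
        speed_hist$undefined),
    tracking = if (is.null(tracks)) NULL else tracks$summary,
    stage_errors = stage_errors,
    provenance = list(config_hash = mp_hash(cfg), seed = cfg$seed,
                      version = as.character(utils::packageVersion("membranepatch")))
  ), class = "pipeline_report")

  report$stages <- list(contours = contours, cyto = cyto,
                        profiles = profiles, calls = calls,
                        speed_map = speed_map, tracks = tracks,
                        kymograph = kymo, center_edge = ce, stack = stack)
  report$truth <- truth

  if (!is.null(cfg$out_dir)) write_report_artifacts(report, cfg)
  report
}

# one centre/edge observation per lineage, taken at its widest frame
pipeline_center_edge <- function(tracks, calls, profiles, cyto,
                                 ring_channel, nf) {
  if (is.null(tracks) || !length(tracks$tracks)) {
    # static or two-frame movies: fall back to per-frame patches
    rows <- lapply(seq_len(nf), function(f) {
      suppressWarnings(
        measure_center_edge(calls[[f]], profiles[[f]][[ring_channel]],
                            cyto[[f]][[ring_channel]]))
    })
    out <- do.call(rbind, rows)
    return(out)
  }
  rows <- lapply(tracks$tracks, function(tr) {
    widths <- vapply(tr$intervals, length, numeric(1))
    # median-width frame: robust against transiently merged intervals
    # (whose midpoints fall between true patches) and against newborn
    # sub-resolution frames
    j <- order(widths)[ceiling(length(widths) / 2)]
    f <- tr$frames[j]
    m <- suppressWarnings(
      measure_center_edge(calls[[f]], profiles[[f]][[ring_channel]],
                          cyto[[f]][[ring_channel]]))
    if (!nrow(m)) return(NULL)
    m[m$patch == tr$call_rows[j], , drop = FALSE]
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) do.call(rbind, rows) else NULL
}

write_report_artifacts <- function(report, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- report$stages
  write_contours_csv(st$contours, file.path(cfg$out_dir, "contours.csv"))
  write_profiles_csv(st$profiles, file.path(cfg$out_dir, "profiles.csv"))
  write_calls_csv(st$calls, file.path(cfg$out_dir, "calls.csv"))
  if (!is.null(st$speed_map)) {
    utils::write.table(st$speed_map$speed,
                       file.path(cfg$out_dir, "speeds.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(st$kymograph)) {
    write_kymograph(st$kymograph,
                    file.path(cfg$out_dir, "membrane_kymograph.csv"),
                    file.path(cfg$out_dir, "membrane_kymograph.tif"))
  }
  if (!is.null(st$tracks)) {
    jsonlite::write_json(
      lapply(st$tracks$tracks, function(tr)
        list(id = tr$id, origin = tr$origin, parent = tr$parent,
             frames = tr$frames,
             intervals = lapply(tr$intervals, identity), end = tr$end)),
      file.path(cfg$out_dir, "tracks.json"), auto_unbox = TRUE, digits = NA)
  }
  write_report_json(report, file.path(cfg$out_dir, "report.json"))
  invisible(NULL)
}

#' Serialize a pipeline report to JSON
#'
#' Deterministic (full precision, no timestamps): identical configuration
#' and seed produce byte-identical files.
#'
#' @param report a `pipeline_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  x$stages <- NULL
  x$truth <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  %d frames (%d failed), %s\n", x$n_frames,
              x$n_frames_failed, x$threshold_rule))
  cat(sprintf("  patches: %.2f per frame, %d sized (mean %.3g um)\n",
              x$patch_counts$mean_per_frame, x$patch_sizes$n,
              x$patch_sizes$mean))
  cat(sprintf("  centre/edge (n=%d): edge %.3g (p=%.3g), centre %.3g (p=%.3g) vs cytosol 1\n",
              x$center_edge$n, x$center_edge$edge_mean,
              x$center_edge$edge_vs_cytosol_p, x$center_edge$center_mean,
              x$center_edge$center_vs_cytosol_p))
  cat(sprintf("  correlations: patch~ring r=%.3g, speed~ring r=%.3g\n",
              x$correlations$patch_vs_ring_r,
              x$correlations$speed_vs_ring_r))
  if (!is.null(x$tracking)) {
    cat(sprintf("  tracking: %d lineages, split fraction %.3g\n",
                x$tracking$n_tracks, x$tracking$split_fraction))
  }
  invisible(x)
}

#' Summarize complete patch lifetimes on the membrane kymograph
#'
#' For every de-novo truth lineage that is born and closes inside the
#' movie (generate mode only), locates the elevated region of the
#' patch-channel membrane kymograph on the rows belonging exclusively to
#' that lineage, and samples the ring channel along an inward edge line
#' through the patch's flank (via [build_edge_kymograph()]) over the
#' lifetime. Lineages whose membrane rows are reused by other patches at
#' any time are skipped — their kymograph signature cannot be attributed
#' unambiguously.
#'
#' @param report a [run_pipeline()] result from generate mode (with
#'   `$truth`).
#' @param elevated normalized intensity above which a kymograph row counts
#'   as occupied (default 1.5: above baseline wobble, low enough to catch a nascent sub-resolution patch).
#' @param line_length_um edge-line length for the ring-channel check.
#' @return Data frame with one row per usable event: `lineage_id`,
#'   `birth`, `close` (truth frames), `span_lo`, `span_hi` (elevated
#'   kymograph columns), `edge_min_fold` (minimum over the lifetime of the
#'   membrane-proximal ring signal on the edge line, in cytosol units), or
#'   NULL when no event is usable.
#' @export
kymograph_event_summary <- function(report, elevated = 1.5,
                                    line_length_um = 2) {
  truth <- report$truth
  if (is.null(truth)) mp_stop("report lacks ground truth", "invalid_config")
  st <- report$stages
  nf <- length(st$profiles)
  n <- st$profiles[[1]][[1]]$n_points
  kym <- build_membrane_kymograph(
    st$profiles,
    if (is.null(st$speed_map)) NULL else st$speed_map$correspondences,
    channel = "patch")
  lin <- truth$lineages
  # usable events: de novo, fully inside the movie, and never a split
  # parent (a parent's retreat from its daughter vacates rows before
  # closure, blurring the lifetime signature)
  parents <- unique(lin$parent_id[!is.na(lin$parent_id)])
  cand <- lin[lin$origin == "de_novo" & lin$closed &
                lin$birth_frame > 2 & lin$last_frame < nf &
                !(lin$lineage_id %in% parents), , drop = FALSE]
  point_angles <- function(f) {
    ct <- st$contours[[f]]
    wrap_angle(atan2(ct$points[, 2] - ct$centroid_um[2],
                     ct$points[, 1] - ct$centroid_um[1]))
  }
  out <- list()
  for (i in seq_len(nrow(cand))) {
    lid <- cand$lineage_id[i]
    b <- cand$birth_frame[i]
    cc <- cand$last_frame[i]
    fmid <- floor((b + cc) / 2)
    tp <- truth_point_indices(truth, fmid, st$contours[[fmid]])
    own <- ((tp[[as.character(lid)]] - 1 + kym$offsets[fmid]) %% n) + 1
    other <- c()
    for (f in seq_len(nf)) {
      tpf <- truth_point_indices(truth, f, st$contours[[f]])
      for (nm in names(tpf)) {
        if (nm != as.character(lid)) {
          other <- c(other, ((tpf[[nm]] - 1 + kym$offsets[f]) %% n) + 1)
        }
      }
    }
    # dilate other patches' rows by the measurement smear (~2 rows)
    other <- unique(other)
    other <- unique(c(other, ((other - 2L) %% n) + 1L,
                      ((other - 3L) %% n) + 1L,
                      (other %% n) + 1L, ((other + 1L) %% n) + 1L))
    if (length(setdiff(own, other)) < 2) next
    # per-column elevation on the lineage's own rows of that frame (the
    # first-visible frame donates rows for columns outside the lifetime,
    # where the check is about absence of signal); rows claimed by other
    # patches are excluded throughout
    f_early <- min(b + 1, cc)
    own_rows_at <- function(f) {
      tpf <- truth_point_indices(truth, f, st$contours[[f]])
      idx <- tpf[[as.character(lid)]]
      if (is.null(idx) || !length(idx)) return(integer(0))
      setdiff(((idx - 1 + kym$offsets[f]) %% n) + 1, other)
    }
    donor <- own_rows_at(f_early)
    # the birth region itself must be mostly uncontested, or onset
    # detection is left with boundary rows only
    if (length(donor) < 4) next
    elev <- logical(nf)
    usable <- TRUE
    for (f in seq_len(nf)) {
      rows_f <- if (f >= f_early && f <= cc) own_rows_at(f) else donor
      if (!length(rows_f)) {
        if (f >= f_early && f <= cc) usable <- FALSE
        rows_f <- donor
      }
      elev[f] <- any(kym$matrix[rows_f, f] > elevated)
    }
    if (!usable || !any(elev)) next
    # the elevated region of THIS event is the contiguous run covering its
    # lifetime midpoint (stray smear from distant columns is not bridged)
    r_elev <- rle(elev)
    ends <- cumsum(r_elev$lengths)
    starts <- ends - r_elev$lengths + 1
    runs <- which(r_elev$values)
    hit <- runs[starts[runs] <= fmid & ends[runs] >= fmid]
    if (!length(hit)) {
      hit <- runs[which.min(pmin(abs(starts[runs] - fmid),
                                 abs(ends[runs] - fmid)))]
    }
    span <- c(starts[hit[1]], ends[hit[1]])
    # ring-channel edge line: inward through the flank just outside the
    # patch's start boundary, tracked frame by frame as the boundary moves
    frames <- b:cc
    pts <- matrix(0, length(frames), 2)
    dirs <- matrix(0, length(frames), 2)
    for (k in seq_along(frames)) {
      f <- frames[k]
      pat_f <- truth$frames[[f]]$patches
      th_flank <- wrap_angle(
        pat_f$theta_start[pat_f$lineage_id == lid][1] - 4 * pi / 180)
      ct <- st$contours[[f]]
      idx <- which.min(abs(wrap_angle(point_angles(f) - th_flank + pi) -
                             pi))
      pts[k, ] <- ct$points[idx, ]
      dirs[k, ] <- -contour_normals(ct)[idx, ]
    }
    ek <- suppressWarnings(
      build_edge_kymograph(st$stack, "ring", pts, dirs, frames = frames,
                           line_length_um = line_length_um,
                           closure_frame = length(frames)))
    prox <- seq_len(max(2, ceiling(0.6 / ek$step_um)))
    cyto_ring <- vapply(frames, function(f) st$cyto[[f]][["ring"]]$mean,
                        numeric(1))
    edge_min <- min(apply(ek$matrix[prox, , drop = FALSE], 2, max) /
                      cyto_ring)
    out[[length(out) + 1L]] <- data.frame(
      lineage_id = lid, birth = b, close = cc,
      span_lo = span[1], span_hi = span[2], edge_min_fold = edge_min)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Compare two pipeline reports (two conditions)
#'
#' Welch two-tailed tests on patch sizes, patch counts per frame and mean
#' patch intensity between two runs, with Holm correction across the
#' family, plus effect sizes.
#'
#' @param report_a,report_b `pipeline_report`s.
#' @return Data frame with one row per metric: means, n, test statistic,
#'   raw and Holm-adjusted p-values, effect size. Metrics with undefined
#'   tests (degenerate input) carry `NA` p-values.
#' @export
compare_conditions <- function(report_a, report_b) {
  metric <- function(name, a, b) {
    if (length(a) < 2 || length(b) < 2) {
      mp_stop(sprintf("metric '%s' missing or insufficient in a report",
                      name), "comparison")
    }
    res <- tryCatch(compare_groups(a, b, paired = FALSE),
                    mp_error = function(e) NULL)
    data.frame(metric = name, mean_a = mean(a), mean_b = mean(b),
               n_a = length(a), n_b = length(b),
               statistic = if (is.null(res)) NA_real_ else res$statistic,
               p_value = if (is.null(res)) NA_real_ else res$p_value,
               effect_size = if (is.null(res)) NA_real_ else
                 res$effect_size)
  }
  rows <- rbind(
    metric("patch_size_um", report_a$patch_sizes$sizes_um,
           report_b$patch_sizes$sizes_um),
    metric("patches_per_frame", report_a$patch_counts$per_frame,
           report_b$patch_counts$per_frame),
    metric("patch_mean_norm_intensity",
           patch_intensities(report_a), patch_intensities(report_b))
  )
  rows$p_holm <- stats::p.adjust(rows$p_value, method = "holm")
  rows
}

patch_intensities <- function(report) {
  unlist(lapply(report$stages$calls, function(c)
    c$intervals$mean_norm_intensity))
}
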