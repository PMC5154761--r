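# Movie / ground-truth / table I-O. Movies are multi-page TIFF, pages
# ordered frame-major channel-minor, with calibration in a JSON sidecar.

#' Write a frame stack as a multi-page TIFF with a metadata sidecar
#'
#' Pages are ordered frame-major, channel-minor (frame 1 channel 1, frame 1
#' channel 2, frame 2 channel 1, ...). Intensities are stored as 32-bit
#' values scaled into `[0, 1]`; the scale factor and the physical
#' calibration go into `<path>.json`.
#'
#' @param stack a `frame_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(stack, path) {
  d <- dim(stack)
  scale <- max(stack, 1e-9)
  pages <- list()
  for (f in seq_len(d[4])) {
    for (k in seq_len(d[3])) {
      pages[[length(pages) + 1L]] <- stack[, , k, f] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(
    pixel_size_um = attr(stack, "pixel_size_um"),
    frame_interval_s = attr(stack, "frame_interval_s"),
    channel_names = attr(stack, "channel_names"),
    n_frames = d[4], n_channels = d[3], intensity_scale = scale
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' Calibration is taken from the JSON sidecar when present; otherwise it
#' must be supplied.
#'
#' @param path TIFF path.
#' @param pixel_size_um,frame_interval_s,channel_names calibration overrides
#'   (required when no sidecar exists).
#' @param n_channels number of channels (overrides sidecar).
#' @return A `frame_stack`.
#' @export
read_movie_tiff <- function(path, pixel_size_um = NULL,
                            frame_interval_s = NULL, channel_names = NULL,
                            n_channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  nch <- n_channels %||% meta$n_channels %||% 1L
  nch <- as.integer(nch)
  scale <- as.numeric(meta$intensity_scale %||% 1)
  nfr <- length(pages) / nch
  if (nfr != floor(nfr)) {
    mp_stop("page count is not a multiple of the channel count", "io")
  }
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  arr <- array(0, dim = c(nr, nc, nch, nfr))
  i <- 1L
  for (f in seq_len(nfr)) {
    for (k in seq_len(nch)) {
      arr[, , k, f] <- pages[[i]] * scale
      i <- i + 1L
    }
  }
  structure(arr, class = c("frame_stack", "array"),
            pixel_size_um = pixel_size_um %||%
              as.numeric(meta$pixel_size_um %||% 1),
            frame_interval_s = frame_interval_s %||%
              as.numeric(meta$frame_interval_s %||% 1),
            channel_names = channel_names %||%
              as.character(unlist(meta$channel_names %||%
                                    paste0("ch", seq_len(nch)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read ground truth as a JSON event and interval file
#'
#' @param truth a `ground_truth`.
#' @param path JSON path.
#' @return `write_ground_truth_json()` returns `path` invisibly;
#'   `read_ground_truth_json()` returns the `ground_truth` (without the
#'   original config object unless it was stored).
#' @export
write_ground_truth_json <- function(truth, path) {
  x <- list(
    n_frames = length(truth$frames),
    frames = lapply(truth$frames, function(fr) list(
      centroid_um = fr$centroid_um,
      radius_um = fr$radius_um,
      protrusion_phase = fr$protrusion_phase,
      patches = fr$patches
    )),
    events = truth$events,
    lineages = truth$lineages
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  empty_pat <- data.frame(lineage_id = integer(0), theta_start = numeric(0),
                          theta_end = numeric(0), width = numeric(0),
                          origin = character(0))
  cols_df <- function(cols, proto) {
    if (is.null(cols) || !length(cols[[1]])) return(proto)
    as.data.frame(lapply(cols, function(v)
      unlist(lapply(v, function(e) if (is.null(e)) NA else e))))
  }
  frames <- lapply(seq_len(x$n_frames), function(i) {
    fr <- x$frames[[i]]
    list(centroid_um = unlist(fr$centroid_um),
         radius_um = fr$radius_um,
         protrusion_phase = fr$protrusion_phase,
         patches = cols_df(fr$patches, empty_pat))
  })
  empty_ev <- data.frame(event = character(0), frame = integer(0),
                         lineage_id = integer(0), parent_id = integer(0),
                         origin = character(0))
  empty_lin <- data.frame(lineage_id = integer(0), birth_frame = integer(0),
                          last_frame = integer(0), origin = character(0),
                          parent_id = integer(0), closed = logical(0))
  structure(list(frames = frames,
                 events = cols_df(x$events, empty_ev),
                 lineages = cols_df(x$lineages, empty_lin),
                 config = NULL),
            class = "ground_truth")
}

#' Write a kymograph as CSV (and optionally TIFF)
#'
#' @param kymo a `kymograph`.
#' @param csv_path CSV output path (matrix, rows = positions).
#' @param tiff_path optional TIFF output path.
#' @return `csv_path`, invisibly.
#' @export
write_kymograph <- function(kymo, csv_path, tiff_path = NULL) {
  utils::write.table(unclass(kymo$matrix), csv_path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(tiff_path)) {
    m <- kymo$matrix
    tiff::writeTIFF(m / max(m, 1e-9), tiff_path, bits.per.sample = 32L,
                    compression = "none")
  }
  invisible(csv_path)
}
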