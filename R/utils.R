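# Internal helpers: conditions, seeded substreams, circular index arithmetic,
# bilinear sampling. Shared by all stages.

#' Signal a classed package error
#'
#' All errors raised by the package carry a subclass of the form
#' `mp_error_<what>` so callers can branch on failure mode.
#'
#' @param message error message.
#' @param class error subclass (without the `mp_error_` prefix).
#' @param call. passed to `stop()`.
#' @keywords internal
mp_stop <- function(message, class, call. = FALSE) {
  cond <- structure(
    class = c(paste0("mp_error_", class), "mp_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

mp_warn <- function(message, class) {
  cond <- structure(
    class = c(paste0("mp_warning_", class), "mp_warning", "warning", "condition"),
    list(message = message, call = NULL)
  )
  warning(cond)
}

#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in the package flows from a single user seed; each stage
#' draws from its own substream so stages can be re-run independently.
#' The derived value stays below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return integer sub-seed.
#' @keywords internal
mp_substream <- function(seed, stage) {
  # small string hash (djb2) folded with the master seed
  h <- 5381
  for (ch in utf8ToInt(stage)) h <- (h * 33 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483629)
}

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# --- circular index arithmetic (1-based, half-open intervals [start, end)) ---

#' Indices covered by a circular half-open interval
#'
#' @param start,end 1-based indices; the interval covers `start`,
#'   `start+1`, ..., `end-1`, wrapping past `n` back to 1. `end == start`
#'   denotes the full circle only when `full = TRUE` is recorded upstream;
#'   here it returns the full circle.
#' @param n number of points on the circle.
#' @keywords internal
circ_indices <- function(start, end, n) {
  len <- (end - start) %% n
  if (len == 0) len <- n
  ((start - 1 + seq_len(len) - 1) %% n) + 1
}

#' Circular interval length in points
#' @keywords internal
circ_length <- function(start, end, n) {
  len <- (end - start) %% n
  if (len == 0) n else len
}

#' Circular midpoint of a half-open interval (ties to the lower index)
#' @keywords internal
circ_center <- function(start, end, n) {
  len <- circ_length(start, end, n)
  # for even lengths the midpoint is ambiguous; take the lower index
  ((start - 1 + ceiling(len / 2) - 1) %% n) + 1
}

#' Wrap angles into [0, 2*pi)
#' @keywords internal
wrap_angle <- function(theta) theta %% (2 * pi)

#' Is angle theta inside the circular arc [start, start + width)?
#' @keywords internal
angle_in_arc <- function(theta, start, width) {
  wrap_angle(theta - start) < width
}

# --- bilinear image sampling -------------------------------------------------

#' Bilinear interpolation of an image at sub-pixel positions
#'
#' Image is a matrix indexed `[row, col]`; positions are in pixel units with
#' the centre of pixel `[r, c]` at `(x = c, y = r)`. Positions outside the
#' image are clamped to the border (callers flag clipping themselves).
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of positions (columns, rows).
#' @return numeric vector of interpolated values.
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + (x0 - 1) * nr
  v00 <- img[i00]; v10 <- img[i00 + nr]
  v01 <- img[i00 + 1]; v11 <- img[i00 + nr + 1]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

#' Shoelace signed area of a closed polygon
#' @param x,y coordinates of the vertices (not repeated at the end).
#' @keywords internal
shoelace_area <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Tiny deterministic hash of an R object (FNV-1a over its deparse)
#' @keywords internal
mp_hash <- function(obj) {
  s <- paste(deparse(obj), collapse = "\n")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), ch)
    h <- (as.numeric(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}
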