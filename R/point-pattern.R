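#' Create a planar point pattern of associated points
#'
#' Each particle of the population is represented by one associated point
#' (e.g. the centre of the smallest rectangle enclosing a head in an aerial
#' picture).  Coordinates follow the mathematical convention: y increases
#' upwards, so "bottom to top" within a stripe is unambiguous.  Raster
#' coordinates (y down) must be flipped at input time; see `flip_y` in
#' [read_points_csv()].
#'
#' @param xy n x 2 matrix or data frame of (x, y) coordinates in pixels.
#' @param bounds axis-aligned region containing all points, either
#'   `c(width, height)` (origin at (0, 0)) or `c(xmin, ymin, xmax, ymax)`.
#'   Defaults to the tight bounding box of the points.
#' @param true_n optional known population size (synthetic patterns); must
#'   equal the number of points when given.
#' @return An object of class `point_pattern` with fields `xy`, `bounds`,
#'   `n` and `true_n`.
#' @export
point_pattern <- function(xy, bounds = NULL, true_n = NULL) {
  xy <- if (length(xy) == 0L) {
    matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("x", "y")))
  } else {
    as_xy(xy)
  }
  if (is.null(bounds)) {
    if (nrow(xy) == 0L) stop("bounds are required for an empty pattern")
    bounds <- c(min(xy[, 1L]), min(xy[, 2L]), max(xy[, 1L]), max(xy[, 2L]))
    if (bounds[3L] <= bounds[1L]) bounds[3L] <- bounds[1L] + 1
    if (bounds[4L] <= bounds[2L]) bounds[4L] <- bounds[2L] + 1
  }
  b <- as_bounds(bounds)
  if (nrow(xy) > 0L) {
    inside <- xy[, 1L] >= b[1L] & xy[, 1L] <= b[3L] &
      xy[, 2L] >= b[2L] & xy[, 2L] <= b[4L]
    if (!all(inside)) stop("all points must lie within bounds")
  }
  if (!is.null(true_n) && !is.na(true_n) && true_n != nrow(xy)) {
    stop("true_n must equal the number of points")
  }
  structure(list(xy = xy, bounds = b, n = nrow(xy),
                 true_n = if (is.null(true_n)) NA_integer_
                          else as.integer(true_n)),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  b <- x$bounds
  cat(sprintf("Planar point pattern: %d associated points\n", x$n))
  cat(sprintf("  bounds: [%g, %g] x [%g, %g] px\n", b[1], b[3], b[2], b[4]))
  if (!is.na(x$true_n)) cat(sprintf("  known true size N = %d\n", x$true_n))
  invisible(x)
}

#' Read or write associated points as CSV
#'
#' The CSV has header columns `x,y` (pixels), one row per particle.
#'
#' @param path file path.
#' @param bounds optional region (see [point_pattern()]); defaults to the
#'   tight bounding box.
#' @param true_n optional known population size.
#' @param flip_y optional region height H; when given, raster y-down
#'   coordinates are converted to y-up via `y <- H - y`.
#' @return `read_points_csv` returns a [point_pattern()]; `write_points_csv`
#'   invisibly returns `path`.
#' @export
read_points_csv <- function(path, bounds = NULL, true_n = NULL,
                            flip_y = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df))) {
    stop("points CSV must have header columns x,y")
  }
  if (!is.null(flip_y)) df$y <- flip_y - df$y
  point_pattern(df[, c("x", "y")], bounds = bounds, true_n = true_n)
}

#' @rdname read_points_csv
#' @param pattern a [point_pattern()] to write.
#' @export
write_points_csv <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  utils::write.csv(as.data.frame(pattern$xy), path, row.names = FALSE)
  invisible(path)
}
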