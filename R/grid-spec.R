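#' Define a systematic quadrat-grid sampling design
#'
#' A square grid of square quadrats of side `t` whose lower-left corners sit
#' at the vertices of a square lattice of period `T` (one quadrat per `T x T`
#' fundamental box), optionally tilted by `theta` degrees.  The grid position
#' is fixed by a uniform-random (UR) offset of the lower-left quadrat corner
#' within the fundamental box; that single randomisation is what makes the
#' number estimator design-unbiased, whatever the spatial pattern of the
#' population.
#'
#' @param t quadrat side length, in pixels; `0 < t <= T`.
#' @param T fundamental box (lattice) side length, in pixels.  `t = T` is the
#'   degenerate exhaustive tiling with sampling fraction 1.
#' @param theta grid tilt in degrees, counter-clockwise, relative to the
#'   pattern's axes.  The grid is rotated about the centre of the sampled
#'   region.  Design-unbiasedness holds for any fixed orientation.
#' @param offset length-2 numeric `(U1, U2)` of unit-interval fractions
#'   positioning the lower-left quadrat corner within the fundamental box.
#' @param seed integer; when `offset` is not given, the offset is drawn
#'   uniformly on `[0, 1)^2` from this seed (see [make_uniform_offset()]).
#' @param offset_px optional length-2 absolute offset in pixels, taken modulo
#'   `T`.  Overrides `offset`; useful for exact integer-offset sweeps where
#'   `u * T` round-off must be avoided.
#'
#' @return An object of class `grid_spec` with fields `t`, `T`, `theta`,
#'   `u` (offset fractions) and `z` (offset in pixels).
#' @seealso [grid_quadrats()], [count_points()], [sampling_fraction()]
#' @examples
#' spec <- grid_spec(t = 50, T = 250, theta = 60, seed = 1)
#' sampling_fraction(spec)  # t^2 / T^2 = 0.04
#' @export
grid_spec <- function(t, T, theta = 0, offset = NULL, seed = NULL,
                      offset_px = NULL) {
  stopifnot(length(t) == 1L, length(T) == 1L, is.numeric(t), is.numeric(T))
  t <- as.numeric(t); T <- as.numeric(T)
  if (!is.finite(t) || !is.finite(T) || t <= 0 || t > T) {
    stop("grid_spec requires 0 < t <= T < Inf")
  }
  if (!is.null(offset_px)) {
    z <- as.numeric(offset_px) %% T
    if (length(z) != 2L) stop("offset_px must have length 2")
    u <- z / T
  } else {
    if (is.null(offset)) {
      if (is.null(seed)) stop("supply offset, offset_px, or a seed")
      offset <- make_uniform_offset(seed)
    }
    u <- as.numeric(offset)
    if (length(u) != 2L || any(u < 0) || any(u >= 1)) {
      stop("offset fractions (U1, U2) must lie in [0, 1)")
    }
    z <- u * T
  }
  structure(list(t = t, T = T, theta = as.numeric(theta), u = u, z = z,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "grid_spec")
}

#' Draw a uniform-random grid offset
#'
#' Returns the pair `(U1, U2)` of independent uniform fractions on `[0, 1)`
#' that positions the lower-left quadrat corner within the fundamental box.
#' Reproducible from the seed; the caller's RNG state is left untouched.
#'
#' @param seed integer seed.
#' @return numeric length-2 vector in `[0, 1)^2`.
#' @export
make_uniform_offset <- function(seed) {
  with_seed(seed, stats::runif(2L))
}

#' Sampling fraction of a grid design
#'
#' The fraction of the plane covered by quadrats, `t^2 / T^2`.  Its inverse
#' is the expansion factor of the number estimator.
#'
#' @param spec a [grid_spec()].
#' @return scalar in `(0, 1]`.
#' @export
sampling_fraction <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  (spec$t / spec$T)^2
}

# Stripe sampling fraction tau = t/T.
grid_tau <- function(spec) spec$t / spec$T

#' @export
print.grid_spec <- function(x, ...) {
  cat("Systematic quadrat grid design\n")
  cat(sprintf("  quadrat side t      : %g px\n", x$t))
  cat(sprintf("  box side T          : %g px\n", x$T))
  cat(sprintf("  tilt theta          : %g deg\n", x$theta))
  cat(sprintf("  UR offset (U1, U2)  : (%.6f, %.6f)\n", x$u[1], x$u[2]))
  cat(sprintf("  sampling fraction   : %g\n", sampling_fraction(x)))
  invisible(x)
}

#' Read or write a grid design configuration
#'
#' Flat configuration with keys `t`, `T`, `theta_deg`, `u1`, `u2`, `seed`;
#' JSON and YAML dialects (chosen by file extension, or forced via `format`).
#' When `u1`/`u2` are absent the offset is drawn from `seed`.
#'
#' @param path file path.
#' @param format `"json"`, `"yaml"`, or `NULL` to infer from the extension.
#' @return `read_grid_spec` returns a [grid_spec()]; `write_grid_spec`
#'   invisibly returns `path`.
#' @export
read_grid_spec <- function(path, format = NULL) {
  cfg <- read_flat_config(path, format)
  offset <- if (!is.null(cfg$u1) && !is.null(cfg$u2)) {
    c(as.numeric(cfg$u1), as.numeric(cfg$u2))
  } else NULL
  grid_spec(t = as.numeric(cfg$t), T = as.numeric(cfg$T),
            theta = if (is.null(cfg$theta_deg)) 0 else as.numeric(cfg$theta_deg),
            offset = offset,
            seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed))
}

#' @rdname read_grid_spec
#' @param spec a [grid_spec()] to serialise.
#' @export
write_grid_spec <- function(spec, path, format = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  cfg <- list(t = spec$t, T = spec$T, theta_deg = spec$theta,
              u1 = spec$u[1], u2 = spec$u[2],
              seed = if (is.na(spec$seed)) NULL else spec$seed)
  write_flat_config(cfg, path, format)
}

config_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("json", "yaml")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) "yaml" else "json"
}

read_flat_config <- function(path, format = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  switch(config_format(path, format),
         json = jsonlite::read_json(path, simplifyVector = TRUE),
         yaml = yaml::read_yaml(path))
}

write_flat_config <- function(cfg, path, format = NULL) {
  switch(config_format(path, format),
         json = jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         yaml = yaml::write_yaml(cfg, path))
  invisible(path)
}
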