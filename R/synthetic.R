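#' Configure a synthetic point pattern
#'
#' Generators with known true size N and controllable spatial structure,
#' standing in for digitised aerial pictures.  Generation is conditioned on
#' exactly `n_points` points inside the bounds, because the method's
#' acceptance surface is recovery of a fixed N.  Kinds:
#'
#' * `homogeneous` — binomial process (uniform, independent points).
#' * `clustered` — parent/offspring: parents uniform, offspring displaced by
#'   an isotropic Gaussian of sd `cluster_sd`; offspring falling outside the
#'   bounds are resampled so N stays exact.
#' * `two_density` — two vertical bands whose point densities stand in the
#'   ratio `density_ratio` (denser band on the right), emulating a picture
#'   with a sparse and a packed subpopulation.
#' * `gradient` — density increasing linearly along x from 0.
#'
#' Defaults mirror a digitised crowd picture: a 1796 x 1200 px region with
#' 1120 particles.
#'
#' @param kind one of `"homogeneous"`, `"clustered"`, `"two_density"`,
#'   `"gradient"`.
#' @param n_points target population size N (exact).
#' @param bounds region, `c(width, height)` or `c(xmin, ymin, xmax, ymax)`.
#' @param cluster_parent_intensity parents per px^2; default places one
#'   parent per `cluster_mean_offspring` points.
#' @param cluster_sd Gaussian dispersal sd in pixels.
#' @param cluster_mean_offspring mean points per cluster.
#' @param density_ratio ratio of band densities (`> 0`), `two_density` kind.
#' @param split_fraction fraction of the width taken by the left (sparse)
#'   band, in `(0, 1)`.
#' @param seed integer seed; same seed, same pattern.
#' @return object of class `pattern_config`.
#' @export
pattern_config <- function(kind = c("homogeneous", "clustered",
                                    "two_density", "gradient"),
                           n_points = 1120L, bounds = c(1796, 1200),
                           cluster_parent_intensity = NULL,
                           cluster_sd = 30, cluster_mean_offspring = 20,
                           density_ratio = 3, split_fraction = 0.5,
                           seed = 1L) {
  kind <- match.arg(kind)
  if (n_points < 0) stop("n_points must be nonnegative")
  if (density_ratio <= 0) stop("density_ratio must be positive")
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must lie in (0, 1)")
  }
  if (cluster_sd <= 0 || cluster_mean_offspring <= 0) {
    stop("cluster parameters must be positive")
  }
  structure(list(kind = kind, n_points = as.integer(n_points),
                 bounds = as_bounds(bounds),
                 cluster_parent_intensity = cluster_parent_intensity,
                 cluster_sd = cluster_sd,
                 cluster_mean_offspring = cluster_mean_offspring,
                 density_ratio = density_ratio,
                 split_fraction = split_fraction,
                 seed = as.integer(seed)),
            class = "pattern_config")
}

#' Generate a synthetic point pattern
#'
#' @param config a [pattern_config()].
#' @return a [point_pattern()] with `true_n = n_points`.
#' @examples
#' pat <- generate_pattern(pattern_config("two_density", n_points = 500,
#'                                        bounds = c(1000, 800), seed = 7))
#' pat$true_n
#' @export
generate_pattern <- function(config) {
  stopifnot(inherits(config, "pattern_config"))
  b <- config$bounds
  n <- config$n_points
  W <- b[3L] - b[1L]; H <- b[4L] - b[2L]
  xy <- with_seed(config$seed, {
    switch(config$kind,
      homogeneous = cbind(stats::runif(n, b[1L], b[3L]),
                          stats::runif(n, b[2L], b[4L])),
      clustered = {
        lambda_p <- config$cluster_parent_intensity
        n_par <- if (!is.null(lambda_p)) max(1L, round(lambda_p * W * H))
                 else max(1L, round(n / config$cluster_mean_offspring))
        px <- stats::runif(n_par, b[1L], b[3L])
        py <- stats::runif(n_par, b[2L], b[4L])
        parent <- sample.int(n_par, n, replace = TRUE)
        x <- px[parent] + stats::rnorm(n, 0, config$cluster_sd)
        y <- py[parent] + stats::rnorm(n, 0, config$cluster_sd)
        bad <- which(x < b[1L] | x > b[3L] | y < b[2L] | y > b[4L])
        while (length(bad) > 0L) {
          x[bad] <- px[parent[bad]] + stats::rnorm(length(bad), 0,
                                                   config$cluster_sd)
          y[bad] <- py[parent[bad]] + stats::rnorm(length(bad), 0,
                                                   config$cluster_sd)
          bad <- bad[x[bad] < b[1L] | x[bad] > b[3L] |
                     y[bad] < b[2L] | y[bad] > b[4L]]
        }
        cbind(x, y)
      },
      two_density = {
        r <- config$density_ratio; f <- config$split_fraction
        # left band has density 1, right band density r; expected share of
        # the right band is r(1-f) / (f + r(1-f)); allocation is exact
        n_right <- round_half_up(n * r * (1 - f) / (f + r * (1 - f)))
        n_left <- n - n_right
        xsplit <- b[1L] + f * W
        x <- c(stats::runif(n_left, b[1L], xsplit),
               stats::runif(n_right, xsplit, b[3L]))
        y <- stats::runif(n, b[2L], b[4L])
        cbind(x, y)
      },
      gradient = {
        # density proportional to (x - xmin): inverse-CDF sampling
        x <- b[1L] + W * sqrt(stats::runif(n))
        y <- stats::runif(n, b[2L], b[4L])
        cbind(x, y)
      })
  })
  if (n == 0L) xy <- matrix(numeric(0), ncol = 2L)
  point_pattern(xy, bounds = b, true_n = n)
}

#' Read or write a pattern configuration
#'
#' Same flat JSON/YAML dialect as the grid configuration; keys mirror the
#' [pattern_config()] arguments plus `width`/`height` for the bounds.
#'
#' @param path file path.
#' @param format `"json"`, `"yaml"`, or `NULL` to infer from the extension.
#' @return a [pattern_config()].
#' @export
read_pattern_config <- function(path, format = NULL) {
  cfg <- read_flat_config(path, format)
  args <- cfg[intersect(names(cfg),
                        c("kind", "n_points", "cluster_parent_intensity",
                          "cluster_sd", "cluster_mean_offspring",
                          "density_ratio", "split_fraction", "seed"))]
  if (!is.null(cfg$width) && !is.null(cfg$height)) {
    args$bounds <- c(as.numeric(cfg$width), as.numeric(cfg$height))
  } else if (!is.null(cfg$bounds)) {
    args$bounds <- as.numeric(unlist(cfg$bounds))
  }
  do.call(pattern_config, args)
}
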