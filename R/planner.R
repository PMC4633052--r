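#' Fundamental box side for a target number of quadrats
#'
#' To place about `target_quadrats` quadrats over a `W x H` region, one
#' quadrat per fundamental box needs a box side of
#' `sqrt(W * H / target_quadrats)`.  A rounded "adopted" value (nearest 10
#' pixels) is also suggested, mirroring field practice.
#'
#' @param region_width,region_height region dimensions in pixels.
#' @param target_quadrats desired number of quadrats (`>= 1`).
#' @return list with `T_exact` and `T_adopted`.
#' @examples
#' recommend_box_side(2359, 826, 50)  # about 197, adopted 200
#' @export
recommend_box_side <- function(region_width, region_height, target_quadrats) {
  stopifnot(region_width > 0, region_height > 0, target_quadrats >= 1)
  T_exact <- sqrt(region_width * region_height / target_quadrats)
  list(T_exact = T_exact, T_adopted = max(10, round_half_up(T_exact / 10) * 10))
}

#' Plan a quadrat-grid sampling design
#'
#' Practical sizing rules for an efficient and convenient grid, requiring no
#' pilot estimate of the population size:
#'
#' * aim at a total count Q of about 50 particles when the population
#'   pattern looks fairly homogeneous, about 150 when it is relatively
#'   heterogeneous;
#' * aim at counting no more than 4 or 5 particles per quadrat;
#' * these imply a planned number of nonempty quadrats between 20 and 50.
#'
#' When a density hint (particles per px^2) is supplied, the quadrat side t
#' is sized so the expected count per quadrat is about
#' `Q / target_quadrats`, capped at 5.  Without a hint, t is left
#' unresolved with the instruction to pick, by eye, a quadrat capturing
#' about 1-6 units.  The grid is tilted (default 45 degrees) to avoid
#' parallelism between stripes and picture edges, which reduces the error
#' variance.
#'
#' @param region region rectangle, `c(width, height)` or
#'   `c(xmin, ymin, xmax, ymax)`.
#' @param heterogeneity `"homogeneous"` or `"heterogeneous"`.
#' @param density_hint optional particles per square pixel.
#' @param target_quadrats optional override; clamped to `[20, 50]`.
#' @param theta grid tilt in degrees.
#' @return object of class `design_advice`: fields `target_q`,
#'   `target_quadrats`, `T_exact`, `T`, `t` (`NA` when unresolved),
#'   `theta`, `expected_per_quadrat`, `notes` (character vector).
#' @examples
#' recommend_design(c(2359, 826), "heterogeneous")
#' @export
recommend_design <- function(region,
                             heterogeneity = c("homogeneous",
                                               "heterogeneous"),
                             density_hint = NULL, target_quadrats = NULL,
                             theta = 45) {
  heterogeneity <- match.arg(heterogeneity)
  b <- as_bounds(region)
  W <- unname(b[3L] - b[1L]); H <- unname(b[4L] - b[2L])
  target_q <- if (heterogeneity == "homogeneous") 50L else 150L
  nq <- if (is.null(target_quadrats)) {
    if (heterogeneity == "homogeneous") 20L else 50L
  } else {
    as.integer(min(50L, max(20L, target_quadrats)))
  }
  box <- recommend_box_side(W, H, nq)
  expected <- target_q / nq
  notes <- c(sprintf("aim at a total count Q of about %d (%s pattern)",
                     target_q, heterogeneity),
             "no pilot estimate of the population size is needed")
  if (expected > 5) {
    expected <- 5
    notes <- c(notes,
               "expected count per quadrat capped at 5 (4-5 is the practical maximum)")
  }
  if (!is.null(density_hint)) {
    stopifnot(density_hint > 0)
    t <- sqrt(expected / density_hint)
    if (t > box$T_adopted) {
      t <- box$T_adopted
      expected <- density_hint * t^2
      notes <- c(notes, "quadrat side clamped to the box side (t <= T)")
    }
    notes <- c(notes, sprintf("expected count per quadrat: about %.1f",
                              expected))
  } else {
    t <- NA_real_
    notes <- c(notes,
               "no density hint: pick, by eye, a quadrat side capturing about 1-6 units")
  }
  structure(list(region = c(W = W, H = H), heterogeneity = heterogeneity,
                 target_q = target_q, target_quadrats = nq,
                 T_exact = box$T_exact, T = box$T_adopted, t = t,
                 theta = theta, expected_per_quadrat = expected,
                 notes = notes),
            class = "design_advice")
}

#' @export
print.design_advice <- function(x, ...) {
  cat("Quadrat-grid design advice\n")
  cat(sprintf("  region                : %g x %g px (%s)\n",
              x$region["W"], x$region["H"], x$heterogeneity))
  cat(sprintf("  target total count Q  : %d in about %d quadrats\n",
              x$target_q, x$target_quadrats))
  cat(sprintf("  box side T            : %.0f px (exact %.1f)\n",
              x$T, x$T_exact))
  if (is.na(x$t)) {
    cat("  quadrat side t        : choose by eye (1-6 units per quadrat)\n")
  } else {
    cat(sprintf("  quadrat side t        : %.0f px\n", x$t))
  }
  cat(sprintf("  tilt                  : %g deg\n", x$theta))
  for (nte in x$notes) cat("  - ", nte, "\n", sep = "")
  invisible(x)
}

#' Serialise design advice to JSON
#'
#' @param advice a [recommend_design()] result.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @export
advice_to_json <- function(advice, path = NULL) {
  stopifnot(inherits(advice, "design_advice"))
  x <- unclass(advice)
  x$region <- as.list(x$region)
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
  }
}
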