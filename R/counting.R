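#' Polygon particles
#'
#' A particle given as a simple closed vertex ring (pixels), for the
#' forbidden-line manual counting rule.
#'
#' @param ring matrix/data frame of at least 3 (x, y) vertices.
#' @param id opaque label.
#' @return object of class `polygon_particle`.
#' @export
polygon_particle <- function(ring, id = NULL) {
  ring <- as_xy(ring)
  if (nrow(ring) < 3L) stop("a particle ring needs at least 3 vertices")
  # drop an explicitly closed duplicate last vertex
  if (all(ring[1L, ] == ring[nrow(ring), ]) && nrow(ring) > 3L) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  if (!ring_is_simple(ring)) stop("invalid particle: self-intersecting ring")
  if (ring_area(ring) <= 0) stop("invalid particle: zero area")
  structure(list(ring = ring, id = if (is.null(id)) NA_character_
                                   else as.character(id)),
            class = "polygon_particle")
}

#' Read polygon particles from JSON
#'
#' Expects a JSON array of objects `{"id": str, "ring": [[x, y], ...]}`.
#'
#' @param path file path.
#' @return list of [polygon_particle()] objects.
#' @export
read_polygons_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(p) {
    ring <- do.call(rbind, lapply(p$ring, function(v) as.numeric(unlist(v))))
    polygon_particle(ring, id = p$id)
  })
}

# Internal constructor for the observable that all estimators consume:
# per-quadrat counts q_ij indexed by (stripe, within).
new_quadrat_sample <- function(counts, spec, bounds = NULL) {
  stopifnot(all(c("stripe", "within", "count") %in% names(counts)),
            all(counts$count >= 0))
  structure(list(counts = counts, spec = spec, bounds = bounds,
                 total_q = sum(counts$count),
                 n_nonempty = sum(counts$count > 0L)),
            class = "quadrat_sample")
}

#' @export
print.quadrat_sample <- function(x, ...) {
  cat("Systematic quadrat sample\n")
  cat(sprintf("  quadrats enumerated : %d (%d nonempty)\n",
              nrow(x$counts), x$n_nonempty))
  cat(sprintf("  total count Q       : %d\n", x$total_q))
  cat(sprintf("  grid: t = %g, T = %g, theta = %g deg\n",
              x$spec$t, x$spec$T, x$spec$theta))
  invisible(x)
}

#' Count associated points per quadrat
#'
#' The associated point rule: a particle is counted in a quadrat if and only
#' if its associated point is contained in the (half-open) quadrat.  Each
#' point is counted at most once; points falling in the gaps between
#' quadrats are not counted.
#'
#' @param pattern a [point_pattern()].
#' @param spec a [grid_spec()].
#' @return a `quadrat_sample`: per-quadrat counts (zero quadrats included)
#'   with total `Q` and the number of nonempty quadrats.
#' @examples
#' pat <- generate_pattern(pattern_config("homogeneous", n_points = 200,
#'                                        bounds = c(500, 400), seed = 1))
#' smp <- count_points(pat, grid_spec(t = 50, T = 100, seed = 2))
#' estimate_n(smp)
#' @export
count_points <- function(pattern, spec) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(spec, "grid_spec"))
  quads <- grid_quadrats(spec, pattern$bounds)
  counts <- quads[, c("stripe", "within", "ix", "iy")]
  if (pattern$n > 0L) {
    loc <- locate_point(pattern$xy, spec, pattern$bounds)
    key <- paste(loc$ix, loc$iy)
    idx <- match(key, paste(quads$ix, quads$iy))
    counts$count <- tabulate(idx[!is.na(idx)], nbins = nrow(quads))
  } else {
    counts$count <- integer(nrow(quads))
  }
  new_quadrat_sample(counts, spec, pattern$bounds)
}

# Forbidden trace of a quadrat with lower-left (x0, y0) in the grid frame:
# the full line through the left edge (the edge with both its infinite
# extensions, here truncated at +-ext) plus the bottom edge.  The top and
# right edges are acceptance edges.  This trace makes the rule an exact
# partition of every convex particle under the exhaustive tiling t = T
# (counted in the quadrat holding the lowest point of its portion within
# the leftmost stripe it touches), which is the property that makes the
# count edge-effect unbiased.
forbidden_trace <- function(x0, y0, t, ext) {
  list(rbind(c(x0, y0 + t + ext), c(x0, y0 - ext)),  # full left line
       rbind(c(x0, y0), c(x0 + t, y0)))              # bottom edge
}

#' Count polygon particles with the forbidden line rule
#'
#' The edge-effect-unbiased manual counting rule: a particle is counted in a
#' quadrat only if it has points in common with the (closed) quadrat but
#' does not hit the quadrat's extended forbidden line.  The forbidden trace
#' adopted here is the full line through the quadrat's left edge (the edge
#' with both its infinite extensions) together with the bottom edge;
#' "hitting" means non-empty intersection with the closed trace.  With the
#' exhaustive tiling `t = T` this trace partitions: every convex particle is
#' counted in exactly one quadrat, whatever its size and position, which is
#' the defining property of an unbiased counting frame.  Particles that are
#' strongly concave toward the left (so that a vertical stripe cuts them
#' into disjoint pieces) can evade the trace and be counted twice; such
#' shapes are rare among head/animal outlines and are flagged as a known
#' limitation.
#'
#' @param particles list of [polygon_particle()] objects.
#' @param spec a [grid_spec()].
#' @param bounds region rectangle (see [grid_quadrats()]).
#' @return a `quadrat_sample`.
#' @export
count_polygons_forbidden_line <- function(particles, spec, bounds) {
  stopifnot(inherits(spec, "grid_spec"))
  if (inherits(particles, "polygon_particle")) particles <- list(particles)
  lapply(particles, function(p) {
    if (!inherits(p, "polygon_particle")) stop("expected polygon_particle objects")
  })
  b <- as_bounds(bounds)
  quads <- grid_quadrats(spec, b)
  t <- spec$t
  ext <- 4 * max(b[3L] - b[1L], b[4L] - b[2L], spec$T)
  rings <- lapply(particles, function(p) to_grid_frame(p$ring, spec, b))
  count <- integer(nrow(quads))
  for (r in rings) {
    for (qi in seq_len(nrow(quads))) {
      x0 <- quads$x0[qi]; y0 <- quads$y0[qi]
      if (!ring_hits_square(r, x0, y0, t)) next
      if (!ring_hits_polyline(r, forbidden_trace(x0, y0, t, ext))) {
        count[qi] <- count[qi] + 1L
      }
    }
  }
  counts <- quads[, c("stripe", "within", "ix", "iy")]
  counts$count <- count
  new_quadrat_sample(counts, spec, b)
}

#' Apply the picture-border rule
#'
#' Units hitting the left border of the picture are discarded; units hitting
#' the right border are retained.  Top and bottom borders are unaffected.
#' This one-sided rule eliminates double counting across potentially
#' adjacent pictures.
#'
#' @param x a [point_pattern()] or a list of [polygon_particle()] objects.
#' @param bounds the picture rectangle.
#' @return the filtered object, same type as `x`.
#' @export
apply_border_rule <- function(x, bounds) {
  b <- as_bounds(bounds)
  if (inherits(x, "point_pattern")) {
    keep <- x$xy[, 1L] > b[1L]
    return(point_pattern(x$xy[keep, , drop = FALSE], bounds = b))
  }
  if (inherits(x, "polygon_particle")) x <- list(x)
  Filter(function(p) min(p$ring[, 1L]) > b[1L], x)
}
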