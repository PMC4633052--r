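# Grid-frame geometry: the grid is conceptually unbounded and axis-aligned in
# its own frame; tilt is handled by rotating coordinates about the centre of
# the sampled region.  All quadrat bookkeeping happens in the grid frame,
# which keeps every per-offset operation axis-aligned and fast.

rotation_matrix <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

# World -> grid frame: g = R(-theta) (p - centre).  `p` is an n x 2 matrix.
to_grid_frame <- function(p, spec, bounds) {
  ctr <- bounds_center(bounds)
  p <- sweep(as_xy(p), 2L, ctr)
  if (spec$theta == 0) return(p)
  p %*% rotation_matrix(spec$theta)  # row-vector form of R(-theta) p
}

# Grid frame -> world.
from_grid_frame <- function(g, spec, bounds) {
  ctr <- bounds_center(bounds)
  g <- as_xy(g)
  if (spec$theta != 0) g <- g %*% t(rotation_matrix(spec$theta))
  sweep(g, 2L, ctr, `+`)
}

#' Enumerate the quadrats of a grid over a region
#'
#' Lists every quadrat of the (conceptually unbounded) grid whose closure can
#' intersect the region after accounting for tilt.  Grazing quadrats —
#' quadrats that only touch or partially overlap the region — are included:
#' grazing quadrats hitting particles must not be ignored, otherwise the
#' estimator is biased.
#'
#' Addresses are `(stripe, within)`: `stripe` numbers the vertical columns of
#' quadrats in the grid's own frame from left to right starting at 1;
#' `within` numbers the quadrats of each stripe from bottom to top starting
#' at 1, counting only quadrats that intersect the region (so positions match
#' manual counting on the picture).
#'
#' @param spec a [grid_spec()].
#' @param bounds region, `c(width, height)` or `c(xmin, ymin, xmax, ymax)`.
#' @return data frame with columns `stripe`, `within`, `ix`, `iy` (raw
#'   lattice indices, as returned by [locate_point()]), `x0`, `y0`
#'   (lower-left corner in the grid frame).  Attributes `spec` and `bounds`.
#' @seealso [quadrat_corners()] for world-frame corner coordinates.
#' @export
grid_quadrats <- function(spec, bounds) {
  stopifnot(inherits(spec, "grid_spec"))
  b <- as_bounds(bounds)
  B <- to_grid_frame(bounds_corners(b), spec, b)  # region as a convex quad
  t <- spec$t; Tb <- spec$T; z <- spec$z
  eps <- 1e-9 * max(Tb, abs(B))
  bx <- range(B[, 1L]); by <- range(B[, 2L])
  # one lattice cell beyond the bounding box in every direction
  i0 <- floor((bx[1L] - t - z[1L]) / Tb) - 1L
  i1 <- ceiling((bx[2L] - z[1L]) / Tb) + 1L
  j0 <- floor((by[1L] - t - z[2L]) / Tb) - 1L
  j1 <- ceiling((by[2L] - z[2L]) / Tb) + 1L
  cells <- expand.grid(ix = i0:i1, iy = j0:j1, KEEP.OUT.ATTRS = FALSE)
  x0 <- z[1L] + cells$ix * Tb
  y0 <- z[2L] + cells$iy * Tb
  # separating-axis test of the closed quadrat square against the region
  # quadrilateral; touching counts as intersecting
  keep <- x0 <= bx[2L] + eps & x0 + t >= bx[1L] - eps &
          y0 <= by[2L] + eps & y0 + t >= by[1L] - eps
  if (spec$theta != 0) {
    for (k in 1:4) {
      e <- B[k %% 4L + 1L, ] - B[k, ]
      a <- c(-e[2L], e[1L])
      projB <- B %*% a
      qlo <- x0 * a[1L] + y0 * a[2L] + min(0, t * a[1L]) + min(0, t * a[2L])
      qhi <- x0 * a[1L] + y0 * a[2L] + max(0, t * a[1L]) + max(0, t * a[2L])
      aeps <- eps * sqrt(sum(a^2))
      keep <- keep & !(qhi < min(projB) - aeps | qlo > max(projB) + aeps)
    }
  }
  cells <- cells[keep, , drop = FALSE]
  cells$x0 <- x0[keep]
  cells$y0 <- y0[keep]
  cells <- cells[order(cells$ix, cells$iy), , drop = FALSE]
  stripe <- match(cells$ix, sort(unique(cells$ix)))
  within <- stats::ave(cells$iy, cells$ix, FUN = seq_along)
  out <- data.frame(stripe = stripe, within = as.integer(within),
                    ix = cells$ix, iy = cells$iy,
                    x0 = cells$x0, y0 = cells$y0)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  attr(out, "bounds") <- b
  out
}

#' Map points to the quadrat containing them
#'
#' Quadrats are half-open `[x0, x0 + t) x [y0, y0 + t)` in the grid frame, so
#' each point belongs to at most one quadrat; points falling in the gap
#' between quadrats map to `NA`.  Returned indices are raw lattice indices
#' `(ix, iy)` — any integers — matching the `ix`, `iy` columns of
#' [grid_quadrats()].
#'
#' @param p points: n x 2 matrix/data frame, or a single `c(x, y)`.
#' @param spec a [grid_spec()].
#' @param bounds the region used to anchor the grid frame (tilt is about its
#'   centre); must match the `bounds` passed to [grid_quadrats()].
#' @return data frame with integer columns `ix`, `iy` (`NA` for gap points).
#' @export
locate_point <- function(p, spec, bounds) {
  stopifnot(inherits(spec, "grid_spec"))
  g <- to_grid_frame(p, spec, bounds)
  s <- sweep(g, 2L, spec$z)
  idx <- floor(s / spec$T)
  r <- s - idx * spec$T
  inside <- r[, 1L] < spec$t & r[, 2L] < spec$t
  data.frame(ix = ifelse(inside, idx[, 1L], NA_integer_),
             iy = ifelse(inside, idx[, 2L], NA_integer_))
}

#' World-frame corner coordinates of enumerated quadrats
#'
#' For overlaying the grid on the original picture with external plotting
#' tools.
#'
#' @param quads output of [grid_quadrats()].
#' @return data frame with columns `stripe`, `within`, `corner` (1-4,
#'   counter-clockwise from lower left), `x`, `y`.
#' @export
quadrat_corners <- function(quads) {
  spec <- attr(quads, "spec"); b <- attr(quads, "bounds")
  t <- spec$t
  dx <- c(0, t, t, 0); dy <- c(0, 0, t, t)
  n <- nrow(quads)
  g <- cbind(rep(quads$x0, each = 4L) + rep(dx, n),
             rep(quads$y0, each = 4L) + rep(dy, n))
  w <- from_grid_frame(g, spec, b)
  data.frame(stripe = rep(quads$stripe, each = 4L),
             within = rep(quads$within, each = 4L),
             corner = rep(1:4, n), x = w[, 1L], y = w[, 2L])
}
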