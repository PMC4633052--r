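# Small, dependency-free planar predicates used by the forbidden-line
# counting rule.  All predicates are closed: touching counts as hitting.

GEOM_EPS <- 1e-9

cross2 <- function(o, a, b) {
  (a[1L] - o[1L]) * (b[2L] - o[2L]) - (a[2L] - o[2L]) * (b[1L] - o[1L])
}

on_segment <- function(p, a, b, eps) {
  if (abs(cross2(a, b, p)) > eps) return(FALSE)
  p[1L] >= min(a[1L], b[1L]) - eps && p[1L] <= max(a[1L], b[1L]) + eps &&
    p[2L] >= min(a[2L], b[2L]) - eps && p[2L] <= max(a[2L], b[2L]) + eps
}

# Closed segment-segment intersection, including touching and collinear
# overlap.
segments_intersect <- function(p1, p2, p3, p4, eps = GEOM_EPS) {
  scale <- max(abs(c(p1, p2, p3, p4)), 1)
  e <- eps * scale
  d1 <- cross2(p3, p4, p1); d2 <- cross2(p3, p4, p2)
  d3 <- cross2(p1, p2, p3); d4 <- cross2(p1, p2, p4)
  if (((d1 > e && d2 < -e) || (d1 < -e && d2 > e)) &&
      ((d3 > e && d4 < -e) || (d3 < -e && d4 > e))) return(TRUE)
  on_segment(p1, p3, p4, e) || on_segment(p2, p3, p4, e) ||
    on_segment(p3, p1, p2, e) || on_segment(p4, p1, p2, e)
}

# Even-odd point-in-polygon; points on the boundary count as inside.
point_in_ring <- function(p, ring, eps = GEOM_EPS) {
  n <- nrow(ring)
  scale <- max(abs(ring), 1)
  e <- eps * scale
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[j, ]
    if (on_segment(p, a, b, e)) return(TRUE)
    if ((a[2L] > p[2L]) != (b[2L] > p[2L])) {
      xint <- a[1L] + (p[2L] - a[2L]) * (b[1L] - a[1L]) / (b[2L] - a[2L])
      if (p[1L] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

ring_edges <- function(ring) {
  n <- nrow(ring)
  list(a = ring, b = ring[c(2:n, 1L), , drop = FALSE])
}

# Does a simple polygon intersect an open polyline (list of segments)?
ring_hits_polyline <- function(ring, segs) {
  ed <- ring_edges(ring)
  for (s in segs) {
    for (i in seq_len(nrow(ring))) {
      if (segments_intersect(ed$a[i, ], ed$b[i, ], s[1L, ], s[2L, ])) {
        return(TRUE)
      }
    }
    # a finite trace segment wholly inside the particle
    if (point_in_ring(s[1L, ], ring) || point_in_ring(s[2L, ], ring)) {
      return(TRUE)
    }
  }
  FALSE
}

# Closed intersection of a simple polygon with an axis-aligned square
# [x0, x0+t] x [y0, y0+t].
ring_hits_square <- function(ring, x0, y0, t) {
  rx <- range(ring[, 1L]); ry <- range(ring[, 2L])
  e <- GEOM_EPS * max(abs(ring), t, 1)
  if (rx[2L] < x0 - e || rx[1L] > x0 + t + e ||
      ry[2L] < y0 - e || ry[1L] > y0 + t + e) return(FALSE)
  sq <- matrix(c(x0, y0, x0 + t, y0, x0 + t, y0 + t, x0, y0 + t),
               ncol = 2L, byrow = TRUE)
  # any particle vertex in the square
  if (any(ring[, 1L] >= x0 - e & ring[, 1L] <= x0 + t + e &
          ring[, 2L] >= y0 - e & ring[, 2L] <= y0 + t + e)) return(TRUE)
  # any square corner inside the particle
  for (k in 1:4) if (point_in_ring(sq[k, ], ring)) return(TRUE)
  # any edge pair crossing
  ed <- ring_edges(ring)
  for (k in 1:4) {
    a <- sq[k, ]; b <- sq[k %% 4L + 1L, ]
    for (i in seq_len(nrow(ring))) {
      if (segments_intersect(ed$a[i, ], ed$b[i, ], a, b)) return(TRUE)
    }
  }
  FALSE
}

# TRUE when the closed ring has a self-intersection between non-adjacent
# edges (used to validate particle input).
ring_is_simple <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(FALSE)
  ed <- ring_edges(ring)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i || j == i %% n + 1L || i == j %% n + 1L) next
      if (segments_intersect(ed$a[i, ], ed$b[i, ], ed$a[j, ], ed$b[j, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

ring_area <- function(ring) {
  n <- nrow(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
}
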