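# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber user randomness.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Normalise a region description to c(xmin, ymin, xmax, ymax).
# Accepts either a length-2 c(width, height) anchored at the origin or an
# explicit length-4 rectangle.
as_bounds <- function(bounds) {
  b <- as.numeric(bounds)
  if (length(b) == 2L) b <- c(0, 0, b)
  if (length(b) != 4L || any(!is.finite(b))) {
    stop("bounds must be c(width, height) or c(xmin, ymin, xmax, ymax)")
  }
  if (b[3L] <= b[1L] || b[4L] <= b[2L]) stop("invalid region: empty bounds")
  names(b) <- c("xmin", "ymin", "xmax", "ymax")
  b
}

bounds_center <- function(bounds) {
  b <- as_bounds(bounds)
  c((b[1L] + b[3L]) / 2, (b[2L] + b[4L]) / 2)
}

# Corner coordinates, counter-clockwise from lower left; 4 x 2 matrix.
bounds_corners <- function(bounds) {
  b <- as_bounds(bounds)
  matrix(c(b[1L], b[2L],
           b[3L], b[2L],
           b[3L], b[4L],
           b[1L], b[4L]), ncol = 2L, byrow = TRUE)
}

# Coerce points input (matrix, data.frame with x/y, or length-2 vector) to an
# n x 2 numeric matrix.
as_xy <- function(p) {
  if (is.data.frame(p)) {
    p <- as.matrix(p[, c("x", "y")])
  } else if (is.null(dim(p))) {
    if (length(p) != 2L) stop("a single point must have two coordinates")
    p <- matrix(as.numeric(p), ncol = 2L)
  } else {
    p <- as.matrix(p)
  }
  storage.mode(p) <- "double"
  if (ncol(p) != 2L) stop("points must have two columns (x, y)")
  colnames(p) <- c("x", "y")
  p
}

# Round-half-up to the nearest integer (5466.67 -> 5467, 0.5 -> 1).
round_half_up <- function(x) floor(x + 0.5)
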