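# Shared fixtures, all built in code.

# Crowd worked example: 6 stripes x 7 within-stripe positions (bottom to
# top), t = 50, T = 250.  Q = 50 in 17 nonempty quadrats.
table1_matrix <- function() {
  matrix(c(0, 0, 1, 0, 0, 0,
           5, 3, 0, 0, 0, 0,
           4, 3, 3, 0, 0, 0,
           0, 2, 0, 4, 0, 0,
           0, 0, 2, 4, 4, 0,
           0, 0, 3, 3, 3, 0,
           0, 0, 0, 2, 2, 2), nrow = 7, byrow = TRUE)
}

table1_sample <- function() stripe_table_sample(table1_matrix(), t = 50, T = 250)

# Penguin worked example: 12 tilted stripes, 76 quadrat counts, t = 30,
# T = 200, 45 degree tilt.  Q = 123.
penguin_lists <- function() {
  list(c(0, 1),
       c(0, 1, 3, 0),
       c(0, 1, 5, 3, 1, 0),
       c(0, 5, 9, 5, 0, 2, 0, 0),
       c(0, 0, 6, 5, 0, 4, 0, 0, 0),
       c(0, 0, 8, 7, 4, 0, 0, 0, 0),
       c(0, 2, 2, 6, 4, 1, 0, 0, 0),
       c(0, 0, 5, 9, 1, 0, 1, 0, 0),
       c(0, 5, 5, 1, 1, 0, 0, 0),
       c(0, 3, 0, 2, 0, 0),
       c(2, 2, 0, 0),
       c(1, 0))
}

penguin_matrix <- function() {
  lists <- penguin_lists()
  m <- matrix(NA_real_, nrow = max(lengths(lists)), ncol = length(lists))
  for (i in seq_along(lists)) m[seq_along(lists[[i]]), i] <- lists[[i]]
  m
}

penguin_sample <- function() {
  stripe_table_sample(penguin_matrix(), t = 30, T = 200, theta = 45)
}

# Random simple convex-ish particles (star polygons about a centre), small
# enough to stay inside the bounds margin.
random_particles <- function(n, bounds, r_max = 12, seed = 1) {
  b <- c(0, 0, bounds[1], bounds[2])
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    c0 <- c(runif(1, r_max + 2, b[3] - r_max - 2),
            runif(1, r_max + 2, b[4] - r_max - 2))
    k <- sample(3:6, 1)
    ang <- 2 * pi * (seq_len(k) - 1) / k + runif(1, 0, 2 * pi / k)
    r <- runif(k, r_max / 4, r_max)
    polygon_particle(cbind(c0[1] + r * cos(ang), c0[2] + r * sin(ang)),
                     id = i)
  }))
}
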