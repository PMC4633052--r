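test_that("uniform offsets are in range, reproducible, and uniform in the mean", {
  u <- make_uniform_offset(0)
  expect_length(u, 2)
  expect_true(all(u >= 0 & u < 1))
  expect_identical(u, make_uniform_offset(0))
  expect_false(identical(u, make_uniform_offset(1)))

  u1 <- vapply(seq_len(10000), function(s) make_uniform_offset(s)[1],
               numeric(1))
  se <- stats::sd(u1) / sqrt(length(u1))
  expect_lt(abs(mean(u1) - 0.5), 3 * se)
})

test_that("grid_spec validates its invariants", {
  expect_error(grid_spec(t = 0, T = 10, offset = c(0, 0)), "0 < t")
  expect_error(grid_spec(t = 11, T = 10, offset = c(0, 0)), "0 < t")
  expect_error(grid_spec(t = 5, T = 10, offset = c(1, 0)), "\\[0, 1\\)")
  expect_error(grid_spec(t = 5, T = 10), "seed")
  expect_equal(sampling_fraction(grid_spec(50, 250, offset = c(0, 0))), 0.04)
})

test_that("exhaustive tiling enumerates the tile plus its grazing ring", {
  # offset (0.5, 0.5): one quadrat coincides with the box (the grid frame
  # is anchored at the bounds centre)
  spec <- grid_spec(t = 10, T = 10, offset = c(0.5, 0.5))
  q <- grid_quadrats(spec, c(10, 10))
  # 1 covering quadrat + 8 touching neighbours
  expect_equal(nrow(q), 9)
  expect_true(any(q$x0 == -5 & q$y0 == -5))  # grid frame is centred
})

test_that("quadrat enumeration covers the region", {
  spec <- grid_spec(t = 50, T = 250, offset = c(0.3, 0.7))
  bounds <- c(1796, 1200)
  q <- grid_quadrats(spec, bounds)
  expect_gte(nrow(q), ceiling(1796 / 250) * ceiling(1200 / 250))
  # addresses are unique and 1-based
  expect_false(anyDuplicated(q[, c("stripe", "within")]) > 0)
  expect_equal(min(q$stripe), 1L)
  expect_equal(min(q$within), 1L)
  expect_error(grid_quadrats(spec, c(0, 0)), "region")
})

test_that("locate_point honours the half-open boundary and the gaps", {
  spec <- grid_spec(t = 25, T = 100, offset = c(0.1, 0.1))
  b <- c(0, 0, 100, 100)
  # the grid frame is anchored at the bounds centre (50, 50); a quadrat
  # lower-left corner sits at centre + (10, 10) = (60, 60) in world coords
  on_corner <- locate_point(c(60, 60), spec, b)
  expect_false(is.na(on_corner$ix))
  just_out <- locate_point(c(60 + 25, 60), spec, b)  # on the right edge
  expect_true(is.na(just_out$ix))
  gap <- locate_point(c(60 + 50, 60 + 50), spec, b)
  expect_true(is.na(gap$ix))
})

test_that("locate_point agrees with a brute-force rectangle loop", {
  spec <- grid_spec(t = 30, T = 80, theta = 25, offset = c(0.42, 0.13))
  b <- c(0, 0, 400, 300)
  quads <- grid_quadrats(spec, b)
  pts <- withr::with_seed(99, cbind(runif(1000, 0, 400), runif(1000, 0, 300)))
  loc <- locate_point(pts, spec, b)
  g <- quadpop:::to_grid_frame(pts, spec, b)
  for (i in seq_len(nrow(pts))) {
    hit <- which(g[i, 1] >= quads$x0 & g[i, 1] < quads$x0 + spec$t &
                 g[i, 2] >= quads$y0 & g[i, 2] < quads$y0 + spec$t)
    if (length(hit) == 0L) {
      expect_true(is.na(loc$ix[i]))
    } else {
      expect_equal(c(quads$ix[hit], quads$iy[hit]),
                   c(loc$ix[i], loc$iy[i]))
    }
  }
})

test_that("disjointness: no point falls in two quadrats; t = T assigns all", {
  b <- c(0, 0, 200, 150)
  pts <- withr::with_seed(5, cbind(runif(500, 0, 200), runif(500, 0, 150)))
  # t < T: locate_point is a function, so uniqueness is structural; check
  # that the exhaustive case assigns every point
  spec1 <- grid_spec(t = 40, T = 40, theta = 0, offset = c(0.6, 0.2))
  loc1 <- locate_point(pts, spec1, b)
  expect_false(anyNA(loc1$ix))
  pat <- point_pattern(pts, bounds = b)
  expect_equal(count_points(pat, spec1)$total_q, 500L)
})

test_that("tilting the grid equals counting the counter-rotated pattern", {
  b <- c(0, 0, 400, 300)
  pts <- withr::with_seed(21, cbind(runif(300, 0, 400), runif(300, 0, 300)))
  theta <- 37
  spec_tilted <- grid_spec(t = 30, T = 80, theta = theta,
                           offset = c(0.2, 0.6))
  spec_flat <- grid_spec(t = 30, T = 80, theta = 0, offset = c(0.2, 0.6))
  ctr <- c(200, 150)
  th <- -theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rotated <- sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr, `+`)
  a <- locate_point(pts, spec_tilted, b)
  c2 <- locate_point(rotated, spec_flat, b)
  expect_equal(a, c2)
})

test_that("exhaustive-offset identity: each point captured by exactly t^2 offsets", {
  # integer coordinates, integer t, T: the sum of Q over all T^2 integer
  # offsets equals N * t^2 with no floating slack
  t <- 2L; T <- 5L
  pts <- withr::with_seed(3, cbind(sample(0:39, 60, TRUE),
                                   sample(0:29, 60, TRUE)))
  pat <- point_pattern(pts, bounds = c(0, 0, 40, 30), true_n = 60)
  total <- 0L
  for (ox in 0:(T - 1)) for (oy in 0:(T - 1)) {
    spec <- grid_spec(t = t, T = T, offset_px = c(ox, oy))
    total <- total + count_points(pat, spec)$total_q
  }
  expect_identical(total, 60L * t * t)
})

test_that("grid config round-trips through JSON and YAML", {
  spec <- grid_spec(t = 30, T = 200, theta = 45, offset = c(0.25, 0.75))
  for (ext in c("json", "yaml")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_grid_spec(spec, f)
    back <- read_grid_spec(f)
    expect_equal(back$t, spec$t)
    expect_equal(back$T, spec$T)
    expect_equal(back$theta, spec$theta)
    expect_equal(back$u, spec$u, tolerance = 1e-12)
  }
})

test_that("quadrat_corners returns world coordinates of every quadrat", {
  spec <- grid_spec(t = 10, T = 20, theta = 60, offset = c(0.1, 0.4))
  q <- grid_quadrats(spec, c(100, 80))
  cor <- quadrat_corners(q)
  expect_equal(nrow(cor), 4 * nrow(q))
  # corner 1 must map back to the stored grid-frame lower-left corner
  g <- quadpop:::to_grid_frame(as.matrix(cor[cor$corner == 1, c("x", "y")]),
                               spec, c(100, 80))
  expect_equal(g[, 1], q$x0, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(g[, 2], q$y0, tolerance = 1e-9, ignore_attr = TRUE)
})
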