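test_that("systematic offsets form a jittered K x K subgrid of the box", {
  spec <- grid_spec(t = 50, T = 250, offset = c(0, 0))
  one <- systematic_offsets(1, seed = 4, spec = spec)
  expect_equal(nrow(one), 1L)
  expect_true(all(one$u_x >= 0 & one$u_x < 250))

  offs <- systematic_offsets(32, seed = 4, spec = spec)
  expect_equal(nrow(offs), 1024L)
  expect_true(all(offs$u_x >= 0 & offs$u_x < 250))
  expect_true(all(offs$u_y >= 0 & offs$u_y < 250))
  expect_false(anyDuplicated(offs[, c("u_x", "u_y")]) > 0)
  # gap Delta = T/K in each axis
  expect_equal(diff(sort(unique(offs$u_x))),
               rep(250 / 32, 31))
  # the whole sweep derives from one pair of uniforms
  expect_equal(sort(unique(offs$u_x))[1], make_uniform_offset(4)[1] * 250 / 32)
})

test_that("t = T sweep recovers N exactly with zero empirical variance", {
  pat <- generate_pattern(pattern_config("homogeneous", n_points = 150,
                                         bounds = c(300, 200), seed = 6))
  spec <- grid_spec(t = 50, T = 50, offset = c(0, 0))
  mc <- run_sweep(pat, spec, k_side = 3, seed = 9)
  expect_true(all(mc$replicates$n_hat_k == 150))
  expect_equal(mc$empirical_mean, 150)
  expect_equal(mc$empirical_var, 0)
  expect_equal(mc$ce2_emp, 0)
})

test_that("stored summaries match recomputation from the replicates", {
  pat <- generate_pattern(pattern_config("two_density", n_points = 400,
                                         bounds = c(800, 500), seed = 2))
  spec <- grid_spec(t = 40, T = 120, theta = 30, offset = c(0, 0))
  mc <- run_sweep(pat, spec, k_side = 6, seed = 11)
  r <- mc$replicates
  expect_equal(nrow(r), 36L)
  f2 <- (120 / 40)^2
  expect_equal(mc$empirical_mean, f2 * mean(r$Q_k))
  expect_equal(mc$empirical_var,
               sum((r$n_hat_k - mc$empirical_mean)^2) / 36)
  expect_equal(mc$ce2_emp, mc$empirical_var / 400^2)
  expect_equal(mc$ce2_ind_mean, mean(r$var_ind_k, na.rm = TRUE) / 400^2)
  expect_equal(mc$ce2_cav_mean, mean(r$var_cav_k, na.rm = TRUE) / 400^2)
})

test_that("k_side = 1 reduces to a single ordinary UR estimate", {
  pat <- generate_pattern(pattern_config("homogeneous", n_points = 200,
                                         bounds = c(500, 400), seed = 3))
  spec <- grid_spec(t = 30, T = 100, offset = c(0, 0))
  mc <- run_sweep(pat, spec, k_side = 1, seed = 7)
  expect_equal(nrow(mc$replicates), 1L)
  # the single offset is U * Delta with Delta = T
  u <- make_uniform_offset(7)
  direct <- count_points(pat, grid_spec(30, 100, offset_px = u * 100))
  expect_equal(mc$replicates$Q_k, direct$total_q)
  expect_equal(mc$empirical_var, 0)
})

test_that("sweeps are reproducible and stable in K", {
  pat <- generate_pattern(pattern_config("gradient", n_points = 300,
                                         bounds = c(600, 400), seed = 8))
  spec <- grid_spec(t = 40, T = 100, offset = c(0, 0))
  a <- run_sweep(pat, spec, k_side = 8, seed = 5)
  b <- run_sweep(pat, spec, k_side = 8, seed = 5)
  expect_identical(a$replicates, b$replicates)
  # doubling K moves the empirical mean by less than the MC standard error
  big <- run_sweep(pat, spec, k_side = 16, seed = 5)
  se <- sqrt(a$empirical_var) / a$k_side
  expect_lt(abs(big$empirical_mean - a$empirical_mean), se)
})

test_that("independence predictor exceeds the Cavalieri predictor on mixed densities", {
  # the bimodal quadrat-content distribution of a two-density population
  # inflates the between-quadrat sample variance that the independence
  # predictor is built on; the Cavalieri predictor discounts the smooth
  # between-stripe trend and sits below it
  pat <- generate_pattern(pattern_config("two_density", n_points = 400,
                                         bounds = c(800, 500), seed = 2))
  mc <- run_sweep(pat, grid_spec(40, 120, theta = 30, offset = c(0, 0)),
                  k_side = 8, seed = 11)
  expect_gt(mean(mc$replicates$var_ind_k, na.rm = TRUE),
            mean(mc$replicates$var_cav_k, na.rm = TRUE))
})

test_that("true_n-less sweeps fall back to the empirical mean and say so", {
  pts <- withr::with_seed(10, cbind(runif(250, 0, 500), runif(250, 0, 300)))
  pat <- point_pattern(pts, bounds = c(0, 0, 500, 300))
  mc <- run_sweep(pat, grid_spec(30, 100, offset = c(0, 0)),
                  k_side = 4, seed = 2)
  expect_equal(mc$ce2_reference, "empirical_mean")
  expect_equal(mc$ce2_emp, mc$empirical_var / mc$empirical_mean^2)
})

test_that("quadrat content distribution is a probability table", {
  pat <- generate_pattern(pattern_config("two_density", n_points = 300,
                                         bounds = c(600, 400), seed = 4))
  spec <- grid_spec(t = 60, T = 120, offset = c(0, 0))
  d <- quadrat_content_distribution(pat, spec, k_side = 4, seed = 3)
  expect_equal(sum(d$probability), 1)
  expect_true(all(d$count >= 1))

  # isolated far-apart points with a small quadrat: all mass at count 1
  iso <- point_pattern(cbind(c(50, 250, 450), c(50, 200, 350)),
                       bounds = c(0, 0, 500, 400), true_n = 3)
  d1 <- quadrat_content_distribution(iso, grid_spec(10, 100,
                                                    offset = c(0, 0)),
                                     k_side = 5, seed = 6)
  expect_equal(d1$count, 1L)
  expect_equal(d1$probability, 1)
})

test_that("sweep exports round-trip", {
  pat <- generate_pattern(pattern_config("homogeneous", n_points = 100,
                                         bounds = c(300, 300), seed = 5))
  mc <- run_sweep(pat, grid_spec(50, 150, offset = c(0, 0)),
                  k_side = 2, seed = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(mc, f)
  back <- utils::read.csv(f)
  expect_equal(back$Q_k, mc$replicates$Q_k)
  js <- jsonlite::fromJSON(sweep_to_json(mc))
  expect_equal(js$empirical_mean, mc$empirical_mean)
})
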