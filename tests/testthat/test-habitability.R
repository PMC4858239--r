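test_that("altitude desirability matches its piecewise definition", {
  expect_equal(altitude_desirability(0), 1)
  expect_equal(altitude_desirability(150), 0.65)
  expect_equal(altitude_desirability(300), 0.3)
  expect_equal(altitude_desirability(2100), 0.5)
  expect_equal(altitude_desirability(4100), 0)
  expect_equal(altitude_desirability(-10), 0)
  expect_equal(altitude_desirability(9000), 0)
  expect_error(altitude_desirability(NaN), "finite")

  # continuity at every breakpoint
  eps <- 1e-7
  for (a0 in c(300, 2100, 4100)) {
    expect_lt(abs(altitude_desirability(a0 - eps) -
                  altitude_desirability(a0 + eps)), 1e-8)
  }
})

test_that("local relief equals the 5-cell stencil oracle", {
  flat <- elevation_grid(matrix(120, 6, 6))
  expect_equal(local_relief(flat), matrix(0, 6, 6))

  # worked value: center 100 with four neighbors at 200
  m <- matrix(200, 3, 3)
  m[2, 2] <- 100
  d <- local_relief(elevation_grid(m))
  expect_equal(d[2, 2], abs((100 + 4 * 200) / 5 - 100) / 1000) # 0.08

  # brute-force oracle over the interior of a random low-altitude grid
  set.seed(3)
  m2 <- matrix(stats::runif(25, 0, 280), 5, 5)
  d2 <- local_relief(elevation_grid(m2))
  for (r in 2:4) for (c in 2:4) {
    am <- mean(c(m2[r, c], m2[r - 1, c], m2[r + 1, c], m2[r, c - 1], m2[r, c + 1]))
    expect_equal(d2[r, c], abs(am - m2[r, c]) / 1000)
  }

  # mid-band cells are scaled by 300/A
  m3 <- matrix(1000, 3, 3)
  m3[2, 2] <- 1200
  d3 <- local_relief(elevation_grid(m3))
  a_mean <- (1200 + 4 * 1000) / 5
  expect_equal(d3[2, 2], abs(a_mean - 1200) / 1000 * (300 / 1200))
})

test_that("surface desirability is continuous at L_flat and classifies land", {
  p <- habitability_params()
  expect_equal(surface_desirability(0, p), 1)
  expect_equal(surface_desirability(0.2, p), 0.5) # flat branch at the breakpoint
  expect_equal(p$L_flat / (2 * (p$L_flat + 1e-12)), 0.5, tolerance = 1e-9)
  expect_equal(surface_desirability(0.3, p), 1 / 3)
  expect_equal(surface_desirability(0.6, p), 0)
  expect_error(surface_desirability(-0.1, p), "non-negative")

  expect_equal(surface_class(c(0, 0.2, 0.3, 0.5, 0.51), p),
               c("flat", "flat", "tolerable", "tolerable", "uninhabitable"))

  # non-increasing in d
  d <- seq(0, 1, by = 0.001)
  v <- surface_desirability(d, p)
  expect_true(all(diff(v) <= 1e-12))
  expect_in_unit_interval(v)
})

test_that("water desirability follows the selected distance law", {
  p <- habitability_params()
  expect_equal(water_desirability(1, p), 1)     # direct access below 2 km
  expect_equal(water_desirability(4, p), 0.25)  # (2/4)^2
  expect_equal(water_desirability(12, p), 0)
  expect_equal(water_desirability(Inf, p), 0)

  lin <- habitability_params(water_mode = "linear")
  expect_equal(water_desirability(6, lin), (10 - 6) / 8)

  ext <- habitability_params(water_mode = "extended_range")
  expect_equal(water_desirability(12, ext), (2 / 12)^2)
  expect_equal(water_desirability(21, ext), 0)

  app <- habitability_params(water_mode = "appendix")
  expect_equal(water_desirability(5, app), 1)
  expect_equal(water_desirability(20, app), 20^-0.0435)
  expect_equal(water_desirability(51, app), 0)

  # monotone non-increasing in every mode
  S <- seq(0, 100, by = 0.25)
  for (mode in c("inverse_square", "linear", "extended_range", "appendix")) {
    v <- water_desirability(S, habitability_params(water_mode = mode))
    expect_true(all(diff(v) <= 1e-12))
    expect_in_unit_interval(v)
  }
})

test_that("site rating follows the class case table and rescales per class", {
  p_raw <- habitability_params(rescale_rating = FALSE)
  # flat, good water
  expect_equal(site_rating(0.8, 0.9, 0.7, "flat", p_raw), 0.9^2 * 0.8 * 0.7)
  # tolerable, good water
  expect_equal(site_rating(0.8, 0.4, 0.7, "tolerable", p_raw),
               (0.4 * 0.8 * 0.7)^2)
  # poor water overrides
  expect_equal(site_rating(0.8, 0.9, 0.3, "flat", p_raw), 0.8^2 * 0.9)
  # high land (altitude above 2100 m)
  expect_equal(site_rating(0.4, 0.9, 0.8, "flat", p_raw, altitude = 3000),
               (0.4 * 0.8)^4)
  # uninhabitable rates zero
  expect_equal(site_rating(1, 1, 1, "uninhabitable", p_raw), 0)
  # maximal flat cell stays 1 with and without rescaling
  expect_equal(site_rating(1, 1, 1, "flat", p_raw), 1)

  # rescaled class minima: flat -> 0.5, tolerable -> 0.25
  p <- habitability_params()
  set.seed(5)
  n <- 40
  D_alt <- stats::runif(n, 0.2, 1)
  D_surf <- stats::runif(n, 0.2, 1)
  D_riv <- stats::runif(n, 0.55, 1)
  cls <- rep(c("flat", "tolerable"), each = n / 2)
  r <- site_rating(D_alt, D_surf, D_riv, cls, p)
  expect_equal(min(r[cls == "flat"]), 0.5)
  expect_equal(max(r[cls == "flat"]), 1)
  expect_equal(min(r[cls == "tolerable"]), 0.25)
  expect_equal(max(r[cls == "tolerable"]), 1)
})

test_that("location desirability and optimum population follow their means", {
  p <- habitability_params()
  expect_equal(location_desirability(1, 1, p), 1)
  expect_equal(location_desirability(0.4, 0.8, p), 0.6)
  p1 <- habitability_params(W_flat = 1)
  expect_equal(location_desirability(0.4, 0.8, p1), 0.8)

  expect_equal(optimum_population(1, 1, 1, P_max = 1e7), 1e7)
  expect_equal(optimum_population(0, 0, 0, P_max = 1e7), 0)
  # mean of the location term 0.5*(D_surf + D_alt)/... and the water term
  expect_equal(optimum_population(0, 1, 0.5, P_max = 8),
               8 * 0.5 * ((0.5 * 1 + 0.5 * 0) + 0.5))
  expect_equal(optimum_population(1, 1, 1, P_max = 10, habitable = FALSE), 0)
  expect_error(optimum_population(1, 1, 1, P_max = -1), "positive")
})

test_that("all scored fields stay in [0, 1] on rough synthetic terrain", {
  terr <- make_terrain(terrain_spec("single_island", 30, 30,
                                    ridge_height = 4500, noise_sd = 60,
                                    n_crags = 2, rng_seed = 9L))
  hf <- compute_habitability(terr$elevation, terr$water)
  for (f in c("D_alt", "D_surf", "D_riv", "D_loc", "R_in")) {
    expect_in_unit_interval(hf[[f]])
  }
  expect_true(all(hf$P_best >= 0 & hf$P_best <= hf$P_max))
  # rating and capacity vanish off habitable land
  off <- hf$land_class %in% c("sea", "freshwater", "uninhabitable")
  expect_true(all(hf$R_in[off] == 0))
  expect_true(all(hf$P_best[off] == 0))

  # fuzz the scalar scorers across their full domains
  expect_in_unit_interval(altitude_desirability(seq(-500, 9000, by = 7)))
  expect_in_unit_interval(surface_desirability(seq(0, 5, by = 0.01)))
  expect_in_unit_interval(water_desirability(seq(0, 100, by = 0.1)))
})
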