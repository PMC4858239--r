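test_that("effective rating falls linearly with population and hits zero at 2*P_best", {
  cfg <- sim_config()
  expect_equal(effective_rating(0.8, 0, 1000, cfg), 0.8)          # empty cell
  expect_equal(effective_rating(0.8, 1000, 1000, cfg), 0.4)       # midpoint
  expect_equal(effective_rating(0.8, 2000, 1000, cfg), 0)         # full crowding
  expect_equal(effective_rating(0.8, 5000, 1000, cfg), 0)         # beyond
  expect_equal(effective_rating(0.8, 100, 0, cfg), 0)             # no capacity
  expect_error(effective_rating(0.8, -1, 1000, cfg), "non-negative")

  lit <- sim_config(rating_mode = "literal")
  expect_equal(effective_rating(0.8, 0, 1000, lit), 0.8)
  expect_equal(effective_rating(0.8, 2000, 1000, lit), 0)
  # below capacity the printed feedback *raises* the rating toward 1
  expect_equal(effective_rating(0.8, 500, 1000, lit), 0.8 + 0.2 * 0.5)
  expect_in_unit_interval(effective_rating(
    rep(0.6, 50), seq(0, 3000, length.out = 50), rep(1000, 50), lit
  ))
})

test_that("boundary flux splits by neighbor rating and respects crowding", {
  # symmetric pair: equal ratings, equal populations -> zero net flux
  f <- manual_fields(matrix(0.5, 1, 2), matrix(1e6, 1, 2))
  st <- seed_population(f, seed_spec(c("a", "b"), c(0, 0), c(0, 1), c(500, 500)))
  tot <- rowSums(st$pop, dims = 2L)
  st2 <- step_population(st, f, config = sim_config(birth_rate = 0))
  expect_equal(rowSums(st2$pop, dims = 2L), tot, tolerance = 1e-12)

  # directed split: infinite capacity keeps R = R_in exactly, so the
  # transferred share is mobile_pool * R_b / (R_a + R_b)
  f2 <- manual_fields(matrix(c(0.3, 0.6), 1, 2), matrix(Inf, 1, 2))
  st <- seed_population(f2, seed_spec("a", 0, 0, 1000))
  st2 <- step_population(st, f2, config = sim_config(birth_rate = 0))
  moved <- 0.25 * 1000 * (1 - 0.3) * (0.6 / 0.9)
  expect_equal(unname(st2$pop[1, 2, 1]), moved, tolerance = 1e-12)
  expect_equal(unname(st2$pop[1, 1, 1]), 1000 - moved, tolerance = 1e-12)

  # a crowded neighbor receives nothing and sheds its own population
  f3 <- manual_fields(matrix(c(0.5, 0.5), 1, 2), matrix(c(1e4, 1e4), 1, 2))
  st <- seed_population(f3, seed_spec(c("a", "b"), c(0, 0), c(0, 1), c(100, 2e4)))
  st2 <- step_population(st, f3, config = sim_config(birth_rate = 0))
  expect_equal(sum(st2$pop[1, 2, ]), 2e4 - (sum(st2$pop[1, 1, ]) - 100))
  expect_lt(sum(st2$pop[1, 2, ]), 2e4)          # crowded cell only loses
  expect_equal(unname(st2$pop[1, 2, 1]), 0)     # no inflow of group a
})

test_that("births add g * P * R using the step's rating", {
  f <- manual_fields(matrix(1, 1, 1), matrix(Inf, 1, 1))
  st <- seed_population(f, seed_spec("a", 0, 0, 1000))
  st2 <- step_population(st, f, config = sim_config(birth_rate = 0.1))
  expect_equal(unname(st2$pop[1, 1, 1]), 1100)  # increment 0.1 * 1000 * 1

  f2 <- manual_fields(matrix(0.5, 1, 1), matrix(Inf, 1, 1))
  st <- seed_population(f2, seed_spec("a", 0, 0, 1000))
  st2 <- step_population(st, f2, config = sim_config(birth_rate = 0.1))
  expect_equal(unname(st2$pop[1, 1, 1]), 1050)  # increment 0.1 * 1000 * 0.5

  f3 <- manual_fields(matrix(0, 1, 1), matrix(Inf, 1, 1))
  st <- seed_population(f3, seed_spec("a", 0, 0, 1000))
  # rating 0 cells are not habitable land for seeding purposes, so build the
  # state on a rated field and zero the rating afterwards
  f3$land_class[] <- "flat"
  st <- seed_population(f3, seed_spec("a", 0, 0, 1000))
  st2 <- step_population(st, f3, config = sim_config(birth_rate = 0.1))
  expect_equal(unname(st2$pop[1, 1, 1]), 1000)  # R = 0 -> no births
})

test_that("mass is conserved without births and populations stay non-negative", {
  fx <- scored_fixture("two_valley")
  cfg <- sim_config(birth_rate = 0)
  sim <- run_simulation(fx$fields, fx$seeds, cfg, n_steps = 200)
  tot <- dplyr::summarise(dplyr::group_by(tidy(sim), step),
                          p = sum(population))
  expect_lt(max(abs(tot$p - tot$p[1])) / tot$p[1], 1e-6)
  expect_true(all(sim$final$pop >= 0))
})

test_that("raising a cell's rating strictly raises its one-step inflow", {
  inflow <- function(r3) {
    f <- manual_fields(matrix(c(0.4, 0.5, r3), 1, 3), matrix(Inf, 1, 3))
    st <- seed_population(f, seed_spec("a", 0, 1, 1000))
    st2 <- step_population(st, f, config = sim_config(birth_rate = 0))
    st2$pop[1, 3, 1]
  }
  got <- vapply(c(0.2, 0.4, 0.6, 0.8), inflow, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("sea links join landmasses only across gaps within reach", {
  t10 <- make_terrain(terrain_spec("two_islands", 20, 40, gap_km = 10))
  links <- build_sea_links(classify_cells(t10$elevation, t10$water))
  expect_equal(nrow(links), 1L)
  expect_lt(abs(links$gap_km - 10), 1 + 1e-9) # within one cell of the request

  t40 <- make_terrain(terrain_spec("two_islands", 20, 70, gap_km = 40))
  expect_equal(nrow(build_sea_links(classify_cells(t40$elevation, t40$water))), 0L)

  one <- make_terrain(terrain_spec("uniform_plain", 10, 10))
  expect_equal(nrow(build_sea_links(classify_cells(one$elevation, one$water))), 0L)
})

test_that("seeding conserves the specified totals and rejects bad cells", {
  fx <- scored_fixture("two_valley")
  st <- seed_population(fx$fields, fx$seeds)
  expect_equal(sum(st$pop), sum(fx$seeds$population))
  expect_equal(dimnames(st$pop)[[3]], fx$seeds$group)

  expect_error(seed_population(fx$fields, seed_spec("x", 0, 0, 10)),
               "non-habitable")
  expect_error(seed_population(fx$fields, seed_spec("x", 500, 0, 10)),
               "outside")
  expect_error(seed_spec(c("a", "a"), c(1, 2), c(1, 2)), "unique")

  # the five-entry default keeps the 1e3:1e1:1e1:1e1:1e5 magnitudes
  s5 <- seed_spec(letters[1:5], rep(24, 5), c(5, 10, 24, 35, 44))
  expect_equal(s5$population, c(1e3, 1e1, 1e1, 1e1, 1e5))
})

test_that("mirror-symmetric terrain and seeds give mirror-symmetric states", {
  fx <- scored_fixture("mirror_island")
  n_c <- ncol(fx$fields$R_in)
  # the island construction is symmetric about its vertical axis
  expect_equal(fx$fields$R_in, fx$fields$R_in[, n_c:1])
  seeds <- seed_spec(c("l", "r"), row = c(19, 19), col = c(10, n_c - 11),
                     population = c(1e4, 1e4))
  sim <- suppressWarnings(
    run_simulation(fx$fields, seeds, sim_config(), n_steps = 80)
  )
  pl <- sim$final$pop[, , 1]
  pr <- sim$final$pop[, , 2]
  expect_lt(max(abs(pl - pr[, n_c:1])), 1e-9)
})

test_that("a two-cell system matches an independent scalar iteration", {
  # scalar re-implementation of the same update rule, no matrices involved
  scalar_step <- function(p, ra_in, rb_in, cap, mu, g) {
    Ra <- ra_in * max(0, 1 - p[1] / (2 * cap))
    Rb <- rb_in * max(0, 1 - p[2] / (2 * cap))
    ca <- p[1] >= 2 * cap
    cb <- p[2] >= 2 * cap
    Ma <- mu * p[1] * (1 - Ra)
    Mb <- mu * p[2] * (1 - Rb)
    Wab <- Rb * (1 - cb)
    Wba <- Ra * (1 - ca)
    t_ab <- if (Wab > 0) Ma * Wab / Wab * (Rb / (Ra + Rb)) else 0
    t_ba <- if (Wba > 0) Mb * Wba / Wba * (Ra / (Ra + Rb)) else 0
    p2 <- c(p[1] + t_ba - t_ab, p[2] - t_ba + t_ab)
    if (g > 0) p2 <- p2 + g * p2 * c(Ra, Rb)
    p2
  }

  cap <- 5e4
  f <- manual_fields(matrix(c(0.4, 0.8), 1, 2), matrix(cap, 1, 2))
  cfg0 <- sim_config(birth_rate = 0)
  st <- seed_population(f, seed_spec("a", 0, 0, 2e4))
  p <- c(2e4, 0)
  for (s in 1:400) {
    st <- step_population(st, f, config = cfg0)
    p <- scalar_step(p, 0.4, 0.8, cap, 0.25, 0)
  }
  expect_equal(unname(st$pop[1, , 1]), p, tolerance = 1e-12)
  expect_equal(sum(p), 2e4, tolerance = 1e-12)  # mass conserved en route
  # the relaxed state is a genuine fixed point of the update
  nxt <- step_population(st, f, config = cfg0)
  expect_lt(max(abs(nxt$pop - st$pop)), 1e-8)

  # with births the equivalence holds along the growing trajectory too
  stg <- seed_population(f, seed_spec("a", 0, 0, 2e4))
  cfgg <- sim_config(birth_rate = 0.1)
  pg <- c(2e4, 0)
  for (s in 1:300) {
    stg <- step_population(stg, f, config = cfgg)
    pg <- scalar_step(pg, 0.4, 0.8, cap, 0.25, 0.1)
  }
  expect_equal(unname(stg$pop[1, , 1]), pg, tolerance = 1e-10)
})

test_that("runs snapshot per epoch and are bit-identical on re-run", {
  fx <- scored_fixture("two_valley")
  cfg <- sim_config(steps_per_epoch = 50, n_epochs = 3)
  sim1 <- suppressWarnings(run_simulation(fx$fields, fx$seeds, cfg))
  sim2 <- suppressWarnings(run_simulation(fx$fields, fx$seeds, cfg))
  expect_equal(vapply(sim1$snapshots, `[[`, integer(1), "step"),
               c(0L, 50L, 100L, 150L))
  expect_identical(sim1$snapshots, sim2$snapshots)
  expect_identical(sim1$contacts, sim2$contacts)

  # empty-ish run bookkeeping: a delayed group enters at its start step
  seeds <- seed_spec(c("w", "e"), row = c(24, 24), col = c(15, 35),
                     population = c(1e4, 1e4), start_step = c(0L, 20L))
  sim3 <- run_simulation(fx$fields, seeds, sim_config(birth_rate = 0),
                         n_steps = 30, snapshot_every = 10)
  tot <- tidy(sim3)
  e_before <- tot$population[tot$group == "e" & tot$step == 10]
  e_after <- tot$population[tot$group == "e" & tot$step == 25]
  expect_equal(e_before, 0)
  expect_equal(e_after, 1e4, tolerance = 1e-9)
})

test_that("groups mix in proportion to source-cell composition", {
  f <- manual_fields(matrix(0.5, 1, 3), matrix(Inf, 1, 3))
  st <- seed_population(f, seed_spec(c("a", "b"), c(0, 0), c(1, 1),
                                     population = c(750, 250)))
  st2 <- step_population(st, f, config = sim_config(birth_rate = 0))
  out_left <- st2$pop[1, 1, ]
  expect_gt(sum(out_left), 0)
  expect_equal(unname(out_left[1] / sum(out_left)), 0.75, tolerance = 1e-12)
})
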