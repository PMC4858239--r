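# Shared helpers: hand-built habitability fields for engine unit tests and
# small terrain constructors. Fixture terrains come from make_fixture_suite().

# minimal habitability_fields with prescribed ratings/capacities; every cell
# with P_best > 0 is flat land, the rest sea
manual_fields <- function(R_in, P_best, cell_size_km = 1) {
  stopifnot(identical(dim(R_in), dim(P_best)))
  lc <- matrix("flat", nrow(R_in), ncol(R_in))
  lc[P_best <= 0] <- "sea"
  zero <- R_in * 0
  structure(
    list(
      D_alt = R_in, d_surf = zero, D_surf = R_in, D_loc = R_in,
      D_riv = R_in, land_class = lc, R_in = R_in, P_best = P_best,
      water_distance = zero, params = habitability_params(),
      P_max = 1e7, cell_size_km = cell_size_km,
      altitude = matrix(50, nrow(R_in), ncol(R_in))
    ),
    class = "habitability_fields"
  )
}

# scored fixture cache so expensive habitability runs happen once per file
scored_fixture <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]])) {
      fx <- make_fixture_suite()[[name]]
      cache[[name]] <<- c(
        fx,
        list(fields = suppressWarnings(
          compute_habitability(fx$elevation, fx$water)
        ))
      )
    }
    cache[[name]]
  }
})

expect_in_unit_interval <- function(x) {
  expect_true(all(x >= 0 & x <= 1))
}
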