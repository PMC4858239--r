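#' Simulation configuration
#'
#' All tunables of the diffusion engine. Defaults follow the model's stated
#' values: global ceiling `P_max = 1e7` persons, birth rate `g = 0.1` per
#' step (the documented alternative is 0.001), emigration ceiling
#' `mobility = 0.25` of a cell per step, von Neumann 4-neighborhood, sea
#' crossings possible up to 25 km, and epochs of 500 steps (4 epochs).
#'
#' @param P_max Maximum population anywhere (persons).
#' @param coupling Rating-population coupling constant `C`; used only by the
#'   `"literal"` rating mode.
#' @param birth_rate Per-step birth fraction `g` in `P += g * P * R`.
#' @param mobility Per-step emigration ceiling as a fraction of a cell's
#'   population, in (0, 1].
#' @param neighborhood `"von_neumann4"` (default) or `"moore9"`.
#' @param sea_gap_max Longest crossable sea gap (km).
#' @param rating_mode `"canonical"` (default) or `"literal"` (the printed
#'   piecewise rating feedback, for comparison).
#' @param steps_per_epoch,n_epochs Snapshot cadence and number of epochs.
#' @param rng_seed Seed reserved for synthetic terrain; the engine itself is
#'   deterministic.
#' @param contact_threshold Persons per group per cell that count as
#'   presence when detecting first contact.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(P_max = 1e7, coupling = 1, birth_rate = 0.1,
                       mobility = 0.25,
                       neighborhood = c("von_neumann4", "moore9"),
                       sea_gap_max = 25,
                       rating_mode = c("canonical", "literal"),
                       steps_per_epoch = 500, n_epochs = 4,
                       rng_seed = 1L, contact_threshold = 1) {
  neighborhood <- match.arg(neighborhood)
  rating_mode <- match.arg(rating_mode)
  if (!(mobility > 0 && mobility <= 1)) stop("need 0 < mobility <= 1", call. = FALSE)
  if (birth_rate < 0) stop("birth_rate must be >= 0", call. = FALSE)
  if (sea_gap_max < 0) stop("sea_gap_max must be >= 0", call. = FALSE)
  if (P_max <= 0) stop("P_max must be > 0", call. = FALSE)
  if (steps_per_epoch < 1 || n_epochs < 0) {
    stop("need steps_per_epoch >= 1 and n_epochs >= 0", call. = FALSE)
  }
  structure(
    list(P_max = P_max, coupling = coupling, birth_rate = birth_rate,
         mobility = mobility, neighborhood = neighborhood,
         sea_gap_max = sea_gap_max, rating_mode = rating_mode,
         steps_per_epoch = as.integer(steps_per_epoch),
         n_epochs = as.integer(n_epochs),
         rng_seed = as.integer(rng_seed),
         contact_threshold = contact_threshold),
    class = "sim_config"
  )
}

neighbor_offsets <- function(neighborhood) {
  four <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (neighborhood == "von_neumann4") return(four)
  c(four, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
}

#' Seeding specification
#'
#' Builds the tibble of entry points: one row per group with its entry cell
#' and initial population. When five groups are given and no populations, the
#' default magnitudes are the five-entry ratio `1e3 : 1e1 : 1e1 : 1e1 : 1e5`
#' (groups in the order supplied); otherwise the default is 1000 persons.
#'
#' @param group Character vector of group labels (unique).
#' @param row,col 0-based cell coordinates of each entry point.
#' @param population Initial populations (> 0); see default above.
#' @param start_step Step at which each group enters (default 0).
#' @return A tibble with class `seed_spec`.
#' @examples
#' seed_spec(c("west", "east"), row = c(0, 0), col = c(0, 20),
#'           population = c(1e5, 1e3))
#' @export
seed_spec <- function(group, row, col, population = NULL, start_step = 0L) {
  group <- as.character(group)
  if (anyDuplicated(group)) stop("group labels must be unique", call. = FALSE)
  n <- length(group)
  if (length(row) != n || length(col) != n) {
    stop("`row` and `col` must match the number of groups", call. = FALSE)
  }
  if (is.null(population)) {
    population <- if (n == 5L) c(1e3, 1e1, 1e1, 1e1, 1e5) else rep(1000, n)
  }
  if (any(population <= 0)) stop("initial populations must be > 0", call. = FALSE)
  out <- tibble::tibble(
    group = group,
    row = as.integer(row),
    col = as.integer(col),
    population = as.numeric(population),
    start_step = as.integer(rep_len(start_step, n))
  )
  class(out) <- c("seed_spec", class(out))
  out
}

#' Initialize a population state from seeds
#'
#' Places each group's initial population on its entry cell. Entry cells must
#' be habitable land (`flat` or `tolerable`); seeding on sea, freshwater or
#' uninhabitable cells is a configuration error.
#'
#' @param fields [compute_habitability()] output.
#' @param seeds A [seed_spec()] tibble.
#' @return A `population_state`: per-group population array plus bookkeeping.
#' @export
seed_population <- function(fields, seeds) {
  stopifnot(inherits(fields, "habitability_fields"))
  seeds <- validate_seeds(fields, seeds)
  n_r <- nrow(fields$R_in)
  n_c <- ncol(fields$R_in)
  pop <- array(0, dim = c(n_r, n_c, nrow(seeds)),
               dimnames = list(NULL, NULL, seeds$group))
  for (k in seq_len(nrow(seeds))) {
    if (seeds$start_step[k] == 0L) {
      pop[seeds$row[k] + 1L, seeds$col[k] + 1L, k] <-
        pop[seeds$row[k] + 1L, seeds$col[k] + 1L, k] + seeds$population[k]
    }
  }
  structure(
    list(pop = pop, groups = seeds$group, step = 0L),
    class = "population_state"
  )
}

validate_seeds <- function(fields, seeds) {
  if (!inherits(seeds, "seed_spec")) {
    seeds <- seed_spec(seeds$group, seeds$row, seeds$col,
                       seeds$population,
                       if (!is.null(seeds$start_step)) seeds$start_step else 0L)
  }
  n_r <- nrow(fields$R_in)
  n_c <- ncol(fields$R_in)
  for (k in seq_len(nrow(seeds))) {
    r <- seeds$row[k] + 1L
    c <- seeds$col[k] + 1L
    if (r < 1L || r > n_r || c < 1L || c > n_c) {
      stop(sprintf("seed '%s' lies outside the grid", seeds$group[k]),
           call. = FALSE)
    }
    cl <- fields$land_class[r, c]
    if (!cl %in% c("flat", "tolerable")) {
      stop(sprintf("seed '%s' placed on non-habitable cell (%d, %d): %s",
                   seeds$group[k], seeds$row[k], seeds$col[k], cl),
           call. = FALSE)
    }
  }
  seeds
}

#' Population-dependent effective rating
#'
#' Canonical mode: `R(P) = R_in * max(0, 1 - P / (2 P_best))`, so the rating
#' equals `R_in` on empty cells, halves at `P = P_best` and reaches 0 at
#' twice the carrying capacity. Literal mode reproduces the printed
#' piecewise feedback (`S1 = (1 - R_in) / P_best`, `S2 = R_in / P_best`):
#' `R = R_in + S1 * P` below `P_best`, `(P - 2 P_best) * S2` clamped into
#' \[0, 1\] between `P_best` and `2 P_best`, and 0 beyond. In both modes
#' `R = 0` wherever `P_best = 0`.
#'
#' @param R_in Population-independent rating field.
#' @param P Current total population field (persons).
#' @param P_best Carrying-capacity field (persons).
#' @param config [sim_config()].
#' @return Effective rating field in \[0, 1\].
#' @export
effective_rating <- function(R_in, P, P_best, config = sim_config()) {
  if (any(P < 0) || any(R_in < 0) || any(P_best < 0)) {
    stop("effective_rating inputs must be non-negative", call. = FALSE)
  }
  if (config$rating_mode == "canonical") {
    R <- R_in * pmax(0, 1 - P / (2 * pmax(P_best, .Machine$double.xmin)))
  } else {
    S1 <- (1 - R_in) / pmax(P_best, .Machine$double.xmin)
    S2 <- R_in / pmax(P_best, .Machine$double.xmin)
    R <- ifelse(P < P_best, R_in + S1 * P, (P - 2 * P_best) * S2)
    R <- pmin(pmax(R, 0), 1)
    R[P >= 2 * P_best] <- 0
  }
  R[P_best <= 0] <- 0
  R
}

#' Sea links between landmasses
#'
#' Finds, for every pair of land connected-components (4-connectivity;
#' freshwater counts as part of the landmass, nodata as sea), the pair of
#' coastal land cells with the smallest sea gap, and keeps the link iff the
#' gap does not exceed `sea_gap_max`. The gap is the center-to-center
#' Euclidean distance minus one cell, i.e. the width of sea actually spanned.
#' During simulation each link behaves as an extra boundary whose flux is
#' damped by `cell_size / gap_km`.
#'
#' @param cls Classification matrix ([classify_cells()] labels, or the
#'   5-level `land_class` of [compute_habitability()]).
#' @param config [sim_config()] (uses `sea_gap_max`).
#' @param cell_size_km Cell size in km.
#' @return A tibble with class `sea_link_set`: rows `(row_a, col_a, row_b,
#'   col_b, gap_km)` (0-based coordinates), one per unordered component pair.
#' @export
build_sea_links <- function(cls, config = sim_config(), cell_size_km = 1) {
  land <- matrix(cls %in% c("land", "flat", "tolerable", "uninhabitable",
                            "freshwater"),
                 nrow(cls), ncol(cls))
  comp <- label_components(land)
  n_comp <- max(comp)
  empty <- tibble::tibble(row_a = integer(), col_a = integer(),
                          row_b = integer(), col_b = integer(),
                          gap_km = numeric())
  class(empty) <- c("sea_link_set", class(empty))
  if (n_comp < 2L) return(empty)
  sea <- !land
  coastal <- land & (
    neighbor_value(sea, -1L, 0L, fill = TRUE) |
    neighbor_value(sea, 1L, 0L, fill = TRUE) |
    neighbor_value(sea, 0L, -1L, fill = TRUE) |
    neighbor_value(sea, 0L, 1L, fill = TRUE)
  )
  # link endpoints must be populable land, not freshwater
  populable <- coastal & matrix(!(cls %in% "freshwater"), nrow(cls), ncol(cls))
  links <- empty
  for (a in seq_len(n_comp - 1L)) {
    ia <- which(comp == a & populable, arr.ind = TRUE)
    if (nrow(ia) == 0L) next
    for (b in (a + 1L):n_comp) {
      ib <- which(comp == b & populable, arr.ind = TRUE)
      if (nrow(ib) == 0L) next
      d2 <- outer(ia[, 1], ib[, 1], `-`)^2 + outer(ia[, 2], ib[, 2], `-`)^2
      k <- arrayInd(which.min(d2), dim(d2))
      gap <- (sqrt(min(d2)) - 1) * cell_size_km
      if (gap > 0 && gap <= config$sea_gap_max) {
        links <- dplyr::bind_rows(links, tibble::tibble(
          row_a = ia[k[1], 1] - 1L, col_a = ia[k[1], 2] - 1L,
          row_b = ib[k[2], 1] - 1L, col_b = ib[k[2], 2] - 1L,
          gap_km = gap
        ))
      }
    }
  }
  class(links) <- c("sea_link_set", class(links))
  links
}

# 4-connected component labels of a logical mask (0 outside the mask)
label_components <- function(mask) {
  n_r <- nrow(mask)
  n_c <- ncol(mask)
  comp <- matrix(0L, n_r, n_c)
  lab <- 0L
  todo <- which(mask & comp == 0L)
  while (length(todo)) {
    lab <- lab + 1L
    frontier <- todo[1]
    comp[frontier] <- lab
    while (length(frontier)) {
      r <- (frontier - 1L) %% n_r + 1L
      c <- (frontier - 1L) %/% n_r + 1L
      nxt <- integer(0)
      for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + off[1]
        cc <- c + off[2]
        ok <- rr >= 1L & rr <= n_r & cc >= 1L & cc <= n_c
        if (!any(ok)) next
        idx <- (cc[ok] - 1L) * n_r + rr[ok]
        idx <- idx[mask[idx] & comp[idx] == 0L]
        if (length(idx)) {
          comp[idx] <- lab
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
    todo <- which(mask & comp == 0L)
  }
  comp
}

# one synchronous engine step; pop is the [rows, cols, groups] array
engine_step <- function(pop, fields, config, link_idx, step_index) {
  n_r <- dim(pop)[1]
  n_c <- dim(pop)[2]
  n_g <- dim(pop)[3]
  P <- rowSums(pop, dims = 2L)
  R_in <- fields$R_in
  P_best <- fields$P_best
  R <- effective_rating(R_in, P, P_best, config)
  crowded <- P_best > 0 & P >= 2 * P_best
  M <- config$mobility * P * (1 - R)

  offs <- neighbor_offsets(config$neighborhood)
  W <- vector("list", length(offs))
  Rn <- vector("list", length(offs))
  D <- matrix(0, n_r, n_c)
  for (d in seq_along(offs)) {
    o <- offs[[d]]
    Rn[[d]] <- neighbor_value(R, o[1], o[2], fill = 0)
    open <- 1 - neighbor_value(crowded * 1, o[1], o[2], fill = 1)
    W[[d]] <- Rn[[d]] * open
    D <- D + W[[d]]
  }
  if (nrow(link_idx)) {
    for (l in seq_len(nrow(link_idx))) {
      a <- link_idx$a[l]
      b <- link_idx$b[l]
      D[a] <- D[a] + R[b] * (!crowded[b])
    }
  }

  frac <- array(0, dim = dim(pop))
  pos <- P > 0
  for (g in seq_len(n_g)) {
    fg <- matrix(0, n_r, n_c)
    fg[pos] <- pop[, , g][pos] / P[pos]
    frac[, , g] <- fg
  }

  new_pop <- pop
  safeD <- ifelse(D > 0, D, 1)
  for (d in seq_along(offs)) {
    o <- offs[[d]]
    B <- ifelse(D > 0, M * W[[d]] / safeD, 0)
    denom <- R + Rn[[d]]
    Fin <- ifelse(denom > 0, Rn[[d]] / denom, 0)
    Td <- B * Fin
    for (g in seq_len(n_g)) {
      send <- Td * frac[, , g]
      new_pop[, , g] <- new_pop[, , g] - send + shift_mat(send, o[1], o[2], fill = 0)
    }
  }
  if (nrow(link_idx)) {
    for (l in seq_len(nrow(link_idx))) {
      a <- link_idx$a[l]
      b <- link_idx$b[l]
      if (D[a] <= 0 || crowded[b]) next
      B <- M[a] * R[b] / D[a]
      Fin <- if (R[a] + R[b] > 0) R[b] / (R[a] + R[b]) else 0
      Tl <- B * Fin * link_idx$damp[l]
      if (Tl <= 0) next
      for (g in seq_len(n_g)) {
        send <- Tl * frac[a + (g - 1L) * n_r * n_c]
        new_pop[a + (g - 1L) * n_r * n_c] <- new_pop[a + (g - 1L) * n_r * n_c] - send
        new_pop[b + (g - 1L) * n_r * n_c] <- new_pop[b + (g - 1L) * n_r * n_c] + send
      }
    }
  }

  clamped <- FALSE
  if (config$birth_rate > 0) {
    pre <- new_pop
    pre_tot <- rowSums(pre, dims = 2L)
    inc_tot <- matrix(0, n_r, n_c)
    for (g in seq_len(n_g)) {
      inc_tot <- inc_tot + config$birth_rate * pre[, , g] * R
    }
    over <- pre_tot + inc_tot > config$P_max & inc_tot > 0
    scale <- matrix(1, n_r, n_c)
    if (any(over)) {
      clamped <- TRUE
      scale[over] <- pmax(0, config$P_max - pre_tot[over]) / inc_tot[over]
    }
    for (g in seq_len(n_g)) {
      new_pop[, , g] <- pre[, , g] + config$birth_rate * pre[, , g] * R * scale
    }
  }

  tiny_neg <- new_pop < 0 & new_pop > -1e-9
  new_pop[tiny_neg] <- 0
  if (any(!is.finite(new_pop)) || any(new_pop < 0)) {
    stop(sprintf("population state corrupted at step %d (negative or non-finite)",
                 step_index), call. = FALSE)
  }
  list(pop = new_pop, clamped = clamped)
}

link_index <- function(links, n_r, n_c, cell_size_km) {
  if (is.null(links) || nrow(links) == 0L) {
    return(tibble::tibble(a = integer(), b = integer(), damp = numeric()))
  }
  a <- (links$col_a) * n_r + links$row_a + 1L
  b <- (links$col_b) * n_r + links$row_b + 1L
  damp <- cell_size_km / links$gap_km
  # both directions: a sea link is symmetric
  src <- c(a, b)
  dst <- c(b, a)
  tibble::tibble(a = src, b = dst, damp = c(damp, damp))
}

#' Advance a population state by one step
#'
#' Order within a step: (1) effective ratings from the pre-step state;
#' (2) boundary fluxes computed from the pre-step state and applied
#' synchronously (including sea links); (3) births `P += g * P * R`;
#' (4) overcrowding clamp of the birth increment at `P_max`. With
#' `birth_rate = 0` the step conserves total population exactly.
#'
#' @param state A `population_state` from [seed_population()].
#' @param fields [compute_habitability()] output.
#' @param links Optional [build_sea_links()] tibble.
#' @param config [sim_config()].
#' @return The advanced `population_state`.
#' @export
step_population <- function(state, fields, links = NULL,
                            config = sim_config()) {
  stopifnot(inherits(state, "population_state"))
  li <- link_index(links, dim(state$pop)[1], dim(state$pop)[2],
                   fields$cell_size_km)
  res <- engine_step(state$pop, fields, config, li, state$step + 1L)
  state$pop <- res$pop
  state$step <- state$step + 1L
  state
}

#' Run the full simulation
#'
#' Seeds the groups, builds sea links, and advances the state for
#' `n_epochs * steps_per_epoch` steps, snapshotting every `snapshot_every`
#' steps (default: every epoch). First contacts between groups are recorded
#' online at `config$contact_threshold`. The engine has no stochastic terms,
#' so re-running an identical configuration reproduces the trajectory
#' bit-identically.
#'
#' @param fields [compute_habitability()] output.
#' @param seeds A [seed_spec()] tibble.
#' @param config [sim_config()].
#' @param links Sea links; computed from the fields' classification when
#'   `NULL`.
#' @param snapshot_every Steps between stored snapshots (default
#'   `config$steps_per_epoch`).
#' @param n_steps Total steps (default `n_epochs * steps_per_epoch`).
#' @return A `migration_sim` object: `snapshots` (list of `step` +
#'   per-group population arrays), `totals` (tibble of per-step per-group
#'   totals), `contacts` (first-contact step matrix, `Inf` = never),
#'   `final`, `config`, `seeds`, `links`, `groups`.
#' @examples
#' terr <- make_terrain(terrain_spec("uniform_plain", 10, 21))
#' hf <- compute_habitability(terr$elevation, terr$water)
#' seeds <- seed_spec(c("w", "e"), row = c(5, 5), col = c(1, 19),
#'                    population = c(1e4, 1e4))
#' sim <- run_simulation(hf, seeds, sim_config(steps_per_epoch = 10, n_epochs = 2))
#' glance(sim)
#' @export
run_simulation <- function(fields, seeds, config = sim_config(),
                           links = NULL, snapshot_every = NULL,
                           n_steps = NULL) {
  stopifnot(inherits(fields, "habitability_fields"))
  seeds <- validate_seeds(fields, seeds)
  if (is.null(links)) links <- build_sea_links(fields$land_class, config,
                                               fields$cell_size_km)
  if (is.null(snapshot_every)) snapshot_every <- config$steps_per_epoch
  if (is.null(n_steps)) n_steps <- config$steps_per_epoch * config$n_epochs
  state <- seed_population(fields, seeds)
  n_r <- dim(state$pop)[1]
  n_c <- dim(state$pop)[2]
  n_g <- dim(state$pop)[3]
  li <- link_index(links, n_r, n_c, fields$cell_size_km)

  contacts <- matrix(Inf, n_g, n_g, dimnames = list(seeds$group, seeds$group))
  diag(contacts) <- 0
  totals <- matrix(NA_real_, n_steps + 1L, n_g)
  colnames(totals) <- seeds$group
  snapshots <- list()
  record <- function(step, pop) {
    snapshots[[length(snapshots) + 1L]] <<- list(step = step, pop = pop)
  }
  update_contacts <- function(step, pop) {
    if (n_g < 2L) return()
    occ <- pop >= config$contact_threshold
    for (g in seq_len(n_g - 1L)) {
      for (h in (g + 1L):n_g) {
        if (is.infinite(contacts[g, h]) && any(occ[, , g] & occ[, , h])) {
          contacts[g, h] <<- step
          contacts[h, g] <<- step
        }
      }
    }
  }
  totals[1L, ] <- colSums(state$pop, dims = 2L)
  record(0L, state$pop)
  update_contacts(0L, state$pop)
  n_clamped <- 0L
  pending <- seeds[seeds$start_step > 0L, , drop = FALSE]
  for (s in seq_len(n_steps)) {
    if (nrow(pending)) {
      due <- pending$start_step == s
      for (k in which(due)) {
        g <- match(pending$group[k], seeds$group)
        state$pop[pending$row[k] + 1L, pending$col[k] + 1L, g] <-
          state$pop[pending$row[k] + 1L, pending$col[k] + 1L, g] +
          pending$population[k]
      }
      pending <- pending[!due, , drop = FALSE]
    }
    res <- engine_step(state$pop, fields, config, li, s)
    state$pop <- res$pop
    state$step <- s
    if (res$clamped) n_clamped <- n_clamped + 1L
    totals[s + 1L, ] <- colSums(state$pop, dims = 2L)
    update_contacts(s, state$pop)
    if (s %% snapshot_every == 0L) record(s, state$pop)
  }
  if (n_clamped > 0L) {
    warning(sprintf("birth increment clamped at P_max in %d step(s)", n_clamped),
            call. = FALSE)
  }
  totals_tbl <- tibble::as_tibble(totals)
  totals_tbl$step <- 0:n_steps
  totals_tbl <- tidyr::pivot_longer(totals_tbl, -"step",
                                    names_to = "group", values_to = "population")
  structure(
    list(
      snapshots = snapshots, totals = totals_tbl, contacts = contacts,
      final = state, config = config, seeds = seeds, links = links,
      groups = seeds$group, fields = fields, n_steps = n_steps,
      snapshot_every = snapshot_every
    ),
    class = "migration_sim"
  )
}

#' @export
print.migration_sim <- function(x, ...) {
  cat(sprintf(
    "<migration_sim> %d groups, %d steps, %d snapshots, total population %.4g\n",
    length(x$groups), x$n_steps, length(x$snapshots),
    sum(x$final$pop)
  ))
  invisible(x)
}

#' Tidy a simulation trajectory
#'
#' @param x A `migration_sim`.
#' @param ... Unused.
#' @return Tibble of per-step, per-group population totals
#'   (`step`, `group`, `population`).
#' @method tidy migration_sim
#' @export
tidy.migration_sim <- function(x, ...) x$totals

#' One-row summary of a simulation
#'
#' @param x A `migration_sim`.
#' @param ... Unused.
#' @return A one-row tibble: steps run, groups, final total population,
#'   occupied cells (total population >= 1) and contacted pairs.
#' @method glance migration_sim
#' @export
glance.migration_sim <- function(x, ...) {
  n_g <- length(x$groups)
  P <- rowSums(x$final$pop, dims = 2L)
  tibble::tibble(
    n_steps = x$n_steps,
    n_groups = n_g,
    total_population = sum(P),
    occupied_cells = sum(P >= 1),
    contacted_pairs = if (n_g > 1) sum(is.finite(x$contacts[upper.tri(x$contacts)]))
                      else 0L
  )
}

#' @rdname tidy.migration_sim
#' @param object A `migration_sim`.
#' @param type `"totals"` (per-step totals curve) or `"map"` (final
#'   per-group population map).
#' @method autoplot migration_sim
#' @export
autoplot.migration_sim <- function(object, type = c("totals", "map"), ...) {
  type <- match.arg(type)
  if (type == "totals") {
    return(
      ggplot2::ggplot(object$totals,
                      ggplot2::aes(x = .data$step, y = .data$population,
                                   color = .data$group)) +
        ggplot2::geom_line() +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = "step", y = "population")
    )
  }
  dfs <- lapply(seq_along(object$groups), function(g) {
    d <- grid_to_tibble(object$final$pop[, , g], "population")
    d$group <- object$groups[g]
    d
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$population)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = "log1p") +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "col", y = "row (north up)")
}
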