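#' Habitability scoring parameters
#'
#' Tunables of the terrain-scoring stage. `L_flat` and `L_tol` are the relief
#' thresholds separating flat, tolerable and uninhabitable surfaces; `r_full`
#' and `r_max` bound direct water access (km); `water_mode` selects the
#' distance-to-water law; `rescale_rating` maps raw site ratings onto the
#' per-class ranges \[0.5, 1\] (flat) and \[0.25, 1\] (tolerable).
#'
#' @param L_flat Relief threshold below which land is flat (default 0.2).
#' @param L_tol Relief threshold above which land is uninhabitable (default 0.5).
#' @param W_flat Weight of `D_surf` in the diagnostic `D_loc` (default 0.5).
#' @param r_full Distance (km) within which water is freely accessed (default 2).
#' @param r_max Maximum practical distance (km) to water (default 10).
#' @param water_mode One of `"inverse_square"`, `"linear"`,
#'   `"extended_range"`, `"appendix"`.
#' @param rescale_rating Rescale ratings per land class (default `TRUE`).
#' @return A list of class `habitability_params`.
#' @export
habitability_params <- function(L_flat = 0.2, L_tol = 0.5, W_flat = 0.5,
                                r_full = 2, r_max = 10,
                                water_mode = c("inverse_square", "linear",
                                               "extended_range", "appendix"),
                                rescale_rating = TRUE) {
  water_mode <- match.arg(water_mode)
  if (!(L_flat > 0 && L_flat < L_tol && L_tol <= 1)) {
    stop("need 0 < L_flat < L_tol <= 1", call. = FALSE)
  }
  if (!(r_full > 0 && r_full < r_max)) {
    stop("need 0 < r_full < r_max", call. = FALSE)
  }
  structure(
    list(L_flat = L_flat, L_tol = L_tol, W_flat = W_flat,
         r_full = r_full, r_max = r_max, water_mode = water_mode,
         rescale_rating = isTRUE(rescale_rating)),
    class = "habitability_params"
  )
}

#' Desirability as a function of altitude
#'
#' Piecewise score of altitude `A` (m): 0 below sea level; a steep linear
#' fall from 1 at sea level to 0.3 at 300 m; a slow rise to 0.5 at 2100 m; a
#' linear fall to 0 at 4100 m; 0 above. Continuous at 300, 2100 and 4100 m.
#'
#' @param A Altitude(s) in meters; vector or matrix, finite.
#' @return Values in \[0, 1\], same shape as `A`.
#' @examples
#' altitude_desirability(c(0, 150, 300, 2100, 4100))
#' @export
altitude_desirability <- function(A) {
  if (any(!is.finite(A))) stop("altitude must be finite", call. = FALSE)
  out <- A
  out[] <- 0
  i <- A >= 0 & A <= 300
  out[i] <- (1000 - (7 / 3) * A[i]) / 1000
  i <- A > 300 & A <= 2100
  out[i] <- ((A[i] - 300) / 9 + 300) / 1000
  i <- A > 2100 & A <= 4100
  out[i] <- (4100 - A[i]) / 4000
  out
}

#' Local relief
#'
#' Mean altitude `A_mean` over the von Neumann 5-cell stencil (center plus
#' the four edge neighbors), excluding sea and nodata neighbors from the
#' mean; border cells use the stencil members that exist. The relief is
#' `d_surf = |A_mean - A| / 1000` for `A <= 300`, the same quantity scaled by
#' `300 / A` for `300 < A <= 4100`, and 0 above 4100 m (and on sea/nodata).
#'
#' @param elev An [elevation_grid()].
#' @param exclude Optional logical matrix of cells to drop from neighbor
#'   means (defaults to sea/nodata: `A < 0` or `NA`).
#' @return Numeric matrix of dimensionless relief values.
#' @export
local_relief <- function(elev, exclude = NULL) {
  stopifnot(inherits(elev, "elevation_grid"))
  a <- elev$altitude
  if (is.null(exclude)) exclude <- is.na(a) | a < 0
  stop_if_shape_mismatch(a, exclude, "exclude mask")
  valid <- (!is.na(a)) & (!exclude)
  av <- ifelse(valid, a, 0)
  vn <- matrix(as.numeric(valid), nrow(a), ncol(a))
  s <- av
  n <- vn
  for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    s <- s + neighbor_value(av, off[1], off[2], fill = 0)
    n <- n + neighbor_value(vn, off[1], off[2], fill = 0)
  }
  a_mean <- ifelse(n > 0, s / n, 0)
  d <- abs(a_mean - ifelse(is.na(a), 0, a)) / 1000
  mid <- !is.na(a) & a > 300 & a <= 4100
  d[mid] <- d[mid] * (300 / a[mid])
  d[!valid] <- 0
  d[!is.na(a) & a > 4100] <- 0
  d
}

#' Desirability as a function of surface relief
#'
#' `d <= L_flat` scores `1 - d / (2 L_flat)` (flat); `L_flat < d <= L_tol`
#' scores `L_flat / (2 d)` (tolerable); above `L_tol` the land is
#' uninhabitable and scores 0. Both flat and tolerable pieces give 0.5 at
#' `d = L_flat`.
#'
#' @param d Non-negative relief value(s) from [local_relief()].
#' @param params [habitability_params()].
#' @return Values in \[0, 1\], same shape as `d`.
#' @seealso [surface_class()] for the matching land classification.
#' @export
surface_desirability <- function(d, params = habitability_params()) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("relief must be finite and non-negative", call. = FALSE)
  }
  out <- d
  out[] <- 0
  i <- d <= params$L_flat
  out[i] <- 1 - d[i] / (2 * params$L_flat)
  i <- d > params$L_flat & d <= params$L_tol
  out[i] <- params$L_flat / (2 * d[i])
  out
}

#' Land class from surface relief
#'
#' @inheritParams surface_desirability
#' @return Character vector/matrix with entries `"flat"`, `"tolerable"`,
#'   `"uninhabitable"`.
#' @export
surface_class <- function(d, params = habitability_params()) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("relief must be finite and non-negative", call. = FALSE)
  }
  out <- ifelse(d <= params$L_flat, "flat",
                ifelse(d <= params$L_tol, "tolerable", "uninhabitable"))
  if (is.matrix(d)) out <- matrix(out, nrow(d), ncol(d))
  out
}

#' Desirability as a function of distance to water
#'
#' Default `inverse_square` mode: free access (`1`) within `r_full` km, an
#' inverse-square fall `(r_full / S)^2` out to `r_max` km, 0 beyond. `linear`
#' replaces the middle piece by the ramp `(r_max - S) / (r_max - r_full)`;
#' `extended_range` doubles `r_max`; `appendix` uses the alternative
#' constants `R = 10`, `R_m = 50` cells with middle piece `S^-0.0435`.
#'
#' @param S Distance(s) to nearest freshwater, km; `Inf` allowed (scores 0).
#' @param params [habitability_params()].
#' @return Values in \[0, 1\], same shape as `S`.
#' @export
water_desirability <- function(S, params = habitability_params()) {
  if (anyNA(S) || any(S < 0)) {
    stop("distance to water must be non-negative and not NA", call. = FALSE)
  }
  out <- S
  out[] <- 0
  mode <- params$water_mode
  r_full <- params$r_full
  r_max <- if (mode == "extended_range") 2 * params$r_max else params$r_max
  if (mode == "appendix") {
    r_full <- 10
    r_max <- 50
  }
  out[S <= r_full] <- 1
  mid <- S > r_full & S <= r_max
  out[mid] <- switch(mode,
    inverse_square = ,
    extended_range = (r_full / S[mid])^2,
    linear         = (r_max - S[mid]) / (r_max - r_full),
    appendix       = S[mid]^-0.0435
  )
  out
}

#' Diagnostic location desirability
#'
#' Linear combination `D_loc = W_flat * D_surf + (1 - W_flat) * D_alt`.
#' Diagnostic only: the canonical site rating uses the case table of
#' [site_rating()].
#'
#' @param D_alt,D_surf Desirabilities in \[0, 1\].
#' @param params [habitability_params()].
#' @return Values in \[0, 1\].
#' @export
location_desirability <- function(D_alt, D_surf, params = habitability_params()) {
  params$W_flat * D_surf + (1 - params$W_flat) * D_alt
}

#' Population-independent site rating
#'
#' Raw rating by land class and water supply:
#' \itemize{
#'   \item uninhabitable (or sea/freshwater): 0
#'   \item poor water (`D_riv <= 0.5`): `D_alt^2 * D_surf`
#'   \item high land (altitude above 2100 m, when `altitude` is supplied):
#'     `(D_alt * D_riv)^4`
#'   \item flat with good water: `D_surf^2 * D_alt * D_riv`
#'   \item tolerable with good water: `(D_surf * D_alt * D_riv)^2`
#' }
#' With `rescale_rating`, raw ratings are affinely mapped per land class onto
#' \[0.5, 1\] (flat) and \[0.25, 1\] (tolerable), using the class-wise
#' min/max over habitable cells of the supplied field; a constant class maps
#' to 1.
#'
#' @param D_alt,D_surf,D_riv Desirability fields in \[0, 1\] (same shape).
#' @param land_class Character field: `"flat"`, `"tolerable"`,
#'   `"uninhabitable"` (entries `"sea"`/`"freshwater"` also rate 0).
#' @param params [habitability_params()].
#' @param altitude Optional altitude field (m) enabling the high-land case.
#' @return Rating field `R_in` in \[0, 1\].
#' @export
site_rating <- function(D_alt, D_surf, D_riv, land_class,
                        params = habitability_params(), altitude = NULL) {
  habitable <- land_class %in% c("flat", "tolerable")
  if (is.matrix(D_alt)) dim(habitable) <- dim(D_alt)
  r <- D_alt
  r[] <- 0
  poor <- habitable & D_riv <= 0.5
  r[poor] <- D_alt[poor]^2 * D_surf[poor]
  good <- habitable & D_riv > 0.5
  if (!is.null(altitude)) {
    high <- good & !is.na(altitude) & altitude > 2100
    r[high] <- (D_alt[high] * D_riv[high])^4
    good <- good & !high
  }
  fl <- good & land_class == "flat"
  r[fl] <- D_surf[fl]^2 * D_alt[fl] * D_riv[fl]
  tl <- good & land_class == "tolerable"
  r[tl] <- (D_surf[tl] * D_alt[tl] * D_riv[tl])^2
  if (params$rescale_rating) {
    r <- rescale_rating_class(r, habitable & land_class == "flat", 0.5)
    r <- rescale_rating_class(r, habitable & land_class == "tolerable", 0.25)
  }
  r
}

# affine map of the ratings under `mask` onto [lo, 1]; constant class -> 1
rescale_rating_class <- function(r, mask, lo) {
  v <- r[mask]
  if (!length(v)) return(r)
  rng <- range(v)
  if (diff(rng) < 1e-12) {
    r[mask] <- 1
  } else {
    r[mask] <- lo + (v - rng[1]) / diff(rng) * (1 - lo)
  }
  r
}

#' Optimum (carrying-capacity) population of a cell
#'
#' Arithmetic mean of a location-based optimum `P_max * (0.5 D_surf +
#' 0.5 D_alt)` and a water-based optimum `P_max * D_riv`; zero on
#' non-habitable cells.
#'
#' @param D_alt,D_surf,D_riv Desirability fields in \[0, 1\].
#' @param P_max Global population ceiling (persons, default 1e7).
#' @param habitable Optional logical field; non-habitable cells get 0.
#' @return `P_best` in persons.
#' @export
optimum_population <- function(D_alt, D_surf, D_riv, P_max = 1e7,
                               habitable = NULL) {
  if (!is.numeric(P_max) || P_max <= 0) stop("P_max must be positive", call. = FALSE)
  p <- P_max * 0.5 * ((0.5 * D_surf + 0.5 * D_alt) + D_riv)
  if (!is.null(habitable)) p[!habitable] <- 0
  p
}

#' Score a terrain: all habitability fields at once
#'
#' Runs the full scoring pipeline on an elevation grid and freshwater mask:
#' classification, distance to water, the four desirability fields, land
#' classes, the site rating `R_in` and the carrying capacity `P_best`.
#'
#' @param elev An [elevation_grid()].
#' @param water Logical freshwater-source matrix, same shape.
#' @param params [habitability_params()].
#' @param P_max Global population ceiling (persons).
#' @return An object of class `habitability_fields`: a list of per-cell
#'   matrices `D_alt`, `d_surf`, `D_surf`, `D_loc`, `D_riv`, `R_in`,
#'   `P_best`, `water_distance`, plus `land_class` (one of `"flat"`,
#'   `"tolerable"`, `"uninhabitable"`, `"sea"`, `"freshwater"`), the
#'   parameters and the cell size.
#' @examples
#' terr <- make_terrain(terrain_spec("uniform_plain", 12, 12))
#' hf <- compute_habitability(terr$elevation, terr$water)
#' summary(hf)
#' @export
compute_habitability <- function(elev, water, params = habitability_params(),
                                 P_max = 1e7) {
  stopifnot(inherits(elev, "elevation_grid"))
  water <- as_water_mask(water, elev)
  cls3 <- classify_cells(elev, water)
  a <- elev$altitude
  a_safe <- ifelse(is.na(a), -1, a)

  D_alt <- altitude_desirability(a_safe)
  d_surf <- local_relief(elev, exclude = cls3 == "sea")
  D_surf <- surface_desirability(d_surf, params)
  scls <- surface_class(d_surf, params)

  S <- distance_to_water(cls3, elev$cell_size_km)
  D_riv <- water_desirability(S, params)

  land_class <- scls
  land_class[cls3 == "sea"] <- "sea"
  land_class[cls3 == "freshwater"] <- "freshwater"
  nonland <- land_class %in% c("sea", "freshwater")
  D_alt[nonland] <- 0
  D_surf[nonland] <- 0
  D_riv[land_class == "sea"] <- 0

  D_loc <- location_desirability(D_alt, D_surf, params)
  R_in <- site_rating(D_alt, D_surf, D_riv, land_class, params, altitude = a_safe)
  R_in[nonland] <- 0
  habitable <- land_class %in% c("flat", "tolerable")
  habitable <- matrix(habitable, elev$n_rows, elev$n_cols)
  P_best <- optimum_population(D_alt, D_surf, D_riv, P_max, habitable)

  structure(
    list(
      D_alt = D_alt, d_surf = d_surf, D_surf = D_surf, D_loc = D_loc,
      D_riv = D_riv, land_class = land_class, R_in = R_in, P_best = P_best,
      water_distance = S, params = params, P_max = P_max,
      cell_size_km = elev$cell_size_km, altitude = a
    ),
    class = "habitability_fields"
  )
}

#' @export
print.habitability_fields <- function(x, ...) {
  cat(sprintf("<habitability_fields> %d x %d cells\n",
              nrow(x$R_in), ncol(x$R_in)))
  print(table(x$land_class))
  invisible(x)
}

#' @export
summary.habitability_fields <- function(object, ...) {
  fields <- c("D_alt", "D_surf", "D_riv", "R_in", "P_best")
  tibble::tibble(
    field = fields,
    min = vapply(fields, function(f) min(object[[f]]), numeric(1)),
    max = vapply(fields, function(f) max(object[[f]]), numeric(1))
  )
}

#' Tidy habitability fields into a long per-cell tibble
#'
#' @param x A `habitability_fields` object.
#' @param ... Unused.
#' @return A tibble with one row per cell: `row`, `col` (0-based),
#'   `land_class` and one column per scored field.
#' @method as_tibble habitability_fields
#' @export
as_tibble.habitability_fields <- function(x, ...) {
  out <- grid_to_tibble(x$D_alt, "D_alt")
  out$D_surf <- as.vector(x$D_surf)
  out$D_riv <- as.vector(x$D_riv)
  out$D_loc <- as.vector(x$D_loc)
  out$R_in <- as.vector(x$R_in)
  out$P_best <- as.vector(x$P_best)
  out$land_class <- as.vector(x$land_class)
  out
}

#' @rdname as_tibble.habitability_fields
#' @param object A `habitability_fields` object.
#' @param field Which field to map (default `"R_in"`).
#' @method autoplot habitability_fields
#' @export
autoplot.habitability_fields <- function(object, field = "R_in", ...) {
  df <- tibble::as_tibble(object)
  df$value <- df[[field]]
  df$value[df$land_class %in% c("sea")] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "col", y = "row (north up)", fill = field)
}
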