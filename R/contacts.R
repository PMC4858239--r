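#' First-contact matrix between seeded groups
#'
#' `t(g, h)` is the first simulation step at which some cell simultaneously
#' holds at least `threshold` persons of group `g` and of group `h`; the
#' diagonal is 0 and pairs that never meet within the run are `Inf`. With the
#' default `threshold = NULL` the matrix recorded online during
#' [run_simulation()] (at `config$contact_threshold`) is returned; with an
#' explicit threshold the matrix is recomputed from the stored snapshots,
#' which is exact only when the run was snapshotted every step.
#'
#' @param sim A `migration_sim`.
#' @param threshold Persons per group per cell counting as presence, or
#'   `NULL` for the online record.
#' @return A symmetric `contact_matrix` (K x K, labeled).
#' @export
detect_contacts <- function(sim, threshold = NULL) {
  stopifnot(inherits(sim, "migration_sim"))
  n_g <- length(sim$groups)
  if (n_g < 2L) {
    stop("contact detection needs at least two seeded groups", call. = FALSE)
  }
  if (is.null(threshold)) {
    cm <- sim$contacts
  } else {
    if (sim$snapshot_every != 1L) {
      warning("snapshots are sparser than one step; contact steps are ",
              "resolved only to the snapshot cadence", call. = FALSE)
    }
    cm <- matrix(Inf, n_g, n_g, dimnames = list(sim$groups, sim$groups))
    diag(cm) <- 0
    for (snap in sim$snapshots) {
      occ <- snap$pop >= threshold
      for (g in seq_len(n_g - 1L)) {
        for (h in (g + 1L):n_g) {
          if (is.infinite(cm[g, h]) && any(occ[, , g] & occ[, , h])) {
            cm[g, h] <- cm[h, g] <- snap$step
          }
        }
      }
    }
  }
  structure(cm, class = c("contact_matrix", "matrix"))
}

#' Normalized distance parameter
#'
#' Divides the first-contact steps by the largest finite off-diagonal entry,
#' so 0 means "same group" and 1 the latest-contacting pair. Pairs that never
#' met stay `Inf` and are excluded from any later correlation.
#'
#' @param cm A [detect_contacts()] matrix (or any symmetric non-negative
#'   matrix of contact steps with zero diagonal).
#' @return A `distance_parameter` matrix in \[0, 1\] (plus `Inf` entries).
#' @export
distance_parameter <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  off <- cm[upper.tri(cm)]
  finite <- off[is.finite(off)]
  if (!length(finite)) {
    stop("no finite off-diagonal contact time: cannot normalize", call. = FALSE)
  }
  m <- max(finite)
  d <- if (m > 0) cm / m else cm
  diag(d) <- 0
  structure(d, class = c("distance_parameter", "matrix"))
}

#' Correlate the distance parameter with a genetic-distance matrix
#'
#' Pearson correlation over the upper-triangle pairs of the two labeled
#' matrices, after dropping excluded groups and pairs with infinite
#' (never-contacted) distance. Labels are matched by name; at least three
#' usable pairs are required.
#'
#' @param d A [distance_parameter()] matrix with group labels as dimnames.
#' @param genetic A symmetric genetic-distance matrix (e.g. pairwise F_ST)
#'   with matching labels, or a path handled by [read_distance_csv()].
#' @param exclude Character vector of group labels to drop before
#'   vectorization.
#' @return A one-row tibble: `r` (Pearson correlation), `n_pairs`,
#'   `n_dropped` (infinite pairs removed).
#' @export
correlate_distance <- function(d, genetic, exclude = NULL) {
  if (is.character(genetic) && length(genetic) == 1L) {
    genetic <- read_distance_csv(genetic)
  }
  d <- unclass(d)
  genetic <- unclass(genetic)
  ld <- rownames(d)
  lg <- rownames(genetic)
  if (is.null(ld) || is.null(lg)) {
    stop("both matrices need group labels as dimnames", call. = FALSE)
  }
  keep <- setdiff(ld, exclude)
  if (!all(keep %in% lg)) {
    stop("group labels do not match: missing ",
         paste(setdiff(keep, lg), collapse = ", "), call. = FALSE)
  }
  d <- d[keep, keep, drop = FALSE]
  genetic <- genetic[keep, keep, drop = FALSE]
  ut <- upper.tri(d)
  x <- d[ut]
  y <- genetic[ut]
  usable <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    warning(sprintf("dropping %d pair(s) with no finite contact time", n_dropped),
            call. = FALSE)
  }
  x <- x[usable]
  y <- y[usable]
  if (length(x) < 3L) {
    stop("need at least 3 usable pairs for a correlation", call. = FALSE)
  }
  tibble::tibble(r = stats::cor(x, y, method = "pearson"),
                 n_pairs = length(x), n_dropped = n_dropped)
}

#' Per-zone group composition of a trajectory
#'
#' Maps snapshots onto user-supplied geographic zones (an integer label
#' raster) and reports, per snapshot and zone, each group's population and
#' the dominant group. Cells with label `NA` or 0 are grouped under
#' `"unassigned"`.
#'
#' @param sim A `migration_sim`.
#' @param zones Integer matrix of zone labels matching the grid, or a named
#'   list with `labels` (matrix) and `legend` (named character vector
#'   mapping label -> zone name).
#' @return A tibble: `step`, `zone`, `group`, `population`, `dominant`.
#' @export
zone_composition <- function(sim, zones) {
  stopifnot(inherits(sim, "migration_sim"))
  legend <- NULL
  if (is.list(zones) && !is.matrix(zones)) {
    legend <- zones$legend
    zones <- zones$labels
  }
  if (!identical(dim(sim$final$pop)[1:2], dim(zones))) {
    stop("zone raster shape does not match the simulation grid", call. = FALSE)
  }
  z <- as.vector(zones)
  z[is.na(z) | z == 0] <- NA
  zname <- if (!is.null(legend)) unname(legend[as.character(z)]) else as.character(z)
  zname[is.na(zname)] <- "unassigned"
  rows <- purrr::map(sim$snapshots, function(snap) {
    purrr::map(seq_along(sim$groups), function(g) {
      tibble::tibble(
        step = snap$step,
        zone = zname,
        group = sim$groups[g],
        population = as.vector(snap$pop[, , g])
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out <- rows |>
    dplyr::group_by(.data$step, .data$zone, .data$group) |>
    dplyr::summarise(population = sum(.data$population), .groups = "drop_last") |>
    dplyr::mutate(dominant = .data$group[which.max(.data$population)]) |>
    dplyr::ungroup()
  out
}

#' Read / write labeled square distance matrices as CSV
#'
#' The CSV carries group labels both as header row and first column;
#' [read_distance_csv()] validates squareness and symmetrizes nothing —
#' asymmetric input is an error.
#'
#' @param path CSV file path.
#' @return For the reader: a labeled numeric matrix.
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square", call. = FALSE)
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column labels differ", call. = FALSE)
  }
  storage.mode(m) <- "double"
  gap <- abs(m - t(m))
  gap[is.infinite(m) & is.infinite(t(m))] <- 0  # Inf == Inf counts as equal
  if (any(gap > 1e-8, na.rm = TRUE) || any(is.infinite(m) != is.infinite(t(m)))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  m
}

#' @rdname read_distance_csv
#' @param m Labeled square matrix to write (`Inf` written as `Inf`).
#' @export
write_distance_csv <- function(m, path) {
  m <- unclass(m)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Tidy a contact or distance matrix into pair rows
#'
#' @param x A `contact_matrix` or `distance_parameter`.
#' @param ... Unused.
#' @return Tibble of unordered pairs: `group_a`, `group_b`, `value`.
#' @method tidy contact_matrix
#' @export
tidy.contact_matrix <- function(x, ...) {
  m <- unclass(x)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    group_a = rownames(m)[ut[, 1]],
    group_b = colnames(m)[ut[, 2]],
    value = m[ut]
  )
}

#' @rdname tidy.contact_matrix
#' @method tidy distance_parameter
#' @export
tidy.distance_parameter <- tidy.contact_matrix

#' @export
print.contact_matrix <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.distance_parameter <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}
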