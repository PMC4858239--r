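#' Elevation grid
#'
#' Constructs a rectangular altitude field. Cells hold altitude in meters
#' above sea level; negative values are sea, `NA` marks nodata. The grid is
#' non-georeferenced: coordinates are 0-based `(row, col)` with row 0 the
#' northernmost row, and all distances are expressed in kilometers through
#' `cell_size_km`.
#'
#' @param altitude Numeric matrix of altitudes (m); `NA` = nodata.
#' @param cell_size_km Edge length of a cell in km (default 1).
#' @return An object of class `elevation_grid`.
#' @examples
#' g <- elevation_grid(matrix(c(0, 100, -5, 300), 2, 2, byrow = TRUE))
#' g$n_rows
#' @export
elevation_grid <- function(altitude, cell_size_km = 1) {
  if (!is.matrix(altitude) || !is.numeric(altitude)) {
    stop("`altitude` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(altitude) < 1L || ncol(altitude) < 1L) {
    stop("grid must contain at least one cell", call. = FALSE)
  }
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1L ||
      !is.finite(cell_size_km) || cell_size_km <= 0) {
    stop("`cell_size_km` must be a single positive number", call. = FALSE)
  }
  if (any(is.infinite(altitude))) {
    stop("altitudes must be finite or NA (nodata)", call. = FALSE)
  }
  structure(
    list(
      altitude     = unname(altitude),
      n_rows       = nrow(altitude),
      n_cols       = ncol(altitude),
      cell_size_km = as.numeric(cell_size_km)
    ),
    class = "elevation_grid"
  )
}

#' @export
print.elevation_grid <- function(x, ...) {
  n_nodata <- sum(is.na(x$altitude))
  cat(sprintf(
    "<elevation_grid> %d x %d cells, %.3g km cells, altitude %s..%s m, %d nodata\n",
    x$n_rows, x$n_cols, x$cell_size_km,
    format(min(x$altitude, na.rm = TRUE)),
    format(max(x$altitude, na.rm = TRUE)), n_nodata
  ))
  invisible(x)
}

#' @export
dim.elevation_grid <- function(x) c(x$n_rows, x$n_cols)

#' Tidy a per-cell field into a tibble
#'
#' Converts an [elevation_grid()] (or any per-cell matrix) into a long tibble
#' with one row per cell, suitable for dplyr/ggplot2 pipelines.
#'
#' @param x An `elevation_grid`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col` (0-based) and `altitude`.
#' @method as_tibble elevation_grid
#' @export
as_tibble.elevation_grid <- function(x, ...) {
  grid_to_tibble(x$altitude, "altitude")
}

# long tibble (row, col, <name>) from a matrix; rows/cols 0-based
grid_to_tibble <- function(m, name = "value") {
  out <- tibble::tibble(
    row = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
    col = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
    value = as.vector(m)
  )
  names(out)[3] <- name
  out
}

#' @rdname as_tibble.elevation_grid
#' @method autoplot elevation_grid
#' @export
autoplot.elevation_grid <- function(x, ...) {
  df <- tibble::as_tibble(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$altitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "col", y = "row (north up)", fill = "altitude (m)")
}

# shifted copy of a matrix: out[i, j] = m[i - dr, j - dc], `fill` outside
shift_mat <- function(m, dr, dc, fill = 0) {
  n_r <- nrow(m)
  n_c <- ncol(m)
  out <- matrix(fill, n_r, n_c)
  r_lo <- max(1L, 1L + dr); r_hi <- min(n_r, n_r + dr)
  c_lo <- max(1L, 1L + dc); c_hi <- min(n_c, n_c + dc)
  if (r_lo > r_hi || c_lo > c_hi) return(out)
  r_dst <- r_lo:r_hi
  c_dst <- c_lo:c_hi
  out[r_dst, c_dst] <- m[r_dst - dr, c_dst - dc]
  out
}

# neighbor value matrix: value of the cell at offset (dr, dc) from each cell
neighbor_value <- function(m, dr, dc, fill = 0) shift_mat(m, -dr, -dc, fill)

# run code under a temporary RNG seed, restoring global RNG state afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_if_shape_mismatch <- function(a, b, what = "water mask") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf(
      "%s shape (%s) does not match grid shape (%s)",
      what, paste(dim(b), collapse = "x"), paste(dim(a), collapse = "x")
    ), call. = FALSE)
  }
}
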