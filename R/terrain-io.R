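#' Read an ESRI ASCII grid
#'
#' Parses the ESRI ASCII raster dialect: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `NODATA_value`) followed by
#' `nrows` space-separated rows, northernmost row first. `cellsize` is taken
#' to be in meters and converted to km internally.
#'
#' @param path Path to a `.asc` file.
#' @return An [elevation_grid()]; nodata cells are `NA`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    key <- tolower(toks[1])
    if (!(key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                     "cellsize", "nodata_value"))) break
    if (length(toks) != 2L) {
      stop("malformed header line in ", path, ": ", lines[[i]], call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(toks[2]))
    if (is.na(val)) {
      stop("non-numeric header value in ", path, ": ", lines[[i]], call. = FALSE)
    }
    hdr[[key]] <- val
    i <- i + 1L
  }
  required <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(required, names(hdr))
  if (length(missing)) {
    stop("malformed ESRI ASCII header: missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n_cols <- as.integer(hdr$ncols)
  n_rows <- as.integer(hdr$nrows)
  if (n_cols < 1L || n_rows < 1L) stop("non-positive grid dimensions", call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- lines[i:length(lines)]
  if (length(body) != n_rows) {
    stop(sprintf("expected %d data rows, found %d", n_rows, length(body)),
         call. = FALSE)
  }
  rows <- lapply(body, function(ln) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (anyNA(v)) stop("non-numeric cell value in data row", call. = FALSE)
    v
  })
  widths <- lengths(rows)
  if (any(widths != n_cols)) {
    stop(sprintf("ragged data row: expected %d values, found %d",
                 n_cols, widths[which(widths != n_cols)[1]]), call. = FALSE)
  }
  m <- do.call(rbind, rows)
  m[m == nodata] <- NA_real_
  elevation_grid(m, cell_size_km = hdr$cellsize / 1000)
}

#' Write a per-cell field as an ESRI ASCII grid
#'
#' Inverse of [read_ascii_grid()]: `read_ascii_grid(write_ascii_grid(x))`
#' reproduces `x` to 1e-6 relative precision on values and exactly on the
#' nodata mask.
#'
#' @param x An [elevation_grid()] or a numeric matrix (`NA` = nodata).
#' @param path Output file path.
#' @param cell_size_km Cell size in km; defaults to the grid's own, or 1 for
#'   bare matrices.
#' @param nodata Sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, cell_size_km = NULL, nodata = -9999) {
  if (inherits(x, "elevation_grid")) {
    if (is.null(cell_size_km)) cell_size_km <- x$cell_size_km
    m <- x$altitude
  } else {
    if (is.null(cell_size_km)) cell_size_km <- 1
    m <- x
  }
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("`x` must be a numeric matrix or elevation_grid", call. = FALSE)
  }
  if (any(is.infinite(m) | is.nan(m))) {
    stop("cannot write non-finite cell values; use NA for nodata", call. = FALSE)
  }
  if (any(m == nodata, na.rm = TRUE)) {
    stop("a data value collides with the nodata sentinel ", nodata, call. = FALSE)
  }
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.10g", cell_size_km * 1000),
    sprintf("NODATA_value %.10g", nodata)
  )
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, function(r) paste(sprintf("%.10g", r), collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write to ", path, call. = FALSE)
  invisible(path)
}

#' Classify cells as land, sea or freshwater
#'
#' A cell is `sea` when its altitude is negative (or nodata, which behaves as
#' sea), `freshwater` when the water mask marks it as a freshwater source
#' (mask priority over altitude), and `land` otherwise. Freshwater cells are
#' never populable.
#'
#' @param elev An [elevation_grid()].
#' @param water Logical matrix of the same shape: freshwater source present.
#' @return Character matrix with entries `"land"`, `"sea"`, `"freshwater"`;
#'   label counts are attached as attribute `"counts"`.
#' @examples
#' g <- elevation_grid(matrix(c(-10, 50, 50, 20), 2, 2))
#' w <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
#' classify_cells(g, w)
#' @export
classify_cells <- function(elev, water) {
  stopifnot(inherits(elev, "elevation_grid"))
  water <- as_water_mask(water, elev)
  a <- elev$altitude
  cls <- matrix("land", elev$n_rows, elev$n_cols)
  cls[is.na(a) | a < 0] <- "sea"
  cls[water] <- "freshwater"
  counts <- c(
    land       = sum(cls == "land"),
    sea        = sum(cls == "sea"),
    freshwater = sum(cls == "freshwater")
  )
  attr(cls, "counts") <- counts
  cls
}

as_water_mask <- function(water, elev) {
  if (is.numeric(water)) water <- water != 0
  if (!is.matrix(water) || !is.logical(water)) {
    stop("`water` must be a logical (or 0/1 numeric) matrix", call. = FALSE)
  }
  stop_if_shape_mismatch(elev$altitude, water)
  water[is.na(water)] <- FALSE
  water
}

#' Distance to the nearest freshwater source
#'
#' Exact Euclidean distance (km, between cell centers) from every cell to its
#' nearest freshwater cell, computed against all sources.
#'
#' @param cls Classification matrix from [classify_cells()].
#' @param cell_size_km Cell size in km.
#' @return Numeric matrix `S` with `S = 0` on freshwater cells; all-`Inf`
#'   (with a warning) when the grid holds no freshwater.
#' @export
distance_to_water <- function(cls, cell_size_km = 1) {
  stopifnot(is.matrix(cls))
  idx <- which(cls == "freshwater", arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("no freshwater cells: distance field is infinite everywhere",
            call. = FALSE)
    return(matrix(Inf, nrow(cls), ncol(cls)))
  }
  n_r <- nrow(cls)
  n_c <- ncol(cls)
  rr <- matrix(seq_len(n_r), n_r, n_c)
  cc <- matrix(seq_len(n_c), n_r, n_c, byrow = TRUE)
  d2 <- matrix(Inf, n_r, n_c)
  for (k in seq_len(nrow(idx))) {
    d2 <- pmin(d2, (rr - idx[k, 1])^2 + (cc - idx[k, 2])^2)
  }
  sqrt(d2) * cell_size_km
}
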