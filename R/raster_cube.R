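#' Masked raster time-series cube
#'
#' A `raster_cube` is the unit of currency between pipeline stages: a
#' `(time, y, x)` numeric array with a shared 2-D validity mask, grid
#' metadata (origin, cell size, CRS tag) and an ordered integer time axis
#' (years). Values at masked cells are `NA` at every time step; a single
#' nodata sentinel is substituted only on disk (see [write_cube()]).
#'
#' @param values numeric array with dimensions `(time, y, x)`.
#' @param years strictly increasing integer vector, one entry per time step.
#' @param mask logical `(y, x)` matrix, `TRUE` where the cell carries valid
#'   data. Defaults to all-valid.
#' @param grid list with elements `origin` (length-2 numeric, x/y of the
#'   upper-left corner), `cellsize` (numeric, degrees or metres per cell) and
#'   `crs` (character tag, free-form).
#' @return An object of class `raster_cube`.
#' @examples
#' cube <- raster_cube(array(1, dim = c(3, 2, 2)), years = 2000:2002)
#' dim(cube$values)
#' @export
raster_cube <- function(values, years,
                        mask = NULL,
                        grid = list(origin = c(0, 0), cellsize = 0.05,
                                    crs = "EPSG:4326")) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array with dimensions (time, y, x)",
         call. = FALSE)
  }
  d <- dim(values)
  years <- as.integer(years)
  if (length(years) != d[1]) {
    stop("length(years) [", length(years), "] != time dimension [", d[1], "]",
         call. = FALSE)
  }
  if (length(years) > 1 && any(diff(years) <= 0)) {
    stop("`years` must be strictly increasing", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  if (!is.matrix(mask) || !identical(dim(mask), d[2:3])) {
    stop("`mask` must be a logical (y, x) matrix matching the cube grid",
         call. = FALSE)
  }
  mode(mask) <- "logical"
  # enforce the invariant: masked cells are NA at every time step
  if (any(!mask)) {
    bad <- which(!mask, arr.ind = TRUE)
    for (i in seq_len(nrow(bad))) values[, bad[i, 1], bad[i, 2]] <- NA_real_
  }
  structure(list(values = values, mask = mask, grid = grid, years = years),
            class = "raster_cube")
}

#' @export
print.raster_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<raster_cube> %d years (%d-%d), %d x %d grid, %d/%d valid cells\n",
    d[1], min(x$years), max(x$years), d[2], d[3], sum(x$mask), d[2] * d[3]))
  invisible(x)
}

#' @export
dim.raster_cube <- function(x) dim(x$values)

#' Annual pixel series
#'
#' A fully valid one-pixel time series: paired value and year vectors of
#' equal length with no missing values. This is the object the
#' decomposition, classification and persistence operations consume.
#'
#' @param values numeric vector, no `NA`.
#' @param years integer years, same length as `values`; defaults to
#'   `seq_along(values)`.
#' @return An object of class `pixel_series`.
#' @export
pixel_series <- function(values, years = seq_along(values)) {
  values <- as.numeric(values)
  years <- as.integer(years)
  if (length(values) != length(years)) {
    stop("`values` and `years` must have the same length", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("`pixel_series` must be fully valid (no NA); mask upstream",
         call. = FALSE)
  }
  structure(list(values = values, years = years), class = "pixel_series")
}

as_pixel_series <- function(x) {
  if (inherits(x, "pixel_series")) return(x)
  pixel_series(x)
}

#' @export
length.pixel_series <- function(x) length(x$values)

#' @export
print.pixel_series <- function(x, ...) {
  cat(sprintf("<pixel_series> %d years (%d-%d)\n", length(x$values),
              min(x$years), max(x$years)))
  invisible(x)
}

#' Extract one pixel's series from a cube
#'
#' @param cube a [raster_cube()].
#' @param row,col 1-based grid indices (row indexes y, col indexes x).
#' @return A [pixel_series()].
#' @export
cube_pixel <- function(cube, row, col) {
  stopifnot(inherits(cube, "raster_cube"))
  if (!cube$mask[row, col]) {
    stop("pixel (", row, ", ", col, ") is masked", call. = FALSE)
  }
  pixel_series(cube$values[, row, col], cube$years)
}

#' Cube as a long tibble
#'
#' One row per (year, row, col) cell; masked cells are omitted.
#'
#' @param x a [raster_cube()].
#' @param ... unused.
#' @return A tibble with columns `year`, `row`, `col`, `value`.
#' @importFrom tibble as_tibble
#' @exportS3Method tibble::as_tibble
as_tibble.raster_cube <- function(x, ...) {
  d <- dim(x$values)
  idx <- which(x$mask, arr.ind = TRUE)
  vals <- vapply(seq_len(nrow(idx)),
                 function(i) x$values[, idx[i, 1], idx[i, 2]],
                 numeric(d[1]))
  tibble::tibble(
    year = rep(x$years, times = nrow(idx)),
    row = rep(idx[, 1], each = d[1]),
    col = rep(idx[, 2], each = d[1]),
    value = as.vector(vals)
  )
}

# shared guard: two cubes must live on the same grid/mask/time axis.
# `check_mask` is relaxed where the caller intersects masks itself.
check_same_grid <- function(a, b, check_mask = TRUE) {
  if (!identical(dim(a$values), dim(b$values))) {
    stop("cube shape mismatch: ", paste(dim(a$values), collapse = "x"),
         " vs ", paste(dim(b$values), collapse = "x"), call. = FALSE)
  }
  if (!identical(a$years, b$years)) {
    stop("cube time_axis mismatch", call. = FALSE)
  }
  if (!isTRUE(all.equal(a$grid$origin, b$grid$origin)) ||
      !isTRUE(all.equal(a$grid$cellsize, b$grid$cellsize))) {
    stop("cube grid (origin/cellsize) mismatch", call. = FALSE)
  }
  if (check_mask && !identical(a$mask, b$mask)) {
    stop("cube mask mismatch", call. = FALSE)
  }
  invisible(TRUE)
}

# rebuild a cube around new values / a tightened mask
cube_like <- function(template, values, mask = template$mask) {
  raster_cube(values, years = template$years, mask = mask,
              grid = template$grid)
}
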