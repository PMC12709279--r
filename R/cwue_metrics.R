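# CWUE indicator cubes and their spatial summaries.
#
# CUE  = NPP / GPP          (unitless)
# WUE  = production / ET    (g C m-2 mm-1), production = NPP or GPP

# shared ratio kernel: cellwise numerator/denominator with the denominator
# guard (<= 0 treated as invalid: fill values in flux products are often
# encoded as negatives). A cell whose denominator is invalid in ANY year is
# masked in the output, so every surviving pixel series is complete.
cube_ratio <- function(num, den) {
  check_same_grid(num, den, check_mask = FALSE)
  mask <- num$mask & den$mask
  invalid <- !is.na(den$values) & den$values <= 0
  bad_den <- apply(invalid, c(2, 3), any)
  mask <- mask & !bad_den
  vals <- num$values / den$values
  vals[invalid] <- NA_real_
  cube_like(num, vals, mask = mask)
}

#' Carbon use efficiency cube
#'
#' Cellwise `NPP / GPP`. Cells where GPP is not strictly positive in any
#' year are masked in the output (an undefined ratio, and negative values
#' in flux products are fill).
#'
#' @param npp,gpp [raster_cube()]s of net and gross primary productivity
#'   (g C m-2 y-1) on the same grid and time axis.
#' @return A unitless [raster_cube()] of CUE.
#' @export
compute_cue <- function(npp, gpp) cube_ratio(npp, gpp)

#' Water use efficiency cube
#'
#' Cellwise `production / ET` in g C m-2 mm-1, where `production` is NPP
#' (giving WUE_NPP) or GPP (giving WUE_GPP). Cells with non-positive ET in
#' any year are masked.
#'
#' @param production [raster_cube()] of NPP or GPP (g C m-2 y-1).
#' @param et [raster_cube()] of evapotranspiration (mm y-1).
#' @return A [raster_cube()] of WUE.
#' @export
compute_wue <- function(production, et) cube_ratio(production, et)

#' Basin-mean annual series
#'
#' Spatial mean over unmasked cells for every year; the basin-scale
#' interannual series of a CWUE indicator.
#'
#' @param cube a [raster_cube()] with at least one unmasked cell.
#' @return A [pixel_series()] of per-year spatial means.
#' @export
annual_mean_series <- function(cube) {
  stopifnot(inherits(cube, "raster_cube"))
  if (!any(cube$mask)) {
    stop("cube is fully masked; no cells to average", call. = FALSE)
  }
  means <- apply(cube$values, 1, mean, na.rm = TRUE)
  pixel_series(means, years = cube$years)
}

#' Zonal profile of the multi-year mean field
#'
#' Bins the multi-year mean of a cube by a zoning field (elevation from a
#' DEM, latitude, or longitude) and summarizes the distribution in each
#' bin. Bins are half-open `[lo, hi)`; the last bin is closed so the edges
#' partition `[first, last]` exactly. Empty bins are retained with
#' `count = 0` and `NA` summaries.
#'
#' @param cube a [raster_cube()].
#' @param zones numeric `(y, x)` matrix of the zoning variable (e.g. DEM
#'   elevations in metres).
#' @param breaks strictly increasing numeric bin edges.
#' @param axis label for the zoning variable, one of `"elevation"`,
#'   `"latitude"`, `"longitude"`.
#' @return A tibble with one row per bin: `axis`, `bin_lo`, `bin_hi`,
#'   `count`, `mean`, `median`, `q25`, `q75`.
#' @export
zonal_profile <- function(cube, zones, breaks,
                          axis = c("elevation", "latitude", "longitude")) {
  axis <- match.arg(axis)
  stopifnot(inherits(cube, "raster_cube"))
  if (!is.matrix(zones) || !identical(dim(zones), dim(cube$values)[2:3])) {
    stop("`zones` must be a (y, x) matrix matching the cube grid",
         call. = FALSE)
  }
  breaks <- as.numeric(breaks)
  if (length(breaks) < 2 || any(diff(breaks) <= 0)) {
    stop("`breaks` must be strictly increasing with >= 2 edges",
         call. = FALSE)
  }
  field <- apply(cube$values, c(2, 3), mean)     # multi-year mean per cell
  keep <- cube$mask & is.finite(field) & is.finite(zones)
  v <- field[keep]
  zz <- zones[keep]
  nb <- length(breaks) - 1
  purrr::map_dfr(seq_len(nb), function(b) {
    lo <- breaks[b]
    hi <- breaks[b + 1]
    inbin <- if (b < nb) zz >= lo & zz < hi else zz >= lo & zz <= hi
    x <- v[inbin]
    if (length(x) == 0) {
      tibble::tibble(axis = axis, bin_lo = lo, bin_hi = hi, count = 0L,
                     mean = NA_real_, median = NA_real_,
                     q25 = NA_real_, q75 = NA_real_)
    } else {
      qs <- quantile(x, c(0.25, 0.75), names = FALSE)
      tibble::tibble(axis = axis, bin_lo = lo, bin_hi = hi,
                     count = length(x), mean = mean(x), median = median(x),
                     q25 = qs[1], q75 = qs[2])
    }
  })
}
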