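#' Canopy height model from surface and terrain models
#'
#' Cellwise `DSM - DTM`. Both rasters must share shape, affine transform and
#' CRS; a no-data cell in either input is no-data in the output.
#'
#' @param dsm,dtm [raster_grid()] layers in metres.
#' @return A `raster_grid` of heights above terrain.
#' @export
compute_chm <- function(dsm, dtm) {
  check_same_geometry(dsm, dtm, "DSM and DTM")
  out <- dsm
  out$values <- dsm$values - dtm$values
  out
}

#' Binary canopy mask by height threshold
#'
#' Cells whose canopy height strictly exceeds the threshold become 1, all
#' others (including no-data) become 0. The comparison is strict: a cell at
#' exactly the threshold is not canopy.
#'
#' @param chm Canopy height model from [compute_chm()].
#' @param threshold_m Height threshold in metres (default 0.5, the usual
#'   vine-canopy cutoff); must be non-negative.
#' @return A `canopy_mask`: a `raster_grid` of 0/1 values with the threshold
#'   recorded in `$threshold_m`.
#' @export
threshold_mask <- function(chm, threshold_m = 0.5) {
  if (!is_raster_grid(chm)) stop("chm must be a raster_grid")
  if (!is.numeric(threshold_m) || length(threshold_m) != 1 || threshold_m < 0)
    stop("threshold_m must be a single non-negative number")
  out <- chm
  v <- chm$values
  out$values <- ifelse(!is.na(v) & v > threshold_m, 1, 0)
  out$nodata <- 255
  out$threshold_m <- threshold_m
  class(out) <- c("canopy_mask", class(chm))
  out
}

#' @export
print.canopy_mask <- function(x, ...) {
  cat(sprintf("<canopy_mask> threshold %.2f m: %d canopy of %d cells (%.1f%%)\n",
              x$threshold_m, sum(x$values == 1), length(x$values),
              100 * mean(x$values == 1)))
  invisible(x)
}

#' Mask a thermal layer to canopy cells
#'
#' Retains thermal values where the mask is 1 and sets every other cell to
#' no-data, producing a layer that contains canopy temperatures only.
#'
#' @param thermal A [raster_grid()] of temperatures.
#' @param mask A [threshold_mask()] result with matching geometry.
#' @return A `raster_grid` with non-canopy cells set to `NA`.
#' @export
apply_mask <- function(thermal, mask) {
  if (!inherits(mask, "canopy_mask")) stop("mask must come from threshold_mask()")
  check_same_geometry(thermal, mask, "thermal layer and mask")
  out <- thermal
  out$values[mask$values != 1] <- NA_real_
  out
}
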