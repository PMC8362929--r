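#' Six-segment angular subdivision of each short-axis slice
#'
#' Assigns every masked voxel to one of six 60-degree angular sectors
#' about its slice's mask centroid, a simplified six-segment scheme in the
#' spirit of the standard myocardial segmentation models. Sector 1 starts
#' at the +X axis and sectors proceed counter-clockwise; anatomical
#' landmarks (e.g. RV insertion) are not available for synthetic shells,
#' so the sector frame is fixed to the grid axes.
#'
#' @param map a [perfusion_map()]
#' @return an object of class `segment_labeling`: `labels` (3D integer
#'   array, 0 outside the mask, 1..6 inside) and `centroids`, a tibble of
#'   per-slice mask centroids in mm.
#' @export
segment_six <- function(map) {
  stopifnot(is_perfusion_map(map))
  d <- dim(map$bf)
  labels <- array(0L, d)
  cents <- vector("list", d[3])
  for (z in seq_len(d[3])) {
    mk <- map$mask[, , z]
    if (!any(mk)) {
      warn(sprintf("slice %d has an empty mask; labeled 0", z))
      cents[[z]] <- tibble(slice = z, cx_mm = NA_real_, cy_mm = NA_real_)
      next
    }
    ij <- which(mk, arr.ind = TRUE)
    px <- (ij[, 1] - 0.5) * map$voxel_mm[1]
    py <- (ij[, 2] - 0.5) * map$voxel_mm[2]
    cx <- mean(px); cy <- mean(py)
    ang <- atan2(py - cy, px - cx)          # (-pi, pi], 0 at +X, CCW
    ang <- ang %% (2 * pi)
    sec <- pmin(floor(ang / (pi / 3)) + 1L, 6L)
    sl <- labels[, , z]
    sl[ij] <- as.integer(sec)
    labels[, , z] <- sl
    cents[[z]] <- tibble(slice = z, cx_mm = cx, cy_mm = cy)
  }
  structure(list(labels = labels, centroids = bind_rows(cents)),
            class = "segment_labeling")
}

#' Per-segment blood-flow statistics
#'
#' One record per (slice, segment) with count, mean, median, min and max
#' of masked blood flow, plus global rows (`slice = 0`, `segment = 0`).
#' Empty segments are reported with `n = 0` and `NA` statistics.
#'
#' @param map a [perfusion_map()]
#' @param labels a [segment_six()] labeling aligned with `map`
#' @return a tibble
#' @export
segment_stats <- function(map, labels) {
  stopifnot(is_perfusion_map(map))
  if (!inherits(labels, "segment_labeling"))
    abort("`labels` must come from segment_six()")
  if (!identical(dim(labels$labels), dim(map$bf)))
    abort("labeling and map have mismatched shapes")
  d <- dim(map$bf)
  rows <- list()
  for (z in seq_len(d[3])) {
    sl <- labels$labels[, , z]
    bfz <- map$bf[, , z]
    for (seg in 1:6) {
      v <- bfz[sl == seg]
      rows[[length(rows) + 1L]] <- tibble(
        slice = z, segment = seg, n = length(v),
        mean_bf = if (length(v)) mean(v) else NA_real_,
        median_bf = if (length(v)) median(v) else NA_real_,
        min_bf = if (length(v)) min(v) else NA_real_,
        max_bf = if (length(v)) max(v) else NA_real_)
    }
  }
  v <- map$bf[map$mask]
  rows[[length(rows) + 1L]] <- tibble(
    slice = 0L, segment = 0L, n = length(v), mean_bf = mean(v),
    median_bf = median(v), min_bf = min(v), max_bf = max(v))
  bind_rows(rows)
}

#' Myocardial perfusion reserve
#'
#' Ratio of the mean stress to the mean rest blood flow over the shared
#' myocardial mask, also expressed as a percentage.
#'
#' @param rest,stress [perfusion_map()]s on the same grid with the same
#'   mask
#' @return a one-row tibble with `mpr`, `mpr_percent`, `rest_mean`,
#'   `stress_mean`
#' @export
compute_mpr <- function(rest, stress) {
  stopifnot(is_perfusion_map(rest), is_perfusion_map(stress))
  if (!identical(dim(rest$bf), dim(stress$bf)) ||
      !identical(rest$mask, stress$mask))
    abort("rest and stress maps must share grid and mask")
  rm_ <- masked_mean(rest); sm_ <- masked_mean(stress)
  if (!is.finite(rm_) || rm_ <= 0)
    abort("rest mean blood flow must be positive")
  tibble(mpr = sm_ / rm_, mpr_percent = 100 * sm_ / rm_,
         rest_mean = rm_, stress_mean = sm_)
}
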