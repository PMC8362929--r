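#' Ischemia severity field from low-flow regions of a perfusion map
#'
#' Maps perfusion heterogeneity onto a per-voxel ischemia severity in
#' [0, 1]: voxels at or above the `low_flow_quantile` threshold get 0;
#' below it, severity grows linearly to 1 at the lowest-flow masked voxel.
#' The threshold is the `floor(q * n) + 1`-th smallest masked value, so for
#' a continuous map exactly `floor(q * n)` voxels receive positive
#' severity, and a uniform map (or `q = 0`) yields an all-zero field.
#'
#' This flow-to-severity coupling is a modeling construction of this
#' package (structural tissue heterogeneity for the wedge simulator), not
#' a measured dose-response.
#'
#' @param map a [perfusion_map()]
#' @param low_flow_quantile fraction of masked voxels to grade as
#'   ischemic, in \[0, 1).
#' @return an `ischemia_field`: list with `severity` (3D array, 0 outside
#'   the mask), `threshold` (mL/min/100 g) and `low_flow_quantile`.
#' @export
generate_heterogeneity_field <- function(map, low_flow_quantile = 0.2) {
  stopifnot(is_perfusion_map(map))
  q <- low_flow_quantile
  if (!is.finite(q) || q < 0 || q >= 1)
    abort("`low_flow_quantile` must lie in [0, 1)")
  v <- map$bf[map$mask]
  n <- length(v)
  sev <- array(0, dim(map$bf))
  k <- floor(q * n)
  if (k >= 1) {
    thr <- sort(v, partial = k + 1)[k + 1]
    lo <- min(v)
    if (thr > lo) {
      s <- array(pmax(0, pmin(1, (thr - map$bf) / (thr - lo))), dim(map$bf))
      s[!map$mask | map$bf >= thr] <- 0
      sev <- s
    }
  } else {
    thr <- min(v)
  }
  structure(list(severity = sev, threshold = thr, low_flow_quantile = q),
            class = "ischemia_field")
}

#' Resample one slice of an ischemia field onto a 2D sheet grid
#'
#' Bilinear resampling of the chosen slice's severity onto an
#' `nx_out x ny_out` node grid, for coupling perfusion-derived structural
#' heterogeneity into the tissue simulator.
#'
#' @param field an `ischemia_field`
#' @param nx_out,ny_out output node counts
#' @param slice slice index; defaults to the mid-stack slice
#' @return numeric matrix `nx_out x ny_out` of severities in \[0, 1]
#' @export
resample_severity_sheet <- function(field, nx_out, ny_out, slice = NULL) {
  if (!inherits(field, "ischemia_field"))
    abort("`field` must come from generate_heterogeneity_field()")
  d <- dim(field$severity)
  if (is.null(slice)) slice <- max(1L, d[3] %/% 2L)
  s <- field$severity[, , slice]
  xi <- seq(1, d[1], length.out = nx_out)
  yi <- seq(1, d[2], length.out = ny_out)
  a <- array(s, c(d[1], d[2], 1))
  g <- expand.grid(x = xi, y = yi)
  out <- matrix(trilinear(a, g$x, g$y, rep(1, nrow(g))), nx_out, ny_out)
  matrix(pmax(0, pmin(1, out)), nx_out, ny_out)
}
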