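#' Create a 3D myocardial perfusion map
#'
#' A perfusion map bundles a 3D voxel array of blood-flow values
#' (mL/min/100 g), a boolean mask of myocardial voxels, and the voxel
#' spacing in mm. It is the unit of perfusion analysis: fractal-dimension
#' estimation, segmental statistics and perfusion reserve all consume it.
#'
#' @param bf 3D numeric array of blood flow, mL/min/100 g. Must be
#'   non-negative everywhere and strictly positive on the mask.
#' @param mask 3D logical array, same shape as `bf`; `TRUE` marks left
#'   ventricular myocardium. Defaults to `bf > 0`.
#' @param voxel_mm numeric length-3, voxel spacing (dx, dy, dz) in mm.
#'
#' @return An object of class `perfusion_map`.
#' @export
perfusion_map <- function(bf, mask = NULL, voxel_mm = c(0.5, 0.5, 5)) {
  if (!is.array(bf) || length(dim(bf)) != 3L)
    abort("`bf` must be a 3D array")
  if (is.null(mask)) mask <- bf > 0
  mask <- array(as.logical(mask), dim(bf))
  if (!identical(dim(mask), dim(bf)))
    abort("`bf` and `mask` must have identical dimensions")
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    abort("`voxel_mm` must be three strictly positive spacings in mm")
  if (any(bf < 0, na.rm = TRUE))
    abort("blood flow must be non-negative everywhere")
  if (any(bf[mask] <= 0))
    abort("blood flow must be strictly positive on masked voxels")
  structure(list(bf = bf, mask = mask, voxel_mm = voxel_mm),
            class = "perfusion_map")
}

#' @export
print.perfusion_map <- function(x, ...) {
  d <- dim(x$bf)
  cat(sprintf("<perfusion_map> %d x %d x %d voxels @ %.2g x %.2g x %.2g mm\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  cat(sprintf("  masked voxels: %d (%.1f%%), mean BF %.1f mL/min/100 g\n",
              sum(x$mask), 100 * mean(x$mask), mean(x$bf[x$mask])))
  invisible(x)
}

#' @export
is_perfusion_map <- function(x) inherits(x, "perfusion_map")

#' Mean blood flow over the masked myocardium
#' @param map a [perfusion_map()]
#' @return scalar, mL/min/100 g
#' @export
masked_mean <- function(map) {
  stopifnot(is_perfusion_map(map))
  mean(map$bf[map$mask])
}

# trilinear interpolation of a 3D array at fractional voxel coordinates
# (1-based, clamped to the grid)
trilinear <- function(a, xi, yi, zi) {
  d <- dim(a)
  xi <- pmin(pmax(xi, 1), d[1]); yi <- pmin(pmax(yi, 1), d[2])
  zi <- pmin(pmax(zi, 1), d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), d[2] - 1L)
  z0 <- pmin(floor(zi), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1L, length(xi))
  if (d[2] == 1L) y0 <- rep(1L, length(yi))
  if (d[3] == 1L) z0 <- rep(1L, length(zi))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  at <- function(i, j, k) a[cbind(i, j, k)]
  (1 - fx) * (1 - fy) * (1 - fz) * at(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * at(x1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * at(x0, y1, z0) +
    fx * fy * (1 - fz) * at(x1, y1, z0) +
    (1 - fx) * (1 - fy) * fz * at(x0, y0, z1) +
    fx * (1 - fy) * fz * at(x1, y0, z1) +
    (1 - fx) * fy * fz * at(x0, y1, z1) +
    fx * fy * fz * at(x1, y1, z1)
}

#' Resample a perfusion map to the standard analysis grid
#'
#' Reconstructions are analysed on a fixed 0.5 x 0.5 x 5 mm grid. Blood
#' flow is resampled by trilinear interpolation, the mask by nearest
#' neighbour. A map already on the target grid is returned unchanged.
#'
#' @param map a [perfusion_map()]
#' @param target_mm target spacing in mm, default `c(0.5, 0.5, 5)`.
#' @return a [perfusion_map()] on the target grid
#' @export
resample_to_standard_grid <- function(map, target_mm = c(0.5, 0.5, 5)) {
  stopifnot(is_perfusion_map(map))
  if (any(target_mm <= 0)) abort("target spacing must be positive")
  if (isTRUE(all.equal(map$voxel_mm, as.numeric(target_mm)))) return(map)
  d <- dim(map$bf)
  extent <- d * map$voxel_mm  # physical size, mm
  nd <- pmax(2L, as.integer(round(extent / target_mm)))
  # voxel-centre physical coordinates of the new grid, mapped to old indices
  coord <- function(n_new, sp_new, sp_old) ((seq_len(n_new) - 0.5) * sp_new) / sp_old + 0.5
  xi <- coord(nd[1], target_mm[1], map$voxel_mm[1])
  yi <- coord(nd[2], target_mm[2], map$voxel_mm[2])
  zi <- coord(nd[3], target_mm[3], map$voxel_mm[3])
  g <- expand.grid(x = xi, y = yi, z = zi)
  bf <- array(trilinear(map$bf, g$x, g$y, g$z), nd)
  mk <- array(map$mask[cbind(pmin(pmax(round(g$x), 1), d[1]),
                             pmin(pmax(round(g$y), 1), d[2]),
                             pmin(pmax(round(g$z), 1), d[3]))], nd)
  bf[!mk] <- 0
  bf[mk & bf <= 0] <- min(bf[bf > 0], 1)
  perfusion_map(bf, mk, target_mm)
}

#' Read a perfusion map from NIfTI
#'
#' Reads a 3D blood-flow volume (and, if present, a companion mask volume
#' `<path>_mask.nii[.gz]`); voxel spacing is taken from the header. Without
#' a companion file the mask defaults to strictly positive voxels, with a
#' warning.
#'
#' @param path path to a 3D NIfTI file of blood flow in mL/min/100 g
#' @param mask_path optional explicit mask file
#' @return a [perfusion_map()]
#' @export
read_perfusion_nifti <- function(path, mask_path = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    abort(sprintf("expected a 3D volume, got %dD (shape %s)",
                  length(dim(img)), paste(dim(img), collapse = "x")))
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    abort("NIfTI header has no usable voxel spacing")
  bf <- array(as.numeric(img), dim(img))
  if (is.null(mask_path)) {
    guess <- sub("\\.nii(\\.gz)?$", "_mask.nii\\1", path)
    if (file.exists(guess)) mask_path <- guess
  }
  if (!is.null(mask_path)) {
    mk <- RNifti::readNifti(mask_path)
    mask <- array(as.numeric(mk) > 0, dim(bf))
  } else {
    warn("no mask companion found; using strictly positive voxels as mask")
    mask <- bf > 0
  }
  perfusion_map(bf, mask, sp)
}

#' Write a perfusion map (and its mask) as NIfTI
#'
#' @param map a [perfusion_map()]
#' @param path output path, `.nii.gz` recommended; the mask is written next
#'   to it with a `_mask` suffix.
#' @return `path`, invisibly
#' @export
write_perfusion_nifti <- function(map, path) {
  stopifnot(is_perfusion_map(map))
  img <- RNifti::asNifti(map$bf)
  RNifti::pixdim(img) <- map$voxel_mm
  RNifti::writeNifti(img, path)
  mpath <- sub("\\.nii(\\.gz)?$", "_mask.nii\\1", path)
  mimg <- RNifti::asNifti(array(as.numeric(map$mask), dim(map$mask)))
  RNifti::pixdim(mimg) <- map$voxel_mm
  RNifti::writeNifti(mimg, mpath)
  invisible(path)
}
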