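box_map <- function(d = c(24, 24, 3), value = 100, voxel = c(0.5, 0.5, 5)) {
  perfusion_map(array(value, d), array(TRUE, d), voxel)
}

test_that("resampling is the identity on the standard grid", {
  m <- generate_perfusion_map(synth_map_spec(grid_shape = c(32, 32, 4),
                                             mask_kind = "box", seed = 1))
  expect_identical(resample_to_standard_grid(m), m)
})

test_that("resampling preserves constant fields", {
  m <- box_map(c(16, 16, 4), value = 77, voxel = c(1, 1, 5))
  r <- resample_to_standard_grid(m)
  expect_equal(r$voxel_mm, c(0.5, 0.5, 5))
  expect_equal(dim(r$bf), c(32, 32, 4))
  expect_true(all(abs(r$bf[r$mask] - 77) < 1e-9))
})

test_that("resampling reproduces a linear ramp in closed form", {
  d <- c(16, 12, 4)
  grid <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                      z = seq_len(d[3]))
  # bf = 10 + 2*x_mm + 3*y_mm + 0.5*z_mm at voxel centres of a 1x1x5 grid
  ramp <- function(xmm, ymm, zmm) 10 + 2 * xmm + 3 * ymm + 0.5 * zmm
  bf <- array(ramp((grid$x - 0.5) * 1, (grid$y - 0.5) * 1,
                   (grid$z - 0.5) * 5), d)
  m <- perfusion_map(bf, array(TRUE, d), c(1, 1, 5))
  r <- resample_to_standard_grid(m)
  d2 <- dim(r$bf)
  g2 <- expand.grid(x = seq_len(d2[1]), y = seq_len(d2[2]),
                    z = seq_len(d2[3]))
  want <- ramp((g2$x - 0.5) * 0.5, (g2$y - 0.5) * 0.5, (g2$z - 0.5) * 5)
  # interior voxels only: linear interpolation is exact there
  interior <- g2$x > 1 & g2$x < d2[1] & g2$y > 1 & g2$y < d2[2]
  expect_lt(max(abs(as.numeric(r$bf)[interior] - want[interior])), 1e-9)
})

annulus_map <- function(n = 40, r_in = 5, r_out = 9, value = 100) {
  d <- c(n, n, 1)
  ctr <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  rad <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2)
  mask <- array(rad >= r_in & rad <= r_out, d)
  bf <- array(0, d); bf[mask] <- value
  perfusion_map(bf, mask, c(0.5, 0.5, 5))
}

test_that("six segments partition an annulus nearly evenly", {
  m <- annulus_map()
  lab <- segment_six(m)
  counts <- table(lab$labels[m$mask])
  expect_equal(length(counts), 6L)
  expect_equal(sum(counts), sum(m$mask))   # labels partition the mask
  expect_lt(max(counts) - min(counts), 3)  # 4-fold symmetric annulus
})

test_that("a voxel at 30 degrees from the centroid lands in sector 1", {
  d <- c(21, 21, 1)
  mask <- array(FALSE, d)
  # centroid-defining symmetric ring plus the probe voxel dominate; use
  # a minimal construction: centroid at the grid centre via 4 symmetric
  # voxels, probe at 30 degrees
  ctr <- 11
  for (off in list(c(5, 0), c(-5, 0), c(0, 5), c(0, -5)))
    mask[ctr + off[1], ctr + off[2], 1] <- TRUE
  probe <- c(round(ctr + 6 * cos(pi / 6)), round(ctr + 6 * sin(pi / 6)))
  mask[probe[1], probe[2], 1] <- TRUE
  bf <- array(0, d); bf[mask] <- 50
  m <- perfusion_map(bf, mask, c(0.5, 0.5, 5))
  lab <- segment_six(m)
  expect_equal(lab$labels[probe[1], probe[2], 1], 1L)
})

test_that("rotating the flow pattern by 60 degrees permutes segment means", {
  n <- 41
  ctr <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  rad <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2)
  ang <- atan2(g$y - ctr, g$x - ctr) %% (2 * pi)
  mask <- array(rad >= 6 & rad <= 12, c(n, n, 1))
  flow <- function(theta) 100 + 40 * cos(theta)
  m1 <- perfusion_map(array(ifelse(mask, flow(ang), 0), dim(mask)), mask)
  m2 <- perfusion_map(array(ifelse(mask, flow(ang - pi / 3), 0), dim(mask)),
                      mask)
  s1 <- segment_stats(m1, segment_six(m1))
  s2 <- segment_stats(m2, segment_six(m2))
  m1means <- s1$mean_bf[s1$slice == 1][1:6]
  m2means <- s2$mean_bf[s2$slice == 1][1:6]
  # rotation by one sector: segment k of m2 matches segment k-1 of m1
  expect_equal(m2means[2:6], m1means[1:5], tolerance = 0.02)
})

test_that("segment statistics report uniform flow exactly", {
  m <- annulus_map(value = 100)
  st <- segment_stats(m, segment_six(m))
  seg_rows <- st[st$segment > 0, ]
  expect_true(all(abs(seg_rows$mean_bf - 100) < 1e-12))
  expect_true(all(abs(seg_rows$median_bf - 100) < 1e-12))
  glob <- st[st$segment == 0, ]
  expect_equal(glob$n, sum(m$mask))
})

test_that("empty slices and empty segments are handled, not fatal", {
  d <- c(20, 20, 2)
  mask <- array(FALSE, d)
  mask[6:15, 6:15, 1] <- TRUE
  bf <- array(0, d); bf[mask] <- 80
  m <- perfusion_map(bf, mask, c(0.5, 0.5, 5))
  expect_warning(lab <- segment_six(m), "empty")
  st <- segment_stats(m, lab)
  empty <- st[st$slice == 2 & st$segment > 0, ]
  expect_true(all(empty$n == 0))
  expect_true(all(is.na(empty$mean_bf)))
})

test_that("misaligned labels are rejected", {
  m <- annulus_map()
  lab <- segment_six(m)
  m2 <- box_map(c(10, 10, 1))
  expect_error(segment_stats(m2, lab), "mismatched")
})

test_that("perfusion reserve is the ratio of masked means", {
  rest <- box_map(value = 100)
  expect_equal(compute_mpr(rest, rest)$mpr, 1)
  stress <- box_map(value = 200)
  expect_equal(compute_mpr(rest, stress)$mpr, 2)
  # the printed group medians: 133 at rest, 271 under stress
  r <- compute_mpr(box_map(value = 133), box_map(value = 271))
  expect_equal(r$mpr, 271 / 133, tolerance = 1e-12)
  expect_equal(r$mpr, 2.038, tolerance = 1e-3)
  expect_equal(r$mpr_percent, 100 * 271 / 133)
})

test_that("perfusion reserve is invariant under joint rescaling", {
  m1 <- generate_perfusion_map(synth_map_spec(grid_shape = c(32, 32, 4),
                                              mask_kind = "box", seed = 6))
  m2 <- perfusion_map(m1$bf * 1.9, m1$mask, m1$voxel_mm)
  base <- compute_mpr(m1, m2)$mpr
  s1 <- perfusion_map(m1$bf * 5, m1$mask, m1$voxel_mm)
  s2 <- perfusion_map(m2$bf * 5, m2$mask, m2$voxel_mm)
  expect_equal(compute_mpr(s1, s2)$mpr, base, tolerance = 1e-12)
})

test_that("perfusion reserve rejects mismatched grids", {
  expect_error(compute_mpr(box_map(c(10, 10, 2)), box_map(c(12, 10, 2))),
               "grid")
})

test_that("NIfTI round trip preserves voxel data and spacing", {
  m <- generate_perfusion_map(synth_map_spec(grid_shape = c(24, 24, 4),
                                             mask_kind = "lv_shell",
                                             voxel_mm = c(2, 2, 5),
                                             seed = 3))
  path <- file.path(withr::local_tempdir(), "map.nii.gz")
  write_perfusion_nifti(m, path)
  m2 <- read_perfusion_nifti(path)
  expect_equal(m2$bf, m$bf, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(unname(m2$mask), unname(m$mask))
  expect_equal(m2$voxel_mm, m$voxel_mm)
})

test_that("NIfTI reader falls back to positive voxels without a mask", {
  m <- generate_perfusion_map(synth_map_spec(grid_shape = c(16, 16, 4),
                                             mask_kind = "box", seed = 3))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "nomask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(m$bf, pixdim = m$voxel_mm), path)
  expect_warning(m2 <- read_perfusion_nifti(path), "mask")
  expect_true(all(m2$mask == (m2$bf > 0)))
})

test_that("NIfTI reader rejects non-3D input", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "vol4d.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 2, 3))), path)
  expect_error(read_perfusion_nifti(path), "3D")
})
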