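test_that("identical spec and seed give bit-identical maps", {
  sp <- synth_map_spec(grid_shape = c(64, 64, 6), mask_kind = "box",
                       target_fd = 1.25, seed = 99)
  m1 <- generate_perfusion_map(sp)
  m2 <- generate_perfusion_map(sp)
  expect_identical(m1$bf, m2$bf)
  expect_identical(m1$mask, m2$mask)
  m3 <- generate_perfusion_map(synth_map_spec(grid_shape = c(64, 64, 6),
                                              mask_kind = "box",
                                              target_fd = 1.25, seed = 100))
  expect_false(identical(m1$bf, m3$bf))
})

test_that("masked mean hits the requested flow within 1%", {
  for (s in 1:3) {
    m <- generate_perfusion_map(synth_map_spec(grid_shape = c(64, 64, 6),
                                               mask_kind = "box",
                                               mean_bf = 133, seed = s))
    expect_lt(abs(masked_mean(m) - 133) / 133, 0.01)
  }
})

test_that("generated flow respects the physical floor and mask flagging", {
  m <- generate_perfusion_map(synth_map_spec(grid_shape = c(64, 64, 6),
                                             rel_sd = 0.9, mask_kind = "box",
                                             mean_bf = 20, seed = 2))
  expect_true(all(m$bf[m$mask] >= 1))
  sh <- generate_perfusion_map(synth_map_spec(seed = 4))
  expect_true(all(sh$bf[!sh$mask] == 0))
})

test_that("invalid specs are rejected", {
  expect_error(synth_map_spec(target_fd = 0.9), "1, 1.5")
  expect_error(synth_map_spec(target_fd = 1.6), "1, 1.5")
  expect_error(synth_map_spec(mean_bf = -5), "mean_bf")
  expect_error(synth_map_spec(noise_fraction = 1.2), "noise_fraction")
  expect_error(synth_map_spec(grid_shape = c(2, 64, 8)), "grid_shape")
  expect_error(
    generate_perfusion_map(synth_map_spec(grid_shape = c(6, 6, 4),
                                          mask_kind = "lv_shell")),
    "degenerate mask")
})

test_that("the LV shell mask spans ~8 cm in Z on the standard grid", {
  sp <- synth_map_spec(seed = 1)
  msk <- lv_shell_mask(sp$grid_shape, sp$voxel_mm)
  z_occ <- apply(msk, 3, any)
  expect_gte(sum(z_occ), 15)       # ~16 slices of 5 mm
  expect_gt(sum(msk), 10000)       # a substantive myocardial volume
  mid <- msk[, , dim(msk)[3] - 1]  # near-base slice is an annulus
  ij <- which(mid, arr.ind = TRUE)
  cx <- mean(range(ij[, 1]))
  expect_false(mid[round(cx), round(mean(range(ij[, 2])))])
})

test_that("cohort generation reproduces the paired study design", {
  spec <- cohort_spec(n_subjects = 3, grid_shape = c(48, 48, 6),
                      mask_kind = "box", seed = 5)
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 12)
  expect_setequal(unique(co$condition), c("NT", "TH"))
  expect_setequal(unique(co$state), c("rest", "stress"))
  expect_true(all(table(co$subject) == 4))
  expect_true(all(sapply(co$map, is_perfusion_map)))
  co2 <- generate_cohort(spec)
  expect_identical(co$fd, co2$fd)
  expect_identical(co$mean_bf, co2$mean_bf)
})

test_that("cohort stress flow scales by the stress ratio", {
  spec <- cohort_spec(n_subjects = 4, stress_ratio = 2,
                      bf_rest_median = 133, grid_shape = c(48, 48, 6),
                      mask_kind = "box", seed = 8)
  co <- generate_cohort(spec, keep_maps = FALSE)
  wide <- tidyr::pivot_wider(co[, c("subject", "condition", "state",
                                    "mean_bf")],
                             names_from = "state", values_from = "mean_bf")
  expect_equal(wide$stress / wide$rest, rep(2, nrow(wide)),
               tolerance = 0.02)
  nt_rest <- co$mean_bf[co$condition == "NT" & co$state == "rest"]
  expect_equal(median(co$mean_bf[co$condition == "NT" &
                                   co$state == "stress"]),
               2 * median(nt_rest), tolerance = 0.05)
})

test_that("null cohort (no effects) has sign-symmetric NT-TH differences", {
  spec <- cohort_spec(n_subjects = 6, fd_th_rest = 1.30,
                      fd_stress_delta = c(nt = 0, th = 0),
                      stress_ratio = 1, bf_th_ratio = 1,
                      grid_shape = c(48, 48, 6), mask_kind = "box",
                      seed = 21)
  co <- generate_cohort(spec, keep_maps = FALSE)
  s <- summarize_paired(co, fd, state = "rest")
  expect_gt(s$p_value, 0.05)
  expect_lt(abs(s$percent_change), 3)
})

test_that("cohort spec validation", {
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
  expect_error(cohort_spec(stress_ratio = 0), "stress_ratio")
  expect_error(cohort_spec(fd_nt_rest = 1.6), "FD")
})

test_that("heterogeneity field grades exactly the prescribed low-flow share", {
  m <- generate_perfusion_map(synth_map_spec(grid_shape = c(48, 48, 4),
                                             mask_kind = "box",
                                             noise_fraction = 1, seed = 13))
  q <- 0.2
  fld <- generate_heterogeneity_field(m, q)
  n_pos <- sum(fld$severity > 0)
  expect_equal(n_pos, floor(q * sum(m$mask)))
  expect_true(all(fld$severity >= 0 & fld$severity <= 1))
  expect_equal(max(fld$severity), 1)       # lowest-flow voxel
  expect_true(all(fld$severity[!m$mask] == 0))
})

test_that("heterogeneity degenerate cases give all-zero fields", {
  m <- generate_perfusion_map(synth_map_spec(grid_shape = c(48, 48, 4),
                                             mask_kind = "box",
                                             noise_fraction = 1, seed = 14))
  expect_true(all(generate_heterogeneity_field(m, 0)$severity == 0))
  u <- generate_perfusion_map(synth_map_spec(grid_shape = c(48, 48, 4),
                                             mask_kind = "box", rel_sd = 0,
                                             seed = 1))
  expect_true(all(generate_heterogeneity_field(u, 0.3)$severity == 0))
  expect_error(generate_heterogeneity_field(m, 1), "low_flow_quantile")
})

test_that("severity resampling to a sheet preserves range and shape", {
  m <- generate_perfusion_map(synth_map_spec(grid_shape = c(48, 48, 4),
                                             mask_kind = "box",
                                             target_fd = 1.3, seed = 15))
  fld <- generate_heterogeneity_field(m, 0.4)
  sf <- resample_severity_sheet(fld, 30, 40)
  expect_equal(dim(sf), c(30, 40))
  expect_true(all(sf >= 0 & sf <= 1))
  expect_gt(sum(sf > 0), 0)
})
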