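test_that("phantom with no regions has an identically zero effect map", {
  spec <- phantom_spec(regions = list())
  ph <- build_phantom(spec)
  expect_true(all(ph$effect_map$values == 0))
  expect_true(all(ph$baseline$values == spec$baseline_level))
})

test_that("sphere rasterization matches per-voxel brute force for disjoint spheres", {
  spec <- phantom_spec(
    grid_shape = c(12L, 12L, 12L), voxel_size_mm = 2,
    regions = list(
      list(center = c(4, 4, 4), radius_mm = 5, effect_sign = 1,
           effect_size = 0.4),
      list(center = c(9, 9, 9), radius_mm = 4, effect_sign = -1,
           effect_size = 0.4)))
  ph <- build_phantom(spec)
  expected <- array(0, dim = spec$grid_shape)
  for (x in 1:12) for (y in 1:12) for (z in 1:12) {
    for (r in spec$regions) {
      dmm <- 2 * sqrt(sum((c(x, y, z) - r$center)^2))
      if (dmm < r$radius_mm)
        expected[x, y, z] <- expected[x, y, z] + r$effect_sign * r$effect_size
    }
  }
  expect_identical(ph$effect_map$values, expected)
  # the two rasterized spheres are disjoint and both non-empty
  expect_gt(sum(expected > 0), 0)
  expect_gt(sum(expected < 0), 0)
  expect_equal(sum(expected != 0), sum(expected > 0) + sum(expected < 0))
})

test_that("overlapping spheres of opposite sign cancel in the overlap", {
  spec <- phantom_spec(
    grid_shape = c(10L, 10L, 10L), voxel_size_mm = 1,
    regions = list(
      list(center = c(4, 5, 5), radius_mm = 3, effect_sign = 1,
           effect_size = 1),
      list(center = c(6, 5, 5), radius_mm = 3, effect_sign = -1,
           effect_size = 1)))
  eff <- build_phantom(spec)$effect_map$values
  expect_equal(eff[5, 5, 5], 0)  # inside both spheres
  expect_equal(eff[3, 5, 5], 1)  # only the positive sphere
  expect_equal(eff[7, 5, 5], -1)
})

test_that("a region centered off the grid is rejected by name", {
  expect_error(
    phantom_spec(grid_shape = c(8L, 8L, 8L),
                 regions = list(list(center = c(9, 4, 4), radius_mm = 2,
                                     effect_sign = 1, effect_size = 1))),
    "region 1.*outside the grid")
})

test_that("the study-sized design yields 38 scans and 38 volumes", {
  design <- default_design(c(13L, 6L))
  expect_equal(nrow(design), 38L)
  spec <- phantom_spec(grid_shape = c(6L, 6L, 6L), regions = list())
  vols <- simulate_cohort(spec, design)
  expect_length(vols, 38L)
})

test_that("cohort design validation enforces the paired two-season structure", {
  expect_error(cohort_design("s1", "nonSAD", "summer"), "exactly twice")
  expect_error(cohort_design(c("s1", "s1"), c("nonSAD", "nonSAD"),
                             c("summer", "summer")), "once per season")
  expect_error(cohort_design(c("s1", "s1"), c("nonSAD", "nonSAD"),
                             c("summer", "autumn")), "unknown season")
  expect_error(cohort_design(c("s1", "s1"), c("nonSAD", "HC"),
                             c("summer", "winter")), "unknown group")
})

test_that("degenerate noise settings reproduce the deterministic signal model", {
  design <- default_design(c(2L, 2L))
  spec0 <- phantom_spec(grid_shape = c(6L, 6L, 6L),
                        regions = list(), subject_sd = 0, noise_sd = 0,
                        n_subjects_per_group = c(2L, 2L))
  vols <- simulate_cohort(spec0, design)
  for (v in vols) expect_equal(v$values, array(1.5, dim = c(6, 6, 6)))

  # with a planted effect but no noise, each scan is baseline + c * effect
  spec1 <- phantom_spec(grid_shape = c(8L, 8L, 8L),
                        regions = list(list(center = c(4, 4, 4),
                                            radius_mm = 4, effect_sign = 1,
                                            effect_size = 0.5)),
                        subject_sd = 0, noise_sd = 0,
                        n_subjects_per_group = c(2L, 2L))
  eff <- build_phantom(spec1)$effect_map$values
  vols1 <- simulate_cohort(spec1, design)
  for (i in seq_len(nrow(design))) {
    w <- condition_weight(design$group[i], design$season[i])
    expect_equal(vols1[[i]]$values, 1.5 + w * eff)
  }
})

test_that("seeding is reproducible and mismatched counts are rejected", {
  design <- default_design(c(3L, 2L))
  spec <- phantom_spec(grid_shape = c(5L, 5L, 5L), regions = list(),
                       n_subjects_per_group = c(3L, 2L), seed = 42L)
  a <- simulate_cohort(spec, design)
  b <- simulate_cohort(spec, design)
  expect_identical(a, b)
  spec2 <- phantom_spec(grid_shape = c(5L, 5L, 5L), regions = list(),
                        n_subjects_per_group = c(3L, 2L), seed = 43L)
  c2 <- simulate_cohort(spec2, design)
  expect_false(identical(a[[1]]$values, c2[[1]]$values))
  spec_bad <- phantom_spec(grid_shape = c(5L, 5L, 5L), regions = list(),
                           n_subjects_per_group = c(4L, 2L))
  expect_error(simulate_cohort(spec_bad, design), "declares 4")
})

test_that("voxelwise means converge to the signal model over noise realizations", {
  design <- default_design(c(2L, 2L))
  n_rep <- 60L
  spec_of <- function(s) phantom_spec(
    grid_shape = c(6L, 6L, 6L),
    regions = list(list(center = c(3, 3, 3), radius_mm = 4,
                        effect_sign = 1, effect_size = 0.5)),
    n_subjects_per_group = c(2L, 2L), subject_sd = 0, noise_sd = 0.2,
    seed = s)
  eff <- build_phantom(spec_of(1))$effect_map$values
  # average the nonSAD-winter scan (record 2) over independent cohorts
  acc <- 0
  for (s in seq_len(n_rep)) acc <- acc + simulate_cohort(spec_of(s), design)[[2]]$values
  avg <- acc / n_rep
  truth <- 1.5 + eff
  # SE per voxel = 0.2 / sqrt(60); deviations should look like that scale
  expect_lt(max(abs(avg - truth)), 5 * 0.2 / sqrt(n_rep))
})

test_that("group-difference image recovers twice the planted map as noise vanishes", {
  spec <- phantom_spec(noise_sd = 0.005, subject_sd = 0, seed = 3L)
  design <- default_design(spec$n_subjects_per_group)
  vols <- simulate_cohort(spec, design)
  eff <- build_phantom(spec)$effect_map$values
  iw_hc <- which(design$group == "nonSAD" & design$season == "winter")
  iw_sad <- which(design$group == "SAD" & design$season == "winter")
  m <- function(ix) Reduce(`+`, lapply(vols[ix], `[[`, "values")) / length(ix)
  dimg <- m(iw_hc) - m(iw_sad)
  expect_gt(cor(as.numeric(dimg), as.numeric(2 * eff)), 0.999)
})
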