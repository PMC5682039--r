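test_that("component labeling agrees with brute-force flood fill", {
  set.seed(51)
  for (conn in c(6L, 18L, 26L)) {
    for (rep in 1:6) {
      d <- sample(3:8, 3, replace = TRUE)
      mask <- array(runif(prod(d)) < 0.4, dim = d)
      expect_true(same_partition(label_components(mask, conn),
                                 flood_fill_labels(mask, conn)),
                  label = sprintf("connectivity %d rep %d", conn, rep))
    }
  }
  # empty and full masks
  empty <- array(FALSE, dim = c(3, 3, 3))
  expect_true(all(label_components(empty, 26L) == 0L))
  full <- array(TRUE, dim = c(3, 3, 3))
  expect_equal(max(label_components(full, 6L)), 1L)
})

test_that("sub-threshold maps give an empty cluster table", {
  z <- voxel_volume(array(runif(5^3, -2, 2), dim = c(5, 5, 5)), 1)
  tab <- threshold_clusters(z, 2.8, 640)
  expect_equal(nrow(tab), 0L)
})

test_that("the extent threshold removes small blobs but keeps large ones", {
  z <- array(0, dim = c(20, 20, 20))
  z[1:7, 1:10, 1:10] <- 3.0    # 700 voxels at z = 3
  z[15:18, 15:19, 15:19] <- 3.5  # 100 voxels at z = 3.5
  tab <- threshold_clusters(voxel_volume(z, 1), 2.8, 640)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$size_vox, 700L)
  expect_equal(tab$peak_zscore, 3.0)
  # brute-force: the suprathreshold set has exactly two components
  expect_equal(max(flood_fill_labels(z > 2.8, 26L)), 2L)
})

test_that("extent is applied in cubic millimetres, not voxels", {
  # 2 mm voxels: 640 mm^3 = 80 voxels; an 80-voxel blob survives, 79 not
  z <- array(0, dim = c(12, 12, 24))
  z[1:4, 1:4, 1:5] <- 3          # 80 voxels
  z79 <- array(0, dim = c(12, 12, 24))
  z79[1:4, 1:4, 20:24] <- 3
  z79[4, 4, 24] <- 0             # 79 voxels
  expect_equal(nrow(threshold_clusters(voxel_volume(z, 2), 2.8, 640)), 1L)
  expect_equal(nrow(threshold_clusters(voxel_volume(z79, 2), 2.8, 640)), 0L)
})

test_that("opposite-sign clusters never merge and peaks break ties lexicographically", {
  z <- array(0, dim = c(10, 4, 4))
  z[1:3, 1:4, 1:4] <- 3     # positive blob, 48 voxels
  z[4:6, 1:4, 1:4] <- -3    # adjacent negative blob
  tab <- threshold_clusters(voxel_volume(z, 2), 2.8, 100)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$sign, c(1, -1))
  # all |z| equal within each blob: peak must be the lexicographically
  # smallest coordinate
  pos <- tab[tab$sign == 1, ]
  expect_equal(c(pos$peak_x, pos$peak_y, pos$peak_z), c(1, 1, 1))
  neg <- tab[tab$sign == -1, ]
  expect_equal(c(neg$peak_x, neg$peak_y, neg$peak_z), c(4, 1, 1))
})

test_that("condition scores are grand-mean centered with sane bootstrap CIs", {
  design <- default_design(c(3L, 2L))
  # all scores equal: zero means and zero-width CIs
  cs0 <- condition_brain_scores(rep(2.5, 10), design, n_boot = 50, seed = 1)
  expect_true(all(cs0$table$mean == 0))
  expect_true(all(cs0$table$ci_low == 0 & cs0$table$ci_high == 0))

  set.seed(52)
  x <- rnorm(10)
  cs <- condition_brain_scores(x, design, n_boot = 500, seed = 2)
  # weighted sum of condition means (weights = sizes) vanishes
  expect_lt(abs(sum(cs$table$mean * cs$table$n)), 1e-9)
  expect_true(all(cs$table$ci_low <= cs$table$mean + 1e-12 &
                    cs$table$mean <= cs$table$ci_high + 1e-12))
  # the alternative centering convention differs with unequal groups
  cs_alt <- condition_brain_scores(x, design, n_boot = 10, seed = 2,
                                   center = "condition_means")
  expect_lt(abs(mean(cs_alt$table$mean)), 1e-9)
  expect_false(isTRUE(all.equal(cs$grand_mean, cs_alt$grand_mean)))
})

test_that("bootstrap CI width shrinks as condition size grows", {
  widths <- vapply(c(6L, 24L, 96L), function(n) {
    design <- default_design(c(n, n))
    set.seed(53)
    x <- rnorm(4 * n, sd = 1)  # fixed variance, growing condition size
    cs <- condition_brain_scores(x, design, n_boot = 400, seed = 3)
    mean(cs$table$ci_high - cs$table$ci_low)
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("planted-effect winter conditions separate with disjoint CIs", {
  dat <- make_cohort_data(strong_spec(seed = 54L))
  m <- fit_pls(dat$X, dat$Y)
  bs <- brain_scores(dat$X, m)
  cs <- condition_brain_scores(bs, n_boot = 400, seed = 4)
  tab <- cs$table
  hw <- tab[tab$condition == "nonSAD.winter", ]
  sw <- tab[tab$condition == "SAD.winter", ]
  expect_true(hw$ci_low > sw$ci_high || sw$ci_low > hw$ci_high)
})

test_that("the six contrasts use paired tests within group and pooled otherwise", {
  design <- default_design(c(4L, 3L))
  set.seed(55)
  x <- rnorm(14)
  cs <- condition_brain_scores(x, design, n_boot = 10, seed = 5)
  tab <- contrast_tests(cs)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$paired, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(tab$p_bonferroni, tab$p_uncorrected * 6)

  # oracle: direct t.test calls on the same centered scores
  xc <- cs$centered
  cond <- paste(design$group, design$season, sep = ".")
  o_paired <- t.test(xc[cond == "nonSAD.summer"], xc[cond == "nonSAD.winter"],
                     paired = TRUE)
  expect_equal(tab$t[1], unname(o_paired$statistic), tolerance = 1e-12)
  expect_equal(tab$p_uncorrected[1], o_paired$p.value, tolerance = 1e-12)
  o_two <- t.test(xc[cond == "nonSAD.winter"], xc[cond == "SAD.winter"],
                  var.equal = TRUE)
  expect_equal(tab$t[6], unname(o_two$statistic), tolerance = 1e-12)
  expect_equal(tab$p_uncorrected[6], o_two$p.value, tolerance = 1e-12)
})

test_that("exchanging the group labels negates t and preserves p", {
  design <- default_design(c(3L, 3L))
  set.seed(56)
  x <- rnorm(12)
  flipped <- structure(
    data.frame(subject = design$subject,
               group = ifelse(design$group == "SAD", "nonSAD", "SAD"),
               season = design$season, stringsAsFactors = FALSE),
    class = c("cohort_design", "data.frame"))
  a <- contrast_tests(x, design)
  b <- contrast_tests(x, flipped)
  # nonSAD.winter vs SAD.winter swaps roles exactly
  expect_equal(b$t[6], -a$t[6], tolerance = 1e-12)
  expect_equal(b$p_uncorrected[6], a$p_uncorrected[6], tolerance = 1e-12)
  # the cross contrasts 4 and 5 swap with each other, negated
  expect_equal(b$t[4], -a$t[5], tolerance = 1e-12)
  expect_equal(b$t[5], -a$t[4], tolerance = 1e-12)
  expect_equal(sort(b$p_uncorrected), sort(a$p_uncorrected), tolerance = 1e-12)
})

test_that("paired contrasts require a complete subject pairing", {
  design <- default_design(c(3L, 3L))
  broken <- design
  broken$subject[design$season == "winter" & design$subject == "HC01"] <- "HC99"
  set.seed(57)
  expect_error(contrast_tests(rnorm(12), broken), "subject sets differ")
})

test_that("summary-statistic t-tests agree with t.test on reconstructed samples", {
  # build samples with exactly the requested mean and SD, then compare
  mk <- function(mean, sd, n) {
    z <- scale(rnorm(n))  # exact mean 0, sd 1
    as.numeric(mean + sd * z)
  }
  set.seed(58)
  g1 <- mk(22.8, 2.3, 13)
  g2 <- mk(20.9, 1.7, 6)
  ours <- t_from_summary(22.8, 2.3, 13, 20.9, 1.7, 6)
  oracle <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(ours$t, unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(ours$df, unname(oracle$parameter))
  expect_equal(ours$p, oracle$p.value, tolerance = 1e-9)

  same <- t_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(t_from_summary(3, 0, 5, 3, 0, 5)$p, 1)
  expect_error(t_from_summary(3, 0, 5, 4, 0, 5), "undefined")
  expect_error(t_from_summary(3, 1, 1, 4, 1, 5), "n >= 2")
})
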