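#' Phantom specification for synthetic parametric-image cohorts
#'
#' Defines the geometry and statistical structure of a synthetic PET-like
#' cohort: a constant baseline volume, a set of spherical regions carrying a
#' planted group-by-season effect, per-subject whole-volume random
#' intercepts, and i.i.d. Gaussian voxel noise.
#'
#' The defaults emulate a two-group, two-season binding-potential study at
#' desk scale: a 16^3 grid of 2 mm voxels, baseline BP_ND 1.5, one positive
#' and one negative 6-mm-radius sphere with effect size 0.25 BP_ND,
#' between-subject SD 0.15 and voxel noise SD 0.10.
#'
#' @param grid_shape integer triple, voxels per axis (all >= 1).
#' @param voxel_size_mm positive scalar, isotropic voxel size.
#' @param baseline_level scalar baseline intensity (BP_ND units).
#' @param regions list of regions, each a list with fields `center`
#'   (1-based voxel triple), `radius_mm` (> 0), `effect_sign` (+1 or -1) and
#'   `effect_size` (>= 0, BP_ND units).
#' @param n_subjects_per_group integer pair `(n_nonSAD, n_SAD)`.
#' @param subject_sd SD of the per-subject whole-volume intercept (>= 0).
#' @param noise_sd SD of i.i.d. voxel noise per scan (>= 0).
#' @param seed integer seed for the cohort's RNG stream.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(16L, 16L, 16L),
                         voxel_size_mm = 2,
                         baseline_level = 1.5,
                         regions = list(
                           list(center = c(5, 8, 8), radius_mm = 6,
                                effect_sign = +1, effect_size = 0.25),
                           list(center = c(12, 8, 8), radius_mm = 6,
                                effect_sign = -1, effect_size = 0.25)
                         ),
                         n_subjects_per_group = c(13L, 6L),
                         subject_sd = 0.15,
                         noise_sd = 0.10,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be three integers >= 1")
  if (voxel_size_mm <= 0) stop("`voxel_size_mm` must be positive")
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    if (!all(c("center", "radius_mm", "effect_sign", "effect_size") %in%
             names(r)))
      stop("region ", i, " is missing fields")
    if (r$radius_mm <= 0) stop("region ", i, ": radius_mm must be > 0")
    if (!r$effect_sign %in% c(-1, 1))
      stop("region ", i, ": effect_sign must be +1 or -1")
    if (r$effect_size < 0) stop("region ", i, ": effect_size must be >= 0")
    if (any(r$center < 1) || any(r$center > grid_shape))
      stop("region ", i, ": center (", paste(r$center, collapse = ", "),
           ") lies outside the grid")
  }
  n_subjects_per_group <- as.integer(n_subjects_per_group)
  if (length(n_subjects_per_group) != 2L || any(n_subjects_per_group < 1L))
    stop("`n_subjects_per_group` must be two positive integers")
  if (subject_sd < 0 || noise_sd < 0)
    stop("`subject_sd` and `noise_sd` must be >= 0")
  structure(
    list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
         baseline_level = baseline_level, regions = regions,
         n_subjects_per_group = n_subjects_per_group,
         subject_sd = subject_sd, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Cohort design table
#'
#' An ordered table of scan records (subject, group, season).  Record order
#' is the canonical row order of every downstream matrix.  Every subject
#' must appear exactly twice, once per season.
#'
#' @param subject character/factor vector of subject ids, one per scan.
#' @param group vector with levels `nonSAD` and `SAD`.
#' @param season vector with levels `summer` and `winter`.
#' @return A `cohort_design` data frame with columns subject, group, season.
#' @export
cohort_design <- function(subject, group, season) {
  subject <- as.character(subject)
  group <- as.character(group)
  season <- as.character(season)
  n <- length(subject)
  if (length(group) != n || length(season) != n)
    stop("subject, group and season must have equal length")
  if (!all(group %in% c("nonSAD", "SAD")))
    stop("unknown group token: ",
         paste(unique(setdiff(group, c("nonSAD", "SAD"))), collapse = ", "))
  if (!all(season %in% c("summer", "winter")))
    stop("unknown season token: ",
         paste(unique(setdiff(season, c("summer", "winter"))), collapse = ", "))
  for (s in unique(subject)) {
    sea <- season[subject == s]
    if (length(sea) != 2L || !setequal(sea, c("summer", "winter")))
      stop("subject ", s, " must appear exactly twice, once per season")
    if (length(unique(group[subject == s])) != 1L)
      stop("subject ", s, " has inconsistent group labels")
  }
  structure(
    data.frame(subject = subject, group = group, season = season,
               stringsAsFactors = FALSE),
    class = c("cohort_design", "data.frame")
  )
}

#' Default study-like design: both groups scanned in both seasons
#'
#' Builds the canonical two-scans-per-subject design for given group sizes,
#' ordered subject-major with summer before winter (13 + 6 subjects give the
#' study-sized 38-scan table).
#'
#' @param n_per_group integer pair `(n_nonSAD, n_SAD)`.
#' @return A [cohort_design()].
#' @export
default_design <- function(n_per_group = c(13L, 6L)) {
  n_per_group <- as.integer(n_per_group)
  ids <- c(sprintf("HC%02d", seq_len(n_per_group[1])),
           sprintf("SAD%02d", seq_len(n_per_group[2])))
  grp <- rep(c("nonSAD", "SAD"), times = n_per_group)
  cohort_design(subject = rep(ids, each = 2L),
                group = rep(grp, each = 2L),
                season = rep(c("summer", "winter"), times = sum(n_per_group)))
}

#' Rasterize the phantom baseline and planted-effect volumes
#'
#' The effect map is zero outside all region spheres; inside a sphere it is
#' `effect_sign * effect_size`, and overlapping spheres sum.  A voxel belongs
#' to a sphere iff its center lies strictly within `radius_mm` of the region
#' center (distances in mm).
#'
#' @param spec a [phantom_spec()].
#' @return List with [voxel_volume()] elements `baseline` and `effect_map`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  baseline <- array(spec$baseline_level, dim = d)
  eff <- array(0, dim = d)
  if (length(spec$regions) > 0L) {
    cx <- slice.index(eff, 1L)
    cy <- slice.index(eff, 2L)
    cz <- slice.index(eff, 3L)
    for (r in spec$regions) {
      dist2 <- (cx - r$center[1])^2 + (cy - r$center[2])^2 +
        (cz - r$center[3])^2
      inside <- dist2 * spec$voxel_size_mm^2 < r$radius_mm^2
      eff[inside] <- eff[inside] + r$effect_sign * r$effect_size
    }
  }
  list(baseline = voxel_volume(baseline, spec$voxel_size_mm),
       effect_map = voxel_volume(eff, spec$voxel_size_mm))
}

#' Group-by-season contrast weights for the planted pattern
#'
#' Default coding plants the effect in winter with opposite sign in the two
#' groups: `c(nonSAD, winter) = +1`, `c(SAD, winter) = -1`, both summers 0 —
#' a seasonal dissociation between the groups.
#'
#' @param group,season character vectors (recycled elementwise).
#' @param weights named numeric vector over the four cells
#'   `nonSAD.summer`, `nonSAD.winter`, `SAD.summer`, `SAD.winter`.
#' @return Numeric vector of contrast weights.
#' @export
condition_weight <- function(group, season,
                             weights = c(nonSAD.summer = 0, nonSAD.winter = 1,
                                         SAD.summer = 0, SAD.winter = -1)) {
  unname(weights[paste(group, season, sep = ".")])
}

#' Simulate a cohort of parametric volumes
#'
#' Each scan volume is
#' `baseline + c(group, season) * effect_map + subject_offset + noise`,
#' with `subject_offset ~ N(0, subject_sd)` constant over the volume and
#' `noise ~ N(0, noise_sd)` i.i.d. per voxel.  A single RNG stream is seeded
#' from `spec$seed`; all subject offsets are drawn before any noise field, so
#' the offsets do not depend on how many noise fields are consumed.
#'
#' @param spec a [phantom_spec()].
#' @param design a [cohort_design()] whose group counts match
#'   `spec$n_subjects_per_group`.
#' @param weights cell weights passed to [condition_weight()].
#' @return List of [voxel_volume()], one per design record, in record order.
#' @export
simulate_cohort <- function(spec, design,
                            weights = c(nonSAD.summer = 0, nonSAD.winter = 1,
                                        SAD.summer = 0, SAD.winter = -1)) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(design, "cohort_design"))
  subj <- unique(design$subject)
  grp_of <- vapply(subj, function(s) design$group[design$subject == s][1], "")
  counts <- c(sum(grp_of == "nonSAD"), sum(grp_of == "SAD"))
  if (!identical(as.integer(counts), spec$n_subjects_per_group))
    stop("design has ", counts[1], " + ", counts[2],
         " subjects but spec declares ",
         spec$n_subjects_per_group[1], " + ", spec$n_subjects_per_group[2])
  ph <- build_phantom(spec)
  base <- ph$baseline$values
  eff <- ph$effect_map$values
  set.seed(spec$seed)
  offsets <- stats::rnorm(length(subj), 0, spec$subject_sd)
  names(offsets) <- subj
  nvox <- prod(spec$grid_shape)
  lapply(seq_len(nrow(design)), function(i) {
    w <- condition_weight(design$group[i], design$season[i], weights)
    noise <- if (spec$noise_sd > 0)
      array(stats::rnorm(nvox, 0, spec$noise_sd), dim = spec$grid_shape)
    else 0
    voxel_volume(base + w * eff + offsets[[design$subject[i]]] + noise,
                 spec$voxel_size_mm)
  })
}

#' Tissue-probability volumes for the phantom
#'
#' Gray-matter probability is 1 inside a brain ellipsoid (default: sphere of
#' radius `radius_voxels` at the grid center) and 0 outside; CSF probability
#' is 0 everywhere, so the default mask thresholds keep the whole phantom
#' brain.
#'
#' @param spec a [phantom_spec()].
#' @param semiaxes_voxels ellipsoid semi-axes in voxels (length 3).
#' @return List with [voxel_volume()] elements `gm` and `csf`.
#' @export
phantom_tissue_maps <- function(spec, semiaxes_voxels = c(7, 7, 7)) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  ctr <- (d + 1) / 2
  a <- array(0, dim = d)
  u <- ((slice.index(a, 1L) - ctr[1]) / semiaxes_voxels[1])^2 +
    ((slice.index(a, 2L) - ctr[2]) / semiaxes_voxels[2])^2 +
    ((slice.index(a, 3L) - ctr[3]) / semiaxes_voxels[3])^2
  gm <- array(as.numeric(u <= 1), dim = d)
  list(gm = voxel_volume(gm, spec$voxel_size_mm),
       csf = voxel_volume(array(0, dim = d), spec$voxel_size_mm))
}

#' Write a simulated cohort to disk
#'
#' Writes one NIfTI volume per scan plus a design table
#' (`design.csv` with columns subject,group,season,filename) and the GM/CSF
#' probability volumes.
#'
#' @param spec a [phantom_spec()].
#' @param design a [cohort_design()].
#' @param dir output directory (created if missing).
#' @param ... passed to [simulate_cohort()].
#' @return Invisibly, the design table with a `filename` column.
#' @export
write_cohort <- function(spec, design, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vols <- simulate_cohort(spec, design, ...)
  fn <- sprintf("scan_%03d_%s_%s.nii.gz", seq_len(nrow(design)),
                design$subject, design$season)
  for (i in seq_along(vols)) write_volume(vols[[i]], file.path(dir, fn[i]))
  tis <- phantom_tissue_maps(spec)
  write_volume(tis$gm, file.path(dir, "gm_prob.nii.gz"))
  write_volume(tis$csf, file.path(dir, "csf_prob.nii.gz"))
  tab <- cbind(as.data.frame(design), filename = fn)
  utils::write.csv(tab, file.path(dir, "design.csv"), row.names = FALSE)
  invisible(tab)
}
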