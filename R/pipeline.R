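#' Build and validate a pipeline run configuration
#'
#' Collects every tunable of the simulate -> mask -> PLS -> NPAIRS ->
#' subspace-selection -> reporting pipeline in one validated list.
#' Protocol defaults follow the analysis conventions this pipeline
#' implements: 1000 split-half resamples, Z threshold 2.8, 640 mm^3 cluster
#' extent, 95% bootstrap CIs.
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"read"`
#'   (read volumes listed in a design CSV).
#' @param phantom a [phantom_spec()] (simulate mode).
#' @param design_csv path to a design table CSV with columns
#'   subject,group,season,filename (read mode).
#' @param gm_path,csf_path tissue-probability NIfTI paths (read mode).
#' @param gm_thresh,csf_thresh mask thresholds (defaults 0.1 and 0.3).
#' @param fwhm_mm Gaussian smoothing FWHM applied to each volume before
#'   masking; 0 (default) disables smoothing.
#' @param n_splits split-half resamples for the final NPAIRS run.
#' @param curve_n_splits shared-schedule resamples for the subspace sweep
#'   (default 200).
#' @param k_max largest PC-subspace dimension (default: min half size - 1).
#' @param z_thresh,extent_mm3,connectivity cluster-reporting parameters.
#' @param n_boot bootstrap resamples for condition-score CIs.
#' @param seed master seed for every random stage.
#' @param out_dir output directory.
#' @param cor_mode see [evaluate_split()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "read"),
                       phantom = phantom_spec(),
                       design_csv = NULL, gm_path = NULL, csf_path = NULL,
                       gm_thresh = 0.1, csf_thresh = 0.3,
                       fwhm_mm = 0,
                       n_splits = 1000L, curve_n_splits = 200L,
                       k_max = NULL,
                       z_thresh = 2.8, extent_mm3 = 640,
                       connectivity = 26L,
                       n_boot = 1000L, seed = 1L, out_dir = NULL,
                       cor_mode = c("matrix", "perlv")) {
  mode <- match.arg(mode)
  cor_mode <- match.arg(cor_mode)
  fail <- function(field, msg) stop("invalid config field `", field, "`: ",
                                    msg, call. = FALSE)
  if (mode == "simulate") {
    if (!inherits(phantom, "phantom_spec"))
      fail("phantom", "must be a phantom_spec")
  } else {
    for (f in c("design_csv", "gm_path", "csf_path")) {
      p <- get(f)
      if (is.null(p) || !file.exists(p))
        fail(f, "path missing or does not exist")
    }
  }
  if (fwhm_mm < 0) fail("fwhm_mm", "must be >= 0")
  if (n_splits < 2) fail("n_splits", "must be >= 2")
  if (curve_n_splits < 2) fail("curve_n_splits", "must be >= 2")
  if (z_thresh <= 0) fail("z_thresh", "must be > 0")
  if (extent_mm3 <= 0) fail("extent_mm3", "must be > 0")
  if (!connectivity %in% c(6L, 18L, 26L))
    fail("connectivity", "must be 6, 18 or 26")
  if (n_boot < 1) fail("n_boot", "must be >= 1")
  structure(
    list(mode = mode, phantom = phantom, design_csv = design_csv,
         gm_path = gm_path, csf_path = csf_path,
         gm_thresh = gm_thresh, csf_thresh = csf_thresh, fwhm_mm = fwhm_mm,
         n_splits = as.integer(n_splits),
         curve_n_splits = as.integer(curve_n_splits),
         k_max = if (is.null(k_max)) NULL else as.integer(k_max),
         z_thresh = z_thresh, extent_mm3 = extent_mm3,
         connectivity = as.integer(connectivity),
         n_boot = as.integer(n_boot), seed = as.integer(seed),
         out_dir = out_dir, cor_mode = cor_mode),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML or JSON document
#'
#' @param path path to a YAML (or JSON, a YAML subset) config file whose
#'   keys mirror the [run_config()] arguments; `phantom` is a mapping of
#'   [phantom_spec()] arguments.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$phantom)) {
    ph <- doc$phantom
    if (!is.null(ph$regions))
      ph$regions <- lapply(ph$regions, function(r) {
        r$center <- as.numeric(unlist(r$center))
        r
      })
    doc$phantom <- do.call(phantom_spec, ph)
  }
  do.call(run_config, doc)
}

# Read a cohort written by write_cohort(): volumes in design order.
read_cohort <- function(design_csv) {
  tab <- utils::read.csv(design_csv, stringsAsFactors = FALSE)
  need <- c("subject", "group", "season", "filename")
  if (!all(need %in% names(tab)))
    stop("design CSV must have columns ", paste(need, collapse = ","))
  dirn <- dirname(design_csv)
  vols <- lapply(tab$filename, function(f) {
    p <- if (file.exists(f)) f else file.path(dirn, f)
    read_volume(p)
  })
  list(design = cohort_design(tab$subject, tab$group, tab$season),
       volumes = vols)
}

#' Run the full analysis pipeline
#'
#' Executes every stage from a single configuration: data (simulated or
#' read), optional Gaussian smoothing, tissue-probability masking, data and
#' design matrix assembly, full-data PLS, adaptive PC-subspace selection by
#' D(k) on a shared split schedule, a final NPAIRS run at the selected k*
#' (salience mean/SE/Z maps, empirical p-values), cluster-extent
#' thresholding, and condition brain scores with bootstrap CIs and
#' Bonferroni-corrected contrasts.  When `out_dir` is set, writes the Z and
#' salience maps as NIfTI, the subspace curve and split metrics as CSV, the
#' cluster and contrast tables as TSV, and a JSON run report.
#'
#' @param config a `run_config` (or path to a YAML config, passed through
#'   [load_run_config()]).
#' @return Invisibly, a list with `design`, `mask`, `model`, `curve`,
#'   `npairs`, `clusters`, `condition_scores`, `contrasts`, `report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))

  if (config$mode == "simulate") {
    design <- default_design(config$phantom$n_subjects_per_group)
    volumes <- simulate_cohort(config$phantom, design)
    tissue <- phantom_tissue_maps(config$phantom)
    gm <- tissue$gm
    csf <- tissue$csf
  } else {
    ch <- read_cohort(config$design_csv)
    design <- ch$design
    volumes <- ch$volumes
    gm <- read_volume(config$gm_path)
    csf <- read_volume(config$csf_path)
  }
  if (config$fwhm_mm > 0)
    volumes <- lapply(volumes, gaussian_smooth, fwhm_mm = config$fwhm_mm)

  mask <- build_mask(gm, csf, config$gm_thresh, config$csf_thresh)
  X <- assemble_data_matrix(volumes, design, mask)
  Y <- encode_design(design)

  model <- fit_pls(X, Y)
  curve <- select_optimal_k(X, Y, design, k_max = config$k_max,
                            n_splits = config$curve_n_splits,
                            seed = config$seed, cor_mode = config$cor_mode)
  np <- run_npairs(X, Y, design, k = curve$k_star,
                   n_splits = config$n_splits, seed = config$seed,
                   cor_mode = config$cor_mode, reference = curve$reference)

  zvol <- unmask_to_volume(np$zmap, mask)
  clusters <- threshold_clusters(zvol, config$z_thresh, config$extent_mm3,
                                 config$connectivity)
  bs <- brain_scores(X, model)
  cs <- condition_brain_scores(bs, lv = 1L, n_boot = config$n_boot,
                               seed = config$seed)
  ct <- contrast_tests(cs)

  report <- list(
    seed = config$seed,
    n_scans = nrow(design),
    n_mask_voxels = nrow(mask$voxel_index),
    lv1_cov_fraction = model$cov_fraction[1],
    k_star = curve$k_star,
    D_k_star = curve$D[curve$k_star],
    D_reference = curve$reference_metrics$D,
    mean_r_test = curve$mean_r_test[curve$k_star],
    mean_r_spatial = curve$mean_r_spatial[curve$k_star],
    p_test = np$p_test,
    p_spatial = np$p_spatial,
    n_clusters = nrow(clusters),
    n_splits = np$n_splits,
    connectivity = config$connectivity,
    z_thresh = config$z_thresh,
    extent_mm3 = config$extent_mm3,
    package_version = as.character(utils::packageVersion("npairspls")),
    r_version = R.version.string
  )

  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    write_volume(zvol, file.path(od, "zmap.nii.gz"))
    write_volume(unmask_to_volume(np$salience_mean, mask),
                 file.path(od, "salience_mean.nii.gz"))
    write_volume(unmask_to_volume(np$salience_se, mask),
                 file.path(od, "salience_se.nii.gz"))
    utils::write.csv(subspace_curve_table(curve),
                     file.path(od, "subspace_curve.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(split_id = seq_len(np$n_splits),
                 r_train_A = np$r_train[, "A"], r_train_B = np$r_train[, "B"],
                 r_test_A = np$r_test[, "A"], r_test_B = np$r_test[, "B"],
                 r_spatial = np$r_spatial),
      file.path(od, "npairs_metrics.csv"), row.names = FALSE)
    utils::write.table(clusters, file.path(od, "clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(ct, file.path(od, "contrasts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cs$table, file.path(od, "condition_scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report, file.path(od, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(design = design, mask = mask, model = model, curve = curve,
                 npairs = np, clusters = clusters, condition_scores = cs,
                 contrasts = ct, report = report))
}
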