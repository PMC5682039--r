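#' Reduce a standardized half to its top-k principal components
#'
#' PCA by SVD of the (already column-standardized) half: the reduced data
#' are the first `k` left singular vectors scaled by their singular values,
#' and the back-projection map is the corresponding right singular vectors,
#' which carries subspace saliences back to voxel space with norms
#' preserved.
#'
#' @param X_half standardized scans-by-voxels matrix.
#' @param k number of components, `1 <= k <= min(rows - 1, columns)`.
#' @return List with `scores` (scans x k), `basis` (voxels x k, orthonormal
#'   columns) and `singvals`.
#' @export
reduce_to_pcs <- function(X_half, k) {
  X_half <- as.matrix(X_half)
  kmax <- min(nrow(X_half) - 1L, ncol(X_half))
  if (k < 1L || k > kmax)
    stop("k = ", k, " out of range; need 1 <= k <= ", kmax,
         " (min(rows - 1, columns))")
  sv <- svd(X_half)
  list(scores = sv$u[, seq_len(k), drop = FALSE] %*%
         diag(sv$d[seq_len(k)], k),
       basis = sv$v[, seq_len(k), drop = FALSE],
       singvals = sv$d[seq_len(k)])
}

#' Joint prediction/reproducibility objective D
#'
#' `D = (1 - mean_r_spatial)^2 + (1 - mean_r_test)^2`: the squared distance
#' of the mean split-half metric pair from the ideal point
#' (reproducibility 1, prediction 1).  Minimizing D picks the subspace that
#' simultaneously maximizes both means (the argmin is the same whether or
#' not the square root is taken).
#'
#' @param mean_r_spatial,mean_r_test mean split-half metrics in `[-1, 1]`.
#' @return Non-negative scalar.
#' @export
distance_D <- function(mean_r_spatial, mean_r_test) {
  (1 - mean_r_spatial)^2 + (1 - mean_r_test)^2
}

# Sign-align `v` to `ref` by inner product, then correlate.
aligned_pattern_cor <- function(v, ref) {
  if (sum(v * ref, na.rm = TRUE) < 0) v <- -v
  stats::cor(v, ref)
}

#' Adaptive PC-subspace optimization
#'
#' Runs the NPAIRS split-half evaluation for every subspace dimension
#' `k = 1..k_max` on one shared split schedule (the same splits for every
#' `k`, so the curves are comparable), plus a no-PCA reference analysis,
#' and selects `k_star = argmin D(k)` (ties broken toward the smallest k).
#' Pattern robustness across `k` is quantified by correlating each `k`'s
#' mean salience map with the `k_star` map after sign alignment.
#'
#' @param X scans-by-voxels matrix or `data_matrix`.
#' @param Y scans-by-4 indicator matrix or `design_matrix`.
#' @param design the [cohort_design()]; taken from `X` when available.
#' @param k_max largest subspace dimension; default (and upper bound)
#'   `min(half sizes) - 1`.
#' @param n_splits number of shared split-half resamples.
#' @param seed master seed for the shared schedule.
#' @param cor_mode see [evaluate_split()].
#' @return A `subspace_curve`: list with `k_values`, `mean_r_test`,
#'   `mean_r_spatial`, `D`, `k_star`, `pattern_corr_to_star`,
#'   `reference_metrics` (no-PCA mean metrics, D and pattern correlation),
#'   `salience_mean` (voxels x k_max), `reference_salience_mean`,
#'   per-k metric samples (`r_test_samples`, `r_spatial_samples`), `plans`
#'   and `reference` (the full-data LV-1 salience).
#' @export
select_optimal_k <- function(X, Y, design = NULL, k_max = NULL,
                             n_splits = 200L, seed = 1L,
                             cor_mode = c("matrix", "perlv")) {
  cor_mode <- match.arg(cor_mode)
  if (is.null(design) && inherits(X, "data_matrix")) design <- X$row_design
  Xm <- if (inherits(X, "data_matrix")) X$X else as.matrix(X)
  Ym <- if (inherits(Y, "design_matrix")) Y$Y else as.matrix(Y)

  subj <- unique(design$subject)
  grp_of <- vapply(subj, function(s) design$group[design$subject == s][1], "")
  min_half_scans <- 2L * sum(vapply(table(grp_of), function(n) n %/% 2L, 0L))
  kbound <- min(min_half_scans - 1L, ncol(Xm))
  if (is.null(k_max)) k_max <- kbound
  if (k_max > kbound)
    stop("k_max = ", k_max, " exceeds min(half sizes) - 1 = ", kbound)

  plans <- split_schedule(design, n_splits, seed)
  reference <- fit_pls(Xm, Ym)$V[, 1]

  nk <- k_max + 1L  # slot nk holds the no-PCA reference analysis
  r_test_s <- r_spatial_s <- vector("list", nk)
  map_sum <- matrix(0, ncol(Xm), nk)
  for (s in seq_along(plans)) {
    prep <- lapply(list(plans[[s]]$half_A, plans[[s]]$half_B),
                   function(ii) prepare_half(Xm, Ym, ii, want_svd = TRUE))
    for (j in seq_len(nk)) {
      k <- if (j <= k_max) j else NULL
      ev <- evaluate_split(Xm, Ym, plans[[s]], k = k, reference = reference,
                           cor_mode = cor_mode, prep = prep)
      r_test_s[[j]] <- c(r_test_s[[j]], ev$r_test)
      r_spatial_s[[j]] <- c(r_spatial_s[[j]], ev$r_spatial)
      map_sum[, j] <- map_sum[, j] + ev$split_map
    }
  }
  maps <- map_sum / length(plans)
  mean_rt <- vapply(r_test_s, mean, 0)
  mean_rs <- vapply(r_spatial_s, mean, 0)
  D <- distance_D(mean_rs, mean_rt)

  k_values <- seq_len(k_max)
  k_star <- k_values[which.min(D[k_values])]  # which.min takes smallest tie
  star_map <- maps[, k_star]
  pattern_corr <- vapply(k_values, function(k)
    aligned_pattern_cor(maps[, k], star_map), 0)

  structure(
    list(k_values = k_values,
         mean_r_test = mean_rt[k_values],
         mean_r_spatial = mean_rs[k_values],
         D = D[k_values],
         k_star = k_star,
         pattern_corr_to_star = pattern_corr,
         reference_metrics = list(mean_r_test = mean_rt[nk],
                                  mean_r_spatial = mean_rs[nk],
                                  D = D[nk],
                                  pattern_corr = aligned_pattern_cor(
                                    maps[, nk], star_map)),
         salience_mean = maps[, k_values, drop = FALSE],
         reference_salience_mean = maps[, nk],
         r_test_samples = r_test_s[k_values],
         r_spatial_samples = r_spatial_s[k_values],
         reference_samples = list(r_test = r_test_s[[nk]],
                                  r_spatial = r_spatial_s[[nk]]),
         plans = plans, reference = reference),
    class = "subspace_curve"
  )
}

#' @export
print.subspace_curve <- function(x, ...) {
  cat(sprintf("<subspace_curve> k = 1..%d, %d shared splits\n",
              max(x$k_values), length(x$plans)))
  cat(sprintf("  k* = %d: mean r_test = %.3f, mean r_spatial = %.3f, D = %.4f\n",
              x$k_star, x$mean_r_test[x$k_star], x$mean_r_spatial[x$k_star],
              x$D[x$k_star]))
  cat(sprintf("  no-PCA reference: mean r_test = %.3f, mean r_spatial = %.3f, D = %.4f\n",
              x$reference_metrics$mean_r_test,
              x$reference_metrics$mean_r_spatial, x$reference_metrics$D))
  invisible(x)
}

#' Pattern robustness across subspace dimensions
#'
#' Correlation of each k's sign-aligned mean salience map with the selected
#' `k_star` map, plus the no-PCA reference correlation.  At `k_star` the
#' correlation is exactly 1.
#'
#' @param curve a `subspace_curve` from [select_optimal_k()].
#' @return Data frame with columns `k` (NA for the no-PCA reference) and
#'   `pattern_corr`.
#' @export
pattern_stability_across_k <- function(curve) {
  stopifnot(inherits(curve, "subspace_curve"))
  data.frame(
    k = c(curve$k_values, NA_integer_),
    pattern_corr = c(curve$pattern_corr_to_star,
                     curve$reference_metrics$pattern_corr)
  )
}

#' Export the subspace curve as a plain table
#'
#' @param curve a `subspace_curve`.
#' @return Data frame with columns k, mean_r_test, mean_r_spatial, D,
#'   pattern_corr.
#' @export
subspace_curve_table <- function(curve) {
  stopifnot(inherits(curve, "subspace_curve"))
  data.frame(k = curve$k_values,
             mean_r_test = curve$mean_r_test,
             mean_r_spatial = curve$mean_r_spatial,
             D = curve$D,
             pattern_corr = curve$pattern_corr_to_star)
}
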