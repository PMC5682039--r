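#' Empirical one-sided p-value against zero
#'
#' Add-one-smoothed exceedance probability that a resampled metric is not
#' positive: `p = (1 + #{samples <= 0}) / (1 + n)`.  Used on the split-half
#' distributions of the prediction and reproducibility correlations.
#'
#' @param samples numeric vector of resampled metric values (length >= 1,
#'   no missing values).
#' @return A p-value in (0, 1].
#' @export
empirical_pvalue <- function(samples) {
  if (length(samples) == 0L) stop("`samples` must be non-empty")
  if (anyNA(samples)) stop("`samples` contains missing values")
  (1 + sum(samples <= 0)) / (1 + length(samples))
}

#' Matched stratified split-half partition
#'
#' Randomly divides subjects into two halves, separately within each group
#' so both halves contain both groups (and, since every subject is scanned
#' in both seasons, both seasons).  Both scans of a subject always land in
#' the same half.  Odd group counts put the extra subject on a randomly
#' chosen side.
#'
#' @param design a [cohort_design()] with at least 2 subjects per group.
#' @param seed optional integer; when given, seeds the RNG for this plan.
#' @return A `split_plan`: list with integer scan-index vectors `half_A`,
#'   `half_B` and the `seed` used (or `NA`).
#' @export
split_half_partition <- function(design, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (!is.null(seed)) set.seed(seed)
  subj <- unique(design$subject)
  grp_of <- vapply(subj, function(s) design$group[design$subject == s][1], "")
  half_of <- character(0)
  for (g in unique(grp_of)) {
    sg <- subj[grp_of == g]
    if (length(sg) < 2L)
      stop("group ", g, " has ", length(sg),
           " subject(s); need at least 2 to split")
    perm <- sample(sg)
    nA <- length(sg) %/% 2L
    if (length(sg) %% 2L == 1L) nA <- nA + sample(c(0L, 1L), 1L)
    h <- c(rep("A", nA), rep("B", length(sg) - nA))
    names(h) <- perm
    half_of <- c(half_of, h)
  }
  in_A <- half_of[design$subject] == "A"
  structure(
    list(half_A = which(in_A), half_B = which(!in_A),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "split_plan"
  )
}

# Standardize one half's data/design and (optionally) SVD the data for PCA.
# Shared by evaluate_split() and the subspace sweep so that truncating the
# cached SVD at k reproduces reduce_to_pcs() bitwise.
prepare_half <- function(X, Y, idx, want_svd = FALSE) {
  Xs <- standardize_columns(X[idx, , drop = FALSE])
  Ys <- standardize_columns(Y[idx, , drop = FALSE])
  list(Xs = Xs, Ys = Ys, sv = if (want_svd) svd(Xs) else NULL)
}

# PLS on one (possibly PC-reduced) half; returns scores basis, voxel-space
# saliences and cross-product.
fit_half <- function(h, k) {
  if (is.null(k)) {
    Z <- h$Xs
    W <- NULL
  } else {
    sv <- if (is.null(h$sv)) svd(h$Xs) else h$sv
    kmax <- min(nrow(h$Xs) - 1L, ncol(h$Xs))
    if (k < 1L || k > kmax)
      stop("k = ", k, " out of range; this half supports 1 <= k <= ", kmax,
           " (min(scans - 1, voxels))")
    Z <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
    W <- sv$v[, seq_len(k), drop = FALSE]
  }
  fit <- pls_svd(Z, h$Ys)
  V_vox <- if (is.null(W)) fit$V else W %*% fit$V
  list(fit = fit, Z = Z, W = W, V_vox = V_vox)
}

# Index of the latent variable whose voxel salience best matches (in
# absolute correlation) the full-data reference pattern; guards against LV
# order swaps between halves.
retained_lv <- function(V_vox, reference) {
  if (is.null(reference) || ncol(V_vox) == 1L) return(1L)
  r <- suppressWarnings(abs(as.numeric(stats::cor(V_vox, reference))))
  r[!is.finite(r)] <- -Inf
  which.max(r)
}

#' Evaluate one split-half pair
#'
#' Standardizes each half with its own column statistics, optionally reduces
#' each half to its top-`k` PC subspace, fits PLS per half, and computes the
#' NPAIRS metrics: for each half i, the training correlation
#' `r_train_i = cor(vec(Ys_i), vec(Z_i t(E_i)))` and the prediction
#' correlation `r_test_i` obtained by projecting the *other* half through
#' `E_i`; and the spatial reproducibility `r_spatial`, the correlation of the
#' two halves' voxel saliences for the retained LV after sign alignment
#' (half B's salience is negated when its inner product with half A's is
#' negative).
#'
#' The retained LV in each half is the one whose voxel salience correlates
#' most strongly (in absolute value) with the `reference` pattern; the
#' averaged pair (the split-map) is also sign-aligned to `reference`, since
#' the pair's overall sign is arbitrary.
#'
#' @param X scans-by-voxels matrix (raw; standardized per half here) or
#'   `data_matrix`.
#' @param Y scans-by-4 indicator matrix or `design_matrix`.
#' @param plan a `split_plan`.
#' @param k PC-subspace dimension, or `NULL` for no reduction.
#' @param reference full-data LV-1 voxel salience used for LV tracking and
#'   split-map sign alignment; computed by [run_npairs()] when omitted.
#' @param cor_mode `"matrix"` (default): correlations of the vectorized
#'   design matrix with the vectorized projection, all columns jointly;
#'   `"perlv"`: correlation of the retained LV's design and brain scores.
#' @param prep internal cache of prepared halves (see [run_npairs()]).
#' @return List with `r_train`, `r_test` (each length 2, halves A and B),
#'   `r_spatial`, `salience_pair` (voxels x 2, aligned), `split_map`
#'   (their mean, reference-aligned) and `lv` (retained LV per half).
#' @export
evaluate_split <- function(X, Y, plan, k = NULL, reference = NULL,
                           cor_mode = c("matrix", "perlv"), prep = NULL) {
  cor_mode <- match.arg(cor_mode)
  Xm <- if (inherits(X, "data_matrix")) X$X else as.matrix(X)
  Ym <- if (inherits(Y, "design_matrix")) Y$Y else as.matrix(Y)
  stopifnot(inherits(plan, "split_plan"))
  idx <- list(plan$half_A, plan$half_B)
  if (!is.null(k)) {
    kbound <- min(lengths(idx)) - 1L
    if (k > kbound)
      stop("k = ", k, " exceeds min(half sizes) - 1 = ", kbound)
  }
  if (is.null(prep))
    prep <- lapply(idx, function(ii)
      prepare_half(Xm, Ym, ii, want_svd = !is.null(k)))
  halves <- lapply(prep, fit_half, k = k)

  r_train <- r_test <- numeric(2L)
  for (i in 1:2) {
    j <- 3L - i
    hi <- halves[[i]]
    Ei <- hi$fit$E
    Zj <- if (is.null(hi$W)) prep[[j]]$Xs else prep[[j]]$Xs %*% hi$W
    if (cor_mode == "matrix") {
      r_train[i] <- stats::cor(as.vector(prep[[i]]$Ys),
                               as.vector(hi$Z %*% t(Ei)))
      r_test[i] <- stats::cor(as.vector(prep[[j]]$Ys),
                              as.vector(Zj %*% t(Ei)))
    } else {
      l <- retained_lv(hi$V_vox, reference)
      u <- hi$fit$U[, l]
      v <- hi$fit$V[, l]
      r_train[i] <- stats::cor(prep[[i]]$Ys %*% u, hi$Z %*% v)
      r_test[i] <- stats::cor(prep[[j]]$Ys %*% u, Zj %*% v)
    }
  }

  l1 <- retained_lv(halves[[1]]$V_vox, reference)
  l2 <- retained_lv(halves[[2]]$V_vox, reference)
  v1 <- halves[[1]]$V_vox[, l1]
  v2 <- halves[[2]]$V_vox[, l2]
  if (sum(v1 * v2) < 0) v2 <- -v2
  r_spatial <- stats::cor(v1, v2)
  split_map <- (v1 + v2) / 2
  if (!is.null(reference) && sum(split_map * reference) < 0) {
    split_map <- -split_map
    v1 <- -v1
    v2 <- -v2
  }
  list(r_train = stats::setNames(r_train, c("A", "B")),
       r_test = stats::setNames(r_test, c("A", "B")),
       r_spatial = r_spatial,
       salience_pair = cbind(v1, v2), split_map = split_map,
       lv = c(l1, l2))
}

# One child seed per split from a master seed (reproducible schedules).
split_schedule <- function(design, n_splits, seed) {
  set.seed(seed)
  child <- sample.int(.Machine$integer.max, n_splits)
  lapply(child, function(s) split_half_partition(design, seed = s))
}

#' Run NPAIRS split-half cross-validation
#'
#' Draws `n_splits` matched stratified split-half partitions (or uses a
#' supplied schedule), evaluates each with [evaluate_split()], and
#' aggregates: the empirical distributions of `r_test` (two values per
#' split) and `r_spatial` give one-sided p-values against zero via
#' [empirical_pvalue()]; the per-split sign-aligned salience maps give the
#' voxelwise salience mean, its split-half standard error (the SD across
#' split-maps) and the ratio Z-map `zmap = salience_mean / salience_se`
#' (voxels with zero SE are reported as `NA`).
#'
#' @param X scans-by-voxels matrix or `data_matrix`.
#' @param Y scans-by-4 indicator matrix or `design_matrix`.
#' @param design the [cohort_design()]; taken from `X` when it is a
#'   `data_matrix`.
#' @param k PC-subspace dimension per half, or `NULL` for no reduction.
#' @param n_splits number of split-half resamples (protocol default 1000).
#' @param seed master seed; spawns one child seed per split.
#' @param plans optional precomputed list of `split_plan`s (shared
#'   schedules across analyses); overrides `n_splits`/`seed`.
#' @param cor_mode see [evaluate_split()].
#' @param reference optional reference salience; defaults to the full-data
#'   LV-1 voxel salience.
#' @return An `npairs_result`: list with `r_train`, `r_test` (n_splits x 2),
#'   `r_spatial`, `p_test`, `p_spatial`, `salience_mean`, `salience_se`,
#'   `zmap`, `n_splits`, `k`, `reference`.
#' @export
run_npairs <- function(X, Y, design = NULL, k = NULL, n_splits = 1000L,
                       seed = 1L, plans = NULL,
                       cor_mode = c("matrix", "perlv"), reference = NULL) {
  cor_mode <- match.arg(cor_mode)
  if (is.null(design) && inherits(X, "data_matrix")) design <- X$row_design
  Xm <- if (inherits(X, "data_matrix")) X$X else as.matrix(X)
  Ym <- if (inherits(Y, "design_matrix")) Y$Y else as.matrix(Y)
  if (is.null(plans)) {
    if (n_splits < 2L) stop("`n_splits` must be >= 2")
    plans <- split_schedule(design, n_splits, seed)
  }
  n_splits <- length(plans)
  if (is.null(reference)) reference <- fit_pls(Xm, Ym)$V[, 1]

  r_train <- r_test <- matrix(NA_real_, n_splits, 2L,
                              dimnames = list(NULL, c("A", "B")))
  r_spatial <- numeric(n_splits)
  maps <- matrix(NA_real_, ncol(Xm), n_splits)
  for (s in seq_len(n_splits)) {
    ev <- evaluate_split(Xm, Ym, plans[[s]], k = k, reference = reference,
                         cor_mode = cor_mode)
    r_train[s, ] <- ev$r_train
    r_test[s, ] <- ev$r_test
    r_spatial[s] <- ev$r_spatial
    maps[, s] <- ev$split_map
  }
  salience_mean <- rowMeans(maps)
  salience_se <- apply(maps, 1L, stats::sd)
  zmap <- ifelse(salience_se > 0, salience_mean / salience_se, NA_real_)
  structure(
    list(r_train = r_train, r_test = r_test, r_spatial = r_spatial,
         p_test = empirical_pvalue(as.vector(r_test)),
         p_spatial = empirical_pvalue(r_spatial),
         salience_mean = salience_mean, salience_se = salience_se,
         zmap = zmap, n_splits = n_splits,
         k = if (is.null(k)) NA_integer_ else as.integer(k),
         reference = reference),
    class = "npairs_result"
  )
}

#' @export
print.npairs_result <- function(x, ...) {
  cat(sprintf("<npairs_result> %d splits, k = %s\n", x$n_splits,
              ifelse(is.na(x$k), "none (no PCA)", x$k)))
  cat(sprintf("  mean r_test = %.3f (p = %.4g), mean r_spatial = %.3f (p = %.4g)\n",
              mean(x$r_test), x$p_test, mean(x$r_spatial), x$p_spatial))
  invisible(x)
}
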