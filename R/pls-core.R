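#' @keywords internal
#' Core contrast-PLS decomposition on preprocessed matrices
#'
#' Computes E = t(Ys) %*% Xs and its economy SVD E = U diag(d) t(V),
#' imposing a canonical sign per latent variable (the largest-magnitude
#' element of each design salience u_l is made positive, and v_l flipped
#' with it) so results are deterministic across linear-algebra backends.
#' No standardization is applied here; callers preprocess.
pls_svd <- function(Xs, Ys) {
  E <- crossprod(Ys, Xs)                        # conditions x voxels
  if (all(E == 0))
    stop("cross-product matrix is identically zero (no shared variance)")
  sv <- svd(E)
  keep <- sv$d > max(sv$d) * 1e-12
  L <- max(1L, sum(keep))
  U <- sv$u[, seq_len(L), drop = FALSE]
  V <- sv$v[, seq_len(L), drop = FALSE]
  d <- sv$d[seq_len(L)]
  for (l in seq_len(L)) {
    i <- which.max(abs(U[, l]))
    if (U[i, l] < 0) {
      U[, l] <- -U[, l]
      V[, l] <- -V[, l]
    }
  }
  list(U = U, singvals = d, V = V,
       cov_fraction = d^2 / sum(sv$d^2), E = E)
}

#' Fit a contrast-based PLS model
#'
#' Standardizes the data matrix `X` (scans x voxels) and the indicator
#' design matrix `Y` (scans x 4) columnwise, forms the cross-product
#' `E = t(Y) %*% X`, and decomposes it by singular value decomposition
#' `E = U diag(singvals) t(V)`.  Each latent variable (LV) pairs a design
#' salience column of `U` with a voxel salience column of `V`; the fraction
#' of design-data covariance an LV carries is its squared singular value over
#' the sum of squares.
#'
#' @param X a `data_matrix` (from [assemble_data_matrix()]) or plain
#'   scans-by-voxels matrix.
#' @param Y a `design_matrix` (from [encode_design()]) or plain
#'   scans-by-conditions matrix.
#' @param cov_mode normalization of the covariance fraction: `"squared"`
#'   (default, squared singular values over their sum — the common PLS
#'   convention) or `"linear"` (singular values over their sum).
#' @return A `pls_model`: list with `U` (conditions x L), `singvals`
#'   (descending), `V` (voxels x L), `cov_fraction` (sums to 1), `E`, and
#'   the column labels when available.
#' @export
fit_pls <- function(X, Y, cov_mode = c("squared", "linear")) {
  cov_mode <- match.arg(cov_mode)
  Xm <- if (inherits(X, "data_matrix")) X$X else as.matrix(X)
  Ym <- if (inherits(Y, "design_matrix")) Y$Y else as.matrix(Y)
  if (nrow(Xm) != nrow(Ym))
    stop("X has ", nrow(Xm), " rows but Y has ", nrow(Ym))
  if (nrow(Xm) < 2L) stop("need at least 2 scans")
  fit <- pls_svd(standardize_columns(Xm), standardize_columns(Ym))
  if (cov_mode == "linear")
    fit$cov_fraction <- fit$singvals / sum(fit$singvals)
  fit$column_labels <- if (inherits(Y, "design_matrix")) Y$column_labels
  else colnames(Ym)
  class(fit) <- "pls_model"
  fit
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), %d voxels\n",
              length(x$singvals), nrow(x$V)))
  cat("  covariance fraction:",
      paste(sprintf("%.1f%%", 100 * x$cov_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' Brain scores: per-scan expression of each latent voxel pattern
#'
#' The brain score of scan i on LV l is the inner product of the scan's
#' standardized voxel vector with the LV's voxel salience:
#' `scores = standardize(X) %*% V`.
#'
#' @param X a `data_matrix` or plain scans-by-voxels matrix (raw scale; it is
#'   standardized columnwise before projection).
#' @param model a `pls_model` whose `V` has one row per column of `X`.
#' @return A `brain_scores` object: list with `scores` (scans x L) and
#'   `row_design` (when `X` carries one).
#' @export
brain_scores <- function(X, model) {
  stopifnot(inherits(model, "pls_model"))
  Xm <- if (inherits(X, "data_matrix")) X$X else as.matrix(X)
  if (ncol(Xm) != nrow(model$V))
    stop("X has ", ncol(Xm), " voxels but model V has ", nrow(model$V))
  structure(
    list(scores = standardize_columns(Xm) %*% model$V,
         row_design = if (inherits(X, "data_matrix")) X$row_design),
    class = "brain_scores"
  )
}

#' Design scores: per-scan expression of each design salience
#'
#' `standardize(Y) %*% U`, the design-side analogue of [brain_scores()].
#'
#' @param Y a `design_matrix` or plain scans-by-4 indicator matrix.
#' @param model a `pls_model`.
#' @return Scans x L matrix.
#' @export
design_scores <- function(Y, model) {
  stopifnot(inherits(model, "pls_model"))
  Ym <- if (inherits(Y, "design_matrix")) Y$Y else as.matrix(Y)
  if (ncol(Ym) != nrow(model$U))
    stop("Y has ", ncol(Ym), " columns but model U has ", nrow(model$U))
  standardize_columns(Ym) %*% model$U
}
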