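#' Build a tissue-probability analysis mask
#'
#' A voxel enters the analysis iff its gray-matter probability exceeds
#' `gm_thresh` AND its CSF probability is below `csf_thresh` (both strict),
#' excluding ventricle and low-gray-matter voxels from the data matrix.
#' Defaults are GM > 0.1 and CSF < 0.3.
#'
#' @param gm,csf [voxel_volume()]s of tissue probabilities in `[0, 1]`,
#'   same grid.
#' @param gm_thresh,csf_thresh probability thresholds.
#' @return An `analysis_mask`: list with `include` (logical 3-D array),
#'   `voxel_index` (matrix of 1-based voxel coordinates of included voxels,
#'   in fixed column-major order) and `voxel_size_mm`.
#' @export
build_mask <- function(gm, csf, gm_thresh = 0.1, csf_thresh = 0.3) {
  stopifnot(inherits(gm, "voxel_volume"), inherits(csf, "voxel_volume"))
  if (!identical(dim(gm$values), dim(csf$values)))
    stop("gm and csf grids differ: ", paste(dim(gm$values), collapse = "x"),
         " vs ", paste(dim(csf$values), collapse = "x"))
  rng_ok <- function(a) min(a) >= 0 && max(a) <= 1
  if (!rng_ok(gm$values) || !rng_ok(csf$values))
    stop("probability volumes must have values in [0, 1]")
  include <- gm$values > gm_thresh & csf$values < csf_thresh
  if (!any(include))
    stop("mask is empty: no voxel satisfies gm > ", gm_thresh,
         " and csf < ", csf_thresh)
  structure(
    list(include = include, voxel_index = which(include, arr.ind = TRUE),
         voxel_size_mm = gm$voxel_size_mm),
    class = "analysis_mask"
  )
}

#' @export
print.analysis_mask <- function(x, ...) {
  cat(sprintf("<analysis_mask> %d of %d voxels included\n",
              nrow(x$voxel_index), length(x$include)))
  invisible(x)
}

#' Assemble the scans-by-voxels data matrix
#'
#' Row i is the masked voxel vector of volume i; rows follow the design
#' record order, columns the fixed mask voxel order.
#'
#' @param volumes list of [voxel_volume()], one per design record.
#' @param design a [cohort_design()].
#' @param mask an `analysis_mask` built on the same grid.
#' @return A `data_matrix`: list with `X` (scans x voxels), `row_design`,
#'   `mask`.
#' @export
assemble_data_matrix <- function(volumes, design, mask) {
  stopifnot(inherits(design, "cohort_design"), inherits(mask, "analysis_mask"))
  if (length(volumes) != nrow(design))
    stop(length(volumes), " volumes but ", nrow(design), " design records")
  keep <- which(mask$include)
  X <- t(vapply(volumes, function(v) {
    stopifnot(inherits(v, "voxel_volume"))
    if (!identical(dim(v$values), dim(mask$include)))
      stop("volume grid ", paste(dim(v$values), collapse = "x"),
           " does not match mask grid ",
           paste(dim(mask$include), collapse = "x"))
    as.numeric(v$values)[keep]
  }, numeric(length(keep))))
  structure(list(X = X, row_design = design, mask = mask),
            class = "data_matrix")
}

#' Scatter a masked voxel vector back into a full volume
#'
#' Inverse of the masking step of [assemble_data_matrix()]: values outside
#' the mask are filled with `fill`.
#'
#' @param values numeric vector, one value per mask voxel.
#' @param mask an `analysis_mask`.
#' @param fill value for voxels outside the mask (default `NA`).
#' @return A [voxel_volume()].
#' @export
unmask_to_volume <- function(values, mask, fill = NA_real_) {
  stopifnot(inherits(mask, "analysis_mask"))
  if (length(values) != sum(mask$include))
    stop("expected ", sum(mask$include), " values, got ", length(values))
  a <- array(fill, dim = dim(mask$include))
  a[which(mask$include)] <- values
  v <- array(a, dim = dim(mask$include))
  structure(list(values = v, voxel_size_mm = mask$voxel_size_mm,
                 meta = list()), class = "voxel_volume")
}

# Fixed cell order for the design matrix columns.
design_cells <- function() {
  c("nonSAD.summer", "nonSAD.winter", "SAD.summer", "SAD.winter")
}

#' Encode the cohort design as a scans-by-4 indicator matrix
#'
#' One-hot coding of the four group-by-season cells, columns in the fixed
#' order nonSAD-summer, nonSAD-winter, SAD-summer, SAD-winter; each row sums
#' to 1.
#'
#' @param design a [cohort_design()].
#' @return A `design_matrix`: list with `Y` (scans x 4) and `column_labels`.
#' @export
encode_design <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  cells <- design_cells()
  lab <- paste(design$group, design$season, sep = ".")
  bad <- setdiff(unique(lab), cells)
  if (length(bad)) stop("unknown group/season cell: ", paste(bad, collapse = ", "))
  Y <- matrix(0, nrow = nrow(design), ncol = 4L,
              dimnames = list(NULL, cells))
  Y[cbind(seq_len(nrow(design)), match(lab, cells))] <- 1
  structure(list(Y = Y, column_labels = cells), class = "design_matrix")
}

#' Standardize matrix columns
#'
#' Subtracts each column mean and divides by the sample standard deviation
#' (denominator n - 1).  Columns with zero spread are set to all-zero rather
#' than dropped, preserving voxel indexing.
#'
#' @param M numeric matrix with at least two rows.
#' @return Matrix of the same shape.
#' @export
standardize_columns <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2L)
    stop("standardization needs at least 2 rows, got ", nrow(M))
  mu <- colMeans(M)
  Mc <- sweep(M, 2L, mu, "-")
  s <- sqrt(colSums(Mc^2) / (nrow(M) - 1L))
  nz <- s > 0
  Mc[, nz] <- sweep(Mc[, nz, drop = FALSE], 2L, s[nz], "/")
  Mc[, !nz] <- 0
  Mc
}
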