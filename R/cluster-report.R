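# Neighborhood offsets for 6- (faces), 18- (faces+edges) or
# 26-connectivity (faces+edges+corners).
connectivity_offsets <- function(connectivity = c(26L, 18L, 6L)) {
  connectivity <- as.integer(connectivity)[1]
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nrm <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nrm == 1,
                 "18" = nrm >= 1 & nrm <= 2,
                 "26" = nrm >= 1)
  g[keep, , drop = FALSE]
}

#' Label connected components of a logical 3-D mask
#'
#' Components are found on the graph whose vertices are `TRUE` voxels and
#' whose edges connect voxels adjacent under the chosen connectivity
#' (6 = faces, 18 = faces + edges, 26 = full neighborhood).
#'
#' @param mask logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer 3-D array: 0 outside the mask, component labels 1..n
#'   inside (labeling order is deterministic: by smallest linear index).
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  lab <- array(0L, dim = d)
  vox <- which(mask, arr.ind = TRUE)
  n <- nrow(vox)
  if (n == 0L) return(lab)
  lin <- which(mask)
  rank_of <- integer(prod(d))
  rank_of[lin] <- seq_len(n)
  off <- connectivity_offsets(connectivity)
  # each unordered pair once: keep offsets lexicographically positive
  off <- off[off[, 1] + 3 * off[, 2] + 9 * off[, 3] > 0, , drop = FALSE]
  edges <- NULL
  for (r in seq_len(nrow(off))) {
    nb <- sweep(vox, 2L, off[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] +
      nb[ok, 1]
    nb_rank <- rank_of[nb_lin]
    src <- which(ok)[nb_rank > 0L]
    if (length(src))
      edges <- rbind(edges, cbind(src, nb_rank[nb_rank > 0L]))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # relabel so component ids follow the smallest member's linear index
  first <- tapply(seq_len(n), comp, min)
  newid <- integer(max(comp))
  newid[order(first)] <- seq_along(first)
  lab[lin] <- newid[comp]
  lab
}

#' Cluster-extent thresholding of a Z map
#'
#' Voxels whose Z exceeds `+z_thresh` and voxels below `-z_thresh` are
#' labeled by connected components separately (opposite signs never merge);
#' components smaller than `extent_mm3` of tissue are discarded.  Each
#' surviving cluster is reported with its size and peak: the voxel of
#' maximum `|z|`, ties broken toward the smallest coordinate
#' lexicographically.
#'
#' @param zmap a [voxel_volume()] of Z values (`NA` allowed, treated as
#'   sub-threshold).
#' @param z_thresh positive Z threshold (protocol default 2.8, two-sided
#'   normal tail p of about 0.005).
#' @param extent_mm3 minimum cluster volume in cubic millimetres (protocol
#'   default 640).
#' @param connectivity 6, 18 or 26 (default).
#' @return A data frame (possibly empty) with columns `label`, `sign`,
#'   `size_vox`, `size_mm3`, `peak_x`, `peak_y`, `peak_z` (1-based voxel
#'   indices) and `peak_zscore`, ordered by decreasing size.
#' @export
threshold_clusters <- function(zmap, z_thresh = 2.8, extent_mm3 = 640,
                               connectivity = 26L) {
  stopifnot(inherits(zmap, "voxel_volume"))
  if (z_thresh <= 0) stop("`z_thresh` must be positive")
  if (extent_mm3 <= 0) stop("`extent_mm3` must be positive")
  z <- zmap$values
  vox_mm3 <- zmap$voxel_size_mm^3
  out <- list()
  for (sgn in c(1, -1)) {
    ex <- if (sgn > 0) !is.na(z) & z > z_thresh else !is.na(z) & z < -z_thresh
    if (!any(ex)) next
    lab <- label_components(ex, connectivity)
    for (id in seq_len(max(lab))) {
      members <- which(lab == id, arr.ind = TRUE)
      size_mm3 <- nrow(members) * vox_mm3
      if (size_mm3 < extent_mm3) next
      zs <- z[lab == id]
      best <- abs(zs) == max(abs(zs))
      cand <- members[best, , drop = FALSE]
      ord <- order(cand[, 1], cand[, 2], cand[, 3])
      peak <- cand[ord[1], ]
      out[[length(out) + 1L]] <- data.frame(
        sign = sgn, size_vox = nrow(members), size_mm3 = size_mm3,
        peak_x = peak[[1]], peak_y = peak[[2]], peak_z = peak[[3]],
        peak_zscore = z[peak[[1]], peak[[2]], peak[[3]]])
    }
  }
  if (!length(out))
    return(data.frame(label = integer(0), sign = numeric(0),
                      size_vox = integer(0), size_mm3 = numeric(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0), peak_zscore = numeric(0)))
  tab <- do.call(rbind, out)
  tab <- tab[order(-tab$size_mm3, -abs(tab$peak_zscore)), , drop = FALSE]
  tab <- cbind(label = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}
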