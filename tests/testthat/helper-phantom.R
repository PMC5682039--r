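# Shared fixtures: small phantoms, assembled matrices, and a brute-force
# flood-fill oracle for connected components.

# Assemble X/Y/mask/effect for a phantom cohort in one call.
make_cohort_data <- function(spec, design = default_design(spec$n_subjects_per_group),
                             mask_all = FALSE) {
  vols <- simulate_cohort(spec, design)
  if (mask_all) {
    gm <- voxel_volume(array(1, spec$grid_shape), spec$voxel_size_mm)
    csf <- voxel_volume(array(0, spec$grid_shape), spec$voxel_size_mm)
  } else {
    tis <- phantom_tissue_maps(spec)
    gm <- tis$gm
    csf <- tis$csf
  }
  mask <- build_mask(gm, csf)
  X <- assemble_data_matrix(vols, design, mask)
  Y <- encode_design(design)
  eff <- build_phantom(spec)$effect_map$values[mask$include]
  list(X = X, Y = Y, design = design, mask = mask, eff = eff, volumes = vols)
}

# Strong, nearly noise-free planted cohort (for recovery/limit checks):
# both noise sources shrunk well below the planted 0.25 effect.
strong_spec <- function(seed = 1L, noise_sd = 0.01, subject_sd = 0.05) {
  phantom_spec(noise_sd = noise_sd, subject_sd = subject_sd, seed = seed)
}

# Pure-noise null cohort on a small grid (effect-free, exchangeable scans).
null_spec <- function(seed, grid = c(8L, 8L, 8L), subject_sd = 0,
                      noise_sd = 0.1) {
  phantom_spec(grid_shape = grid, regions = list(), subject_sd = subject_sd,
               noise_sd = noise_sd, seed = seed)
}

# Independent connected-components oracle: breadth-first flood fill with an
# explicit queue, no graph machinery shared with the implementation.
flood_fill_labels <- function(mask, connectivity) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nrm <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = nrm == 1, "18" = nrm >= 1 & nrm <= 2,
                    "26" = nrm >= 1), , drop = FALSE]
  lab <- array(0L, dim = d)
  nxt <- 0L
  todo <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(todo))) {
    p0 <- todo[r, ]
    if (lab[p0[1], p0[2], p0[3]] != 0L) next
    nxt <- nxt + 1L
    queue <- list(p0)
    lab[p0[1], p0[2], p0[3]] <- nxt
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(off))) {
        q <- p + off[k, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# Two labelings describe the same partition (up to label renaming)?
same_partition <- function(a, b) {
  if (!all((a == 0) == (b == 0))) return(FALSE)
  ia <- a[a != 0]
  ib <- b[b != 0]
  key <- paste(ia, ib)
  length(unique(key)) == length(unique(ia)) &&
    length(unique(key)) == length(unique(ib))
}
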