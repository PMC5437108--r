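# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (plain loops, stats::cor, igraph) so that each dual-route
# check stays a real cross-validation.

# degree centrality: double loop over voxel pairs
oracle_degree <- function(series, r_threshold) {
  V <- ncol(series)
  deg <- integer(V)
  for (i in seq_len(V)) {
    for (j in seq_len(V)) {
      if (i == j) next
      if (stats::cor(series[, i], series[, j]) > r_threshold)
        deg[i] <- deg[i] + 1L
    }
  }
  deg
}

# connected components via igraph on the suprathreshold voxel graph
oracle_components <- function(vox, dim, connectivity) {
  if (!length(vox)) return(integer(0))
  ci <- arrayInd(vox, dim)
  key <- match(vox, vox)
  edges <- NULL
  for (a in seq_along(vox)) {
    for (b in seq_along(vox)) {
      if (a >= b) next
      dd <- abs(ci[a, ] - ci[b, ])
      if (max(dd) > 1) next
      s <- sum(dd)
      ok <- switch(as.character(connectivity),
                   `6` = s == 1, `18` = s <= 2 && max(dd) == 1, `26` = TRUE)
      if (ok) edges <- rbind(edges, c(a, b))
    }
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

oracle_max_cluster <- function(vox, dim, connectivity) {
  if (!length(vox)) return(0L)
  max(tabulate(oracle_components(vox, dim, connectivity)))
}

# Kendall's W by its rank-sum definition, scalar loops
oracle_kendall_w <- function(series) {  # rows = rankers (voxels), cols = items
  m <- nrow(series); k <- ncol(series)
  R <- matrix(0, m, k)
  for (i in seq_len(m)) R[i, ] <- rank(series[i, ])
  S <- colSums(R)
  12 * sum((S - mean(S))^2) / (m^2 * (k^3 - k))
}

# partial correlation: residualize with lm(), then stats::cor
oracle_partial_r <- function(x, y, C) {
  C <- as.matrix(C)
  rx <- stats::residuals(stats::lm(x ~ C))
  ry <- stats::residuals(stats::lm(y ~ C))
  stats::cor(rx, ry)
}

# small helpers for fixtures
toy_volume <- function(arr, voxel_mm = 3) {
  volume(arr, grid_affine(dim(arr), voxel_mm))
}

# hand-built tensor field (for tractography phantoms): e1 and FA given
# directly, every voxel reliable
phantom_tensor_field <- function(e1_array, fa_array, voxel_mm = 1) {
  d <- dim(fa_array)
  vox <- seq_len(prod(d))
  e1 <- matrix(e1_array, ncol = 3)
  structure(list(evals = NULL, e1 = e1, D = NULL,
                 fa = volume(fa_array, grid_affine(d, voxel_mm)),
                 md = NULL, voxels = vox, dim = d,
                 affine = grid_affine(d, voxel_mm),
                 flags = list(), unreliable = rep(FALSE, prod(d))),
            class = "nb_tensor_field")
}

# noiseless DWI signal from a single diffusion tensor, replicated on a grid
phantom_dwi_from_tensor <- function(D, gtab, dim = c(3, 3, 3), s0 = 100) {
  sig <- vapply(seq_along(gtab$bvals), function(k) {
    g <- gtab$bvecs[k, ]
    s0 * exp(-gtab$bvals[k] * as.numeric(t(g) %*% D %*% g))
  }, numeric(1))
  arr <- array(0, c(dim, length(sig)))
  for (k in seq_along(sig)) arr[, , , k] <- sig[k]
  arr
}

fast_synth_config <- function(...) {
  synthetic_config(n_volumes = 60L, ...)
}

fast_pipeline_config <- function(...) {
  pipeline_config(alphasim_iterations = 200L, seeds_per_voxel = 10L, ...)
}
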