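#' Voxel-wise two-sample t map
#'
#' @param groupA,groupB lists of `nb_volume` (e.g. patients, controls).
#' @param mask analysis mask.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return list with `t` (`nb_volume`, NA outside mask and at zero-variance
#'   voxels), `df` (`nb_volume` for welch, scalar for pooled), and
#'   `residuals` (list of `nb_volume`: observation minus group mean, for
#'   smoothness estimation).
#' @export
group_t_map <- function(groupA, groupB, mask, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  m <- as_mask_array(mask)
  vox <- which(m)
  getv <- function(v) v$data[vox]
  A <- vapply(groupA, getv, numeric(length(vox)))
  B <- vapply(groupB, getv, numeric(length(vox)))
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1)
  v2 <- rowSums((B - m2)^2) / (n2 - 1)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      (pmax(v1 / n1, 1e-300)^2 / (n1 - 1) + pmax(v2 / n2, 1e-300)^2 / (n2 - 1))
  }
  t <- ifelse(se > 0, (m1 - m2) / se, NA_real_)
  d <- dim(groupA[[1]]$data)
  aff <- groupA[[1]]$affine
  tarr <- array(NA_real_, d); tarr[vox] <- t
  mk_res <- function(X, mu) {
    lapply(seq_len(ncol(X)), function(j) {
      arr <- array(NA_real_, d); arr[vox] <- X[, j] - mu
      volume(arr, aff, units = "residual")
    })
  }
  list(t = volume(tarr, aff, units = "t"),
       df = df,
       n = c(n1, n2),
       residuals = c(mk_res(A, m1), mk_res(B, m2)))
}

#' Residual-based spatial smoothness (FWHM) estimation
#'
#' Classic first-difference estimator: per axis `d`,
#' `FWHM_d = voxel_d * sqrt(-2 log(2) / log(1 - v_d / (2 v)))`, where `v_d`
#' is the variance of first spatial differences along the axis (both voxels
#' in the mask) and `v` the residual variance, each pooled over volumes.
#' Axes with `v_d >= 2 v` (rougher than resolvable) are reported as NA.
#'
#' @param residuals list of residual `nb_volume`s.
#' @param mask analysis mask.
#' @return object of class `nb_smoothness`: `fwhm_mm` (length 3, possibly
#'   NA), `method`.
#' @export
estimate_fwhm <- function(residuals, mask) {
  stopifnot(length(residuals) >= 2L)
  m <- as_mask_array(mask)
  d <- dim(m)
  vx <- voxel_sizes(residuals[[1]]$affine)
  shift_pairs <- function(axis) {
    idx_lo <- lapply(1:3, function(a) seq_len(d[a] - (a == axis)))
    idx_hi <- idx_lo
    idx_hi[[axis]] <- idx_hi[[axis]] + 1L
    list(lo = idx_lo, hi = idx_hi)
  }
  ss_diff <- c(0, 0, 0); n_diff <- c(0, 0, 0)
  ss_val <- 0; n_val <- 0
  for (r in residuals) {
    a <- r$data
    vals <- a[m]
    vals <- vals[!is.na(vals)]
    vals <- vals - mean(vals)
    ss_val <- ss_val + sum(vals^2); n_val <- n_val + length(vals)
    for (axis in 1:3) {
      sp <- shift_pairs(axis)
      lo <- do.call(`[`, c(list(a), sp$lo, drop = FALSE))
      hi <- do.call(`[`, c(list(a), sp$hi, drop = FALSE))
      mlo <- do.call(`[`, c(list(m), sp$lo, drop = FALSE))
      mhi <- do.call(`[`, c(list(m), sp$hi, drop = FALSE))
      ok <- mlo & mhi & !is.na(lo) & !is.na(hi)
      dd <- (hi - lo)[ok]
      ss_diff[axis] <- ss_diff[axis] + sum(dd^2)
      n_diff[axis] <- n_diff[axis] + length(dd)
    }
  }
  v <- ss_val / (n_val - 1)
  if (v <= 0) stop("constant residuals: smoothness undefined")
  fwhm <- numeric(3)
  for (axis in 1:3) {
    vd <- ss_diff[axis] / max(1, n_diff[axis] - 1)
    arg <- 1 - vd / (2 * v)
    fwhm[axis] <- if (arg <= 0) NA_real_
                  else vx[axis] * sqrt(-2 * log(2) / log(arg))
  }
  structure(list(fwhm_mm = fwhm, method = "first-difference residual"),
            class = "nb_smoothness")
}

neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 `6` = rowSums(abs(g)) == 1,
                 `18` = rowSums(abs(g)) <= 2,
                 `26` = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

# Neighbor lookup: m x noff matrix of linear indices (NA out of bounds)
# for the given voxels only.
neighbor_table <- function(vox, dim, connectivity) {
  off <- neighbor_offsets(connectivity)
  noff <- nrow(off)
  ci <- arrayInd(vox, dim)
  n <- length(vox)
  tab <- matrix(NA_integer_, n, noff)
  for (j in seq_len(noff)) {
    nb <- ci + matrix(off[j, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dim[1] &
          nb[, 2] >= 1 & nb[, 2] <= dim[2] &
          nb[, 3] >= 1 & nb[, 3] <= dim[3]
    tab[ok, j] <- nb[ok, 1] + dim[1] * (nb[ok, 2] - 1L) +
      dim[1] * dim[2] * (nb[ok, 3] - 1L)
  }
  tab
}

# Connected-component labelling of a voxel set (vectorized BFS over a
# precomputed neighbor table).
label_components <- function(vox, dim, connectivity = 26L, full_table = NULL) {
  if (!length(vox)) return(integer(0))
  vox <- as.integer(vox)
  ord <- order(vox)
  sv <- vox[ord]
  tab <- if (is.null(full_table)) neighbor_table(sv, dim, connectivity)
         else full_table[sv, , drop = FALSE]
  # map neighbor linear indices to positions within the set
  pos <- matrix(match(tab, sv), nrow(tab))
  lab <- integer(length(sv))
  nextlab <- 0L
  for (i in seq_along(sv)) {
    if (lab[i] != 0L) next
    nextlab <- nextlab + 1L
    lab[i] <- nextlab
    frontier <- i
    while (length(frontier)) {
      cand <- pos[frontier, ]
      cand <- unique(cand[!is.na(cand)])
      cand <- cand[lab[cand] == 0L]
      lab[cand] <- nextlab
      frontier <- cand
    }
  }
  lab[match(vox, sv)]
}

#' Monte-Carlo (AlphaSim-style) minimum cluster size
#'
#' Per iteration: simulate an iid Gaussian field over the grid, smooth it to
#' the given FWHM, re-standardize within the mask, threshold at the voxel
#' p (two-sided by default), and record the largest suprathreshold cluster.
#' The minimum cluster size is the smallest `k` with empirical
#' `P(max cluster >= k) <= alpha`.
#'
#' @param mask analysis mask (`nb_volume` or logical array).
#' @param fwhm_mm smoothness of the simulated fields (scalar or length 3, mm).
#' @param voxel_p voxel-level threshold in (0, 1).
#' @param alpha family-wise error target, default 0.05.
#' @param n_iterations Monte-Carlo iterations, default 1000.
#' @param connectivity 6, 18 or 26 (default).
#' @param seed RNG seed.
#' @param two_sided threshold `|z|` (default) or positive tail only.
#' @param voxel_mm voxel size when `mask` is a bare array.
#' @return object of class `nb_alphasim`: `min_cluster_voxels`,
#'   `null_max_sizes`, plus the call parameters.
#' @export
alphasim_min_cluster <- function(mask, fwhm_mm, voxel_p, alpha = 0.05,
                                 n_iterations = 1000L, connectivity = 26L,
                                 seed = 1L, two_sided = TRUE, voxel_mm = NULL) {
  if (!(voxel_p > 0 && voxel_p < 1)) stop("voxel_p must be in (0,1)")
  if (any(is.na(fwhm_mm))) stop("unresolvable fwhm")
  if (inherits(mask, "nb_volume")) {
    vx <- voxel_sizes(mask$affine)
  } else {
    vx <- rep(if (is.null(voxel_mm)) 1 else voxel_mm, length.out = 3)
  }
  m <- as_mask_array(mask)
  vox <- which(m)
  if (!length(vox)) stop("empty mask")
  d <- dim(m)
  zc <- if (two_sided) stats::qnorm(1 - voxel_p / 2) else stats::qnorm(1 - voxel_p)
  fwhm_mm <- rep(fwhm_mm, length.out = 3)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vx
  Ks <- lapply(1:3, function(a) gaussian_kernel_matrix(d[a], sigma_vox[a]))

  set.seed(seed)
  full_tab <- neighbor_table(seq_len(prod(d)), d, connectivity)
  max_sizes <- integer(n_iterations)
  batch <- 50L
  done <- 0L
  while (done < n_iterations) {
    nb <- min(batch, n_iterations - done)
    field <- array(stats::rnorm(prod(d) * nb), c(d, nb))
    for (axis in 1:3) field <- apply_axis(field, Ks[[axis]], axis)
    fm <- matrix(field, prod(d), nb)[vox, , drop = FALSE]
    fm <- scale(fm)                      # re-standardize within mask
    for (j in seq_len(nb)) {
      supra <- if (two_sided) abs(fm[, j]) > zc else fm[, j] > zc
      sv <- vox[supra]
      max_sizes[done + j] <- if (!length(sv)) 0L else {
        lb <- label_components(sv, d, connectivity, full_table = full_tab)
        max(tabulate(lb))
      }
    }
    done <- done + nb
  }
  # smallest k with empirical P(max >= k) <= alpha
  k <- 1L
  while (mean(max_sizes >= k) > alpha) k <- k + 1L
  structure(list(voxel_p = voxel_p, alpha = alpha, min_cluster_voxels = k,
                 n_iterations = n_iterations, connectivity = connectivity,
                 fwhm_mm = fwhm_mm, two_sided = two_sided,
                 null_max_sizes = max_sizes),
            class = "nb_alphasim")
}

#' @export
print.nb_alphasim <- function(x, ...) {
  cat(sprintf(
    "<alphasim: voxel p=%g, alpha=%g -> min cluster %d voxels (%d iters, conn %d)>\n",
    x$voxel_p, x$alpha, x$min_cluster_voxels, x$n_iterations, x$connectivity))
  invisible(x)
}

#' Extract suprathreshold clusters
#'
#' Connected components of voxels exceeding the threshold (two-sided:
#' `|stat| > voxel_threshold`), filtered by minimum size. Peaks take the
#' maximum `|stat|`; ties break toward the smallest linear index.
#'
#' @param stat_map `nb_volume`.
#' @param mask analysis mask.
#' @param voxel_threshold statistic threshold (strict `>`).
#' @param min_cluster_voxels minimum surviving size (clusters of size
#'   `>= min_cluster_voxels` are kept).
#' @param connectivity 6, 18 or 26 (default).
#' @param two_sided threshold on `|stat|` (default) or signed stat.
#' @return object of class `nb_cluster_table`: a data.frame (`label`,
#'   `size_voxels`, `size_mm3`, `peak_i/j/k`, `peak_x/y/z_mm`, `peak_stat`)
#'   plus attribute `voxels`, a list of linear-index vectors per cluster.
#' @export
extract_clusters <- function(stat_map, mask, voxel_threshold,
                             min_cluster_voxels = 1L, connectivity = 26L,
                             two_sided = TRUE) {
  stopifnot(is.finite(voxel_threshold), is.finite(min_cluster_voxels))
  m <- as_mask_array(mask)
  s <- stat_map$data
  supra <- m & !is.na(s) &
    (if (two_sided) abs(s) > voxel_threshold else s > voxel_threshold)
  vox <- which(supra)
  d <- dim(s)
  vx <- voxel_sizes(stat_map$affine)
  empty <- data.frame(label = integer(0), size_voxels = integer(0),
                      size_mm3 = numeric(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0),
                      peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                      peak_z_mm = numeric(0), peak_stat = numeric(0))
  if (!length(vox)) {
    return(structure(empty, voxels = list(), class = c("nb_cluster_table",
                                                       "data.frame")))
  }
  lab <- label_components(vox, d, connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_cluster_voxels)
  if (!length(keep)) {
    return(structure(empty, voxels = list(), class = c("nb_cluster_table",
                                                       "data.frame")))
  }
  rows <- lapply(seq_along(keep), function(i) {
    cl_vox <- sort(vox[lab == keep[i]])
    st <- s[cl_vox]
    peak <- cl_vox[which.max(abs(st))]   # which.max: first (smallest index) tie-break
    pc <- as.integer(arrayInd(peak, d))
    pm <- as.numeric(voxel_to_mm(matrix(pc, 1), stat_map$affine))
    data.frame(label = i, size_voxels = length(cl_vox),
               size_mm3 = length(cl_vox) * prod(vx),
               peak_i = pc[1], peak_j = pc[2], peak_k = pc[3],
               peak_x_mm = pm[1], peak_y_mm = pm[2], peak_z_mm = pm[3],
               peak_stat = s[peak])
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$size_voxels)
  tab <- tab[ord, , drop = FALSE]
  tab$label <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  vlist <- lapply(keep[ord], function(k) sort(vox[lab == k]))
  structure(tab, voxels = vlist, class = c("nb_cluster_table", "data.frame"))
}
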