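#' Log-linear diffusion tensor fit
#'
#' Per voxel, least squares on `log(S_k / S0) = -b g_k' D g_k` over the
#' weighted volumes, followed by eigendecomposition and the standard
#' fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((lambda - MD)^2)) / sqrt(sum(lambda^2))`.
#' Negative eigenvalues are clamped to zero and flagged; voxels with
#' non-positive signals are flagged and fitted on clamped signals.
#'
#' @param dwi 4D array (x, y, z, volumes) or `nb_bold`-like array.
#' @param gradients a `nb_gradient_table`.
#' @param mask optional analysis mask (default: all voxels).
#' @param affine voxel-to-mm affine for the output maps.
#' @return object of class `nb_tensor_field`: `evals` (V x 3, descending),
#'   `e1` (V x 3 principal directions), `D` (V x 6: xx, yy, zz, xy, xz, yz),
#'   `fa` (`nb_volume`), `md` (`nb_volume`), `voxels`, `flags` (list of
#'   flagged voxel indices), `unreliable` (logical per voxel: near-degenerate
#'   principal direction).
#' @export
fit_tensor <- function(dwi, gradients, mask = NULL, affine = NULL) {
  if (inherits(dwi, "nb_bold")) { affine <- dwi$affine; dwi <- dwi$data }
  d <- dim(dwi)[1:3]
  if (is.null(affine)) affine <- grid_affine(d, 1)
  if (is.null(mask)) mask <- array(TRUE, d)
  vox <- mask_indices(mask)
  nvol <- dim(dwi)[4]
  b0_idx <- which(gradients$bvals == 0)
  w_idx <- which(gradients$bvals > 0)
  if (!length(b0_idx)) stop("need at least one b=0 volume")
  if (length(w_idx) < 6L) stop("need at least 6 weighted volumes")
  stopifnot(nvol == length(gradients$bvals))
  Y <- matrix(dwi, prod(d), nvol)[vox, , drop = FALSE]
  S0 <- rowMeans(Y[, b0_idx, drop = FALSE])
  S <- Y[, w_idx, drop = FALSE]
  bad_signal <- S0 <= 0 | rowSums(S <= 0) > 0
  eps <- 1e-6
  S0 <- pmax(S0, eps)
  S <- pmax(S, eps * 1e-3)
  X <- weighted_design(gradients$bvecs[w_idx, , drop = FALSE],
                       gradients$bvals[w_idx])
  # D = argmin || -log(S/S0) - X D ||^2, solved once for all voxels
  lhs <- -(log(S) - log(S0))                    # V x k, equals X %*% D + err
  Dmat <- t(solve(crossprod(X), crossprod(X, t(lhs))))   # V x 6
  nv <- length(vox)
  evals <- matrix(NA_real_, nv, 3)
  e1 <- matrix(NA_real_, nv, 3)
  clamped <- logical(nv)
  unreliable <- logical(nv)
  for (i in seq_len(nv)) {
    Dc <- Dmat[i, ]
    Dm <- matrix(c(Dc[1], Dc[4], Dc[5],
                   Dc[4], Dc[2], Dc[6],
                   Dc[5], Dc[6], Dc[3]), 3, 3)
    eg <- eigen(Dm, symmetric = TRUE)
    lam <- eg$values
    if (any(lam < 0)) { clamped[i] <- TRUE; lam <- pmax(lam, 0) }
    evals[i, ] <- lam
    e1[i, ] <- eg$vectors[, 1]
    scale_ref <- max(abs(lam[1]), 1e-12)
    unreliable[i] <- (lam[1] - lam[2]) < 1e-3 * scale_ref
  }
  md <- rowMeans(evals)
  num <- sqrt(rowSums((evals - md)^2))
  den <- sqrt(rowSums(evals^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  fa_arr <- array(NA_real_, d); fa_arr[vox] <- fa
  md_arr <- array(NA_real_, d); md_arr[vox] <- md
  structure(list(evals = evals, e1 = e1, D = Dmat,
                 fa = volume(fa_arr, affine, units = "FA"),
                 md = volume(md_arr, affine, units = "MD"),
                 voxels = vox, dim = d, affine = affine,
                 flags = list(non_positive_signal = vox[bad_signal],
                              clamped_eigenvalues = vox[clamped]),
                 unreliable = unreliable),
            class = "nb_tensor_field")
}

#' Deterministic FACT streamline tracking
#'
#' Fiber Assignment by Continuous Tracking: from random start points inside
#' each seed voxel, streamlines follow the per-voxel constant principal
#' diffusion direction to the voxel boundary, enter the next voxel and
#' re-orient to its principal direction with the sign that minimizes
#' turning. Launch is bidirectional (`+e1` and `-e1` from the seed voxel).
#' Propagation terminates when the voxel FA drops below `fa_min` (strict),
#' the turning angle exceeds `angle_max_deg` (strict), the streamline
#' leaves the grid, or the principal direction is flagged unreliable
#' (near-degenerate tensor).
#'
#' @param tensors a `nb_tensor_field` covering the grid.
#' @param seed_voxels linear indices of seed voxels.
#' @param seeds_per_voxel random start points per voxel, default 100.
#' @param angle_max_deg turning-angle threshold, default 45.
#' @param fa_min FA stopping threshold, default 0.15.
#' @param rng_seed RNG seed for the in-voxel start points.
#' @param max_steps per-direction step cap (safety), default 500.
#' @return object of class `nb_streamlines`: `visited` (list of linear
#'   voxel-index vectors per streamline, both directions merged),
#'   `termination` (n x 2 character matrix, forward/backward reasons among
#'   `"fa"`, `"angle"`, `"exit"`, `"degenerate"`), `length_mm` (total arc
#'   length per streamline, isotropic-voxel approximation), `seed_voxel`
#'   (per streamline), `dim`, `affine`.
#' @export
fact_track <- function(tensors, seed_voxels, seeds_per_voxel = 100L,
                       angle_max_deg = 45, fa_min = 0.15, rng_seed = 1L,
                       max_steps = 500L) {
  if (!length(seed_voxels)) stop("empty seed set")
  d <- tensors$dim
  nvox_grid <- prod(d)
  # dense per-grid-voxel lookup tables
  e1g <- matrix(NA_real_, nvox_grid, 3)
  e1g[tensors$voxels, ] <- tensors$e1
  fag <- rep(NA_real_, nvox_grid)
  fag[tensors$voxels] <- tensors$fa$data[tensors$voxels]
  unrel <- rep(TRUE, nvox_grid)
  unrel[tensors$voxels] <- tensors$unreliable

  set.seed(rng_seed)
  ns <- length(seed_voxels) * seeds_per_voxel
  seed_vox <- rep(seed_voxels, each = seeds_per_voxel)
  sc <- arrayInd(seed_vox, d)                 # 1-based voxel subscripts
  start <- (sc - 1) + matrix(stats::runif(ns * 3), ns, 3)  # 0-based continuous
  cos_max <- cos(angle_max_deg * pi / 180)

  run_half <- function(sign0) {
    pos <- start
    active <- rep(TRUE, ns)
    prev <- matrix(NA_real_, ns, 3)
    term <- rep(NA_character_, ns)
    vstep <- matrix(NA_integer_, max_steps, ns)
    seglen <- numeric(ns)
    step <- 0L
    cur_vox <- seed_vox
    first <- rep(TRUE, ns)
    while (any(active) && step < max_steps) {
      step <- step + 1L
      idx <- which(active)
      v <- cur_vox[idx]
      # stopping rules evaluated on the entered voxel
      fa_v <- fag[v]
      bad_fa <- is.na(fa_v) | fa_v < fa_min
      bad_deg <- unrel[v] & !bad_fa
      vstep[step, idx] <- v                  # terminal voxel stays in visited
      stop_now <- bad_fa | bad_deg
      term[idx[bad_fa]] <- "fa"
      term[idx[bad_deg]] <- "degenerate"
      go <- idx[!stop_now]
      active[idx[stop_now]] <- FALSE
      if (!length(go)) next
      v <- cur_vox[go]
      dirv <- e1g[v, , drop = FALSE]
      pv <- prev[go, , drop = FALSE]
      isfirst <- first[go]
      dots <- rowSums(dirv * pv)
      flip <- !isfirst & !is.na(dots) & dots < 0
      dirv[flip, ] <- -dirv[flip, ]
      dots <- abs(dots)
      # first step: orient along the requested launch hemisphere
      if (any(isfirst)) {
        l0 <- sign0
        d0 <- dirv[isfirst, , drop = FALSE]
        s0 <- sign(d0 %*% l0)
        s0[s0 == 0] <- 1
        dirv[isfirst, ] <- d0 * as.numeric(s0)
      }
      ang_bad <- !isfirst & dots < cos_max
      term[go[ang_bad]] <- "angle"
      active[go[ang_bad]] <- FALSE
      go2 <- go[!ang_bad]
      if (!length(go2)) next
      dirv <- dirv[!ang_bad, , drop = FALSE]
      # step to the boundary of the current voxel
      p <- pos[go2, , drop = FALSE]
      vox0 <- arrayInd(cur_vox[go2], d)      # 1-based
      tmin <- rep(Inf, length(go2))
      for (a in 1:3) {
        da <- dirv[, a]
        bound <- ifelse(da > 0, vox0[, a], vox0[, a] - 1)
        ta <- ifelse(abs(da) > 1e-12, (bound - p[, a]) / da, Inf)
        ta[ta < 0] <- Inf
        tmin <- pmin(tmin, ta)
      }
      tmin[!is.finite(tmin)] <- 0
      pnew <- p + (tmin + 1e-6) * dirv
      newsub <- floor(pnew) + 1
      out <- newsub[, 1] < 1 | newsub[, 1] > d[1] |
             newsub[, 2] < 1 | newsub[, 2] > d[2] |
             newsub[, 3] < 1 | newsub[, 3] > d[3]
      term[go2[out]] <- "exit"
      active[go2[out]] <- FALSE
      keep <- !out
      gk <- go2[keep]
      seglen[go2] <- seglen[go2] + tmin
      if (length(gk)) {
        pos[gk, ] <- pnew[keep, , drop = FALSE]
        prev[gk, ] <- dirv[keep, , drop = FALSE]
        cur_vox[gk] <- newsub[keep, 1] + d[1] * (newsub[keep, 2] - 1) +
          d[1] * d[2] * (newsub[keep, 3] - 1)
        first[gk] <- FALSE
      }
      prev[go2[out], ] <- NA
    }
    term[is.na(term)] <- "exit"              # hit step cap
    list(vstep = vstep[seq_len(step), , drop = FALSE], term = term,
         len = seglen)
  }

  fwd <- run_half(c(1, 0, 0))
  bwd <- run_half(c(-1, 0, 0))
  visited <- lapply(seq_len(ns), function(i) {
    v <- c(fwd$vstep[, i], bwd$vstep[, i])
    sort(unique(v[!is.na(v)]))
  })
  voxlen <- mean(voxel_sizes(tensors$affine))
  structure(list(visited = visited,
                 termination = cbind(forward = fwd$term, backward = bwd$term),
                 length_mm = (fwd$len + bwd$len) * voxlen,
                 seed_voxel = seed_vox, dim = d, affine = tensors$affine,
                 seeds_per_voxel = seeds_per_voxel,
                 angle_max_deg = angle_max_deg, fa_min = fa_min),
            class = "nb_streamlines")
}

#' Tract mask between two regions
#'
#' Keeps the streamlines (seeded in region A) that touch any voxel of
#' region B, and returns the union of all voxels those streamlines
#' traverse.
#'
#' @param streamlines a `nb_streamlines` seeded in `roi_a`.
#' @param roi_a,roi_b masks of the endpoint regions.
#' @param labels endpoint labels recorded in the result.
#' @return object of class `nb_tract`: `mask` (`nb_volume` 0/1, possibly
#'   empty), `n_streamlines_kept`, `roi_labels`.
#' @export
tract_mask_between <- function(streamlines, roi_a, roi_b,
                               labels = c("A", "B")) {
  bv <- array(FALSE, streamlines$dim)
  bv[mask_indices(roi_b)] <- TRUE
  hit <- vapply(streamlines$visited, function(v) any(bv[v]), logical(1))
  arr <- array(0, streamlines$dim)
  if (any(hit)) {
    vox <- sort(unique(unlist(streamlines$visited[hit])))
    arr[vox] <- 1
  }
  structure(list(mask = volume(arr, streamlines$affine, units = "mask"),
                 n_streamlines_kept = sum(hit), roi_labels = labels),
            class = "nb_tract")
}

#' Group tract count-map threshold
#'
#' A voxel enters the group tract when it is present in at least
#' `min_subjects` subject masks (default 4, the "more than 3 subjects"
#' rule).
#'
#' @param subject_masks list of `nb_tract` or mask volumes on a common grid.
#' @param min_subjects inclusion threshold (voxel kept iff count >= this).
#' @return `nb_tract` with the thresholded mask and the `count_map`.
#' @export
group_count_mask <- function(subject_masks, min_subjects = 4L) {
  stopifnot(length(subject_masks) >= 1L)
  get_arr <- function(x) {
    if (inherits(x, "nb_tract")) x$mask$data
    else if (inherits(x, "nb_volume")) x$data
    else x
  }
  arrs <- lapply(subject_masks, get_arr)
  d <- dim(arrs[[1]])
  for (a in arrs) if (!all(dim(a) == d)) stop("grid mismatch between subject masks")
  cnt <- Reduce(`+`, lapply(arrs, function(a) (a != 0) + 0))
  aff <- if (inherits(subject_masks[[1]], "nb_tract"))
    subject_masks[[1]]$mask$affine
  else if (inherits(subject_masks[[1]], "nb_volume")) subject_masks[[1]]$affine
  else grid_affine(d, 1)
  structure(list(mask = volume((cnt >= min_subjects) + 0, aff, units = "mask"),
                 count_map = volume(cnt, aff, units = "count"),
                 min_subjects = min_subjects,
                 n_subjects = length(subject_masks)),
            class = "nb_tract")
}

#' Local diffusion homogeneity (Kendall's W over a voxel neighborhood)
#'
#' For each voxel, Kendall's coefficient of concordance of the raw
#' diffusion-weighted signal series across the voxel and its in-mask
#' neighbors within the 3x3x3 (27-voxel) neighborhood:
#' `W = 12 * sum((R_t - mean(R))^2) / (m^2 (k^3 - k))` with `m` voxels,
#' `k` weighted volumes and `R_t` the rank sums per volume. Weighted-only
#' series by default (`include_b0 = FALSE`).
#'
#' @param dwi 4D array of diffusion signals.
#' @param gradients a `nb_gradient_table`.
#' @param mask analysis mask.
#' @param include_b0 include the b=0 volumes in the concordance series.
#' @param affine output affine.
#' @return `nb_volume` of W values in [0, 1]; voxels whose neighborhood
#'   holds fewer than 2 in-mask voxels (nothing to rank against) are NA.
#' @export
ldh_map <- function(dwi, gradients, mask = NULL, include_b0 = FALSE,
                    affine = NULL) {
  d <- dim(dwi)[1:3]
  if (is.null(affine)) affine <- grid_affine(d, 1)
  if (is.null(mask)) mask <- array(TRUE, d)
  m <- as_mask_array(mask)
  sel <- if (include_b0) seq_along(gradients$bvals) else which(gradients$bvals > 0)
  k <- length(sel)
  if (k < 2L) stop("need at least 2 volumes for concordance")
  Y <- matrix(dwi, prod(d), dim(dwi)[4])[, sel, drop = FALSE]
  R <- t(apply(Y, 1, rank))                   # V x k ranks per voxel series
  R[!m, ] <- 0
  rank_sum <- array(0, c(d, k))
  count <- array(0L, d)
  off <- neighbor_offsets(26L)
  off <- rbind(c(0L, 0L, 0L), off)
  pad_shift <- function(arr3, o) {
    src <- lapply(1:3, function(a) {
      i <- seq_len(d[a]) + o[a]
      i[i < 1 | i > d[a]] <- NA
      i
    })
    out <- array(0, d)
    okd <- lapply(src, function(i) which(!is.na(i)))
    out[okd[[1]], okd[[2]], okd[[3]]] <-
      arr3[src[[1]][okd[[1]]], src[[2]][okd[[2]]], src[[3]][okd[[3]]]]
    out
  }
  Rarr <- array(R, c(d, k))
  Marr <- (m) + 0
  for (j in seq_len(nrow(off))) {
    o <- off[j, ]
    count <- count + pad_shift(Marr, o)
    for (t in seq_len(k)) {
      rank_sum[, , , t] <- rank_sum[, , , t] + pad_shift(Rarr[, , , t], o)
    }
  }
  mcnt <- count
  dev <- matrix(rank_sum, prod(d), k) - as.numeric(mcnt) * (k + 1) / 2
  S <- array(rowSums(dev^2), d)
  W <- 12 * S / (mcnt^2 * (k^3 - k))
  W[!m | mcnt < 2] <- NA          # need at least one in-mask neighbor to rank against
  volume(W, affine, units = "ldh")
}

#' Tract integrity statistics
#'
#' @param tract a `nb_tract` (non-empty mask).
#' @param fa_map,ldh_map `nb_volume`s on the same grid.
#' @return list with `mean_fa`, `mean_ldh`, `n_voxels`.
#' @export
tract_integrity <- function(tract, fa_map, ldh_map) {
  vox <- mask_indices(tract$mask)
  if (!length(vox)) stop("empty tract mask")
  list(mean_fa = mean(fa_map$data[vox], na.rm = TRUE),
       mean_ldh = mean(ldh_map$data[vox], na.rm = TRUE),
       n_voxels = length(vox))
}
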