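#' Discard initial equilibration frames
#'
#' @param bold a `nb_bold`.
#' @param k number of leading frames to drop (default 10).
#' @return `nb_bold` with the first `k` frames removed, TR unchanged.
#' @export
discard_initial_volumes <- function(bold, k = 10L) {
  nt <- dim(bold$data)[4]
  if (nt <= k) stop("cannot discard ", k, " of ", nt, " frames")
  if (k == 0L) return(bold)
  bold_series(bold$data[, , , (k + 1):nt, drop = FALSE], bold$tr_s,
              bold$affine, bold$band)
}

#' Head-motion exclusion rule
#'
#' @param motion 6-vector of maximum absolute translations (mm) and
#'   rotations (degrees).
#' @param trans_limit,rot_limit exclusion limits (strict `>`), default 2.5.
#' @return TRUE to keep the observation, FALSE to exclude.
#' @export
motion_exclude <- function(motion, trans_limit = 2.5, rot_limit = 2.5) {
  m <- as.numeric(motion)
  stopifnot(length(m) == 6L)
  !(any(abs(m[1:3]) > trans_limit) || any(abs(m[4:6]) > rot_limit))
}

gaussian_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma_vox^2))
  K[K < exp(-16)] <- 0
  K / rowSums(K)           # truncated+renormalized: constants stay constant
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian with `sigma = fwhm / (2 * sqrt(2 * log(2)))` per axis
#' in mm, converted to voxels per axis. 4D input is smoothed frame-wise.
#' Boundaries renormalize the truncated kernel.
#'
#' @param x 3D/4D array, `nb_volume`, or `nb_bold`.
#' @param fwhm_mm full width at half maximum in mm (0 = identity).
#' @param voxel_mm voxel size(s); taken from the object's affine when present.
#' @return smoothed object of the same type.
#' @export
gaussian_smooth <- function(x, fwhm_mm, voxel_mm = NULL) {
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (inherits(x, "nb_volume")) {
    return(volume(gaussian_smooth(x$data, fwhm_mm, voxel_sizes(x$affine)),
                  x$affine, x$units))
  }
  if (inherits(x, "nb_bold")) {
    return(bold_series(gaussian_smooth(x$data, fwhm_mm, voxel_sizes(x$affine)),
                       x$tr_s, x$affine, x$band))
  }
  if (fwhm_mm == 0) return(x)
  if (is.null(voxel_mm)) voxel_mm <- 1
  v <- rep(voxel_mm, length.out = 3)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / v
  d <- dim(x)
  for (axis in 1:3) {
    K <- gaussian_kernel_matrix(d[axis], sigma_vox[axis])
    x <- apply_axis(x, K, axis)
  }
  x
}

bold_vox_by_time <- function(bold) {
  d <- dim(bold$data)
  matrix(bold$data, prod(d[1:3]), d[4])
}

#' Linear detrend and frequency-domain band-pass
#'
#' Removes, per voxel, the least-squares linear trend, then applies a hard
#' frequency mask retaining `[low_hz, high_hz]` (inclusive; the zero
#' frequency is outside any positive band).
#'
#' @param bold a `nb_bold`.
#' @param low_hz,high_hz pass band in Hz, default 0.01-0.10.
#' @return filtered `nb_bold` with `band` recorded.
#' @export
detrend_bandpass <- function(bold, low_hz = 0.01, high_hz = 0.10) {
  nt <- dim(bold$data)[4]
  nyquist <- 1 / (2 * bold$tr_s)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyquist + 1e-12))
    stop("invalid band [", low_hz, ", ", high_hz, "] for Nyquist ", nyquist)
  Y <- t(bold_vox_by_time(bold))           # time x voxel
  X <- cbind(1, seq_len(nt))
  Y <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
  f <- fft_freqs(nt, bold$tr_s)
  keep <- f >= low_hz - 1e-12 & f <= high_hz + 1e-12
  Yf <- stats::mvfft(Y)
  Yf[!keep, ] <- 0
  Y <- Re(stats::mvfft(Yf, inverse = TRUE)) / nt
  bold_series(array(t(Y), dim(bold$data)), bold$tr_s, bold$affine,
              band = c(low_hz, high_hz))
}

#' Nuisance regression
#'
#' Regresses an intercept plus the given confound columns out of every
#' voxel time course; residuals are returned (orthogonal to each confound).
#'
#' @param bold a `nb_bold`.
#' @param confounds numeric matrix (frames x q), or NULL for intercept only
#'   (mean centering).
#' @return residual `nb_bold`.
#' @export
nuisance_regress <- function(bold, confounds = NULL) {
  nt <- dim(bold$data)[4]
  X <- cbind(intercept = rep(1, nt), confounds)
  if (ncol(X) >= nt) stop("more confounds than frames")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient confound design")
  Y <- t(bold_vox_by_time(bold))
  Y <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
  bold_series(array(t(Y), dim(bold$data)), bold$tr_s, bold$affine, bold$band)
}

#' Mean-normalized fractional amplitude of low-frequency fluctuations
#'
#' Per voxel, fALFF is the sum of the amplitude spectrum inside the band
#' divided by the sum over all positive frequencies; the map is then
#' divided by its mean within the mask (the "m" normalization).
#'
#' @param bold a `nb_bold` (detrended, not band-passed).
#' @param mask analysis mask.
#' @param band numerator band in Hz, default 0.01-0.10.
#' @return `nb_volume`; values outside the mask are NA.
#' @export
mfalff_map <- function(bold, mask, band = c(0.01, 0.10)) {
  m <- as_mask_array(mask)
  nt <- dim(bold$data)[4]
  Y <- t(bold_vox_by_time(bold))
  amp <- Mod(stats::mvfft(Y))
  f <- fft_freqs(nt, bold$tr_s)
  pos <- seq(2, floor(nt / 2) + 1)              # positive frequencies
  inband <- pos[f[pos] >= band[1] - 1e-12 & f[pos] <= band[2] + 1e-12]
  tot <- colSums(amp[pos, , drop = FALSE])
  if (all(tot[as.vector(m)] == 0)) stop("zero spectrum inside mask")
  falff <- colSums(amp[inband, , drop = FALSE]) / tot
  falff[tot == 0] <- NA
  arr <- array(falff, dim(bold$data)[1:3])
  arr[!m] <- NA
  arr <- arr / mean(arr[m], na.rm = TRUE)
  volume(arr, bold$affine, units = "mfalff")
}

#' Voxel-pairwise functional connectivity matrix
#'
#' Pearson correlation between the time courses of every pair of mask
#' voxels. Constant voxels are flagged and their rows/columns set NA (they
#' never contribute to degree counts).
#'
#' @param bold a preprocessed `nb_bold`.
#' @param mask analysis mask.
#' @return object of class `nb_fc`: `r` (V x V, unit diagonal), `voxels`
#'   (linear indices), `defined` (logical per voxel).
#' @export
fc_matrix <- function(bold, mask) {
  vox <- mask_indices(mask)
  nt <- dim(bold$data)[4]
  if (nt < 3L) stop("need at least 3 frames")
  Y <- t(bold_vox_by_time(bold)[vox, , drop = FALSE])    # time x V
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  ss <- sqrt(colSums(Yc^2))
  defined <- ss > 0
  r <- matrix(NA_real_, ncol(Y), ncol(Y))
  if (any(defined)) {
    Yn <- sweep(Yc[, defined, drop = FALSE], 2, ss[defined], `/`)
    r[defined, defined] <- crossprod(Yn)    # Pearson via unit-norm columns
  }
  diag(r) <- 1
  structure(list(r = r, voxels = vox, defined = defined,
                 dim = dim(bold$data)[1:3], affine = bold$affine),
            class = "nb_fc")
}

#' Voxel-wise degree centrality
#'
#' Per voxel, the number of other mask voxels whose correlation exceeds the
#' threshold (strict `r > r_threshold`, binary count). `weighted = TRUE`
#' sums the suprathreshold r values instead (degree "strength").
#'
#' @param fc a `nb_fc`.
#' @param r_threshold effective-connection threshold, default 0.10.
#' @param weighted count (default) or sum suprathreshold correlations.
#' @return object of class `nb_degree`: `data` (nb_volume of counts, NA
#'   outside mask and at undefined voxels), `r_threshold`, `voxels`.
#' @export
degree_map <- function(fc, r_threshold = 0.10, weighted = FALSE) {
  r <- fc$r
  dg <- diag(r)
  supra <- r > r_threshold
  deg <- if (weighted) rowSums(r * supra, na.rm = TRUE) - dg * (dg > r_threshold)
         else rowSums(supra, na.rm = TRUE) - (dg > r_threshold)
  deg[!fc$defined] <- NA
  arr <- array(NA_real_, fc$dim)
  arr[fc$voxels] <- deg
  structure(list(data = volume(arr, fc$affine, units = "degree"),
                 r_threshold = r_threshold, voxels = fc$voxels,
                 weighted = weighted),
            class = "nb_degree")
}

#' Z-standardize a map within a mask
#'
#' @param map `nb_volume` or 3D array.
#' @param mask analysis mask.
#' @return `nb_volume` with within-mask mean 0 and sample sd 1 (NA outside).
#' @export
z_standardize <- function(map, mask) {
  arr <- if (inherits(map, "nb_volume")) map$data else map
  aff <- if (inherits(map, "nb_volume")) map$affine else grid_affine(dim(arr), 1)
  m <- as_mask_array(mask)
  vals <- arr[m]
  ok <- !is.na(vals)
  if (sum(ok) < 2L) stop("need at least 2 mask voxels")
  s <- stats::sd(vals[ok])
  if (s == 0) stop("constant map within mask")
  out <- array(NA_real_, dim(arr))
  out[m] <- (vals - mean(vals[ok])) / s
  volume(out, aff, units = "z")
}

#' Spherical seed at the peak of a statistic map
#'
#' The center is the voxel with the largest `|statistic|` within the mask;
#' the seed contains all mask voxels whose centers lie within `radius_mm`
#' of the center (inclusive).
#'
#' @param stat_map `nb_volume`.
#' @param mask analysis mask.
#' @param radius_mm sphere radius, default 3.
#' @return object of class `nb_seed`: `center_vox`, `center_mm`,
#'   `radius_mm`, `voxels` (linear indices).
#' @export
seed_from_peak <- function(stat_map, mask, radius_mm = 3) {
  m <- as_mask_array(mask)
  vox <- which(m)
  if (!length(vox)) stop("empty mask")
  vals <- abs(stat_map$data[vox])
  vals[is.na(vals)] <- -Inf
  peak <- vox[which.max(vals)]
  d <- dim(stat_map$data)
  cv <- as.integer(arrayInd(peak, d))
  sph <- sphere_voxels(d, cv, radius_mm, stat_map$affine)
  sel <- intersect(sph, vox)
  if (!length(sel)) stop("empty seed after masking")
  structure(list(center_vox = cv,
                 center_mm = as.numeric(voxel_to_mm(matrix(cv, 1), stat_map$affine)),
                 radius_mm = radius_mm, voxels = sort(sel),
                 dim = d, affine = stat_map$affine),
            class = "nb_seed")
}

#' Seed-based functional connectivity z-map
#'
#' Correlates the unweighted mean time series over the seed voxels with
#' every mask voxel and Fisher-transforms the correlations. Seed voxels and
#' saturated correlations (|r| >= 1, e.g. a voxel equal to the seed mean)
#' are excluded (NA).
#'
#' @param bold preprocessed `nb_bold`.
#' @param seed a `nb_seed`.
#' @param mask analysis mask.
#' @return `nb_volume` of Fisher z values (NA outside mask / at exclusions).
#' @export
seed_fc_zmap <- function(bold, seed, mask) {
  vox <- mask_indices(mask)
  Y <- t(bold_vox_by_time(bold))
  seed_ts <- rowMeans(Y[, seed$voxels, drop = FALSE])
  if (stats::sd(seed_ts) == 0) stop("constant seed time series")
  sds <- apply(Y[, vox, drop = FALSE], 2, stats::sd)
  r <- rep(NA_real_, length(vox))
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(seed_ts, Y[, vox[ok], drop = FALSE]))
  r[abs(r) >= 1 - 1e-12] <- NA           # saturated: flagged, excluded
  z <- atanh(r)
  arr <- array(NA_real_, dim(bold$data)[1:3])
  arr[vox] <- z
  arr[seed$voxels] <- NA
  volume(arr, bold$affine, units = "fisher_z")
}

#' Voxel-wise map-behavior correlation
#'
#' Pearson (or partial, given covariates) correlation between per-voxel map
#' values and a behavioral score across observations.
#'
#' @param maps list of `nb_volume`, one per observation.
#' @param scores numeric vector aligned with `maps`.
#' @param covariates optional numeric matrix (observations x q).
#' @param mask analysis mask.
#' @return list with `r` and `p` (`nb_volume`s) and `df`.
#' @export
map_behavior_correlation <- function(maps, scores, covariates = NULL,
                                     mask = NULL) {
  n <- length(maps)
  if (n < 4L) stop("need at least 4 observations")
  if (length(scores) != n) stop("scores/maps length mismatch")
  d <- dim(maps[[1]]$data)
  vox <- if (is.null(mask)) seq_len(prod(d)) else mask_indices(mask)
  M <- vapply(maps, function(v) v$data[vox], numeric(length(vox)))  # V x n
  M <- t(M)                                                         # n x V
  q <- 0L
  y <- scores
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    C <- as.matrix(covariates)
    q <- ncol(C)
    X <- cbind(1, C)
    if (qr(X)$rank < ncol(X)) stop("rank-deficient covariates")
    H <- X %*% solve(crossprod(X))
    y <- y - H %*% crossprod(X, y)
    M <- M - H %*% crossprod(X, M)
  } else {
    y <- y - mean(y)
    M <- sweep(M, 2, colMeans(M))
  }
  num <- as.numeric(crossprod(M, as.numeric(y)))
  den <- sqrt(colSums(M^2) * sum(y^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  df <- n - 2L - q
  tstat <- r * sqrt(df / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df)
  rr <- array(NA_real_, d); rr[vox] <- r
  pp <- array(NA_real_, d); pp[vox] <- p
  list(r = volume(rr, maps[[1]]$affine, units = "r"),
       p = volume(pp, maps[[1]]$affine, units = "p"),
       df = df)
}
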