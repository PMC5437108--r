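mk_bold <- function(arr, tr = 2, voxel_mm = 3) {
  bold_series(arr, tr, grid_affine(dim(arr)[1:3], voxel_mm))
}

test_that("discard_initial_volumes and motion_exclude follow the stated rules", {
  b <- mk_bold(array(rnorm(2 * 2 * 2 * 200), c(2, 2, 2, 200)))
  expect_equal(dim(discard_initial_volumes(b, 10)$data)[4], 190)
  expect_identical(discard_initial_volumes(b, 0), b)
  b10 <- mk_bold(array(rnorm(2 * 2 * 2 * 11), c(2, 2, 2, 11)))
  expect_error(discard_initial_volumes(mk_bold(array(rnorm(80), c(2, 2, 2, 10))), 10),
               "discard")

  expect_true(motion_exclude(rep(0, 6)))
  expect_false(motion_exclude(c(2.6, 0, 0, 0, 0, 0)))
  expect_false(motion_exclude(c(0, 0, 0, 0, 2.6, 0)))
  expect_true(motion_exclude(rep(2.5, 6)))     # strict >
})

test_that("gaussian_smooth preserves constants and realizes the target FWHM", {
  const <- array(3.7, c(8, 8, 8))
  expect_equal(gaussian_smooth(const, 6, 3), const, tolerance = 1e-12)
  x <- array(rnorm(8^3), c(8, 8, 8))
  expect_identical(gaussian_smooth(x, 0, 3), x)
  expect_error(gaussian_smooth(x, -1, 3), "non-negative")

  # impulse response: second moment of the profile gives the kernel sd
  d <- c(41, 41, 41)
  a <- array(0, d); a[21, 21, 21] <- 1
  sm <- gaussian_smooth(a, 6, 3)
  prof <- sm[, 21, 21]
  mm <- (1:41 - 21) * 3
  fwhm <- 2 * sqrt(2 * log(2)) * sqrt(sum(prof * mm^2) / sum(prof))
  expect_lt(abs(fwhm - 6) / 6, 0.05)
})

test_that("detrend_bandpass removes trends and gates frequencies", {
  nt <- 200
  ramp <- array(rep(1:nt, each = 8), c(2, 2, 2, nt))
  out <- detrend_bandpass(mk_bold(ramp))
  expect_lt(max(abs(out$data)), 1e-8 * nt)

  pw <- function(f) {
    sig <- sin(2 * pi * f * (1:nt) * 2)
    b <- mk_bold(array(rep(sig, each = 8), c(2, 2, 2, nt)))
    o <- detrend_bandpass(b)
    sum(o$data[1, 1, 1, ]^2) / sum((sig - mean(sig))^2)
  }
  expect_gt(pw(0.05), 0.95)
  expect_lt(pw(0.20), 0.05)
  expect_error(detrend_bandpass(mk_bold(ramp), 0.01, 0.30), "band")
})

test_that("nuisance_regress residuals are orthogonal to the confounds", {
  set.seed(21)
  nt <- 50
  b <- mk_bold(array(rnorm(8 * nt), c(2, 2, 2, nt)))
  C <- matrix(rnorm(nt * 3), nt, 3)
  out <- nuisance_regress(b, C)
  R <- matrix(out$data, 8, nt)
  expect_lt(max(abs(R %*% C)), 1e-8)
  expect_lt(max(abs(rowSums(R))), 1e-8)      # intercept removed

  # confound equal to a voxel's own series zeroes that voxel
  own <- b$data[1, 1, 1, ]
  out2 <- nuisance_regress(b, matrix(own))
  expect_lt(max(abs(out2$data[1, 1, 1, ])), 1e-8)

  # empty confounds = mean centering
  out3 <- nuisance_regress(b, NULL)
  expect_equal(array(b$data - rep(apply(b$data, 1:3, mean), nt), dim(b$data)),
               out3$data, tolerance = 1e-10)
  expect_error(nuisance_regress(b, cbind(C[, 1], C[, 1])), "rank")
})

test_that("mfalff_map normalizes to mask mean 1 and tracks in-band fraction", {
  set.seed(31)
  nt <- 200
  arr <- array(rnorm(27 * nt), c(3, 3, 3, nt))
  sig <- 10 * sin(2 * pi * 0.05 * (1:nt) * 2)
  arr[1, 1, 1, ] <- sig + 0.1 * rnorm(nt)
  b <- mk_bold(arr)
  mask <- array(TRUE, c(3, 3, 3))
  m1 <- mfalff_map(b, mask)
  expect_equal(mean(m1$data[mask]), 1, tolerance = 1e-10)
  # the almost-pure in-band voxel has above-average mfALFF
  expect_gt(m1$data[1, 1, 1], max(m1$data[-1]))

  # independent spectrum computation for the in-band fraction
  f <- (1:(nt / 2)) / (nt * 2)
  amp <- Mod(fft(arr[1, 1, 1, ]))[2:(nt / 2 + 1)]
  frac <- sum(amp[f >= 0.01 - 1e-12 & f <= 0.10 + 1e-12]) / sum(amp)
  raw <- m1$data[1, 1, 1] * mean(
    vapply(which(mask), function(v) {
      ij <- arrayInd(v, c(3, 3, 3))
      a <- Mod(fft(arr[ij[1], ij[2], ij[3], ]))[2:(nt / 2 + 1)]
      sum(a[f >= 0.01 - 1e-12 & f <= 0.10 + 1e-12]) / sum(a)
    }, numeric(1)))
  expect_equal(raw, frac, tolerance = 1e-8)
})

test_that("fc_matrix is a symmetric Pearson matrix with flagged constants", {
  set.seed(41)
  arr <- array(rnorm(8 * 30), c(2, 2, 2, 30))
  arr[2, 1, 1, ] <- arr[1, 1, 1, ]               # duplicated series
  arr[1, 2, 1, ] <- 5                            # constant voxel
  fc <- fc_matrix(mk_bold(arr), array(TRUE, c(2, 2, 2)))
  expect_equal(fc$r[1, 2], 1, tolerance = 1e-12)
  expect_false(fc$defined[3])
  expect_true(all(is.na(fc$r[3, -3])))
  expect_lt(max(abs(fc$r - t(fc$r)), na.rm = TRUE), 1e-12)
  expect_equal(diag(fc$r), rep(1, 8))

  arr2 <- array(0, c(2, 1, 1, 3))
  arr2[1, 1, 1, ] <- c(1, 2, 3); arr2[2, 1, 1, ] <- c(1, 3, 2)
  fc2 <- fc_matrix(mk_bold(arr2), array(TRUE, c(2, 1, 1)))
  expect_equal(fc2$r[1, 2], 0.5, tolerance = 1e-12)
})

test_that("degree_map equals the brute-force pair loop and is affine invariant", {
  set.seed(51)
  d <- c(4, 3, 3); nt <- 25
  arr <- array(rnorm(prod(d) * nt), c(d, nt))
  b <- mk_bold(arr)
  mask <- array(TRUE, d)
  fc <- fc_matrix(b, mask)
  dm <- degree_map(fc, 0.10)
  series <- t(matrix(arr, prod(d), nt))
  expect_identical(as.integer(dm$data$data[mask]), oracle_degree(series, 0.10))

  # per-voxel affine rescaling leaves degree unchanged
  sc <- array(runif(prod(d), 0.5, 2), d)
  of <- array(rnorm(prod(d)), d)
  arr2 <- arr * as.numeric(sc) + as.numeric(of)
  dm2 <- degree_map(fc_matrix(mk_bold(arr2), mask), 0.10)
  expect_equal(dm$data$data, dm2$data$data, tolerance = 1e-12)

  # all identical series -> N-1; impossible threshold -> 0
  same <- array(rep(rnorm(nt), each = prod(d)), c(d, nt))
  dms <- degree_map(fc_matrix(mk_bold(same), mask), 0.10)
  expect_true(all(dms$data$data == prod(d) - 1))
  expect_true(all(degree_map(fc, 1.0)$data$data == 0))

  # weighted variant sums the suprathreshold correlations
  dw <- degree_map(fc, 0.10, weighted = TRUE)
  r <- fc$r; diag(r) <- NA
  expect_equal(dw$data$data[mask],
               rowSums(r * (r > 0.10), na.rm = TRUE), tolerance = 1e-12)
})

test_that("z_standardize centers and scales within the mask", {
  v <- toy_volume(array(c(1, 2, 3, 4), c(4, 1, 1)))
  z <- z_standardize(v, array(TRUE, c(4, 1, 1)))
  expect_equal(as.numeric(z$data), c(-1.162, -0.387, 0.387, 1.162),
               tolerance = 1e-3)
  set.seed(61)
  a <- array(rnorm(27), c(3, 3, 3)); m <- array(TRUE, c(3, 3, 3))
  z1 <- z_standardize(toy_volume(a), m)
  expect_equal(mean(z1$data[m]), 0, tolerance = 1e-10)
  expect_equal(sd(z1$data[m]), 1, tolerance = 1e-10)
  z2 <- z_standardize(toy_volume(3 * a - 7), m)
  expect_equal(z1$data, z2$data, tolerance = 1e-10)
  expect_error(z_standardize(toy_volume(array(1, c(3, 3, 3))), m), "constant")
})

test_that("seed_from_peak enumerates the 3 mm sphere correctly", {
  d <- c(9, 9, 9)
  a <- array(0, d); a[5, 5, 5] <- 10
  v <- toy_volume(a, 3)
  s <- seed_from_peak(v, array(TRUE, d), 3)
  expect_equal(length(s$voxels), 7)       # center + 6 face neighbors
  expect_equal(s$center_vox, c(5, 5, 5))

  a2 <- array(0, d); a2[1, 1, 1] <- -10   # peak by |stat| at a corner
  s2 <- seed_from_peak(toy_volume(a2, 3), array(TRUE, d), 3)
  expect_equal(length(s2$voxels), 4)

  m <- array(FALSE, d); m[5, 5, 5] <- TRUE
  a3 <- array(0, d); a3[5, 5, 5] <- 1
  s3 <- seed_from_peak(toy_volume(a3, 3), m, 3)
  expect_equal(s3$voxels, which(m))
})

test_that("seed_fc_zmap excludes the seed, flags saturation, bounds null z", {
  set.seed(71)
  d <- c(6, 6, 4); nt <- 120
  arr <- array(rnorm(prod(d) * nt), c(d, nt))
  seed_ts <- rnorm(nt)
  arr[1, 1, 1, ] <- seed_ts
  arr[2, 1, 1, ] <- seed_ts                        # equals the seed mean
  b <- mk_bold(arr)
  m <- array(TRUE, d)
  stat <- array(0, d); stat[1, 1, 1] <- 5
  mask1 <- array(FALSE, d); mask1[1, 1, 1] <- TRUE
  s <- seed_from_peak(toy_volume(stat, 3), mask1, 1)
  z <- seed_fc_zmap(b, s, m)
  expect_true(is.na(z$data[1, 1, 1]))              # seed excluded
  expect_true(is.na(z$data[2, 1, 1]))              # saturated |r| = 1
  zs <- z$data[m]; zs <- zs[!is.na(zs)]
  expect_gt(mean(abs(zs) < 3 / sqrt(nt - 3)), 0.9) # Fisher null variance
})

test_that("map_behavior_correlation recovers perfect and null couplings", {
  set.seed(81)
  d <- c(5, 5, 3); n <- 24
  scores <- rnorm(n)
  maps <- lapply(1:n, function(i) {
    a <- array(rnorm(prod(d)), d)
    a[2, 2, 2] <- scores[i]
    toy_volume(a)
  })
  out <- map_behavior_correlation(maps, scores)
  expect_equal(out$r$data[2, 2, 2], 1, tolerance = 1e-10)
  expect_equal(out$df, n - 2)
  # null voxels: about 5% below p = .05 (binomial bound over 74 voxels)
  pv <- out$p$data[-which(array(seq_len(prod(d)), d) == 2 + 5 + 25)]
  expect_lt(mean(pv < 0.05, na.rm = TRUE), 0.15)
  expect_error(map_behavior_correlation(maps, scores[-1]), "mismatch")
})
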