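gtab40 <- gradient_table(netbeh:::fibonacci_directions(40), b_value = 1000,
                         n_b0 = 1)

test_that("gradient_table validates directions", {
  expect_error(gradient_table(matrix(c(1, 1, 0), 6, 3, byrow = TRUE)), "unit")
  one_axis <- matrix(rep(c(1, 0, 0), 7), ncol = 3, byrow = TRUE)
  expect_error(gradient_table(one_axis), "collinear|degenerate")
  expect_equal(sum(gtab40$bvals == 0), 1)
  expect_equal(nrow(gtab40$bvecs), 41)
})

test_that("fit_tensor inverts noiseless synthetic signals", {
  D <- diag(c(1.7e-3, 0.2e-3, 0.2e-3))
  # rotate so the fit is not axis-aligned
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Dr <- R %*% D %*% t(R)
  dwi <- phantom_dwi_from_tensor(Dr, gtab40)
  tf <- fit_tensor(dwi, gtab40)
  # round-trip on the tensor components
  Dfit <- tf$D[1, ]
  Dm <- matrix(c(Dfit[1], Dfit[4], Dfit[5],
                 Dfit[4], Dfit[2], Dfit[6],
                 Dfit[5], Dfit[6], Dfit[3]), 3, 3)
  expect_lt(max(abs(Dm - Dr)) / max(abs(Dr)), 1e-8)
  expect_equal(sort(tf$evals[1, ], decreasing = TRUE),
               c(1.7e-3, 0.2e-3, 0.2e-3), tolerance = 1e-6)
  # closed-form FA for eigenvalues (1.7, 0.2, 0.2) x 1e-3
  expect_equal(tf$fa$data[1, 1, 1], 0.8704, tolerance = 1e-4)
  # principal direction
  expect_gt(abs(sum(tf$e1[1, ] * c(cos(th), sin(th), 0))), 1 - 1e-6)

  iso <- fit_tensor(phantom_dwi_from_tensor(diag(rep(7e-4, 3)), gtab40), gtab40)
  expect_lt(max(abs(iso$fa$data)), 1e-7)
  expect_true(all(iso$unreliable))
})

test_that("FA stays in [0, 1] with eigenvalue clamping", {
  set.seed(31)
  gt <- gtab40
  d <- c(4, 4, 2)
  arr <- array(abs(rnorm(prod(d) * 41, 50, 20)) + 1, c(d, 41))
  tf <- fit_tensor(arr, gt)
  fa <- tf$fa$data
  expect_true(all(fa >= 0 & fa <= 1))
  expect_true(all(tf$evals >= 0))
})

test_that("FACT on a uniform +x field spans the grid and exits", {
  d <- c(12, 5, 5)
  e1 <- array(0, c(d, 3)); e1[, , , 1] <- 1
  fa <- array(0.5, d)
  tf <- phantom_tensor_field(e1, fa)
  seeds <- which(array(seq_len(prod(d)), d) ==
                   (6 + 12 * 2 + 60 * 2))          # voxel (6,3,3)
  st <- fact_track(tf, seeds, seeds_per_voxel = 20, rng_seed = 3)
  expect_equal(length(st$visited), 20)
  expect_true(all(st$termination %in% "exit"))
  for (v in st$visited) {
    ci <- arrayInd(v, d)
    expect_equal(sort(unique(ci[, 1])), 1:12)      # full x span
    expect_equal(unique(ci[, 2]), 3)
    expect_equal(unique(ci[, 3]), 3)
  }
  # determinism
  st2 <- fact_track(tf, seeds, seeds_per_voxel = 20, rng_seed = 3)
  expect_identical(st$visited, st2$visited)
  expect_identical(st$length_mm, st2$length_mm)
})

test_that("FACT terminates with reason angle at a 90-degree plane", {
  d <- c(10, 5, 5)
  e1 <- array(0, c(d, 3))
  e1[1:5, , , 1] <- 1          # +x on the left half
  e1[6:10, , , 2] <- 1         # +y on the right half
  fa <- array(0.5, d)
  tf <- phantom_tensor_field(e1, fa)
  seeds <- which(array(seq_len(prod(d)), d) == (2 + 10 * 2 + 50 * 2))
  st <- fact_track(tf, seeds, seeds_per_voxel = 25, rng_seed = 5)
  # forward half runs into the rotation plane
  expect_true(all(st$termination[, "forward"] == "angle"))
  expect_true(all(st$termination[, "backward"] == "exit"))
})

test_that("FACT stops below the FA threshold and on degenerate tensors", {
  d <- c(10, 3, 3)
  e1 <- array(0, c(d, 3)); e1[, , , 1] <- 1
  fa <- array(0.5, d); fa[7:10, , ] <- 0.10
  tf <- phantom_tensor_field(e1, fa)
  seeds <- which(array(seq_len(prod(d)), d) == (2 + 10 + 30))
  st <- fact_track(tf, seeds, seeds_per_voxel = 10, rng_seed = 6)
  expect_true(all(st$termination[, "forward"] == "fa"))
  # FA along visited voxels >= threshold except the terminal one
  for (i in seq_along(st$visited)) {
    ci <- arrayInd(st$visited[[i]], d)
    expect_lte(sum(fa[ci] < 0.15), 1)
  }
  tf2 <- phantom_tensor_field(e1, array(0.5, d))
  tf2$unreliable[4 + 10 + 30] <- TRUE       # voxel (4,2,2)
  st2 <- fact_track(tf2, seeds, seeds_per_voxel = 5, rng_seed = 6)
  expect_true(all(st2$termination[, "forward"] == "degenerate"))
  expect_error(fact_track(tf2, integer(0)), "empty seed")
})

test_that("curved quarter-circle field yields the planted arc length", {
  # tangent field of a quarter circle of radius 14 voxels centered at origin
  d <- c(20, 20, 3)
  e1 <- array(0, c(d, 3))
  R <- 14
  for (i in 1:20) for (j in 1:20) {
    x <- i - 0.5; y <- j - 0.5
    th <- atan2(y, x)
    e1[i, j, , 1] <- -sin(th)
    e1[i, j, , 2] <- cos(th)
  }
  fa <- array(0, d)
  for (i in 1:20) for (j in 1:20) {
    r <- sqrt((i - 0.5)^2 + (j - 0.5)^2)
    if (abs(r - R) < 1.6) fa[i, j, ] <- 0.5
  }
  tf <- phantom_tensor_field(e1, fa)
  start <- which(fa[, 1, 2] > 0)[2]
  seeds <- start + 0 * 20 + 20 * 20 * 1   # (start, 1, 2)
  st <- fact_track(tf, seeds, seeds_per_voxel = 30, rng_seed = 7)
  planted <- pi / 2 * R
  med <- median(st$length_mm)
  expect_lt(abs(med - planted) / planted, 0.10)
})

test_that("tract_mask_between keeps exactly the streamlines reaching B", {
  d <- c(12, 5, 5)
  e1 <- array(0, c(d, 3)); e1[, , , 1] <- 1
  tf <- phantom_tensor_field(e1, array(0.5, d))
  roiA <- array(FALSE, d); roiA[2, 3, 3] <- TRUE
  roiB <- array(FALSE, d); roiB[11, 3, 3] <- TRUE
  st <- fact_track(tf, which(roiA), seeds_per_voxel = 10, rng_seed = 8)
  tm <- tract_mask_between(st, roiA, roiB)
  expect_equal(tm$n_streamlines_kept, 10)
  # the mask is the connecting x column
  ci <- arrayInd(which(tm$mask$data > 0), d)
  expect_equal(sort(unique(ci[, 1])), 1:12)
  expect_true(all(ci[, 2] == 3 & ci[, 3] == 3))
  # kept-streamline voxels are exactly the mask
  expect_equal(sort(unique(unlist(st$visited))), which(tm$mask$data > 0))
  # unreachable B -> empty mask
  roiC <- array(FALSE, d); roiC[6, 1, 1] <- TRUE
  tm2 <- tract_mask_between(st, roiA, roiC)
  expect_equal(sum(tm2$mask$data), 0)
  expect_equal(tm2$n_streamlines_kept, 0)
})

test_that("group_count_mask applies the more-than-3-subjects rule", {
  d <- c(4, 4, 1)
  mk <- function(v) { a <- array(0, d); a[v] <- 1; toy_volume(a) }
  masks <- c(lapply(1:3, function(i) mk(c(1, 2))),   # voxel 1,2 in 3 subjects
             lapply(1:1, function(i) mk(c(2))),      # voxel 2 in 4 subjects
             lapply(1:14, function(i) mk(c(5))))     # 18 subjects total
  gm <- group_count_mask(masks, 4)
  expect_equal(gm$count_map$data[1], 3)
  expect_equal(gm$count_map$data[2], 4)
  expect_equal(gm$mask$data[1], 0)                   # exactly 3 -> excluded
  expect_equal(gm$mask$data[2], 1)                   # 4 -> included
  expect_equal(gm$mask$data[5], 1)
  # min 1 = union; min n = intersection
  u <- group_count_mask(masks, 1)
  expect_equal(which(u$mask$data > 0), c(1, 2, 5))
  it <- group_count_mask(masks, length(masks))
  expect_equal(sum(it$mask$data), 0)
  same <- lapply(1:5, function(i) mk(c(3, 7)))
  expect_equal(group_count_mask(same, 5)$mask$data, same[[1]]$data)
  expect_error(group_count_mask(list(mk(1), toy_volume(array(0, c(2, 2, 1))))),
               "mismatch")
})

test_that("ldh_map equals the brute-force concordance oracle", {
  set.seed(41)
  d <- c(3, 3, 3)
  k <- 12
  gt <- gradient_table(netbeh:::fibonacci_directions(k), n_b0 = 1)
  arr <- array(rnorm(prod(d) * (k + 1), 100, 10), c(d, k + 1))
  m <- array(TRUE, d)
  W <- ldh_map(arr, gt, m)
  Y <- matrix(arr, prod(d), k + 1)[, -1]     # weighted volumes only
  for (v in seq_len(prod(d))) {
    ci <- as.integer(arrayInd(v, d))
    nb <- as.matrix(expand.grid(ci[1] + (-1:1), ci[2] + (-1:1), ci[3] + (-1:1)))
    nb <- nb[apply(nb, 1, function(r) all(r >= 1 & r <= d)), , drop = FALSE]
    lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
    expect_equal(W$data[v], oracle_kendall_w(Y[lin, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("ldh_map limit cases: identical series give W = 1, reversed give 0", {
  k <- 8
  gt <- gradient_table(netbeh:::fibonacci_directions(k), n_b0 = 1)
  d <- c(3, 3, 3)
  base <- rnorm(k)
  arr <- array(0, c(d, k + 1))
  arr[, , , 1] <- 100
  for (t in seq_len(k)) arr[, , , t + 1] <- base[t]
  W <- ldh_map(arr, gt, array(TRUE, d))
  expect_true(all(abs(W$data - 1) < 1e-12))

  # two in-mask voxels with exactly reversed rankings
  m2 <- array(FALSE, d); m2[1, 1, 1] <- TRUE; m2[2, 1, 1] <- TRUE
  arr2 <- arr
  arr2[1, 1, 1, -1] <- 1:k
  arr2[2, 1, 1, -1] <- k:1
  W2 <- ldh_map(arr2, gt, m2)
  expect_true(all(abs(W2$data[m2]) < 1e-12))   # rank sums all equal -> W = 0
  # an isolated voxel has nothing to rank against
  m1 <- array(FALSE, d); m1[1, 1, 1] <- TRUE
  expect_true(is.na(ldh_map(arr2, gt, m1)$data[1, 1, 1]))
})

test_that("tract_integrity averages over the tract mask", {
  d <- c(3, 1, 1)
  tr <- structure(list(mask = toy_volume(array(c(1, 1, 1), d))),
                  class = "nb_tract")
  fa <- toy_volume(array(c(0.2, 0.4, 0.6), d))
  ld <- toy_volume(array(c(0.1, 0.2, 0.3), d))
  out <- tract_integrity(tr, fa, ld)
  expect_equal(out$mean_fa, 0.4)
  expect_equal(out$mean_ldh, 0.2)
  expect_equal(out$n_voxels, 3)
  empty <- structure(list(mask = toy_volume(array(0, d))), class = "nb_tract")
  expect_error(tract_integrity(empty, fa, ld), "empty")
})
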