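#' Volumetric containers
#'
#' A `nb_volume` is a 3D scalar grid (gray-matter volume, statistic map,
#' mask, ...) together with a 4x4 voxel-to-mm affine (RAS+). Voxel indices
#' are 0-based in world-coordinate computations: the mm position of voxel
#' `(i, j, k)` (1-based R subscripts) is `affine %*% c(i-1, j-1, k-1, 1)`.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to mm.
#' @param units optional label for the voxel values.
#' @return An object of class `nb_volume`.
#' @export
volume <- function(data, affine = NULL, units = "arbitrary") {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (is.null(affine)) affine <- grid_affine(dim(data), 1)
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  structure(list(data = data, affine = affine, units = units),
            class = "nb_volume")
}

#' @export
print.nb_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<nb_volume %dx%dx%d, voxel %s mm, units=%s>\n",
              d[1], d[2], d[3],
              paste(signif(voxel_sizes(x$affine), 3), collapse = "x"),
              x$units))
  invisible(x)
}

#' Centered RAS+ affine for an isotropic grid
#'
#' @param dim integer grid shape (length 3).
#' @param voxel_mm scalar or length-3 voxel size in mm.
#' @return 4x4 affine with the grid center at the mm origin.
#' @export
grid_affine <- function(dim, voxel_mm) {
  v <- rep(voxel_mm, length.out = 3)
  a <- diag(c(v, 1))
  a[1:3, 4] <- -v * (dim - 1) / 2
  a
}

voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Convert voxel subscripts to mm coordinates
#' @param ijk n x 3 matrix of 1-based voxel subscripts.
#' @param affine 4x4 affine.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  h <- cbind(ijk - 1, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

#' A 4D BOLD-like time series
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr_s repetition time in seconds.
#' @param affine voxel-to-mm affine.
#' @param band optional `(low_hz, high_hz)` recording an applied band-pass.
#' @return An object of class `nb_bold`.
#' @export
bold_series <- function(data, tr_s, affine = NULL, band = NULL) {
  if (length(dim(data)) != 4L) stop("bold data must be a 4D array")
  if (dim(data)[4] < 2L) stop("bold series needs at least 2 frames")
  if (tr_s <= 0) stop("TR must be positive")
  if (is.null(affine)) affine <- grid_affine(dim(data)[1:3], 1)
  structure(list(data = data, tr_s = tr_s, affine = affine, band = band),
            class = "nb_bold")
}

#' @export
print.nb_bold <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<nb_bold %dx%dx%d x %d frames, TR=%gs%s>\n", d[1], d[2], d[3],
              d[4], x$tr_s,
              if (is.null(x$band)) "" else
                sprintf(", band=[%g,%g]Hz", x$band[1], x$band[2])))
  invisible(x)
}

as_mask_array <- function(mask) {
  m <- if (inherits(mask, "nb_volume")) mask$data else mask
  if (length(dim(m)) != 3L) stop("mask must be a 3D array or nb_volume")
  m != 0 & !is.na(m)
}

#' Linear indices of the voxels in a mask
#' @param mask 3D logical/numeric array or `nb_volume`.
#' @return integer vector of linear indices.
#' @export
mask_indices <- function(mask) which(as_mask_array(mask))

#' Spherical voxel set around a center voxel
#'
#' Membership is by center-to-center distance with an inclusive boundary
#' (`<= radius_mm`).
#'
#' @param dim grid shape.
#' @param center_vox 1-based voxel subscripts of the center.
#' @param radius_mm sphere radius in mm.
#' @param affine voxel-to-mm affine.
#' @return integer vector of linear voxel indices.
#' @export
sphere_voxels <- function(dim, center_vox, radius_mm, affine) {
  vx <- voxel_sizes(affine)
  r_vox <- ceiling(radius_mm / vx)
  rng <- lapply(1:3, function(a) {
    seq(max(1L, center_vox[a] - r_vox[a]), min(dim[a], center_vox[a] + r_vox[a]))
  })
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  cm <- voxel_to_mm(matrix(center_vox, 1), affine)
  gm <- voxel_to_mm(g, affine)
  d <- sqrt(rowSums((gm - matrix(cm, nrow(gm), 3, byrow = TRUE))^2))
  keep <- g[d <= radius_mm + 1e-9, , drop = FALSE]
  sort(keep[, 1] + dim[1] * (keep[, 2] - 1) + dim[1] * dim[2] * (keep[, 3] - 1))
}

# Apply a (n_out x n_in) matrix along one axis of an n-d array.
apply_axis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  out <- K %*% m
  d2 <- d[perm]
  d2[1] <- nrow(K)
  aperm(array(out, d2), order(perm))
}
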