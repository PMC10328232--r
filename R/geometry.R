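#' Labelled or intensity image volume
#'
#' Container for a 3-D image grid together with its voxel-to-world affine.
#' Voxel indices are 0-based and the affine maps an index to the world-RAS
#' position (in mm) of that voxel's center, the dominant neuroimaging
#' convention. The `frame` tag records whether world coordinates are scanner
#' RAS or FreeSurfer-style surface RAS so that accidental mixing of the two
#' frames is detectable downstream.
#'
#' @param grid 3-D numeric or integer array (I x J x K).
#' @param affine invertible 4x4 matrix mapping 0-based voxel index to world mm.
#' @param frame `"scanner_ras"` or `"surface_ras"`.
#' @param kind `"label"` for integer region-id volumes (sampled
#'   nearest-neighbour), `"intensity"` for continuous volumes (sampled
#'   trilinearly). Guessed from the storage mode when missing.
#' @return An object of class `volume_image` with fields `grid`, `affine`,
#'   `frame`, `kind`.
#' @export
volume_image <- function(grid, affine = diag(4),
                         frame = c("scanner_ras", "surface_ras"),
                         kind = NULL) {
  frame <- match.arg(frame)
  if (length(dim(grid)) != 3L)
    stop("'grid' must be a 3-D array")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("'affine' is not invertible")
  if (is.null(kind)) {
    kind <- if (is.integer(grid) || all(grid == round(grid))) "label" else "intensity"
  }
  kind <- match.arg(kind, c("label", "intensity"))
  structure(list(grid = grid, affine = affine, frame = frame, kind = kind),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<volume_image> %dx%dx%d %s volume (%s)\n",
              d[1], d[2], d[3], x$kind, x$frame))
  invisible(x)
}

#' Rigid (or general linear) world-to-world transform
#'
#' Wraps a 4x4 homogeneous matrix such as the one produced by manual
#' co-registration of a post-operative CT onto the pre-operative MRI. When
#' `rigid = TRUE` the rotation block must be orthonormal (within 1e-6).
#'
#' @param matrix 4x4 homogeneous matrix.
#' @param rigid declare the transform rigid and validate orthonormality.
#' @export
rigid_transform <- function(matrix, rigid = TRUE) {
  m <- as.matrix(matrix)
  if (!identical(dim(m), c(4L, 4L)))
    stop("transform matrix must be 4x4")
  if (abs(det(m)) < .Machine$double.eps)
    stop("transform matrix is not invertible: ",
         paste(utils::capture.output(print(unname(m))), collapse = "\n"))
  if (rigid) {
    R <- m[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      stop("rotation block is not orthonormal but transform declared rigid")
  }
  structure(list(matrix = m, rigid = rigid), class = "rigid_transform")
}

#' Invert a transform
#' @param transform a [rigid_transform()].
#' @export
transform_inverse <- function(transform) {
  rigid_transform(solve(transform$matrix), rigid = transform$rigid)
}

#' Compose two transforms (apply `first`, then `second`)
#' @param second,first [rigid_transform()] objects.
#' @export
transform_compose <- function(second, first) {
  rigid_transform(second$matrix %*% first$matrix,
                  rigid = second$rigid && first$rigid)
}

as_points_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L) stop("a point must have 3 coordinates")
    points <- matrix(points, nrow = 1L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (!all(is.finite(points))) stop("points must be finite")
  points
}

#' Apply a world-to-world transform to points
#'
#' Maps picked contact coordinates from the post-operative frame into the
#' pre-operative frame (or any other linear world-to-world mapping).
#'
#' @param points n x 3 matrix (or length-3 vector) of world mm coordinates.
#' @param transform a [rigid_transform()].
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(points, transform) {
  p <- as_points_matrix(points)
  h <- cbind(p, 1) %*% t(transform$matrix)
  h[, 1:3, drop = FALSE] / h[, 4]
}

#' World to continuous voxel index (0-based)
#'
#' No clipping is performed: coordinates outside the grid map to indices
#' outside `[0, dim-1]`, which is legal.
#'
#' @param points n x 3 world mm.
#' @param vol a [volume_image()].
#' @export
world_to_voxel <- function(points, vol) {
  p <- as_points_matrix(points)
  h <- cbind(p, 1) %*% t(solve(vol$affine))
  h[, 1:3, drop = FALSE] / h[, 4]
}

#' Voxel index (0-based, possibly fractional) to world mm
#' @param index n x 3 voxel indices.
#' @param vol a [volume_image()].
#' @export
voxel_to_world <- function(index, vol) {
  p <- as_points_matrix(index)
  h <- cbind(p, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE] / h[, 4]
}

# round half away from zero, componentwise (R's round() is banker's)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Sample a label volume at world points
#'
#' Returns the label of the nearest voxel center (round half away from zero
#' on each index axis); points falling outside the grid return 0
#' (background). This is the shared lookup primitive of the probabilistic
#' and volumetric labelling routes.
#'
#' @param vol a label [volume_image()].
#' @param points n x 3 world mm.
#' @return integer vector of label ids.
#' @export
sample_label <- function(vol, points) {
  if (vol$kind != "label") stop("'vol' is not a label volume")
  idx <- round_half_away(world_to_voxel(points, vol))
  d <- dim(vol$grid)
  inside <- idx[, 1] >= 0 & idx[, 1] < d[1] &
            idx[, 2] >= 0 & idx[, 2] < d[2] &
            idx[, 3] >= 0 & idx[, 3] < d[3]
  out <- integer(nrow(idx))
  if (any(inside)) {
    ii <- idx[inside, , drop = FALSE] + 1  # to 1-based
    out[inside] <- vol$grid[cbind(ii[, 1], ii[, 2], ii[, 3])]
  }
  out
}

#' Trilinear intensity sampling at world points
#'
#' Out-of-grid points return 0. Used for MRI-style continuous volumes; label
#' volumes must go through [sample_label()] since interpolating region ids is
#' meaningless.
#'
#' @inheritParams sample_label
#' @export
sample_intensity <- function(vol, points) {
  v <- world_to_voxel(points, vol)
  d <- dim(vol$grid)
  f0 <- floor(v)
  w <- v - f0
  out <- numeric(nrow(v))
  g <- vol$grid
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- f0[, 1] + dx; iy <- f0[, 2] + dy; iz <- f0[, 3] + dz
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3] & wt > 0
    if (any(ok))
      out[ok] <- out[ok] + wt[ok] * g[cbind(ix[ok], iy[ok], iz[ok]) + 1]
  }
  out
}

#' Oblique reslice along an electrode trajectory
#'
#' Extracts the planar image containing the segment `p0 -> p1` whose first
#' in-plane axis is the trajectory direction and whose second axis is the
#' in-plane direction closest to world inferior-superior, reproducing the
#' "re-sliced coronal view" along the long axis of a depth electrode shaft.
#' Label volumes are sampled nearest-neighbour, intensity volumes
#' trilinearly.
#'
#' @param vol a [volume_image()].
#' @param p0,p1 trajectory endpoints, world mm (`p0 != p1`).
#' @param width_mm extent of the plane perpendicular to the trajectory.
#' @param spacing_mm pixel pitch of the resliced image.
#' @param pad_mm extra extent beyond each endpoint along the trajectory.
#' @return list with `image` (s x t matrix), `s`/`t` pixel-center offsets in
#'   mm along the two in-plane axes, `origin`, `axis_s`, `axis_t` defining
#'   the pixel-to-world mapping `origin + s*axis_s + t*axis_t`, and
#'   `p0_pixel`/`p1_pixel`, the (row, col) positions of the endpoints.
#' @export
reslice_along_trajectory <- function(vol, p0, p1, width_mm = 40,
                                     spacing_mm = 1, pad_mm = 0) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  L <- sqrt(sum((p1 - p0)^2))
  if (L < .Machine$double.eps) stop("trajectory endpoints p0 and p1 coincide")
  u <- (p1 - p0) / L
  # second in-plane axis: closest to world superior (coronal-like view);
  # fall back to anterior for near-vertical shafts
  ref <- c(0, 0, 1)
  w <- ref - sum(ref * u) * u
  if (sqrt(sum(w^2)) < 1e-6) {
    ref <- c(0, 1, 0)
    w <- ref - sum(ref * u) * u
  }
  w <- w / sqrt(sum(w^2))
  ns <- ceiling(pad_mm / spacing_mm)
  s <- seq(-ns, ceiling(L / spacing_mm) + ns) * spacing_mm
  nt <- ceiling((width_mm / 2) / spacing_mm)
  t <- seq(-nt, nt) * spacing_mm
  pts <- cbind(rep(s, times = length(t)), rep(t, each = length(s)))
  world <- outer(pts[, 1], u) + outer(pts[, 2], w) +
    matrix(p0, nrow(pts), 3, byrow = TRUE)
  vals <- if (vol$kind == "label") sample_label(vol, world)
          else sample_intensity(vol, world)
  img <- matrix(vals, nrow = length(s), ncol = length(t))
  list(image = img, s = s, t = t,
       origin = p0, axis_s = u, axis_t = w,
       p0_pixel = c(which(abs(s) < spacing_mm / 2)[1], which(t == 0)),
       p1_pixel = c(which.min(abs(s - L)), which(t == 0)))
}
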