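#' Least-squares rigid transform from paired fiducials
#'
#' Closed-form orthogonal-Procrustes (Kabsch) solution: given paired
#' landmark sets in the model frame and the image frame, finds the
#' rotation and translation minimizing the mean squared distance
#' `|| R p_i + t - q_i ||^2`, with a reflection guard (det(R) = +1). The
#' fiducial registration error (FRE, root-mean-square residual in mm) is
#' reported on the result.
#'
#' @param model_points,image_points Paired n x 3 matrices (mm), n >= 3,
#'   not collinear.
#' @return Object of class `rigid_transform`: `rotation` (3 x 3),
#'   `translation` (length 3), `fre` (mm).
#' @export
rigid_from_fiducials <- function(model_points, image_points) {
  p <- as.matrix(model_points)
  q <- as.matrix(image_points)
  if (!all(dim(p) == dim(q)) || ncol(p) != 3L)
    .stopf("fiducial sets must be paired n x 3 matrices")
  if (nrow(p) < 3L) .stopf("at least 3 fiducial pairs are required")
  pc <- colMeans(p); qc <- colMeans(q)
  pp <- sweep(p, 2, pc); qq <- sweep(q, 2, qc)
  if (svd(pp)$d[2] < 1e-9 * max(1, svd(pp)$d[1]))
    .stopf("fiducials are collinear; rigid fit is degenerate")
  h <- crossprod(pp, qq)            # 3x3 cross-covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- qc - as.vector(rot %*% pc)
  resid <- sweep(p %*% t(rot), 2, tr, "+") - q
  structure(list(rotation = rot, translation = tr,
                 fre = sqrt(mean(rowSums(resid^2)))),
            class = "rigid_transform")
}

#' Apply, compose and invert rigid transforms
#'
#' @param transform A `rigid_transform`.
#' @param points n x 3 matrix of mm coordinates.
#' @return `transform_points`: the mapped n x 3 matrix.
#' @export
transform_points <- function(transform, points) {
  points <- rbind(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' @rdname transform_points
#' @export
invert_transform <- function(transform) {
  structure(list(rotation = t(transform$rotation),
                 translation = as.vector(-t(transform$rotation) %*%
                                           transform$translation),
                 fre = transform$fre),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (model -> image)\n")
  cat("  rotation:\n")
  print(round(x$rotation, 6))
  cat(sprintf("  translation: %s mm\n",
              paste(round(x$translation, 3), collapse = ", ")))
  if (!is.null(x$fre)) cat(sprintf("  FRE: %.4f mm\n", x$fre))
  invisible(x)
}

#' Map an airway tree into image voxel coordinates
#'
#' Applies a rigid transform to every branch endpoint and expresses the
#' result in continuous (1-based) voxel coordinates of the target image.
#' Adds columns `vx0..vz1`, midpoint voxel coordinates `mx`, `my`, `mz`
#' and an `in_grid` flag (out-of-grid branches are flagged, not dropped).
#'
#' @param tree An `airway_tree` in model mm coordinates.
#' @param transform A `rigid_transform` (model -> image mm).
#' @param image A `volumetric_image` supplying grid, spacing and origin.
#' @return The tree with voxel-coordinate columns;
#'   `metadata$coordinate_frame` becomes `"voxel"`.
#' @export
apply_transform <- function(tree, transform, image) {
  b <- tree$branches
  p0 <- transform_points(transform, as.matrix(b[, c("x0", "y0", "z0")]))
  p1 <- transform_points(transform, as.matrix(b[, c("x1", "y1", "z1")]))
  v0 <- world_to_voxel(image, p0)
  v1 <- world_to_voxel(image, p1)
  mid <- (v0 + v1) / 2
  dm <- dim(image$data)
  b$vx0 <- v0[, 1]; b$vy0 <- v0[, 2]; b$vz0 <- v0[, 3]
  b$vx1 <- v1[, 1]; b$vy1 <- v1[, 2]; b$vz1 <- v1[, 3]
  b$mx <- mid[, 1]; b$my <- mid[, 2]; b$mz <- mid[, 3]
  b$in_grid <- mid[, 1] >= 1 & mid[, 1] <= dm[1] &
    mid[, 2] >= 1 & mid[, 2] <= dm[2] &
    mid[, 3] >= 1 & mid[, 3] <= dm[3]
  tree$branches <- b
  tree$metadata$coordinate_frame <- "voxel"
  tree$metadata$transform <- transform
  tree
}

#' Slab assignment and anterior-posterior slab resampling
#'
#' `slab_index` assigns a z coordinate (mm) to a half-open 15 mm slab
#' `[z0 + (i-1) T, z0 + i T)`, returning the 1-based slab index.
#' `resample_to_slabs` collapses a finer-z 3D mask into `n_slabs`
#' contiguous slabs by taking the occupancy union of the z-planes falling
#' in each slab (the mask's z spacing times its extent must tile the slab
#' range exactly).
#'
#' @param z_mm Numeric z coordinates, mm.
#' @param slab_thickness Slab thickness, mm (default 15).
#' @param z0 z of the first slab's lower edge, mm.
#' @return `slab_index`: integer slab indices (1-based).
#' @export
slab_index <- function(z_mm, slab_thickness = 15, z0 = 0) {
  if (slab_thickness <= 0) .stopf("'slab_thickness' must be positive")
  as.integer(floor((z_mm - z0) / slab_thickness)) + 1L
}

#' @rdname slab_index
#' @param mask Logical 3D array with z the third axis.
#' @param z_spacing Spacing of the mask's z-planes, mm.
#' @param n_slabs Required number of output slabs; an inconsistent slab
#'   count is an error.
#' @return `resample_to_slabs`: logical array with `n_slabs` z-planes.
#' @export
resample_to_slabs <- function(mask, z_spacing, slab_thickness = 15,
                              n_slabs, z0 = 0) {
  dm <- dim(mask)
  z_planes <- z0 + (seq_len(dm[3]) - 1) * z_spacing
  idx <- slab_index(z_planes, slab_thickness, z0)
  if (max(idx) != n_slabs)
    .stopf("mask z-extent implies %d slabs but %d were requested",
           max(idx), n_slabs)
  out <- array(FALSE, c(dm[1], dm[2], n_slabs))
  for (s in seq_len(n_slabs)) {
    planes <- which(idx == s)
    out[, , s] <- apply(mask[, , planes, drop = FALSE], c(1, 2), any)
  }
  out
}

#' Dice similarity coefficient of two masks
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`. Two empty masks give 0 with
#' attribute `both_empty = TRUE`.
#'
#' @param mask_a,mask_b Logical arrays on the same grid.
#' @return DSC in `[0, 1]`.
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    .stopf("masks must share the same grid")
  s <- sum(mask_a) + sum(mask_b)
  if (s == 0) return(structure(0, both_empty = TRUE))
  2 * sum(mask_a & mask_b) / s
}
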