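#' Volumetric image container
#'
#' A thin wrapper around a 3D numeric array with voxel spacing, world
#' origin and a modality label. Voxel indices are R-style 1-based; the
#' world coordinate of voxel `(i, j, k)` is `origin + (index - 1) *
#' spacing` (mm). The default grid, 128 x 128 x 14 voxels at
#' 3.13 x 3.13 x 15 mm, matches a coronal thoracic acquisition with 15 mm
#' slices.
#'
#' @param data 3D numeric array.
#' @param spacing Voxel spacing per axis, mm.
#' @param origin World coordinate of voxel (1,1,1), mm.
#' @param modality `"proton"` or `"ventilation"` (free-form allowed).
#' @return Object of class `volumetric_image`.
#' @export
volumetric_image <- function(data, spacing = c(3.13, 3.13, 15),
                             origin = c(0, 0, 0), modality = "ventilation") {
  if (length(dim(data)) != 3L) .stopf("'data' must be a 3D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    .stopf("'spacing' must be three positive numbers (mm)")
  if (length(origin) != 3L) .stopf("'origin' must be length 3")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), modality = modality),
            class = "volumetric_image")
}

#' @export
print.volumetric_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("%s image: %d x %d x %d voxels at %.2f x %.2f x %.2f mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Convert between voxel indices and world coordinates
#'
#' @param image A `volumetric_image` (or anything with `spacing`/`origin`).
#' @param voxels,world Matrix (n x 3) of 1-based voxel indices
#'   (possibly fractional) or world mm coordinates.
#' @return The converted n x 3 matrix.
#' @export
voxel_to_world <- function(image, voxels) {
  voxels <- rbind(voxels)
  sweep(sweep(voxels - 1, 2, image$spacing, "*"), 2, image$origin, "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(image, world) {
  world <- rbind(world)
  sweep(sweep(world, 2, image$origin, "-"), 2, image$spacing, "/") + 1
}

#' Read / write volumetric images as NIfTI
#'
#' Thin wrappers over \pkg{RNifti}. `write_nifti_image` stores the voxel
#' spacing in the NIfTI header; `read_nifti_image` recovers spacing and
#' returns a [volumetric_image()].
#'
#' @param image A `volumetric_image`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param modality Modality label to attach on read.
#' @return `read_nifti_image` returns a `volumetric_image`;
#'   `write_nifti_image` returns `path` invisibly.
#' @export
write_nifti_image <- function(image, path) {
  img <- RNifti::asNifti(image$data, reference = NULL)
  RNifti::pixdim(img) <- image$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_image
#' @export
read_nifti_image <- function(path, modality = "ventilation") {
  img <- RNifti::readNifti(path)
  volumetric_image(array(as.numeric(img), dim = dim(img)),
                   spacing = RNifti::pixdim(img)[1:3],
                   modality = modality)
}

# ---- binary-mask utilities ----------------------------------------------

# The 26-neighbourhood offsets (one representative per +/- pair -> 13).
.half_offsets_26 <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), ]
  keep <- off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
    (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0)
  off[keep, , drop = FALSE]
}

#' Label 26-connected components of a 3D mask
#'
#' Connected-component labelling on a logical 3D array using the full
#' 26-neighbourhood, built on \pkg{igraph}.
#'
#' @param mask Logical 3D array.
#' @return Integer array of the same dimension: 0 outside the mask,
#'   component labels 1..n inside (labels ordered by first voxel).
#' @export
label_components <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask)
  out <- array(0L, dm)
  if (!length(idx)) return(out)
  coord <- arrayInd(idx, dm)
  inmask <- array(0L, dm)
  inmask[idx] <- seq_along(idx)
  edges <- list()
  offsets <- .half_offsets_26()
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    nb <- sweep(coord, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    nbl <- inmask[nb[ok, , drop = FALSE]]
    src <- seq_along(idx)[ok]
    hit <- nbl > 0L
    if (any(hit)) edges[[length(edges) + 1L]] <- cbind(src[hit], nbl[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  # relabel components in order of first appearance
  first <- match(unique(comp), comp)
  relabel <- integer(max(comp))
  relabel[comp[sort(first)]] <- seq_along(first)
  out[idx] <- relabel[comp]
  out
}

#' Binary dilation of a 3D mask (26-connected)
#'
#' One iteration extends the mask to every voxel whose Chebyshev distance
#' to it is 1; `iterations = n` gives a Chebyshev-radius-n dilation.
#'
#' @param mask Logical 3D array.
#' @param iterations Number of dilation passes (>= 0).
#' @return Logical array of the same dimension.
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  if (iterations < 0) .stopf("'iterations' must be >= 0")
  m <- mask
  for (it in seq_len(iterations)) {
    # separable Chebyshev max-filter: dilating along each axis in turn
    # yields the full 26-connected (radius-1 Chebyshev) dilation
    for (d in 1:3)
      m <- m | .shift_array(m, d, 1L) | .shift_array(m, d, -1L)
  }
  m
}

# Shift a 3D logical array by `by` voxels along axis `d`, padding FALSE.
.shift_array <- function(x, d, by) {
  dm <- dim(x)
  out <- array(FALSE, dm)
  src <- lapply(dm, seq_len)
  dst <- src
  n <- dm[d]
  if (by > 0) { dst[[d]] <- (1 + by):n; src[[d]] <- 1:(n - by) }
  else if (by < 0) { dst[[d]] <- 1:(n + by); src[[d]] <- (1 - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# Grayscale (label-propagating) dilation: each background voxel takes the
# maximum label among its 26-neighbours. Used to attribute dilated defect
# voxels back to a source region (ties resolved toward the larger label).
.dilate_labels <- function(labels, iterations = 1L) {
  m <- labels
  for (it in seq_len(iterations)) {
    for (d in 1:3)
      m <- pmax(m, .shift_int(m, d, 1L), .shift_int(m, d, -1L))
  }
  m
}

.shift_int <- function(x, d, by) {
  dm <- dim(x)
  out <- array(0L, dm)
  src <- lapply(dm, seq_len)
  dst <- src
  n <- dm[d]
  if (by > 0) { dst[[d]] <- (1 + by):n; src[[d]] <- 1:(n - by) }
  else { dst[[d]] <- 1:(n + by); src[[d]] <- (1 - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}
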