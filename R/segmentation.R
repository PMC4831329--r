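#' Seeded region-growing segmentation of the thoracic cavity
#'
#' Grows a 26-connected region from one or more seed voxels of a
#' proton-like anatomical image. A voxel is eligible when its intensity
#' lies within the seed-region intensity range widened by
#' `tolerance * (global intensity range)`; the returned mask is the union
#' of eligible connected components containing a seed.
#'
#' @param proton A `volumetric_image` (anatomical/proton contrast).
#' @param seeds Matrix (n x 3) of 1-based voxel indices, or a length-3
#'   vector for one seed.
#' @param tolerance Fraction of the global intensity range, in (0, 1].
#'   Tolerance 0 is accepted and grows only through exactly seed-valued
#'   voxels.
#' @return Logical 3D mask with attribute `volume_ml` (cavity volume).
#'   An empty growth triggers a warning and returns an all-`FALSE` mask.
#' @export
segment_thoracic_cavity <- function(proton, seeds, tolerance = 0.15) {
  if (tolerance < 0 || tolerance > 1)
    .stopf("'tolerance' must lie in [0, 1]")
  img <- proton$data
  dm <- dim(img)
  seeds <- rbind(seeds)
  if (ncol(seeds) != 3L) .stopf("'seeds' must be n x 3 voxel indices")
  if (any(seeds < 1) || any(sweep(seeds, 2, dm, ">")))
    .stopf("seed voxel outside the image grid")
  seed_idx <- seeds[, 1] + dm[1] * (seeds[, 2] - 1) +
    dm[1] * dm[2] * (seeds[, 3] - 1)
  vals <- img[seed_idx]
  band <- tolerance * (max(img) - min(img))
  eligible <- img >= (min(vals) - band) & img <= (max(vals) + band)
  lab <- label_components(eligible)
  keep <- unique(lab[seed_idx])
  keep <- keep[keep > 0L]
  mask <- array(lab %in% keep, dm)
  if (!any(mask)) warning("region growing produced an empty mask")
  attr(mask, "volume_ml") <- sum(mask) * prod(proton$spacing) / 1000
  mask
}

# One Lloyd stage with k-means++ seeding: up to five seedings, keeping the
# solution with the smallest total within-cluster sum of squares. Consumes
# RNG; callers fix the seed.
.lloyd_1d <- function(x, k) {
  best <- NULL
  for (attempt in 1:5) {
    centers <- .kmeanspp_centers(x, k)
    res <- tryCatch(
      suppressWarnings(
        stats::kmeans(x, centers = matrix(centers, ncol = 1),
                      iter.max = 100L, algorithm = "Lloyd")),
      error = function(e) NULL)   # empty cluster -> reseed and retry
    if (!is.null(res) &&
        (is.null(best) || res$tot.withinss < best$tot.withinss))
      best <- res
  }
  if (is.null(best)) .stopf("k-means failed to converge on this image")
  list(cluster = best$cluster, centers = as.numeric(best$centers))
}

# Deterministic k-means++ style seeding on a 1D feature (distinct values).
.kmeanspp_centers <- function(x, k) {
  ux <- unique(x)
  centers <- numeric(k)
  centers[1] <- ux[sample.int(length(ux), 1L)]
  d2 <- (ux - centers[1])^2
  for (i in 2:k) {
    p <- d2 / sum(d2)
    centers[i] <- ux[sample.int(length(ux), 1L, prob = p)]
    d2 <- pmin(d2, (ux - centers[i])^2)
  }
  centers
}

#' Hierarchical K-means cluster map of a ventilation image
#'
#' Classifies cavity-voxel intensities into `k` clusters ranging from
#' signal void (cluster 1, the ventilation-defect class) to hyperintense
#' (cluster `k`). Without a noise reference this is single-stage Lloyd
#' k-means on the cavity intensities. With a `noise_reference` the
#' clustering is hierarchical, as in the validated segmentation this
#' emulates: a first 2-means split (anchored by the reference) separates
#' the signal-void class from ventilated signal, then the ventilated
#' voxels are subdivided into `k - 1` classes. Every stage runs Lloyd's
#' algorithm with k-means++ style seeding (100 iteration cap, best of up
#' to five seedings). Clusters are relabelled by ascending mean intensity,
#' which makes the map invariant to initialization order. The two-stage
#' split keeps the void/ventilated boundary from drifting into the
#' ventilated distribution when the void class is large, a failure mode
#' of plain 5-cluster k-means on these intensity mixtures.
#'
#' When `noise_reference` intensities are supplied (typically a sample of
#' background voxels outside the cavity), they participate in the
#' clustering but not in the returned map. This anchors the signal-void
#' class at the image noise floor -- the behaviour of the hierarchical
#' variant of the published segmentation -- so that a fully ventilated
#' lung yields a near-empty cluster 1 instead of the lowest quantile of
#' the ventilated distribution.
#'
#' @param ventilation A `volumetric_image`.
#' @param cavity Logical thoracic-cavity mask (same grid).
#' @param k Number of clusters (default 5).
#' @param seed RNG seed; the map is deterministic given the seed.
#' @param noise_reference Optional numeric vector of background
#'   intensities used to anchor cluster 1 (see Details).
#' @return Integer array of class `cluster_map`: 0 outside the cavity,
#'   labels 1..k inside. Attributes: `centers` (ascending cluster means),
#'   `spacing`, `cavity`.
#' @export
cluster_ventilation <- function(ventilation, cavity, k = 5L, seed = 1L,
                                noise_reference = NULL) {
  if (k < 2) .stopf("'k' must be >= 2")
  dm <- dim(ventilation$data)
  if (!identical(dim(cavity), dm)) .stopf("cavity mask grid mismatch")
  if (!any(cavity)) .stopf("cavity mask is empty")
  x <- ventilation$data[cavity]
  n_cav <- length(x)
  if (!is.null(noise_reference)) x <- c(x, as.numeric(noise_reference))
  if (length(unique(x)) < k)
    .stopf("fewer distinct intensities (%d) than clusters (%d)",
           length(unique(x)), k)
  labels <- with_seed(seed, {
    if (is.null(noise_reference)) {
      # single-stage k-means on the cavity intensities
      fit <- .lloyd_1d(x, k)
      order(order(fit$centers))[fit$cluster]
    } else {
      # stage 1: signal void vs ventilated, anchored by the reference
      top <- .lloyd_1d(x, 2L)
      void <- top$cluster == which.min(top$centers)
      lab <- integer(length(x))
      lab[void] <- 1L
      # stage 2: subdivide the ventilated intensities into k - 1 classes
      if (k == 2L) {
        lab[!void] <- 2L
      } else {
        xv <- x[!void]
        if (length(unique(xv)) < k - 1L)
          .stopf("fewer distinct ventilated intensities than clusters")
        sub <- .lloyd_1d(xv, k - 1L)
        lab[!void] <- 1L + order(order(sub$centers))[sub$cluster]
      }
      lab
    }
  })
  map <- array(0L, dm)
  map[cavity] <- labels[seq_len(n_cav)]
  centers <- vapply(seq_len(k), function(i) mean(x[labels == i]),
                    numeric(1))
  structure(map, class = "cluster_map",
            centers = centers,
            spacing = ventilation$spacing,
            cavity = cavity)
}

#' Ventilation defect percent (VDP)
#'
#' The volume of cluster-1 (signal void) voxels as a percentage of the
#' thoracic-cavity volume.
#'
#' @param clusters A `cluster_map`.
#' @param cavity Logical cavity mask; defaults to the mask stored in the
#'   cluster map.
#' @return VDP in percent, within `[0, 100]`.
#' @export
compute_vdp <- function(clusters, cavity = attr(clusters, "cavity")) {
  if (is.null(cavity)) .stopf("no cavity mask available")
  n_cav <- sum(cavity)
  if (n_cav == 0) .stopf("cavity mask is empty")
  100 * sum(clusters == 1L & cavity) / n_cav
}

#' Extract ventilation-defect regions
#'
#' 26-connected components of the cluster-1 voxels, filtered to regions
#' whose bounding box strictly exceeds `min_inplane_extent` voxels in the
#' x or y direction (at 3.13 mm in-plane spacing the default threshold of
#' 10 voxels corresponds to about 3 cm), sorted by descending volume.
#'
#' @param clusters A `cluster_map`.
#' @param min_inplane_extent Strict lower bound on the larger in-plane
#'   bounding-box extent, voxels.
#' @return List of `defect_region` objects: `id`, `voxels` (n x 3 index
#'   matrix), `bbox_extent` (voxels per axis), `volume_ml`, `centroid_mm`.
#' @export
extract_defect_regions <- function(clusters, min_inplane_extent = 10L) {
  spacing <- attr(clusters, "spacing")
  if (is.null(spacing)) spacing <- c(3.13, 3.13, 15)
  mask <- array(unclass(clusters) == 1L, dim(clusters))
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  regions <- list()
  for (i in seq_len(n)) {
    vox <- arrayInd(which(lab == i), dim(lab))
    ext <- apply(vox, 2, function(v) diff(range(v)) + 1L)
    if (!(ext[1] > min_inplane_extent || ext[2] > min_inplane_extent)) next
    centroid <- (colMeans(vox) - 1) * spacing
    regions[[length(regions) + 1L]] <- structure(list(
      id = i, voxels = vox, bbox_extent = ext,
      volume_ml = nrow(vox) * prod(spacing) / 1000,
      centroid_mm = centroid), class = "defect_region")
  }
  if (!length(regions)) return(list())
  regions[order(vapply(regions, function(r) r$volume_ml, numeric(1)),
                decreasing = TRUE)]
}
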