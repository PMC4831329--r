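#' Specification of a synthetic thoracic phantom
#'
#' Collects the parameters of one phantom subject-condition: grid geometry,
#' target ventilation-defect fraction, blob count, noise level and seed.
#' The defaults emulate a coronal thoracic acquisition: 128 x 128 x 14
#' voxels at 3.13 x 3.13 x 15 mm, a two-ellipsoid lung cavity, a smooth
#' ventilated signal with Gaussian noise at the target SNR, and compact
#' signal-void defect blobs grown around airway-tree locations.
#'
#' @param grid Image dimensions (x, y, z voxels).
#' @param spacing Voxel spacing, mm.
#' @param defect_fraction Target defect volume as percent of cavity volume,
#'   in `[0, 100]`.
#' @param n_blobs Number of defect blobs; `NULL` scales with the target
#'   fraction (one blob per ~5 percentage points, 1..6).
#' @param snr Ventilated-signal mean over noise standard deviation (> 0).
#' @param seed Integer seed; the phantom is bit-identical given the seed.
#' @param fiducial_noise_mm Isotropic noise added to the image-frame
#'   fiducials, mm.
#' @param defect_seed_generation Airway generation whose branch midpoints
#'   seed defect blobs when a tree is supplied (segmental-level airways by
#'   default, so defects are subtree-aligned).
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(128L, 128L, 14L),
                         spacing = c(3.13, 3.13, 15),
                         defect_fraction = 10,
                         n_blobs = NULL,
                         snr = 20,
                         seed = 1L,
                         fiducial_noise_mm = 1,
                         defect_seed_generation = 9L) {
  if (defect_fraction < 0 || defect_fraction > 100)
    .stopf("'defect_fraction' must lie in [0, 100]")
  if (snr <= 0) .stopf("'snr' must be positive")
  if (is.null(n_blobs))
    n_blobs <- max(1L, min(6L, as.integer(ceiling(defect_fraction / 5))))
  structure(list(grid = as.integer(grid), spacing = as.numeric(spacing),
                 defect_fraction = defect_fraction,
                 n_blobs = as.integer(n_blobs), snr = snr,
                 seed = as.integer(seed),
                 fiducial_noise_mm = fiducial_noise_mm,
                 defect_seed_generation = as.integer(defect_seed_generation)),
            class = "phantom_spec")
}

# ellipsoid membership of mm points (n x 3)
.in_ellipsoid <- function(p, center, semi) {
  rowSums(sweep(sweep(p, 2, center), 2, semi, "/")^2) <= 1
}

# membership of mm points in a two-lung cavity
.in_cavity <- function(p, lungs) {
  .in_ellipsoid(p, lungs$right$center, lungs$right$semi) |
    .in_ellipsoid(p, lungs$left$center, lungs$left$semi)
}

# world coordinates (mm) of every voxel centre of an image grid: n x 3
.grid_world <- function(grid, spacing, origin = c(0, 0, 0)) {
  cbind(rep(origin[1] + (seq_len(grid[1]) - 1) * spacing[1],
            times = grid[2] * grid[3]),
        rep(rep(origin[2] + (seq_len(grid[2]) - 1) * spacing[2],
                each = grid[1]), times = grid[3]),
        rep(origin[3] + (seq_len(grid[3]) - 1) * spacing[3],
            each = grid[1] * grid[2]))
}

#' Voxelize the model lung cavity through a transform
#'
#' Maps every voxel centre of `image` back through `transform` into the
#' model frame and tests membership in the two-ellipsoid lung cavity.
#' With `z_subdivide > 1` the z axis is sampled that many times more
#' finely (for anterior-posterior slab resampling via
#' [resample_to_slabs()]).
#'
#' @param lungs Lung geometry as stored in a phantom (`$right`/`$left`,
#'   each with `center` and `semi`, model-frame mm).
#' @param transform `rigid_transform`, model -> image mm.
#' @param image Target `volumetric_image` (grid template).
#' @param z_subdivide Integer z oversampling factor.
#' @return Logical array, `dim(image$data)` (or finer in z).
#' @export
model_cavity_mask <- function(lungs, transform, image, z_subdivide = 1L) {
  dm <- dim(image$data)
  sp <- image$spacing
  grid <- c(dm[1], dm[2], dm[3] * z_subdivide)
  spacing <- c(sp[1], sp[2], sp[3] / z_subdivide)
  w <- .grid_world(grid, spacing, image$origin)
  p <- transform_points(invert_transform(transform), w)
  array(.in_cavity(p, lungs), grid)
}

#' Generate a synthetic phantom subject
#'
#' Builds one phantom: a proton-like anatomical image (bright body shell,
#' darker air-filled cavity), a ventilation image (smooth ventilated
#' signal, signal-void defect blobs, Gaussian noise at the target SNR),
#' the ground-truth cavity and defect masks, paired fiducial landmarks in
#' the model and image frames, and the true model-to-image rigid
#' transform. When an `airway_tree` is supplied, defect blobs are grown
#' around the midpoints of randomly chosen branches of
#' `spec$defect_seed_generation`, so defects are spatially aligned with
#' subtrees (segmental/subsegmental in character); otherwise blob seeds
#' are random cavity voxels. Blobs are the `N` cavity voxels nearest (mm)
#' to the seeds, `N = round(fraction * cavity voxels)`, so the achieved
#' defect fraction matches the target to well within 0.5 percentage
#' points.
#'
#' @param spec A [phantom_spec()].
#' @param tree Optional `airway_tree` in model coordinates.
#' @return List of class `lung_phantom`: `proton`, `ventilation`
#'   (`volumetric_image`s), `cavity`, `defects` (logical ground-truth
#'   masks), `lungs`, `transform` (true model -> image), `fiducials`
#'   (`$model`, `$image`), `cavity_seeds` (voxel indices for region
#'   growing), `vdp_true` (achieved fraction, %), `spec`.
#' @export
generate_phantom <- function(spec, tree = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid; sp <- spec$spacing
  with_seed(spec$seed, {
    # lung geometry in the model frame (matches the default tree bounding
    # box 300 x 250 x 210 mm), with mild per-subject variation
    jit <- function(x, f = 0.05) x * stats::runif(length(x), 1 - f, 1 + f)
    lungs <- list(
      right = list(center = c(80, 125, 105) + stats::runif(3, -5, 5),
                   semi = jit(c(70, 110, 95))),
      left = list(center = c(220, 125, 105) + stats::runif(3, -5, 5),
                  semi = jit(c(70, 110, 95))))

    # true rigid transform: small in-plane rotation + centring translation
    theta <- stats::runif(1, -4, 4) * pi / 180
    rot <- rbind(c(cos(theta), -sin(theta), 0),
                 c(sin(theta), cos(theta), 0),
                 c(0, 0, 1))
    img_center <- (grid - 1) * sp / 2
    model_center <- c(150, 125, 105)
    tr <- img_center - as.vector(rot %*% model_center) +
      c(stats::runif(2, -5, 5), stats::runif(1, -3, 3))
    transform <- structure(list(rotation = rot, translation = tr, fre = 0),
                           class = "rigid_transform")

    w <- .grid_world(grid, sp)
    p_model <- transform_points(invert_transform(transform), w)
    cavity <- array(.in_cavity(p_model, lungs), grid)
    n_cav <- sum(cavity)

    # proton image: background air 0, body shell 200, cavity 60
    # z semi-axis exceeds the grid so the shell encloses the lungs on
    # every slice (no cavity-background contact for region growing)
    body <- .in_ellipsoid(w, img_center, c(185, 185, 130))
    proton_arr <- array(0, grid)
    proton_arr[body] <- 200
    proton_arr[cavity] <- 60
    proton_arr <- proton_arr + stats::rnorm(length(proton_arr), 0, 200 / spec$snr / 2)

    # defect mask: nearest-N cavity voxels around subtree-aligned seeds
    defects <- array(FALSE, grid)
    n_target <- round(spec$defect_fraction / 100 * n_cav)
    if (n_target > 0) {
      cav_idx <- which(cavity)
      cav_mm <- (arrayInd(cav_idx, grid) - 1) *
        matrix(sp, length(cav_idx), 3, byrow = TRUE)
      seeds_mm <- NULL
      if (!is.null(tree)) {
        img <- volumetric_image(array(0, grid), sp)
        tv <- apply_transform(tree, transform, img)
        b <- tv$branches
        cand <- which(b$generation == spec$defect_seed_generation)
        if (length(cand)) {
          mid_vox <- round(cbind(b$mx[cand], b$my[cand], b$mz[cand]))
          inside <- mid_vox[, 1] >= 1 & mid_vox[, 1] <= grid[1] &
            mid_vox[, 2] >= 1 & mid_vox[, 2] <= grid[2] &
            mid_vox[, 3] >= 1 & mid_vox[, 3] <= grid[3]
          inside[inside] <- cavity[mid_vox[inside, , drop = FALSE]]
          cand <- cand[inside]
          if (length(cand)) {
            pick <- cand[sample.int(length(cand),
                                    min(spec$n_blobs, length(cand)))]
            seeds_mm <- (cbind(b$mx[pick], b$my[pick], b$mz[pick]) - 1) *
              matrix(sp, length(pick), 3, byrow = TRUE)
          }
        }
      }
      if (is.null(seeds_mm)) {
        pick <- sample.int(n_cav, min(spec$n_blobs, n_cav))
        seeds_mm <- cav_mm[pick, , drop = FALSE]
      }
      d2 <- rep(Inf, n_cav)
      for (s in seq_len(nrow(seeds_mm)))
        d2 <- pmin(d2, rowSums(sweep(cav_mm, 2, seeds_mm[s, ])^2))
      take <- order(d2)[seq_len(n_target)]
      defects[cav_idx[take]] <- TRUE
    }

    # ventilation image: smooth ventilated field, void defects, noise
    sigma <- 100 / spec$snr
    vent_arr <- array(0, grid)
    vox <- arrayInd(seq_along(vent_arr), grid)
    # mild regional heterogeneity: one in-plane harmonic plus an
    # anterior-posterior gradient, spanning roughly 83-117% of the mean
    field <- 100 * (1 + 0.12 * sin(2 * pi * vox[, 1] / grid[1]) *
                      sin(2 * pi * vox[, 2] / grid[2]) +
                      0.05 * (vox[, 3] - (grid[3] + 1) / 2) /
                        (grid[3] / 2))
    vent_arr[cavity] <- field[cavity]
    vent_arr[defects] <- 0
    vent_arr <- vent_arr + stats::rnorm(length(vent_arr), 0, sigma)

    # fiducials: fixed directions on each lung surface, model frame
    ang <- cbind(theta = rep(c(0, 72, 144, 216, 288) * pi / 180, 2),
                 phi = rep(c(35, -35) * pi / 180, each = 5))
    fid_model <- do.call(rbind, lapply(list(lungs$right, lungs$left),
      function(lg) cbind(
        lg$center[1] + lg$semi[1] * cos(ang[, 2]) * cos(ang[, 1]),
        lg$center[2] + lg$semi[2] * cos(ang[, 2]) * sin(ang[, 1]),
        lg$center[3] + lg$semi[3] * sin(ang[, 2]))))
    fid_image <- transform_points(transform, fid_model) +
      matrix(stats::rnorm(length(fid_model), 0, spec$fiducial_noise_mm),
             ncol = 3)

    seeds_vox <- round(world_to_voxel(
      volumetric_image(array(0, grid), sp),
      transform_points(transform, rbind(lungs$right$center,
                                        lungs$left$center))))

    structure(list(
      proton = volumetric_image(proton_arr, sp, modality = "proton"),
      ventilation = volumetric_image(vent_arr, sp,
                                     modality = "ventilation"),
      cavity = cavity, defects = defects, lungs = lungs,
      transform = transform,
      fiducials = list(model = fid_model, image = fid_image),
      cavity_seeds = seeds_vox,
      vdp_true = 100 * sum(defects) / n_cav,
      spec = spec), class = "lung_phantom")
  })
}

#' @export
print.lung_phantom <- function(x, ...) {
  cat(sprintf(
    "Synthetic phantom: %s grid, cavity %.0f mL, true VDP %.2f%%\n",
    paste(x$spec$grid, collapse = "x"),
    sum(x$cavity) * prod(x$spec$spacing) / 1000, x$vdp_true))
  invisible(x)
}
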