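test_that("mask utilities: components, dilation and dice behave as defined", {
  m <- array(FALSE, c(8, 8, 3))
  m[2:3, 2:3, 1] <- TRUE        # blob A
  m[6:7, 6:7, 2] <- TRUE        # blob B (not 26-adjacent to A)
  m[5, 5, 2] <- TRUE            # diagonal toucher of B -> same component
  lab <- label_components(m)
  expect_equal(max(lab), 2L)
  expect_equal(sum(lab > 0), sum(m))
  expect_equal(lab[5, 5, 2], lab[6, 6, 2])
  expect_false(lab[2, 2, 1] == lab[6, 6, 2])

  d <- dilate_mask(m, 1)
  expect_true(all(d[m]))
  expect_true(d[4, 4, 1])       # Chebyshev-1 neighbour incl. diagonal+z
  expect_false(d[8, 1, 3])
  expect_equal(sum(dilate_mask(m, 0)), sum(m))

  a <- array(FALSE, c(4, 4, 1)); b <- a
  a[1:2, 1, 1] <- TRUE; b[2:3, 1, 1] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, b), 0.5)       # 2*1/(2+2)
  expect_equal(dice_coefficient(a, !a & FALSE), 0)
  empty <- array(FALSE, c(4, 4, 1))
  expect_equal(as.numeric(dice_coefficient(empty, empty)), 0)
  expect_true(attr(dice_coefficient(empty, empty), "both_empty"))
  expect_error(dice_coefficient(a, array(FALSE, c(5, 4, 1))), "grid")
})

test_that("region growing recovers a two-compartment cavity", {
  dm <- c(40, 40, 5)
  img <- array(200, dm)                    # bright body
  truth <- array(FALSE, dm)
  truth[8:32, 8:32, 2:4] <- TRUE           # dark cavity
  img[truth] <- 50
  set.seed(1)
  img <- img + array(rnorm(prod(dm), 0, 4), dm)
  vi <- volumetric_image(img, spacing = c(1, 1, 1), modality = "proton")
  mask <- segment_thoracic_cavity(vi, rbind(c(20, 20, 3)), tolerance = 0.15)
  expect_gte(dice_coefficient(mask, truth), 0.99)
  expect_equal(attr(mask, "volume_ml"), sum(mask) / 1000)
  expect_error(segment_thoracic_cavity(vi, rbind(c(99, 1, 1))), "outside")
})

test_that("region growing degenerate cases", {
  arr <- array(c(1, 5, 5, 5, 5, 5, 5, 5), c(2, 2, 2))
  vi <- volumetric_image(arr, spacing = c(1, 1, 1), modality = "proton")
  m <- segment_thoracic_cavity(vi, rbind(c(1, 1, 1)), tolerance = 0)
  expect_equal(sum(m), 1L)
  expect_true(m[1, 1, 1])
  const <- volumetric_image(array(7, c(3, 3, 2)), spacing = c(1, 1, 1))
  m2 <- segment_thoracic_cavity(const, rbind(c(2, 2, 1)), tolerance = 0.15)
  expect_true(all(m2))
})

test_that("clustering recovers exact and noisy plateaus", {
  ph <- plateau_image(0)
  cl <- cluster_ventilation(ph$image, ph$cavity, k = 5, seed = 3)
  expect_equal(unclass(cl)[ph$cavity], ph$truth[ph$cavity])
  expect_true(all(diff(attr(cl, "centers")) > 0))
  # noise at 10% of the inter-level gap (gap 20 -> sd 2)
  phn <- plateau_image(2, seed = 5)
  cln <- cluster_ventilation(phn$image, phn$cavity, k = 5, seed = 3)
  agree <- mean(unclass(cln)[phn$cavity] == phn$truth[phn$cavity])
  expect_gte(agree, 0.95)
})

test_that("clustering is deterministic and validates inputs", {
  phn <- plateau_image(2, seed = 5)
  c1 <- cluster_ventilation(phn$image, phn$cavity, seed = 11)
  c2 <- cluster_ventilation(phn$image, phn$cavity, seed = 11)
  expect_identical(c1, c2)
  # binary image, k = 2: C1 is the zero class
  arr <- array(rep(c(0, 1), each = 12), c(4, 3, 2))
  vi <- volumetric_image(arr, spacing = c(1, 1, 1))
  cav <- array(TRUE, dim(arr))
  cb <- cluster_ventilation(vi, cav, k = 2, seed = 1)
  expect_true(all(cb[arr == 0] == 1L))
  expect_true(all(cb[arr == 1] == 2L))
  const <- volumetric_image(array(5, c(4, 3, 2)), spacing = c(1, 1, 1))
  expect_error(cluster_ventilation(const, cav, k = 5, seed = 1),
               "distinct intensities")
  expect_error(cluster_ventilation(vi, cav & FALSE, seed = 1), "empty")
})

test_that("VDP is the C1 share of the cavity", {
  dm <- c(20, 20, 3)
  cav <- array(FALSE, dm); cav[3:18, 3:17, ] <- TRUE   # 720-voxel cavity
  stopifnot(sum(cav) == 720)
  cl <- array(0L, dm)
  cl[cav] <- 3L
  idx <- which(cav)[1:72]
  cl[idx] <- 1L
  cl <- structure(cl, class = "cluster_map", cavity = cav,
                  spacing = c(1, 1, 1))
  expect_equal(compute_vdp(cl), 10)
  cl0 <- cl; cl0[idx] <- 2L
  expect_equal(compute_vdp(cl0), 0)
  clall <- cl; clall[cav] <- 1L
  expect_equal(compute_vdp(clall), 100)
  expect_error(compute_vdp(cl, cav & FALSE), "empty")
})

test_that("defect region extraction applies the strict in-plane rule", {
  dm <- c(40, 30, 4)
  cl <- array(0L, dm)
  cav <- array(TRUE, dm)
  cl[cav] <- 5L
  cl[2:13, 5:8, 2] <- 1L     # x-extent 12 > 10 -> kept
  cl[20:24, 20:24, 3] <- 1L  # extents 5, 5 -> dropped
  cl[35, 2, 1] <- 1L         # single voxel -> dropped
  cl <- structure(cl, class = "cluster_map", cavity = cav,
                  spacing = c(3.13, 3.13, 15))
  regs <- extract_defect_regions(cl)
  expect_length(regs, 1L)
  expect_equal(regs[[1]]$bbox_extent[1], 12L)
  expect_equal(nrow(regs[[1]]$voxels), 12 * 4)
  expect_equal(regs[[1]]$volume_ml, 12 * 4 * 3.13 * 3.13 * 15 / 1000)
  # no gain/loss: retained voxels are exactly the C1 voxels of kept blobs
  kept <- array(FALSE, dm); kept[regs[[1]]$voxels] <- TRUE
  expect_equal(which(kept), which(cl == 1L & cav)[
    arrayInd(which(cl == 1L & cav), dm)[, 1] <= 13])
  # empty C1
  cl2 <- structure(array(5L, dm), class = "cluster_map", cavity = cav,
                   spacing = c(3.13, 3.13, 15))
  expect_length(extract_defect_regions(cl2), 0L)
  # boundary case: extent exactly 10 in both axes is excluded (strict >)
  cl3 <- array(0L, dm); cl3[cav] <- 5L
  cl3[5:14, 5:14, 2] <- 1L
  cl3 <- structure(cl3, class = "cluster_map", cavity = cav,
                   spacing = c(3.13, 3.13, 15))
  expect_length(extract_defect_regions(cl3), 0L)
})

test_that("a 10-voxel in-plane span at 3.13 mm is 3 cm to the nearest cm", {
  expect_equal(round(10 * 3.13 / 10), 3)
})
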