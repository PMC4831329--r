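# A toy scene: tree generated in a 60 x 40 x 30 mm box, mapped by the
# identity transform onto a 1 mm isotropic grid of the same size.
toy_scene <- function(gens = 4L, seed = 2L) {
  tr <- generate_tree(symmetric_morphometry(gens), seed = seed,
                      lung_extent = c(60, 40, 30))
  img <- volumetric_image(array(0, c(60, 40, 30)), spacing = c(1, 1, 1))
  idt <- structure(list(rotation = diag(3), translation = c(0, 0, 0),
                        fre = 0), class = "rigid_transform")
  list(tree = apply_transform(tr, idt, img), img = img)
}

# Defect-region stand-in from a logical mask.
regions_from_mask <- function(mask, id = 1L) {
  list(structure(list(id = id, voxels = arrayInd(which(mask), dim(mask)),
                      bbox_extent = c(0L, 0L, 0L), volume_ml = sum(mask),
                      centroid_mm = c(0, 0, 0)), class = "defect_region"))
}

test_that("no defects or absent generations give empty plans", {
  sc <- toy_scene()
  plan <- select_branches_for_defects(sc$tree, list(), dim(sc$img$data), 2L)
  expect_length(plan$branch_ids, 0L)
  mask <- array(TRUE, dim(sc$img$data))
  expect_warning(
    p2 <- select_branches_for_defects(sc$tree, regions_from_mask(mask),
                                      dim(sc$img$data), 99L),
    "absent")
  expect_length(p2$branch_ids, 0L)
})

test_that("selection matches a brute-force point-in-mask oracle", {
  sc <- toy_scene()
  b <- sc$tree$branches
  dm <- dim(sc$img$data)
  # defect: a box covering the spatial extent of the first gen-2 subtree
  sub_ids <- c(b$id[b$generation == 2][1])
  sub_ids <- c(sub_ids, lungsim:::.descendant_ids(sc$tree, sub_ids))
  mids <- round(cbind(b$mx, b$my, b$mz))[match(sub_ids, b$id), , drop = FALSE]
  mask <- array(FALSE, dm)
  lo <- pmax(apply(mids, 2, min) - 1, 1)
  hi <- pmin(apply(mids, 2, max) + 1, dm)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE

  for (g in c(2L, 3L, 4L)) {
    for (margin in c(0L, 2L)) {
      plan <- select_branches_for_defects(sc$tree, regions_from_mask(mask),
                                          dm, g, margin_voxels = margin)
      dil <- if (margin > 0) dilate_mask(mask, margin) else mask
      cand <- which(b$generation == g)
      mid <- round(cbind(b$mx[cand], b$my[cand], b$mz[cand]))
      expected <- b$id[cand][vapply(seq_along(cand), function(i) {
        v <- mid[i, ]
        all(v >= 1) && all(v <= dm) && dil[v[1], v[2], v[3]]
      }, logical(1))]
      expect_setequal(plan$branch_ids, expected)
      expect_true(all(b$generation[match(plan$branch_ids, b$id)] == g))
    }
  }
})

test_that("the margin admits branches just outside the defect", {
  sc <- toy_scene()
  b <- sc$tree$branches
  dm <- dim(sc$img$data)
  target <- b[b$generation == 3, ][1, ]
  mid <- round(c(target$mx, target$my, target$mz))
  # defect one voxel away from the midpoint in x
  mask <- array(FALSE, dm)
  mask[mid[1] - 1, mid[2], mid[3]] <- TRUE
  p0 <- select_branches_for_defects(sc$tree, regions_from_mask(mask), dm,
                                    3L, margin_voxels = 0L)
  p2 <- select_branches_for_defects(sc$tree, regions_from_mask(mask), dm,
                                    3L, margin_voxels = 2L)
  expect_false(target$id %in% p0$branch_ids)
  expect_true(target$id %in% p2$branch_ids)
  # provenance names the defect region
  expect_true(all(p2$provenance$region_id == 1L))
})

test_that("growing a defect never removes branches from the plan", {
  sc <- toy_scene()
  dm <- dim(sc$img$data)
  mask <- array(FALSE, dm)
  mask[10:20, 10:20, 10:15] <- TRUE
  prev <- integer(0)
  for (grow in 0:4) {
    m <- if (grow > 0) dilate_mask(mask, grow) else mask
    plan <- select_branches_for_defects(sc$tree, regions_from_mask(m), dm, 3L)
    expect_true(all(prev %in% plan$branch_ids))
    prev <- plan$branch_ids
  }
})

test_that("empty plans leave the spectrum at baseline; closure perturbs it", {
  sc <- toy_scene()
  dm <- dim(sc$img$data)
  empty <- select_branches_for_defects(sc$tree, list(), dm, 2L)
  sim0 <- simulate_condition(sc$tree, empty)
  expect_equal(sim0$spectrum, sim0$baseline_spectrum)

  # close one gen-2 subtree (partial closure: open pathways remain, as
  # when defects cover part of the lung)
  b <- sc$tree$branches
  first <- b[b$generation == 2, ][1, ]
  mask <- array(FALSE, dm)
  mid <- round(c(first$mx, first$my, first$mz))
  mask[mid[1], mid[2], mid[3]] <- TRUE
  plan <- select_branches_for_defects(sc$tree, regions_from_mask(mask),
                                      dm, 2L)
  expect_length(plan$branch_ids, 1L)
  sim <- simulate_condition(sc$tree, plan)
  expect_gt(sim$metrics$Rrs5, sim$baseline_metrics$Rrs5)
  expect_lt(sim$metrics$Xrs5, sim$baseline_metrics$Xrs5)
})

test_that("R_rs5 and -X_rs5 are non-decreasing in the closure set", {
  # partial closures only: with every pathway closed, the narrowed tubes'
  # inertance dominates and the reactance direction flips, a regime the
  # defect-driven closures never reach
  sc <- toy_scene(5L)
  b <- sc$tree$branches
  gen4 <- b$id[b$generation == 4]     # 8 branches; close up to half
  prev_r <- -Inf; prev_x <- -Inf
  for (k in c(0, 1, 2, 4)) {
    plan <- structure(list(generation = 4L, margin_voxels = 2L,
                           diameter_factor = 0.1,
                           narrow_scope = "at_generation",
                           branch_ids = gen4[seq_len(k)],
                           narrow_ids = gen4[seq_len(k)],
                           provenance = NULL), class = "closure_plan")
    sim <- simulate_condition(sc$tree, plan)
    expect_gte(sim$metrics$Rrs5, prev_r - 1e-12)
    expect_gte(-sim$metrics$Xrs5, prev_x - 1e-12)
    prev_r <- sim$metrics$Rrs5
    prev_x <- -sim$metrics$Xrs5
  }
})

test_that("proximal closure dominates distal closure on nested subtrees", {
  sc <- toy_scene(5L)
  b <- sc$tree$branches
  dm <- dim(sc$img$data)
  # defect covering one whole gen-2 subtree
  sub <- c(b$id[b$generation == 2][1])
  sub <- c(sub, lungsim:::.descendant_ids(sc$tree, sub))
  mids <- round(cbind(b$mx, b$my, b$mz))[match(sub, b$id), , drop = FALSE]
  mask <- array(FALSE, dm)
  mask[mids] <- TRUE
  mask <- dilate_mask(mask, 1)
  prox <- simulate_condition(sc$tree, select_branches_for_defects(
    sc$tree, regions_from_mask(mask), dm, 2L))
  dist <- simulate_condition(sc$tree, select_branches_for_defects(
    sc$tree, regions_from_mask(mask), dm, 4L))
  expect_gte(prox$metrics$Rrs5, dist$metrics$Rrs5 - 1e-12)
})

test_that("10% narrowing blocks distal flow almost completely", {
  # subtree admittance at 5 Hz after narrowing its root branch to 10%
  sub <- make_tree(parent_id = c(NA, 1, 1),
                   diameter_mm = c(4, 2.5, 3), length_mm = c(20, 10, 12))
  el <- elastance_model(10, 2)
  y0 <- abs(1 / input_impedance(sub, 5, elastance = el))
  y1 <- abs(1 / input_impedance(narrow_branches(sub, 1L, 0.1), 5,
                                elastance = el))
  expect_lt(y1 / y0, 0.01)
})

test_that("at_and_distal scope narrows the whole subtree", {
  sc <- toy_scene()
  dm <- dim(sc$img$data)
  mask <- array(TRUE, dm)
  plan <- select_branches_for_defects(sc$tree, regions_from_mask(mask), dm,
                                      2L, narrow_scope = "at_and_distal")
  b <- sc$tree$branches
  expect_setequal(plan$narrow_ids, b$id[b$generation >= 2])
  expect_setequal(plan$branch_ids, b$id[b$generation == 2])
})
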