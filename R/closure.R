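#' Select airways of a target generation inside ventilation defects
#'
#' Operationalizes "airways within ventilation defects and within two
#' voxels of their boundary": a branch is selected when its generation
#' equals `generation` and its midpoint voxel falls inside the union of
#' the defect regions dilated by `margin_voxels` (26-connected Chebyshev
#' dilation). The plan records which defect region justified each branch
#' (ties toward the larger region id).
#'
#' @param tree An `airway_tree` already mapped to voxel coordinates with
#'   [apply_transform()].
#' @param defects List of `defect_region` objects (already filtered by the
#'   in-plane extent rule, see [extract_defect_regions()]).
#' @param grid_dim Dimension of the defect map grid (x, y, z voxels).
#' @param generation Target generation (9 and 14 are the conventional
#'   proximal/distal choices).
#' @param margin_voxels Dilation margin in voxels (default 2).
#' @param diameter_factor Narrowing factor recorded in the plan
#'   (default 0.1).
#' @param narrow_scope `"at_generation"` narrows the selected branches
#'   themselves (their Poiseuille resistance rises ~1e4, functionally
#'   closing the distal subtree); `"at_and_distal"` additionally narrows
#'   every descendant branch.
#' @return Object of class `closure_plan`: `generation`, `margin_voxels`,
#'   `diameter_factor`, `narrow_scope`, `branch_ids` (selected
#'   generation-level branches), `narrow_ids` (branches actually narrowed
#'   under the scope), `provenance` (data frame branch_id / region_id).
#'   If the generation is absent from the tree an empty plan is returned
#'   with a warning.
#' @export
select_branches_for_defects <- function(tree, defects, grid_dim,
                                        generation, margin_voxels = 2L,
                                        diameter_factor = 0.1,
                                        narrow_scope = c("at_generation",
                                                         "at_and_distal")) {
  narrow_scope <- match.arg(narrow_scope)
  b <- tree$branches
  if (is.null(b$mx))
    .stopf("tree has no voxel coordinates; run apply_transform() first")
  empty_plan <- function() structure(list(
    generation = generation, margin_voxels = margin_voxels,
    diameter_factor = diameter_factor, narrow_scope = narrow_scope,
    branch_ids = integer(0), narrow_ids = integer(0),
    provenance = data.frame(branch_id = integer(0),
                            region_id = integer(0))),
    class = "closure_plan")
  if (!any(b$generation == generation)) {
    warning(sprintf("generation %d absent from tree; empty plan",
                    generation))
    return(empty_plan())
  }
  if (!length(defects)) return(empty_plan())

  labels <- array(0L, grid_dim)
  for (r in defects) labels[r$voxels] <- as.integer(r$id)
  if (margin_voxels > 0) labels <- .dilate_labels(labels, margin_voxels)

  cand <- which(b$generation == generation)
  mid <- round(cbind(b$mx[cand], b$my[cand], b$mz[cand]))
  ok <- mid[, 1] >= 1 & mid[, 1] <= grid_dim[1] &
    mid[, 2] >= 1 & mid[, 2] <= grid_dim[2] &
    mid[, 3] >= 1 & mid[, 3] <= grid_dim[3]
  region <- integer(length(cand))
  region[ok] <- labels[mid[ok, , drop = FALSE]]
  sel <- region > 0L
  ids <- b$id[cand[sel]]
  narrow_ids <- ids
  if (narrow_scope == "at_and_distal" && length(ids))
    narrow_ids <- c(ids, .descendant_ids(tree, ids))
  structure(list(
    generation = generation, margin_voxels = margin_voxels,
    diameter_factor = diameter_factor, narrow_scope = narrow_scope,
    branch_ids = ids, narrow_ids = narrow_ids,
    provenance = data.frame(branch_id = ids, region_id = region[sel])),
    class = "closure_plan")
}

#' @export
print.closure_plan <- function(x, ...) {
  cat(sprintf(
    "Closure plan: generation %d, margin %d voxels, factor %.2f (%s)\n",
    x$generation, x$margin_voxels, x$diameter_factor, x$narrow_scope))
  cat(sprintf("  %d branch(es) selected from %d defect region(s)\n",
              length(x$branch_ids),
              length(unique(x$provenance$region_id))))
  invisible(x)
}

#' Simulate the impedance of a defect-constrained closure condition
#'
#' Narrows the branches of a [closure plan][select_branches_for_defects]
#' by the plan's diameter factor and sweeps respiratory impedance over the
#' frequency grid; the unperturbed tree's spectrum is reported alongside
#' as the baseline.
#'
#' @param tree An `airway_tree` (model or voxel coordinates; geometry
#'   columns are used).
#' @param plan A `closure_plan`.
#' @param gas,elastance,config,frequencies See [frequency_sweep()].
#' @param za_cache Optional precomputed branch-impedance matrix for the
#'   *unnarrowed* tree (internal fast path: only narrowed branches are
#'   recomputed).
#' @param baseline Optional precomputed baseline `impedance_spectrum`.
#' @return List of class `closure_simulation`: `plan`, `spectrum`,
#'   `metrics`, `baseline_spectrum`, `baseline_metrics`.
#' @export
simulate_condition <- function(tree, plan,
                               gas = gas_properties(),
                               elastance = NULL,
                               config = respiratory_config(),
                               frequencies = default_frequencies(),
                               za_cache = NULL, baseline = NULL) {
  if (is.null(elastance))
    elastance <- elastance_model(10, sum(tree$branches$is_terminal))
  if (is.null(za_cache))
    za_cache <- .branch_za_matrix(tree$branches, frequencies, gas)
  if (is.null(baseline))
    baseline <- frequency_sweep(tree, frequencies, gas, elastance, config,
                                za_cache = za_cache)
  narrowed <- narrow_branches(tree, plan$narrow_ids, plan$diameter_factor)
  za <- za_cache
  if (length(plan$narrow_ids)) {
    idx <- match(plan$narrow_ids, narrowed$branches$id)
    za[idx, ] <- .branch_za_matrix(narrowed$branches[idx, , drop = FALSE],
                                   frequencies, gas)
  }
  spec <- frequency_sweep(narrowed, frequencies, gas, elastance, config,
                          za_cache = za)
  structure(list(plan = plan,
                 spectrum = spec, metrics = derived_metrics(spec),
                 baseline_spectrum = baseline,
                 baseline_metrics = derived_metrics(baseline)),
            class = "closure_simulation")
}

#' @export
print.closure_simulation <- function(x, ...) {
  print(x$plan)
  m <- x$metrics; b <- x$baseline_metrics
  cat(sprintf("  Rrs5: %.3f (baseline %.3f); Xrs5: %.3f (baseline %.3f)\n",
              m$Rrs5, b$Rrs5, m$Xrs5, b$Xrs5))
  invisible(x)
}
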