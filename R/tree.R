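#' Generate a morphometry-matched airway tree
#'
#' Builds an asymmetric, at-most-binary airway tree whose per-generation
#' branch counts, terminal counts and diameter statistics match a
#' [morphometry table][load_morphometry]. Which branches of a generation
#' terminate is chosen by seeded random draw, constrained to reproduce the
#' terminal counts exactly. Branch centerlines are embedded by recursive
#' halving of a lung bounding box along its longest axis, so that every
#' subtree occupies a spatially compact, contiguous region -- the property
#' that matters when overlaying the tree on ventilation-defect maps. The
#' centerlines are not anatomical.
#'
#' Diameters are drawn from a normal distribution clipped to
#' `[d_min, d_max]`; the pre-clip mean is recentred (analytically, per
#' generation) so that the clipped distribution's expectation equals
#' `d_mean`, keeping generation means unbiased.
#'
#' @param morphometry A `morphometry` table (e.g. [default_morphometry()]).
#' @param seed Integer RNG seed; the same seed yields a bit-identical tree.
#' @param lung_extent Numeric length-3, bounding box of the lung in mm
#'   (x, y, z). Default `c(300, 250, 210)` matches a 128x128x14 thoracic
#'   image at 3.13 x 3.13 x 15 mm voxels.
#' @return An object of class `airway_tree`: a list with elements
#'   `branches` (data frame with columns `id`, `parent_id`, `generation`,
#'   `diameter_mm`, `length_mm`, `x0`,`y0`,`z0`,`x1`,`y1`,`z1`,
#'   `is_terminal`), `root_id` and `metadata`.
#' @examples
#' toy <- as_morphometry(data.frame(
#'   generation = 1:3, branches = c(1, 2, 4),
#'   terminal_branches = c(0, 0, 4),
#'   d_mean = c(10, 7, 5), d_max = c(10, 8, 6),
#'   d_min = c(10, 6, 4), d_std = c(0, 0.5, 0.5)))
#' tr <- generate_tree(toy, seed = 1)
#' sum(tr$branches$is_terminal)  # 4
#' @export
generate_tree <- function(morphometry, seed = 1L,
                          lung_extent = c(300, 250, 210)) {
  m <- as_morphometry(morphometry)
  .check_branching_feasibility(m)
  if (length(lung_extent) != 3L || any(lung_extent <= 0))
    .stopf("'lung_extent' must be three positive extents in mm")
  G <- nrow(m)

  with_seed(seed, {
    gen_box <- vector("list", G)   # n x 6 matrix: xlo ylo zlo xhi yhi zhi
    gen_prox <- vector("list", G)  # n x 3 proximal endpoints
    gen_parent <- vector("list", G)
    gen_term <- vector("list", G)

    gen_box[[1L]] <- matrix(c(0, 0, 0, lung_extent), nrow = 1L)
    gen_prox[[1L]] <- matrix(c(lung_extent[1] / 2, lung_extent[2] / 2,
                               lung_extent[3]), nrow = 1L)
    gen_parent[[1L]] <- NA_integer_

    for (g in seq_len(G)) {
      n_g <- m$branches[g]
      t_g <- m$terminal_branches[g]
      term <- rep(FALSE, n_g)
      if (t_g > 0) term[sample.int(n_g, t_g)] <- TRUE
      if (g == G) term[] <- TRUE
      gen_term[[g]] <- term
      if (g == G) break

      open <- which(!term)
      n_open <- length(open)
      n_child <- m$branches[g + 1L]
      two <- rep(FALSE, n_open)
      k2 <- n_child - n_open
      if (k2 > 0) two[sample.int(n_open, k2)] <- TRUE

      box <- gen_box[[g]][open, , drop = FALSE]
      prox <- .box_center(gen_box[[g]])[open, , drop = FALSE]  # parent distal
      ext <- box[, 4:6, drop = FALSE] - box[, 1:3, drop = FALSE]
      ax <- max.col(ext, ties.method = "first")
      half <- ext[cbind(seq_len(n_open), ax)] / 2

      lower <- box
      lower[cbind(seq_len(n_open), 3L + ax)] <-
        lower[cbind(seq_len(n_open), ax)] + half
      upper <- box
      upper[cbind(seq_len(n_open), ax)] <-
        upper[cbind(seq_len(n_open), ax)] + half

      # single children take the half whose center is farther (along the
      # split axis) from the parent's distal point, so flow keeps advancing
      lc <- .box_center(lower)[cbind(seq_len(n_open), ax)]
      uc <- .box_center(upper)[cbind(seq_len(n_open), ax)]
      pa <- prox[cbind(seq_len(n_open), ax)]
      take_upper <- !two & (abs(uc - pa) > abs(lc - pa))
      first <- lower
      first[take_upper, ] <- upper[take_upper, ]

      child_box <- rbind(first, upper[two, , drop = FALSE])
      child_parent_local <- c(open, open[two])
      ord <- order(child_parent_local)
      gen_box[[g + 1L]] <- child_box[ord, , drop = FALSE]
      local_parent <- child_parent_local[ord]
      gen_parent[[g + 1L]] <- local_parent    # local index within gen g
      gen_prox[[g + 1L]] <- .box_center(gen_box[[g]])[local_parent, ,
                                                      drop = FALSE]
    }

    # assemble branch table with generation-major sequential ids
    offsets <- c(0L, cumsum(m$branches))[seq_len(G)]
    pieces <- vector("list", G)
    for (g in seq_len(G)) {
      n_g <- m$branches[g]
      dist_pt <- .box_center(gen_box[[g]])
      prox_pt <- gen_prox[[g]]
      parent <- if (g == 1L) NA_integer_ else
        gen_parent[[g]] + offsets[g - 1L]
      d <- .sample_diameters(n_g, m$d_mean[g], m$d_std[g],
                             m$d_min[g], m$d_max[g])
      len <- sqrt(rowSums((dist_pt - prox_pt)^2))
      pieces[[g]] <- data.frame(
        id = offsets[g] + seq_len(n_g),
        parent_id = parent,
        generation = g,
        diameter_mm = d,
        length_mm = len,
        x0 = prox_pt[, 1], y0 = prox_pt[, 2], z0 = prox_pt[, 3],
        x1 = dist_pt[, 1], y1 = dist_pt[, 2], z1 = dist_pt[, 3],
        is_terminal = gen_term[[g]])
    }
    branches <- do.call(rbind, pieces)
    rownames(branches) <- NULL

    structure(list(
      branches = branches,
      root_id = 1L,
      metadata = list(seed = as.integer(seed),
                      lung_extent = lung_extent,
                      coordinate_frame = "model_mm",
                      scaling = list(),
                      narrowing = list())),
      class = "airway_tree")
  })
}

.box_center <- function(box) {
  (box[, 1:3, drop = FALSE] + box[, 4:6, drop = FALSE]) / 2
}

# Clipped-normal sampling whose expectation matches `target` exactly.
.sample_diameters <- function(n, target, sd, lo, hi) {
  if (sd <= 0 || hi - lo < .Machine$double.eps) {
    return(rep(target, n))
  }
  mu <- .recentre_clipped_mean(target, sd, lo, hi)
  pmin(pmax(stats::rnorm(n, mu, sd), lo), hi)
}

.clipped_normal_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  a * stats::pnorm(al) + b * (1 - stats::pnorm(be)) +
    mu * (stats::pnorm(be) - stats::pnorm(al)) -
    sd * (stats::dnorm(be) - stats::dnorm(al))
}

.recentre_clipped_mean <- function(target, sd, a, b) {
  f <- function(mu) .clipped_normal_mean(mu, sd, a, b) - target
  lo <- a - 8 * sd
  hi <- b + 8 * sd
  if (f(lo) > 0) return(lo)
  if (f(hi) < 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

.truncated_normal_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) /
    (stats::pnorm(be) - stats::pnorm(al))
}

.recentre_truncated_mean <- function(target, sd, a, b) {
  f <- function(mu) .truncated_normal_mean(mu, sd, a, b) - target
  lo <- a - 8 * sd
  hi <- b + 8 * sd
  if (f(lo) > 0) return(lo)
  if (f(hi) < 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Validate the structural invariants of an airway tree
#'
#' Checks that the tree has exactly one root, that every non-root branch has
#' an existing parent one generation above it, that terminal flags agree
#' with the child table, and that stored lengths equal the Euclidean
#' distance between endpoints (1e-6 mm).
#'
#' @param tree An `airway_tree`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_airway_tree <- function(tree) {
  if (!inherits(tree, "airway_tree")) .stopf("not an airway_tree")
  b <- tree$branches
  roots <- which(is.na(b$parent_id))
  if (length(roots) != 1L) .stopf("tree must have exactly one root")
  if (b$generation[roots] != 1L) .stopf("root must have generation 1")
  if (b$id[roots] != tree$root_id) .stopf("root_id does not match")
  nonroot <- b[!is.na(b$parent_id), ]
  pidx <- match(nonroot$parent_id, b$id)
  if (anyNA(pidx)) .stopf("orphan branches present")
  if (any(nonroot$generation != b$generation[pidx] + 1L))
    .stopf("child generation must equal parent generation + 1")
  has_child <- b$id %in% nonroot$parent_id
  if (any(has_child == b$is_terminal))
    .stopf("is_terminal flags disagree with the child table")
  len <- sqrt((b$x1 - b$x0)^2 + (b$y1 - b$y0)^2 + (b$z1 - b$z0)^2)
  if (any(abs(len - b$length_mm) > 1e-6))
    .stopf("stored lengths disagree with endpoint distance")
  if (any(b$diameter_mm <= 0) || any(b$length_mm <= 0))
    .stopf("non-positive geometry")
  invisible(TRUE)
}

#' Rescale a tree from TLC to FRC (or any linear factor)
#'
#' Multiplies every diameter and length by `linear_factor` and rescales the
#' centerline about the root inlet, so total airway volume scales by
#' `linear_factor^3`. The conventional deflation from total lung capacity
#' to functional residual capacity uses `linear_factor = 0.8` (volume ratio
#' 0.512).
#'
#' @param tree An `airway_tree`.
#' @param linear_factor Scale factor in (0, 1].
#' @return The rescaled `airway_tree`; the factor is appended to
#'   `metadata$scaling`.
#' @export
scale_to_frc <- function(tree, linear_factor = 0.8) {
  .assert_scalar_number(linear_factor, "linear_factor")
  if (linear_factor <= 0 || linear_factor > 1)
    .stopf("'linear_factor' must lie in (0, 1]")
  b <- tree$branches
  origin <- unlist(b[match(tree$root_id, b$id), c("x0", "y0", "z0")])
  for (i in seq_len(3)) {
    p <- c("x0", "y0", "z0")[i]; q <- c("x1", "y1", "z1")[i]
    b[[p]] <- origin[i] + linear_factor * (b[[p]] - origin[i])
    b[[q]] <- origin[i] + linear_factor * (b[[q]] - origin[i])
  }
  b$diameter_mm <- b$diameter_mm * linear_factor
  b$length_mm <- b$length_mm * linear_factor
  tree$branches <- b
  tree$metadata$scaling <- c(tree$metadata$scaling, list(linear_factor))
  tree
}

#' Narrow selected branches
#'
#' Multiplies the diameters of the listed branches by `diameter_factor`,
#' leaving all other branches untouched. Narrowing to 10% of the initial
#' diameter raises a branch's Poiseuille resistance by a factor of 10^4 and
#' is the package's standard stand-in for airway closure (avoiding zero
#' diameters).
#'
#' @param tree An `airway_tree`.
#' @param branch_ids Integer ids of branches to narrow.
#' @param diameter_factor Factor in (0, 1].
#' @return The modified `airway_tree`; the operation is appended to
#'   `metadata$narrowing`.
#' @export
narrow_branches <- function(tree, branch_ids, diameter_factor = 0.1) {
  .assert_scalar_number(diameter_factor, "diameter_factor")
  if (diameter_factor <= 0 || diameter_factor > 1)
    .stopf("'diameter_factor' must lie in (0, 1]")
  if (length(branch_ids) == 0L) return(tree)
  idx <- match(branch_ids, tree$branches$id)
  if (anyNA(idx))
    .stopf("unknown branch id(s): %s",
           paste(branch_ids[is.na(idx)], collapse = ", "))
  tree$branches$diameter_mm[idx] <-
    tree$branches$diameter_mm[idx] * diameter_factor
  tree$metadata$narrowing <- c(tree$metadata$narrowing,
                               list(list(ids = branch_ids,
                                         factor = diameter_factor)))
  tree
}

#' Per-generation summary of a tree
#'
#' Recomputes a [morphometry table][as_morphometry] from an `airway_tree`:
#' branch and terminal counts plus diameter statistics per generation.
#'
#' @param tree An `airway_tree`.
#' @return A `morphometry` data frame.
#' @export
tree_summary <- function(tree) {
  b <- tree$branches
  gl <- sort(unique(b$generation))
  out <- data.frame(
    generation = gl,
    branches = as.integer(tapply(b$id, b$generation, length)),
    terminal_branches = as.integer(tapply(b$is_terminal, b$generation, sum)),
    d_mean = as.numeric(tapply(b$diameter_mm, b$generation, mean)),
    d_max = as.numeric(tapply(b$diameter_mm, b$generation, max)),
    d_min = as.numeric(tapply(b$diameter_mm, b$generation, min)),
    d_std = as.numeric(tapply(b$diameter_mm, b$generation,
                              function(x) if (length(x) > 1) stats::sd(x) else 0)))
  rownames(out) <- NULL
  class(out) <- c("morphometry", "data.frame")
  out
}

#' Total airway volume of a tree
#'
#' @param tree An `airway_tree`.
#' @return Total cylinder volume, mm^3.
#' @export
airway_volume <- function(tree) {
  b <- tree$branches
  sum(pi * (b$diameter_mm / 2)^2 * b$length_mm)
}

# All descendants (ids) of the given branch ids, excluding the branches
# themselves. Single generation-ordered pass.
.descendant_ids <- function(tree, ids) {
  b <- tree$branches
  marked <- b$id %in% ids
  out <- logical(nrow(b))
  for (g in sort(unique(b$generation))) {
    sel <- b$generation == g & !is.na(b$parent_id)
    hit <- sel & (marked[match(b$parent_id, b$id)] | out[match(b$parent_id, b$id)])
    hit[is.na(hit)] <- FALSE
    out <- out | hit
  }
  b$id[out]
}

#' Write / read an airway tree as CSV
#'
#' One branch per row with the columns documented in [generate_tree()];
#' world coordinates in mm. The CSV round-trips exactly enough for
#' downstream use (`read_airway_tree` revalidates).
#'
#' @param tree An `airway_tree`.
#' @param path Output CSV path.
#' @return `write_airway_tree` returns `path` invisibly;
#'   `read_airway_tree` returns an `airway_tree`.
#' @export
write_airway_tree <- function(tree, path) {
  utils::write.csv(tree$branches, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_airway_tree
#' @export
read_airway_tree <- function(path) {
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "parent_id", "generation", "diameter_mm", "length_mm",
            "x0", "y0", "z0", "x1", "y1", "z1", "is_terminal")
  missing <- setdiff(need, names(b))
  if (length(missing))
    .stopf("tree CSV missing column(s): %s", paste(missing, collapse = ", "))
  tree <- structure(list(
    branches = b[need],
    root_id = b$id[is.na(b$parent_id)][1L],
    metadata = list(coordinate_frame = "model_mm",
                    scaling = list(), narrowing = list())),
    class = "airway_tree")
  validate_airway_tree(tree)
  tree
}

#' @export
print.airway_tree <- function(x, ...) {
  b <- x$branches
  cat(sprintf(
    "Airway tree: %d branches, %d generations, %d terminal branches\n",
    nrow(b), max(b$generation), sum(b$is_terminal)))
  cat(sprintf("  diameters %.2f-%.2f mm, total airway volume %.1f mL\n",
              min(b$diameter_mm), max(b$diameter_mm),
              airway_volume(x) / 1000))
  if (length(x$metadata$scaling))
    cat(sprintf("  scaled by: %s\n",
                paste(unlist(x$metadata$scaling), collapse = ", ")))
  if (length(x$metadata$narrowing))
    cat(sprintf("  narrowing operations: %d\n",
                length(x$metadata$narrowing)))
  invisible(x)
}

#' @export
summary.airway_tree <- function(object, ...) tree_summary(object)
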