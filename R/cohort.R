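#' Generate a synthetic study cohort
#'
#' Draws `n_subjects` synthetic asthmatic subjects, each observed under
#' three conditions (baseline, post-methacholine, post-salbutamol). True
#' ventilation defect percent (VDP) is drawn per condition from truncated
#' normal distributions with (mean, sd) = (4, 4), (11, 10) and (4, 2)
#' percent respectively, truncated to `[0, 60]`. Simulated FEV1 %predicted
#' is drawn per condition (means 84, 64, 87; sd 15) negatively coupled to
#' the subject-condition VDP (default correlation -0.6); simulated airways
#' resistance Raw %predicted (mean 126, sd 69, floored at 10) is
#' positively coupled (default +0.7). The couplings are generator choices
#' on the latent scale, not measured values.
#'
#' @param n_subjects Number of subjects (>= 2; default 25).
#' @param seed Integer seed.
#' @param fev1_coupling,raw_coupling Latent correlations with VDP.
#' @param vdp_params 3 x 2 matrix of (mean, sd) per condition. The
#'   pre-truncation location is recentred so the truncated expectation
#'   equals the stated mean.
#' @param fev1_sd,raw_sd Marginal standard deviations of the simulated
#'   lung-function measures (set everything to zero for degenerate,
#'   identical subjects).
#' @return Data frame of class `lung_cohort` with one row per
#'   subject-condition: `subject`, `condition`, `vdp_true`,
#'   `fev1_pct_pred`, `raw_pct_pred`, `phantom_seed`.
#' @export
generate_cohort <- function(n_subjects = 25L, seed = 1L,
                            fev1_coupling = -0.6, raw_coupling = 0.7,
                            vdp_params = rbind(baseline = c(4, 4),
                                               post_methacholine = c(11, 10),
                                               post_salbutamol = c(4, 2)),
                            fev1_sd = 15, raw_sd = 69) {
  if (n_subjects < 2) .stopf("'n_subjects' must be >= 2")
  conditions <- rownames(vdp_params)
  fev1_mean <- c(baseline = 84, post_methacholine = 64,
                 post_salbutamol = 87)[conditions]
  fev1_mean[is.na(fev1_mean)] <- 84
  with_seed(seed, {
    rows <- list()
    for (ci in seq_along(conditions)) {
      m <- vdp_params[ci, 1]; s <- vdp_params[ci, 2]
      if (s > 0) {
        # truncated normal on [0, 60], recentred so E[vdp] = m;
        # z_v is the latent draw used for the lung-function couplings
        mu <- .recentre_truncated_mean(m, s, 0, 60)
        lo <- stats::pnorm((0 - mu) / s); hi <- stats::pnorm((60 - mu) / s)
        z_v <- stats::qnorm(lo + stats::runif(n_subjects) * (hi - lo))
        vdp <- mu + s * z_v
      } else {
        z_v <- rep(0, n_subjects)
        vdp <- rep(m, n_subjects)
      }
      fev1 <- fev1_mean[ci] + fev1_sd *
        (fev1_coupling * z_v +
           sqrt(1 - fev1_coupling^2) * stats::rnorm(n_subjects))
      raw <- pmax(10, 126 + raw_sd *
                    (raw_coupling * z_v +
                       sqrt(1 - raw_coupling^2) * stats::rnorm(n_subjects)))
      rows[[ci]] <- data.frame(
        subject = seq_len(n_subjects),
        condition = conditions[ci],
        vdp_true = vdp,
        fev1_pct_pred = fev1,
        raw_pct_pred = raw)
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$subject), ]
    rownames(out) <- NULL
    out$phantom_seed <- as.integer(seed %% 10000L * 1000L +
                                     seq_len(nrow(out)))
    class(out) <- c("lung_cohort", "data.frame")
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Run the full imaging-to-impedance pipeline on a cohort
#'
#' For every subject-condition row: generates the phantom at the true VDP,
#' segments the thoracic cavity from the proton image, builds the
#' five-cluster ventilation map (background-anchored), estimates VDP,
#' extracts the defect regions passing the in-plane extent rule, recovers
#' the model-to-image rigid transform from the phantom's fiducials, maps
#' the airway tree into voxel space, selects and narrows the airways of
#' each target generation inside the dilated defect masks, and records the
#' impedance band metrics of the narrowed tree. A single FRC-scaled tree
#' (shared across subjects, as with a common computational airway model)
#' and a single baseline spectrum are reused throughout.
#'
#' @param cohort A `lung_cohort` from [generate_cohort()].
#' @param tree An `airway_tree` at TLC, or `NULL` to generate the default
#'   morphometry-matched tree (seeded from the cohort seed) and scale it
#'   to FRC by 0.8.
#' @param generations Closure generations to simulate (default 9 and 14).
#' @param gas,config,frequencies See [frequency_sweep()].
#' @param E_L Total lung elastance, cmH2O/L.
#' @param margin_voxels,diameter_factor,narrow_scope Passed to
#'   [select_branches_for_defects()].
#' @param verbose Print per-subject progress?
#' @return Data frame of class `cohort_records`: the cohort columns plus
#'   `vdp_est`, `dsc_mean`, `fre_mm`, `n_selected_g<G>` and, per
#'   generation `<G>`, metric columns `g<G>_rrs0_2`, `g<G>_rrs5`,
#'   `g<G>_rrs20`, `g<G>_rrs0_2_5`, `g<G>_rrs5_20`, `g<G>_xrs0_2`,
#'   `g<G>_xrs5`, `g<G>_xrs20`, `g<G>_ers0_2`, `g<G>_ers5`. Baseline
#'   (unnarrowed) metrics are attached as attribute `baseline_metrics`.
#' @export
run_cohort_pipeline <- function(cohort, tree = NULL,
                                generations = c(9L, 14L),
                                gas = gas_properties(),
                                config = respiratory_config(),
                                frequencies = default_frequencies(),
                                E_L = 10,
                                margin_voxels = 2L,
                                diameter_factor = 0.1,
                                narrow_scope = "at_generation",
                                verbose = FALSE) {
  seed <- attr(cohort, "seed")
  if (is.null(seed)) seed <- 1L
  if (is.null(tree)) {
    tree <- generate_tree(default_morphometry(), seed = seed)
    tree <- scale_to_frc(tree, 0.8)
  }
  elastance <- elastance_model(E_L, sum(tree$branches$is_terminal))
  za <- .branch_za_matrix(tree$branches, frequencies, gas)
  baseline <- frequency_sweep(tree, frequencies, gas, elastance, config,
                              za_cache = za)
  metric_cols <- c("rrs0_2", "rrs5", "rrs20", "rrs0_2_5", "rrs5_20",
                   "xrs0_2", "xrs5", "xrs20", "ers0_2", "ers5")

  out <- as.data.frame(cohort)
  out$vdp_est <- NA_real_
  out$dsc_mean <- NA_real_
  out$fre_mm <- NA_real_
  for (g in generations) {
    out[[sprintf("n_selected_g%d", g)]] <- NA_integer_
    for (mc in metric_cols) out[[sprintf("g%d_%s", g, mc)]] <- NA_real_
  }

  for (i in seq_len(nrow(out))) {
    sp <- phantom_spec(defect_fraction = out$vdp_true[i],
                       seed = out$phantom_seed[i])
    ph <- generate_phantom(sp, tree = tree)
    cavity_est <- segment_thoracic_cavity(ph$proton, ph$cavity_seeds)
    bg <- with_seed(sp$seed + 1L, {
      pool <- which(!ph$cavity)
      # a modest anchor (~10% of the cavity mass) pins C1 at the noise
      # floor without dominating the within-cluster variance budget
      n_ref <- max(500L, as.integer(0.1 * sum(cavity_est)))
      ph$ventilation$data[pool[sample.int(length(pool),
                                          min(n_ref, length(pool)))]]
    })
    cl <- cluster_ventilation(ph$ventilation, cavity_est,
                              seed = sp$seed, noise_reference = bg)
    out$vdp_est[i] <- compute_vdp(cl)
    defects <- extract_defect_regions(cl)

    xf <- rigid_from_fiducials(ph$fiducials$model, ph$fiducials$image)
    out$fre_mm[i] <- xf$fre
    tv <- apply_transform(tree, xf, ph$ventilation)

    model_cav <- model_cavity_mask(ph$lungs, xf, ph$ventilation)
    nonempty <- which(vapply(seq_len(dim(cavity_est)[3]), function(s)
      any(model_cav[, , s]) || any(cavity_est[, , s]), logical(1)))
    out$dsc_mean[i] <- mean(vapply(nonempty, function(s)
      as.numeric(dice_coefficient(model_cav[, , s], cavity_est[, , s])),
      numeric(1)))

    for (g in generations) {
      plan <- select_branches_for_defects(
        tv, defects, dim(ph$ventilation$data), g,
        margin_voxels = margin_voxels,
        diameter_factor = diameter_factor,
        narrow_scope = narrow_scope)
      sim <- simulate_condition(tree, plan, gas, elastance, config,
                                frequencies, za_cache = za,
                                baseline = baseline)
      out[[sprintf("n_selected_g%d", g)]][i] <- length(plan$branch_ids)
      vals <- unlist(sim$metrics)
      for (k in seq_along(metric_cols))
        out[[sprintf("g%d_%s", g, metric_cols[k])]][i] <- vals[k]
    }
    if (verbose)
      message(sprintf("subject %d/%d: VDP %.1f -> est %.1f",
                      i, nrow(out), out$vdp_true[i], out$vdp_est[i]))
  }
  class(out) <- c("cohort_records", "data.frame")
  attr(out, "baseline_metrics") <- derived_metrics(baseline)
  attr(out, "generations") <- generations
  out
}
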