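#' Correlation with automatic normality screening
#'
#' Screens both variables with the Shapiro-Wilk test (alpha 0.05); when
#' `method = "auto"`, uses Pearson correlation if both pass and Spearman's
#' rank correlation otherwise.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, finite, non-constant.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return List of class `correlation_result`: `method`, `r`, `n`,
#'   `p` (two-sided), `normal_x`, `normal_y` (screen p-values).
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) .stopf("'x' and 'y' must have equal length")
  if (length(x) < 3) .stopf("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    .stopf("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .stopf("correlation undefined for a constant variable")
  px <- stats::shapiro.test(x)$p.value
  py <- stats::shapiro.test(y)$p.value
  if (method == "auto")
    method <- if (px > 0.05 && py > 0.05) "pearson" else "spearman"
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  structure(list(method = method, r = unname(ct$estimate),
                 n = length(x), p = ct$p.value,
                 normal_x = px, normal_y = py),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f (n = %d, p = %.3g)\n",
              x$method, x$r, x$n, x$p))
  invisible(x)
}

#' Compare two correlation coefficients via Fisher z
#'
#' Independent-samples test:
#' `z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided p
#' from the standard normal. With `sign_agnostic = TRUE` the magnitudes
#' `|r|` are compared (appropriate when testing whether one relationship
#' is *stronger* than another of opposite sign). A dependent-correlations
#' variant (both correlations share a variable) is available by supplying
#' `r12`, the correlation between the two non-shared variables: Steiger's
#' Z1* is then used with the common `n = n1`.
#'
#' @param r1,r2 Correlation coefficients, `|r| < 1`.
#' @param n1,n2 Sample sizes, > 3.
#' @param sign_agnostic Compare `|r|` instead of signed r.
#' @param r12 Optional inter-predictor correlation for the dependent test.
#' @return List with `z` and two-sided `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2, sign_agnostic = FALSE,
                             r12 = NULL) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    .stopf("|r| must be < 1 for the Fisher transform")
  if (n1 <= 3 || n2 <= 3) .stopf("sample sizes must exceed 3")
  if (sign_agnostic) { r1 <- abs(r1); r2 <- abs(r2) }
  if (is.null(r12)) {
    z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  } else {
    # Steiger (1980) Z1*: dependent correlations sharing one variable
    n <- n1
    rbar <- (r1 + r2) / 2
    det <- (1 - r12^2 - r1^2 - r2^2 + 2 * r1 * r2 * r12)
    psi <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)
    c12 <- psi / (1 - rbar^2)^2
    z <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - c12)))
    if (det < 0) warning("implied correlation matrix is not positive definite")
  }
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' ANCOVA test of slope homogeneity across groups
#'
#' Fits `y ~ group + x + group:x` by least squares and tests the
#' interaction term (equality of within-group slopes), reporting the
#' interaction F and p and each group's slope.
#'
#' @param groups Named list (>= 2) of data frames, each with columns `x`
#'   and `y` (n >= 3 per group).
#' @return List of class `ancova_result`: `F`, `p`, `df`, `slopes`.
#' @export
ancova_slopes <- function(groups) {
  if (length(groups) < 2) .stopf("need at least 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  for (g in groups)
    if (nrow(g) < 3) .stopf("each group needs at least 3 observations")
  dat <- do.call(rbind, lapply(names(groups), function(nm)
    data.frame(x = groups[[nm]]$x, y = groups[[nm]]$y, group = nm)))
  dat$group <- factor(dat$group, levels = names(groups))
  full <- stats::lm(y ~ group + x + group:x, data = dat)
  if (any(!is.finite(stats::coef(full))))
    .stopf("rank-deficient ANCOVA design")
  reduced <- stats::lm(y ~ group + x, data = dat)
  rss_full <- sum(stats::residuals(full)^2)
  rss_red <- sum(stats::residuals(reduced)^2)
  df1 <- length(groups) - 1L
  df2 <- nrow(dat) - 2L * length(groups)
  # direct F from the nested RSS (identical fits give exactly F = 0,
  # where anova() would blank the statistic on round-off)
  fstat <- max(0, (rss_red - rss_full) / df1) / (rss_full / df2)
  slopes <- vapply(names(groups), function(nm) {
    unname(stats::coef(stats::lm(y ~ x, data = dat[dat$group == nm, ]))[2])
  }, numeric(1))
  structure(list(F = fstat, p = stats::pf(fstat, df1, df2, lower.tail = FALSE),
                 df = c(df1, df2), slopes = slopes),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("Slope-homogeneity ANCOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat("  slopes:", paste(sprintf("%s = %.4g", names(x$slopes), x$slopes),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Holm-Bonferroni step-down multiple-comparison correction
#'
#' Sorts the p-values ascending, compares `p_(i)` with
#' `alpha / (m - i + 1)` and stops at the first failure; everything before
#' it is rejected. Adjusted p-values are the running maximum of
#' `(m - i + 1) * p_(i)`, capped at 1, returned in the original order.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return List: `reject` (logical), `adjusted` (numeric), both in input
#'   order.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1) || any(!is.finite(p)))
    .stopf("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  mult <- m - seq_len(m) + 1
  adj_sorted <- pmin(1, cummax(mult * ps))
  reject_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (ps[i] <= alpha / mult[i]) reject_sorted[i] <- TRUE else break
  }
  reject <- logical(m); adjusted <- numeric(m)
  reject[ord] <- reject_sorted
  adjusted[ord] <- adj_sorted
  list(reject = reject, adjusted = adjusted)
}

#' Full statistical analysis of a simulated cohort
#'
#' Reproduces the study's analysis matrix on a [cohort-records
#' table][run_cohort_pipeline]: correlations of VDP with FEV1 %predicted,
#' Raw %predicted and the closure-generation impedance metrics at 5 Hz
#' (auto-screened Pearson/Spearman); sign-agnostic Fisher-z comparisons of
#' the model-metric correlations against the FEV1 correlation and between
#' closure generations, Holm-Bonferroni corrected as one family; the
#' per-frequency slope table of each impedance metric against VDP; and
#' ANCOVA tests of slope homogeneity across frequencies for resistance
#' (0.2, 5, 20 Hz) and reactance (0.2, 5 Hz). All subject-conditions are
#' pooled as independent observations (n = subjects x conditions), as in
#' the study design this emulates; the result flags this pooling.
#'
#' @param records A `cohort_records` data frame.
#' @param vdp Column used as the VDP axis: `"vdp_est"` (default) or
#'   `"vdp_true"`.
#' @return List of class `cohort_analysis`.
#' @export
analyze_cohort <- function(records, vdp = c("vdp_est", "vdp_true")) {
  vdp <- match.arg(vdp)
  if (!vdp %in% names(records)) vdp <- "vdp_true"
  v <- records[[vdp]]
  gens <- attr(records, "generations")
  if (is.null(gens))
    gens <- as.integer(sub("^g(\\d+)_rrs5$", "\\1",
                           grep("^g\\d+_rrs5$", names(records),
                                value = TRUE)))
  cors <- list(fev1 = correlate(v, records$fev1_pct_pred),
               raw = correlate(v, records$raw_pct_pred))
  for (g in gens) {
    cors[[sprintf("rrs5_g%d", g)]] <-
      correlate(v, records[[sprintf("g%d_rrs5", g)]])
    cors[[sprintf("xrs5_g%d", g)]] <-
      correlate(v, records[[sprintf("g%d_xrs5", g)]])
  }

  # perfect correlations (degenerate noiseless cohorts) are clamped just
  # inside the open interval so the Fisher transform stays finite
  clamp <- function(r) sign(r) * min(abs(r), 1 - 1e-12)
  cmp <- list()
  for (g in gens) {
    for (metric in c("rrs5", "xrs5")) {
      key <- sprintf("%s_g%d", metric, g)
      cmp[[paste0(key, "_vs_fev1")]] <- fisher_z_compare(
        clamp(cors[[key]]$r), cors[[key]]$n,
        clamp(cors$fev1$r), cors$fev1$n, sign_agnostic = TRUE)
    }
  }
  if (length(gens) >= 2) {
    g1 <- gens[1]; g2 <- gens[2]
    for (metric in c("rrs5", "xrs5")) {
      k1 <- sprintf("%s_g%d", metric, g1)
      k2 <- sprintf("%s_g%d", metric, g2)
      cmp[[sprintf("%s_g%d_vs_g%d", metric, g2, g1)]] <- fisher_z_compare(
        clamp(cors[[k2]]$r), cors[[k2]]$n,
        clamp(cors[[k1]]$r), cors[[k1]]$n,
        sign_agnostic = TRUE)
    }
  }
  holm <- holm_bonferroni(vapply(cmp, function(x) x$p, numeric(1)))

  metric_cols <- c("rrs0_2", "rrs5", "rrs20", "rrs0_2_5", "rrs5_20",
                   "xrs0_2", "xrs5", "xrs20", "ers0_2", "ers5")
  slopes <- list()
  ancova <- list()
  for (g in gens) {
    sl <- vapply(metric_cols, function(mc) {
      unname(stats::coef(stats::lm(records[[sprintf("g%d_%s", g, mc)]] ~ v))[2])
    }, numeric(1))
    slopes[[sprintf("g%d", g)]] <- sl
    ancova[[sprintf("g%d_rrs", g)]] <- ancova_slopes(list(
      `0.2Hz` = data.frame(x = v, y = records[[sprintf("g%d_rrs0_2", g)]]),
      `5Hz` = data.frame(x = v, y = records[[sprintf("g%d_rrs5", g)]]),
      `20Hz` = data.frame(x = v, y = records[[sprintf("g%d_rrs20", g)]])))
    ancova[[sprintf("g%d_xrs", g)]] <- ancova_slopes(list(
      `0.2Hz` = data.frame(x = v, y = records[[sprintf("g%d_xrs0_2", g)]]),
      `5Hz` = data.frame(x = v, y = records[[sprintf("g%d_xrs5", g)]])))
  }

  structure(list(vdp_axis = vdp, n = nrow(records),
                 generations = gens, correlations = cors,
                 comparisons = cmp, holm = holm, slopes = slopes,
                 ancova = ancova,
                 pooled_repeated_measures = TRUE),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("Cohort analysis (n = %d pooled subject-conditions, %s)\n",
              x$n, x$vdp_axis))
  cat("Correlations with VDP:\n")
  for (nm in names(x$correlations)) {
    cr <- x$correlations[[nm]]
    cat(sprintf("  %-10s r = %6.3f (%s, p = %.3g)\n",
                nm, cr$r, cr$method, cr$p))
  }
  cat("Correlation-magnitude comparisons (Fisher z, Holm-adjusted):\n")
  for (i in seq_along(x$comparisons)) {
    cat(sprintf("  %-22s z = %6.2f, adj. p = %.3g%s\n",
                names(x$comparisons)[i], x$comparisons[[i]]$z,
                x$holm$adjusted[i],
                if (x$holm$reject[i]) " *" else ""))
  }
  cat("Slopes vs VDP:\n")
  for (g in names(x$slopes)) {
    cat(sprintf("  %s: %s\n", g,
                paste(sprintf("%s = %.4g", names(x$slopes[[g]]),
                              x$slopes[[g]]), collapse = ", ")))
  }
  if (isTRUE(x$pooled_repeated_measures))
    cat("Note: repeated measures pooled as independent observations.\n")
  invisible(x)
}
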