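#' Gas properties for oscillatory airway flow
#'
#' Defaults are humid air at body temperature: density 1.16 kg/m^3 and
#' dynamic viscosity 1.85e-5 Pa.s.
#'
#' @param density Gas density, kg/m^3.
#' @param viscosity Dynamic viscosity, Pa.s.
#' @return List of class `gas_properties`.
#' @export
gas_properties <- function(density = 1.16, viscosity = 1.85e-5) {
  if (density <= 0 || viscosity <= 0)
    .stopf("gas density and viscosity must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "gas_properties")
}

#' Womersley number of an airway branch
#'
#' `alpha = r * sqrt(2 * pi * rho * f / mu)`: the dimensionless ratio of
#' oscillatory inertial to viscous forces in tube flow. Zero exactly when
#' the frequency is zero.
#'
#' @param radius Inner radius, m. May be a vector.
#' @param frequency Oscillation frequency, Hz (>= 0).
#' @param gas A [gas_properties()] object.
#' @return Dimensionless Womersley number(s).
#' @export
womersley_number <- function(radius, frequency, gas = gas_properties()) {
  if (any(radius < 0) || any(frequency < 0))
    .stopf("radius and frequency must be non-negative")
  radius * sqrt(2 * pi * gas$density * frequency / gas$viscosity)
}

# ---- complex Bessel machinery -------------------------------------------
#
# The Womersley branch impedance needs the factor
#   W(alpha) = [1 - 2 J1(z) / (z J0(z))]^(-1),  z = alpha * sqrt(-1i),
# with J0, J1 the Bessel functions of complex argument. For alpha <= 50 the
# ratio is evaluated from the defining power series in u = z^2/4 = -1i
# alpha^2 / 4 (numerator and denominator share the (z/2) prefactor, so only
# the series in u are needed). Beyond alpha = 50 the series loses digits to
# cancellation and the Hankel asymptotic expansion of J1/J0 is used; the two
# regimes agree to ~1e-12 at the switch.

# S0 = sum_k u^k / (k!)^2, S1 = sum_k u^k / (k! (k+1)!), with u complex
# (vectorised over u). Returns ratio 2 J1(z)/(z J0(z)) = S1/S0 evaluated at
# u = z^2/4 passed negated internally via the alternating series.
.bessel_ratio_series <- function(u) {
  term0 <- rep(1 + 0i, length(u))
  term1 <- term0
  s0 <- term0
  s1 <- term1
  for (k in 0:200) {
    term0 <- term0 * (-u) / ((k + 1)^2)
    term1 <- term1 * (-u) / ((k + 1) * (k + 2))
    s0 <- s0 + term0
    s1 <- s1 + term1
    if (max(abs(term0) / abs(s0)) < 1e-17) break
  }
  s1 / s0
}

# Hankel asymptotic J1(z)/J0(z) for |z| large with Im(z) < 0, using the
# P/Q modulus-phase series through z^-4.
.bessel_ratio_asymptotic <- function(z) {
  zi2 <- 1 / (z * z)
  p0 <- 1 - 9 / 128 * zi2 + 3675 / 32768 * zi2^2
  q0 <- (-1 / 8 + 75 / 1024 * zi2) / z
  p1 <- 1 + 15 / 128 * zi2 - 4725 / 32768 * zi2^2
  q1 <- (3 / 8 - 105 / 1024 * zi2) / z
  j1_over_j0 <- -1i * (p1 + 1i * q1) / (p0 + 1i * q0)
  2 * j1_over_j0 / z
}

# Womersley factor [1 - 2J1/(zJ0)]^-1, vectorised over alpha.
.womersley_factor <- function(alpha) {
  out <- complex(length(alpha))
  z <- alpha * exp(-1i * pi / 4)
  small <- alpha <= 1e-3
  mid <- !small & alpha <= 50
  large <- alpha > 50
  if (any(small)) {
    # 1 - ratio = -u/2 (1 + 2u/3 + 11u^2/24 + ...), u = z^2/4
    u <- -1i * alpha[small]^2 / 4
    out[small] <- 1 / (-u / 2 * (1 + 2 * u / 3 + 11 * u^2 / 24))
  }
  if (any(mid)) {
    u <- -1i * alpha[mid]^2 / 4
    out[mid] <- 1 / (1 - .bessel_ratio_series(u))
  }
  if (any(large)) {
    out[large] <- 1 / (1 - .bessel_ratio_asymptotic(z[large]))
  }
  out
}

#' Oscillatory (Womersley) impedance of one or more airway branches
#'
#' Evaluates, in SI units and converts to cmH2O.s/L, the complex impedance
#' of a rigid cylindrical branch under fully developed oscillatory flow:
#' `Z_a(f) = j 2 f rho l / r^2 * [1 - 2 J1(a sqrt(-j)) /
#' (a sqrt(-j) J0(a sqrt(-j)))]^-1`, where `a` is the Womersley number. The
#' real part is always positive; at low Womersley number the real part
#' tends to the Poiseuille resistance `8 mu l / (pi r^4)`, and at high
#' Womersley number the imaginary part is inertance-dominated and positive.
#'
#' @param diameter_mm,length_mm Branch geometry in mm (vectors allowed).
#' @param frequency Frequency in Hz, strictly positive (scalar).
#' @param gas A [gas_properties()] object.
#' @return Complex impedance(s) in cmH2O.s/L.
#' @export
branch_impedance <- function(diameter_mm, length_mm, frequency,
                             gas = gas_properties()) {
  .assert_scalar_number(frequency, "frequency")
  if (frequency <= 0)
    .stopf("'frequency' must be > 0 (use poiseuille_resistance at 0 Hz)")
  if (any(diameter_mm <= 0) || any(length_mm <= 0))
    .stopf("branch geometry must be positive")
  r <- diameter_mm / 2000   # m
  l <- length_mm / 1000     # m
  alpha <- womersley_number(r, frequency, gas)
  z_si <- 1i * 2 * frequency * gas$density * l / r^2 *
    .womersley_factor(alpha)
  z_si / .PA_S_M3_PER_CMH2O_S_L
}

#' Poiseuille (zero-frequency) resistance of a branch
#'
#' `R = 8 mu l / (pi r^4)`, converted to cmH2O.s/L.
#'
#' @inheritParams branch_impedance
#' @return Resistance(s) in cmH2O.s/L.
#' @export
poiseuille_resistance <- function(diameter_mm, length_mm,
                                  gas = gas_properties()) {
  if (any(diameter_mm <= 0) || any(length_mm <= 0))
    .stopf("branch geometry must be positive")
  r <- diameter_mm / 2000
  l <- length_mm / 1000
  8 * gas$viscosity * l / (pi * r^4) / .PA_S_M3_PER_CMH2O_S_L
}

#' Terminal-unit elastance model
#'
#' Lung compliance is distributed evenly over the terminal airways: each of
#' the `n_terminals` leaves carries elastance `E_t = E_L * n_terminals`
#' (cmH2O/L), so that the parallel combination of all terminal units
#' returns the total lung elastance `E_L`.
#'
#' @param E_L Total lung elastance, cmH2O/L (default 10).
#' @param n_terminals Number of terminal airways.
#' @return List of class `elastance_model` with `E_L`, `E_t`, `n_terminals`.
#' @export
elastance_model <- function(E_L = 10, n_terminals) {
  if (E_L <= 0 || n_terminals < 1)
    .stopf("E_L must be positive and n_terminals >= 1")
  structure(list(E_L = E_L, E_t = E_L * n_terminals,
                 n_terminals = as.integer(n_terminals)),
            class = "elastance_model")
}

#' Impedance of a terminal airway
#'
#' `Z_t = Z_a - j E_t / omega` with `omega = 2 pi f`: the branch's
#' Womersley impedance in series with its alveolar (elastic) compartment.
#'
#' @inheritParams branch_impedance
#' @param E_t Terminal-unit elastance, cmH2O/L (>= 0).
#' @return Complex impedance(s) in cmH2O.s/L.
#' @export
terminal_impedance <- function(diameter_mm, length_mm, E_t, frequency,
                               gas = gas_properties()) {
  if (any(E_t < 0)) .stopf("'E_t' must be non-negative")
  branch_impedance(diameter_mm, length_mm, frequency, gas) -
    1i * E_t / (2 * pi * frequency)
}

#' Respiratory-system configuration
#'
#' Series central-airway and chest-wall resistances, chest-wall elastance
#' and an optional upper-airway shunt. The shunt table, if enabled, gives
#' the complex upper-airway impedance `Z_uaw` per frequency; it is
#' interpolated linearly in log-frequency (and linearly extrapolated below
#' the lowest tabulated frequency).
#'
#' @param R_central Central (upper) airway resistance, cmH2O.s/L.
#' @param R_cw Chest-wall resistance, cmH2O.s/L.
#' @param E_cw Chest-wall elastance, cmH2O/L.
#' @param shunt_table Data frame with columns `frequency_hz`, `r_uaw`,
#'   `x_uaw`, or `NULL`.
#' @param shunt_enabled Apply the shunt in [respiratory_impedance()]?
#' @return List of class `respiratory_config`.
#' @export
respiratory_config <- function(R_central = 0.5, R_cw = 0.5, E_cw = 10.6,
                               shunt_table = NULL, shunt_enabled = FALSE) {
  if (R_central < 0 || R_cw < 0) .stopf("resistances must be >= 0")
  if (E_cw < 0) .stopf("'E_cw' must be non-negative")
  if (!is.null(shunt_table)) {
    need <- c("frequency_hz", "r_uaw", "x_uaw")
    if (!all(need %in% names(shunt_table)))
      .stopf("shunt_table needs columns %s", paste(need, collapse = ", "))
    if (is.unsorted(shunt_table$frequency_hz, strictly = TRUE))
      .stopf("shunt_table frequencies must be strictly increasing")
  }
  if (shunt_enabled && is.null(shunt_table))
    .stopf("shunt enabled but no shunt_table supplied")
  structure(list(R_central = R_central, R_cw = R_cw, E_cw = E_cw,
                 shunt_table = shunt_table, shunt_enabled = shunt_enabled),
            class = "respiratory_config")
}

#' Packaged synthetic upper-airway shunt table
#'
#' A literature-plausible, synthetic stand-in for tabulated upper-airway
#' shunt impedance: a resistance-inertance-compliance model (R = 15
#' cmH2O.s/L, C = 0.8 mL/cmH2O, I = 0.01 cmH2O.s^2/L) evaluated on the
#' default frequency grid. Replace with measured values where available.
#'
#' @return Data frame with columns `frequency_hz`, `r_uaw`, `x_uaw`.
#' @export
default_shunt_table <- function() {
  utils::read.csv(system.file("extdata", "zuaw_shunt_synthetic.csv",
                              package = "lungsim", mustWork = TRUE))
}

#' Default oscillation frequency grid (Hz)
#'
#' Eleven frequencies spanning 0.2-32 Hz and containing 0.2, 5 and 20 Hz,
#' the points used for band metrics.
#'
#' @return Numeric vector of frequencies.
#' @export
default_frequencies <- function() c(0.2, 0.5, 1, 2, 5, 8, 12, 16, 20, 24, 32)

# ---- network aggregation -------------------------------------------------

# Branch Womersley impedances for all branches at each frequency.
# Returns an n_branches x n_frequencies complex matrix (cmH2O.s/L).
.branch_za_matrix <- function(branches, frequencies, gas) {
  vapply(frequencies, function(f)
    branch_impedance(branches$diameter_mm, branches$length_mm, f, gas),
    complex(nrow(branches)))
}

# Post-order (generation-descending) parallel/series reduction of the tree
# at one frequency. `za` is the per-branch Womersley impedance vector
# aligned with `branches` rows. Returns Z at the root inlet.
.reduce_tree <- function(branches, za, frequency, E_t) {
  zin <- za
  zin[branches$is_terminal] <- za[branches$is_terminal] -
    1i * E_t / (2 * pi * frequency)
  gens <- sort(unique(branches$generation), decreasing = TRUE)
  for (g in gens[-length(gens)]) {
    child <- branches$generation == g
    y <- 1 / zin[child]
    agg <- rowsum(cbind(Re(y), Im(y)), branches$parent_id[child])
    pidx <- match(as.integer(rownames(agg)), branches$id)
    zin[pidx] <- za[pidx] + 1 / complex(real = agg[, 1], imaginary = agg[, 2])
  }
  zin[match(branches$id[is.na(branches$parent_id)], branches$id)]
}

#' Input impedance of an airway tree at one frequency
#'
#' Lumped-element reduction of the whole tree: each branch contributes its
#' Womersley impedance in series with the parallel combination of its
#' children; terminal branches carry the alveolar elastance of
#' [elastance_model()]. The recursion is evaluated as an iterative
#' generation-by-generation sweep, so 26-generation trees pose no stack
#' issues.
#'
#' @param tree An `airway_tree` (validated structurally on entry).
#' @param frequency Frequency, Hz (> 0).
#' @param gas A [gas_properties()] object.
#' @param elastance An [elastance_model()]; defaults to `E_L = 10` cmH2O/L
#'   spread over the tree's terminals.
#' @return Complex lung input impedance `Z_L` (cmH2O.s/L).
#' @export
input_impedance <- function(tree, frequency, gas = gas_properties(),
                            elastance = NULL) {
  validate_airway_tree(tree)
  if (is.null(elastance))
    elastance <- elastance_model(10, sum(tree$branches$is_terminal))
  za <- branch_impedance(tree$branches$diameter_mm,
                         tree$branches$length_mm, frequency, gas)
  .reduce_tree(tree$branches, za, frequency, elastance$E_t)
}

#' Respiratory-system impedance from lung impedance
#'
#' Adds the series central-airway resistance, chest-wall resistance and
#' chest-wall elastance to the lung impedance:
#' `Z' = Z_L + R_central + R_cw - j E_cw / (2 pi f)`. If the upper-airway
#' shunt is enabled, returns the parallel combination
#' `Z' Z_uaw / (Z' + Z_uaw)` with `Z_uaw` interpolated from the config's
#' shunt table.
#'
#' @param z_lung Complex lung impedance (cmH2O.s/L); may be a vector if
#'   `frequency` is a vector of equal length.
#' @param frequency Frequency (or frequencies), Hz.
#' @param config A [respiratory_config()].
#' @return Complex respiratory-system impedance (cmH2O.s/L).
#' @export
respiratory_impedance <- function(z_lung, frequency,
                                  config = respiratory_config()) {
  if (any(frequency <= 0)) .stopf("'frequency' must be > 0")
  z <- z_lung + config$R_central + config$R_cw -
    1i * config$E_cw / (2 * pi * frequency)
  if (isTRUE(config$shunt_enabled)) {
    st <- config$shunt_table
    if (is.null(st)) .stopf("shunt enabled but no shunt_table supplied")
    r <- .linterp_extrap(log(st$frequency_hz), st$r_uaw, log(frequency))
    xx <- .linterp_extrap(log(st$frequency_hz), st$x_uaw, log(frequency))
    zu <- complex(real = r, imaginary = xx)
    z <- z * zu / (z + zu)
  }
  z
}

#' Impedance spectrum of a tree over a frequency grid
#'
#' Runs [input_impedance()] and [respiratory_impedance()] at every
#' frequency and returns both the lung-only and the respiratory-system
#' stages.
#'
#' @param tree An `airway_tree`.
#' @param frequencies Strictly increasing frequencies in Hz; the default
#'   grid spans 0.2-32 Hz. Frequencies outside `[0.2, 32]` are allowed but
#'   atypical.
#' @param gas,elastance,config See [input_impedance()] and
#'   [respiratory_impedance()].
#' @param za_cache Optional precomputed branch-impedance matrix from
#'   `.branch_za_matrix` (internal fast path used by the cohort pipeline).
#' @return Data frame of class `impedance_spectrum` with columns
#'   `frequency_hz`, `R_lung`, `X_lung`, `R_rs`, `X_rs`.
#' @export
frequency_sweep <- function(tree, frequencies = default_frequencies(),
                            gas = gas_properties(), elastance = NULL,
                            config = respiratory_config(),
                            za_cache = NULL) {
  if (is.unsorted(frequencies, strictly = TRUE))
    .stopf("'frequencies' must be strictly increasing")
  if (any(frequencies <= 0)) .stopf("frequencies must be > 0")
  validate_airway_tree(tree)
  if (is.null(elastance))
    elastance <- elastance_model(10, sum(tree$branches$is_terminal))
  za <- if (is.null(za_cache))
    .branch_za_matrix(tree$branches, frequencies, gas) else za_cache
  zl <- vapply(seq_along(frequencies), function(i)
    .reduce_tree(tree$branches, za[, i], frequencies[i], elastance$E_t),
    complex(1))
  zr <- respiratory_impedance(zl, frequencies, config)
  out <- data.frame(frequency_hz = frequencies,
                    R_lung = Re(zl), X_lung = Im(zl),
                    R_rs = Re(zr), X_rs = Im(zr))
  class(out) <- c("impedance_spectrum", "data.frame")
  out
}

#' Band metrics of an impedance spectrum
#'
#' Point values at 0.2, 5 and 20 Hz, the two frequency-dependence bands
#' `Rrs0.2-5 = Rrs(0.2) - Rrs(5)` and `Rrs5-20 = Rrs(5) - Rrs(20)`, and
#' respiratory elastance `Ers(f) = 2 pi f |Xrs(f)|` at the low frequencies
#' 0.2 and 5 Hz only (where reactance is elastance-dominated; the magnitude
#' makes elastance positive).
#'
#' @param spectrum An `impedance_spectrum` containing 0.2, 5 and 20 Hz.
#' @return Named list of class `impedance_metrics`.
#' @export
derived_metrics <- function(spectrum) {
  at <- function(f) {
    i <- which(abs(spectrum$frequency_hz - f) < 1e-9)
    if (length(i) != 1L)
      .stopf("spectrum must contain frequency %g Hz exactly", f)
    i
  }
  i02 <- at(0.2); i5 <- at(5); i20 <- at(20)
  R <- spectrum$R_rs; X <- spectrum$X_rs
  out <- list(
    `Rrs0.2` = R[i02], Rrs5 = R[i5], Rrs20 = R[i20],
    `Rrs0.2_5` = R[i02] - R[i5], Rrs5_20 = R[i5] - R[i20],
    `Xrs0.2` = X[i02], Xrs5 = X[i5], Xrs20 = X[i20],
    `Ers0.2` = 2 * pi * 0.2 * abs(X[i02]),
    Ers5 = 2 * pi * 5 * abs(X[i5]))
  class(out) <- "impedance_metrics"
  out
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat("Respiratory impedance spectrum (cmH2O.s/L)\n")
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.impedance_metrics <- function(x, ...) {
  cat("Impedance band metrics (cmH2O.s/L; Ers in cmH2O/L)\n")
  v <- unlist(x)
  for (n in names(v)) cat(sprintf("  %-9s %8.4f\n", n, v[[n]]))
  invisible(x)
}

#' @export
plot.impedance_spectrum <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$frequency_hz, x$R_rs, log = "x", type = "b", pch = 16,
                 xlab = "Frequency (Hz)", ylab = "Rrs (cmH2O.s/L)", ...)
  graphics::plot(x$frequency_hz, x$X_rs, log = "x", type = "b", pch = 16,
                 xlab = "Frequency (Hz)", ylab = "Xrs (cmH2O.s/L)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
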