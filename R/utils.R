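# Internal helpers shared across modules.

# 1 cmH2O.s/L expressed in SI acoustic-impedance units (Pa.s/m^3):
# 1 cmH2O = 98.0665 Pa and 1 m^3 = 1000 L.
.PA_S_M3_PER_CMH2O_S_L <- 98066.5

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  invisible(x)
}

# Piecewise-linear interpolation with linear extrapolation beyond the ends
# (stats::approx only offers constant extrapolation).
.linterp_extrap <- function(x, y, xout) {
  if (length(x) == 1L) return(rep(y, length(xout)))
  res <- stats::approx(x, y, xout = xout, rule = 2)$y
  lo <- xout < x[1L]
  hi <- xout > x[length(x)]
  if (any(lo)) {
    s <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    res[lo] <- y[1L] + s * (xout[lo] - x[1L])
  }
  if (any(hi)) {
    n <- length(x)
    s <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    res[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  res
}
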