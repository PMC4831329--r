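# Independent oracles and small fixture builders used across the suite.

# --- complex Bessel J_n via the integral representation -------------------
# J_n(z) = (1/2pi) int_{-pi}^{pi} exp(i (z sin t - n t)) dt. The integrand
# is periodic, so the trapezoid rule converges spectrally; 4000 nodes give
# ~1e-12 for the |z| <= 30 arguments used in tests. Entirely independent
# of the package's power-series/asymptotic evaluation.
oracle_bessel_J <- function(n, z, nodes = 4000L) {
  th <- seq(-pi, pi, length.out = nodes + 1L)[-1L]
  dt <- th[2L] - th[1L]
  vapply(z, function(zz) sum(exp(1i * (zz * sin(th) - n * th))) * dt / (2 * pi),
         complex(1))
}

# Womersley branch impedance evaluated straight from the printed formula
# with the integral-representation Bessel functions (SI -> cmH2O.s/L).
oracle_branch_impedance <- function(diameter_mm, length_mm, frequency,
                                    rho = 1.16, mu = 1.85e-5,
                                    convention = c("sqrt_minus_j", "j_3_2")) {
  convention <- match.arg(convention)
  r <- diameter_mm / 2000
  l <- length_mm / 1000
  alpha <- r * sqrt(2 * pi * rho * frequency / mu)
  z <- if (convention == "sqrt_minus_j") alpha * exp(-1i * pi / 4)
  else alpha * (1i)^(3 / 2)
  bracket <- 1 - 2 * oracle_bessel_J(1, z) / (z * oracle_bessel_J(0, z))
  (1i * 2 * frequency * rho * l / r^2 / bracket) / 98066.5
}

# --- brute-force nodal analysis of a tree network -------------------------
# Unknowns: oscillatory pressure at the root inlet and at the distal
# junction of every non-terminal branch; terminal branches drain to the
# zero-pressure reference through Z_t. Unit flow is injected at the inlet;
# the input impedance is the inlet pressure. Independent of the package's
# generation-sweep reduction.
oracle_input_impedance <- function(tree, frequency, E_L = 10,
                                   gas = gas_properties()) {
  b <- tree$branches
  n_term <- sum(b$is_terminal)
  E_t <- E_L * n_term
  zb <- branch_impedance(b$diameter_mm, b$length_mm, frequency, gas)
  zb[b$is_terminal] <- zb[b$is_terminal] - 1i * E_t / (2 * pi * frequency)
  # node numbering: 1 = inlet; 1 + k for the k-th non-terminal branch
  nonterm <- b$id[!b$is_terminal]
  node_of <- function(id) {
    if (is.na(id)) 1L else 1L + match(id, nonterm)
  }
  n_nodes <- 1L + length(nonterm)
  A <- matrix(0 + 0i, n_nodes, n_nodes)
  rhs <- complex(n_nodes)
  rhs[1L] <- 1 + 0i
  for (i in seq_len(nrow(b))) {
    y <- 1 / zb[i]
    u <- node_of(b$parent_id[i])
    if (b$is_terminal[i]) {
      A[u, u] <- A[u, u] + y
    } else {
      v <- node_of(b$id[i])
      A[u, u] <- A[u, u] + y
      A[v, v] <- A[v, v] + y
      A[u, v] <- A[u, v] - y
      A[v, u] <- A[v, u] - y
    }
  }
  p <- solve(A, rhs)
  p[1L]
}

# --- small tree builders --------------------------------------------------

# Tree from an explicit branch table (fills endpoints consistently along x
# so the stored length equals the endpoint distance).
make_tree <- function(parent_id, diameter_mm, length_mm) {
  n <- length(parent_id)
  id <- seq_len(n)
  generation <- integer(n)
  x0 <- numeric(n); x1 <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(parent_id[i])) {
      generation[i] <- 1L
      x0[i] <- 0
    } else {
      generation[i] <- generation[parent_id[i]] + 1L
      x0[i] <- x1[parent_id[i]]
    }
    x1[i] <- x0[i] + length_mm[i]
  }
  is_terminal <- !(id %in% parent_id)
  structure(list(
    branches = data.frame(
      id = id, parent_id = parent_id, generation = generation,
      diameter_mm = diameter_mm, length_mm = length_mm,
      x0 = x0, y0 = 0, z0 = 0, x1 = x1, y1 = 0, z1 = 0,
      is_terminal = is_terminal),
    root_id = 1L,
    metadata = list(coordinate_frame = "model_mm",
                    scaling = list(), narrowing = list())),
    class = "airway_tree")
}

# Random tree with <= max_branches branches (at most binary), random
# plausible geometry. RNG is the caller's responsibility.
random_tree <- function(max_branches = 15L) {
  n <- sample(2:max_branches, 1L)
  parent <- c(NA_integer_, integer(n - 1L))
  nchild <- integer(n)
  for (i in 2:n) {
    open <- which(nchild[seq_len(i - 1L)] < 2L)
    p <- open[sample.int(length(open), 1L)]
    parent[i] <- p
    nchild[p] <- nchild[p] + 1L
  }
  make_tree(parent,
            diameter_mm = stats::runif(n, 0.5, 12),
            length_mm = stats::runif(n, 2, 40))
}

toy_morphometry_3gen <- function() {
  as_morphometry(data.frame(
    generation = 1:3, branches = c(1L, 2L, 4L),
    terminal_branches = c(0L, 0L, 4L),
    d_mean = c(10, 7, 5), d_max = c(10, 8, 6),
    d_min = c(10, 6, 4), d_std = c(0, 0.5, 0.5)))
}

# Symmetric binary tree of `gens` generations as a morphometry table.
symmetric_morphometry <- function(gens = 4L, d_top = 12) {
  nb <- 2^(seq_len(gens) - 1L)
  d <- d_top * 0.7^(seq_len(gens) - 1L)
  as_morphometry(data.frame(
    generation = seq_len(gens), branches = nb,
    terminal_branches = c(rep(0L, gens - 1L), nb[gens]),
    d_mean = d, d_max = d, d_min = d, d_std = rep(0, gens)))
}

# --- imaging fixtures -----------------------------------------------------

# Cuboid five-plateau cavity image for clustering tests.
plateau_image <- function(noise_sd = 0, seed = 1) {
  dm <- c(34L, 10L, 3L)
  arr <- array(0, dm)
  cavity <- array(FALSE, dm)
  cavity[3:32, 2:9, ] <- TRUE
  levels <- c(10, 30, 50, 70, 90)
  truth <- array(0L, dm)
  for (i in seq_len(5)) {
    xr <- (3 + (i - 1) * 6):(2 + i * 6)
    arr[xr, 2:9, ] <- levels[i]
    truth[xr, 2:9, ] <- i
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    arr <- arr + array(stats::rnorm(prod(dm), 0, noise_sd), dm)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  list(image = volumetric_image(arr, spacing = c(1, 1, 1)),
       cavity = cavity, truth = truth)
}

# Random rigid rotation via QR with positive determinant.
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  r <- qr.Q(qr_d)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}
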