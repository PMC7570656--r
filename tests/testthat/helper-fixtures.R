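# Shared fixtures and independent oracles for the suite.

# 3-factor ESI factor set used throughout (nebulizer / SGT / nozzle voltage)
bbd_factors <- function() {
  factor_set(data.frame(
    name = c("Nebulizer", "SGT", "Nozzle Voltage"),
    units = c("psi", "°C", "V"),
    low = c(40, 300, 700), center = c(50, 350, 1100), high = c(60, 400, 1500)))
}

pbd_factors <- function() {
  factor_set(data.frame(
    name = c("Gas temperature", "Gas flow", "Nebulizer", "SGT", "SGF",
             "Capillary Voltage", "Nozzle Voltage"),
    units = c("°C", "mL/min", "psi", "°C", "mL/min", "V", "V"),
    low = c(250, 4, 30, 200, 6, 3000, 300),
    center = c(300, 7, 45, 250, 9, 3500, 500),
    high = c(350, 10, 60, 300, 12, 4000, 700)))
}

# random nonsingular quadratic in k factors (as an rsm_fit container)
random_quadratic <- function(k = 3, seed = 1) {
  set.seed(seed)
  quadratic_model(b0 = stats::rnorm(1, 0, 10),
                  linear = stats::rnorm(k, 0, 5),
                  quadratic = stats::rnorm(k, 0, 3),
                  interaction = stats::rnorm(k * (k - 1) / 2, 0, 2))
}

# independent Gaussian-elimination solver (oracle for stationary_point;
# no calls to solve())
gauss_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (i in seq_len(n)) {
    p <- which.max(abs(M[i:n, i])) + i - 1
    if (p != i) M[c(i, p), ] <- M[c(p, i), ]
    M[i, ] <- M[i, ] / M[i, i]
    for (j in seq_len(n)[-i]) M[j, ] <- M[j, ] - M[j, i] * M[i, ]
  }
  M[, n + 1]
}

# brute-force grid oracle for the cube-constrained maximum
grid_max <- function(model, step = 0.01) {
  s <- seq(-1, 1, by = step)
  g <- as.matrix(expand.grid(x1 = s, x2 = s, x3 = s))
  v <- predict(model, g)
  i <- which.max(v)
  list(point = g[i, ], value = v[i])
}

# independently-built quadratic model matrix [1, x, x^2, x_i x_j]
quad_mm <- function(X) {
  cbind(1, X, X^2, X[, 1] * X[, 2], X[, 1] * X[, 3], X[, 2] * X[, 3])
}

# Hessian assembled directly from a coefficient set (k = 3)
rsm_hessian_for_test <- function(m) {
  rbind(c(2 * m$quadratic[1], m$interaction[1], m$interaction[2]),
        c(m$interaction[1], 2 * m$quadratic[2], m$interaction[3]),
        c(m$interaction[2], m$interaction[3], 2 * m$quadratic[3]))
}

# exact integral of the Bateman curve over [0, t]
bateman_integral <- function(t, ka, ke, v_over_f, dose_mg) {
  A <- dose_mg * ka / (v_over_f * (ka - ke))
  A * ((1 - exp(-ke * t)) / ke - (1 - exp(-ka * t)) / ka)
}
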