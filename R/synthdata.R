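#' The 17-point blood-sampling grid, in hours
#'
#' 5, 15, 30, 60, 90, 120, 180, 240, 300, 360, 420, 480, 540, 600, 720,
#' 1080 and 1440 minutes converted to hours — the tail-vein sampling
#' schedule of a 24 h rodent PK study.
#'
#' @return Numeric vector of 17 times (h).
#' @export
pk_time_grid <- function() {
  c(5, 15, 30, 60, 90, 120, 180, 240, 300, 360, 420, 480, 540, 600,
    720, 1080, 1440) / 60
}

#' Simulate responses from a quadratic surface on a design
#'
#' Evaluates a known quadratic coefficient set at every coded design
#' point and adds i.i.d. Gaussian noise — ground truth for exercising
#' [fit_quadratic] and [constrained_optimum].
#'
#' @param design a `doe_design`.
#' @param model an `rsm_fit`/[quadratic_model] holding the true
#'   coefficients.
#' @param noise_sd response-unit noise sd (0 gives the exact polynomial).
#' @param seed integer seed; the same seed and design give identical
#'   responses.
#' @return Numeric response vector, one per run.
#' @export
simulate_surface <- function(design, model, noise_sd = 0, seed = 1) {
  stopifnot(inherits(design, "doe_design"), inherits(model, "rsm_fit"))
  fnames <- vapply(design$factors, `[[`, character(1), "name")
  X <- design$runs[, fnames, drop = FALSE]
  stopifnot(ncol(X) == model$k)
  mu <- predict(model, X)
  if (noise_sd > 0) {
    set.seed(seed)
    mu <- mu + stats::rnorm(length(mu), 0, noise_sd)
  }
  mu
}

#' Simulate a calibration table
#'
#' Areas follow `intercept + slope * level` with either constant-sd or
#' proportional-CV Gaussian noise.
#'
#' @param slope,intercept true line (area per ng/mL, area).
#' @param levels concentration levels, ng/mL (> 0).
#' @param reps replicates per level.
#' @param noise `list(type = "constant", sd = ...)` or
#'   `list(type = "proportional", cv = ...)` (cv a fraction).
#' @param seed integer seed.
#' @return Data frame `level_ng_per_ml`, `area` with `reps * length(levels)` rows.
#' @export
simulate_calibration <- function(slope, intercept, levels,
                                 reps = 3,
                                 noise = list(type = "constant", sd = 0),
                                 seed = 1) {
  stopifnot(all(levels > 0))
  lv <- rep(levels, each = reps)
  mu <- intercept + slope * lv
  set.seed(seed)
  area <- switch(noise$type,
    constant = mu + stats::rnorm(length(mu), 0, noise$sd),
    proportional = mu * (1 + stats::rnorm(length(mu), 0, noise$cv)),
    stop("unknown noise type", call. = FALSE))
  data.frame(level_ng_per_ml = lv, area = area)
}

#' Simulate R1/R2/R3 recovery and matrix-effect replicate sets
#'
#' Pure-standard areas (R1) have expectation `intercept + slope * level`;
#' post-extraction-spike areas (R2) are scaled by the true matrix factor
#' µ; pre-extraction-spike areas (R3) by the true recovery ρ on top of
#' µ. So the estimators 100·R2/R1 and 100·R3/R2 target 100 µ and 100 ρ.
#'
#' @param slope,intercept true response line.
#' @param levels QC concentrations (ng/mL).
#' @param rho true extraction recovery in (0, 1].
#' @param mu true matrix factor (> 0; 1 = no matrix effect).
#' @param n replicates per set (default 6).
#' @param noise as in [simulate_calibration].
#' @param seed integer seed.
#' @return Data frame `level_ng_per_ml`, `set` (R1/R2/R3), `replicate`,
#'   `area`.
#' @export
simulate_recovery_sets <- function(slope, intercept, levels,
                                   rho = 1, mu = 1, n = 6,
                                   noise = list(type = "constant", sd = 0),
                                   seed = 1) {
  stopifnot(rho > 0, rho <= 1, mu > 0)
  set.seed(seed)
  rows <- list()
  for (lv in levels) {
    base <- intercept + slope * lv
    for (set_ in c("R1", "R2", "R3")) {
      m <- base * switch(set_, R1 = 1, R2 = mu, R3 = rho * mu)
      a <- switch(noise$type,
        constant = m + stats::rnorm(n, 0, noise$sd),
        proportional = m * (1 + stats::rnorm(n, 0, noise$cv)),
        stop("unknown noise type", call. = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        level_ng_per_ml = lv, set = set_, replicate = seq_len(n), area = a)
    }
  }
  do.call(rbind, rows)
}

#' One-compartment oral-absorption (Bateman) concentration curve
#'
#' \deqn{C(t) = \frac{D\,k_a}{(V/F)(k_a - k_e)}
#'   \left(e^{-k_e t} - e^{-k_a t}\right)}
#' with dose D in mg, V/F in (mg)/(ng/mL) so concentrations come out in
#' ng/mL. The degenerate case \eqn{k_a = k_e} is rejected.
#'
#' @param t times, h.
#' @param ka absorption rate constant, 1/h.
#' @param ke elimination rate constant, 1/h.
#' @param v_over_f apparent volume V/F, (mg)/(ng/mL).
#' @param dose_mg dose, mg.
#' @return Concentrations, ng/mL.
#' @export
bateman <- function(t, ka, ke, v_over_f, dose_mg) {
  stopifnot(ka > 0, ke > 0, v_over_f > 0)
  if (abs(ka - ke) < 1e-12)
    stop("degenerate Bateman curve (ka = ke) is not supported", call. = FALSE)
  dose_mg * ka / (v_over_f * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

#' Simulate a sparse destructive-sampling PK study
#'
#' Each of the `length(time_grid)` timepoints is sampled in
#' `n_per_timepoint` different animals (17 x 3 = 51 animals on the
#' default grid). Per-animal concentrations are the Bateman mean curve
#' times a lognormal deviate \eqn{e^\eta}, \eqn{\eta \sim N(0,
#' \log(1 + cv^2))}, so the multiplicative error has coefficient of
#' variation `residual_cv`. Defaults echo a flavonoid of roughly 3 h
#' half-life dosed at ~69 mg/kg in a 225 g rat.
#'
#' @param ka,ke absorption/elimination rate constants, 1/h.
#' @param v_over_f apparent volume, (mg)/(ng/mL).
#' @param dose_mg dose, mg.
#' @param residual_cv between-animal CV (fraction; 0 = noise free).
#' @param n_per_timepoint animals per timepoint (default 3).
#' @param time_grid sampling times, h (default [pk_time_grid]).
#' @param seed integer seed.
#' @param analyte,arm labels carried into the table.
#' @return Data frame with `time_h`, `animal`, `conc_ng_ml`, `analyte`,
#'   `arm`; the true parameters are attached as `attr(, "truth")`.
#' @export
simulate_pk <- function(ka = 1.5, ke = log(2) / 3, v_over_f = 0.34,
                        dose_mg = 69 * 0.225, residual_cv = 0.1,
                        n_per_timepoint = 3, time_grid = pk_time_grid(),
                        seed = 1, analyte = "hesperidin", arm = "single") {
  mu <- bateman(time_grid, ka, ke, v_over_f, dose_mg)
  set.seed(seed)
  k <- length(time_grid)
  eta <- if (residual_cv > 0)
    stats::rnorm(k * n_per_timepoint, 0, sqrt(log(1 + residual_cv^2)))
  else rep(0, k * n_per_timepoint)
  out <- data.frame(
    time_h = rep(time_grid, each = n_per_timepoint),
    animal = rep(seq_len(n_per_timepoint), times = k),
    conc_ng_ml = rep(mu, each = n_per_timepoint) * exp(eta),
    analyte = analyte, arm = arm, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(ka = ka, ke = ke, v_over_f = v_over_f,
                             dose_mg = dose_mg, residual_cv = residual_cv,
                             n_per_timepoint = n_per_timepoint,
                             time_grid = time_grid, seed = seed,
                             tmax = log(ka / ke) / (ka - ke),
                             t_half = log(2) / ke)
  out
}
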