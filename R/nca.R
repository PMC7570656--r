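#' Construct a concentration-time profile
#'
#' @param times sampling times in hours, strictly increasing, >= 0.
#' @param conc concentrations in ng/mL, >= 0 (`NA` allowed for BLQ
#'   already removed upstream).
#' @param subject_id,analyte,arm identifying labels (`arm` is
#'   `"single"` or `"mixture"` in a two-arm study).
#' @param dose_mg_per_kg,body_weight_kg dose and body weight; `dose_mg`
#'   is their product unless given directly.
#' @param dose_mg absolute dose in mg (overrides the product).
#' @return Object of class `conc_profile`.
#' @export
conc_profile <- function(times, conc, subject_id = "s1",
                         analyte = NA_character_, arm = NA_character_,
                         dose_mg_per_kg = NA_real_, body_weight_kg = 0.225,
                         dose_mg = NULL) {
  times <- as.numeric(times); conc <- as.numeric(conc)
  stopifnot(length(times) == length(conc))
  if (length(times) < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be >= 0", call. = FALSE)
  if (is.null(dose_mg)) dose_mg <- dose_mg_per_kg * body_weight_kg
  structure(list(times = times, conc = conc, subject_id = subject_id,
                 analyte = analyte, arm = arm,
                 dose_mg_per_kg = dose_mg_per_kg,
                 body_weight_kg = body_weight_kg, dose_mg = dose_mg),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("Concentration-time profile %s (%s, %s): %d points, %g-%g h\n",
              x$subject_id, x$analyte, x$arm, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Assemble profiles from a sparse destructive-sampling table
#'
#' In a destructive design each timepoint is measured in a different
#' group of animals (17 timepoints x 3 rats = 51 animals here), so no
#' animal contributes a full curve. Two assembly schemes:
#'
#' * `"mean-profile"`: one composite profile of per-timepoint means
#'   (per-timepoint sds kept in `attr(, "sd")`).
#' * `"pseudo-subject"`: n composite profiles, the i-th concatenating
#'   the i-th animal at every timepoint; requires equal n per timepoint.
#'   This is what allows per-"subject" NCA and between-arm sds.
#'
#' @param records data frame with columns `time_h`, `conc_ng_ml` and
#'   `animal` (replicate index within timepoint); optional `analyte`,
#'   `arm` columns (first value used).
#' @param scheme `"pseudo-subject"` (default) or `"mean-profile"`.
#' @param ... passed to [conc_profile] (dose metadata).
#' @return List of `conc_profile` objects (length n or 1).
#' @export
assemble_profiles <- function(records, scheme = c("pseudo-subject", "mean-profile"),
                              ...) {
  scheme <- match.arg(scheme)
  need <- c("time_h", "conc_ng_ml", "animal")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  analyte <- if ("analyte" %in% names(records)) records$analyte[1] else NA_character_
  arm <- if ("arm" %in% names(records)) records$arm[1] else NA_character_
  times <- sort(unique(records$time_h))
  split_t <- split(records, records$time_h)
  counts <- vapply(split_t, nrow, integer(1))
  if (scheme == "mean-profile") {
    mu <- vapply(split_t, function(d) mean(d$conc_ng_ml), numeric(1))
    sdv <- vapply(split_t, function(d) stats::sd(d$conc_ng_ml), numeric(1))
    p <- conc_profile(times, mu[order(as.numeric(names(mu)))],
                      subject_id = "mean", analyte = analyte, arm = arm, ...)
    attr(p, "sd") <- sdv[order(as.numeric(names(sdv)))]
    return(list(p))
  }
  n <- unique(counts)
  if (length(n) != 1)
    stop("pseudo-subject assembly needs the same number of animals at every timepoint",
         call. = FALSE)
  lapply(seq_len(n), function(i) {
    conc <- vapply(as.character(times), function(tm) {
      d <- split_t[[tm]]
      d$conc_ng_ml[order(d$animal)][i]
    }, numeric(1))
    conc_profile(times, conc, subject_id = paste0("pseudo", i),
                 analyte = analyte, arm = arm, ...)
  })
}

#' Peak of a concentration-time profile
#'
#' @param profile a `conc_profile`.
#' @return List `cmax` (maximum observed concentration) and `tmax` (the
#'   earliest time attaining it). If every concentration is zero a
#'   `no_absorption` flag is set and both values are returned as is.
#' @export
profile_summary <- function(profile) {
  stopifnot(inherits(profile, "conc_profile"))
  conc <- profile$conc
  i <- which.max(conc)              # which.max takes the first maximum
  list(cmax = conc[i], tmax = profile$times[i],
       no_absorption = all(conc == 0, na.rm = TRUE))
}

#' Terminal elimination rate constant by log-linear regression
#'
#' Fits OLS of log concentration on time over a terminal tail of the
#' profile and reports \eqn{\lambda_z} = minus the slope and
#' \eqn{t_{1/2} = \ln 2/\lambda_z}. The default point-selection rule
#' scans every contiguous tail (ending at the last positive
#' concentration) of length >= 3 whose points lie strictly after tmax,
#' and keeps the tail with the largest adjusted R-squared, preferring
#' more points on ties — the "best fit" convention of standard NCA
#' software.
#'
#' @param profile a `conc_profile`.
#' @param selection `"best-adjusted-r2"` (default) or `"manual"`.
#' @param indices for `"manual"`: indices (into the profile) of the
#'   points to regress on.
#' @return List: `lambda_z` (1/h), `t_half` (h), `points` (indices
#'   used), `r2_adj`, `intercept` (log scale).
#' @export
fit_lambda_z <- function(profile, selection = c("best-adjusted-r2", "manual"),
                         indices = NULL) {
  stopifnot(inherits(profile, "conc_profile"))
  selection <- match.arg(selection)
  tm <- profile$times; cc <- profile$conc
  loglm <- function(idx) {
    # closed-form simple regression of log(C) on t (avoids summary.lm's
    # perfect-fit warning on exactly log-linear tails)
    x <- tm[idx]; y <- log(cc[idx])
    n <- length(idx)
    sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    ss_res <- sum((y - mean(y) - sl * (x - mean(x)))^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
    list(lambda_z = -sl, intercept = mean(y) - sl * mean(x),
         r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2), points = idx)
  }
  if (selection == "manual") {
    if (is.null(indices) || length(indices) < 3)
      stop("manual selection needs >= 3 indices", call. = FALSE)
    if (any(cc[indices] <= 0)) stop("selected points must be positive", call. = FALSE)
    res <- loglm(indices)
  } else {
    itmax <- which.max(cc)
    usable <- which(seq_along(cc) > itmax & cc > 0)
    last <- if (length(usable)) max(usable) else 0L
    # contiguous tails ending at the last usable point
    starts <- usable[usable <= last - 2]
    cands <- list()
    for (s in starts) {
      idx <- s:last
      if (all(cc[idx] > 0)) cands[[length(cands) + 1L]] <- loglm(idx)
    }
    if (!length(cands))
      stop("need >= 3 positive concentrations strictly after tmax", call. = FALSE)
    r2s <- vapply(cands, `[[`, numeric(1), "r2_adj")
    ns <- vapply(cands, function(z) length(z$points), numeric(1))
    best <- order(-r2s, -ns)[1]           # ties -> more points
    res <- cands[[best]]
  }
  if (res$lambda_z <= 0)
    stop("terminal phase is not declining: nonpositive lambda_z", call. = FALSE)
  res$t_half <- log(2) / res$lambda_z
  res
}

#' Trapezoidal AUC and AUMC over 0 to t_end
#'
#' Linear-trapezoid area under the concentration and first-moment
#' curves:
#' \deqn{AUC = \sum (t_{i+1}-t_i)(C_i + C_{i+1})/2,\qquad
#'       AUMC = \sum (t_{i+1}-t_i)(t_i C_i + t_{i+1} C_{i+1})/2.}
#' For an oral profile with no sample at t = 0, a C(0) = 0 anchor is
#' prepended (`c0`). The profile must reach `t_end`; if the last sample
#' lies beyond it the curve is linearly interpolated at `t_end`, but no
#' extrapolation past the data is performed. The `"log-down"`
#' alternative uses the log-trapezoid on strictly declining positive
#' segments.
#'
#' @param profile a `conc_profile`.
#' @param t_end end of the integration window, h (default 24).
#' @param method `"linear"` (default) or `"log-down"`.
#' @param c0 concentration assumed at t = 0 when the first sample is
#'   later (default 0; set `NULL` to integrate from the first sample).
#' @return List: `auc_0_t` (ng·h/mL), `aumc_0_t` (ng·h²/mL), `mrt` (h).
#' @export
auc_aumc <- function(profile, t_end = 24, method = c("linear", "log-down"),
                     c0 = 0) {
  stopifnot(inherits(profile, "conc_profile"))
  method <- match.arg(method)
  tm <- profile$times; cc <- profile$conc
  if (!is.null(c0) && tm[1] > 0) { tm <- c(0, tm); cc <- c(c0, cc) }
  if (max(tm) < t_end - 1e-9)
    stop(sprintf("profile ends at %g h, before t_end = %g h (no extrapolation)",
                 max(tm), t_end), call. = FALSE)
  keep <- tm <= t_end + 1e-12
  if (max(tm[keep]) < t_end - 1e-12) {   # interpolate the cut point
    cend <- stats::approx(tm, cc, xout = t_end)$y
    tm <- c(tm[keep], t_end); cc <- c(cc[keep], cend)
  } else {
    tm <- tm[keep]; cc <- cc[keep]
  }
  dt <- diff(tm)
  c1 <- cc[-length(cc)]; c2 <- cc[-1]
  t1 <- tm[-length(tm)]; t2 <- tm[-1]
  if (method == "linear") {
    auc_seg <- dt * (c1 + c2) / 2
    aumc_seg <- dt * (t1 * c1 + t2 * c2) / 2
  } else {
    lin <- c2 >= c1 | c1 <= 0 | c2 <= 0
    auc_seg <- ifelse(lin, dt * (c1 + c2) / 2,
                      dt * (c1 - c2) / log(c1 / c2))
    aumc_seg <- ifelse(lin, dt * (t1 * c1 + t2 * c2) / 2,
                       dt * (t1 * c1 - t2 * c2) / log(c1 / c2) -
                         dt^2 * (c1 - c2) / log(c1 / c2)^2)
  }
  auc <- sum(auc_seg); aumc <- sum(aumc_seg)
  list(auc_0_t = auc, aumc_0_t = aumc,
       mrt = if (auc > 0) aumc / auc else NA_real_, t_end = t_end)
}

#' Apparent clearance and volume of distribution
#'
#' \eqn{CL/F = dose/AUC_{0-t}} and \eqn{V/F = (CL/F)/\lambda_z}, in the
#' (mg)/(ng/mL)/h and (mg)/(ng/mL) unit convention of oral NCA tables
#' (dose in mg over concentration in ng/mL).
#'
#' @param auc_0_t AUC in ng·h/mL (> 0).
#' @param lambda_z terminal rate constant, 1/h (> 0).
#' @param dose_mg dose in mg.
#' @return List `cl_f`, `v_f`.
#' @export
clearance_volume <- function(auc_0_t, lambda_z, dose_mg) {
  if (auc_0_t <= 0) stop("AUC must be positive", call. = FALSE)
  if (lambda_z <= 0) stop("lambda_z must be positive", call. = FALSE)
  cl <- dose_mg / auc_0_t
  list(cl_f = cl, v_f = cl / lambda_z)
}

#' Full noncompartmental analysis of one profile
#'
#' Chains [profile_summary], [fit_lambda_z], [auc_aumc] and
#' [clearance_volume].
#'
#' @param profile a `conc_profile` (with dose metadata for CL/V).
#' @param t_end AUC window end, h.
#' @param ... passed to [auc_aumc].
#' @return A one-row data frame of class `nca_result` with `tmax`,
#'   `cmax`, `lambda_z`, `t_half`, `auc_0_t`, `aumc_0_t`, `mrt`, `cl_f`,
#'   `v_f`, `lambda_z_r2_adj`, `lambda_z_n`.
#' @export
nca <- function(profile, t_end = 24, ...) {
  ps <- profile_summary(profile)
  lz <- fit_lambda_z(profile)
  au <- auc_aumc(profile, t_end = t_end, ...)
  cv <- if (is.finite(profile$dose_mg))
    clearance_volume(au$auc_0_t, lz$lambda_z, profile$dose_mg)
  else list(cl_f = NA_real_, v_f = NA_real_)
  out <- data.frame(subject_id = profile$subject_id, arm = profile$arm,
                    analyte = profile$analyte,
                    tmax = ps$tmax, cmax = ps$cmax,
                    lambda_z = lz$lambda_z, t_half = lz$t_half,
                    auc_0_t = au$auc_0_t, aumc_0_t = au$aumc_0_t,
                    mrt = au$mrt, cl_f = cv$cl_f, v_f = cv$v_f,
                    lambda_z_r2_adj = lz$r2_adj,
                    lambda_z_n = length(lz$points),
                    stringsAsFactors = FALSE)
  class(out) <- c("nca_result", "data.frame")
  out
}

nca_params <- c("t_half", "tmax", "cmax", "auc_0_t", "v_f", "cl_f", "mrt")

#' Per-arm mean ± sd summary of NCA parameters
#'
#' Runs [nca] on every profile and summarizes the seven standard
#' parameters (T1/2, Tmax, Cmax, AUC0-t, V/F, CL/F, MRT) per arm as
#' arithmetic mean and sample sd. With a single profile in an arm the sd
#' is reported as `NA`, not 0.
#'
#' @param profiles list of `conc_profile` objects (their `arm` labels
#'   define the grouping).
#' @param t_end AUC window end, h.
#' @return Data frame with columns `parameter`, `arm`, `mean`, `sd`, `n`.
#' @export
nca_table <- function(profiles, t_end = 24) {
  res <- do.call(rbind, lapply(profiles, nca, t_end = t_end))
  out <- do.call(rbind, lapply(split(res, res$arm), function(d) {
    do.call(rbind, lapply(nca_params, function(p) {
      v <- d[[p]]
      data.frame(parameter = p, arm = d$arm[1], mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  attr(out, "per_profile") <- res
  out
}

#' Compare a PK parameter between two arms with a t-test
#'
#' Two-sided t-test, Welch by default, pooled-variance optionally.
#' Accepts either raw per-profile values (vectors) or printed summary
#' statistics (`mean`, `sd`, `n` lists), so published tables can be
#' compared without the raw data.
#'
#' @param a,b numeric vectors of per-profile parameter values, or lists
#'   `list(mean =, sd =, n =)`.
#' @param var.equal pooled-variance test instead of Welch.
#' @param parameter optional label.
#' @return List: `parameter`, `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`,
#'   `n_b`, `t_statistic`, `df`, `p_value`, `significant` (at 0.05).
#' @export
compare_arms <- function(a, b, var.equal = FALSE, parameter = NA_character_) {
  as_sum <- function(x) {
    if (is.list(x)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(x)))
      list(mean = x$mean, sd = x$sd, n = x$n)
    } else {
      if (length(x) < 2) stop("need n >= 2 per arm", call. = FALSE)
      list(mean = mean(x), sd = stats::sd(x), n = length(x))
    }
  }
  sa <- as_sum(a); sb <- as_sum(b)
  if (sa$n < 2 || sb$n < 2) stop("need n >= 2 per arm", call. = FALSE)
  va <- sa$sd^2; vb <- sb$sd^2
  if (va == 0 && vb == 0 && sa$mean == sb$mean) {
    t <- 0; df <- sa$n + sb$n - 2; p <- 1
  } else if (var.equal) {
    df <- sa$n + sb$n - 2
    sp2 <- ((sa$n - 1) * va + (sb$n - 1) * vb) / df
    t <- (sa$mean - sb$mean) / sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    p <- 2 * stats::pt(-abs(t), df)
  } else {
    se2 <- va / sa$n + vb / sb$n
    t <- (sa$mean - sb$mean) / sqrt(se2)
    df <- se2^2 / ((va / sa$n)^2 / (sa$n - 1) + (vb / sb$n)^2 / (sb$n - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(parameter = parameter,
       mean_a = sa$mean, sd_a = sa$sd, n_a = sa$n,
       mean_b = sb$mean, sd_b = sb$sd, n_b = sb$n,
       t_statistic = t, df = df, p_value = p,
       significant = is.finite(p) && p < 0.05)
}

#' Slope of the concentration decline after Tmax
#'
#' OLS slope of concentration (linear scale, ng/mL) on time over
#' \eqn{[t_{max}, t_{last}]} — a crude descriptor of how steeply the
#' curve falls after the peak.
#'
#' @param profile a `conc_profile`.
#' @return Slope in ng/mL per h.
#' @export
post_tmax_slope <- function(profile) {
  stopifnot(inherits(profile, "conc_profile"))
  i <- which.max(profile$conc)
  idx <- i:length(profile$conc)
  if (length(idx) < 2) stop("need >= 2 points from tmax to the end", call. = FALSE)
  unname(stats::coef(stats::lm(profile$conc[idx] ~ profile$times[idx]))[2])
}
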