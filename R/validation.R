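#' Fit a calibration curve (peak area vs concentration)
#'
#' Unweighted ordinary least squares of peak area on concentration, with
#' Student-t confidence half-widths for slope and intercept, the Pearson
#' correlation, the residual standard deviation \eqn{S_{y,x}} (df = n-2)
#' and, when replicate areas exist at one or more levels, a lack-of-fit
#' F test against pure error. Optional weights (e.g. `1/x`, `1/x^2`) are
#' accepted but off by default — the classical unweighted regression is
#' the reference behaviour.
#'
#' @param levels concentrations (ng/mL); at least 3 distinct values.
#' @param areas peak areas, same length as `levels`.
#' @param alpha confidence level complement for the t intervals (0.05
#'   gives 95% intervals).
#' @param weights optional regression weights.
#' @param analyte optional analyte label carried in the result.
#' @return An object of class `calibration_curve`: `slope`, `intercept`,
#'   `slope_ci_halfwidth`, `intercept_ci_halfwidth`, `r`, `s_yx`, `n`,
#'   `crosses_origin` (TRUE when the intercept interval contains 0),
#'   `lack_of_fit` (list with `f`, `p`, dfs; NULL without replicates).
#' @export
fit_calibration <- function(levels, areas, alpha = 0.05, weights = NULL,
                            analyte = NA_character_) {
  levels <- as.numeric(levels); areas <- as.numeric(areas)
  stopifnot(length(levels) == length(areas))
  if (length(unique(levels)) < 3)
    stop("need at least 3 distinct concentration levels", call. = FALSE)
  if (stats::sd(levels) == 0)
    stop("zero variance in concentration levels", call. = FALSE)
  fit <- stats::lm(areas ~ levels, weights = weights)
  sm <- summary(fit)
  cf <- sm$coefficients
  n <- length(areas)
  tcrit <- stats::qt(1 - alpha / 2, n - 2)
  s_yx <- sm$sigma
  intercept <- cf[1, 1]; slope <- cf[2, 1]
  ihw <- tcrit * cf[1, 2]; shw <- tcrit * cf[2, 2]
  lof <- NULL
  if (anyDuplicated(levels)) {
    grp <- factor(levels)
    ss_pe <- sum(tapply(areas, grp, function(v) sum((v - mean(v))^2)))
    df_pe <- n - nlevels(grp)
    ss_res <- sum(stats::residuals(fit)^2)
    df_res <- n - 2
    df_lof <- df_res - df_pe
    if (df_lof > 0 && df_pe > 0 && ss_pe > 0) {
      f <- (max(ss_res - ss_pe, 0) / df_lof) / (ss_pe / df_pe)
      lof <- list(f = f, p = stats::pf(f, df_lof, df_pe, lower.tail = FALSE),
                  df_lof = df_lof, df_pe = df_pe,
                  ss_lack_of_fit = max(ss_res - ss_pe, 0), ss_pure_error = ss_pe)
    }
  }
  structure(list(analyte = analyte, levels = levels, areas = areas,
                 slope = slope, intercept = intercept,
                 slope_ci_halfwidth = shw, intercept_ci_halfwidth = ihw,
                 r = stats::cor(levels, areas), s_yx = s_yx, n = n,
                 alpha = alpha,
                 crosses_origin = abs(intercept) <= ihw,
                 lack_of_fit = lof),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration%s: area = %.4g + %.4g * conc  (n = %d)\n",
              if (is.na(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              x$intercept, x$slope, x$n))
  cat(sprintf("  b ± t S_b: %.4g ± %.4g | a ± t S_a: %.4g ± %.4g | r = %.4f | S_y,x = %.4g\n",
              x$slope, x$slope_ci_halfwidth, x$intercept,
              x$intercept_ci_halfwidth, x$r, x$s_yx))
  if (x$crosses_origin) cat("  intercept interval crosses the origin\n")
  if (!is.null(x$lack_of_fit))
    cat(sprintf("  lack-of-fit: F = %.3f, p = %.4f\n",
                x$lack_of_fit$f, x$lack_of_fit$p))
  invisible(x)
}

#' Detection and quantification limits from a calibration curve
#'
#' \deqn{L = k \cdot S_{y,x} / b} with k = 3 for the LOD and k = 10 for
#' the LOQ, so LOQ/LOD = 10/3 identically. Concentration limits are also
#' expressed as on-column mass via the injection volume.
#'
#' @param curve a `calibration_curve` (fitted on a low-range curve for
#'   meaningful limits).
#' @param injection_volume_ul injection volume in µL (default 2).
#' @return List: `lod_conc`, `loq_conc` (ng/mL), `lod_mass`, `loq_mass`
#'   (pg), `injection_volume_ul`, `k_lod = 3`, `k_loq = 10`.
#' @export
detection_limits <- function(curve, injection_volume_ul = 2) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop("slope must be positive to compute detection limits", call. = FALSE)
  lod <- 3 * curve$s_yx / curve$slope
  loq <- 10 * curve$s_yx / curve$slope
  list(lod_conc = lod, loq_conc = loq,
       lod_mass = on_column_mass(lod, injection_volume_ul),
       loq_mass = on_column_mass(loq, injection_volume_ul),
       injection_volume_ul = injection_volume_ul,
       k_lod = 3, k_loq = 10)
}

#' Convert a concentration to on-column mass
#'
#' ng/mL times µL gives pg: a 2 µL injection of a 0.4 ng/mL solution
#' loads 0.8 pg on the column.
#'
#' @param conc_ng_ml concentration in ng/mL (>= 0).
#' @param volume_ul injection volume in µL (> 0).
#' @return Mass in pg.
#' @export
on_column_mass <- function(conc_ng_ml, volume_ul) {
  if (any(conc_ng_ml < 0)) stop("concentration must be non-negative", call. = FALSE)
  if (any(volume_ul <= 0)) stop("injection volume must be positive", call. = FALSE)
  conc_ng_ml * volume_ul
}

#' Intra- and inter-day precision and accuracy of QC replicates
#'
#' Precision is the relative standard deviation, RSD = 100 sd/mean
#' (sample sd, n-1), and accuracy is 100 mean/nominal. Intra-day
#' statistics use the replicates of a single day (all replicates of that
#' run, the n = 9 convention for 9 replicates/day); inter-day statistics
#' pool every replicate across days (n = 27 for 3 days of 9).
#'
#' @param measurements numeric matrix of measured concentrations, rows =
#'   days, columns = within-day replicates; or a numeric vector for a
#'   single day.
#' @param nominal nominal (spiked) concentration, ng/mL.
#' @param intra_day which day's replicates define the intra-day run
#'   (default 1).
#' @return List: `intra_rsd`, `inter_rsd`, `intra_accuracy`,
#'   `inter_accuracy` (all percent), `intra_mean`, `inter_mean`,
#'   `n_intra`, `n_inter`.
#' @export
precision_accuracy <- function(measurements, nominal, intra_day = 1) {
  if (is.vector(measurements)) measurements <- matrix(measurements, nrow = 1)
  measurements <- as.matrix(measurements)
  if (any(measurements < 0)) stop("measured concentrations must be >= 0", call. = FALSE)
  if (ncol(measurements) < 2) stop("need >= 2 replicates per day", call. = FALSE)
  intra <- measurements[intra_day, ]
  all_v <- as.vector(measurements)
  rsd <- function(v) {
    m <- mean(v)
    if (m == 0) stop("zero mean: RSD undefined", call. = FALSE)
    100 * stats::sd(v) / m
  }
  list(intra_mean = mean(intra), inter_mean = mean(all_v),
       intra_rsd = rsd(intra), inter_rsd = if (nrow(measurements) >= 2) rsd(all_v) else NA_real_,
       intra_accuracy = 100 * mean(intra) / nominal,
       inter_accuracy = if (nrow(measurements) >= 2) 100 * mean(all_v) / nominal else NA_real_,
       n_intra = length(intra), n_inter = length(all_v),
       nominal = nominal)
}

#' Extraction recovery and matrix effect at one QC level
#'
#' Three peak-area sets enter per level: R1, the pure standard solution;
#' R2, blank matrix extracted and spiked afterwards; R3, matrix spiked
#' before extraction. Then
#' \deqn{recovery = 100\,\bar{R3}/\bar{R2}, \qquad
#'       matrix\ effect = 100\,\bar{R2}/\bar{R1}.}
#' A matrix effect below 85% is classified as ionization suppression,
#' above 115% as enhancement, otherwise none. Replicate RSDs are
#' checked against the 15% acceptance bound.
#'
#' @param r1,r2,r3 numeric replicate peak-area vectors (>= 2 each).
#' @param level QC concentration (ng/mL), carried in the result.
#' @return A one-row data frame of class `matrix_effect_level`:
#'   means and RSDs per set, `recovery`, `matrix_effect`,
#'   `classification`, `rsd_ok`.
#' @export
recovery_matrix_effect <- function(r1, r2, r3, level = NA_real_) {
  sets <- list(r1 = as.numeric(r1), r2 = as.numeric(r2), r3 = as.numeric(r3))
  for (nm in names(sets)) {
    if (length(sets[[nm]]) < 2)
      stop(sprintf("set %s needs >= 2 replicates", toupper(nm)), call. = FALSE)
    if (mean(sets[[nm]]) <= 0)
      stop(sprintf("set %s has non-positive mean", toupper(nm)), call. = FALSE)
  }
  ms <- vapply(sets, mean, numeric(1))
  rsds <- vapply(sets, function(v) 100 * stats::sd(v) / mean(v), numeric(1))
  out <- matrix_effect_from_means(ms[1], ms[2], ms[3], level)
  out$r1_rsd <- rsds[1]; out$r2_rsd <- rsds[2]; out$r3_rsd <- rsds[3]
  out$rsd_ok <- all(rsds <= 15)
  out
}

#' Recovery and matrix effect from set means
#'
#' Same ratios as [recovery_matrix_effect], computed directly from the
#' mean peak areas (as reported in a summary table).
#'
#' @param r1_mean,r2_mean,r3_mean mean peak areas of the three sets.
#' @param level QC concentration (ng/mL).
#' @return One-row data frame of class `matrix_effect_level`.
#' @export
matrix_effect_from_means <- function(r1_mean, r2_mean, r3_mean,
                                     level = NA_real_) {
  if (any(c(r1_mean, r2_mean) <= 0))
    stop("denominator means must be positive", call. = FALSE)
  me <- 100 * r2_mean / r1_mean
  out <- data.frame(level = level,
                    r1_mean = r1_mean, r2_mean = r2_mean, r3_mean = r3_mean,
                    r1_rsd = NA_real_, r2_rsd = NA_real_, r3_rsd = NA_real_,
                    recovery = 100 * r3_mean / r2_mean,
                    matrix_effect = me,
                    classification = if (me < 85) "suppression"
                                     else if (me > 115) "enhancement" else "none",
                    rsd_ok = NA, stringsAsFactors = FALSE)
  class(out) <- c("matrix_effect_level", "data.frame")
  out
}

#' Pool per-level matrix-effect results across QC levels
#'
#' The overall matrix effect (and recovery) is the arithmetic mean ± the
#' sample sd of the per-level percentages. Report tables print integer
#' percentages; `rounded = TRUE` averages those integer percentages
#' instead of the raw ones, reproducing the summary a reader computes
#' from the printed table.
#'
#' @param levels list (or rbind) of `matrix_effect_level` rows.
#' @param rounded average the half-away-from-zero integer-rounded
#'   per-level percentages (default FALSE: raw values).
#' @return List with `matrix_effect_mean`, `matrix_effect_sd`,
#'   `recovery_mean`, `recovery_sd`, `n_levels`.
#' @export
overall_matrix_effect <- function(levels, rounded = FALSE) {
  if (is.data.frame(levels)) df <- levels else df <- do.call(rbind, levels)
  stopifnot(nrow(df) >= 1)
  me <- df$matrix_effect; rec <- df$recovery
  if (rounded) { me <- round_half_up(me, 0); rec <- round_half_up(rec, 0) }
  list(matrix_effect_mean = mean(me),
       matrix_effect_sd = if (nrow(df) > 1) stats::sd(me) else NA_real_,
       recovery_mean = mean(rec),
       recovery_sd = if (nrow(df) > 1) stats::sd(rec) else NA_real_,
       n_levels = nrow(df))
}

#' Half-away-from-zero rounding
#'
#' Report tables round 0.5 away from zero (101.5 -> 102), unlike base
#' `round()`'s half-to-even rule.
#'
#' @param x numeric.
#' @param digits decimal places (default 0).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
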