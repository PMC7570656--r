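#' Estimate two-level main effects
#'
#' For each design column the effect is
#' \deqn{E(X_i) = 2\,(\sum M_{i+} - \sum M_{i-})/N,}
#' where \eqn{M_{i+}} and \eqn{M_{i-}} are the responses of the runs with
#' the factor at its high and low level and \eqn{N} is the number of
#' two-level runs. Center runs are excluded from the computation. On a
#' balanced design this equals the high-level mean minus the low-level
#' mean, and twice the OLS coefficient of the coded column. Dummy-column
#' effects are computed identically and carried along for error
#' estimation.
#'
#' @param design a `doe_design` (typically from [pb_design]).
#' @param response numeric response vector, one value per design run
#'   (peak areas, counts, ...).
#' @return A data frame of class `effect_table` with columns `term`,
#'   `effect`, `is_dummy`, plus attributes used by [rank_effects].
#' @export
estimate_main_effects <- function(design, response) {
  stopifnot(inherits(design, "doe_design"))
  response <- as.numeric(response)
  if (length(response) != nrow(design$runs))
    stop("response length must equal the number of design runs", call. = FALSE)
  keep <- !design$center
  X <- design$runs[keep, , drop = FALSE]
  y <- response[keep]
  n <- nrow(X)
  eff <- vapply(seq_len(ncol(X)), function(j) {
    hi <- X[, j] > 0; lo <- X[, j] < 0
    if (!any(hi) || !any(lo))
      stop(sprintf("column '%s' has only one level present", colnames(X)[j]),
           call. = FALSE)
    2 * (sum(y[hi]) - sum(y[lo])) / n
  }, numeric(1))
  out <- data.frame(term = colnames(X), effect = eff,
                    is_dummy = colnames(X) %in% design$dummy,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_runs") <- n
  attr(out, "center_response") <- response[design$center]
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Standardize, test and rank screening effects
#'
#' Completes an effect table with standard errors, t statistics,
#' two-sided p-values and a Pareto rank (1 = largest absolute
#' standardized effect). Three error-estimation routes are available:
#'
#' * `"lenth"` (default): Lenth's pseudo-standard-error. With effects
#'   \eqn{c_j}, \eqn{s_0 = 1.5\,\mathrm{median}|c_j|} and
#'   \eqn{PSE = 1.5\,\mathrm{median}\{|c_j| : |c_j| < 2.5 s_0\}};
#'   t statistics use \eqn{m/3} degrees of freedom where m is the
#'   number of effect columns. Needs no replication, which is why it is
#'   the default for saturated screening designs.
#' * `"dummy"`: the root-mean-square of the dummy-column effects as the
#'   standard error, with df equal to the number of dummy columns.
#' * `"center"`: standard error from replicated center runs,
#'   \eqn{SE = 2 s_c / \sqrt N} with df = (number of center runs - 1).
#'
#' @param effects an `effect_table` from [estimate_main_effects].
#' @param method error-estimation route, see Details.
#' @param alpha significance level for the threshold line (default 0.05).
#' @return The effect table with `se`, `t`, `p`, `rank` and `significant`
#'   columns, ordered by rank; attributes `threshold` (the critical
#'   absolute effect drawn on a Pareto chart), `df` and `method`. If the
#'   requested error source is unavailable a warning is issued and the
#'   table is returned ranked by magnitude with `se`/`t`/`p` set to `NA`.
#' @references Lenth, R.V. (1989) Quick and easy analysis of unreplicated
#'   factorials. Technometrics 31, 469-473.
#' @export
rank_effects <- function(effects, method = c("lenth", "dummy", "center"),
                         alpha = 0.05) {
  stopifnot(inherits(effects, "effect_table"))
  method <- match.arg(method)
  eff <- effects$effect
  m <- length(eff)
  se <- df <- NA_real_
  if (method == "lenth") {
    if (m < 3) {
      warning("Lenth's method needs at least 3 effect columns; ranking only")
    } else {
      s0 <- 1.5 * stats::median(abs(eff))
      trimmed <- abs(eff)[abs(eff) < 2.5 * s0]
      if (!length(trimmed)) trimmed <- abs(eff)   # all-equal corner case
      se <- 1.5 * stats::median(trimmed)
      df <- m / 3
    }
  } else if (method == "dummy") {
    d <- eff[effects$is_dummy]
    if (!length(d)) {
      warning("no dummy columns available; ranking only")
    } else {
      se <- sqrt(mean(d^2))
      df <- length(d)
    }
  } else { # center
    cr <- attr(effects, "center_response")
    n <- attr(effects, "n_runs")
    if (length(cr) < 2) {
      warning("need at least 2 center replicates; ranking only")
    } else {
      se <- 2 * stats::sd(cr) / sqrt(n)
      df <- length(cr) - 1
    }
  }
  out <- effects
  if (is.finite(se) && se > 0) {
    out$se <- se
    out$t <- eff / se
    out$p <- pmax(2 * stats::pt(-abs(out$t), df), .Machine$double.xmin)
    attr(out, "threshold") <- stats::qt(1 - alpha / 2, df) * se
  } else if (is.finite(se) && se == 0) {
    # error estimate degenerate (e.g. all dummy effects exactly zero):
    # nonzero effects are unboundedly significant
    out$se <- 0
    out$t <- ifelse(eff == 0, 0, sign(eff) * Inf)
    out$p <- ifelse(eff == 0, 1, .Machine$double.xmin)
    attr(out, "threshold") <- 0
  } else {
    out$se <- out$t <- out$p <- NA_real_
    attr(out, "threshold") <- NA_real_
  }
  ord <- order(-abs(if (all(is.na(out$t))) eff else out$t))
  out$rank[ord] <- seq_len(m)
  out$significant <- !is.na(out$p) & out$p < alpha
  attr(out, "df") <- df
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  out[order(out$rank), ]
}
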