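new_doe_design <- function(runs, factors, type, center, dummy = character(0)) {
  structure(list(runs = runs,            # numeric matrix, coded, named cols
                 factors = factors,      # factor_set (real factors only)
                 type = type,            # "pb" or "bbd"
                 center = center,        # logical per row
                 dummy = dummy),         # dummy column names (PB)
            class = "doe_design")
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("%s design: %d runs (%d center), %d factors",
              toupper(x$type), nrow(x$runs), sum(x$center), length(x$factors)))
  if (length(x$dummy)) cat(sprintf(", %d dummy columns", length(x$dummy)))
  cat("\n")
  df <- as.data.frame(x$runs)
  df$center <- x$center
  print(utils::head(df, 20))
  if (nrow(df) > 20) cat("...\n")
  invisible(x)
}

# 12-run Plackett-Burman first row (cyclic generator, N = 12)
pb12_generator <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)

#' Generate a 12-run Plackett-Burman screening design
#'
#' Builds the cyclic 12-run Plackett-Burman base design: the 11-column
#' generator row is cycled to give 11 rows and a final all-low row is
#' appended. The first `k` columns carry the real factors; the remaining
#' `11 - k` columns are kept as dummy (unassigned) columns whose effects
#' estimate experimental error. Optional center runs (all factors at
#' coded 0) can be appended for curvature/pure-error checks.
#'
#' @param factors a `factor_set` of 2 to 11 factors.
#' @param n_center number of center runs to append (default 0).
#' @return A `doe_design` with an 11-column coded run matrix, dummy
#'   column names in `$dummy`, and a logical `$center` flag per run.
#' @examples
#' fs <- factor_set(data.frame(
#'   name = c("SGT", "SGF"), units = c("°C", "mL/min"),
#'   low = c(200, 6), center = c(250, 9), high = c(300, 12)))
#' pb_design(fs, n_center = 3)
#' @export
pb_design <- function(factors, n_center = 0) {
  k <- length(factors)
  if (k < 2) stop("need at least 2 factors", call. = FALSE)
  if (k > 11) stop("the 12-run Plackett-Burman base supports at most 11 factors",
                   call. = FALSE)
  rows <- lapply(0:10, function(s) {
    idx <- ((seq_len(11) - 1 - s) %% 11) + 1
    pb12_generator[idx]
  })
  m <- rbind(do.call(rbind, rows), rep(-1, 11))
  fnames <- vapply(factors, `[[`, character(1), "name")
  dummy <- if (k < 11) paste0("D", seq_len(11 - k)) else character(0)
  colnames(m) <- c(fnames, dummy)
  center <- rep(FALSE, 12)
  if (n_center > 0) {
    m <- rbind(m, matrix(0, n_center, 11))
    center <- c(center, rep(TRUE, n_center))
  }
  rownames(m) <- paste0("run", seq_len(nrow(m)))
  new_doe_design(m, factors, "pb", center, dummy)
}

#' Generate a three-factor Box-Behnken design
#'
#' The 12 edge-midpoint runs place each factor pair at all four
#' \eqn{(\pm 1, \pm 1)} combinations while the third factor sits at its
#' center, plus `n_center` replicated center runs used to estimate pure
#' error. The 12 + 5 layout gives the classical 17-run design.
#'
#' @param factors a `factor_set` of exactly 3 factors.
#' @param n_center number of center replicates (default 5). Fewer than 2
#'   leaves pure error inestimable (a warning is issued).
#' @return A `doe_design`.
#' @export
bbd_design <- function(factors, n_center = 5) {
  if (length(factors) != 3)
    stop("Box-Behnken generator implemented for exactly 3 factors", call. = FALSE)
  if (n_center < 2)
    warning("fewer than 2 center replicates: pure error cannot be estimated")
  pm <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  blocks <- list(cbind(pm[, 1], pm[, 2], 0),
                 cbind(pm[, 1], 0, pm[, 2]),
                 cbind(0, pm[, 1], pm[, 2]))
  m <- do.call(rbind, blocks)
  center <- rep(FALSE, 12)
  if (n_center > 0) {
    m <- rbind(m, matrix(0, n_center, 3))
    center <- c(center, rep(TRUE, n_center))
  }
  colnames(m) <- vapply(factors, `[[`, character(1), "name")
  rownames(m) <- paste0("run", seq_len(nrow(m)))
  new_doe_design(m, factors, "bbd", center)
}

#' Decode a design's coded runs to actual units
#'
#' @param design a `doe_design`.
#' @return Data frame of actual-unit settings for the real factor columns.
#' @export
decode_design <- function(design) {
  stopifnot(inherits(design, "doe_design"))
  fnames <- vapply(design$factors, `[[`, character(1), "name")
  out <- as.data.frame(lapply(seq_along(fnames), function(i)
    decode_factor(design$factors[[i]], design$runs[, fnames[i]])))
  names(out) <- fnames
  out
}
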