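#' Define an experimental factor with coded levels
#'
#' An ESI source factor (or any design factor) is described by its name,
#' units, and the three actual-unit settings mapped to coded levels
#' \eqn{-1}, \eqn{0}, \eqn{+1}. The center need not be the arithmetic
#' midpoint of low and high, so coding is piecewise affine on
#' \eqn{[low, center]} and \eqn{[center, high]}.
#'
#' @param name factor name (e.g. `"Nozzle Voltage"`).
#' @param units unit string (e.g. `"V"`, `"psi"`, `"°C"`).
#' @param low,center,high actual-unit settings for coded -1, 0, +1.
#'   Must satisfy `low < center < high`.
#' @return An object of class `factor_def`.
#' @examples
#' nv <- factor_def("Nozzle Voltage", "V", 700, 1100, 1500)
#' decode_factor(nv, c(-1, 0, 1))
#' @export
factor_def <- function(name, units, low, center, high) {
  stopifnot(is.character(name), length(name) == 1L)
  low <- as.numeric(low); center <- as.numeric(center); high <- as.numeric(high)
  if (!(is.finite(low) && is.finite(center) && is.finite(high)))
    stop("factor levels must be finite numbers", call. = FALSE)
  if (!(low < center && center < high))
    stop(sprintf("factor '%s': need low < center < high (got %g, %g, %g)",
                 name, low, center, high), call. = FALSE)
  structure(list(name = name, units = as.character(units),
                 low = low, center = center, high = high),
            class = "factor_def")
}

#' @export
print.factor_def <- function(x, ...) {
  cat(sprintf("Factor %s [%s]: -1 = %g, 0 = %g, +1 = %g\n",
              x$name, x$units, x$low, x$center, x$high))
  invisible(x)
}

#' Build a set of factors from a data frame
#'
#' @param df data frame with columns `name`, `units`, `low`, `center`, `high`.
#' @return A list of [factor_def] objects, classed `factor_set`.
#' @export
factor_set <- function(df) {
  need <- c("name", "units", "low", "center", "high")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing factor column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    factor_def(df$name[i], df$units[i], df$low[i], df$center[i], df$high[i]))
  names(out) <- df$name
  structure(out, class = "factor_set")
}

#' @export
print.factor_set <- function(x, ...) {
  for (f in x) print(f)
  invisible(x)
}

#' Code actual factor settings to the -1..+1 scale
#'
#' Piecewise-affine coding: `[low, center]` maps onto `[-1, 0]` and
#' `[center, high]` onto `[0, 1]`, so `code_factor` and [decode_factor]
#' are exact inverses on `[low, high]` even when the center is not the
#' midpoint.
#'
#' @param factor a [factor_def].
#' @param x actual-unit values within `[low, high]`.
#' @return Coded values in `[-1, 1]`.
#' @export
code_factor <- function(factor, x) {
  stopifnot(inherits(factor, "factor_def"))
  x <- as.numeric(x)
  if (any(x < factor$low - 1e-9 | x > factor$high + 1e-9, na.rm = TRUE))
    stop(sprintf("value out of range [%g, %g] for factor '%s'",
                 factor$low, factor$high, factor$name), call. = FALSE)
  ifelse(x <= factor$center,
         (x - factor$center) / (factor$center - factor$low),
         (x - factor$center) / (factor$high - factor$center))
}

#' Decode -1..+1 settings back to actual units
#'
#' @inheritParams code_factor
#' @param z coded values in `[-1, 1]`.
#' @return Actual-unit values.
#' @export
decode_factor <- function(factor, z) {
  stopifnot(inherits(factor, "factor_def"))
  z <- as.numeric(z)
  if (any(abs(z) > 1 + 1e-9, na.rm = TRUE))
    stop(sprintf("coded value outside [-1, 1] for factor '%s'", factor$name),
         call. = FALSE)
  ifelse(z <= 0,
         factor$center + z * (factor$center - factor$low),
         factor$center + z * (factor$high - factor$center))
}

#' Decode a coded design point across a factor set
#'
#' @param factors a `factor_set` (or list of [factor_def]).
#' @param z numeric vector of coded coordinates, one per factor.
#' @return Named numeric vector in actual units.
#' @export
decode_point <- function(factors, z) {
  stopifnot(length(factors) == length(z))
  out <- vapply(seq_along(factors), function(i) decode_factor(factors[[i]], z[i]),
                numeric(1))
  names(out) <- vapply(factors, `[[`, character(1), "name")
  out
}
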