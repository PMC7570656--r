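quad_terms <- function(k) {
  # canonical term ordering: intercept, linear, quadratic, interactions (i<j)
  ij <- if (k > 1) utils::combn(k, 2) else matrix(numeric(0), 2, 0)
  list(k = k, pairs = ij)
}

quad_model_matrix <- function(X) {
  k <- ncol(X)
  tt <- quad_terms(k)
  lin <- X
  qd <- X^2
  colnames(qd) <- paste0(colnames(X), "^2")
  int <- if (ncol(tt$pairs)) {
    m <- sapply(seq_len(ncol(tt$pairs)), function(c_) {
      i <- tt$pairs[1, c_]; j <- tt$pairs[2, c_]
      X[, i] * X[, j]
    })
    m <- matrix(m, nrow = nrow(X))
    colnames(m) <- apply(tt$pairs, 2, function(p)
      paste(colnames(X)[p[1]], colnames(X)[p[2]], sep = ":"))
    m
  } else NULL
  cbind(`(Intercept)` = 1, lin, qd, int)
}

#' Construct a quadratic response-surface model from known coefficients
#'
#' Used to hold a published or simulated coefficient set in the same
#' container [fit_quadratic] produces, so it can be passed to
#' [stationary_point], [constrained_optimum] and [predict.rsm_fit].
#'
#' @param b0 intercept.
#' @param linear length-k vector of linear coefficients.
#' @param quadratic length-k vector of pure quadratic coefficients.
#' @param interaction interaction coefficients in column-major
#'   upper-triangle order (x1:x2, x1:x3, x2:x3 for k = 3).
#' @param factors optional `factor_set` for decoding.
#' @return An `rsm_fit` object (without regression diagnostics).
#' @export
quadratic_model <- function(b0, linear, quadratic, interaction,
                            factors = NULL) {
  k <- length(linear)
  stopifnot(length(quadratic) == k, length(interaction) == k * (k - 1) / 2)
  structure(list(b0 = b0, linear = as.numeric(linear),
                 quadratic = as.numeric(quadratic),
                 interaction = as.numeric(interaction),
                 k = k, factors = factors,
                 residual_sd = NA_real_, r2 = NA_real_, r2_adj = NA_real_,
                 anova = NULL),
            class = "rsm_fit")
}

#' Fit the full second-order response-surface model
#'
#' Ordinary least squares of the response on the model matrix
#' \eqn{[1, x_i, x_i^2, x_i x_j]} over the coded design. For a 3-factor
#' Box-Behnken design the model has 10 parameters, so at least 11 runs
#' are required for a residual degree of freedom.
#'
#' @param design a `doe_design` (coded runs).
#' @param response numeric response per run.
#' @return An `rsm_fit`: coefficient blocks (`b0`, `linear`, `quadratic`,
#'   `interaction`), `residual_sd`, `r2`, `r2_adj`, the underlying `lm`
#'   fit, and the design/response for downstream ANOVA.
#' @export
fit_quadratic <- function(design, response) {
  stopifnot(inherits(design, "doe_design"))
  response <- as.numeric(response)
  fnames <- vapply(design$factors, `[[`, character(1), "name")
  X <- design$runs[, fnames, drop = FALSE]
  if (length(response) != nrow(X))
    stop("response length must equal the number of design runs", call. = FALSE)
  k <- ncol(X)
  p <- 1 + 2 * k + k * (k - 1) / 2
  if (nrow(X) < p + 1)
    stop(sprintf("need at least %d runs for the %d-parameter model", p + 1, p),
         call. = FALSE)
  mm <- quad_model_matrix(X)
  if (qr(mm)$rank < ncol(mm))
    stop("singular design: quadratic model matrix is rank deficient",
         call. = FALSE)
  fit <- stats::lm.fit(mm, response)
  cf <- fit$coefficients
  n <- nrow(X)
  rss <- sum(fit$residuals^2)
  tss <- sum((response - mean(response))^2)
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  tt <- quad_terms(k)
  structure(list(
    b0 = unname(cf[1]),
    linear = unname(cf[2:(k + 1)]),
    quadratic = unname(cf[(k + 2):(2 * k + 1)]),
    interaction = unname(cf[-(1:(2 * k + 1))]),
    k = k, factors = design$factors,
    residual_sd = sqrt(rss / (n - p)),
    r2 = r2, r2_adj = r2_adj,
    df_residual = n - p, ss_residual = rss, ss_total = tss,
    fitted = fit$fitted.values, residuals = fit$residuals,
    design = design, response = response,
    anova = NULL), class = "rsm_fit")
}

#' Predict from a quadratic response-surface model
#'
#' @param object an `rsm_fit`.
#' @param newdata matrix or data frame of coded points (k columns), or a
#'   single length-k vector.
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.rsm_fit <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  X <- as.matrix(newdata)
  stopifnot(ncol(X) == object$k)
  tt <- quad_terms(object$k)
  y <- rep(object$b0, nrow(X))
  y <- y + X %*% object$linear + X^2 %*% object$quadratic
  if (ncol(tt$pairs))
    for (c_ in seq_len(ncol(tt$pairs))) {
      i <- tt$pairs[1, c_]; j <- tt$pairs[2, c_]
      y <- y + object$interaction[c_] * X[, i] * X[, j]
    }
  drop(y)
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("Quadratic response-surface model, k = %d\n", x$k))
  cat("  b0:", format(x$b0), "\n")
  cat("  linear:", paste(format(x$linear), collapse = ", "), "\n")
  cat("  quadratic:", paste(format(x$quadratic), collapse = ", "), "\n")
  cat("  interaction:", paste(format(x$interaction), collapse = ", "), "\n")
  if (is.finite(x$r2))
    cat(sprintf("  R2 = %.4f, adj R2 = %.4f, residual sd = %.4g\n",
                x$r2, x$r2_adj, x$residual_sd))
  invisible(x)
}

#' Lack-of-fit ANOVA for a fitted response surface
#'
#' Splits the residual sum of squares into pure error (within the
#' replicated center runs) and lack of fit, and tests lack of fit with
#' an F statistic on (df_lof, df_pe) degrees of freedom. A
#' non-significant lack of fit supports the second-order model.
#'
#' @param fit an `rsm_fit` from [fit_quadratic].
#' @return The `rsm_fit` with an `anova` list: sums of squares
#'   (`ss_regression`, `ss_residual`, `ss_lack_of_fit`, `ss_pure_error`),
#'   degrees of freedom, `f_lack_of_fit`, `p_lack_of_fit` and
#'   `f_undefined` (TRUE when pure error is exactly zero, in which case
#'   no F ratio is formed).
#' @export
anova_quadratic <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  if (is.null(fit$design))
    stop("fit carries no design/response; refit with fit_quadratic", call. = FALSE)
  ctr <- fit$design$center
  if (sum(ctr) < 2)
    stop("pure error needs at least 2 replicated center runs", call. = FALSE)
  yc <- fit$response[ctr]
  ss_pe <- sum((yc - mean(yc))^2)
  df_pe <- sum(ctr) - 1
  ss_res <- fit$ss_residual
  df_res <- fit$df_residual
  ss_lof <- max(ss_res - ss_pe, 0)
  df_lof <- df_res - df_pe
  an <- list(ss_regression = fit$ss_total - ss_res,
             ss_residual = ss_res,
             ss_lack_of_fit = ss_lof, ss_pure_error = ss_pe,
             df_regression = length(fit$linear) * 2 + length(fit$interaction),
             df_residual = df_res, df_lack_of_fit = df_lof, df_pure_error = df_pe,
             f_undefined = FALSE, f_lack_of_fit = NA_real_,
             p_lack_of_fit = NA_real_)
  if (ss_pe == 0) {
    an$f_undefined <- TRUE
  } else if (df_lof > 0) {
    an$f_lack_of_fit <- (ss_lof / df_lof) / (ss_pe / df_pe)
    an$p_lack_of_fit <- stats::pf(an$f_lack_of_fit, df_lof, df_pe,
                                  lower.tail = FALSE)
  }
  fit$anova <- an
  fit
}

rsm_hessian <- function(fit) {
  k <- fit$k
  H <- diag(2 * fit$quadratic, k)
  tt <- quad_terms(k)
  if (ncol(tt$pairs))
    for (c_ in seq_len(ncol(tt$pairs))) {
      i <- tt$pairs[1, c_]; j <- tt$pairs[2, c_]
      H[i, j] <- H[j, i] <- fit$interaction[c_]
    }
  H
}

rsm_gradient <- function(fit, x) {
  drop(rsm_hessian(fit) %*% x) + fit$linear
}

#' Stationary point of a fitted quadratic surface
#'
#' Solves the zero-gradient system \eqn{H x = -b} (H the Hessian with
#' \eqn{2 b_{ii}} on the diagonal and \eqn{b_{ij}} off it) and classifies
#' the critical point from the Hessian eigenvalue signs. A stationary
#' point can lie far outside the explored region, in which case the
#' classification describes the surface, not an attainable setting —
#' use [constrained_optimum] for the operational optimum.
#'
#' @param fit an `rsm_fit`.
#' @return List with `coded_point`, `actual_point` (if the fit carries
#'   factors and the point is inside the region), `classification`
#'   (`"maximum"`, `"minimum"` or `"saddle"`), `inside_region`,
#'   `predicted_response` and the Hessian `eigenvalues`.
#' @export
stationary_point <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  H <- rsm_hessian(fit)
  if (abs(det(H)) < 1e-12 * max(abs(H), 1))
    stop("singular Hessian: the surface has a ridge system, no isolated stationary point",
         call. = FALSE)
  x <- drop(solve(H, -fit$linear))
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  classification <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum" else "saddle"
  inside <- all(abs(x) <= 1 + 1e-9)
  actual <- if (!is.null(fit$factors) && inside) decode_point(fit$factors, x) else NULL
  list(coded_point = x,
       actual_point = actual,
       classification = classification,
       inside_region = inside,
       predicted_response = predict(fit, x),
       eigenvalues = ev)
}

# stationary solution of the quadratic restricted to a face of the cube:
# coordinates in `fixed` are pinned at `vals`, the rest solve the reduced
# zero-gradient system
face_candidate <- function(H, b, fixed, vals, k) {
  x <- numeric(k)
  x[fixed] <- vals
  free <- setdiff(seq_len(k), fixed)
  if (length(free)) {
    Hff <- H[free, free, drop = FALSE]
    rhs <- -(b[free] + H[free, fixed, drop = FALSE] %*% vals)
    sol <- tryCatch(solve(Hff, rhs), error = function(e) NULL)
    if (is.null(sol) || any(abs(sol) > 1)) return(NULL)
    x[free] <- sol
  }
  x
}

#' Constrained optimum of a quadratic over the coded cube
#'
#' Finds the exact global maximum (or minimum) of the fitted quadratic
#' over \eqn{[-1, 1]^k} by enumerating every face of the cube: each of
#' the \eqn{3^k} cells pins a subset of coordinates at \eqn{\pm 1} and
#' solves the reduced stationary system for the free coordinates,
#' keeping solutions that stay inside the face. Because a quadratic
#' restricted to a face is again a quadratic, the global optimum over
#' the compact cube is among these candidates; no iterative descent is
#' involved.
#'
#' @param fit an `rsm_fit`.
#' @param sense `"maximize"` (default) or `"minimize"`.
#' @return List with `coded_point`, `actual_point` (decoded when the fit
#'   carries factors), `predicted_response`, and the unconstrained
#'   [stationary_point] result under `$stationary` (NULL if the Hessian
#'   is singular).
#' @export
constrained_optimum <- function(fit, sense = c("maximize", "minimize")) {
  stopifnot(inherits(fit, "rsm_fit"))
  sense <- match.arg(sense)
  k <- fit$k
  H <- rsm_hessian(fit)
  b <- fit$linear
  states <- expand.grid(rep(list(c(-1, 0, 1)), k))  # 0 = free coordinate
  cand <- list()
  for (r in seq_len(nrow(states))) {
    s <- as.numeric(states[r, ])
    fixed <- which(s != 0)
    x <- face_candidate(H, b, fixed, s[fixed], k)
    if (!is.null(x)) cand[[length(cand) + 1L]] <- x
  }
  # vertices are always included (fixed = all coordinates)
  cand <- do.call(rbind, cand)
  vals <- predict(fit, cand)
  best <- if (sense == "maximize") which.max(vals) else which.min(vals)
  x <- cand[best, ]
  sp <- tryCatch(stationary_point(fit), error = function(e) NULL)
  actual <- if (!is.null(fit$factors)) decode_point(fit$factors, x) else NULL
  list(coded_point = x,
       actual_point = actual,
       predicted_response = vals[best],
       sense = sense,
       stationary = sp)
}
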