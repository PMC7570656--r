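#' Read a delimited table with schema validation
#'
#' Auto-detects comma vs tab delimiting from the header line, checks
#' that required columns are present, and coerces declared numeric
#' columns, reporting the offending row on failure.
#'
#' @param path file path.
#' @param required character vector of required column names.
#' @param numeric_cols columns that must parse as numbers (default: the
#'   required ones that look numeric is not guessed — pass explicitly).
#' @param unique_key optional column whose values must be unique
#'   (e.g. `run_id`).
#' @return Data frame.
#' @export
read_table <- function(path, required = character(0),
                       numeric_cols = character(0), unique_key = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  for (cl in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "")
    if (length(bad))
      stop(sprintf("%s: non-numeric value in column '%s' at data row %d ('%s')",
                   path, cl, bad[1], df[[cl]][bad[1]]), call. = FALSE)
    df[[cl]] <- v
  }
  if (!is.null(unique_key) && unique_key %in% names(df)) {
    dup <- df[[unique_key]][duplicated(df[[unique_key]])]
    if (length(dup))
      stop(sprintf("%s: duplicate %s: %s", path, unique_key,
                   paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a factor-definition CSV
#'
#' Columns `name`, `units`, `low`, `center`, `high`.
#'
#' @param path file path.
#' @return A `factor_set`.
#' @export
read_factors <- function(path) {
  df <- read_table(path, required = c("name", "units", "low", "center", "high"),
                   numeric_cols = c("low", "center", "high"))
  factor_set(df)
}

#' Packaged ESI factor tables
#'
#' The screening (7-factor) and optimization (3-factor) ESI source
#' factor definitions shipped with the package as plain CSV.
#'
#' @param design `"pbd"` (screening) or `"bbd"` (optimization).
#' @return A `factor_set`.
#' @export
esi_factors <- function(design = c("bbd", "pbd")) {
  design <- match.arg(design)
  read_factors(system.file("extdata",
                           paste0("esi_factors_", design, ".csv"),
                           package = "flavopk", mustWork = TRUE))
}

#' Packaged MRM transition metadata
#'
#' Retention segments, precursor/product m/z and voltages per analyte.
#' Stored verbatim as configuration; not used in any computation.
#'
#' @return Data frame.
#' @export
mrm_metadata <- function() {
  read_table(system.file("extdata", "mrm_transitions.csv",
                         package = "flavopk", mustWork = TRUE),
             required = c("compound", "precursor_mz", "product_mz"),
             numeric_cols = c("precursor_mz", "product_mz", "fragmentor_v",
                              "collision_energy_v", "cell_accelerator_v"))
}

#' Render results as report-style tables
#'
#' Formats computed results the way validation/PK reports print them:
#' `"calibration"` (one row per statistic), `"qc"` (precision/accuracy,
#' 2-decimal rounding), `"matrix"` (integer percentages) and `"nca"`
#' (per-arm mean ± sd). Rounding is half-away-from-zero; with
#' `rounding = FALSE` full precision is kept. Rendering is
#' deterministic: identical input gives byte-identical output.
#'
#' @param results the matching result object(s): a list of
#'   `calibration_curve`s, a data frame of QC rows, a data frame of
#'   `matrix_effect_level` rows, or an [nca_table] data frame.
#' @param style one of `"calibration"`, `"qc"`, `"matrix"`, `"nca"`.
#' @param rounding apply the report rounding profile (default TRUE).
#' @param path optional CSV output path.
#' @return The rendered data frame (invisibly when `path` is given).
#' @export
render_report <- function(results, style = c("calibration", "qc", "matrix", "nca"),
                          rounding = TRUE, path = NULL) {
  style <- match.arg(style)
  rnd <- function(x, d) if (rounding) round_half_up(x, d) else x
  out <- switch(style,
    calibration = {
      if (inherits(results, "calibration_curve")) results <- list(results)
      do.call(rbind, lapply(results, function(cv) {
        stopifnot(inherits(cv, "calibration_curve"))
        data.frame(analyte = cv$analyte,
                   slope = rnd(cv$slope, 2), intercept = rnd(cv$intercept, 2),
                   slope_halfwidth = rnd(cv$slope_ci_halfwidth, 2),
                   intercept_halfwidth = rnd(cv$intercept_ci_halfwidth, 2),
                   r = rnd(cv$r, 4), stringsAsFactors = FALSE)
      }))
    },
    qc = {
      stopifnot(is.data.frame(results))
      df <- results
      for (cl in intersect(c("measured", "rsd", "accuracy"), names(df)))
        df[[cl]] <- rnd(df[[cl]], 2)
      df
    },
    matrix = {
      stopifnot(is.data.frame(results))
      data.frame(level = results$level,
                 r1_mean = rnd(results$r1_mean, 0), r1_rsd = rnd(results$r1_rsd, 0),
                 r2_mean = rnd(results$r2_mean, 0), r2_rsd = rnd(results$r2_rsd, 0),
                 r3_mean = rnd(results$r3_mean, 0), r3_rsd = rnd(results$r3_rsd, 0),
                 recovery = rnd(results$recovery, 0),
                 matrix_effect = rnd(results$matrix_effect, 0),
                 stringsAsFactors = FALSE)
    },
    nca = {
      stopifnot(is.data.frame(results),
                all(c("parameter", "arm", "mean", "sd") %in% names(results)))
      df <- results
      df$mean <- rnd(df$mean, 2); df$sd <- rnd(df$sd, 2)
      df
    })
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
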