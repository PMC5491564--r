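#' SD threshold set
#'
#' The single-point SD cutoffs used for fraction tables and colour maps.
#' The defaults 0.07, 0.175, 0.35 and 0.7 mm correspond, through the
#' error-propagation law [sd_to_ci95()], to point-to-point distance 95% CIs
#' of roughly 0.25, 0.5, 1 and 2 mm — 2 mm being the classical acceptable
#' osteometric measurement error.
#'
#' @param cutoffs strictly increasing positive SD values in mm.
#' @export
sd_thresholds <- function(cutoffs = c(0.07, 0.175, 0.35, 0.7)) {
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) < 1 || any(!is.finite(cutoffs)) || any(cutoffs <= 0))
    stop("sd_thresholds: cutoffs must be positive and finite")
  if (any(diff(cutoffs) <= 0))
    stop("sd_thresholds: cutoffs must be strictly increasing")
  structure(cutoffs, class = "sd_thresholds")
}

#' Table of SD threshold fractions per condition
#'
#' One row per condition; columns give the fraction of balanced
#' single-point SD values strictly below each threshold, plus the fraction
#' strictly above the largest threshold.
#'
#' @param rows named list; each element a numeric vector of length
#'   `length(thresholds) + 1` (fractions below each threshold, then the
#'   fraction above the largest).
#' @param thresholds an [sd_thresholds()] object.
#' @return an object of class `result_table` (a data frame).
#' @export
result_table <- function(rows, thresholds = sd_thresholds()) {
  if (length(rows) == 0) stop("result_table: empty table")
  nt <- length(thresholds)
  df <- as.data.frame(do.call(rbind, lapply(names(rows), function(lab) {
    fr <- as.numeric(rows[[lab]])
    if (length(fr) != nt + 1)
      stop(sprintf("result_table: row '%s' must have %d fractions", lab,
                   nt + 1))
    fr
  })))
  names(df) <- c(sprintf("below_%g", as.numeric(thresholds)),
                 sprintf("above_%g", max(thresholds)))
  df <- cbind(condition = names(rows), df)
  rownames(df) <- NULL
  out <- structure(df, class = c("result_table", "data.frame"),
                   thresholds = as.numeric(thresholds))
  validate_result_table(out)
  out
}

validate_result_table <- function(table) {
  nt <- length(attr(table, "thresholds"))
  fr <- as.matrix(table[, -1, drop = FALSE])
  if (any(fr < 0) || any(fr > 1))
    stop("result_table: fractions must lie in [0, 1]")
  below <- fr[, seq_len(nt), drop = FALSE]
  if (nt > 1 && any(t(apply(below, 1, diff)) < -1e-12))
    stop("result_table: fractions must be non-decreasing across thresholds")
  if (any(abs(fr[, nt + 1] - (1 - below[, nt])) > 1e-9))
    stop("result_table: above-fraction must equal 1 - below-largest")
  invisible(table)
}

#' Write a fraction table to CSV or JSON
#'
#' CSV output uses the 3-decimal `.564`-style formatting of fraction
#' tables in the osteometric literature; JSON keeps full precision.
#'
#' @param table a [result_table()].
#' @param path output file.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, format = NULL) {
  validate_result_table(table)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (format == "csv") {
    out <- table
    for (j in seq(2, ncol(out)))
      out[[j]] <- sub("^(-?)0\\.", "\\1.", sprintf("%.3f", out[[j]]))
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else if (format == "json") {
    payload <- list(thresholds = attr(table, "thresholds"),
                    rows = lapply(seq_len(nrow(table)), function(i)
                      c(list(condition = table$condition[i]),
                        as.list(table[i, -1]))))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else stop(sprintf("write_table: unsupported format '%s'", format))
  invisible(path)
}

#' Read a fraction table written by [write_table()] (JSON only, lossless)
#' @param path JSON file path.
#' @export
read_table_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- sd_thresholds(payload$thresholds)
  rows <- payload$rows
  labs <- rows$condition
  fr <- as.matrix(rows[, setdiff(names(rows), "condition"), drop = FALSE])
  lst <- lapply(seq_len(nrow(fr)), function(i) as.numeric(fr[i, ]))
  names(lst) <- labs
  result_table(lst, thr)
}
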