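# CSV interchange format: header names on disk vs. internal column names.
impact_csv_cols <- c(impact_id = "impact_id",
                     linear_acc = "linear_acc_g",
                     rotational_acc = "rotational_acc_rad_s2",
                     label = "label",
                     reassigned = "reassigned")

#' Read an impact table from CSV
#'
#' Expects the header `impact_id,linear_acc_g,rotational_acc_rad_s2,label`
#' (the `label` column may be absent for pure scoring runs; a `reassigned`
#' column and a `cp` score column are accepted). Rows are validated —
#' non-finite or negative accelerations and labels outside \{0, 1\} are
#' rejected with the offending line number — and row order is preserved as
#' the stable tiebreak order downstream.
#'
#' @param path Path to a CSV file.
#' @return Impact data frame (internal column names).
#' @export
read_impact_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(impact_id = "character"))
  required <- impact_csv_cols[c("impact_id", "linear_acc", "rotational_acc")]
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(impact_id = raw[[impact_csv_cols["impact_id"]]],
                    linear_acc = raw[[impact_csv_cols["linear_acc"]]],
                    rotational_acc = raw[[impact_csv_cols["rotational_acc"]]],
                    stringsAsFactors = FALSE)
  has_label <- impact_csv_cols["label"] %in% names(raw)
  if (has_label) out$label <- as.integer(raw[[impact_csv_cols["label"]]])
  if (impact_csv_cols["reassigned"] %in% names(raw)) {
    out$reassigned <- as.integer(raw[[impact_csv_cols["reassigned"]]])
  }
  if ("cp" %in% names(raw)) out$cp <- as.numeric(raw$cp)

  # per-row validation with file line numbers (header is line 1)
  for (col in c("linear_acc", "rotational_acc")) {
    x <- out[[col]]
    bad <- which(!is.finite(x) | x < 0)
    if (length(bad) > 0) {
      stop(sprintf("%s: line %d, column %s: value must be finite and non-negative",
                   path, bad[1] + 1L, impact_csv_cols[col]), call. = FALSE)
    }
  }
  if (has_label) {
    bad <- which(is.na(out$label) | !(out$label %in% c(0L, 1L)))
    if (length(bad) > 0) {
      stop(sprintf("%s: line %d, column label: value must be 0 or 1",
                   path, bad[1] + 1L), call. = FALSE)
    }
  }
  out
}

#' Write an impact table to CSV
#'
#' Inverse of [read_impact_table()]. Numeric columns are written with 17
#' significant digits so the write/read round trip reproduces the doubles
#' exactly.
#'
#' @param impacts Impact data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_impact_table <- function(impacts, path) {
  validate_impacts(impacts, require_label = FALSE)
  out <- impacts
  known <- names(impact_csv_cols)
  names(out)[match(known, names(out), nomatch = 0)] <-
    impact_csv_cols[known[known %in% names(out)]]
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write risk coefficients as flat key-value text
#'
#' Serialization used by the command-line pipeline: one `key = value` line
#' per field (`beta0..beta3`, `se0..se3`, `n`, `log_likelihood`), full
#' double precision.
#'
#' @param coeffs A [risk_coefficients()] object.
#' @param path File path.
#' @return `write_coefficients()` returns `path` invisibly;
#'   `read_coefficients()` returns a [risk_coefficients()] object.
#' @name coefficient_io
NULL

#' @rdname coefficient_io
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "risk_coefficients"))
  vals <- c(as.list(coeffs$beta),
            if (!is.null(coeffs$se)) as.list(coeffs$se),
            list(n = coeffs$n, log_likelihood = coeffs$log_likelihood))
  lines <- vapply(names(vals), function(k) {
    sprintf("%s = %s", k, formatC(as.numeric(vals[[k]]), digits = 17,
                                  format = "g"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname coefficient_io
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad) > 0) {
    stop(path, ": malformed line ", bad[1], call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, character(1), 2L)))
  names(vals) <- keys
  needed <- paste0("beta", 0:3)
  if (!all(needed %in% keys)) {
    stop(path, ": missing coefficient(s): ",
         paste(setdiff(needed, keys), collapse = ", "), call. = FALSE)
  }
  se <- if (all(paste0("se", 0:3) %in% keys)) {
    unname(vals[paste0("se", 0:3)])
  }
  risk_coefficients(vals[["beta0"]], vals[["beta1"]], vals[["beta2"]],
                    vals[["beta3"]], se = se,
                    n = if ("n" %in% keys) vals[["n"]] else NA_integer_,
                    log_likelihood = if ("log_likelihood" %in% keys) {
                      vals[["log_likelihood"]]
                    } else NA_real_)
}

#' Write the underreporting-adjustment report as JSON
#'
#' @param adjusted An `adjusted_dataset` from
#'   [adjust_for_underreporting()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adjustment_report <- function(adjusted, path) {
  stopifnot(inherits(adjusted, "adjusted_dataset"))
  if (is.null(adjusted$report)) {
    stop("adjusted dataset carries no report (was it produced by ",
         "adjust_for_underreporting()?)", call. = FALSE)
  }
  jsonlite::write_json(adjusted$report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
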