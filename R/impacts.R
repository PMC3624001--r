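#' Construct an impact dataset
#'
#' Builds the canonical impact data frame used throughout the package: one
#' row per head impact with peak resultant kinematics and an optional
#' concussion label.
#'
#' @param linear_acc Numeric vector of peak resultant linear accelerations
#'   (g). Must be finite and non-negative.
#' @param rotational_acc Numeric vector of peak resultant rotational
#'   accelerations (rad/s^2). Must be finite and non-negative.
#' @param label Optional integer vector of concussion labels
#'   (1 = concussive, 0 = sub-concussive).
#' @param impact_id Optional character vector of identifiers; generated as
#'   `"imp-<row>"` when omitted.
#' @return A data frame with columns `impact_id`, `linear_acc`,
#'   `rotational_acc` and, when labels are given, `label`.
#' @export
impact_data <- function(linear_acc, rotational_acc, label = NULL,
                        impact_id = NULL) {
  n <- length(linear_acc)
  if (length(rotational_acc) != n) {
    stop("linear_acc and rotational_acc must have the same length",
         call. = FALSE)
  }
  if (is.null(impact_id)) {
    impact_id <- sprintf("imp-%d", seq_len(n))
  }
  out <- data.frame(
    impact_id = as.character(impact_id),
    linear_acc = as.numeric(linear_acc),
    rotational_acc = as.numeric(rotational_acc),
    stringsAsFactors = FALSE
  )
  if (!is.null(label)) out$label <- as.integer(label)
  validate_impacts(out, require_label = !is.null(label))
  out
}

# Shared validation for impact data frames. `where` prefixes error messages
# so file readers can point at the offending line.
validate_impacts <- function(impacts, require_label = TRUE, where = NULL) {
  prefix <- if (is.null(where)) "" else paste0(where, ": ")
  needed <- c("impact_id", "linear_acc", "rotational_acc")
  missing_cols <- setdiff(needed, names(impacts))
  if (length(missing_cols) > 0) {
    stop(prefix, "missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("linear_acc", "rotational_acc")) {
    x <- impacts[[col]]
    bad <- which(!is.finite(x) | x < 0)
    if (length(bad) > 0) {
      stop(prefix, "column ", col, " must be finite and non-negative (first ",
           "offending row ", bad[1], ")", call. = FALSE)
    }
  }
  if (require_label || "label" %in% names(impacts)) {
    if (!"label" %in% names(impacts)) {
      stop(prefix, "missing column: label", call. = FALSE)
    }
    lab <- impacts$label
    bad <- which(is.na(lab) | !(lab %in% c(0L, 1L)))
    if (length(bad) > 0) {
      stop(prefix, "column label must be 0 or 1 (first offending row ",
           bad[1], ")", call. = FALSE)
    }
  }
  invisible(impacts)
}
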