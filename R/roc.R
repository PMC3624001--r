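check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length", call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  invisible(NULL)
}

#' Empirical ROC curve
#'
#' Sweeps every distinct score as a "score >= threshold implies positive"
#' rule. Tied scores collapse to a single vertex, so the trapezoidal area
#' under this curve equals the Mann-Whitney AUC with half-credit for ties.
#' The (0, 0) endpoint (threshold `Inf`) is prepended and the curve always
#' ends at (1, 1).
#'
#' @param scores Real-valued predictor, higher = more concussion-like.
#' @param labels Binary outcome (1 = concussive).
#' @param predictor_name Optional label carried in the result.
#' @return An object of class `roc_curve`: data frame with columns
#'   `threshold` (descending), `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels, predictor_name = "score") {
  check_scores_labels(scores, labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)   # last index of each tied block
  tpr <- cumsum(y)[keep] / n_pos
  fpr <- cumsum(1 - y)[keep] / n_neg
  out <- data.frame(threshold = c(Inf, s[keep]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  structure(out, class = c("roc_curve", "data.frame"),
            predictor_name = predictor_name)
}

#' Trapezoidal area under an ROC curve
#'
#' @param curve A [roc_curve()] object.
#' @return Area in `[0, 1]`.
#' @export
roc_area <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  k <- nrow(curve)
  sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-k]) / 2)
}

#' AUC with Hanley-McNeil standard error
#'
#' The AUC is the Mann-Whitney probability that a random concussive impact
#' outscores a random sub-concussive one (ties count 1/2), computed from
#' mid-ranks. The standard error uses the Hanley-McNeil exponential
#' approximation with moments `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`:
#' \deqn{SE^2 = [A(1-A) + (n^+ - 1)(Q_1 - A^2) + (n^- - 1)(Q_2 - A^2)] /
#' (n^+ n^-)}
#' The 95% confidence interval is `A +/- 1.96 SE`, clipped to `[0, 1]`.
#'
#' @inheritParams roc_curve
#' @return An object of class `auc_result`: list with `auc`, `se`, `ci95`,
#'   `n_pos`, `n_neg`, `q1`, `q2`, `predictor_name`.
#' @export
auc <- function(scores, labels, predictor_name = "score") {
  check_scores_labels(scores, labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  a <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  v <- (a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
    (n_pos * n_neg)
  se <- sqrt(max(v, 0))
  ci <- c(max(0, a - 1.96 * se), min(1, a + 1.96 * se))
  structure(
    list(auc = a, se = se, ci95 = ci, n_pos = n_pos, n_neg = n_neg,
         q1 = q1, q2 = q2, predictor_name = predictor_name),
    class = "auc_result"
  )
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("%s: AUC = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], n+ = %d, n- = %d\n",
              x$predictor_name, x$auc, x$se, x$ci95[1], x$ci95[2],
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Test an AUC against chance
#'
#' Normal z-test of the AUC against 0.5 (random guessing):
#' `z = (AUC - 0.5)/SE`, two-sided p-value.
#'
#' @param result An [auc()] result.
#' @return List with `z`, `p`, and `degenerate` (TRUE when SE = 0 and the
#'   p-value is reported at machine epsilon).
#' @export
test_vs_chance <- function(result) {
  stopifnot(inherits(result, "auc_result"))
  if (result$se == 0) {
    if (result$auc == 0.5) {
      stop("test undefined: SE = 0 with AUC = 0.5", call. = FALSE)
    }
    return(list(z = sign(result$auc - 0.5) * Inf, p = .Machine$double.eps,
                degenerate = TRUE))
  }
  z <- (result$auc - 0.5) / result$se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Compare two correlated AUCs measured on the same impacts
#'
#' Hanley-style z-test for two predictors scored on the same cases:
#' `z = (A1 - A2) / sqrt(SE1^2 + SE2^2 - 2 r SE1 SE2)`, where `r` is the
#' average of the within-positive and within-negative Pearson correlations
#' of the paired scores. A within-class correlation that is undefined
#' (constant scores) contributes 0. When both AUCs are equal and the
#' variance of the difference vanishes (e.g. a predictor compared with
#' itself), z = 0 and p = 1.
#'
#' @param scores1,scores2 Paired predictor scores on the same impacts, in
#'   the same order.
#' @param labels Shared binary outcome.
#' @return List with `z`, `p`, `auc1`, `auc2`, `r`.
#' @export
compare_auc_correlated <- function(scores1, scores2, labels) {
  if (length(scores1) != length(scores2)) {
    stop("paired score vectors must have the same length", call. = FALSE)
  }
  check_scores_labels(scores1, labels)
  check_scores_labels(scores2, labels)
  a1 <- auc(scores1, labels)
  a2 <- auc(scores2, labels)
  pos <- labels == 1L
  r_pos <- suppressWarnings(stats::cor(scores1[pos], scores2[pos]))
  r_neg <- suppressWarnings(stats::cor(scores1[!pos], scores2[!pos]))
  if (is.na(r_pos)) r_pos <- 0
  if (is.na(r_neg)) r_neg <- 0
  r <- (r_pos + r_neg) / 2
  v <- a1$se^2 + a2$se^2 - 2 * r * a1$se * a2$se
  d <- a1$auc - a2$auc
  if (v <= 0) {
    if (abs(d) < 1e-12) {
      return(list(z = 0, p = 1, auc1 = a1$auc, auc2 = a2$auc, r = r))
    }
    stop("variance of the AUC difference is not positive", call. = FALSE)
  }
  z <- d / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), auc1 = a1$auc, auc2 = a2$auc,
       r = r)
}

#' False positive rate at a required sensitivity
#'
#' Smallest false positive rate among ROC operating points whose true
#' positive rate meets the target — the conservative step-function
#' convention, with no interpolation between operating points.
#'
#' @param curve A [roc_curve()] object.
#' @param tpr_target Required true positive rate in (0, 1].
#' @return False positive rate at the cheapest qualifying operating point.
#' @export
fpr_at_tpr <- function(curve, tpr_target) {
  stopifnot(inherits(curve, "roc_curve"))
  if (!is.finite(tpr_target) || tpr_target <= 0 || tpr_target > 1) {
    stop("tpr_target must lie in (0, 1]", call. = FALSE)
  }
  min(curve$fpr[curve$tpr >= tpr_target - 1e-12])
}

#' Severity subset of an impact dataset
#'
#' Keeps every concussive impact plus the top `fraction` of sub-concussive
#' impacts ranked by peak linear acceleration (the severity gauge). The
#' cut is the `(1 - fraction)` empirical quantile of the sub-concussive
#' linear accelerations; ties at the cut are kept.
#'
#' @param impacts Labelled impact data frame.
#' @param fraction Proportion of sub-concussive exposure to keep, in
#'   (0, 1].
#' @return The subset, rows in original order.
#' @export
top_fraction_subset <- function(impacts, fraction) {
  validate_impacts(impacts, require_label = TRUE)
  if (nrow(impacts) == 0) stop("empty dataset", call. = FALSE)
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  sub <- impacts$label == 0L
  if (!any(sub) || fraction == 1) return(impacts)
  cut <- stats::quantile(impacts$linear_acc[sub], probs = 1 - fraction,
                         names = FALSE, type = 7)
  keep <- !sub | impacts$linear_acc >= cut
  impacts[keep, , drop = FALSE]
}
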