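#' Risk-curve coefficients
#'
#' Container for the four coefficients of the combined-probability risk
#' function: intercept, linear-acceleration term (per g),
#' rotational-acceleration term (per rad/s^2) and the interaction term
#' (per g.rad/s^2).
#'
#' @param beta0,beta1,beta2,beta3 Finite numeric coefficients.
#' @param se Optional numeric vector of four standard errors.
#' @param n Number of impacts the coefficients were fitted on.
#' @param log_likelihood Maximised log-likelihood of the fit.
#' @return An object of class `risk_coefficients`.
#' @seealso [published_coefficients()] for the published values.
#' @export
risk_coefficients <- function(beta0, beta1, beta2, beta3, se = NULL,
                              n = NA_integer_, log_likelihood = NA_real_) {
  beta <- c(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3)
  if (!all(is.finite(beta))) {
    stop("all four coefficients must be finite", call. = FALSE)
  }
  if (!is.null(se)) {
    stopifnot(length(se) == 4L, all(is.finite(se)), all(se >= 0))
    names(se) <- c("se0", "se1", "se2", "se3")
  }
  structure(
    list(beta = beta, se = se, n = as.integer(n),
         log_likelihood = log_likelihood),
    class = "risk_coefficients"
  )
}

#' @export
print.risk_coefficients <- function(x, ...) {
  cat("Combined-probability risk coefficients\n")
  tab <- data.frame(estimate = x$beta)
  if (!is.null(x$se)) tab$std_error <- unname(x$se)
  print(format(tab, digits = 6))
  if (!is.na(x$n)) cat("n =", x$n, "\n")
  if (!is.na(x$log_likelihood)) {
    cat("log-likelihood =", format(x$log_likelihood, digits = 8), "\n")
  }
  invisible(x)
}

#' Published combined-probability coefficients
#'
#' The fitted coefficients of the combined-probability risk curve derived
#' from instrumented-football head-impact data after underreporting
#' adjustment: intercept -10.2, 0.0433 per g, 0.000873 per rad/s^2 and
#' -9.20e-7 on the product term.
#'
#' @return A [risk_coefficients()] object.
#' @export
published_coefficients <- function() {
  risk_coefficients(beta0 = -10.2, beta1 = 0.0433, beta2 = 0.000873,
                    beta3 = -0.000000920)
}

#' Combined probability of concussion
#'
#' Evaluates the risk function
#' \deqn{CP = 1 / (1 + e^{-(\beta_0 + \beta_1 a + \beta_2 \alpha +
#' \beta_3 a \alpha)})}
#' where `a` is peak resultant linear acceleration (g) and `alpha` is peak
#' resultant rotational acceleration (rad/s^2). The logistic is evaluated
#' through [stats::plogis()], which is numerically stable for large logit
#' magnitudes in either direction.
#'
#' @param coeffs A [risk_coefficients()] object.
#' @param linear_acc Peak linear acceleration(s), g; finite, non-negative.
#' @param rotational_acc Peak rotational acceleration(s), rad/s^2; finite,
#'   non-negative. Recycled against `linear_acc`.
#' @return Probabilities strictly inside (0, 1).
#' @examples
#' combined_probability(published_coefficients(), 100, 5000)
#' @export
combined_probability <- function(coeffs, linear_acc, rotational_acc) {
  stopifnot(inherits(coeffs, "risk_coefficients"))
  if (any(!is.finite(linear_acc)) || any(linear_acc < 0)) {
    stop("linear_acc must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(rotational_acc)) || any(rotational_acc < 0)) {
    stop("rotational_acc must be finite and non-negative", call. = FALSE)
  }
  b <- coeffs$beta
  eta <- b[1] + b[2] * linear_acc + b[3] * rotational_acc +
    b[4] * linear_acc * rotational_acc
  p <- stats::plogis(eta)
  # the logistic is strictly inside (0,1); at extreme logits the double
  # rounds onto a boundary, so return the nearest representable interior
  # value instead
  p <- pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
  unname(p)
}

# log-likelihood of a logistic model, stable for large |eta|:
# log(1 + e^eta) = max(eta, 0) + log1p(e^{-|eta|}).
logistic_loglik <- function(y, eta) {
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

#' Fit the combined-probability risk model
#'
#' Maximum-likelihood logistic regression of the concussion label on
#' linear acceleration, rotational acceleration and their product, with
#' intercept, fitted by iteratively reweighted least squares (IRLS). Each
#' IRLS step is guarded by step-halving so the log-likelihood never
#' decreases; standard errors come from the observed information matrix at
#' the optimum.
#'
#' @param impacts Labelled impact data frame (see [impact_data()]); both
#'   classes must be present.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   update (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @return A [risk_coefficients()] object with standard errors, sample
#'   size, log-likelihood, and attributes `iterations`, `loglik_trace` and
#'   `converged`.
#' @export
fit_risk_model <- function(impacts, tol = 1e-8, max_iter = 100L) {
  validate_impacts(impacts, require_label = TRUE)
  y <- impacts$label
  if (length(unique(y)) < 2L) {
    stop("both concussive and sub-concussive impacts are required",
         call. = FALSE)
  }
  a <- impacts$linear_acc
  r <- impacts$rotational_acc
  if (stats::sd(a) == 0 || stats::sd(r) == 0) {
    stop("degenerate constant predictor", call. = FALSE)
  }
  X <- cbind(1, a, r, a * r)
  n <- length(y)

  p0 <- min(max(mean(y), 1e-8), 1 - 1e-8)
  beta <- c(stats::qlogis(p0), 0, 0, 0)
  eta <- drop(X %*% beta)
  ll <- logistic_loglik(y, eta)
  trace <- ll
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    fit <- stats::lm.fit(X * sw, z * sw)
    beta_prop <- unname(fit$coefficients)
    if (any(!is.finite(beta_prop))) {
      stop_fit_error("IRLS produced non-finite coefficients", beta, trace)
    }
    # step-halve until the log-likelihood does not decrease
    step <- beta_prop - beta
    h <- 1
    repeat {
      beta_new <- beta + h * step
      eta_new <- drop(X %*% beta_new)
      ll_new <- logistic_loglik(y, eta_new)
      if (ll_new >= ll - 1e-12 || h < 1e-8) break
      h <- h / 2
    }
    # separation: coefficients diverging on the working scale, or the
    # likelihood saturating at a perfect fit
    if (any(abs(beta_new) > 1e3) || ll_new > -1e-6) {
      stop(errorCondition(
        paste("complete separation suspected: coefficients diverge and the",
              "maximum likelihood does not exist"),
        class = c("cprisk_separation_error", "error", "condition"),
        last_coefficients = beta_new
      ))
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- eta_new
    ll <- ll_new
    trace <- c(trace, ll)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop_fit_error(sprintf("IRLS did not converge in %d iterations",
                           max_iter), beta, trace)
  }

  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  covb <- tryCatch(solve(info), error = function(e) {
    stop_fit_error("observed information matrix is singular", beta, trace)
  })
  se <- sqrt(diag(covb))

  out <- risk_coefficients(beta[1], beta[2], beta[3], beta[4], se = se,
                           n = n, log_likelihood = ll)
  attr(out, "iterations") <- iter
  attr(out, "loglik_trace") <- trace
  attr(out, "converged") <- TRUE
  out
}

stop_fit_error <- function(msg, beta, trace) {
  stop(errorCondition(
    msg,
    class = c("cprisk_fit_error", "error", "condition"),
    last_coefficients = beta,
    loglik_trace = trace
  ))
}

#' Constant-risk contour of the combined-probability surface
#'
#' For each linear acceleration `a` on a grid, solves the logit equation
#' `beta0 + beta1*a + beta2*alpha + beta3*a*alpha = logit(risk_level)` for
#' the rotational acceleration `alpha` in closed form (the model is linear
#' in `alpha` at fixed `a`). Grid points with negative or non-finite
#' solutions are dropped; a grid point where the denominator
#' `beta2 + beta3*a` vanishes is skipped with a message.
#'
#' @param coeffs A [risk_coefficients()] object.
#' @param risk_level Target probability, strictly inside (0, 1).
#' @param linear_range Interval of linear accelerations (g) to sweep.
#' @param n_points Number of grid points.
#' @return An object of class `risk_contour`: list with `risk_level` and a
#'   data frame `points` (`linear_acc`, `rotational_acc`) in ascending
#'   `linear_acc` order.
#' @export
risk_contour <- function(coeffs, risk_level, linear_range = c(0, 250),
                         n_points = 200L) {
  stopifnot(inherits(coeffs, "risk_coefficients"))
  if (!is.finite(risk_level) || risk_level <= 0 || risk_level >= 1) {
    stop("risk_level must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (length(linear_range) != 2L || diff(linear_range) <= 0 ||
      any(linear_range < 0)) {
    stop("linear_range must be a positive, increasing interval",
         call. = FALSE)
  }
  b <- coeffs$beta
  target <- stats::qlogis(risk_level)
  a <- seq(linear_range[1], linear_range[2], length.out = n_points)
  denom <- b[3] + b[4] * a
  degenerate <- denom == 0
  if (any(degenerate)) {
    message(sum(degenerate), " grid point(s) skipped: beta2 + beta3*a = 0")
  }
  alpha <- ifelse(degenerate, NA_real_, (target - b[1] - b[2] * a) / denom)
  keep <- is.finite(alpha) & alpha >= 0
  structure(
    list(risk_level = risk_level,
         points = data.frame(linear_acc = a[keep],
                             rotational_acc = alpha[keep])),
    class = "risk_contour"
  )
}

#' @export
print.risk_contour <- function(x, ...) {
  cat(sprintf("Risk contour at CP = %g (%d points)\n", x$risk_level,
              nrow(x$points)))
  invisible(x)
}
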