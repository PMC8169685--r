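# GloSensor cAMP dose-response analysis: per-experiment normalization to the
# maximum average luminescence, and logistic curve fitting reporting
# pEC50/pIC50 with uncertainties.

#' Normalize luminescence readings within each experiment
#'
#' Every reading is divided by the maximum, over doses, of the per-dose mean
#' luminescence within its experiment, so the best-responding dose level has
#' mean 1. The operation is idempotent.
#'
#' @param readings data.frame with columns `experiment`, `dose_M` and
#'   `luminescence` (a `well` column is carried through if present).
#' @return the same data.frame with `luminescence` replaced by its normalized
#'   value.
#' @export
normalize_luminescence <- function(readings) {
  req <- c("experiment", "dose_M", "luminescence")
  if (!is.data.frame(readings) || !all(req %in% names(readings)))
    .stop_fmt("`readings` needs columns %s", paste(req, collapse = ", "))
  if (nrow(readings) == 0L) .stop_fmt("no readings")
  out <- readings
  for (ex in unique(readings$experiment)) {
    rows <- readings$experiment == ex
    dose_means <- tapply(readings$luminescence[rows], readings$dose_M[rows], mean)
    mx <- max(dose_means)
    if (!is.finite(mx) || mx <= 0)
      .stop_fmt("degenerate experiment '%s': maximum per-dose mean is not positive", ex)
    out$luminescence[rows] <- readings$luminescence[rows] / mx
  }
  out
}

#' Fit a logistic dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + 10^((pXC50 + log10(dose)) * h * s))`
#' on log10 dose, with `s = -1` for agonist curves (response rises to `top`)
#' and `s = +1` for antagonist curves. The default is the three-parameter
#' model (`bottom`, `top`, `pXC50`) with the hill slope fixed at 1; the
#' four-parameter variable-slope model is available with `hill = "fitted"`.
#' Starting values are deterministic: `bottom` = smallest per-dose mean,
#' `top` = largest, `pXC50` = -log10 of the dose nearest half-maximum, h = 1.
#'
#' @param doses molar concentrations (> 0); at least 4 distinct doses (5 for
#'   the variable-slope model). Vehicle (dose 0) wells belong in the
#'   normalization step, not the fit.
#' @param responses normalized responses parallel to `doses`.
#' @param orientation `"agonist"` or `"antagonist"`; determines whether the
#'   reported potency is a pEC50 or a pIC50.
#' @param hill `"fixed"` (slope 1) or `"fitted"`.
#' @return an object of class `dr_fit` with coefficients, asymptotic standard
#'   errors, residual sum of squares and convergence diagnostics. `coef()`,
#'   `predict()`, `residuals()`, `summary()` and `plot()` methods apply.
#' @examples
#' d <- simulate_dose_response(seed = 1)
#' fit <- fit_logistic(d$dose_M, d$luminescence, "agonist")
#' coef(fit)["pXC50"]
#' @export
fit_logistic <- function(doses, responses, orientation = c("agonist", "antagonist"),
                         hill = c("fixed", "fitted")) {
  orientation <- match.arg(orientation)
  hill <- match.arg(hill)
  doses <- as.numeric(doses); responses <- as.numeric(responses)
  if (length(doses) != length(responses)) .stop_fmt("doses/responses length mismatch")
  if (any(!is.finite(doses)) || any(doses <= 0))
    .stop_fmt("doses must be positive molar concentrations")
  n_distinct <- length(unique(doses))
  need <- if (hill == "fixed") 4L else 5L
  if (n_distinct < need)
    .stop_fmt("need at least %d distinct doses for this model (got %d)",
              need, n_distinct)
  s <- if (orientation == "agonist") -1 else 1
  lx <- log10(doses)
  dose_means <- tapply(responses, lx, mean)
  lo <- min(dose_means); hi <- max(dose_means)
  if (hi - lo < 1e-8)
    .stop_fmt("degenerate input: responses are constant, potency is undefined")
  half <- (lo + hi) / 2
  start_p <- -as.numeric(names(dose_means))[which.min(abs(dose_means - half))]
  start <- c(bottom = lo, top = hi, pxc50 = start_p)
  if (hill == "fitted") start <- c(start, h = 1)
  mu_at <- function(par) {
    hh <- if (hill == "fixed") 1 else par[["h"]]
    par[["bottom"]] + (par[["top"]] - par[["bottom"]]) /
      (1 + 10^((par[["pxc50"]] + lx) * hh * s))
  }
  resid_at <- function(par) responses - mu_at(par)
  # Levenberg-Marquardt on the explicit residual function; this stays stable
  # in the zero-residual regime where nls()-style relative-offset machinery
  # breaks down on noiseless data.
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_at,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      .stop_fmt("dose-response fit failed to converge: %s", conditionMessage(e)))
  if (fit$info < 1 || fit$info > 4)
    .stop_fmt("dose-response fit failed to converge: %s", fit$message)
  cf <- fit$par
  # asymptotic covariance: sigma^2 * (J'J)^-1, J by central differences
  k <- length(cf)
  J <- matrix(0, length(responses), k)
  for (j in seq_len(k)) {
    step <- max(1e-6, abs(cf[[j]]) * 1e-6)
    up <- cf; up[[j]] <- up[[j]] + step
    dn <- cf; dn[[j]] <- dn[[j]] - step
    J[, j] <- (mu_at(up) - mu_at(dn)) / (2 * step)
  }
  rss <- sum(resid_at(cf)^2)
  dof <- max(1L, length(responses) - k)
  se <- tryCatch(sqrt(diag(solve(crossprod(J))) * rss / dof),
                 error = function(e) rep(NA_real_, k))
  names(se) <- names(cf)
  est <- c(bottom = cf[["bottom"]], top = cf[["top"]], pXC50 = cf[["pxc50"]],
           hill = if (hill == "fixed") 1 else cf[["h"]])
  ses <- c(bottom = unname(se["bottom"]), top = unname(se["top"]),
           pXC50 = unname(se["pxc50"]),
           hill = if (hill == "fixed") NA_real_ else unname(se["h"]))
  res <- structure(list(
    coefficients = est, se = ses, orientation = orientation,
    hill_mode = hill, rss = rss,
    rss_start = sum(resid_at(start)^2),
    converged = fit$info >= 1 && fit$info <= 4, iterations = fit$niter,
    n = length(doses), n_doses = n_distinct,
    data = data.frame(dose_M = doses, log10_dose = lx, response = responses,
                      fitted = mu_at(cf)),
    fit = fit), class = "dr_fit")
  # flag non-monotone response patterns beyond noise
  ord <- order(as.numeric(names(dose_means)))
  mono <- if (s < 0) cummax(dose_means[ord]) else cummin(dose_means[ord])
  rmse <- sqrt(res$rss / max(1, length(doses) - length(start)))
  if (max(abs(dose_means[ord] - mono)) > 4 * max(rmse, 1e-12))
    warning("dose-response means violate monotonicity beyond the noise level",
            call. = FALSE)
  res
}

#' @export
coef.dr_fit <- function(object, ...) object$coefficients

#' @export
print.dr_fit <- function(x, ...) {
  pname <- if (x$orientation == "agonist") "pEC50" else "pIC50"
  cat(sprintf("Logistic dose-response fit (%s, hill %s)\n",
              x$orientation, if (x$hill_mode == "fixed") "fixed at 1" else "fitted"))
  cat(sprintf("  %s = %.3f +/- %.3f  (bottom %.3f, top %.3f, hill %.2f)\n",
              pname, x$coefficients["pXC50"], x$se["pXC50"],
              x$coefficients["bottom"], x$coefficients["top"],
              x$coefficients["hill"]))
  cat(sprintf("  n = %d readings over %d doses, RSS = %.4g, converged: %s\n",
              x$n, x$n_doses, x$rss, x$converged))
  invisible(x)
}

#' @export
summary.dr_fit <- function(object, ...) {
  out <- data.frame(estimate = object$coefficients, se = object$se)
  rownames(out)[rownames(out) == "pXC50"] <-
    if (object$orientation == "agonist") "pEC50" else "pIC50"
  structure(list(coefficients = out, orientation = object$orientation,
                 rss = object$rss, n = object$n), class = "summary.dr_fit")
}

#' @export
print.summary.dr_fit <- function(x, ...) {
  print(round(x$coefficients, 4)); invisible(x)
}

#' @export
predict.dr_fit <- function(object, doses = NULL, ...) {
  if (is.null(doses)) return(object$data$fitted)
  if (any(doses <= 0)) .stop_fmt("doses must be positive")
  cf <- object$coefficients
  s <- if (object$orientation == "agonist") -1 else 1
  cf["bottom"] + (cf["top"] - cf["bottom"]) /
    (1 + 10^((cf["pXC50"] + log10(doses)) * cf["hill"] * s))
}

#' @export
residuals.dr_fit <- function(object, ...)
  object$data$response - object$data$fitted

#' @export
plot.dr_fit <- function(x, ...) {
  pname <- if (x$orientation == "agonist") "pEC50" else "pIC50"
  plot(x$data$log10_dose, x$data$response,
       xlab = "log10 dose (M)", ylab = "normalized response",
       main = sprintf("%s = %.2f", pname, x$coefficients["pXC50"]), ...)
  gx <- seq(min(x$data$log10_dose), max(x$data$log10_dose), length.out = 200)
  graphics::lines(gx, predict(x, 10^gx))
  invisible(x)
}

#' Fit dose-response curves across experiments
#'
#' Normalizes readings per experiment with [normalize_luminescence()], fits
#' each experiment with [fit_logistic()], and reports the potency both ways
#' the uncertainty can be quoted: the asymptotic fit standard error (per
#' experiment) and the spread of the per-experiment estimates.
#'
#' @param readings data.frame with experiment, dose_M, luminescence; dose 0
#'   rows (vehicle) are used in normalization, then excluded from the fit.
#' @param orientation,hill passed to [fit_logistic()].
#' @return list with `fits` (per experiment), `pXC50_mean`,
#'   `pXC50_sd_experiments` (NA with a single experiment) and
#'   `pXC50_se_fit` (mean asymptotic SE).
#' @export
fit_dose_response <- function(readings, orientation = c("agonist", "antagonist"),
                              hill = c("fixed", "fitted")) {
  orientation <- match.arg(orientation); hill <- match.arg(hill)
  norm <- normalize_luminescence(readings)
  norm <- norm[norm$dose_M > 0, , drop = FALSE]
  fits <- lapply(split(norm, norm$experiment), function(d)
    fit_logistic(d$dose_M, d$luminescence, orientation, hill))
  p <- vapply(fits, function(f) unname(f$coefficients["pXC50"]), numeric(1))
  list(fits = fits,
       pXC50_mean = mean(p),
       pXC50_sd_experiments = if (length(p) > 1L) stats::sd(p) else NA_real_,
       pXC50_se_fit = mean(vapply(fits, function(f) unname(f$se["pXC50"]),
                                  numeric(1))),
       orientation = orientation)
}
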