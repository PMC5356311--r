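# pH and thermal stability summaries: residual-activity normalisation,
# T50 from activity-loss curves, and melting midpoints (Tm) from
# two-state sigmoid fits to circular-dichroism melting profiles.

#' Residual-activity profile relative to a reference condition
#'
#' Expresses raw activities as percentages of the activity at a reference
#' condition (conventionally: after 1 min at 25 degC in pH 5 buffer = 100%).
#' Values above 100% are allowed.
#'
#' @param activities Tibble with columns `condition` and `activity`.
#' @param reference Value of `condition` to use as 100%.
#' @return The input with a `residual_pct` column.
#' @export
residual_activity_profile <- function(activities, reference) {
  stopifnot(all(c("condition", "activity") %in% names(activities)))
  i <- match(reference, activities$condition)
  if (is.na(i)) abort(paste0("reference condition not found: ", reference))
  ref <- activities$activity[i]
  if (ref <= 0) abort("reference activity must be > 0")
  mutate(activities, residual_pct = 100 * .data$activity / ref)
}

#' T50 from a residual-activity-vs-temperature curve
#'
#' The temperature at which half the activity is lost: linear interpolation
#' between the bracketing temperatures of the first downward crossing of
#' 50% residual activity.
#'
#' @param curve Tibble with columns `temperature_C` and `residual_pct`.
#' @return T50 in degC.
#' @export
t50_from_curve <- function(curve) {
  stopifnot(all(c("temperature_C", "residual_pct") %in% names(curve)))
  curve <- arrange(curve, .data$temperature_C)
  x <- curve$temperature_C
  y <- curve$residual_pct
  for (i in seq_len(length(x) - 1)) {
    if (y[i] >= 50 && y[i + 1] < 50) {
      return(x[i] + (y[i] - 50) / (y[i] - y[i + 1]) * (x[i + 1] - x[i]))
    }
  }
  abort("no T50 in range: the curve never crosses 50% downward")
}

#' Melting midpoint Tm from a thermal melting profile
#'
#' Least-squares fit of a two-state sigmoid with four parameters (folded and
#' unfolded baselines, midpoint, slope width) to a CD-vs-temperature curve;
#' Tm is the fitted midpoint. The extraction is invariant to uniform
#' rescaling of the signal axis.
#'
#' @param curve Tibble with columns `temperature_C` and `signal` (CD at
#'   222 nm or any monotone-transition observable, arbitrary units).
#' @return A `melting_fit`: `tm_C`, `parameters` tibble, `fit`, `data`.
#' @export
tm_from_melting <- function(curve) {
  stopifnot(all(c("temperature_C", "signal") %in% names(curve)))
  curve <- arrange(curve, .data$temperature_C)
  x <- curve$temperature_C
  y <- curve$signal
  amp <- diff(range(y))
  if (!(amp > 0) || amp < 1e-10 * max(abs(y), 1)) {
    abort("no transition: melting curve is flat")
  }
  mid0 <- x[which.min(abs(y - (min(y) + amp / 2)))]
  width0 <- diff(range(x)) / 10
  # baseline_f at low temperature, baseline_u at high temperature
  start <- c(baseline_f = y[1], baseline_u = y[length(y)],
             tm = mid0, width = width0)
  model_fn <- function(p, xx) {
    p[["baseline_f"]] + (p[["baseline_u"]] - p[["baseline_f"]]) *
      plogis((xx - p[["tm"]]) / p[["width"]])
  }
  # nls.lm directly: a perfect (noiseless) fit leaves a singular
  # crossproduct Hessian, which must not be treated as failure
  fit <- minpack.lm::nls.lm(
    par = start, fn = function(p) y - model_fn(p, x),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4) {
    abort(paste0("melting fit failed to converge: ", fit$message))
  }
  est <- fit$par
  if (est[["tm"]] < min(x) - diff(range(x)) ||
      est[["tm"]] > max(x) + diff(range(x))) {
    abort("no transition: fitted midpoint far outside the measured range")
  }
  rss <- sum(fit$fvec^2)
  n <- length(y)
  sigma2 <- rss / max(n - 4, 1)
  covm <- tryCatch(sigma2 * solve(fit$hessian),
                   error = function(e) matrix(NA_real_, 4, 4))
  se <- sqrt(pmax(diag(covm), 0))
  z <- stats::qnorm(0.975)
  params <- tibble(term = names(est), estimate = unname(est),
                   std_error = unname(se),
                   ci_lower = unname(est - z * se),
                   ci_upper = unname(est + z * se))
  structure(
    list(tm_C = est[["tm"]], parameters = params,
         rss = rss, n = n,
         aic = n * (log(2 * pi * max(rss, .Machine$double.eps) / n) + 1) + 10,
         predict_fn = function(xx) model_fn(est, xx),
         data = curve),
    class = "melting_fit")
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf("<melting_fit> Tm = %.2f degC (n = %d)\n", x$tm_C, nrow(x$data)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.melting_fit <- function(x, ...) x$parameters

#' @exportS3Method generics::glance
glance.melting_fit <- function(x, ...) {
  tibble(tm_C = x$tm_C, n = x$n, rss = x$rss, aic = x$aic)
}

#' Simulate a sigmoidal melting (or activity-loss) curve
#'
#' @param temperature_C Temperatures sampled.
#' @param midpoint True midpoint (degC).
#' @param width Transition width (degC).
#' @param baseline_f,baseline_u Folded/unfolded baselines.
#' @param sd Gaussian noise SD (signal units).
#' @param seed Optional seed.
#' @return Tibble with `temperature_C`, `signal`.
#' @export
simulate_melting_curve <- function(temperature_C, midpoint, width = 2,
                                   baseline_f = 1, baseline_u = 0,
                                   sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  y <- baseline_f + (baseline_u - baseline_f) *
    plogis((temperature_C - midpoint) / width)
  if (sd > 0) y <- y + rnorm(length(y), 0, sd)
  tibble(temperature_C = temperature_C, signal = y)
}
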