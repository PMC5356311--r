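# Steady-state enzyme kinetics: single-site Michaelis-Menten and biphasic
# two-site fits, catalytic efficiencies, fold changes, and relative
# efficiency profiles. Units are fixed throughout: Km in uM, kcat in 1/s,
# efficiency in 1/(s*mM); the uM -> mM factor of 1000 is applied in exactly
# one place (catalytic_efficiency).

#' Extinction coefficients for the standard assay products
#'
#' Molar absorption coefficients used to convert absorbance slopes into
#' reaction rates for the usual peroxidase substrates.
#'
#' @return Tibble with `product`, `substrate`, `wavelength_nm`,
#'   `epsilon_M_cm` (M^-1 cm^-1).
#' @export
extinction_coefficients <- function() {
  tibble(
    product = c("Mn3+-tartrate", "veratraldehyde", "coerulignone",
                "ABTS cation radical", "Reactive Black 5"),
    substrate = c("Mn2+", "VA", "DMP", "ABTS", "RB5"),
    wavelength_nm = c(238, 310, 469, 436, 598),
    epsilon_M_cm = c(6500, 9300, 55000, 29300, 30000))
}

#' Turnover rate from an absorbance slope
#'
#' Beer-Lambert conversion: `dA/dt / (epsilon * path)` gives the molar
#' product rate, converted to uM/s and normalised per enzyme to a turnover
#' in 1/s.
#'
#' @param dA_per_s Absorbance change per second.
#' @param epsilon Molar absorption coefficient (M^-1 cm^-1), > 0.
#' @param path_cm Optical path length (cm), > 0.
#' @param enzyme_uM Enzyme concentration (uM), > 0.
#' @return Turnover rate (1/s).
#' @export
rate_from_absorbance <- function(dA_per_s, epsilon, path_cm = 1, enzyme_uM) {
  if (epsilon <= 0) abort("epsilon must be > 0")
  if (path_cm <= 0) abort("path length must be > 0")
  if (enzyme_uM <= 0) abort("enzyme concentration must be > 0")
  rate_uM_s <- dA_per_s / (epsilon * path_cm) * 1e6
  rate_uM_s / enzyme_uM
}

validate_curve <- function(curve, min_conc = 5L) {
  if (!all(c("substrate_uM", "rate_per_s") %in% names(curve))) {
    abort("curve needs columns `substrate_uM` and `rate_per_s`")
  }
  if (any(curve$substrate_uM < 0)) abort("substrate concentrations must be >= 0")
  if (any(!is.finite(curve$rate_per_s))) abort("rates must be finite")
  if (length(unique(curve$substrate_uM)) < min_conc) {
    abort(sprintf("need >= %d distinct substrate concentrations", min_conc))
  }
  arrange(curve, .data$substrate_uM)
}

mm_ci <- function(fit, level = 0.95) {
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble(term = names(est), estimate = unname(est), std_error = unname(se),
         ci_lower = unname(est - z * se), ci_upper = unname(est + z * se))
}

new_kinetic_fit <- function(model, params, fit, curve, warnings = character(0),
                            comparison = NULL) {
  rss <- sum(stats::residuals(fit)^2)
  structure(
    list(model = model, parameters = params, rss = rss, aic = AIC(fit),
         n = nrow(curve), data = curve, fit = fit, warnings = warnings,
         comparison = comparison),
    class = "kinetic_fit")
}

#' Fit single-site Michaelis-Menten kinetics
#'
#' Nonlinear least squares of `v = kcat [S] / (Km + [S])`, initialised from
#' the largest observed rate and the concentration nearest half of it.
#' Confidence limits come from the asymptotic parameter covariance. A
#' saturation warning is attached when the fitted Km exceeds the largest
#' assayed concentration.
#'
#' @param curve Tibble with columns `substrate_uM`, `rate_per_s` (replicates
#'   as repeated concentrations are fine).
#' @return A `kinetic_fit` with one site: tibble of Km (uM), kcat (1/s) with
#'   standard errors and 95% limits, efficiency (1/(s*mM)), RSS and AIC.
#' @export
fit_michaelis_menten <- function(curve) {
  curve <- validate_curve(curve, min_conc = 5L)
  vmax0 <- max(curve$rate_per_s)
  km0 <- curve$substrate_uM[which.min(abs(curve$rate_per_s - vmax0 / 2))]
  km0 <- max(km0, min(curve$substrate_uM[curve$substrate_uM > 0]), 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate_per_s ~ kcat * substrate_uM / (Km + substrate_uM),
      data = curve, start = list(kcat = vmax0, Km = km0),
      lower = c(kcat = 1e-12, Km = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) abort(paste0("Michaelis-Menten fit failed: ",
                                     conditionMessage(e))))
  params <- mm_ci(fit) %>%
    mutate(site = 1L, .before = 1)
  warnings <- character(0)
  km_hat <- params$estimate[params$term == "Km"]
  if (km_hat > max(curve$substrate_uM)) {
    warnings <- "fitted Km exceeds the largest assayed concentration (curve not saturated)"
    warn(warnings)
  }
  new_kinetic_fit("single", params, fit, curve, warnings)
}

#' Fit biphasic two-site kinetics
#'
#' Fits the sum of two independent Michaelis-Menten terms,
#' `v = kcat1 [S]/(Km1 + [S]) + kcat2 [S]/(Km2 + [S])`, the standard model
#' for two independent oxidation sites on one enzyme. Sites are ordered by
#' ascending Km, so site 1 is the low-Km ("high efficiency") site. The fit
#' is compared with the single-site model by AIC; a separation of fitted Km
#' values below 5-fold triggers an ill-conditioning warning.
#'
#' @param curve Tibble with columns `substrate_uM`, `rate_per_s`; at least 8
#'   distinct concentrations spanning both phases.
#' @return A `kinetic_fit` with two sites and a `comparison` tibble of AIC
#'   values (`preferred` marks the AIC-preferred model).
#' @export
fit_two_site <- function(curve) {
  curve <- validate_curve(curve, min_conc = 8L)
  single <- fit_michaelis_menten(curve)
  km_s <- single$parameters$estimate[single$parameters$term == "Km"]
  kcat_s <- single$parameters$estimate[single$parameters$term == "kcat"]
  starts <- list()
  for (split in c(0.5, 0.2, 0.8)) {
    for (sep in c(10, 100, 1000)) {
      starts[[length(starts) + 1]] <- list(
        kcat1 = kcat_s * split, Km1 = km_s / sqrt(sep),
        kcat2 = kcat_s * (1 - split), Km2 = km_s * sqrt(sep))
    }
  }
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        rate_per_s ~ kcat1 * substrate_uM / (Km1 + substrate_uM) +
          kcat2 * substrate_uM / (Km2 + substrate_uM),
        data = curve, start = st,
        lower = rep(1e-12, 4),
        control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(stats::residuals(f)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best)) abort("two-site fit failed to converge from any start")
  fit <- best$fit
  est <- coef(fit)
  # order sites by Km ascending
  if (est["Km1"] > est["Km2"]) {
    perm <- c(kcat1 = "kcat2", Km1 = "Km2", kcat2 = "kcat1", Km2 = "Km1")
    fit <- minpack.lm::nlsLM(
      rate_per_s ~ kcat1 * substrate_uM / (Km1 + substrate_uM) +
        kcat2 * substrate_uM / (Km2 + substrate_uM),
      data = curve, start = as.list(setNames(est[perm], names(perm))),
      lower = rep(1e-12, 4),
      control = minpack.lm::nls.lm.control(maxiter = 1000))
    est <- coef(fit)
  }
  params <- mm_ci(fit) %>%
    mutate(site = ifelse(grepl("1$", .data$term), 1L, 2L),
           term = sub("[12]$", "", .data$term), .before = 1)
  warnings <- character(0)
  if (est["Km2"] / est["Km1"] < 5) {
    warnings <- "Km separation < 5-fold: two-site fit is ill-conditioned"
    warn(warnings)
  }
  comparison <- tibble(
    model = c("single", "two-site"),
    aic = c(single$aic, AIC(fit)))
  comparison$preferred <- comparison$aic == min(comparison$aic)
  new_kinetic_fit("two-site", params, fit, curve, warnings, comparison)
}

#' Catalytic efficiency kcat/Km
#'
#' With Km in uM and kcat in 1/s the efficiency is `1000 * kcat / Km` in
#' 1/(s*mM).
#'
#' @param Km_uM Michaelis constant (uM), > 0.
#' @param kcat_s Turnover number (1/s).
#' @param signif_digits Optional rounding to significant figures (the usual
#'   report precision is 2-3).
#' @return Efficiency in s^-1 mM^-1.
#' @export
catalytic_efficiency <- function(Km_uM, kcat_s, signif_digits = NULL) {
  if (any(Km_uM <= 0)) abort("Km must be > 0")
  eff <- 1000 * kcat_s / Km_uM
  if (!is.null(signif_digits)) eff <- signif(eff, signif_digits)
  eff
}

#' Fold change between two values
#'
#' @param value_a Numerator.
#' @param value_b Denominator (non-zero).
#' @param mode `"ratio"` (exact) or `"rounded"` (nearest integer, the usual
#'   "n-fold" statement).
#' @return Ratio, or nearest-integer fold.
#' @export
fold_change <- function(value_a, value_b, mode = c("ratio", "rounded")) {
  mode <- match.arg(mode)
  if (any(value_b == 0)) abort("fold change undefined: division by zero")
  r <- value_a / value_b
  if (mode == "rounded") round(r) else r
}

#' Relative catalytic-efficiency profile
#'
#' Normalises efficiencies so that the maximum for each substrate is 100%;
#' absent activities (NA) are reported as 0%.
#'
#' @param efficiencies Tibble with columns `enzyme`, `substrate`,
#'   `efficiency` (NA = no activity).
#' @return The input with a `relative_pct` column added.
#' @export
relative_efficiency_profile <- function(efficiencies) {
  stopifnot(all(c("enzyme", "substrate", "efficiency") %in% names(efficiencies)))
  safe_max <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  out <- efficiencies %>%
    group_by(.data$substrate) %>%
    mutate(.max = safe_max(.data$efficiency)) %>%
    ungroup()
  if (any(!is.finite(out$.max) | out$.max <= 0)) {
    bad <- unique(out$substrate[!is.finite(out$.max) | out$.max <= 0])
    abort(paste0("no positive efficiency for substrate(s): ",
                 paste(bad, collapse = ", ")))
  }
  out %>%
    mutate(relative_pct = ifelse(is.na(.data$efficiency), 0,
                                 100 * .data$efficiency / .data$.max)) %>%
    select(-".max")
}

#' Simulate a saturation-kinetics curve
#'
#' Generates noisy (or noiseless) rates from one or two Michaelis-Menten
#' sites at given concentrations; the synthetic counterpart of a measured
#' curve, used for validation.
#'
#' @param substrate_uM Concentrations (uM).
#' @param Km,kcat Per-site parameters (vectors of equal length 1 or 2).
#' @param sd Gaussian noise SD on the rate (same units as the rate).
#' @param replicates Replicate measurements per concentration.
#' @param seed Optional seed.
#' @return Tibble with `substrate_uM`, `rate_per_s`, `replicate`.
#' @export
simulate_kinetic_curve <- function(substrate_uM, Km, kcat, sd = 0,
                                   replicates = 1L, seed = NULL) {
  stopifnot(length(Km) == length(kcat))
  if (!is.null(seed)) set.seed(as.integer(seed))
  s <- rep(substrate_uM, times = replicates)
  repl <- rep(seq_len(replicates), each = length(substrate_uM))
  v <- rowSums(vapply(seq_along(Km),
                      function(i) kcat[i] * s / (Km[i] + s),
                      numeric(length(s))))
  if (sd > 0) v <- v + rnorm(length(v), 0, sd)
  tibble(substrate_uM = s, rate_per_s = v, replicate = repl)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s model, n = %d, RSS = %.4g, AIC = %.2f\n",
              x$model, x$n, x$rss, x$aic))
  print(tidy(x))
  invisible(x)
}

#' Tidy a kinetic fit (one row per site)
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return Tibble with `site`, `Km_uM`, `kcat_s`, `efficiency_s_mM` and the
#'   95% limits of Km and kcat.
#' @exportS3Method generics::tidy
tidy.kinetic_fit <- function(x, ...) {
  p <- x$parameters
  purrr::map_dfr(sort(unique(p$site)), function(s) {
    km <- p[p$site == s & p$term == "Km", ]
    kc <- p[p$site == s & p$term == "kcat", ]
    tibble(site = s,
           Km_uM = km$estimate, Km_lower = km$ci_lower, Km_upper = km$ci_upper,
           kcat_s = kc$estimate, kcat_lower = kc$ci_lower,
           kcat_upper = kc$ci_upper,
           efficiency_s_mM = catalytic_efficiency(km$estimate, kc$estimate))
  })
}

#' Glance at a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return One-row tibble with `model`, `n`, `rss`, `aic`, `n_warnings`.
#' @exportS3Method generics::glance
glance.kinetic_fit <- function(x, ...) {
  tibble(model = x$model, n = x$n, rss = x$rss, aic = x$aic,
         n_warnings = length(x$warnings))
}

#' Export kinetic fits as a TSV table
#'
#' One row per (enzyme, substrate, site) mirroring the usual kinetic-table
#' layout (Km, kcat, kcat/Km with confidence limits).
#'
#' @param fits Named list of `kinetic_fit` objects (names = "enzyme/substrate"
#'   or any identifier).
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_kinetic_table <- function(fits, path) {
  df <- purrr::map_dfr(names(fits), function(nm) {
    mutate(tidy(fits[[nm]]), id = nm, .before = 1)
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
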