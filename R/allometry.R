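#' Fit the allometric mass-scaling of metabolic rate across hosts
#'
#' Fits `ln(rate) ~ ln(mass) + host` by maximum likelihood (a common scaling
#' exponent with host-specific intercepts) together with the interaction
#' model `ln(rate) ~ ln(mass) * host` (host-specific exponents), and
#' compares them with a likelihood-ratio test. Per-host multiplicative
#' coefficients are reported as `exp(intercept)` under the convention rate
#' in mL h^-1 and mass in g, i.e. `a_host` is the predicted rate of a 1 g
#' animal in mL CO2 per hour. Host and slope Wald chi-square tests (Type II)
#' accompany the fit.
#'
#' @param data Tibble with mass, rate and host columns.
#' @param mass,rate,host Column names (strings).
#' @param rate_unit Unit of the rate column: `"ml_min"` (default; converted
#'   to mL h^-1 for the fit) or `"ml_h"`.
#' @return An object of class `allometry_fit`: `exponent_b`, named
#'   `coefficient_a`, `interaction_lrt`, `host_test`, `slope_test`, the two
#'   underlying `lm` fits and the modelling data. Use [tidy()]/[glance()] or
#'   `autoplot()`.
#' @export
#' @examples
#' d <- tibble::tibble(mass_g = c(0.1, 0.2, 0.4, 0.8),
#'                     vco2_ml_min = 0.43 * mass_g^0.84 / 60,
#'                     host = "Urtica")
#' fit <- fit_mass_scaling(d)
#' fit$exponent_b
fit_mass_scaling <- function(data, mass = "mass_g", rate = "vco2_ml_min",
                             host = "host", rate_unit = c("ml_min", "ml_h")) {
  rate_unit <- match.arg(rate_unit)
  data <- tibble::as_tibble(data)
  for (col in c(mass, rate, host)) {
    if (!col %in% names(data)) abort(sprintf("column `%s` not found.", col))
  }
  d <- tibble::tibble(
    ln_mass = log(data[[mass]]),
    ln_rate = log(data[[rate]] * if (rate_unit == "ml_min") 60 else 1),
    host = factor(as.character(data[[host]]),
                  levels = intersect(host_levels(), unique(as.character(data[[host]]))))
  )
  d <- d[stats::complete.cases(d) & is.finite(d$ln_rate) & is.finite(d$ln_mass), ]
  n_hosts <- nlevels(d$host)
  counts <- table(d$host)
  if ((n_hosts >= 2L && any(counts < 3L)) || (n_hosts == 1L && nrow(d) < 2L)) {
    abort("need at least 3 observations per host (2 suffice for a single host).")
  }

  if (n_hosts >= 2L) {
    additive <- lm(ln_rate ~ ln_mass + host, data = d)
    means_form <- lm(ln_rate ~ 0 + host + ln_mass, data = d)  # per-host intercepts
    a <- exp(coef(means_form)[paste0("host", levels(d$host))])
  } else {
    additive <- lm(ln_rate ~ ln_mass, data = d)
    means_form <- additive
    a <- exp(coef(means_form)[["(Intercept)"]])
  }
  if (any(!is.finite(coef(additive)))) abort("degenerate design: rank-deficient fit.")
  b <- unname(coef(means_form)[["ln_mass"]])
  names(a) <- levels(d$host)

  if (n_hosts >= 2L) {
    interaction <- lm(ln_rate ~ ln_mass * host, data = d)
    interaction_lrt <- lrt(interaction, additive)
    wald <- wald_chi2_tests(additive)
    host_test <- wald[wald$term == "host", c("chisq", "df", "p_value")]
    slope_test <- wald[wald$term == "ln_mass", c("chisq", "df", "p_value")]
  } else {
    interaction <- NULL
    interaction_lrt <- tibble::tibble(chisq = NA_real_, df = NA_integer_,
                                      p_value = NA_real_)
    wald <- wald_chi2_tests(additive)
    host_test <- tibble::tibble(chisq = NA_real_, df = NA_integer_, p_value = NA_real_)
    slope_test <- wald[wald$term == "ln_mass", c("chisq", "df", "p_value")]
  }

  structure(
    list(
      exponent_b = b,
      coefficient_a = a,
      interaction_lrt = interaction_lrt,
      host_test = host_test,
      slope_test = slope_test,
      fit_additive = additive,
      fit_interaction = interaction,
      data = d,
      n = nrow(d),
      unit = "mL CO2 h^-1 at 1 g"
    ),
    class = "allometry_fit"
  )
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat("<allometry_fit> rate = a * mass^b,", x$n, "observations\n")
  cat(sprintf("  b = %.4f\n", x$exponent_b))
  for (h in names(x$coefficient_a)) {
    cat(sprintf("  a[%s] = %.4f %s\n", h, x$coefficient_a[[h]], x$unit))
  }
  if (is.finite(x$interaction_lrt$chisq[1])) {
    cat(sprintf("  mass x host interaction LRT: chi2 = %.3f, df = %d, p = %.3g\n",
                x$interaction_lrt$chisq, x$interaction_lrt$df,
                x$interaction_lrt$p_value))
  }
  invisible(x)
}

#' Likelihood-ratio test between nested models
#'
#' `chi2 = 2 * (logLik(full) - logLik(reduced))`, clamped at zero, with
#' degrees of freedom equal to the parameter-count difference and the
#' p-value from the upper chi-square tail. Mixed models fitted by REML are
#' refitted with maximum likelihood first (fixed-effect LRTs are only valid
#' under ML).
#'
#' @param model_full,model_reduced Nested fits on identical data: `lm`,
#'   `merMod`, or [fit_lmm()] objects.
#' @return One-row tibble `chisq`, `df`, `p_value`.
#' @export
#' @examples
#' f <- lm(mpg ~ wt + hp, data = mtcars)
#' r <- lm(mpg ~ wt, data = mtcars)
#' lrt(f, r)
lrt <- function(model_full, model_reduced) {
  unwrap <- function(m) {
    if (inherits(m, "lmm_fit")) m <- m$fit
    if (inherits(m, "merMod") && lme4::isREML(m)) m <- lme4::refitML(m)
    m
  }
  mf <- unwrap(model_full)
  mr <- unwrap(model_reduced)
  if (nobs(mf) != nobs(mr)) {
    abort("models are fitted to different data (unequal observation counts).")
  }
  ll_f <- logLik(mf)
  ll_r <- logLik(mr)
  df <- attr(ll_f, "df") - attr(ll_r, "df")
  if (df < 0) abort("`model_full` has fewer parameters than `model_reduced`; not nested.")
  chisq <- max(0, 2 * (as.numeric(ll_f) - as.numeric(ll_r)))
  p <- if (df == 0) {
    if (chisq < 1e-8) 1 else NA_real_
  } else {
    pchisq(chisq, df = df, lower.tail = FALSE)
  }
  tibble::tibble(chisq = chisq, df = as.integer(df), p_value = p)
}
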