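#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an allometric mass-scaling fit
#'
#' @param x An `allometry_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: the common exponent `b` and
#'   each host's back-transformed coefficient `a` (mL CO2 h^-1 at 1 g).
#' @method tidy allometry_fit
#' @export
tidy.allometry_fit <- function(x, ...) {
  cf <- summary(x$fit_additive)$coefficients
  dplyr::bind_rows(
    tibble::tibble(term = "exponent_b", estimate = x$exponent_b,
                   std_error = cf["ln_mass", "Std. Error"]),
    tibble::tibble(term = paste0("a_", names(x$coefficient_a)),
                   estimate = unname(x$coefficient_a),
                   std_error = NA_real_)
  )
}

#' @rdname tidy.allometry_fit
#' @method glance allometry_fit
#' @export
glance.allometry_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    sigma = summary(x$fit_additive)$sigma,
    r_squared = summary(x$fit_additive)$r.squared,
    log_lik = as.numeric(logLik(x$fit_additive)),
    interaction_chisq = x$interaction_lrt$chisq,
    interaction_df = x$interaction_lrt$df,
    interaction_p = x$interaction_lrt$p_value
  )
}

#' Tidy a mixed-model fit
#'
#' @param x An `lmm_fit`.
#' @param effects `"fixed"`, `"ran_pars"` or `"all"`.
#' @param ... Unused.
#' @return Tibble of fixed-effect estimates with SEs and/or random-effect
#'   variance components.
#' @method tidy lmm_fit
#' @export
tidy.lmm_fit <- function(x, effects = c("all", "fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  cf <- summary(x$fit)$coefficients
  fixed <- tibble::tibble(
    effect = "fixed",
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    statistic = cf[, "t value"]
  )
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  ran <- tibble::tibble(
    effect = "ran_pars",
    term = paste0("var_", ifelse(is.na(vc$var1), vc$grp, paste(vc$grp, vc$var1, sep = "."))),
    estimate = vc$vcov,
    std_error = NA_real_,
    statistic = NA_real_
  )
  switch(effects,
         fixed = fixed,
         ran_pars = ran,
         all = dplyr::bind_rows(fixed, ran))
}

#' @rdname tidy.lmm_fit
#' @method glance lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    sigma = stats::sigma(x$fit),
    log_lik = as.numeric(logLik(x$fit)),
    reml = x$reml,
    converged = x$converged,
    singular = x$singular
  )
}
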