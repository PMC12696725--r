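#' Larval growth rate from final mass and development time
#'
#' Growth rate is the logged mass at measurement, in milligrams (the mg
#' conversion keeps the log positive for realistic larvae), divided by the
#' development time in days:
#' `growth_rate = log(mass_g * 1000) / dev_time_days`.
#'
#' @param mass_g Fresh mass in grams, > 0 (vectorized).
#' @param dev_time_days Days from hatching to the measured stage, > 0.
#' @param log_base `"natural"` (default) or `"base10"`. The choice rescales
#'   the metric by a constant and does not affect host comparisons.
#' @return Growth rate in log-mg per day.
#' @export
#' @examples
#' growth_rate(0.1, 10)                      # ln(100)/10
#' growth_rate(0.1, 10, log_base = "base10") # 0.2
growth_rate <- function(mass_g, dev_time_days, log_base = c("natural", "base10")) {
  log_base <- match.arg(log_base)
  if (!is.numeric(mass_g) || !is.numeric(dev_time_days)) {
    abort("`mass_g` and `dev_time_days` must be numeric.")
  }
  if (any(mass_g <= 0, na.rm = TRUE) || any(dev_time_days <= 0, na.rm = TRUE)) {
    abort("`mass_g` and `dev_time_days` must be > 0.")
  }
  lg <- if (log_base == "natural") log(mass_g * 1000) else log10(mass_g * 1000)
  lg / dev_time_days
}

#' Growth cost: CO2 production extrapolated over development per gram gained
#'
#' `growth_cost = (dev_time_days / mass_g) * 24 * 60 * vco2_ml_min`: the
#' measured per-minute rate scaled to the whole development period and
#' normalized by the attained mass, in mL CO2 per gram. A lower value means
#' less metabolic expenditure per unit of growth.
#'
#' @param dev_time_days Development time in days, > 0 (vectorized).
#' @param mass_g Mass in grams, > 0.
#' @param vco2_ml_min CO2 production rate in mL min^-1. Slightly negative
#'   processed rates (noise around zero) are propagated, not truncated.
#' @return Growth cost in mL CO2 g^-1.
#' @export
#' @examples
#' growth_cost(10, 0.1, 0.001)  # 144
growth_cost <- function(dev_time_days, mass_g, vco2_ml_min) {
  if (!is.numeric(dev_time_days) || !is.numeric(mass_g) || !is.numeric(vco2_ml_min)) {
    abort("all arguments must be numeric.")
  }
  if (any(mass_g <= 0, na.rm = TRUE) || any(dev_time_days <= 0, na.rm = TRUE)) {
    abort("`mass_g` and `dev_time_days` must be > 0.")
  }
  (dev_time_days / mass_g) * 24 * 60 * vco2_ml_min
}

#' Attach processed VCO2 and derived metrics to a cohort table
#'
#' Left-joins the processed rate table onto the cohort by
#' (`individual_id`, `stage`), then adds `growth_rate` and `growth_cost`
#' columns. Rows without a processed rate keep `NA` growth cost and are
#' never dropped; a join report (matched / unmatched counts) is emitted as a
#' message.
#'
#' @param cohort Tibble with `individual_id`, `stage`, `mass_g`,
#'   `dev_time_days` (as written by [sim_cohort()] / [read_cohort()]).
#' @param vco2 Tibble with `individual_id`, `stage`, `vco2_ml_min` (as
#'   returned by [process_study()]).
#' @param log_base Passed to [growth_rate()].
#' @param keys Join keys; must be unique in both tables.
#' @return The cohort tibble with `vco2_ml_min`, `qc_flags`, `growth_rate`
#'   and `growth_cost` columns appended.
#' @export
attach_metrics <- function(cohort, vco2, log_base = c("natural", "base10"),
                           keys = c("individual_id", "stage")) {
  log_base <- match.arg(log_base)
  cohort <- tibble::as_tibble(cohort)
  vco2 <- tibble::as_tibble(vco2)
  keys <- intersect(keys, names(vco2))
  if (length(keys) == 0) abort("no join keys shared between cohort and vco2.")
  if (anyDuplicated(cohort[keys])) {
    abort("duplicate join keys in `cohort`; keys must identify one measurement.")
  }
  if (anyDuplicated(vco2[keys])) {
    abort("duplicate join keys in `vco2`; keys must identify one measurement.")
  }
  take <- c(keys, intersect(c("vco2_ml_min", "qc_flags"), names(vco2)))
  merged <- dplyr::left_join(cohort,
                             dplyr::select(vco2, dplyr::all_of(take)),
                             by = keys)
  n_match <- sum(!is.na(merged$vco2_ml_min))
  inform(sprintf("attach_metrics: %d/%d rows matched a processed VCO2 (%d unmatched).",
                 n_match, nrow(merged), nrow(merged) - n_match))
  merged$growth_rate <- growth_rate(merged$mass_g, merged$dev_time_days, log_base)
  merged$growth_cost <- growth_cost(merged$dev_time_days, merged$mass_g,
                                    merged$vco2_ml_min)
  merged
}
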