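#' Default replicate counts per developmental stage and host plant
#'
#' The study design the simulator reproduces: 15 split-brood families reared
#' on three host plants, with metabolic-rate measurements at the 3rd instar
#' (49/52/56 individuals on Urtica/Salix/Ribes), the 4th instar (88/97/109)
#' and the pupal stage (18/21/29).
#'
#' @return A tibble with columns `stage`, `host`, `n`.
#' @export
default_replicates <- function() {
  tibble::tibble(
    stage = rep(stage_levels(), each = 3L),
    host  = rep(host_levels(), times = 3L),
    n     = c(49L, 52L, 56L, 88L, 97L, 109L, 18L, 21L, 29L)
  )
}

#' Default mass and development-time distributions
#'
#' Lognormal medians and log-scale SDs per (stage, host). These are free
#' modelling choices: the medians are ordered so that larvae on Urtica grow
#' fastest (shortest development, highest mass) and larvae on Ribes slowest,
#' matching the reported performance hierarchy; absolute values are
#' plausible for mid-instar nymphalid caterpillars, not calibrated to any
#' real cohort.
#'
#' @return A tibble with columns `stage`, `host`, `mass_median_g`,
#'   `mass_sdlog`, `dev_median_d`, `dev_sdlog`.
#' @export
default_distributions <- function() {
  tibble::tibble(
    stage = rep(stage_levels(), each = 3L),
    host  = rep(host_levels(), times = 3L),
    mass_median_g = c(0.050, 0.045, 0.042,
                      0.32,  0.28,  0.26,
                      0.40,  0.36,  0.34),
    mass_sdlog    = c(rep(0.25, 6L), rep(0.20, 3L)),
    dev_median_d  = c(9.0, 10.0, 11.5,
                      14.0, 15.5, 18.0,
                      24.0, 26.5, 30.0),
    dev_sdlog     = rep(0.08, 9L)
  )
}

#' Trace-synthesis parameters for the syringe respirometry emulator
#'
#' Describes one analyzer run: a few minutes of CO2-scrubbed reference air,
#' then injection of `injected_volume_ml` of the incubated syringe air, which
#' appears at the analyzer as a roughly Gaussian bolus riding on a slowly
#' drifting baseline. Injected volume defaults follow the measurement
#' protocol: 7 mL for 3rd instars, 10 mL for 4th instars and pupae, from a
#' 20 mL syringe incubated for 60 min.
#'
#' @param flow_rate_ml_min Carrier flow through the analyzer (mL min^-1).
#' @param syringe_volume_ml Total incubation volume (mL).
#' @param injected_volume_ml Named numeric, injected volume per stage (mL).
#' @param incubation_min Minutes the animal spends sealed in the syringe.
#' @param baseline_ppm Analyzer reading on scrubbed air (ppm).
#' @param drift_ppm_per_s Linear baseline drift (ppm s^-1).
#' @param noise_sd_ppm SD of white analyzer noise (ppm).
#' @param bolus_sd_s Gaussian SD of the injection bolus (s). The bolus shape
#'   is a free choice; area-based processing must not depend on it.
#' @param sample_hz Analyzer sampling rate (samples s^-1).
#' @param injection_time_s Time of the injection marker (s).
#' @param duration_s Total trace length (s).
#' @return A list of class `trace_params`.
#' @export
trace_params <- function(flow_rate_ml_min = 150,
                         syringe_volume_ml = 20,
                         injected_volume_ml = c(instar3 = 7, instar4 = 10, pupa = 10),
                         incubation_min = 60,
                         baseline_ppm = 2,
                         drift_ppm_per_s = 0.002,
                         noise_sd_ppm = 2,
                         bolus_sd_s = 8,
                         sample_hz = 1,
                         injection_time_s = 150,
                         duration_s = 300) {
  assert_scalar_number(flow_rate_ml_min, "flow_rate_ml_min", 0, strict = TRUE)
  assert_scalar_number(syringe_volume_ml, "syringe_volume_ml", 0, strict = TRUE)
  if (!is.numeric(injected_volume_ml) || any(injected_volume_ml <= 0)) {
    abort("`injected_volume_ml` must be positive.")
  }
  if (any(injected_volume_ml > syringe_volume_ml)) {
    abort("`injected_volume_ml` cannot exceed `syringe_volume_ml`.")
  }
  assert_scalar_number(incubation_min, "incubation_min", 0, strict = TRUE)
  assert_scalar_number(noise_sd_ppm, "noise_sd_ppm", 0)
  assert_scalar_number(bolus_sd_s, "bolus_sd_s", 0, strict = TRUE)
  assert_scalar_number(sample_hz, "sample_hz", 0, strict = TRUE)
  assert_scalar_number(injection_time_s, "injection_time_s", 0, strict = TRUE)
  assert_scalar_number(duration_s, "duration_s", injection_time_s, strict = TRUE)
  structure(
    list(
      flow_rate_ml_min = flow_rate_ml_min,
      syringe_volume_ml = syringe_volume_ml,
      injected_volume_ml = injected_volume_ml,
      incubation_min = incubation_min,
      baseline_ppm = baseline_ppm,
      drift_ppm_per_s = drift_ppm_per_s,
      noise_sd_ppm = noise_sd_ppm,
      bolus_sd_s = bolus_sd_s,
      sample_hz = sample_hz,
      injection_time_s = injection_time_s,
      duration_s = duration_s
    ),
    class = "trace_params"
  )
}

#' Simulation configuration for a synthetic host-plant energetics study
#'
#' Bundles everything the generator needs: the split-brood design (families,
#' replicate counts), the allometric rate model, the variance components, the
#' mass / development-time distributions and the trace-synthesis parameters.
#'
#' The latent metabolic rate of each measurement is
#' \deqn{\dot{V}CO_2\;[\mathrm{mL\,h^{-1}}] = a_{host} \times mass_g^{\,b}
#'   \times \exp(family + individual + residual)}
#' with Normal random effects on the natural-log scale. The coefficient
#' `scaling_coefficient_a` is defined with rate in mL h^-1 at a mass of 1 g;
#' rates are carried internally in mL min^-1.
#'
#' @param n_families Number of split-brood families (default 15).
#' @param replicates Tibble (`stage`, `host`, `n`) of measurement counts;
#'   defaults to [default_replicates()].
#' @param scaling_exponent_b Common mass-scaling exponent (default 0.84).
#' @param scaling_coefficient_a Named per-host coefficient, mL CO2 h^-1 at
#'   1 g (defaults Urtica 0.43, Salix 0.39, Ribes 0.44).
#' @param family_sd SD of the family random intercept on the log-rate scale.
#' @param individual_sd SD of the individual random intercept (log-rate
#'   scale), shared across an individual's repeated measurements.
#' @param residual_sd SD of per-measurement lognormal noise on the rate.
#' @param distributions Tibble as [default_distributions()].
#' @param sex_prob Named probabilities for sex assignment.
#' @param batch_size Animal sessions per measurement batch; each batch gets
#'   one empty-syringe control session.
#' @param trace [trace_params()] object.
#' @param seed Optional default seed used when the generator is called
#'   without one.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config()
#' sum(cfg$replicates$n)  # 519 measurements
sim_config <- function(n_families = 15,
                       replicates = default_replicates(),
                       scaling_exponent_b = 0.84,
                       scaling_coefficient_a = c(Urtica = 0.43, Salix = 0.39, Ribes = 0.44),
                       family_sd = 0.05,
                       individual_sd = 0.05,
                       residual_sd = 0.10,
                       distributions = default_distributions(),
                       sex_prob = c(F = 0.4, M = 0.4, unknown = 0.2),
                       batch_size = 8,
                       trace = trace_params(),
                       seed = NULL) {
  assert_scalar_number(n_families, "n_families", 0, strict = TRUE)
  replicates <- tibble::as_tibble(replicates)
  req <- c("stage", "host", "n")
  if (!all(req %in% names(replicates))) {
    abort("`replicates` needs columns stage, host, n.")
  }
  if (nrow(replicates) > 0) {
    if (!all(replicates$stage %in% stage_levels()) ||
        !all(replicates$host %in% host_levels())) {
      abort("`replicates` contains unknown stage or host levels.")
    }
    if (any(replicates$n <= 0)) abort("replicate counts must be > 0.")
    if (anyDuplicated(replicates[c("stage", "host")])) {
      abort("duplicate (stage, host) rows in `replicates`.")
    }
  }
  assert_scalar_number(scaling_exponent_b, "scaling_exponent_b")
  if (!is.numeric(scaling_coefficient_a) ||
      !all(host_levels() %in% names(scaling_coefficient_a)) ||
      any(scaling_coefficient_a <= 0)) {
    abort("`scaling_coefficient_a` must be positive and named for every host.")
  }
  assert_scalar_number(family_sd, "family_sd", 0)
  assert_scalar_number(individual_sd, "individual_sd", 0)
  assert_scalar_number(residual_sd, "residual_sd", 0)
  distributions <- tibble::as_tibble(distributions)
  needed <- unique(replicates[c("stage", "host")])
  have <- unique(distributions[c("stage", "host")])
  if (nrow(dplyr::anti_join(needed, have, by = c("stage", "host"))) > 0) {
    abort("`distributions` must cover every (stage, host) cell in `replicates`.")
  }
  if (nrow(distributions) > 0 &&
      (any(distributions$mass_median_g <= 0) || any(distributions$dev_median_d <= 0) ||
       any(distributions$mass_sdlog < 0) || any(distributions$dev_sdlog < 0))) {
    abort("`distributions` medians must be > 0 and sdlogs >= 0.")
  }
  if (!inherits(trace, "trace_params")) abort("`trace` must be a trace_params() object.")
  assert_scalar_number(batch_size, "batch_size", 0, strict = TRUE)
  structure(
    list(
      n_families = as.integer(n_families),
      replicates = replicates,
      scaling_exponent_b = scaling_exponent_b,
      scaling_coefficient_a = scaling_coefficient_a[host_levels()],
      family_sd = family_sd,
      individual_sd = individual_sd,
      residual_sd = residual_sd,
      distributions = distributions,
      sex_prob = sex_prob,
      batch_size = as.integer(batch_size),
      trace = trace,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  families:", x$n_families,
      " measurements:", sum(x$replicates$n), "\n")
  cat("  allometry: a =",
      paste(sprintf("%s %.2f", names(x$scaling_coefficient_a),
                    x$scaling_coefficient_a), collapse = ", "),
      " b =", x$scaling_exponent_b, "\n")
  cat("  sds (log rate): family", x$family_sd, "individual", x$individual_sd,
      "residual", x$residual_sd, "\n")
  invisible(x)
}
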