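# shared fixture builders -- everything is generated in code at test time

uniform_replicates <- function(n_each = 5L) {
  reps <- default_replicates()
  reps$n <- as.integer(n_each)
  reps
}

noiseless_config <- function(replicates = uniform_replicates(5L), ...) {
  sim_config(
    replicates = replicates,
    family_sd = 0, individual_sd = 0, residual_sd = 0,
    trace = trace_params(noise_sd_ppm = 0),
    ...
  )
}

# instar-4-only design with no host differences at all
null_config <- function() {
  reps <- dplyr::filter(default_replicates(), stage == "instar4")
  dists <- dplyr::mutate(
    dplyr::filter(default_distributions(), stage == "instar4"),
    mass_median_g = 0.29, dev_median_d = 16
  )
  sim_config(replicates = reps, distributions = dists,
             scaling_coefficient_a = c(Urtica = 0.43, Salix = 0.43, Ribes = 0.43))
}

# identical hosts except an extra multiplicative rate (hence cost) on Ribes
inflated_ribes_config <- function(multiplier = 1.3) {
  cfg <- null_config()
  sim_config(replicates = cfg$replicates, distributions = cfg$distributions,
             scaling_coefficient_a = c(Urtica = 0.43, Salix = 0.43,
                                       Ribes = 0.43 * multiplier))
}

# hand-built analyzer session for unit tests of the processing chain
make_session <- function(time_s, co2_ppm, flow = 100, syringe = 20,
                         injected = 10, incubation = 60, injection_time = 100,
                         is_control = FALSE, id = "manual") {
  hostcost:::new_resp_session(
    trace = tibble::tibble(time_s = time_s, co2_ppm = co2_ppm),
    params = list(flow_rate_ml_min = flow, syringe_volume_ml = syringe,
                  incubation_min = incubation, injection_time_s = injection_time),
    injected_volume_ml = injected,
    session_id = id, is_control = is_control
  )
}

# latent-rate metrics table straight from the generator (no trace synthesis);
# used where inference on the cohort scale is under test
cohort_metrics <- function(config, seed) {
  cohort <- sim_cohort(config, seed = seed)
  cohort$growth_rate <- growth_rate(cohort$mass_g, cohort$dev_time_days)
  cohort$growth_cost <- growth_cost(cohort$dev_time_days, cohort$mass_g,
                                    cohort$true_vco2_ml_min)
  cohort
}
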