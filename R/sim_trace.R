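new_resp_session <- function(trace, params, injected_volume_ml, session_id,
                             individual_id = NA_character_, is_control = FALSE,
                             control_session_id = NA_character_,
                             stage = NA_character_) {
  structure(
    list(
      session_id = session_id,
      individual_id = individual_id,
      is_control = is_control,
      control_session_id = control_session_id,
      stage = stage,
      trace = trace,
      flow_rate_ml_min = params$flow_rate_ml_min,
      syringe_volume_ml = params$syringe_volume_ml,
      injected_volume_ml = injected_volume_ml,
      incubation_min = params$incubation_min,
      injection_time_s = params$injection_time_s
    ),
    class = "resp_session"
  )
}

#' @export
print.resp_session <- function(x, ...) {
  cat("<resp_session>", x$session_id,
      if (x$is_control) "(control)" else paste0("animal ", x$individual_id), "\n")
  cat("  ", nrow(x$trace), "samples,",
      sprintf("flow %.0f mL/min, syringe %.0f mL, injected %.0f mL, %.0f min incubation\n",
              x$flow_rate_ml_min, x$syringe_volume_ml, x$injected_volume_ml,
              x$incubation_min))
  invisible(x)
}

#' Synthesize one raw syringe-injection CO2 trace
#'
#' Emulates a stop-flow analyzer run: a pre-injection reference segment at
#' `baseline_ppm` with linear drift and white noise, followed by a Gaussian
#' injection bolus. The bolus excess area is set so that the integral of
#' (air fraction x carrier flow) over time equals the CO2 volume carried by
#' the injected aliquot,
#' `true_vco2_ml_min * incubation_min * injected_volume / syringe_volume`,
#' i.e. processing the trace back through the calculation chain recovers the
#' true rate. Control syringes are generated with a true rate of zero.
#'
#' @param true_vco2_ml_min Latent CO2 production rate (mL min^-1), >= 0.
#' @param params A [trace_params()] object.
#' @param seed Integer seed; same seed gives an identical trace.
#' @param injected_volume_ml Injected aliquot (mL); defaults to the stage
#'   entry of `params$injected_volume_ml` named by `stage`.
#' @param stage Stage label used to pick the injected volume.
#' @param session_id,individual_id,is_control,control_session_id Metadata
#'   carried on the returned session.
#' @return A `resp_session` object with a `trace` tibble (`time_s`,
#'   `co2_ppm`) and the session metadata.
#' @export
sim_trace <- function(true_vco2_ml_min, params = trace_params(), seed = 1,
                      injected_volume_ml = NULL, stage = "instar4",
                      session_id = "s_001", individual_id = NA_character_,
                      is_control = FALSE, control_session_id = NA_character_) {
  if (!is.numeric(true_vco2_ml_min) || length(true_vco2_ml_min) != 1L ||
      !is.finite(true_vco2_ml_min) || true_vco2_ml_min < 0) {
    abort("`true_vco2_ml_min` must be a single finite rate >= 0.")
  }
  stopifnot(inherits(params, "trace_params"))
  if (is.null(injected_volume_ml)) {
    iv <- params$injected_volume_ml
    injected_volume_ml <- if (!is.null(names(iv)) && stage %in% names(iv)) {
      iv[[stage]]
    } else {
      iv[[1L]]
    }
  }
  if (injected_volume_ml <= 0 || injected_volume_ml > params$syringe_volume_ml) {
    abort("injected volume must be in (0, syringe volume].")
  }

  t <- seq(0, params$duration_s, by = 1 / params$sample_hz)
  baseline <- params$baseline_ppm + params$drift_ppm_per_s * t

  # CO2 volume in the injected aliquot, then its excess area in ppm*s:
  # volume [mL] = area [ppm*s] * 1e-6 * flow [mL/min] / 60 [s/min]
  v_bolus <- true_vco2_ml_min * params$incubation_min *
    injected_volume_ml / params$syringe_volume_ml
  area_ppm_s <- v_bolus * 60e6 / params$flow_rate_ml_min
  centre <- params$injection_time_s + 5 * params$bolus_sd_s
  excess <- area_ppm_s / (params$bolus_sd_s * sqrt(2 * pi)) *
    exp(-0.5 * ((t - centre) / params$bolus_sd_s)^2)

  ppm <- withr::with_seed(as.integer(seed), {
    baseline + excess + rnorm(length(t), 0, params$noise_sd_ppm)
  })

  new_resp_session(
    trace = tibble::tibble(time_s = t, co2_ppm = ppm),
    params = params,
    injected_volume_ml = injected_volume_ml,
    session_id = session_id,
    individual_id = individual_id,
    is_control = is_control,
    control_session_id = control_session_id,
    stage = as.character(stage)
  )
}

#' Generate a complete synthetic respirometry study
#'
#' Composes [sim_cohort()] and [sim_trace()]: one animal session per cohort
#' measurement plus one empty-syringe control session per measurement batch
#' (batches of `config$batch_size` animals within a stage). Purely in-memory;
#' use [write_study()] to lay it out on disk.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical (config, seed) gives an identical
#'   dataset, traces included.
#' @return A list of class `study_dataset` with elements `cohort` (tibble),
#'   `sessions` (named list of `resp_session`), `session_index` (tibble) and
#'   `config`.
#' @export
#' @examples
#' study <- sim_study(sim_config(replicates = dplyr::slice(default_replicates(), 4:6)),
#'                    seed = 1)
#' length(study$sessions)
sim_study <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) abort("a `seed` is required (none set in the config).")
  cohort <- sim_cohort(config, seed = derive_seed(seed, 1))

  sessions <- list()
  index <- list()
  if (nrow(cohort) > 0) {
    cohort$.row <- seq_len(nrow(cohort))
    by_stage <- split(cohort, cohort$stage, drop = TRUE)
    for (stg in names(by_stage)) {
      rows <- by_stage[[stg]]
      n_batches <- ceiling(nrow(rows) / config$batch_size)
      batch_of <- rep(seq_len(n_batches), each = config$batch_size)[seq_len(nrow(rows))]
      for (b in seq_len(n_batches)) {
        ctrl_id <- sprintf("ctrl_%s_%02d", stg, b)
        ctrl <- sim_trace(
          0, params = config$trace,
          seed = derive_seed(seed, 500000 + match(stg, stage_levels()) * 1000 + b),
          stage = stg, session_id = ctrl_id, is_control = TRUE
        )
        sessions[[ctrl_id]] <- ctrl
        index[[length(index) + 1L]] <- tibble::tibble(
          session_id = ctrl_id, individual_id = NA_character_, stage = stg,
          batch = b, is_control = TRUE, control_session_id = NA_character_
        )
        in_batch <- rows[batch_of == b, ]
        for (j in seq_len(nrow(in_batch))) {
          r <- in_batch[j, ]
          sid <- sprintf("s_%04d", r$.row)
          sessions[[sid]] <- sim_trace(
            r$true_vco2_ml_min, params = config$trace,
            seed = derive_seed(seed, 1000 + r$.row),
            stage = stg, session_id = sid, individual_id = r$individual_id,
            control_session_id = ctrl_id
          )
          index[[length(index) + 1L]] <- tibble::tibble(
            session_id = sid, individual_id = r$individual_id, stage = stg,
            batch = b, is_control = FALSE, control_session_id = ctrl_id
          )
        }
      }
    }
    cohort$.row <- NULL
  }

  structure(
    list(
      cohort = cohort,
      sessions = sessions,
      session_index = if (length(index)) dplyr::bind_rows(index) else
        tibble::tibble(session_id = character(), individual_id = character(),
                       stage = character(), batch = integer(),
                       is_control = logical(), control_session_id = character()),
      config = config
    ),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset>", nrow(x$cohort), "measurements,",
      length(x$sessions), "sessions",
      sprintf("(%d controls)\n", sum(x$session_index$is_control)))
  invisible(x)
}
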