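#' Write a study dataset to disk
#'
#' Lays out the on-disk exchange format: `cohort.csv` (one row per
#' measurement) and a `traces/` directory with one `<session_id>.csv`
#' (`time_s`, `co2_ppm`) plus a JSON sidecar per session carrying the
#' session metadata (`individual_id` is the string `"control"` for control
#' syringes).
#'
#' @param study A `study_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$cohort, file.path(dir, "cohort.csv"))
  for (s in study$sessions) {
    stem <- file.path(dir, "traces", s$session_id)
    readr::write_csv(s$trace, paste0(stem, ".csv"))
    side <- list(
      session_id = s$session_id,
      individual_id = if (s$is_control) "control" else s$individual_id,
      stage = s$stage,
      flow_rate_ml_min = s$flow_rate_ml_min,
      syringe_volume_ml = s$syringe_volume_ml,
      injected_volume_ml = s$injected_volume_ml,
      incubation_min = s$incubation_min,
      injection_time_s = s$injection_time_s,
      control_session_id = if (s$is_control) NULL else s$control_session_id
    )
    side <- side[!vapply(side, is.null, logical(1))]
    jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read one respirometry session from a trace CSV and its JSON sidecar
#'
#' @param csv_path Path to `<session_id>.csv`; the sidecar is the same path
#'   with a `.json` extension.
#' @return A `resp_session`.
#' @export
read_session <- function(csv_path) {
  json_path <- sub("\\.csv$", ".json", csv_path)
  if (!file.exists(csv_path)) abort(paste0("trace file not found: ", csv_path))
  if (!file.exists(json_path)) abort(paste0("sidecar not found: ", json_path))
  trace <- readr::read_csv(csv_path, show_col_types = FALSE)
  if (!all(c("time_s", "co2_ppm") %in% names(trace))) {
    abort("trace CSV must have columns time_s, co2_ppm.")
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  is_control <- identical(meta$individual_id, "control")
  ctrl_id <- meta$control_session_id
  if (!is.character(ctrl_id) || length(ctrl_id) != 1L) ctrl_id <- NA_character_
  structure(
    list(
      session_id = meta$session_id,
      individual_id = if (is_control) NA_character_ else meta$individual_id,
      is_control = is_control,
      control_session_id = ctrl_id,
      stage = meta$stage %||% NA_character_,
      trace = tibble::as_tibble(trace),
      flow_rate_ml_min = meta$flow_rate_ml_min,
      syringe_volume_ml = meta$syringe_volume_ml,
      injected_volume_ml = meta$injected_volume_ml,
      incubation_min = meta$incubation_min,
      injection_time_s = meta$injection_time_s
    ),
    class = "resp_session"
  )
}

#' Read every session in a traces directory
#'
#' @param dir Directory of `<session_id>.csv` / `.json` pairs.
#' @return Named list of `resp_session` objects.
#' @export
read_sessions <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) abort(paste0("no trace CSVs in ", dir))
  sessions <- purrr::map(files, read_session)
  names(sessions) <- purrr::map_chr(sessions, "session_id")
  sessions
}

#' Read a cohort table written by [write_study()]
#'
#' @param path Path to `cohort.csv`.
#' @return Tibble with host and stage as factors in analysis order.
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("individual_id", "family_id", "host", "stage", "dev_time_days",
           "mass_g", "sex")
  if (!all(req %in% names(cohort))) {
    abort(paste0("cohort.csv must have columns: ", paste(req, collapse = ", ")))
  }
  cohort$host <- factor(cohort$host, levels = host_levels())
  cohort$stage <- factor(cohort$stage, levels = stage_levels())
  cohort
}

#' Read a study directory back into memory
#'
#' @param dir Directory written by [write_study()].
#' @return A `study_dataset` (with `config = NULL`).
#' @export
read_study <- function(dir) {
  cohort <- read_cohort(file.path(dir, "cohort.csv"))
  sessions <- read_sessions(file.path(dir, "traces"))
  index <- purrr::map_dfr(sessions, function(s) {
    tibble::tibble(session_id = s$session_id, individual_id = s$individual_id,
                   is_control = s$is_control,
                   control_session_id = s$control_session_id)
  })
  if (!all(is.na(index$individual_id) |
           index$individual_id %in% cohort$individual_id)) {
    abort("a session references an individual that is not in the cohort.")
  }
  structure(list(cohort = cohort, sessions = sessions, session_index = index,
                 config = NULL),
            class = "study_dataset")
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path YAML file path.
#' @return `path` invisibly; [read_sim_config()] returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- list(
    n_families = config$n_families,
    replicates = as.data.frame(config$replicates),
    scaling_exponent_b = config$scaling_exponent_b,
    scaling_coefficient_a = as.list(config$scaling_coefficient_a),
    family_sd = config$family_sd,
    individual_sd = config$individual_sd,
    residual_sd = config$residual_sd,
    distributions = as.data.frame(config$distributions),
    sex_prob = as.list(config$sex_prob),
    batch_size = config$batch_size,
    trace = unclass(config$trace),
    seed = config$seed
  )
  out$trace$injected_volume_ml <- as.list(out$trace$injected_volume_ml)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tr <- raw$trace
  tr$injected_volume_ml <- unlist(tr$injected_volume_ml)
  sim_config(
    n_families = raw$n_families,
    replicates = tibble::as_tibble(as.data.frame(raw$replicates)),
    scaling_exponent_b = raw$scaling_exponent_b,
    scaling_coefficient_a = unlist(raw$scaling_coefficient_a),
    family_sd = raw$family_sd,
    individual_sd = raw$individual_sd,
    residual_sd = raw$residual_sd,
    distributions = tibble::as_tibble(as.data.frame(raw$distributions)),
    sex_prob = unlist(raw$sex_prob),
    batch_size = raw$batch_size,
    trace = do.call(trace_params, tr),
    seed = raw$seed
  )
}
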