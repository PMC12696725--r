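fit_to_list <- function(fit) {
  list(
    formula = deparse(fit$formula),
    fixed_effects = as.data.frame(tidy(fit, "fixed")),
    random_variances = as.data.frame(tidy(fit, "ran_pars")[, c("term", "estimate")]),
    wald = as.data.frame(wald_chi2_tests(fit)),
    contrasts = as.data.frame(pairwise_contrasts_tukey(fit, "host")),
    singular = fit$singular,
    converged = fit$converged
  )
}

#' Run the full analysis pipeline: simulate, process, metrics, fit
#'
#' One reproducible end-to-end run. Stages: (1) simulate a study and write
#' it under `out_dir`; (2) read the traces back and process them to VCO2
#' (`vco2.csv`); (3) join metrics onto the cohort (`metrics.csv`); (4) fit
#' the growth-rate, metabolic-rate and growth-cost mixed models and the
#' mass-scaling regression (`fits.json`); (5) write a `manifest.json` with
#' the seed, file hashes and QC counters. The single seed fans out to
#' per-stage child seeds via [derive_seed()]. Growth-rate and growth-cost
#' models use 4th-instar measurements (the stage at which performance is
#' scored); the metabolic-rate model and mass-scaling fit use both larval
#' stages.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param out_dir Writable output directory.
#' @return The run manifest (list of class `run_manifest`), invisibly.
#' @export
run_all <- function(config, seed, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_name <- "simulate"
  manifest <- tryCatch({
    study <- sim_study(config, seed = seed)
    write_study(study, out_dir)

    stage_name <- "process"
    sessions <- if (length(study$sessions)) read_sessions(file.path(out_dir, "traces")) else list()
    vco2 <- if (length(sessions)) process_study(sessions) else
      tibble::tibble(session_id = character(), individual_id = character(),
                     stage = character(), vco2_ml_min = numeric(),
                     qc_flags = character())
    readr::write_csv(vco2, file.path(out_dir, "vco2.csv"))

    stage_name <- "metrics"
    cohort <- read_cohort(file.path(out_dir, "cohort.csv"))
    metrics <- if (nrow(cohort)) attach_metrics(cohort, vco2) else cohort
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
    if (nrow(metrics) != nrow(cohort)) {
      abort("row loss between cohort and metrics tables.")
    }

    stage_name <- "fit"
    fits <- list()
    if (nrow(metrics) > 0) {
      larvae <- dplyr::filter(metrics, .data$stage != "pupa")
      fourth <- dplyr::filter(metrics, .data$stage == "instar4")
      larvae$ln_mass <- log(larvae$mass_g)
      if (nrow(fourth) > 0 && dplyr::n_distinct(fourth$host) >= 2) {
        fits$growth_rate <- fit_to_list(
          fit_lmm(fourth, growth_rate ~ host + (1 | family_id))
        )
        fits$growth_cost <- fit_to_list(
          fit_lmm(fourth, growth_cost ~ host + (1 | family_id))
        )
      }
      if (nrow(larvae) > 0 && dplyr::n_distinct(larvae$host) >= 2) {
        fits$vco2 <- fit_to_list(
          fit_lmm(larvae,
                  vco2_ml_min ~ host * stage + ln_mass + (1 | family_id / individual_id))
        )
        ms <- fit_mass_scaling(larvae)
        fits$mass_scaling <- list(
          exponent_b = ms$exponent_b,
          coefficient_a = as.list(ms$coefficient_a),
          unit = ms$unit,
          interaction_lrt = as.data.frame(ms$interaction_lrt),
          host_test = as.data.frame(ms$host_test),
          slope_test = as.data.frame(ms$slope_test),
          n = ms$n
        )
      }
    }
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")

    stage_name <- "manifest"
    files <- c("cohort.csv", "vco2.csv", "metrics.csv", "fits.json")
    files <- c(files, file.path("traces", list.files(file.path(out_dir, "traces"))))
    hashes <- tools::md5sum(file.path(out_dir, files))
    qc <- list(
      n_measurements = nrow(cohort),
      n_sessions = length(sessions),
      n_controls = sum(purrr::map_lgl(sessions, "is_control")),
      n_flagged = if (nrow(vco2)) sum(vco2$qc_flags != "") else 0L,
      n_missing_vco2 = if (nrow(metrics) && "vco2_ml_min" %in% names(metrics))
        sum(is.na(metrics$vco2_ml_min)) else nrow(metrics)
    )
    manifest <- structure(
      list(
        seed = seed,
        package_version = as.character(packageVersion("hostcost")),
        out_dir = normalizePath(out_dir),
        files = tibble::tibble(path = files, md5 = unname(hashes)),
        qc = qc,
        has_fits = length(fits) > 0
      ),
      class = "run_manifest"
    )
    manifest_json <- list(
      seed = manifest$seed, package_version = manifest$package_version,
      files = as.data.frame(manifest$files), qc = manifest$qc,
      has_fits = manifest$has_fits
    )
    jsonlite::write_json(manifest_json, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest
  },
  error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s (partial outputs kept in %s)",
                  stage_name, conditionMessage(e), out_dir))
  })
  invisible(manifest)
}

#' Read a run manifest back from disk
#'
#' @param out_dir Directory of a completed [run_all()] run.
#' @return A `run_manifest`.
#' @export
read_manifest <- function(out_dir) {
  path <- file.path(out_dir, "manifest.json")
  if (!file.exists(path)) abort("no manifest.json found; incomplete run.")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(seed = raw$seed, package_version = raw$package_version,
         out_dir = normalizePath(out_dir),
         files = tibble::as_tibble(raw$files), qc = as.list(raw$qc),
         has_fits = isTRUE(raw$has_fits)),
    class = "run_manifest"
  )
}

#' Human-readable summary report of a pipeline run
#'
#' Verifies the manifest's file hashes, then renders the fitted model
#' tables, contrasts, mass-scaling estimates and QC counters as plain text.
#' Runs with no data produce a report with explicit "no data" sections and a
#' `complete = FALSE` status (the CLI exits nonzero in that case); tampered
#' or missing files fail verification.
#'
#' @param manifest A `run_manifest` or the path of a run directory.
#' @param file Optional path to also write the report to.
#' @return Character vector of report lines, invisibly; attribute
#'   `complete` is `FALSE` for empty runs.
#' @export
make_report <- function(manifest, file = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "run_manifest"))
  out_dir <- manifest$out_dir

  paths <- file.path(out_dir, manifest$files$path)
  current <- tools::md5sum(paths)
  bad <- manifest$files$path[is.na(current) | current != manifest$files$md5]
  if (length(bad)) {
    abort(paste0("manifest verification failed for: ", paste(bad, collapse = ", ")))
  }

  lines <- c(
    "Host-plant energetics pipeline report",
    strrep("=", 42),
    sprintf("seed: %s   hostcost %s", manifest$seed, manifest$package_version),
    sprintf("outputs: %s (%d files, hashes verified)", out_dir, nrow(manifest$files)),
    "",
    "QC summary",
    sprintf("  measurements: %s", manifest$qc$n_measurements),
    sprintf("  sessions: %s (%s controls)", manifest$qc$n_sessions, manifest$qc$n_controls),
    sprintf("  flagged sessions: %s", manifest$qc$n_flagged),
    sprintf("  rows without VCO2: %s", manifest$qc$n_missing_vco2),
    ""
  )

  complete <- isTRUE(manifest$has_fits)
  if (!complete) {
    lines <- c(lines, "Model fits", "  no data: no models were fitted.", "")
  } else {
    fits <- jsonlite::read_json(file.path(out_dir, "fits.json"), simplifyVector = TRUE)
    fmt_tab <- function(df) {
      if (is.null(df) || nrow(as.data.frame(df)) == 0) return("  (empty)")
      paste0("  ", utils::capture.output(print(as.data.frame(df), digits = 4,
                                               row.names = FALSE)))
    }
    for (nm in setdiff(names(fits), "mass_scaling")) {
      f <- fits[[nm]]
      lines <- c(lines,
                 sprintf("Model: %s", nm),
                 sprintf("  %s", f$formula),
                 "  Wald chi-square (Type II):", fmt_tab(f$wald),
                 "  Tukey pairwise contrasts:", fmt_tab(f$contrasts),
                 "")
    }
    if (!is.null(fits$mass_scaling)) {
      ms <- fits$mass_scaling
      lines <- c(lines,
                 "Mass scaling: rate = a * mass^b",
                 sprintf("  b = %.4f   (n = %d)", ms$exponent_b, ms$n),
                 sprintf("  a[%s] = %.4f %s", names(ms$coefficient_a),
                         unlist(ms$coefficient_a), ms$unit),
                 "  interaction LRT:", fmt_tab(ms$interaction_lrt),
                 "")
    }
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(structure(lines, complete = complete))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed", x$seed, "-", nrow(x$files), "files in", x$out_dir, "\n")
  invisible(x)
}
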