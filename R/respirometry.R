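#' Convert an analyzer signal in ppm to a dimensionless air fraction
#'
#' @param co2_ppm Numeric vector of CO2 readings (ppm).
#' @return `co2_ppm * 1e-6`.
#' @export
#' @examples
#' ppm_to_fraction(c(0, 100, 1e6))
ppm_to_fraction <- function(co2_ppm) {
  if (!is.numeric(co2_ppm) || any(!is.finite(co2_ppm))) {
    abort("`co2_ppm` must be finite numeric.")
  }
  co2_ppm * 1e-6
}

#' Fit the reference (baseline) model of a respirometry trace
#'
#' The analyzer reads CO2-scrubbed reference air before the sample is
#' injected; that segment defines the baseline subtracted from the whole
#' trace. A linear fit (default) absorbs slow analyzer drift; a constant
#' (mean) baseline is available for drift-free runs.
#'
#' @param session A `resp_session`.
#' @param reference_window Numeric `c(t0, t1)` in seconds; must end at or
#'   before the injection marker and contain at least 5 samples. Default:
#'   from the start of the trace to 5 s before `injection_time_s`.
#' @param method `"linear"` or `"constant"`.
#' @return An object of class `resp_baseline`: coefficients, the residual
#'   noise SD over the reference window, and the window used. Evaluate it at
#'   arbitrary times with `predict()`.
#' @export
fit_baseline <- function(session, reference_window = NULL,
                         method = c("linear", "constant")) {
  stopifnot(inherits(session, "resp_session"))
  method <- match.arg(method)
  if (is.null(reference_window)) {
    reference_window <- c(min(session$trace$time_s), session$injection_time_s - 5)
  }
  if (length(reference_window) != 2L || diff(reference_window) <= 0) {
    abort("`reference_window` must be c(t0, t1) with t1 > t0.")
  }
  if (reference_window[2] > session$injection_time_s) {
    abort("reference window must end at or before the injection time.")
  }
  keep <- session$trace$time_s >= reference_window[1] &
    session$trace$time_s <= reference_window[2]
  if (sum(keep) < 5L) {
    abort("reference window contains fewer than 5 samples.")
  }
  t <- session$trace$time_s[keep]
  y <- session$trace$co2_ppm[keep]
  if (method == "linear") {
    fit <- lm(y ~ t)
    coefs <- c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
    res <- residuals(fit)
  } else {
    coefs <- c(intercept = mean(y), slope = 0)
    res <- y - mean(y)
  }
  structure(
    list(method = method, coefficients = coefs,
         noise_sd = if (length(res) > 2) sd(res) else 0,
         window = reference_window, n = length(t)),
    class = "resp_baseline"
  )
}

#' @export
predict.resp_baseline <- function(object, time_s, ...) {
  object$coefficients[["intercept"]] + object$coefficients[["slope"]] * time_s
}

#' @export
print.resp_baseline <- function(x, ...) {
  cat(sprintf("<resp_baseline> %s fit over [%g, %g] s: %.4g + %.4g t ppm (noise SD %.3g ppm)\n",
              x$method, x$window[1], x$window[2],
              x$coefficients[["intercept"]], x$coefficients[["slope"]], x$noise_sd))
  invisible(x)
}

#' Integrate the baseline-excess bolus into a CO2 volume
#'
#' Baseline-corrected readings are converted to air fractions, multiplied by
#' the carrier flow rate and integrated over time (trapezoidal rule, time in
#' minutes), giving the CO2 volume in mL that passed the analyzer within the
#' window.
#'
#' @param session A `resp_session`.
#' @param baseline A fitted `resp_baseline`.
#' @param window Numeric `c(t0, t1)` in seconds covering the bolus.
#' @return CO2 volume in mL (may be slightly negative under noise).
#' @export
integrate_bolus <- function(session, baseline, window) {
  stopifnot(inherits(session, "resp_session"), inherits(baseline, "resp_baseline"))
  if (length(window) != 2L || diff(window) <= 0) {
    abort("`window` must be c(t0, t1) with t1 > t0.")
  }
  keep <- session$trace$time_s >= window[1] & session$trace$time_s <= window[2]
  if (sum(keep) < 2L) {
    abort("integration window lies outside the trace (fewer than 2 samples).")
  }
  t_min <- session$trace$time_s[keep] / 60
  excess_frac <- ppm_to_fraction(
    session$trace$co2_ppm[keep] - predict(baseline, session$trace$time_s[keep])
  )
  pracma::trapz(t_min, excess_frac * session$flow_rate_ml_min)
}

#' CO2 production rate from integrated bolus volumes
#'
#' Implements the stop-flow correction chain: the control syringe's volume is
#' subtracted first, the difference is scaled by total syringe volume over
#' injected volume (the un-injected air carries CO2 at the same fraction),
#' and the total is divided by the incubation time, giving mL CO2 min^-1.
#'
#' @param sample_volume_ml Integrated bolus volume of the animal syringe (mL).
#' @param control_volume_ml Integrated volume of the paired empty syringe.
#' @param syringe_volume_ml Total incubation volume (mL).
#' @param injected_volume_ml Injected aliquot (mL), > 0.
#' @param incubation_min Minutes sealed, > 0.
#' @return VCO2 in mL min^-1 (vectorized).
#' @export
#' @examples
#' compute_vco2(0.06, 0.01, 20, 10, 60)  # 0.05 * 2 / 60
compute_vco2 <- function(sample_volume_ml, control_volume_ml,
                         syringe_volume_ml, injected_volume_ml, incubation_min) {
  if (any(injected_volume_ml <= 0)) abort("`injected_volume_ml` must be > 0.")
  if (any(syringe_volume_ml < injected_volume_ml)) {
    abort("`syringe_volume_ml` must be >= `injected_volume_ml`.")
  }
  if (any(incubation_min <= 0)) abort("`incubation_min` must be > 0.")
  (sample_volume_ml - control_volume_ml) *
    (syringe_volume_ml / injected_volume_ml) / incubation_min
}

detect_bolus_window <- function(session, baseline, k = 3) {
  t <- session$trace$time_s
  excess <- session$trace$co2_ppm - predict(baseline, t)
  thr <- k * max(baseline$noise_sd, 1e-9)
  candidate <- excess > thr & t > baseline$window[2]
  if (!any(candidate)) return(NULL)
  runs <- rle(candidate)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  on <- which(runs$values)
  # keep the run containing the largest excess
  peak <- which.max(replace(excess, !candidate, -Inf))
  hit <- on[starts[on] <= peak & ends[on] >= peak]
  if (length(hit) == 0) hit <- on[which.max(ends[on] - starts[on])]
  c(t[starts[hit]], t[ends[hit]])
}

#' Process one animal/control session pair into a VCO2 estimate
#'
#' Full calculation chain for a single syringe run: fit the pre-injection
#' baseline, auto-detect the bolus window (contiguous excess above `k` times
#' the reference noise SD, unless a window is supplied), integrate
#' (fraction x flow) over the window for both the animal and the paired
#' control syringe, then apply [compute_vco2()]. The control is integrated
#' over the same time window as the sample so noise treatment is symmetric.
#'
#' Sessions whose bolus cannot be detected are flagged (`qc_flags`
#' "no_bolus") and integrated over the whole post-injection segment rather
#' than dropped; negative corrected volumes are retained and flagged
#' ("negative_volume"), since truncating them at zero would bias low rates
#' upward.
#'
#' @param session Animal `resp_session`.
#' @param control_session Paired empty-syringe `resp_session` (may be the
#'   session itself for self-checks).
#' @param windows Optional list with elements `reference` and/or
#'   `integration`, each `c(t0, t1)` seconds.
#' @param baseline_method `"linear"` (default) or `"constant"`.
#' @param k Detection threshold in reference-noise SDs (default 3).
#' @return One-row tibble: `session_id`, `individual_id`, `vco2_ml_min`,
#'   `integrated_volume_ml`, `control_volume_ml`, `window_lo_s`,
#'   `window_hi_s`, `baseline_model`, `qc_flags`.
#' @export
process_session <- function(session, control_session, windows = NULL,
                            baseline_method = c("linear", "constant"), k = 3) {
  stopifnot(inherits(session, "resp_session"),
            inherits(control_session, "resp_session"))
  baseline_method <- match.arg(baseline_method)
  if (!isTRUE(all.equal(session$flow_rate_ml_min, control_session$flow_rate_ml_min))) {
    warn("sample and control sessions have different flow rates.")
  }
  flags <- character()

  bl_s <- fit_baseline(session, windows$reference, method = baseline_method)
  bl_c <- fit_baseline(control_session, windows$reference, method = baseline_method)

  win <- windows$integration
  if (is.null(win)) {
    win <- detect_bolus_window(session, bl_s, k = k)
    if (is.null(win)) {
      if (!session$is_control) flags <- c(flags, "no_bolus")
      win <- c(session$injection_time_s, max(session$trace$time_s))
    }
  }

  v_sample <- integrate_bolus(session, bl_s, win)
  v_control <- integrate_bolus(control_session, bl_c, win)
  vco2 <- compute_vco2(v_sample, v_control, session$syringe_volume_ml,
                       session$injected_volume_ml, session$incubation_min)
  if (v_sample - v_control < 0) flags <- c(flags, "negative_volume")

  tibble::tibble(
    session_id = session$session_id,
    individual_id = session$individual_id,
    stage = session$stage %||% NA_character_,
    vco2_ml_min = vco2,
    integrated_volume_ml = v_sample,
    control_volume_ml = v_control,
    window_lo_s = win[1],
    window_hi_s = win[2],
    baseline_model = sprintf("%s (%.4g + %.4g t ppm)", bl_s$method,
                             bl_s$coefficients[["intercept"]],
                             bl_s$coefficients[["slope"]]),
    qc_flags = paste(flags, collapse = ";")
  )
}

#' Process every animal session of a study against its paired control
#'
#' @param study A `study_dataset` from [sim_study()] or [read_study()], or a
#'   named list of `resp_session` objects (controls resolved through each
#'   session's `control_session_id`).
#' @param ... Passed to [process_session()].
#' @return Tibble with one row per non-control session, plus a `stage`
#'   column when the study carries a session index.
#' @export
process_study <- function(study, ...) {
  sessions <- if (inherits(study, "study_dataset")) study$sessions else study
  stopifnot(is.list(sessions), length(sessions) > 0 || TRUE)
  animal <- purrr::keep(sessions, ~ !.x$is_control)
  out <- purrr::map_dfr(animal, function(s) {
    ctrl <- sessions[[s$control_session_id]]
    if (is.null(ctrl)) {
      abort(sprintf("session %s: control %s not found.", s$session_id,
                    s$control_session_id))
    }
    process_session(s, ctrl, ...)
  })
  out
}
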