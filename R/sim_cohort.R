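#' Generate a synthetic split-brood cohort
#'
#' Simulates one measurement record per (individual, stage) cell of the
#' replicate design. Individuals are created per host at the largest stage
#' count for that host; stages with fewer measurements use a seeded random
#' subset of the same individuals, so repeated measurements across stages
#' share an individual (and its random intercept), as in a longitudinal
#' respirometry protocol. Families are allocated to hosts round-robin from a
#' seeded shuffle, so every family contributes to every host whenever counts
#' allow (split-brood design).
#'
#' The latent rate for each record is
#' `a_host * mass_g^b * exp(family + individual + residual)` in mL h^-1,
#' returned as `true_vco2_ml_min` in mL min^-1.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical (config, seed) gives identical output.
#' @param strict_balance If `TRUE`, error when replicate counts are not
#'   multiples of `n_families` (perfectly balanced broods impossible).
#' @return A tibble with columns `individual_id`, `family_id`, `host`,
#'   `stage`, `dev_time_days`, `mass_g`, `sex`, `true_vco2_ml_min`.
#' @export
#' @examples
#' cohort <- sim_cohort(sim_config(), seed = 1)
#' dplyr::count(cohort, stage, host)
sim_cohort <- function(config, seed = config$seed, strict_balance = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) abort("a `seed` is required (none set in the config).")
  reps <- config$replicates
  empty <- tibble::tibble(
    individual_id = character(), family_id = character(),
    host = factor(character(), levels = host_levels()),
    stage = factor(character(), levels = stage_levels()),
    dev_time_days = numeric(), mass_g = numeric(), sex = character(),
    true_vco2_ml_min = numeric()
  )
  if (nrow(reps) == 0) return(empty)
  if (strict_balance && any(reps$n %% config$n_families != 0)) {
    abort("replicate counts are not multiples of n_families (strict_balance).")
  }

  withr::with_seed(as.integer(seed), {
    fam_ids <- sprintf("fam_%02d", seq_len(config$n_families))
    fam_eff <- setNames(rnorm(config$n_families, 0, config$family_sd), fam_ids)

    hosts <- intersect(host_levels(), unique(reps$host))
    individuals <- purrr::map_dfr(hosts, function(h) {
      n_ind <- max(reps$n[reps$host == h])
      fams <- rep(sample(fam_ids), length.out = n_ind)
      tibble::tibble(
        individual_id = sprintf("ind_%s_%03d", h, seq_len(n_ind)),
        family_id = fams,
        host = h,
        ind_eff = rnorm(n_ind, 0, config$individual_sd),
        sex = sample(names(config$sex_prob), n_ind, replace = TRUE,
                     prob = config$sex_prob)
      )
    })

    reps <- dplyr::arrange(
      reps,
      factor(.data$stage, levels = stage_levels()),
      factor(.data$host, levels = host_levels())
    )
    dists <- config$distributions
    rows <- purrr::pmap_dfr(reps, function(stage, host, n) {
      pool <- individuals[individuals$host == host, ]
      take <- if (n >= nrow(pool)) seq_len(nrow(pool)) else sort(sample(nrow(pool), n))
      ind <- pool[take, ]
      d <- dists[dists$stage == stage & dists$host == host, ]
      mass <- rlnorm(n, meanlog = log(d$mass_median_g), sdlog = d$mass_sdlog)
      dev  <- rlnorm(n, meanlog = log(d$dev_median_d), sdlog = d$dev_sdlog)
      resid <- rnorm(n, 0, config$residual_sd)
      a <- config$scaling_coefficient_a[[host]]
      rate_ml_h <- a * mass^config$scaling_exponent_b *
        exp(fam_eff[ind$family_id] + ind$ind_eff + resid)
      tibble::tibble(
        individual_id = ind$individual_id,
        family_id = ind$family_id,
        host = host,
        stage = stage,
        dev_time_days = dev,
        mass_g = mass,
        sex = ind$sex,
        true_vco2_ml_min = unname(rate_ml_h) / 60
      )
    })
    rows$host <- factor(rows$host, levels = host_levels())
    rows$stage <- factor(rows$stage, levels = stage_levels())
    rows
  })
}
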