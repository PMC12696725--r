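test_that("noiseless log-linear data are interpolated exactly", {
  mass <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  d <- tibble::tibble(mass_g = mass,
                      vco2_ml_min = 0.43 * mass^0.84 / 60,
                      host = "Urtica")
  # zero-residual data: the subsidiary Wald test is skipped with a warning
  expect_warning(fit <- fit_mass_scaling(d), "Wald test skipped")
  expect_equal(fit$exponent_b, 0.84, tolerance = 1e-10)
  expect_equal(unname(fit$coefficient_a[["Urtica"]]), 0.43, tolerance = 1e-10)

  # two points, one host: the slope is the secant of the log-log pair
  two <- tibble::tibble(mass_g = c(0.1, 0.4), vco2_ml_min = c(0.002, 0.007),
                        host = "Salix")
  f2 <- suppressWarnings(fit_mass_scaling(two))  # saturated 2-point fit
  secant <- (log(0.007) - log(0.002)) / (log(0.4) - log(0.1))
  expect_equal(f2$exponent_b, secant, tolerance = 1e-10)
})

test_that("mass-scaling parameters are recovered from latent cohort rates", {
  cohort <- sim_cohort(sim_config(), seed = 314)
  larvae <- dplyr::filter(cohort, stage != "pupa")
  fit <- fit_mass_scaling(larvae, rate = "true_vco2_ml_min")
  expect_lt(abs(fit$exponent_b - 0.84), 0.03)
  expect_lt(max(abs(fit$coefficient_a - c(0.43, 0.39, 0.44))), 0.05)
  expect_equal(unname(fit$interaction_lrt$df), 2L)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 4L)  # b + three a's
})

test_that("the likelihood-ratio test satisfies its identities", {
  d <- tibble::tibble(y = rnorm(40), x = rnorm(40), g = rep(c("a", "b"), 20))
  full <- lm(y ~ x + g, data = d)
  reduced <- lm(y ~ x, data = d)

  self <- lrt(full, full)
  expect_equal(self$chisq, 0)
  expect_equal(self$p_value, 1)

  ours <- lrt(full, reduced)
  ref <- lmtest::lrtest(reduced, full)  # independent implementation
  expect_equal(ours$chisq, ref$Chisq[2], tolerance = 1e-10)
  expect_equal(ours$p_value, ref$`Pr(>Chisq)`[2], tolerance = 1e-10)
  expect_gte(ours$chisq, 0)

  expect_error(lrt(full, lm(y ~ x, data = d[1:30, ])), "different data")
  expect_error(lrt(reduced, full), "not nested")
})

test_that("the interaction LRT holds its size under a null simulation", {
  n <- 120
  rejections <- 0L
  n_rep <- 200
  withr::with_seed(2024, {
    for (i in seq_len(n_rep)) {
      g <- factor(rep(c("a", "b", "c"), length.out = n))
      x <- rnorm(n)
      y <- 0.5 * x + c(a = 0, b = 0.3, c = -0.2)[g] + rnorm(n)
      d <- data.frame(y = y, x = x, g = g)
      out <- lrt(lm(y ~ x * g, data = d), lm(y ~ x + g, data = d))
      if (out$p_value < 0.05) rejections <- rejections + 1L
    }
  })
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_gte(rejections / n_rep, ci[1])
  expect_lte(rejections / n_rep, ci[2])
})

test_that("mixed models degenerate gracefully to OLS and exact means", {
  # family variance truly zero: fixed effects match least squares
  withr::with_seed(7, {
    d <- data.frame(
      y = rnorm(120), g = rep(c("a", "b", "c"), 40),
      fam = rep(sprintf("f%02d", 1:15), length.out = 120)
    )
  })
  fit <- suppressMessages(fit_lmm(d, y ~ g + (1 | fam)))
  ols <- lm(y ~ g, data = d)
  expect_lt(max(abs(lme4::fixef(fit$fit) - coef(ols))), 1e-6)
  expect_true(fit$singular || tidy(fit, "ran_pars")$estimate[1] < 1e-6)

  # balanced one-way design with no group-mean noise: each family sees the
  # same +/- deviation pattern in every group, so the estimated fixed
  # effects are the group means exactly
  exact <- data.frame(
    y = rep(c(1, 3, 7), each = 6) + rep(c(-0.2, 0.2), 9),
    g = rep(c("a", "b", "c"), each = 6),
    fam = rep(rep(c("f1", "f2", "f3"), each = 2), 3)
  )
  f2 <- suppressMessages(fit_lmm(exact, y ~ 0 + g + (1 | fam)))
  expect_equal(unname(lme4::fixef(f2$fit)), c(1, 3, 7), tolerance = 1e-8)
})

test_that("the family variance component is recoverable", {
  sims <- purrr::map_dbl(1:100, function(i) {
    withr::with_seed(5000 + i, {
      fam <- rep(sprintf("f%02d", 1:30), each = 10)
      eff <- rep(rnorm(30, 0, 0.3), each = 10)
      d <- data.frame(y = eff + rnorm(300, 0, 0.5), fam = fam)
    })
    fit <- suppressMessages(fit_lmm(d, y ~ 1 + (1 | fam)))
    tidy(fit, "ran_pars")$estimate[1]
  })
  expect_gt(median(sims), 0.09 * 0.5)
  expect_lt(median(sims), 0.09 * 1.5)
})

test_that("Wald chi-square tests respect marginality and the 1-df identity", {
  withr::with_seed(99, {
    d <- data.frame(
      y = rnorm(100), x = rep(c(0, 1), 50),
      fam = rep(sprintf("f%02d", 1:10), each = 10)
    )
    d$y <- d$y + 0.4 * d$x
  })
  fit <- suppressMessages(fit_lmm(d, y ~ x + (1 | fam)))
  w <- wald_chi2_tests(fit)
  cf <- summary(fit$fit)$coefficients
  z2 <- (cf["x", "Estimate"] / cf["x", "Std. Error"])^2
  expect_equal(w$chisq[w$term == "x"], z2, tolerance = 1e-8)
  expect_equal(w$p_value[w$term == "x"],
               pchisq(z2, 1, lower.tail = FALSE), tolerance = 1e-10)

  # balanced orthogonal design: Type II sums equal sequential (Type I) sums
  withr::with_seed(4, {
    d2 <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:10)
    d2$y <- rnorm(nrow(d2)) + (d2$a == "a2") * 0.5 + (d2$b == "b2") * 0.3
  })
  m <- lm(y ~ a + b, data = d2)
  t2 <- car::Anova(m, type = "II")
  t1 <- anova(m)
  expect_equal(t2["a", "Sum Sq"], t1["a", "Sum Sq"], tolerance = 1e-10)
  expect_equal(t2["b", "Sum Sq"], t1["b", "Sum Sq"], tolerance = 1e-10)
})

test_that("Wald p-values are uniform when the tested term is null", {
  pvals <- purrr::map_dbl(1:500, function(i) {
    withr::with_seed(20000 + i, {
      d <- data.frame(y = rnorm(150), x = rnorm(150),
                      g = factor(rep(c("a", "b", "c"), 50)))
      d$y <- d$y + 0.5 * d$x  # g is absent from the truth
    })
    w <- wald_chi2_tests(lm(y ~ x + g, data = d))
    w$p_value[w$term == "g"]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Tukey adjustment matches its studentized-range definition", {
  # two levels: adjusted equals unadjusted
  withr::with_seed(11, {
    d2 <- data.frame(y = rnorm(30) + rep(c(0, 0.5), 15),
                     g = factor(rep(c("a", "b"), 15)))
  })
  ct2 <- pairwise_contrasts_tukey(lm(y ~ g, data = d2), "g")
  expect_equal(nrow(ct2), 1L)
  expect_equal(ct2$p_value, ct2$p_unadjusted, tolerance = 1e-12)

  # identical group compositions: all differences exactly zero, p = 1
  same <- data.frame(y = rep(c(1, 2, 3), times = 3),
                     g = factor(rep(c("a", "b", "c"), each = 3)))
  cts <- pairwise_contrasts_tukey(lm(y ~ g, data = same), "g")
  expect_equal(cts$estimate, rep(0, 3))
  expect_equal(cts$p_value, rep(1, 3))

  # three balanced groups: adjusted p matches a Monte-Carlo studentized-range
  # null within 0.005
  withr::with_seed(23, {
    d3 <- data.frame(y = rnorm(24) + rep(c(0, 0.6, 0.9), each = 8),
                     g = factor(rep(c("a", "b", "c"), each = 8)))
  })
  fit3 <- lm(y ~ g, data = d3)
  ct3 <- pairwise_contrasts_tukey(fit3, "g")
  df_resid <- fit3$df.residual
  withr::with_seed(77, {
    n_draw <- 1e5
    z <- matrix(rnorm(n_draw * 3), nrow = 3)
    s <- sqrt(stats::rchisq(n_draw, df_resid) / df_resid)
    q_null <- (apply(z, 2, max) - apply(z, 2, min)) / s
  })
  for (i in seq_len(nrow(ct3))) {
    mc_p <- mean(q_null >= sqrt(2) * abs(ct3$statistic[i]))
    expect_lt(abs(mc_p - ct3$p_value[i]), 0.005)
  }

  # adjusted p never falls below unadjusted p
  expect_true(all(ct3$p_value >= ct3$p_unadjusted - 1e-12))
  expect_error(pairwise_contrasts_tukey(fit3, "host"), "not a term")
})
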