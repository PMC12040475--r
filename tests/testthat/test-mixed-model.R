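test_that("time scaling uses the sample SD and round-trips", {
  st <- scale_time(tibble::tibble(time_days = c(0, 2, 4)))
  expect_equal(st$records$time_scaled, c(-1, 0, 1))
  expect_equal(st$center, 2)
  expect_equal(st$scale, 2)
  set.seed(5)
  t <- runif(40, 0, 30)
  st2 <- scale_time(tibble::tibble(time_days = t))
  expect_equal(st2$records$time_scaled * st2$scale + st2$center, t)
  expect_error(scale_time(tibble::tibble(time_days = rep(3, 5))), "distinct")
})

test_that("slopes on scaled and raw time agree after back-transformation", {
  rec <- make_linear_records(rate = 0.42, n_id = 3, times = seq(0, 12, by = 2))
  st <- scale_time(rec)
  raw <- coef(lm(healing_distance_mm ~ time_days, rec))[2]
  scl <- coef(lm(healing_distance_mm ~ time_scaled, st$records))[2]
  expect_equal(unname(scl) / st$scale, unname(raw), tolerance = 1e-12)
})

test_that("noiseless identical individuals give the exact rate with floored variances", {
  rec <- make_linear_records(rate = 0.6, n_id = 4, times = seq(0, 12, by = 3))
  fit <- fit_healing_lmm(rec)
  rates <- healing_rates(fit)
  expect_equal(rates$rate_mm_per_day, 0.6, tolerance = 1e-6)
  expect_lt(fit$sigma2, 1e-6)
  expect_lt(sum(diag(fit$G)), 1e-4)
  expect_true(fit$converged)
})

test_that("mm/day rates are invariant to the time-scaling choice on noiseless data", {
  rec <- make_linear_records(rate = 0.31, n_id = 3, times = seq(0, 10, by = 2),
                             groups = c("a", "b"))
  r_std <- healing_rates(fit_healing_lmm(rec, time_scaling = "standardize"))
  r_raw <- healing_rates(fit_healing_lmm(rec, time_scaling = "none"))
  expect_equal(r_std$rate_mm_per_day, r_raw$rate_mm_per_day, tolerance = 1e-6)
})

test_that("with a balanced design the fixed effects equal closed-form OLS", {
  # every individual shares the same time grid, so GLS reduces to OLS exactly
  set.seed(42)
  times <- seq(0, 14, by = 2)
  rec <- make_linear_records(rate = 0.6, n_id = 6, times = times,
                             groups = c("a", "b"))
  rec$healing_distance_mm <- rec$healing_distance_mm + rnorm(nrow(rec), sd = 0.8)
  fit <- fit_healing_lmm(rec, penalty = 0)

  st <- scale_time(rec)
  g <- factor(rec$species)
  X <- cbind(stats::model.matrix(~ 0 + g), stats::model.matrix(~ 0 + g) * st$records$time_scaled)
  beta_ols <- solve(crossprod(X), crossprod(X, rec$healing_distance_mm))
  expect_equal(unname(fit$beta), unname(drop(beta_ols)), tolerance = 1e-6)
})

test_that("penalized engine matches lme4 REML when the penalty vanishes", {
  skip_if_not_installed("lme4")
  cfg <- make_study_emulation("null_two_groups", seed = 3)
  rec <- healing_distances(simulate_healing_data(cfg)$observations)
  fit <- fit_healing_lmm(rec, penalty = 0)
  d <- scale_time(rec)$records
  lfit <- lme4::lmer(
    healing_distance_mm ~ 0 + species + species:time_scaled +
      (1 + time_scaled | individual_id),
    data = d, REML = TRUE
  )
  expect_equal(fit$neg2reml, lme4::REMLcrit(lfit), tolerance = 1e-6)
  expect_equal(unname(sort(fit$beta)), unname(sort(lme4::fixef(lfit))), tolerance = 1e-5)
  expect_equal(fit$sigma2, unname(lme4::getME(lfit, "sigma"))^2, tolerance = 1e-4)
  vc <- lme4::VarCorr(lfit)$individual_id
  expect_equal(unname(fit$G), unname(vc[1:2, 1:2]), tolerance = 1e-3)
})

test_that("a vanishing penalty converges to the unpenalized REML optimum", {
  cfg <- make_study_emulation("null_two_groups", seed = 9)
  rec <- healing_distances(simulate_healing_data(cfg)$observations)
  f0 <- fit_healing_lmm(rec, penalty = 0)
  f1 <- fit_healing_lmm(rec, penalty = 1e-8)
  expect_lt(abs(f1$neg2reml - f0$neg2reml), 1e-4)
})

test_that("the default penalty keeps the random-effect covariance non-singular", {
  set.seed(13)
  # data generated WITHOUT random effects tempt the optimizer onto the boundary
  rec <- make_linear_records(rate = 0.5, n_id = 6, times = seq(0, 12, by = 2),
                             groups = c("a", "b"))
  rec$healing_distance_mm <- rec$healing_distance_mm + rnorm(nrow(rec), sd = 0.7)
  fit <- fit_healing_lmm(rec, penalty = 0.01)
  ev <- eigen(fit$G, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_false(fit$singular)
  expect_true(isSymmetric(fit$G, tol = 1e-10))
})

test_that("rates and standard errors back-transform by the time SD", {
  # slope 0.5 on time scaled with sd 2 means 0.25 mm/day
  rec <- make_linear_records(rate = 0.25, n_id = 3, times = c(0, 2, 4))
  fit <- fit_healing_lmm(rec)
  expect_equal(fit$time_scale, sd(rec$time_days))
  j <- match("slope_baboon", names(fit$beta))
  expect_equal(unname(fit$beta[j]) / fit$time_scale,
               healing_rates(fit)$rate_mm_per_day, tolerance = 1e-12)
})

test_that("slope contrasts are null at zero, symmetric under relabeling", {
  # two groups with literally identical data
  rec <- make_linear_records(rate = 0.6, n_id = 3, times = seq(0, 12, by = 3),
                             groups = c("a", "b"))
  set.seed(77)
  noise <- rnorm(nrow(rec) / 2, sd = 0.5)
  rec$healing_distance_mm <- rec$healing_distance_mm + rep(noise, 2)
  fit <- fit_healing_lmm(rec)
  ct <- compare_rates(fit)
  expect_lt(ct$statistic, 1e-8)
  expect_equal(ct$p.value, 1, tolerance = 1e-4)
  expect_equal(ct$df, 1L)

  # relabeling invariance on unequal groups
  set.seed(88)
  cfg <- make_study_emulation("null_two_groups", seed = 88)
  rec2 <- healing_distances(simulate_healing_data(cfg)$observations)
  f2 <- fit_healing_lmm(rec2)
  s_ab <- compare_rates(f2, c("group_a", "group_b"))$statistic
  s_ba <- compare_rates(f2, c("group_b", "group_a"))$statistic
  expect_equal(s_ab, s_ba, tolerance = 1e-10)

  expect_error(compare_rates(f2, "group_a"), "at least 2")
  expect_error(compare_rates(f2, c("group_a", "nope")), "unknown")
})

test_that("contrasts have power against a strongly shifted slope", {
  set.seed(202)
  hits <- 0
  for (k in 1:20) {
    profiles <- list(
      species_profile("a", 6, 0.6, interval_min = 2, interval_max = 2, horizon = 14),
      species_profile("b", 6, 0.6, interval_min = 2, interval_max = 2, horizon = 14),
      species_profile("c", 6, 0.6, interval_min = 2, interval_max = 2, horizon = 14),
      # shifted by ~5 SEs of a pairwise slope difference (SE_diff ~ 0.09 mm/d
      # at this design), a strong, clearly detectable departure
      species_profile("d", 6, 1.05, interval_min = 2, interval_max = 2, horizon = 14)
    )
    cfg <- simulation_config(profiles, seed = 5000 + k)
    rec <- healing_distances(simulate_healing_data(cfg)$observations)
    p <- compare_rates(fit_healing_lmm(rec))$p.value
    hits <- hits + (p < 0.001)
  }
  expect_gte(hits / 20, 0.95)
})

test_that("group and individual preconditions are enforced with clear messages", {
  rec_bad <- dplyr::bind_rows(
    make_linear_records(rate = 0.5, n_id = 2, times = c(0, 2, 4), groups = "duo"),
    make_linear_records(rate = 0.5, n_id = 1, times = c(0, 2, 4), groups = "solo")
  )
  expect_error(fit_healing_lmm(rec_bad), "solo")

  one_time <- make_linear_records(rate = 0.5, n_id = 2, times = 0)
  expect_error(fit_healing_lmm(one_time), "time points")
})

test_that("age classes split at quantiles with ties going low", {
  expect_equal(as.character(assign_age_classes(c(1, 2, 3, 4), "median")),
               c("low", "low", "high", "high"))
  expect_equal(as.character(assign_age_classes(1:6, "tertile")),
               rep(c("low", "mid", "high"), each = 2))
  set.seed(3)
  ages <- sample(20:90, 24)
  q <- assign_age_classes(ages, "quartile")
  expect_equal(unname(table(q)), rep(6L, 4), ignore_attr = TRUE)
  # a value exactly on the boundary joins the lower class
  m <- assign_age_classes(c(1, 2, 2, 4), "median")
  expect_equal(as.character(m), c("low", "low", "low", "high"))
  expect_error(assign_age_classes(c(1, 1, 1), "tertile"), "distinct")
})

test_that("tidy, glance and autoplot expose the fit", {
  cfg <- make_study_emulation("null_two_groups", seed = 4)
  rec <- healing_distances(simulate_healing_data(cfg)$observations)
  fit <- fit_healing_lmm(rec)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  rp <- tidy(fit, effects = "ran_pars")
  expect_equal(rp$estimate[rp$term == "var_residual"], fit$sigma2)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$nobs, nrow(rec))
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_healing_records(rec), "ggplot")
})

test_that("Wald intervals for a group slope approach nominal coverage", {
  # Nominal 95%; with 6 individuals/group the normal-quantile Wald interval
  # is expected to under-cover by a few points (roughly t with ~10 df), so
  # this guards against gross miscalibration rather than asserting 95%.
  set.seed(505)
  n_rep <- 400
  covered <- logical(n_rep)
  for (k in seq_len(n_rep)) {
    cfg <- make_study_emulation("null_two_groups", seed = 60000 + k)
    rec <- healing_distances(simulate_healing_data(cfg)$observations)
    rt <- healing_rates(fit_healing_lmm(rec))
    covered[k] <- abs(rt$rate_mm_per_day[1] - 0.6) <= qnorm(0.975) * rt$se[1]
  }
  expect_gte(mean(covered), 0.88)
  expect_lte(mean(covered), 0.97)
})
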