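#' Scale record times
#'
#' Standardizes time over all records, `s = (t - mean(t)) / sd(t)` (sample
#' SD), returning the scaling constants so model slopes can always be
#' back-transformed to mm/day.
#'
#' @param records Healing-record tibble with a `time_days` column.
#' @return A list with `records` (the input plus a `time_scaled` column),
#'   `center` and `scale`.
#' @export
#' @examples
#' r <- tibble::tibble(time_days = c(0, 2, 4))
#' scale_time(r)$records$time_scaled  # -1, 0, 1
scale_time <- function(records) {
  records <- as_tibble(records)
  t <- records$time_days
  if (length(unique(t)) < 2) {
    stop_user("need at least 2 distinct record times to scale time")
  }
  ctr <- mean(t)
  scl <- sd(t)
  records$time_scaled <- (t - ctr) / scl
  list(records = records, center = ctr, scale = scl)
}

#' Fit the wound-healing mixed model
#'
#' Gaussian linear mixed model of healing distance (mm) on scaled time with
#' group-specific slopes (and, by default, group-specific intercepts), a
#' per-individual random intercept and random slope -- the maximal random
#' structure the longitudinal design supports -- and independent residuals
#' absorbing duplicate measurements as repeated measures:
#'
#' \deqn{d_{it} = \beta_{0,g(i)} + \beta_{1,g(i)} s(t) + u_{0i} + u_{1i} s(t)
#'   + \varepsilon_{it},\quad (u_0,u_1) \sim N(0, G),\
#'   \varepsilon \sim N(0,\sigma^2).}
#'
#' Variance components are estimated by profiled REML over a log-Cholesky
#' parameterization of \eqn{G/\sigma^2}, with a configurable log-determinant
#' penalty on \eqn{G} that keeps the estimate away from singular
#' (boundary) fits; `penalty = 0` gives plain REML.
#'
#' @param records Healing-record tibble (see [healing_distances()]).
#' @param group Grouping column whose levels get their own slope
#'   (tidy evaluation; default `species`). Any factor-like column works:
#'   species, setting, sex, age class, wound site.
#' @param penalty Non-negative strength of the covariance penalty
#'   `penalty * (-log|G| + tr(G))`; default 0.01.
#' @param time_scaling `"standardize"` (default) or `"none"`. Reported rates
#'   are in mm/day either way.
#' @param common_intercept Force a single intercept shared by all groups.
#' @param n_starts Number of optimizer starts (1-3) before the fit is
#'   declared non-convergent.
#' @return An object of class `healing_lmm`.
#' @seealso [healing_rates()], [compare_rates()], [tidy.healing_lmm()]
#' @export
fit_healing_lmm <- function(records, group = species, penalty = 0.01,
                            time_scaling = c("standardize", "none"),
                            common_intercept = FALSE, n_starts = 3L) {
  time_scaling <- match.arg(time_scaling)
  records <- as_tibble(records)
  needed <- c("individual_id", "time_days", "healing_distance_mm")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop_user("records are missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  g <- factor(dplyr::pull(records, {{ group }}))
  group_name <- as_name(enquo(group))
  id <- factor(records$individual_id)

  per_group <- tapply(id, g, function(x) length(unique(x)))
  thin <- names(per_group)[per_group < 2]
  if (length(thin)) {
    stop_user("group(s) with fewer than 2 individuals cannot support the random-slope model: %s",
              paste(thin, collapse = ", "))
  }
  per_ind_times <- tapply(records$time_days, id, function(x) length(unique(x)))
  if (any(per_ind_times < 2)) {
    stop_user("individual(s) with fewer than 2 time points: %s",
              paste(names(per_ind_times)[per_ind_times < 2], collapse = ", "))
  }

  if (time_scaling == "standardize") {
    st <- scale_time(records)
    s <- st$records$time_scaled
    ctr <- st$center
    scl <- st$scale
  } else {
    s <- records$time_days
    ctr <- 0
    scl <- 1
  }

  lev <- levels(g)
  # indicator columns built directly so a single-group fit also works
  ind <- vapply(lev, function(l) as.numeric(g == l), numeric(length(g)))
  colnames(ind) <- lev
  slopes <- ind * s
  colnames(slopes) <- paste0("slope_", lev)
  X <- if (common_intercept) {
    cbind(`(Intercept)` = 1, slopes)
  } else {
    colnames(ind) <- paste0("intercept_", lev)
    cbind(ind, slopes)
  }
  Z <- cbind(1, s)

  eng <- reml_engine(records$healing_distance_mm, X, Z, id,
                     penalty = penalty, n_starts = n_starts)
  records$.group <- g
  structure(
    c(eng,
      list(group_levels = lev, group_name = group_name,
           time_center = ctr, time_scale = scl,
           time_scaling = time_scaling,
           common_intercept = common_intercept,
           data = records, call = match.call())),
    class = "healing_lmm"
  )
}

#' @export
print.healing_lmm <- function(x, ...) {
  cat(sprintf("<healing_lmm>  %d records, %d individuals, groups by %s\n",
              x$n_records, x$n_individuals, x$group_name))
  cat(sprintf("  residual sd %.4g mm; covariance penalty %.3g%s%s\n",
              sqrt(x$sigma2), x$penalty,
              if (x$converged) "" else "; NOT CONVERGED",
              if (x$singular) "; singular random-effect covariance" else ""))
  print(healing_rates(x))
  invisible(x)
}

#' Per-group healing rates in mm/day
#'
#' Back-transforms the fitted slopes on scaled time to the raw time scale:
#' `rate = slope / sd(t)`, with standard errors from the fixed-effect
#' covariance divided by the same constant.
#'
#' @param fit A [fit_healing_lmm()] object.
#' @return Tibble with `group`, `rate_mm_per_day`, `se`.
#' @export
healing_rates <- function(fit) {
  stopifnot(inherits(fit, "healing_lmm"))
  terms <- paste0("slope_", fit$group_levels)
  j <- match(terms, names(fit$beta))
  se <- sqrt(diag(fit$cov_beta))[j]
  tibble(
    group = fit$group_levels,
    rate_mm_per_day = unname(fit$beta[j]) / fit$time_scale,
    se = unname(se) / fit$time_scale
  )
}

#' Wald chi-square test of equal healing rates
#'
#' Tests the null hypothesis that all slope coefficients among the named
#' groups are equal, using the Wald quadratic form on the fixed-effect
#' covariance. The statistic is invariant to which group serves as the
#' contrast baseline and to the time scaling.
#'
#' @param fit A [fit_healing_lmm()] object.
#' @param groups Character vector of group levels to compare (default: all).
#' @return Tibble with `groups`, `statistic`, `df`, `p.value`.
#' @export
compare_rates <- function(fit, groups = NULL) {
  stopifnot(inherits(fit, "healing_lmm"))
  groups <- groups %||% fit$group_levels
  unknown <- setdiff(groups, fit$group_levels)
  if (length(unknown)) {
    stop_user("unknown group(s): %s", paste(unknown, collapse = ", "))
  }
  if (length(groups) < 2) {
    stop_user("need at least 2 groups to test a slope contrast")
  }
  terms <- paste0("slope_", groups)
  j <- match(terms, names(fit$beta))
  k <- length(j)
  H <- matrix(0, k - 1, length(fit$beta))
  for (r in seq_len(k - 1)) {
    H[r, j[1]] <- -1
    H[r, j[r + 1]] <- 1
  }
  hb <- drop(H %*% fit$beta)
  V <- H %*% fit$cov_beta %*% t(H)
  Rv <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(Rv)) {
    stop("fixed-effect contrast covariance is singular; the contrast is not testable")
  }
  stat <- sum(backsolve(Rv, hb, transpose = TRUE)^2)
  df <- k - 1
  tibble(
    groups = paste(groups, collapse = ","),
    statistic = stat,
    df = as.integer(df),
    p.value = pchisq(stat, df, lower.tail = FALSE)
  )
}

#' Assign age classes by sample quantiles
#'
#' Splits ages into classes at the sample median, tertiles, or quartiles;
#' a value falling exactly on a boundary goes to the lower class.
#'
#' @param ages Numeric ages (years).
#' @param scheme `"median"`, `"tertile"`, or `"quartile"`.
#' @return A factor of class labels, ordered low to high.
#' @export
#' @examples
#' assign_age_classes(c(1, 2, 3, 4), "median")
assign_age_classes <- function(ages, scheme = c("median", "tertile", "quartile")) {
  scheme <- match.arg(scheme)
  k <- c(median = 2L, tertile = 3L, quartile = 4L)[[scheme]]
  if (!is.numeric(ages) || any(!is.finite(ages))) {
    stop_user("ages must be finite numeric")
  }
  if (length(unique(ages)) < k) {
    stop_user("need at least %d distinct ages for the %s split, got %d",
              k, scheme, length(unique(ages)))
  }
  inner <- quantile(ages, probs = seq_len(k - 1) / k, names = FALSE, type = 7)
  labels <- switch(scheme,
                   median = c("low", "high"),
                   tertile = c("low", "mid", "high"),
                   quartile = c("q1", "q2", "q3", "q4"))
  cut(ages, breaks = c(-Inf, inner, Inf), labels = labels, right = TRUE)
}

#' Broom-style methods for healing_lmm fits
#'
#' `tidy()` returns the fixed effects on the scaled-time coordinates (use
#' [healing_rates()] for mm/day) or the variance components; `glance()` gives
#' one row of fit-level summaries.
#'
#' @param x,object A [fit_healing_lmm()] object.
#' @param effects `"fixed"` (default) or `"ran_pars"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method tidy healing_lmm
tidy.healing_lmm <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    tibble(
      term = names(x$beta),
      estimate = unname(x$beta),
      std.error = sqrt(diag(x$cov_beta))
    )
  } else {
    tibble(
      term = c("var_intercept", "cov_intercept_slope", "var_slope", "var_residual"),
      estimate = c(x$G[1, 1], x$G[1, 2], x$G[2, 2], x$sigma2)
    )
  }
}

#' @rdname tidy.healing_lmm
#' @export
#' @method glance healing_lmm
glance.healing_lmm <- function(x, ...) {
  tibble(
    nobs = x$n_records,
    n_individuals = x$n_individuals,
    sigma = sqrt(x$sigma2),
    objective = x$objective,
    neg2reml = x$neg2reml,
    penalty = x$penalty,
    converged = x$converged,
    singular = x$singular
  )
}

#' @rdname tidy.healing_lmm
#' @export
#' @method autoplot healing_lmm
autoplot.healing_lmm <- function(object, ...) {
  d <- object$data
  rates <- healing_rates(object)
  # back-transform fitted lines to the raw day scale
  terms_int <- if (object$common_intercept) {
    rep("(Intercept)", length(object$group_levels))
  } else {
    paste0("intercept_", object$group_levels)
  }
  b0 <- unname(object$beta[match(terms_int, names(object$beta))])
  b1 <- unname(object$beta[match(paste0("slope_", object$group_levels), names(object$beta))])
  lines <- tibble(
    group = object$group_levels,
    intercept = b0 - b1 * object$time_center / object$time_scale,
    slope = b1 / object$time_scale
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_days, y = .data$healing_distance_mm,
                                  colour = .data$.group)) +
    ggplot2::geom_point(alpha = 0.45, size = 0.9) +
    ggplot2::geom_abline(
      data = lines,
      mapping = ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                             colour = .data$group)
    ) +
    ggplot2::labs(x = "time (days)", y = "healing distance (mm)",
                  colour = object$group_name) +
    ggplot2::theme_minimal()
}

#' Serialize a fit summary to JSON
#'
#' Writes per-group rates (mm/day) with standard errors, the random-effect
#' covariance, residual variance, any requested slope contrasts, and the
#' convergence block.
#'
#' @param fit A [fit_healing_lmm()] object.
#' @param path Output path.
#' @param contrasts Optional list of character vectors of group levels; each
#'   is run through [compare_rates()].
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, contrasts = NULL) {
  stopifnot(inherits(fit, "healing_lmm"))
  if (is.null(contrasts)) {
    contrasts <- if (length(fit$group_levels) >= 2) list(fit$group_levels) else list()
  }
  rates <- healing_rates(fit)
  tests <- purrr::map(contrasts, function(gr) {
    ct <- compare_rates(fit, gr)
    list(groups = gr, chisq = ct$statistic, df = ct$df, p = ct$p.value)
  })
  out <- list(
    group_factor = fit$group_name,
    rates = purrr::pmap(rates, function(group, rate_mm_per_day, se) {
      list(group = group, rate_mm_per_day = rate_mm_per_day, se = se)
    }),
    random_effect_covariance = fit$G,
    sigma2 = fit$sigma2,
    contrasts = tests,
    time_scaling = list(center = fit$time_center, scale = fit$time_scale),
    convergence = list(converged = fit$converged, singular = fit$singular,
                       objective = fit$objective, penalty = fit$penalty,
                       n_records = fit$n_records, n_individuals = fit$n_individuals)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
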