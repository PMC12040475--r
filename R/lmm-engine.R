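# Penalized profiled-REML engine for the two-dimensional random-effect
# (per-individual intercept + slope) Gaussian mixed model
#
#   y_it = x_it' beta + u0_i + u1_i * s_it + e_it,
#   (u0, u1) ~ N(0, G),  e ~ N(0, sigma^2)
#
# Parameterization follows the standard relative-covariance route:
# Gamma = G / sigma^2 = L L' with L lower triangular and log-scaled diagonal
# (theta = c(log L11, L21, log L22)), so the marginal covariance of one
# individual's records is sigma^2 * (Z_i Gamma Z_i' + I). Fixed effects and
# sigma^2 are profiled out in closed form; only theta is optimized.
#
# Because Z_i has two columns, every per-individual quantity reduces to 2x2
# algebra on precomputed cross-products (Woodbury identity):
#   W_i^{-1}  = I - Z_i B_i Z_i',   B_i = Gamma (I + M_i Gamma)^{-1},
#   log|W_i|  = log|I + M_i Gamma|,          M_i = Z_i' Z_i,
# which makes one objective evaluation O(#individuals) regardless of the
# number of records.
#
# The boundary-avoiding penalty is a log-Wishart-style term on G itself,
#   penalty * ( -log|G| + tr(G) ),
# which diverges as G approaches rank deficiency (keeping fits interior, in
# the spirit of weakly-informative covariance priors) while the trace term
# keeps it bounded away from inflating G. penalty = 0 gives plain REML.

reml_crossprods <- function(y, X, Z, id) {
  id <- factor(id)
  idx <- split(seq_along(y), id)
  p <- ncol(X)
  list(
    idx = idx,
    n = length(y),
    p = p,
    n_ind = length(idx),
    XtX = crossprod(X),
    Xty = crossprod(X, y),
    yty = sum(y * y),
    M = lapply(idx, function(i) crossprod(Z[i, , drop = FALSE])),
    ZtX = lapply(idx, function(i) crossprod(Z[i, , drop = FALSE], X[i, , drop = FALSE])),
    Zty = lapply(idx, function(i) crossprod(Z[i, , drop = FALSE], y[i]))
  )
}

theta_to_gamma <- function(theta) {
  d1 <- exp(min(max(theta[1], -15), 8))
  l21 <- min(max(theta[2], -1e3), 1e3)
  d2 <- exp(min(max(theta[3], -15), 8))
  Lc <- matrix(c(d1, l21, 0, d2), 2, 2)
  list(gamma = Lc %*% t(Lc), logdet = 2 * (log(d1) + log(d2)))
}

# Profiled (penalized) -2 * restricted log-likelihood at theta, plus the
# by-products needed to assemble a fit. Returns a big finite value on
# numerical failure so derivative-free optimization can continue.
reml_objective <- function(theta, cp, penalty, details = FALSE) {
  gm <- theta_to_gamma(theta)
  G <- gm$gamma
  logdet_w <- 0
  corr_XX <- matrix(0, cp$p, cp$p)
  corr_Xy <- numeric(cp$p)
  corr_yy <- 0
  I2 <- diag(2)
  for (i in seq_len(cp$n_ind)) {
    K <- I2 + cp$M[[i]] %*% G
    detK <- K[1, 1] * K[2, 2] - K[1, 2] * K[2, 1]
    if (!is.finite(detK) || detK <= 1e-300) {
      return(if (details) NULL else 1e10)
    }
    Kinv <- matrix(c(K[2, 2], -K[2, 1], -K[1, 2], K[1, 1]), 2, 2) / detK
    B <- G %*% Kinv
    B <- (B + t(B)) / 2
    logdet_w <- logdet_w + log(detK)
    C <- cp$ZtX[[i]]
    zy <- cp$Zty[[i]]
    Bzy <- B %*% zy
    corr_XX <- corr_XX + crossprod(C, B %*% C)
    corr_Xy <- corr_Xy + drop(crossprod(C, Bzy))
    corr_yy <- corr_yy + sum(zy * Bzy)
  }
  XtWX <- (cp$XtX - corr_XX)
  XtWX <- (XtWX + t(XtWX)) / 2
  XtWy <- drop(cp$Xty) - corr_Xy
  R <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(R)) {
    return(if (details) NULL else 1e10)
  }
  beta <- backsolve(R, backsolve(R, XtWy, transpose = TRUE))
  rss <- cp$yty - corr_yy - sum(beta * XtWy)
  rss <- max(rss, 1e-12)
  df <- cp$n - cp$p
  sigma2 <- rss / df
  logdet_xtwx <- 2 * sum(log(diag(R)))
  neg2reml <- df * (1 + log(2 * pi * sigma2)) + logdet_w + logdet_xtwx
  obj <- neg2reml
  if (penalty > 0) {
    # G_abs = sigma^2 * Gamma is the covariance on the data scale
    logdet_G <- 2 * log(sigma2) + gm$logdet
    tr_G <- sigma2 * (G[1, 1] + G[2, 2])
    obj <- obj + penalty * (-logdet_G + tr_G)
  }
  if (!is.finite(obj)) {
    return(if (details) NULL else 1e10)
  }
  if (!details) {
    return(obj)
  }
  cov_beta <- sigma2 * chol2inv(R)
  list(objective = as.numeric(obj), neg2reml = as.numeric(neg2reml),
       beta = drop(beta), cov_beta = cov_beta, sigma2 = as.numeric(sigma2),
       gamma = G, G = sigma2 * G, logdet_w = logdet_w)
}

# Data-driven starting value: per-individual OLS intercept/slope spread
# relative to a pooled residual variance.
reml_start <- function(y, X, Z, id) {
  id <- factor(id)
  sl <- tapply(seq_along(y), id, function(i) {
    zi <- Z[i, 2]
    if (length(unique(zi)) < 2) return(c(NA, NA))
    f <- lm.fit(cbind(1, zi), y[i])
    coef(f)
  })
  cf <- do.call(rbind, sl)
  v0 <- var(cf[, 1], na.rm = TRUE)
  v1 <- var(cf[, 2], na.rm = TRUE)
  s2 <- max(var(y) / 4, 1e-4)
  g1 <- sqrt(max(v0 / s2, 1e-4))
  g2 <- sqrt(max(v1 / s2, 1e-4))
  th <- c(log(g1), 0, log(g2))
  th[!is.finite(th)] <- 0
  th
}

#' @keywords internal
#' @noRd
reml_engine <- function(y, X, Z, id, penalty = 0.01, n_starts = 3L) {
  stopifnot(length(y) == nrow(X), nrow(X) == nrow(Z), ncol(Z) == 2)
  cp <- reml_crossprods(y, X, Z, id)
  if (cp$n <= cp$p) {
    stop_user("not enough records (%d) for %d fixed effects", cp$n, cp$p)
  }
  starts <- list(
    reml_start(y, X, Z, id),
    c(0, 0, 0),
    c(-3, 0, -3)
  )[seq_len(max(1L, min(n_starts, 3L)))]
  best <- NULL
  diagnostics <- list()
  for (k in seq_along(starts)) {
    opt <- tryCatch(
      optim(starts[[k]], reml_objective, cp = cp, penalty = penalty,
            method = "Nelder-Mead",
            control = list(maxit = 1000, reltol = 1e-10)),
      error = function(e) NULL
    )
    diagnostics[[k]] <- if (is.null(opt)) "optim error" else
      sprintf("start %d: value %.6g, convergence %d", k, opt$value, opt$convergence)
    if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e9 &&
        (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) {
    rlang::abort(
      paste0("mixed-model fit failed to converge after ", length(starts),
             " starts:\n", paste(unlist(diagnostics), collapse = "\n")),
      class = "woundrate_convergence_error"
    )
  }
  det <- reml_objective(best$par, cp, penalty, details = TRUE)
  if (is.null(det)) {
    rlang::abort("mixed-model objective undefined at the optimum",
                 class = "woundrate_convergence_error")
  }
  ev <- eigen(det$G, symmetric = TRUE, only.values = TRUE)$values
  singular <- ev[2] < 1e-6 * max(sum(ev), .Machine$double.eps)
  list(
    beta = setNames(det$beta, colnames(X)),
    cov_beta = det$cov_beta,
    G = det$G,
    sigma2 = det$sigma2,
    theta = best$par,
    objective = det$objective,
    neg2reml = det$neg2reml,
    converged = best$convergence == 0,
    singular = singular,
    n_records = cp$n,
    n_individuals = cp$n_ind,
    penalty = penalty,
    diagnostics = unlist(diagnostics)
  )
}
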