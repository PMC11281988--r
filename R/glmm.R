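# Day-level Poisson generalized linear mixed model with a person random
# intercept, fitted by Laplace-approximated maximum likelihood.
#
# Model:  y_ij ~ Poisson(exp(x_ij' beta + b_i)),  b_i ~ N(0, tau00).
#
# The Laplace marginal log-likelihood has a closed inner problem per
# person: with S_i = sum_j exp(x_ij' beta + b_i) evaluated at the mode
# b-hat_i,
#
#   ll = sum_i [ h_i(b-hat_i) - 1/2 log(1 + tau00 * S_i) ] - sum log(y!)
#   h_i(b) = sum_j (y_ij eta_ij - exp(eta_ij)) - b^2 / (2 tau00)
#
# The inner modes are found by a damped 1-D Newton iteration (vectorized
# over persons); the outer problem maximizes over (beta, log tau00) by
# BFGS. At tau00 = 0 the expression reduces exactly to the ordinary
# Poisson GLM log-likelihood, which provides an independent oracle.

#' Grand-mean centre continuous design columns
#'
#' Subtracts the column mean from each requested column. Binary 0/1
#' indicator columns are conventionally left uncentred (coded 0/1); pass
#' only the continuous columns. Centring is idempotent. Constant columns
#' trigger a warning (they centre to all-zero and are collinear with the
#' intercept).
#'
#' @param data data.frame
#' @param cols character vector of column names to centre
#' @return `data` with the named columns centred; the applied means are
#'   stored in `attr(, "centers")`
#' @export
center_grand_mean <- function(data, cols) {
  centers <- numeric(0)
  for (cl in cols) {
    x <- data[[cl]]
    if (!is.numeric(x)) stop("cannot centre non-numeric column: ", cl)
    mu <- mean(x)
    if (stats::sd(x) == 0) {
      warning("column ", cl, " is constant; centred to all-zero")
    }
    data[[cl]] <- x - mu
    centers[cl] <- mu
  }
  attr(data, "centers") <- centers
  data
}

# Fixed-term order of the day-level design; mirrors the coefficient-table
# layout (sociodemographics, social environment, health, care, built
# environment, education indicators, counter).
DESIGN_TERMS <- c("sex_female", "age", "social_network_satisfaction",
                  "cohabiting", "ksk12", "psk12", "health_literacy",
                  "health_reach_count", "pt_reach_count", "subjective_access",
                  "intersection_density", "sidewalk_quality",
                  "green_share_pct", "utilization_score", "active_driving",
                  "edu_middle", "edu_high", "counter")
BINARY_TERMS <- c("sex_female", "cohabiting", "active_driving",
                  "edu_middle", "edu_high")

#' Assemble the day-level design matrix
#'
#' Joins the valid person-days of the indicator table with the
#' person-level covariates and environment profiles, derives the day
#' counter (1..7 within person, by date), rounds the chosen indicator to a
#' non-negative integer count, grand-mean centres the continuous terms and
#' returns the pieces a mixed-model fit needs. Persons with any missing
#' covariate (or zero valid days) are dropped listwise and counted.
#'
#' @param mobility indicator table from [daily_mobility]
#' @param persons data.frame with columns `person_id`, `age`, `sex_female`,
#'   `cohabiting`, `education` ("low"/"middle"/"high"), `ksk12`, `psk12`,
#'   `health_literacy`, `social_network_satisfaction`, `active_driving`
#' @param env data.frame from [env_profile] (may include survey scores)
#' @param response `"toh"` (minutes) or `"chull"` (km^2)
#' @param center centre continuous terms (default TRUE); binaries stay 0/1
#' @return a `day_design` list: `y` (integer response), `X` (model matrix
#'   with intercept), `group` (person factor), plus bookkeeping
#' @export
build_day_design <- function(mobility, persons, env,
                             response = c("toh", "chull"), center = TRUE) {
  response <- match.arg(response)
  mob <- mobility[mobility$valid, , drop = FALSE]
  if (nrow(mob) == 0L) stop("no valid person-days")
  mob <- mob[order(mob$person_id, mob$mobility_date), , drop = FALSE]
  cnt <- stats::ave(seq_len(nrow(mob)), mob$person_id, FUN = seq_along)
  mob$counter <- as.numeric(cnt)

  persons$edu_middle <- as.numeric(persons$education == "middle")
  persons$edu_high <- as.numeric(persons$education == "high")
  pl <- merge(persons, env, by = "person_id", sort = FALSE)
  need <- setdiff(DESIGN_TERMS, "counter")
  missing_cols <- setdiff(need, names(pl))
  if (length(missing_cols)) {
    stop("missing covariate columns: ", paste(missing_cols, collapse = ", "))
  }
  complete <- stats::complete.cases(pl[, need])
  n_dropped_persons <- sum(!complete)
  if (n_dropped_persons > 0) {
    message(n_dropped_persons,
            " person(s) dropped (missing covariates): ",
            paste(utils::head(pl$person_id[!complete], 5), collapse = ", "))
  }
  pl <- pl[complete, , drop = FALSE]

  df <- merge(mob, pl, by = "person_id", sort = FALSE)
  if (nrow(df) == 0L) stop("no fitted rows after covariate join")
  df <- df[order(df$person_id, df$mobility_date), , drop = FALSE]

  y <- if (response == "toh") round(df$toh_min) else round(df$chull_km2)
  y <- as.integer(pmax(y, 0))

  cont <- setdiff(DESIGN_TERMS, BINARY_TERMS)
  if (center) df <- center_grand_mean(df, cont)
  X <- cbind(`(Intercept)` = 1, as.matrix(df[, DESIGN_TERMS]))
  structure(list(y = y, X = X, group = factor(df$person_id),
                 response = response, centered = center,
                 centers = attr(df, "centers"),
                 n_dropped_persons = n_dropped_persons,
                 person_days = df[, c("person_id", "mobility_date")]),
            class = "day_design")
}

# ---------------------------------------------------------------------------
# Laplace machinery

# inner Newton for the random-intercept modes; vectorized over groups.
# Returns list(b, S) with S_i = sum_j mu_ij at the mode.
laplace_modes <- function(eta_fix, y, gidx, ngrp, tau, b0 = NULL,
                          tol = 1e-10, max_iter = 50L) {
  sumy <- as.numeric(rowsum(y, gidx, reorder = TRUE))
  b <- if (is.null(b0)) numeric(ngrp) else b0
  h_val <- function(b) {
    eta <- eta_fix + b[gidx]
    as.numeric(rowsum(y * eta - exp(eta), gidx, reorder = TRUE)) -
      b^2 / (2 * tau)
  }
  for (it in seq_len(max_iter)) {
    eta <- eta_fix + b[gidx]
    S <- as.numeric(rowsum(exp(eta), gidx, reorder = TRUE))
    grad <- sumy - S - b / tau
    if (max(abs(grad)) < tol) break
    step <- grad / (S + 1 / tau)
    # damped update: halve any step that decreases h
    h_old <- h_val(b)
    repeat {
      b_new <- b + step
      h_new <- h_val(b_new)
      worse <- !is.finite(h_new) | h_new < h_old - 1e-12
      if (!any(worse) || max(abs(step)) < 1e-14) break
      step[worse] <- step[worse] / 2
    }
    b <- b_new
  }
  eta <- eta_fix + b[gidx]
  list(b = b, S = as.numeric(rowsum(exp(eta), gidx, reorder = TRUE)))
}

# Laplace-approximated marginal log-likelihood (up to the -sum log(y!)
# constant, which is included for comparability with glm's logLik).
laplace_loglik <- function(beta, log_tau, y, X, gidx, ngrp, mode_env = NULL) {
  eta_fix <- as.numeric(X %*% beta)
  # wild trial values during line searches: return a finite penalty
  if (!all(is.finite(eta_fix)) || max(eta_fix) > 50 || !is.finite(log_tau) ||
      log_tau > 20) {
    return(-1e10)
  }
  tau <- exp(log_tau)
  if (tau < 1e-12) {
    eta <- eta_fix
    return(sum(y * eta - exp(eta)) - sum(lgamma(y + 1)))
  }
  b0 <- if (!is.null(mode_env)) mode_env$b else NULL
  m <- laplace_modes(eta_fix, y, gidx, ngrp, tau, b0 = b0)
  if (!is.null(mode_env)) mode_env$b <- m$b
  eta <- eta_fix + m$b[gidx]
  h <- sum(y * eta - exp(eta)) - sum(m$b^2) / (2 * tau)
  h - 0.5 * sum(log1p(tau * m$S)) - sum(lgamma(y + 1))
}

# Newton/IRLS fit of the plain Poisson GLM (the tau00 = 0 special case).
poisson_irls <- function(y, X, tol = 1e-12, max_iter = 100L) {
  beta <- qr.solve(X, log(pmax(y, 0.5)))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- exp(eta)
    grad <- crossprod(X, y - mu)
    H <- crossprod(X * mu, X)
    delta <- solve(H, grad)
    beta <- beta + as.numeric(delta)
    if (max(abs(grad)) < tol) break
  }
  eta <- as.numeric(X %*% beta)
  mu <- exp(eta)
  vcov <- solve(crossprod(X * mu, X))
  list(beta = beta, vcov = vcov,
       loglik = sum(y * eta - mu) - sum(lgamma(y + 1)),
       converged = max(abs(crossprod(X, y - mu))) < 1e-6)
}

#' Fit the Poisson random-intercept GLMM (Laplace ML)
#'
#' Maximizes the Laplace-approximated marginal likelihood of a Poisson
#' log-link model with one random intercept per group. Standard errors come
#' from the observed information (numerical Hessian of the Laplace
#' log-likelihood) at the optimum; p-values are two-sided Wald with a
#' normal reference. The random-intercept variance is optimized on the log
#' scale, which enforces non-negativity; estimates collapsing to the
#' boundary are reported as ~0 with `tau_boundary = TRUE`.
#'
#' @param design a `day_design` from [build_day_design], or `NULL` when
#'   `y`, `X`, `group` are given directly
#' @param y integer response vector
#' @param X model matrix including an intercept column
#' @param group grouping factor (person)
#' @param fix_tau fix the random-intercept variance at this value instead
#'   of estimating it; `fix_tau = 0` reduces the model to an ordinary
#'   Poisson GLM and is fitted by Newton scoring
#' @param start optional list with `beta`, `log_tau` starting values
#' @param control list: `reltol` for the outer optimizer, `maxit`
#' @return a `glmm_fit` list: `beta`, `se`, `z`, `p`, `tau00`,
#'   `sigma2_resid`, `icc`, `r2_marginal`, `r2_conditional`, `loglik`,
#'   `n_persons`, `n_obs`, `converged`, `tau_boundary`, `vcov`, `ranef`
#' @export
fit_poisson_glmm <- function(design = NULL, y = NULL, X = NULL, group = NULL,
                             fix_tau = NULL, start = NULL,
                             control = list(reltol = 1e-12, maxit = 500)) {
  if (!is.null(design)) {
    stopifnot(inherits(design, "day_design"))
    y <- design$y; X <- design$X; group <- design$group
  }
  y <- as.numeric(y)
  if (any(y < 0) || any(y != floor(y))) stop("response must be non-negative integers")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  group <- factor(group)
  if (nlevels(group) < 2L && is.null(fix_tau)) {
    stop("need at least 2 groups to estimate a random-intercept variance")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient fixed design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  gidx <- as.integer(group)
  ngrp <- nlevels(group)
  p <- ncol(X)

  if (!is.null(fix_tau) && fix_tau == 0) {
    f <- poisson_irls(y, X)
    se <- sqrt(diag(f$vcov))
    fit <- make_glmm_fit(f$beta, se, tau00 = 0, loglik = f$loglik,
                         X = X, ngrp = ngrp, nobs = length(y),
                         converged = f$converged, tau_boundary = TRUE,
                         vcov = f$vcov, ranef = numeric(ngrp))
    return(fit)
  }

  g0 <- poisson_irls(y, X)
  beta0 <- if (!is.null(start$beta)) start$beta else g0$beta
  lt0 <- if (!is.null(start$log_tau)) start$log_tau else {
    # moment start: variance of within-group mean Pearson-ish residuals
    r <- log(pmax(as.numeric(rowsum(y, gidx)) /
                    pmax(as.numeric(rowsum(exp(X %*% beta0), gidx)), 1e-8),
                  1e-3))
    log(max(stats::var(r), 1e-3))
  }
  mode_env <- new.env(parent = emptyenv())
  mode_env$b <- numeric(ngrp)

  if (!is.null(fix_tau)) {
    obj <- function(th) -laplace_loglik(th, log(fix_tau), y, X, gidx, ngrp, mode_env)
    opt <- stats::optim(beta0, obj, method = "BFGS",
                        control = list(reltol = control$reltol,
                                       maxit = control$maxit))
    theta <- c(opt$par, log(fix_tau))
    est_idx <- seq_len(p)
  } else {
    obj <- function(th) -laplace_loglik(th[seq_len(p)], th[p + 1L],
                                        y, X, gidx, ngrp, mode_env)
    opt <- stats::optim(c(beta0, lt0), obj, method = "BFGS",
                        control = list(reltol = control$reltol,
                                       maxit = control$maxit))
    theta <- opt$par
    est_idx <- seq_len(p + 1L)
  }
  beta <- unname(theta[seq_len(p)])
  log_tau <- unname(theta[p + 1L])
  tau <- exp(log_tau)
  tau_boundary <- tau < 1e-3

  # observed information of the estimated parameters
  H <- stats::optimHess(theta[est_idx], function(th) {
    full <- theta
    full[est_idx] <- th
    -laplace_loglik(full[seq_len(p)], full[p + 1L], y, X, gidx, ngrp, mode_env)
  })
  vcov_all <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, length(est_idx), length(est_idx))
  })
  vcov_beta <- vcov_all[seq_len(p), seq_len(p), drop = FALSE]
  se <- sqrt(pmax(diag(vcov_beta), 0))

  m <- laplace_modes(as.numeric(X %*% beta), y, gidx, ngrp, tau)
  ll <- laplace_loglik(beta, log_tau, y, X, gidx, ngrp)
  make_glmm_fit(beta, se, tau00 = tau, loglik = ll, X = X, ngrp = ngrp,
                nobs = length(y), converged = opt$convergence == 0,
                tau_boundary = tau_boundary, vcov = vcov_beta, ranef = m$b)
}

make_glmm_fit <- function(beta, se, tau00, loglik, X, ngrp, nobs,
                          converged, tau_boundary, vcov, ranef) {
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  fit <- structure(list(beta = beta, se = se, z = z, p = p,
                        tau00 = tau00, loglik = loglik,
                        n_persons = ngrp, n_obs = nobs,
                        converged = converged, tau_boundary = tau_boundary,
                        vcov = vcov, ranef = ranef, X = X),
                   class = "glmm_fit")
  fit$sigma2_resid <- distribution_specific_variance(fit)
  fit$icc <- if (fit$tau00 + fit$sigma2_resid > 0) {
    icc(fit$tau00, fit$sigma2_resid)
  } else NA_real_
  r2 <- r2_nakagawa(fit)
  fit$r2_marginal <- r2[["marginal"]]
  fit$r2_conditional <- r2[["conditional"]]
  fit
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Poisson random-intercept GLMM (Laplace ML)\n")
  cat(sprintf("  persons: %d  observations: %d  logLik: %.2f%s\n",
              x$n_persons, x$n_obs, x$loglik,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  cat(sprintf("  tau00: %.4f%s  sigma2_d: %.4f  ICC: %.3f  R2m/R2c: %.3f/%.3f\n",
              x$tau00, if (x$tau_boundary) " (boundary)" else "",
              x$sigma2_resid, x$icc, x$r2_marginal, x$r2_conditional))
  print(coefficient_table(x), digits = 3)
  invisible(x)
}

#' Distribution-specific residual variance of a Poisson-log model
#'
#' Lognormal approximation `sigma2_d = ln(1 + 1/lambda-bar)` with
#' `lambda-bar = exp(beta0 + tau00/2)`, the expected count at the centred
#' covariate means. This is the latent-scale residual variance the ICC and
#' R2 denominators need.
#'
#' @param fit a `glmm_fit`
#' @return variance on the latent log scale
#' @export
distribution_specific_variance <- function(fit) {
  lambda_bar <- exp(fit$beta[[1]] + fit$tau00 / 2)
  log1p(1 / lambda_bar)
}

#' Intraclass correlation of a two-level model
#'
#' Share of latent-scale variance attributable to between-person
#' differences: `tau00 / (tau00 + sigma2)`.
#'
#' @param tau00 random-intercept variance (>= 0)
#' @param sigma2 distribution-specific residual variance (>= 0)
#' @return fraction in \[0, 1\]
#' @export
icc <- function(tau00, sigma2) {
  if (tau00 < 0 || sigma2 < 0) stop("variance components must be >= 0")
  if (tau00 + sigma2 == 0) stop("ICC undefined: both variance components are 0")
  tau00 / (tau00 + sigma2)
}

#' Marginal and conditional R-squared (latent scale)
#'
#' Variance explained by the fixed effects alone (marginal) and by fixed
#' plus random effects (conditional), with the fixed-effect variance
#' `sigma2_f = var(X beta)` over the fitted rows and the lognormal
#' distribution-specific variance in the denominator.
#'
#' @param fit a `glmm_fit`
#' @return named numeric vector `c(marginal=, conditional=)`
#' @export
r2_nakagawa <- function(fit) {
  eta_fix <- as.numeric(fit$X %*% fit$beta)
  s2f <- if (length(eta_fix) > 1L) stats::var(eta_fix) else 0
  s2d <- distribution_specific_variance(fit)
  denom <- s2f + fit$tau00 + s2d
  c(marginal = s2f / denom, conditional = (s2f + fit$tau00) / denom)
}

#' Coefficient table of a fitted model
#'
#' One row per fixed term with estimate, SE, z and two-sided Wald p;
#' significance is starred at p < 0.05.
#'
#' @param fit a `glmm_fit`
#' @return data.frame with columns `term`, `beta`, `se`, `z`, `p`, `sig`
#' @export
coefficient_table <- function(fit) {
  data.frame(term = names(fit$beta),
             beta = unname(fit$beta), se = unname(fit$se),
             z = unname(fit$z), p = unname(fit$p),
             sig = ifelse(fit$p < 0.05, "*", ""),
             stringsAsFactors = FALSE)
}

#' Plain-text report of a fit, Table-2 style
#'
#' @param fit a `glmm_fit`
#' @param label model label for the header
#' @return character vector of report lines (also printable via `cat`)
#' @export
format_fit_report <- function(fit, label = "model") {
  tab <- coefficient_table(fit)
  fmt <- function(x) formatC(x, format = "f", digits = 3)
  lines <- c(
    sprintf("Predictors of out-of-home mobility (%s)", label),
    sprintf("%-28s %8s %8s %8s %8s", "term", "beta", "SE", "z", "p"),
    sprintf("%-28s %8s %8s %8s %8s%s", tab$term, fmt(tab$beta), fmt(tab$se),
            fmt(tab$z), fmt(tab$p), tab$sig),
    "Random effects",
    sprintf("  sigma2 %s", fmt(fit$sigma2_resid)),
    sprintf("  tau00  %s", fmt(fit$tau00)),
    sprintf("  ICC    %s", formatC(fit$icc, format = "f", digits = 2)),
    sprintf("  N persons %d  observations %d", fit$n_persons, fit$n_obs),
    sprintf("  marginal R2 / conditional R2  %s/%s",
            fmt(fit$r2_marginal), fmt(fit$r2_conditional)))
  lines
}
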