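test_that("grand-mean centring: values, zero mean, idempotence, constants", {
  df <- data.frame(a = c(1, 2, 3), b = c(10, 10, 10))
  out <- center_grand_mean(df, "a")
  expect_equal(out$a, c(-1, 0, 1))
  expect_lt(abs(mean(out$a)), 1e-12)
  again <- center_grand_mean(out, "a")
  expect_equal(again$a, out$a)
  expect_warning(center_grand_mean(df, "b"), "constant")
})

make_design_inputs <- function(ids, days = 7) {
  mob <- do.call(rbind, lapply(ids, function(id) {
    data.frame(person_id = id,
               mobility_date = as.Date("2022-07-01") + seq_len(days) - 1,
               toh_min = 300 + seq_len(days) * 5.4,
               chull_km2 = 2 + seq_len(days) * 0.3,
               n_fixes = 500, coverage_hours = 12, valid = TRUE,
               stringsAsFactors = FALSE)
  }))
  list(mob = mob, persons = make_persons(ids), env = make_env_table(ids))
}

test_that("design assembly: row counts, counter, rounding, listwise deletion", {
  inp <- make_design_inputs(c("A", "B"))
  inp$persons$education <- c("middle", "high")
  d <- build_day_design(inp$mob, inp$persons, inp$env, response = "toh")
  expect_equal(length(d$y), 14L)
  expect_equal(unname(d$X[, "counter"] + mean(rep(1:7, 2))), rep(1:7, 2))
  # continuous columns centred to mean 0; binaries left 0/1
  expect_lt(abs(mean(d$X[, "age"])), 1e-9)
  expect_true(all(d$X[, "sex_female"] %in% c(0, 1)))
  # response rounding: toh 305.4 -> 305
  expect_equal(d$y[1], round(inp$mob$toh_min[1]))

  inp3 <- make_design_inputs(c("A", "B", "C"))
  inp3$persons$health_literacy[2] <- NA
  expect_message(
    d3 <- build_day_design(inp3$mob, inp3$persons, inp3$env, response = "toh"),
    "dropped")
  expect_equal(length(d3$y), 14L)
  expect_equal(d3$n_dropped_persons, 1L)
  expect_false("B" %in% levels(d3$group))
})

test_that("intercept-only GLM path recovers the closed-form Poisson MLE", {
  set.seed(51)
  y <- rpois(2000, 10)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_poisson_glmm(y = y, X = X, group = seq_along(y), fix_tau = 0)
  expect_equal(unname(f$beta), log(mean(y)), tolerance = 1e-9)
  expect_lt(abs(f$beta - log(10)), 3 * f$se)
})

test_that("Laplace fit with tau00 = 0 equals the ordinary Poisson GLM", {
  set.seed(52)
  for (rep in 1:10) {
    n <- 150
    X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    y <- rpois(n, exp(1.2 + 0.4 * X[, 2] - 0.5 * X[, 3]))
    f <- fit_poisson_glmm(y = y, X = X, group = seq_len(n), fix_tau = 0)
    g <- stats::glm(y ~ X[, 2] + X[, 3], family = stats::poisson)
    expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-6)
    expect_equal(unname(f$se), unname(summary(g)$coefficients[, 2]),
                 tolerance = 1e-6)
    expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
  }
})

sim_glmm_data <- function(seed, ngrp = 150, d = 7, beta = c(2, 0.5, -0.3),
                          tau = 0.8) {
  set.seed(seed)
  b <- rnorm(ngrp, 0, sqrt(tau))
  gidx <- rep(seq_len(ngrp), each = d)
  x1 <- rnorm(ngrp * d)
  x2 <- rnorm(ngrp * d)
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2 + b[gidx]
  X <- cbind(1, x1, x2)
  colnames(X) <- c("(Intercept)", "x1", "x2")
  list(y = rpois(ngrp * d, exp(eta)), X = X, g = gidx, b = b,
       beta = beta, tau = tau)
}

test_that("Laplace fit agrees with lme4 glmer on a mixed design", {
  dat <- sim_glmm_data(53)
  f <- fit_poisson_glmm(y = dat$y, X = dat$X, group = dat$g)
  df <- data.frame(y = dat$y, x1 = dat$X[, 2], x2 = dat$X[, 3], g = dat$g)
  m <- lme4::glmer(y ~ x1 + x2 + (1 | g), data = df, family = stats::poisson)
  expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-3)
  expect_equal(f$tau00, unname(unlist(lme4::VarCorr(m))), tolerance = 1e-3)
  expect_equal(unname(f$se), unname(sqrt(diag(as.matrix(vcov(m))))),
               tolerance = 5e-3)
})

test_that("boundary recovery: data generated with tau00 = 0", {
  dat <- sim_glmm_data(54, tau = 0)
  f <- fit_poisson_glmm(y = dat$y, X = dat$X, group = dat$g)
  expect_lt(f$tau00, 0.02)
  expect_true(f$tau_boundary)
})

test_that("likelihood at the optimum dominates the truth; invariances hold", {
  dat <- sim_glmm_data(55, ngrp = 80)
  f <- fit_poisson_glmm(y = dat$y, X = dat$X, group = dat$g)
  ll_truth <- lifespace:::laplace_loglik(dat$beta, log(dat$tau), dat$y, dat$X,
                                         dat$g, max(dat$g))
  expect_gte(f$loglik, ll_truth - 1e-6)

  # row-order and group-relabeling invariance
  set.seed(56)
  perm <- sample(length(dat$y))
  f2 <- fit_poisson_glmm(y = dat$y[perm], X = dat$X[perm, ], group = dat$g[perm])
  expect_equal(f2$beta, f$beta, tolerance = 1e-6)
  expect_equal(f2$tau00, f$tau00, tolerance = 1e-6)
  relab <- paste0("person_", sprintf("%03d", max(dat$g) + 1 - dat$g))
  f3 <- fit_poisson_glmm(y = dat$y, X = dat$X, group = relab)
  expect_equal(f3$beta, f$beta, tolerance = 1e-6)
})

test_that("fit errors: rank deficiency is named, bad responses rejected", {
  dat <- sim_glmm_data(57, ngrp = 30)
  X <- cbind(dat$X, dup = dat$X[, "x1"])
  expect_error(fit_poisson_glmm(y = dat$y, X = X, group = dat$g), "dup")
  expect_error(fit_poisson_glmm(y = c(-1, 1), X = cbind(c(1, 1)),
                                group = c(1, 2)), "non-negative")
})

test_that("distribution-specific variance: closed form and monotonicity", {
  mkfit <- function(beta0, tau) {
    structure(list(beta = c("(Intercept)" = beta0), tau00 = tau),
              class = "glmm_fit")
  }
  expect_equal(distribution_specific_variance(mkfit(0, 0)), log(2))
  # strictly decreasing in lambda-bar, tending to 0
  lams <- c(0.5, 1, 5, 50, 500)
  s2 <- vapply(lams, function(l) {
    distribution_specific_variance(mkfit(log(l), 0))
  }, 0)
  expect_true(all(diff(s2) < 0))
  expect_lt(s2[length(s2)], 0.01)
})

test_that("ICC arithmetic, bounds and degenerate inputs", {
  expect_equal(round(icc(3.44, 0.13), 2), 0.96)
  expect_equal(icc(3.44, 0.13), 3.44 / 3.57, tolerance = 1e-12)
  expect_equal(icc(0, 1), 0)
  expect_equal(icc(2, 2), 0.5)
  expect_error(icc(0, 0), "undefined")
  expect_error(icc(-1, 1), ">= 0")
})

test_that("Nakagawa R2: null fixed effects, ordering, variance-dominant cases", {
  dat <- sim_glmm_data(58, ngrp = 60, beta = c(2, 0, 0), tau = 1.5)
  # intercept-only fit: marginal exactly 0, conditional near 1
  X0 <- dat$X[, 1, drop = FALSE]
  f0 <- fit_poisson_glmm(y = dat$y, X = X0, group = dat$g)
  expect_equal(f0$r2_marginal, 0)
  expect_gt(f0$r2_conditional, 0.6)
  expect_gte(f0$r2_conditional, f0$r2_marginal)

  f <- fit_poisson_glmm(y = dat$y, X = dat$X, group = dat$g)
  expect_gte(f$r2_conditional, f$r2_marginal)
  expect_gte(f$icc, 0)
  expect_lte(f$icc, 1)
})

test_that("coefficient table: z identity, normal p, row count, report shape", {
  dat <- sim_glmm_data(59, ngrp = 60)
  f <- fit_poisson_glmm(y = dat$y, X = dat$X, group = dat$g)
  tab <- coefficient_table(f)
  expect_equal(nrow(tab), ncol(dat$X))
  expect_equal(tab$z, tab$beta / tab$se, tolerance = 1e-9)
  expect_equal(2 * pnorm(-1.96), 0.05, tolerance = 1e-3)
  expect_equal(tab$p, 2 * pnorm(-abs(tab$z)), tolerance = 1e-12)
  rep <- format_fit_report(f, "TOH")
  expect_true(any(grepl("tau00", rep)))
  expect_true(any(grepl("marginal R2", rep)))
})
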