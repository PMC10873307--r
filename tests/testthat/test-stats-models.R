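test_that("Shapiro-Francia statistic behaves as a squared correlation", {
  # near-perfectly normal-spaced data
  x <- qnorm(ppoints(60))
  sf <- shapiro_francia(x)
  expect_gt(sf$w_prime, 0.995)
  expect_lte(sf$w_prime, 1)
  # detects heavy exponential samples at n = 50 in almost every draw
  set.seed(5)
  rej <- mean(vapply(1:100, function(i) {
    shapiro_francia(rexp(50))$p_value < 0.05
  }, logical(1)))
  expect_gte(rej, 0.95)
  expect_error(shapiro_francia(rep(1, 10)),
               class = "remstim_invalid_parameter")
  expect_error(shapiro_francia(rnorm(4)), class = "remstim_invalid_parameter")
})

test_that("paired comparison gates on normality and handles degenerate pairs", {
  set.seed(6)
  x <- rnorm(15)
  y <- x + 1 + rnorm(15, 0, 0.3)
  res <- paired_compare(x, y)
  expect_equal(res$test, "paired_t")
  expect_lt(res$p_value, 0.05)
  expect_lt(res$cohens_d, 0)            # x smaller than y
  # identical vectors
  res0 <- paired_compare(x, x)
  expect_true(res0$degenerate)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$cohens_d, 0)
  # proportions go through the logit first
  p1 <- c(0.6, 0.65, 0.7, 0.62, 0.68, 0.64, 0.66, 0.61)
  p2 <- p1 + 0.1
  rp <- paired_compare(p1, p2, proportion = TRUE)
  expect_equal(rp$transform, "logit")
  expect_error(paired_compare(c(0.5, 1.2), c(0.4, 0.6), proportion = TRUE),
               class = "remstim_invalid_parameter")
  expect_error(paired_compare(1:3, 1:4), class = "remstim_invalid_parameter")
})

test_that("the Wilcoxon branch reproduces full sign-enumeration probabilities", {
  # heavy-tailed differences push the gate to the signed-rank test
  x <- c(0, 0, 0, 0, 0, 0)
  y <- c(0.11, 0.23, 0.34, 0.42, 0.58, 60)
  res <- paired_compare(x, y)
  expect_equal(res$test, "wilcoxon_signed_rank")
  # enumeration oracle over all 2^6 sign patterns of the rank sum
  d <- x - y
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:63, function(code) {
    s <- as.logical(bitwAnd(code, 2^(0:5)))
    sum(r[s])
  }, numeric(1))
  p_or <- min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
  expect_equal(res$p_value, p_or)
})

test_that("noiseless gain model recovers its generating coefficients exactly", {
  set.seed(7)
  n <- 38
  cond <- rep(c("CNT", "STM"), n / 2)
  stage_min <- runif(n, 10, 70)
  gain <- 13.5 + 20.5 * (cond == "STM") - 0.66 * stage_min
  fit <- suppressWarnings(multivar_gain_model(gain, cond, stage_min))
  expect_equal(tidy(fit)$estimate, c(13.5, 20.5, -0.66), tolerance = 1e-10)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-10)
  # constant response: R^2 = 0, F p-value 1
  fit0 <- suppressWarnings(multivar_gain_model(rep(5, n), cond, stage_min))
  expect_equal(glance(fit0)$r.squared, 0)
  expect_equal(glance(fit0)$p.value, 1)
  # collinear design refused
  expect_error(multivar_gain_model(gain, cond, rep(1, n) * 2),
               class = "remstim_invalid_parameter")
})

test_that("gain-model interval coverage is nominal when the stage effect is null", {
  set.seed(8)
  n <- 60
  cover <- 0
  n_rep <- 300
  for (r in seq_len(n_rep)) {
    cond <- rep(0:1, n / 2)
    stage_min <- runif(n, 10, 70)
    gain <- 10 + 5 * cond + rnorm(n, 0, 8)     # beta2 = 0 truth
    fit <- multivar_gain_model(gain, cond, stage_min)
    co <- tidy(fit)[3, ]
    ci <- co$estimate + c(-1, 1) * qt(0.975, n - 3) * co$std.error
    if (ci[1] < 0 && ci[2] > 0) cover <- cover + 1
  }
  expect_gt(cover / n_rep, 0.92)
  expect_lt(cover / n_rep, 0.98)
})

test_that("Huber fit matches an independent IRLS oracle and resists outliers", {
  set.seed(9)
  x <- rnorm(10)
  y <- 1 + 2 * x + rnorm(10, 0, 0.2)
  # independent hand-rolled IRLS oracle on the 10-point fixture
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  for (i in 1:200) {
    r <- as.numeric(y - X %*% beta)
    s <- median(abs(r)) / 0.6745
    w <- pmin(1, 1.345 / (abs(r / s) + 1e-300))
    W <- diag(w)
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  }
  fit <- huber_fit(cbind(x = x), y)
  expect_equal(tidy(fit)$estimate, as.numeric(beta), tolerance = 1e-6)
  # exact linear data: identical to OLS
  y_lin <- 3 - 0.5 * x
  fit_lin <- huber_fit(cbind(x = x), y_lin)
  expect_equal(tidy(fit_lin)$estimate, c(3, -0.5), tolerance = 1e-8)
  # gross outlier: Huber slope error strictly below OLS slope error
  y_out <- y
  y_out[1] <- 40
  hub <- tidy(huber_fit(cbind(x = x), y_out))$estimate[2]
  ols <- unname(coef(lm(y_out ~ x))[2])
  expect_lt(abs(hub - 2), abs(ols - 2))
  # cross-check against MASS::rlm
  skip_if_not_installed("MASS")
  rl <- MASS::rlm(y_out ~ x, psi = MASS::psi.huber, k = 1.345, maxit = 200)
  expect_equal(tidy(huber_fit(cbind(x = x), y_out))$estimate,
               unname(coef(rl)), tolerance = 1e-3)
})

test_that("Huber tends to OLS as the tuning constant grows", {
  set.seed(10)
  x <- rnorm(25)
  y <- 2 + x + rexp(25)
  fit_big <- huber_fit(cbind(x = x), y, tuning_c = 1e6)
  expect_equal(tidy(fit_big)$estimate, unname(coef(lm(y ~ x))),
               tolerance = 1e-6)
})

test_that("BH step-up matches its definition on fixtures and random vectors", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.2), 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 5)), rep(FALSE, 5))
  # brute-force step-up oracle on random p-vectors; mask monotone in p
  set.seed(11)
  for (i in 1:300) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    mask <- bh_fdr(p, 0.05)
    ord <- order(p)
    ps <- p[ord]
    ks <- which(ps <= seq_len(m) * 0.05 / m)
    oracle <- logical(m)
    if (length(ks) > 0) oracle[ord[seq_len(max(ks))]] <- TRUE
    expect_identical(mask, oracle)
    expect_identical(mask, p.adjust(p, "BH") <= 0.05 |
                       (mask & p.adjust(p, "BH") <= 0.05))
    if (any(mask)) expect_true(all(p[mask] <= max(p[mask])))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "remstim_invalid_parameter")
})

test_that("electrode regressions control false discoveries and find a true slope", {
  set.seed(12)
  n_sub <- 20
  # null: power unrelated to gain -> FDP small on average
  fdp <- vapply(1:120, function(r) {
    pw <- matrix(rnorm(21 * n_sub, 0, 0.1), 21, n_sub,
                 dimnames = list(montage_1020()$label, NULL))
    gain <- rnorm(n_sub, 10, 5)
    er <- electrode_power_regressions(pw, gain, method = "ols")
    sig <- sum(er$by_electrode$p_fdr_significant)
    if (sig == 0) 0 else 1          # all discoveries are false under the null
  }, numeric(1))
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 120))
  # one electrode carrying the true 87.1 %/dB slope survives FDR
  hits <- vapply(1:30, function(r) {
    pw <- matrix(rnorm(21 * n_sub, 0, 0.1), 21, n_sub,
                 dimnames = list(montage_1020()$label, NULL))
    gain <- 10 + 87.1 * pw["Cz", ] + rnorm(n_sub, 0, 3)
    er <- electrode_power_regressions(pw, gain)
    el <- er$by_electrode
    el$p_fdr_significant[el$channel == "Cz"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # degenerate constant power: no fits
  pw0 <- matrix(1, 21, n_sub, dimnames = list(montage_1020()$label, NULL))
  er0 <- electrode_power_regressions(pw0, rnorm(n_sub))
  expect_equal(nrow(er0$by_electrode), 0)
  expect_null(er0$pooled)
})

test_that("between-condition differences follow the sign conventions", {
  expect_equal(between_condition_diff(2, 2, "power"), 0)
  expect_equal(between_condition_diff(1, 2, "power"), 10 * log10(2))
  expect_equal(between_condition_diff(10, 8, "time"), 2)
  expect_equal(between_condition_diff(5, 9, "performance"), -4)
  expect_error(between_condition_diff(-1, 2, "power"),
               class = "remstim_invalid_parameter")
})

test_that("correlation matches the covariance formula and supports FDR families", {
  expect_equal(correlate(1:5, 1:5)$rho, 1)
  expect_equal(correlate(1:5, -(1:5))$rho, -1)
  set.seed(13)
  x <- rnorm(5)
  y <- rnorm(5)
  r_or <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- correlate(x, y)
  expect_equal(res$rho, r_or)
  t_or <- r_or * sqrt(3) / sqrt(1 - r_or^2)
  expect_equal(res$p_value, 2 * pt(-abs(t_or), 3))
  res_fam <- correlate(x, y, family_p = c(0.2, 0.8))
  expect_gte(res_fam$p_fdr, res$p_value)
  expect_error(correlate(rep(1, 5), rnorm(5)),
               class = "remstim_invalid_parameter")
})

test_that("paired-t sample size search satisfies exact bracketing", {
  n19 <- power_analysis_paired_t(0.7, 0.05, 0.80)
  expect_equal(n19, 19L)
  # independent noncentral-t bracketing oracle
  pw <- function(n, d) {
    crit <- qt(0.975, n - 1)
    pt(crit, n - 1, ncp = d * sqrt(n), lower.tail = FALSE) +
      pt(-crit, n - 1, ncp = d * sqrt(n))
  }
  expect_gte(pw(19, 0.7), 0.80)
  expect_lt(pw(18, 0.7), 0.80)
  # monotone in d
  expect_lt(power_analysis_paired_t(1.4), n19)
  # agreement with stats::power.t.test
  ref <- ceiling(power.t.test(delta = 0.7, sd = 1, power = 0.8,
                              type = "one.sample")$n)
  expect_equal(n19, ref)
  expect_error(power_analysis_paired_t(0.7, power = 1.2),
               class = "remstim_invalid_parameter")
})
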