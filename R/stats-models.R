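#' Shapiro-Francia normality test
#'
#' W' is the squared correlation between the ordered sample and the
#' expected standard-normal order statistics; the p-value uses the
#' established log-transform normal approximation (as implemented in
#' nortest).
#'
#' @param x Numeric vector, 5 <= n <= 5000, non-constant.
#' @return A one-row tibble: `w_prime`, `p_value`, `n`.
#' @export
shapiro_francia <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5 || n > 5000) {
    abort("Sample size must be between 5 and 5000.",
          class = "remstim_invalid_parameter")
  }
  if (sd(x) == 0) {
    abort("Constant sample: normality test undefined.",
          class = "remstim_invalid_parameter")
  }
  res <- nortest::sf.test(x)
  tibble(w_prime = unname(res$statistic), p_value = res$p.value, n = n)
}

#' Normality-gated paired comparison
#'
#' Compares two paired vectors the way the analysis pipeline does: for
#' proportion-scale data both vectors are logit-transformed first; the
#' vector of paired differences is then gated through the Shapiro-Francia
#' test at alpha = 0.05 -- a paired t-test when it passes, a Wilcoxon
#' signed-rank test (exact for n <= 25, zero differences dropped)
#' otherwise. The paired Cohen's d (mean difference over SD of differences)
#' is reported alongside.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param proportion Set `TRUE` for proportion/odds data (logit transform).
#' @param normality_alpha Gate level.
#' @return A one-row tibble: `test`, `statistic`, `p_value`, `cohens_d`,
#'   `w_prime`, `normality_p`, `transform`, `n`, `degenerate`.
#' @export
paired_compare <- function(x, y, proportion = FALSE, normality_alpha = 0.05) {
  if (length(x) != length(y)) {
    abort("Paired vectors must have equal length.",
          class = "remstim_invalid_parameter")
  }
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  transform <- "none"
  if (proportion) {
    if (any(c(x, y) <= 0 | c(x, y) >= 1)) {
      abort("Proportions must lie strictly in (0, 1) for the logit transform.",
            class = "remstim_invalid_parameter")
    }
    x <- log(x / (1 - x))
    y <- log(y / (1 - y))
    transform <- "logit"
  }
  d <- x - y
  if (all(d == 0)) {
    return(tibble(test = "degenerate", statistic = NA_real_, p_value = 1,
                  cohens_d = 0, w_prime = NA_real_, normality_p = NA_real_,
                  transform = transform, n = length(d), degenerate = TRUE))
  }
  sf <- shapiro_francia(d)
  if (sf$p_value >= normality_alpha) {
    tt <- t.test(x, y, paired = TRUE)
    test <- "paired_t"
    stat <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    wt <- wilcox.test(x, y, paired = TRUE, exact = length(d) <= 25,
                      correct = FALSE)
    test <- "wilcoxon_signed_rank"
    stat <- unname(wt$statistic)
    p <- wt$p.value
  }
  tibble(test = test, statistic = stat, p_value = p,
         cohens_d = mean(d) / sd(d), w_prime = sf$w_prime,
         normality_p = sf$p_value, transform = transform, n = length(d),
         degenerate = FALSE)
}

# shared constructor for regression results
new_regression_fit <- function(coef_tbl, r2, fstat, df1, df2, n, method,
                               converged = TRUE) {
  structure(list(coefficients = coef_tbl, r_squared = r2, f_statistic = fstat,
                 df = c(df1, df2), n = n, method = method,
                 converged = converged),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit (%s): n = %d, R^2 = %.3f>\n",
              x$method, x$n, x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.regression_fit <- function(x, ...) x$coefficients

#' @export
glance.regression_fit <- function(x, ...) {
  p <- if (is.na(x$f_statistic)) NA_real_ else
    stats::pf(x$f_statistic, x$df[1], x$df[2], lower.tail = FALSE)
  tibble(r.squared = x$r_squared, statistic = x$f_statistic,
         df = x$df[1], df.residual = x$df[2], p.value = p, nobs = x$n,
         method = x$method, converged = x$converged)
}

#' Multivariable overnight-gain model
#'
#' Ordinary least squares for the explanatory model
#' gain = b0 + b1 * condition + b2 * stage_minutes, with the condition
#' coded 0 for the control night and 1 for the stimulation night.
#'
#' @param gain Overnight performance gain, percent.
#' @param condition Condition codes: 0/1, logical, or `"CNT"`/`"STM"`.
#' @param stage_minutes Time in the sleep stage of interest, minutes.
#' @return A `regression_fit`; [tidy()] gives the coefficient table,
#'   [glance()] the model fit (R^2, F, p).
#' @export
multivar_gain_model <- function(gain, condition, stage_minutes) {
  if (is.character(condition) || is.factor(condition)) {
    condition <- as.integer(as.character(condition) == "STM")
  }
  condition <- as.numeric(condition)
  n <- length(gain)
  if (n <= 3) {
    abort("More than 3 observations are required.",
          class = "remstim_invalid_parameter")
  }
  X <- cbind(1, condition, stage_minutes)
  if (qr(X)$rank < ncol(X)) {
    abort("Collinear design matrix.", class = "remstim_invalid_parameter")
  }
  fit <- lm(gain ~ condition + stage_minutes)
  sm <- summary(fit)
  co <- sm$coefficients
  coef_tbl <- tibble(term = c("(Intercept)", "condition", "stage_minutes"),
                     estimate = unname(co[, 1]), std.error = unname(co[, 2]),
                     statistic = unname(co[, 3]), p.value = unname(co[, 4]))
  r2 <- sm$r.squared
  fstat <- if (is.null(sm$fstatistic)) NA_real_ else unname(sm$fstatistic[1])
  if (sd(gain) < 1e-12 * max(1, abs(mean(gain)))) {
    r2 <- 0                       # constant response: no variance explained
    fstat <- 0
  }
  new_regression_fit(coef_tbl, r2, fstat, 2, n - 3, n, "OLS")
}

# Huber psi weight: 1 inside +-c, c/|u| outside
huber_weight <- function(u, c) {
  w <- rep(1, length(u))
  big <- abs(u) > c
  w[big] <- c / abs(u[big])
  w
}

#' Huber M-estimator regression
#'
#' Robust linear regression by iteratively reweighted least squares with
#' Huber's weight function (tuning constant 1.345 for 95% Gaussian
#' efficiency), scale re-estimated each iteration by the MAD of residuals,
#' iterated until the maximum coefficient change is below `tol` or
#' `max_iter` is reached. Standard errors use the standard M-estimation
#' asymptotic formula.
#'
#' @param X Design matrix (an intercept column is added unless the first
#'   column is constant), or a numeric predictor vector.
#' @param y Response.
#' @param tuning_c Huber tuning constant.
#' @param tol,max_iter Convergence control.
#' @return A `regression_fit` with method `"huber"`; `converged` is `FALSE`
#'   when the iteration limit was hit.
#' @export
huber_fit <- function(X, y, tuning_c = 1.345, tol = 1e-8, max_iter = 100) {
  if (is.null(dim(X))) X <- cbind(X)
  if (!all(X[, 1] == 1)) X <- cbind(`(Intercept)` = 1, X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    abort("More observations than coefficients are required.",
          class = "remstim_invalid_parameter")
  }
  beta <- qr.solve(X, y)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- y - X %*% beta
    s <- median(abs(r)) / 0.6745
    if (s < 1e-10) {                      # exact fit
      converged <- TRUE
      break
    }
    w <- huber_weight(as.numeric(r) / s, tuning_c)
    Xw <- X * sqrt(w)
    beta_new <- qr.solve(Xw, y * sqrt(w))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  r <- as.numeric(y - X %*% beta)
  s <- median(abs(r)) / 0.6745
  if (s < 1e-10) s <- sd(r) + 1e-12
  u <- r / s
  psi <- pmin(pmax(u, -tuning_c), tuning_c)
  psi_d <- as.numeric(abs(u) <= tuning_c)
  kappa <- 1 + p / n * var(psi_d) / mean(psi_d)^2   # Huber's correction
  sigma2 <- s^2 * kappa^2 * sum(psi^2) / (n - p) / mean(psi_d)^2
  XtXi <- solve(crossprod(X))
  se <- sqrt(diag(XtXi) * sigma2)
  tval <- as.numeric(beta) / se
  pv <- 2 * pt(-abs(tval), n - p)
  terms <- colnames(X) %||% paste0("x", seq_len(p))
  if (is.null(colnames(X))) terms[1] <- "(Intercept)"
  coef_tbl <- tibble(term = terms, estimate = as.numeric(beta),
                     std.error = se, statistic = tval, p.value = pv)
  # report the OLS-style R^2 of the robust fit for orientation
  r2 <- 1 - sum(r^2) / sum((y - mean(y))^2)
  new_regression_fit(coef_tbl, r2, NA_real_, p - 1, n - p, n, "huber",
                     converged = converged)
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure at level q: with ordered p-values p(1) <= ... <= p(m),
#' find the largest k with p(k) <= k q / m and reject the k smallest.
#'
#' @param p_values Numeric vector in [0, 1].
#' @param q FDR level.
#' @return Logical rejection mask in the input order.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].", class = "remstim_invalid_parameter")
  }
  m <- length(p_values)
  if (m == 0) return(logical(0))
  ord <- order(p_values)
  ps <- p_values[ord]
  k <- which(ps <= seq_len(m) * q / m)
  mask <- logical(m)
  if (length(k) > 0) mask[ord[seq_len(max(k))]] <- TRUE
  mask
}

#' Electrode-wise power-vs-gain regressions with FDR control
#'
#' Fits, per electrode, a robust (Huber) regression of overnight
#' performance gain on cluster power in dB; slope p-values are corrected
#' across electrodes by Benjamini-Hochberg FDR at level q, and a pooled fit
#' of gain on the mean power across surviving electrodes summarizes their
#' joint effect.
#'
#' @param power Tibble from [cluster_power_per_electrode()] (`subject`,
#'   `channel`, `power_db`) or an electrode x subject matrix with electrode
#'   rownames.
#' @param gain Numeric vector of per-subject gains (percent), subject order
#'   matching `power`.
#' @param q FDR level.
#' @param method `"huber"` (default) or `"ols"` per-electrode fits.
#' @return A list of class `electrode_regressions`: `by_electrode` (tibble:
#'   `channel`, `slope`, `p_value`, `p_fdr_significant`), `fits` (named list
#'   of `regression_fit`), `pooled` (a `regression_fit` over significant
#'   electrodes, or `NULL` when none survive).
#' @export
electrode_power_regressions <- function(power, gain, q = 0.05,
                                        method = c("huber", "ols")) {
  method <- match.arg(method)
  if (is.matrix(power)) {
    power <- purrr::map_dfr(seq_len(nrow(power)), function(i) {
      tibble(subject = seq_len(ncol(power)),
             channel = rownames(power)[i] %||% paste0("ch", i),
             power_db = power[i, ])
    })
  }
  wide <- tidyr::pivot_wider(power, names_from = "channel",
                             values_from = "power_db") |>
    dplyr::arrange(.data$subject)
  chans <- setdiff(names(wide), "subject")
  if (length(gain) < 4) {
    abort("At least 4 subjects are required.",
          class = "remstim_invalid_parameter")
  }
  fit_one <- function(pw) {
    if (sd(pw) == 0) return(NULL)
    if (method == "huber") huber_fit(cbind(power_db = pw), gain)
    else {
      f <- lm(gain ~ pw)
      sm <- summary(f)
      co <- sm$coefficients
      new_regression_fit(
        tibble(term = c("(Intercept)", "power_db"),
               estimate = unname(co[, 1]), std.error = unname(co[, 2]),
               statistic = unname(co[, 3]), p.value = unname(co[, 4])),
        sm$r.squared, unname(sm$fstatistic[1]), 1, length(gain) - 2,
        length(gain), "OLS")
    }
  }
  fits <- lapply(chans, function(ch) fit_one(wide[[ch]]))
  names(fits) <- chans
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) {
    return(structure(list(by_electrode = tibble(channel = character(0),
                                                slope = numeric(0),
                                                p_value = numeric(0),
                                                p_fdr_significant = logical(0)),
                          fits = list(), pooled = NULL),
                     class = "electrode_regressions"))
  }
  fits <- fits[keep]
  chans <- chans[keep]
  slopes <- vapply(fits, function(f) f$coefficients$estimate[2], numeric(1))
  pvals <- vapply(fits, function(f) f$coefficients$p.value[2], numeric(1))
  mask <- bh_fdr(pvals, q)
  pooled <- NULL
  if (any(mask)) {
    mean_power <- rowMeans(as.matrix(wide[chans[mask]]))
    pooled <- if (method == "huber") {
      huber_fit(cbind(mean_power = mean_power), gain)
    } else {
      fit_one(mean_power)
    }
  }
  structure(list(by_electrode = tibble(channel = chans, slope = slopes,
                                       p_value = pvals,
                                       p_fdr_significant = mask),
                 fits = fits, pooled = pooled),
            class = "electrode_regressions")
}

#' @export
print.electrode_regressions <- function(x, ...) {
  cat(sprintf("<electrode_regressions: %d electrodes, %d significant after FDR>\n",
              nrow(x$by_electrode), sum(x$by_electrode$p_fdr_significant)))
  invisible(x)
}

#' @export
tidy.electrode_regressions <- function(x, ...) x$by_electrode

#' Between-condition difference with the pipeline's sign conventions
#'
#' Time and performance variables are differenced as control minus
#' stimulation (CNT - STM, positive = larger under control); power
#' variables are expressed as the decibel ratio 10 log10(STM / CNT)
#' (positive = larger under stimulation).
#'
#' @param cnt_value,stm_value Values from the control and stimulation
#'   nights.
#' @param kind `"time"`, `"performance"`, or `"power"`.
#' @return Numeric difference (same length as the inputs).
#' @export
between_condition_diff <- function(cnt_value, stm_value,
                                   kind = c("time", "performance", "power")) {
  kind <- match.arg(kind)
  if (kind == "power") {
    if (any(cnt_value <= 0 | stm_value <= 0)) {
      abort("Powers must be positive for the dB ratio.",
            class = "remstim_invalid_parameter")
    }
    10 * log10(stm_value / cnt_value)
  } else {
    cnt_value - stm_value
  }
}

#' Pearson correlation with optional FDR within a family
#'
#' @param x,y Numeric vectors, n >= 3, non-constant.
#' @param family_p Optional vector of the other p-values in the correction
#'   family; when given, the BH-adjusted p of this correlation within that
#'   family is reported.
#' @return A one-row tibble: `rho`, `p_value`, `p_fdr`, `n`.
#' @export
correlate <- function(x, y, family_p = NULL) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    abort("At least 3 complete pairs are required.",
          class = "remstim_invalid_parameter")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance input.", class = "remstim_invalid_parameter")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  p_fdr <- if (is.null(family_p)) NA_real_ else {
    stats::p.adjust(c(ct$p.value, family_p), method = "BH")[1]
  }
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, p_fdr = p_fdr,
         n = length(x))
}

#' Sample size for a paired t-test
#'
#' Smallest N such that a two-sided one-sample t-test on paired differences
#' with effect size d (noncentrality d sqrt(N), N - 1 degrees of freedom)
#' reaches the requested power, found by exact noncentral-t evaluation and
#' integer search.
#'
#' @param d Cohen's d of the paired differences (> 0).
#' @param alpha Two-sided significance level.
#' @param power Target power in (0, 1).
#' @param n_max Search limit.
#' @return Required N (integer).
#' @export
power_analysis_paired_t <- function(d, alpha = 0.05, power = 0.80,
                                    n_max = 10000) {
  check_scalar(d, "d")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("alpha and power must lie in (0, 1).",
          class = "remstim_invalid_parameter")
  }
  pw <- function(n) {
    ncp <- d * sqrt(n)
    crit <- qt(1 - alpha / 2, n - 1)
    pt(crit, n - 1, ncp = ncp, lower.tail = FALSE) +
      pt(-crit, n - 1, ncp = ncp)
  }
  for (n in 2:n_max) {
    if (pw(n) >= power) return(as.integer(n))
  }
  abort("Requested power not reachable within n_max.",
        class = "remstim_invalid_parameter")
}
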