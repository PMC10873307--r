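#' Score a psychomotor vigilance test session
#'
#' Mean reaction time over valid trials, where valid means an RT in the
#' closed interval 100 to 500 ms.
#'
#' @param trials Tibble with an `rt_ms` column (extra columns ignored), or a
#'   numeric RT vector.
#' @return A one-row tibble: `task`, `value` (mean RT, ms), `n_valid_trials`.
#' @export
pvt_score <- function(trials) {
  rt <- if (is.numeric(trials)) trials else trials$rt_ms
  if (length(rt) == 0) {
    abort("At least one trial is required.", class = "remstim_invalid_parameter")
  }
  valid <- rt >= 100 & rt <= 500
  if (!any(valid)) {
    abort("No valid trials (RT within 100-500 ms).",
          class = "remstim_invalid_parameter")
  }
  tibble(task = "PVT", value = mean(rt[valid]), n_valid_trials = sum(valid))
}

# cumulative-Gaussian psychometric curve with guess and lapse rates
psychometric_curve <- function(soa, mu, sigma, gamma = 0.5, lambda = 0) {
  gamma + (1 - gamma - lambda) * pnorm((soa - mu) / sigma)
}

#' Estimate the threshold SOA from a visual discrimination session
#'
#' Fits a cumulative-Gaussian psychometric function to Bernoulli
#' orientation-judgement outcomes by maximum likelihood and returns the
#' stimulus-onset asynchrony at which the fitted curve reaches 80% correct.
#' Trials on which the concurrent letter task was answered incorrectly are
#' removed before fitting. The guess rate is fixed at 0.5 (two-alternative
#' judgement) and the lapse rate is estimated within [0, 0.06].
#'
#' @param trials Tibble with `soa_ms`, `orientation_correct`, and optionally
#'   `letter_correct` columns.
#' @param target Accuracy defining the threshold (default 0.80).
#' @param gamma Fixed guess rate.
#' @param lapse_max Upper bound for the lapse rate.
#' @return A one-row tibble: `task`, `value` (threshold SOA, ms),
#'   `n_valid_trials`, `mu`, `sigma`, `lambda`, `converged`, `flagged`
#'   (`TRUE` when the fit failed or the threshold fell outside
#'   [min SOA / 2, 2 max SOA]).
#' @export
vdt_threshold <- function(trials, target = 0.80, gamma = 0.5,
                          lapse_max = 0.06) {
  stopifnot(all(c("soa_ms", "orientation_correct") %in% names(trials)))
  if ("letter_correct" %in% names(trials)) {
    trials <- trials[!is.na(trials$letter_correct) & trials$letter_correct, ]
  }
  soa <- trials$soa_ms
  y <- as.numeric(trials$orientation_correct)
  if (length(unique(soa)) < 2) {
    abort("At least two distinct SOA levels are required.",
          class = "remstim_invalid_parameter")
  }
  # aggregate to binomial counts per SOA level (identical likelihood)
  lv <- sort(unique(soa))
  k <- vapply(lv, function(s) sum(y[soa == s]), numeric(1))
  n_lv <- vapply(lv, function(s) sum(soa == s), numeric(1))
  nll <- function(par) {
    mu <- par[1]
    sigma <- exp(par[2])
    lambda <- par[3]
    p <- psychometric_curve(lv, mu, sigma, gamma, lambda)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n_lv - k) * log(1 - p))
  }
  # multi-start: a data-driven midpoint guess with two slope scales plus a
  # broad fallback; the likelihood has local optima that bias the threshold
  acc <- k / n_lv
  mid <- (target + gamma) / 2
  guess <- lv[which.min(abs(acc - mid))]
  inits <- list(c(guess, log(diff(range(soa)) / 8), 0.01),
                c(guess, log(diff(range(soa)) / 4), 0.01),
                c(stats::median(soa), log(diff(range(soa)) / 4), 0.01))
  lower <- c(min(soa) - diff(range(soa)), log(1), 0)
  upper <- c(max(soa) + diff(range(soa)), log(10 * diff(range(soa))),
             lapse_max)
  fit <- NULL
  for (init in inits) {
    f <- tryCatch(optim(init, nll, method = "L-BFGS-B", lower = lower,
                        upper = upper),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(fit) || f$value < fit$value)) fit <- f
  }
  if (is.null(fit)) {
    return(tibble(task = "VDT", value = NA_real_, n_valid_trials = length(y),
                  mu = NA_real_, sigma = NA_real_, lambda = NA_real_,
                  converged = FALSE, flagged = TRUE))
  }
  mu <- fit$par[1]
  sigma <- exp(fit$par[2])
  lambda <- fit$par[3]
  q <- (target - gamma) / (1 - gamma - lambda)
  thr <- if (q <= 0 || q >= 1) NA_real_ else mu + sigma * qnorm(q)
  flagged <- is.na(thr) || thr < min(soa) / 2 || thr > 2 * max(soa) ||
    fit$convergence != 0
  tibble(task = "VDT", value = thr, n_valid_trials = length(y),
         mu = mu, sigma = sigma, lambda = lambda,
         converged = fit$convergence == 0, flagged = flagged)
}

#' Score a mirror-tracing session
#'
#' Performance is the mean log on-path time over retained trials; trials
#' whose log-time lies more than 3.5 pooled-group standard deviations from
#' the group mean are removed as outliers or failed attempts. Group
#' statistics come from `group_values` (all subjects' log-times pooled)
#' when supplied, else from the session itself.
#'
#' @param trials Tibble with an `on_path_time_s` column, or a numeric vector
#'   of on-path times (seconds, > 0).
#' @param group_values Pooled log-times defining the outlier criterion.
#' @param sd_limit Outlier cut in group standard deviations.
#' @return A one-row tibble: `task`, `value` (mean log-time),
#'   `n_valid_trials`, `n_removed`.
#' @export
mtt_score <- function(trials, group_values = NULL, sd_limit = 3.5) {
  tt <- if (is.numeric(trials)) trials else trials$on_path_time_s
  if (any(tt <= 0)) {
    abort("On-path times must be positive.",
          class = "remstim_invalid_parameter")
  }
  lt <- log(tt)
  gv <- if (is.null(group_values)) lt else group_values
  mu <- mean(gv)
  s <- sd(gv)
  keep <- if (is.na(s) || s == 0) rep(TRUE, length(lt)) else
    abs(lt - mu) <= sd_limit * s
  if (!any(keep)) {
    abort("All trials removed as outliers.",
          class = "remstim_invalid_parameter")
  }
  tibble(task = "MTT", value = mean(lt[keep]), n_valid_trials = sum(keep),
         n_removed = sum(!keep))
}

#' Overnight performance gain
#'
#' The relative overnight change of a task's performance measure,
#' 100 x (evening - morning) / evening, applied verbatim to whatever the
#' task's measure is (mean RT, threshold SOA, mean log-time); no per-task
#' sign flipping is performed, so for measures where smaller is better a
#' positive gain means improvement.
#'
#' @param evening,morning Scores (one-row tibbles from the scoring
#'   functions, or bare numbers).
#' @return Gain in percent; `NA` with a warning when the evening value is 0.
#' @export
overnight_gain <- function(evening, morning) {
  ev <- if (is.data.frame(evening)) evening$value else evening
  mo <- if (is.data.frame(morning)) morning$value else morning
  if (any(ev == 0)) {
    warn("Evening performance of 0: gain undefined.")
    return(ifelse(ev == 0, NA_real_, 100 * (ev - mo) / ev))
  }
  100 * (ev - mo) / ev
}

#' Score a full behavioural trial table
#'
#' Applies the per-task scoring functions to every (subject, condition,
#' session, task) cell of a trial tibble in the layout produced by
#' [generate_behavioural_dataset()], then computes overnight gains.
#'
#' @param trials Trial tibble with `subject_id`, `condition`, `session`,
#'   `task` and the task measurement columns.
#' @return A tibble of gains: `subject_id`, `condition`, `task`,
#'   `evening`, `morning`, `gain_pct`.
#' @export
score_behaviour <- function(trials) {
  score_one <- function(df) {
    switch(df$task[1],
           PVT = pvt_score(df),
           VDT = vdt_threshold(df),
           MTT = mtt_score(df, group_values = log(trials$on_path_time_s[
             trials$task == "MTT" & !is.na(trials$on_path_time_s)])))
  }
  scores <- trials |>
    dplyr::group_by(.data$subject_id, .data$condition, .data$session,
                    .data$task) |>
    dplyr::group_modify(~ score_one(.x |> dplyr::mutate(task = .y$task)) |>
                          dplyr::select(-"task")) |>
    dplyr::ungroup()
  scores |>
    dplyr::select("subject_id", "condition", "session", "task", "value") |>
    tidyr::pivot_wider(names_from = "session", values_from = "value") |>
    dplyr::mutate(gain_pct = overnight_gain(.data$pre, .data$post)) |>
    dplyr::rename(evening = "pre", morning = "post")
}
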