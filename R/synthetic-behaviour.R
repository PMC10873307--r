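#' Generate synthetic behavioural task datasets
#'
#' Simulates trial tables for the three tasks, for every subject under both
#' overnight conditions (CNT, STM) and both sessions (pre, post):
#'
#' * **PVT**: reaction times are shifted log-normal (100 ms floor), with a
#'   subject-specific mean.
#' * **VDT**: each trial is a Bernoulli draw from a cumulative-Gaussian
#'   psychometric curve (guess rate 0.5, lapse 0.02) over the standard SOA
#'   block ladder (two blocks of 400/300/200/160 ms, three of
#'   120/100/80/60/40 ms, 50 trials per block); the letter task is correct
#'   with probability 0.95 independently.
#' * **MTT**: six figures per session with log-normal on-path times.
#'
#' Condition effects are expressed as target overnight performance gains in
#' percent (of the evening performance measure): the morning performance
#' parameter is the evening one scaled by `1 - gain/100`. `effects` gives
#' the STM-minus-CNT differential gain per task; `base_gain` the CNT-night
#' gain. The defaults reproduce the condition contrasts the analysis is
#' designed to detect: +20.71 percentage points of differential VDT gain and
#' -11.60 for the MTT, with no PVT effect.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param effects Named list/vector: differential STM-CNT overnight gain in
#'   percentage points for `pvt`, `vdt`, `mtt`.
#' @param base_gain Named list/vector: CNT-night overnight gain per task.
#' @param n_pvt_trials PVT trials per session.
#' @param seed Integer seed.
#' @return A tibble of trials with columns `subject_id`, `condition`,
#'   `session`, `task`, `trial` and the task-specific measurement columns
#'   (`rt_ms`; `soa_ms`, `letter_correct`, `orientation_correct`; `figure`,
#'   `on_path_time_s`). The generating parameters are attached as the
#'   `"ground_truth"` attribute.
#' @export
generate_behavioural_dataset <- function(n_subjects,
                                         effects = c(pvt = 0, vdt = 20.71,
                                                     mtt = -11.60),
                                         base_gain = c(pvt = 0, vdt = 10,
                                                       mtt = 25),
                                         n_pvt_trials = 80,
                                         seed = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    abort("n_subjects must be >= 2.", class = "remstim_invalid_parameter")
  }
  soa_blocks <- c(rep(c(400, 300, 200, 160), 2), rep(c(120, 100, 80, 60, 40), 3))
  gamma <- 0.5
  lambda <- 0.02
  sigma_psy <- 40
  # SOA offset between the 80%-accuracy threshold and the curve midpoint
  thr_off <- sigma_psy * qnorm((0.8 - gamma) / (1 - gamma - lambda))
  with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(n_subjects), function(sj) {
      pvt_mu_e <- rnorm(1, 280, 25)
      vdt_thr_e <- rnorm(1, 150, 20)
      mtt_lt_e <- rnorm(1, log(60), 0.12)
      purrr::map_dfr(c("CNT", "STM"), function(cond) {
        gains <- vapply(c("pvt", "vdt", "mtt"), function(tk) {
          base_gain[[tk]] + if (cond == "STM") effects[[tk]] else 0
        }, numeric(1))
        purrr::map_dfr(c("pre", "post"), function(sess) {
          shrink <- function(evening, g) {
            if (sess == "pre") evening else evening * (1 - g / 100)
          }
          pvt_mu <- shrink(pvt_mu_e, gains[["pvt"]])
          vdt_thr <- shrink(vdt_thr_e, gains[["vdt"]])
          mtt_lt <- shrink(mtt_lt_e, gains[["mtt"]])
          # PVT: shifted lognormal above a 100 ms floor
          sdl <- 0.25
          rt <- 100 + rlnorm(n_pvt_trials,
                             log(max(pvt_mu - 100, 20)) - sdl^2 / 2, sdl)
          rt <- pmin(rt, 1000)
          pvt <- tibble(task = "PVT", trial = seq_len(n_pvt_trials),
                        rt_ms = rt, soa_ms = NA_real_,
                        letter_correct = NA, orientation_correct = NA,
                        figure = NA_integer_, on_path_time_s = NA_real_)
          # VDT: Bernoulli draws from the subject's psychometric curve
          soa <- rep(soa_blocks, each = 50)
          mu <- vdt_thr - thr_off
          p_corr <- gamma + (1 - gamma - lambda) * pnorm((soa - mu) / sigma_psy)
          vdt <- tibble(task = "VDT", trial = seq_along(soa),
                        rt_ms = NA_real_, soa_ms = soa,
                        letter_correct = runif(length(soa)) < 0.95,
                        orientation_correct = runif(length(soa)) < p_corr,
                        figure = NA_integer_, on_path_time_s = NA_real_)
          # MTT: six figures, log-normal on-path times
          lt <- rnorm(6, mtt_lt, 0.08)
          mtt <- tibble(task = "MTT", trial = 1:6, rt_ms = NA_real_,
                        soa_ms = NA_real_, letter_correct = NA,
                        orientation_correct = NA, figure = 1:6,
                        on_path_time_s = exp(lt))
          dplyr::bind_rows(pvt, vdt, mtt) |>
            dplyr::mutate(subject_id = sj, condition = cond, session = sess,
                          .before = 1)
        })
      })
    })
    attr(rows, "ground_truth") <- list(effects = effects,
                                       base_gain = base_gain,
                                       gamma = gamma, lambda = lambda,
                                       sigma_psy = sigma_psy)
    rows
  })
}
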