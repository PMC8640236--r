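#' QUEST adaptive staircase
#'
#' A Bayesian adaptive staircase (Watson-Pelli QUEST) controlling the
#' number of Gabor features shown per trial so that accuracy converges on
#' a target level (75% by default). Intensity is `log10(number of
#' features)`: thresholds on a feature count are ratio-scaled, and QUEST
#' assumes translation invariance on its intensity axis.
#'
#' The assumed psychometric function is a Weibull in log10 intensity,
#' `p(x; T) = gamma + (1 - gamma - delta) * (1 - exp(-10^(beta (x - T + eps))))`,
#' with `eps` fixed so that `p(T) = target_p` exactly: the threshold
#' parameter *is* the target-performance point. Defaults (`beta = 3.5`,
#' `gamma = 0.5`, `delta = 0.01`, Gaussian prior on the log10 threshold,
#' posterior-mean placement) follow common psychophysics-toolbox usage;
#' all are configurable.
#'
#' @param n_max Largest presentable feature count (upper end of the
#'   intensity range).
#' @param prior_mean,prior_sd Gaussian prior over the log10 threshold
#'   (defaults: log10(300) and 1.0).
#' @param beta Weibull slope.
#' @param gamma Guess rate (0.5 for 2-AFC).
#' @param delta Lapse rate of the assumed psychometric function.
#' @param target_p Targeted probability correct; must lie in
#'   `(gamma, 1 - delta)`.
#' @param grid_step Grid resolution in log10 units.
#' @return A `dfm_quest` state: posterior over the log10-threshold grid
#'   plus the psychometric parameters and a trial counter.
#' @examples
#' q <- quest_init()
#' quest_recommend(q)  # 300, the prior mean
#' q <- quest_update(q, presented_n = 300, correct = TRUE)
#' quest_recommend(q) < 300  # correct -> easier than threshold -> go down
#' @export
quest_init <- function(n_max = 2200, prior_mean = log10(300), prior_sd = 1.0,
                       beta = 3.5, gamma = 0.5, delta = 0.01,
                       target_p = 0.75, grid_step = 0.01) {
  if (!(target_p > gamma && target_p < 1 - delta)) {
    stop("invalid config: target_p must lie in (gamma, 1 - delta)",
         call. = FALSE)
  }
  stopifnot(prior_sd > 0, beta > 0, n_max >= 1)
  lo <- min(0, prior_mean - 4 * prior_sd)
  hi <- max(log10(n_max), prior_mean + 4 * prior_sd)
  # symmetric grid about the prior mean so the initial posterior mean is
  # the prior mean to grid precision
  half <- max(prior_mean - lo, hi - prior_mean)
  grid <- seq(prior_mean - half, prior_mean + half, by = grid_step)
  posterior <- stats::dnorm(grid, prior_mean, prior_sd)
  posterior <- posterior / sum(posterior)
  structure(list(grid = grid, posterior = posterior, n_max = n_max,
                 beta = beta, gamma = gamma, delta = delta,
                 target_p = target_p, trial_count = 0L),
            class = "dfm_quest")
}

#' @rdname quest_init
#' @param state A `dfm_quest` state.
#' @param presented_n Number of features presented on the trial.
#' @param correct Logical, was the response correct.
#' @export
quest_update <- function(state, presented_n, correct) {
  stopifnot(presented_n >= 1, presented_n <= state$n_max)
  p <- weibull_p(log10(presented_n), state$grid, state$beta, state$gamma,
                 state$delta, state$target_p)
  state$posterior <- state$posterior * (if (correct) p else 1 - p)
  state$posterior <- state$posterior / sum(state$posterior)
  state$trial_count <- state$trial_count + 1L
  state
}

#' @rdname quest_init
#' @return `quest_recommend()`: the feature count for the next trial —
#'   posterior-mean log10 threshold, exponentiated, rounded, clipped to
#'   `[1, n_max]`.
#' @export
quest_recommend <- function(state) {
  m <- sum(state$posterior * state$grid)
  as.integer(min(max(round(10^m), 1), state$n_max))
}

#' Threshold estimate from a QUEST posterior
#'
#' @param state A `dfm_quest` state.
#' @return A `dfm_threshold` list: `n_gabors_threshold` (posterior-mean
#'   threshold on the feature-count scale, clipped to `[1, n_max]`) and
#'   `posterior_sd` (log10 units).
#' @export
threshold_estimate <- function(state) {
  m <- sum(state$posterior * state$grid)
  v <- sum(state$posterior * (state$grid - m)^2)
  structure(list(n_gabors_threshold = min(max(10^m, 1), state$n_max),
                 posterior_sd = sqrt(v),
                 trials = state$trial_count),
            class = "dfm_threshold")
}

#' @export
print.dfm_threshold <- function(x, ...) {
  cat("<dfm_threshold> ", round(x$n_gabors_threshold, 2), " features (",
      x$trials, " trials, posterior sd ", signif(x$posterior_sd, 3),
      " log10 units)\n", sep = "")
  invisible(x)
}

#' @export
print.dfm_quest <- function(x, ...) {
  est <- threshold_estimate(x)
  cat("<dfm_quest> ", x$trial_count, " trials, threshold estimate ",
      round(est$n_gabors_threshold, 1), " features (target p = ",
      x$target_p, ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.dfm_quest <- function(x, ...) {
  tibble::tibble(log10_threshold = x$grid, threshold = 10^x$grid,
                 posterior = x$posterior)
}

#' @export
glance.dfm_quest <- function(x, ...) {
  est <- threshold_estimate(x)
  tibble::tibble(n_gabors_threshold = est$n_gabors_threshold,
                 posterior_sd = est$posterior_sd,
                 trials = est$trials, target_p = x$target_p)
}
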