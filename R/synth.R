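## Synthetic escape-event generator: emulates the per-event table of a
## dummy-predator escape experiment (23 individuals, ~264 events) so the
## whole pipeline is testable without the deposited dataset, and supports
## parameter-recovery experiments.

#' Generate a synthetic escape-event dataset
#'
#' For each event a fish and an initial orientation are drawn, the
#' `T_diff'` profile under the generating truth is computed, and the escape
#' trajectory is sampled by the truncated-normal ranking rule. Turn angle and
#' directionality follow from `ET - beta`. Turn-time observations are the
#' truth curve plus a per-fish offset and residual noise; post-turn initial
#' velocities come from the rise-then-flat curve plus noise. Optionally a
#' per-trial predator speed is drawn uniformly from the pooled slow/fast
#' dummy-predator ranges (0.13-0.93 and 1.29-1.88 mm/ms).
#'
#' @param true_params Generating [model_params()] (defaults to
#'   [pagrus_params()]).
#' @param turn_truth Generating `T1(|alpha|)` [turn_model()] (defaults to
#'   [default_turn_model()]).
#' @param v0_truth Generating `v0(|alpha|)` curve ([default_v0_model()]).
#' @param sd_choice Scale of the generating choice distribution.
#' @param n_fish Number of individuals.
#' @param n_events Number of events (`>= n_fish`; every fish appears).
#' @param beta_dist Either `"uniform"` (default: beta ~ U(0, 180)) or a
#'   function `function(n)` returning `n` orientations in degrees.
#' @param t1_noise_sd Residual sd of the turn-time observations, ms.
#' @param fish_sd Sd of the per-fish turn-time offsets, ms.
#' @param v0_noise_sd Residual sd of the velocity observations, mm/ms.
#' @param predator_speed Add a per-trial dummy predator speed column.
#' @param mirror Randomly mirror events to the left side (adds a `side`
#'   column with sign-flipped angles, for testing the pooling reader).
#' @param seed Integer seed.
#' @return A data frame with columns `fish_id`, `trial_id`, `beta`, `alpha`,
#'   `et`, `direction`, `predator_speed` (optional), `t1_obs`, `v0_obs`
#'   (+ `side` if mirrored). The generating truth is kept in
#'   `attr(, "truth")`.
#' @examples
#' ev <- synth_events(n_events = 50, seed = 1)
#' head(ev)
#' @export
synth_events <- function(true_params = pagrus_params(),
                         turn_truth = default_turn_model(),
                         v0_truth = default_v0_model(),
                         sd_choice = 0.33, n_fish = 23, n_events = 264,
                         beta_dist = "uniform",
                         t1_noise_sd = 2, fish_sd = 2, v0_noise_sd = 0.05,
                         predator_speed = FALSE, mirror = FALSE,
                         seed = NULL) {
  stopifnot(n_events >= n_fish)
  if (!is.null(seed)) set.seed(seed)
  choice <- choice_dist(max(sd_choice, 1e-9))

  fish <- sprintf("f%02d", c(seq_len(n_fish),
                             sample.int(n_fish, n_events - n_fish,
                                        replace = TRUE)))
  fish <- sample(fish)
  beta <- if (is.function(beta_dist)) beta_dist(n_events)
          else stats::runif(n_events, 0, 180)
  offs <- stats::rnorm(n_fish, 0, fish_sd)
  names(offs) <- sprintf("f%02d", seq_len(n_fish))

  et <- alpha <- t1 <- v0 <- numeric(n_events)
  dir <- character(n_events)
  for (i in seq_len(n_events)) {
    pr <- et_profile(beta[i], true_params, turn_truth)
    d <- if (sd_choice > 0) sample_et(pr, choice, 1)
         else pr$entries[which(pr$entries$et == pr$optimal_et), ][1, ]
    et[i] <- d$et
    alpha[i] <- d$alpha
    dir[i] <- if (d$alpha >= 0) "away" else "toward"
    t1[i] <- predict_t1(turn_truth, abs(d$alpha)) + offs[fish[i]] +
      stats::rnorm(1, 0, t1_noise_sd)
    v0[i] <- predict_t1(v0_truth, abs(d$alpha)) + stats::rnorm(1, 0, v0_noise_sd)
  }
  out <- data.frame(fish_id = fish,
                    trial_id = seq_len(n_events),
                    beta = beta, alpha = alpha, et = et, direction = dir,
                    stringsAsFactors = FALSE)
  if (predator_speed) {
    slow <- stats::runif(n_events, 0.13, 0.93)
    fast <- stats::runif(n_events, 1.29, 1.88)
    out$predator_speed <- ifelse(stats::runif(n_events) < 0.5, slow, fast)
  }
  out$t1_obs <- pmax(t1, 0.1)
  out$v0_obs <- pmax(v0, 0.01)
  if (mirror) {
    # left-side attacks are recorded with lab-frame (mirror-image) signs;
    # directionality (away/toward) is frame-independent
    left <- stats::runif(n_events) < 0.5
    out$side <- ifelse(left, "left", "right")
    out$alpha[left] <- -out$alpha[left]
    out$et[left] <- out$beta[left] + out$alpha[left]
  }
  attr(out, "truth") <- list(params = true_params, turn = turn_truth,
                             v0 = v0_truth, sd_choice = sd_choice,
                             fish_offsets = offs)
  out
}
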