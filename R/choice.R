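## Optimal vs suboptimal choice analysis: how the advantage of the best
## escape trajectory over the second-best modulates which one the prey uses.

#' Optimal-ET advantage of a profile
#'
#' The difference between the maximum of `T_diff` (at the optimal ET) and its
#' second local maximum (at the suboptimal ET): the extra buffer time the
#' optimal choice buys. `NA` when the profile has a single peak.
#'
#' @param profile A [et_profile()] result.
#' @return Advantage in ms (non-negative), or `NA`.
#' @export
optimal_advantage <- function(profile) {
  profile$advantage
}

#' Circular distance between two angles
#'
#' @param a,b Angles in degrees.
#' @return Distance in `[0, 180]` degrees.
#' @export
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Assign observed escape trajectories to the optimal or suboptimal peak
#'
#' Each observed ET is assigned to the nearer of the profile's two peaks by
#' circular distance; events farther than `threshold` from both peaks are
#' excluded, as are events whose profile lacks a second peak.
#'
#' @param events Event data frame (columns `beta`, `et`).
#' @param params A [model_params()] object.
#' @param turn A [turn_model()].
#' @param threshold Exclusion distance, degrees.
#' @return A data frame: the events plus `choice` (`"optimal"`,
#'   `"suboptimal"` or `"excluded"`), `advantage` (ms), `optimal_et`,
#'   `suboptimal_et`.
#' @export
classify_choice <- function(events, params, turn, threshold = 35) {
  events <- as.data.frame(events)
  ub <- unique(events$beta)
  prof <- lapply(ub, et_profile, params = params, turn = turn)
  names(prof) <- as.character(ub)
  out <- events
  out$choice <- "excluded"
  out$advantage <- NA_real_
  out$optimal_et <- NA_real_
  out$suboptimal_et <- NA_real_
  for (i in seq_len(nrow(out))) {
    p <- prof[[as.character(out$beta[i])]]
    out$optimal_et[i] <- p$optimal_et
    out$suboptimal_et[i] <- p$suboptimal_et
    out$advantage[i] <- p$advantage
    if (is.na(p$suboptimal_et)) next
    d_opt <- circ_dist(out$et[i], p$optimal_et)
    d_sub <- circ_dist(out$et[i], p$suboptimal_et)
    if (min(d_opt, d_sub) > threshold) next
    out$choice[i] <- if (d_opt <= d_sub) "optimal" else "suboptimal"
  }
  out
}

#' Mixed-effects logistic regression of choice on optimal-ET advantage
#'
#' Fits `P(optimal)` as a logistic function of the advantage with a random
#' intercept per individual (Laplace approximation via `lme4::glmer`), and
#' tests the advantage effect by a likelihood-ratio test. Falls back to a
#' plain `glm` when there are fewer than 3 individuals or the mixed fit
#' fails.
#'
#' @param advantage Optimal-ET advantage per event, ms.
#' @param choice Binary choice per event: 1/TRUE = optimal.
#' @param fish_id Individual identifiers.
#' @return A list with `slope`, `intercept`, `chisq`, `df`, `p`, `n`,
#'   `model` (the fitted object) and `method` (`"glmer"` or `"glm"`).
#' @export
logistic_choice_fit <- function(advantage, choice, fish_id = NULL) {
  y <- as.integer(as.logical(choice))
  keep <- is.finite(advantage) & !is.na(y)
  adv <- advantage[keep]; y <- y[keep]
  fish <- if (is.null(fish_id)) rep("all", length(y)) else as.character(fish_id[keep])
  if (length(unique(y)) < 2)
    stop("both choice classes must be present")
  dat <- data.frame(y = y, adv = adv, fish = factor(fish))

  use_glmer <- nlevels(dat$fish) >= 3
  fit <- NULL
  if (use_glmer) {
    fit <- tryCatch({
      full <- lme4::glmer(y ~ adv + (1 | fish), data = dat, family = stats::binomial,
                          control = lme4::glmerControl(calc.derivs = FALSE))
      null <- lme4::glmer(y ~ 1 + (1 | fish), data = dat, family = stats::binomial,
                          control = lme4::glmerControl(calc.derivs = FALSE))
      lrt <- 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(null)))
      list(full = full, chisq = lrt,
           coef = lme4::fixef(full), method = "glmer")
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      # retry without suppressing convergence warnings before giving up
      fit <- tryCatch({
        full <- suppressWarnings(lme4::glmer(y ~ adv + (1 | fish), data = dat,
                                             family = stats::binomial))
        null <- suppressWarnings(lme4::glmer(y ~ 1 + (1 | fish), data = dat,
                                             family = stats::binomial))
        lrt <- 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(null)))
        list(full = full, chisq = lrt, coef = lme4::fixef(full), method = "glmer")
      }, error = function(e) NULL)
    }
  }
  if (is.null(fit)) {
    full <- stats::glm(y ~ adv, data = dat, family = stats::binomial)
    if (any(abs(stats::coef(full)) > 20))
      warning("possible complete separation; estimates are unstable")
    null <- stats::glm(y ~ 1, data = dat, family = stats::binomial)
    lrt <- as.numeric(null$deviance - full$deviance)
    fit <- list(full = full, chisq = lrt, coef = stats::coef(full),
                method = "glm")
  }
  list(slope = unname(fit$coef["adv"]), intercept = unname(fit$coef[1]),
       chisq = max(fit$chisq, 0), df = 1,
       p = stats::pchisq(max(fit$chisq, 0), df = 1, lower.tail = FALSE),
       n = nrow(dat), model = fit$full, method = fit$method)
}

#' Advantage sweep over initial orientations
#'
#' Computes the optimal-ET advantage for a grid of initial orientations.
#'
#' @param betas Initial orientations, degrees.
#' @param params A [model_params()] object.
#' @param turn A [turn_model()].
#' @return Data frame with `beta`, `advantage`, `optimal_et`,
#'   `suboptimal_et`.
#' @export
advantage_sweep <- function(betas, params, turn) {
  rows <- lapply(betas, function(b) {
    p <- et_profile(b, params, turn)
    data.frame(beta = b, advantage = p$advantage, optimal_et = p$optimal_et,
               suboptimal_et = p$suboptimal_et)
  })
  do.call(rbind, rows)
}
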