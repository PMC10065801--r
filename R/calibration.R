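## Rank-based calibration of the unobservable predator parameters
## (D_attack, U_pred) and the truncated-normal stochastic choice scale.

## ---- truncated normal with mode at 0, support [0, 1] -------------------

#' Truncated-normal choice distribution over the ranking index
#'
#' A half-normal (location fixed at 0) truncated to `[0, 1]`, parameterised
#' by its scale `sd_choice`. It governs how far down the model-ranked list of
#' escape trajectories the prey's actual choice falls: 0 is the theoretical
#' optimum, 1 the worst option.
#'
#' @param sd_choice Positive scale of the underlying normal.
#' @return An object of class `choice_dist`.
#' @export
choice_dist <- function(sd_choice) {
  stopifnot(is.finite(sd_choice), sd_choice > 0)
  structure(list(sd_choice = sd_choice), class = "choice_dist")
}

#' @method print choice_dist
#' @export
print.choice_dist <- function(x, ...) {
  cat(sprintf("truncated-normal choice distribution, sd_choice = %.4f\n",
              x$sd_choice))
  invisible(x)
}

#' @rdname choice_dist
#' @param x Quantile(s) in `[0, 1]`.
#' @param dist A `choice_dist` object.
#' @export
dtrunc_choice <- function(x, dist) {
  s <- dist$sd_choice
  z <- stats::pnorm(1 / s) - 0.5
  out <- stats::dnorm(x, 0, s) / z
  out[x < 0 | x > 1] <- 0
  out
}

#' @rdname choice_dist
#' @param q Quantile(s).
#' @export
ptrunc_choice <- function(q, dist) {
  s <- dist$sd_choice
  z <- stats::pnorm(1 / s) - 0.5
  pmin(pmax((stats::pnorm(q, 0, s) - 0.5) / z, 0), 1)
}

#' @rdname choice_dist
#' @param n Number of draws.
#' @export
rtrunc_choice <- function(n, dist) {
  s <- dist$sd_choice
  z <- stats::pnorm(1 / s) - 0.5
  s * stats::qnorm(0.5 + stats::runif(n) * z)
}

#' Maximum-likelihood fit of the choice scale
#'
#' Fits the scale of the zero-mode truncated normal to observed ranking
#' indices by maximum likelihood.
#'
#' @param ranking_indices Values in `[0, 1]`.
#' @param interval Search interval for the scale.
#' @return A [choice_dist()].
#' @export
fit_choice_sd <- function(ranking_indices, interval = c(1e-3, 10)) {
  x <- ranking_indices[is.finite(ranking_indices)]
  stopifnot(length(x) > 0, all(x >= 0 & x <= 1))
  if (all(x == 0)) {
    warning("all ranking indices are zero; returning minimal scale")
    return(choice_dist(interval[1]))
  }
  nll <- function(s) {
    z <- stats::pnorm(1 / s) - 0.5
    -sum(stats::dnorm(x, 0, s, log = TRUE) - log(z))
  }
  opt <- stats::optimize(nll, interval = interval)
  choice_dist(opt$minimum)
}

## ---- ranking engine ----------------------------------------------------

## Precompute the candidate-independent pieces of the ranking objective for
## a set of events: the signed alpha grid, folded grid ETs per event, the
## feasibility mask and the grid index nearest each observed ET.
ranking_setup <- function(events, params) {
  a_away <- seq(params$alpha_min, params$alpha_max, by = params$grid_step)
  alpha_grid <- c(a_away, -a_away)
  n <- nrow(events)
  ET <- outer(events$beta, alpha_grid, "+")        # full-circle grid ETs
  EF <- fold_et(ET)
  feas <- EF > 1e-9
  # circular distance between each observed ET and each grid ET
  dd <- abs(ET - events$et)
  dd <- pmin(dd %% 360, 360 - dd %% 360)
  dd[!feas] <- Inf
  j_obs <- max.col(-dd, ties.method = "first")
  ABS <- matrix(rep(abs(alpha_grid), each = n), nrow = n)
  list(alpha_grid = alpha_grid, EF = EF, ABS = ABS, feas = feas,
       j_obs = j_obs, n = n)
}

## mean ranking index of the observed events under one parameter set,
## given a precomputed setup (fully vectorised over events x grid)
mean_ranking_impl <- function(setup, params, turn) {
  TD <- matrix(tdiff_rel_fold(as.vector(setup$EF), as.vector(setup$ABS),
                              params, turn),
               nrow = setup$n)
  TD[!setup$feas] <- NA
  idx <- cbind(seq_len(setup$n), setup$j_obs)
  t_sel <- TD[idx]
  gt <- rowSums(TD > t_sel, na.rm = TRUE)
  eq <- rowSums(TD == t_sel, na.rm = TRUE)
  N <- rowSums(setup$feas)
  rank <- gt + (eq + 1) / 2
  mean((rank - 1) / (N - 1))
}

#' Ranking index of observed escape trajectories
#'
#' For each event, all feasible grid ETs of its initial orientation are
#' ordered by decreasing relative time margin `T_diff'`; the observed ET is
#' mapped to the nearest feasible grid ET (circular distance) and its
#' standardised rank `(rank - 1) / (N - 1)` is returned: 0 means the prey
#' chose the theoretical optimum, 1 the theoretical worst. Ties in `T_diff'`
#' share the mean rank. The two directionality branches are ranked jointly
#' as one list.
#'
#' @param events A data frame of escape events with at least `beta` and `et`
#'   (degrees; see [synth_events()] / [read_events()] for the schema).
#' @param params A [model_params()] object.
#' @param turn A [turn_model()].
#' @return Numeric vector of ranking indices in `[0, 1]`.
#' @export
ranking_index <- function(events, params, turn) {
  events <- as.data.frame(events)
  setup <- ranking_setup(events, params)
  TD <- matrix(tdiff_rel_fold(as.vector(setup$EF), as.vector(setup$ABS),
                              params, turn),
               nrow = setup$n)
  TD[!setup$feas] <- NA
  t_sel <- TD[cbind(seq_len(setup$n), setup$j_obs)]
  gt <- rowSums(TD > t_sel, na.rm = TRUE)
  eq <- rowSums(TD == t_sel, na.rm = TRUE)
  N <- rowSums(setup$feas)
  (gt + (eq + 1) / 2 - 1) / (N - 1)
}

#' Calibrate the predator attack endpoint and speed
#'
#' Finds the `(D_attack, U_pred)` pair minimising the mean ranking index of
#' the observed escape trajectories, by deterministic coarse-to-fine grid
#' refinement down to a resolution of 0.01 mm and 0.01 mm/ms. For model
#' variants without an attack endpoint (`attack_endpoint = FALSE`) only
#' `U_pred` is searched.
#'
#' @param events Event data frame (columns `beta`, `et`).
#' @param params Template [model_params()]; all fields except `D_attack` and
#'   `U_pred` are held fixed.
#' @param turn A [turn_model()].
#' @param d_attack_bounds,u_pred_bounds Search intervals. The defaults span
#'   the plausible strike distances and the live-predator speed range.
#' @param grid_n Points per axis at each refinement stage.
#' @param tol Final grid resolution (applies to both axes).
#' @return A list with `D_attack` (NA when not searched), `U_pred`,
#'   `mean_ranking` and `params` (the template with the optimum filled in).
#' @export
optimize_params <- function(events, params, turn,
                            d_attack_bounds = c(5, 120),
                            u_pred_bounds = c(0.1, 3),
                            grid_n = 9, tol = 0.01) {
  events <- as.data.frame(events)
  stopifnot(nrow(events) >= 1)
  setup <- ranking_setup(events, params)
  two_dim <- params$attack_endpoint

  obj <- function(da, up) {
    p <- params
    if (two_dim) p$D_attack <- da
    p$U_pred <- up
    mean_ranking_impl(setup, p, turn)
  }

  da_lo <- d_attack_bounds[1]; da_hi <- d_attack_bounds[2]
  up_lo <- u_pred_bounds[1]; up_hi <- u_pred_bounds[2]
  best <- NULL
  repeat {
    das <- if (two_dim) seq(da_lo, da_hi, length.out = grid_n) else params$D_attack
    ups <- seq(up_lo, up_hi, length.out = grid_n)
    grid <- expand.grid(da = das, up = ups)
    vals <- mapply(obj, grid$da, grid$up)
    i <- which.min(vals)
    best <- list(da = grid$da[i], up = grid$up[i], val = vals[i])
    step_da <- if (two_dim && length(das) > 1) das[2] - das[1] else 0
    step_up <- ups[2] - ups[1]
    if (step_da <= tol && step_up <= tol) break
    if (two_dim) {
      da_lo <- max(d_attack_bounds[1], best$da - 1.5 * step_da)
      da_hi <- min(d_attack_bounds[2], best$da + 1.5 * step_da)
    }
    up_lo <- max(u_pred_bounds[1], best$up - 1.5 * step_up)
    up_hi <- min(u_pred_bounds[2], best$up + 1.5 * step_up)
  }
  # snap to the requested resolution
  da <- if (two_dim) round(best$da / tol) * tol else NA_real_
  up <- round(best$up / tol) * tol
  p <- params
  if (two_dim) p$D_attack <- da
  p$U_pred <- up
  list(D_attack = da, U_pred = up,
       mean_ranking = mean_ranking_impl(setup, p, turn), params = p)
}
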