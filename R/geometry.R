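## Danger/safety-zone geometry of the straight-attack escape model.
##
## Coordinate frame: prey centre of mass at the origin; the predator
## approaches along the +x axis moving toward -x, with the tip of its capture
## device starting at x = +D_initial and stopping at x = -D_attack.  The
## escape trajectory (ET) is measured counter-clockwise from +x; by mirror
## symmetry only the folded angle in [0, 180] matters to the geometry.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Fold a full-circle escape trajectory onto the symmetric semicircle
#'
#' The danger zone is mirror-symmetric about the predator's approach axis, so
#' an ET and its mirror image are geometrically equivalent. This returns the
#' unsigned angle in `[0, 180]` between the escape ray and the approach axis.
#' The function is total and idempotent: `fold_et(et) == fold_et(-et) ==
#' fold_et(360 - et)`.
#'
#' @param et Escape trajectory angle(s) in degrees, any real value.
#' @return Angle(s) in `[0, 180]` degrees.
#' @examples
#' fold_et(c(190, -80, 100)) # 170, 80, 100
#' @export
fold_et <- function(et) {
  abs(((et + 180) %% 360) - 180)
}

#' Sagitta of the capture-device arc
#'
#' The lag `D2` of the capture-device edge (at the half-width `D_width`)
#' behind the device tip, for an arc of radius `R_device`:
#' `D2 = R_device * (1 - cos(asin(D_width / R_device)))`.
#'
#' @param params A [model_params()] object.
#' @return Length in mm, between 0 and `R_device`.
#' @export
sagitta_d2 <- function(params) {
  with(params, R_device * (1 - cos(asin(D_width / R_device))))
}

#' Escape trajectory aimed at the corner of the danger zone
#'
#' The corner is where the lateral edge of the danger zone (`y = D_width`)
#' meets the end-of-attack arc, at `(D2 - D_attack, D_width)`. ETs below this
#' angle cross the lateral edge; ETs at or above it cross the arc. When the
#' attack has no endpoint (`attack_endpoint = FALSE`) there is no corner and
#' 180 degrees is returned (all crossings are lateral).
#'
#' @param params A [model_params()] object.
#' @return Angle in degrees, in `(0, 180]`.
#' @export
theta_corner <- function(params) {
  if (!params$attack_endpoint) return(180)
  d2 <- sagitta_d2(params)
  ang <- rad2deg(atan2(params$D_width, d2 - params$D_attack))
  (ang + 360) %% 360
}

## Vectorised crossing of the escape ray with the safety-zone boundary.
## et_semi in (0, 180]; returns x, y, dist (ray parameter).  Infeasible rays
## (et == 0, or lateral rays that never exit such as 180 under an infinite
## attack) get dist = Inf.
crossing_point_impl <- function(et_semi, params) {
  th <- deg2rad(et_semi)
  s <- sin(th); cs <- cos(th)
  thc <- theta_corner(params)
  lateral <- et_semi < thc
  dist <- rep(Inf, length(et_semi))
  x <- rep(NA_real_, length(et_semi)); y <- x

  lat <- lateral & s > 1e-12
  dist[lat] <- params$D_width / s[lat]
  x[lat] <- dist[lat] * cs[lat]
  y[lat] <- params$D_width

  if (params$attack_endpoint) {
    arc <- !lateral
    cc <- params$R_device - params$D_attack   # centre of the end-of-attack arc
    disc <- cc^2 * cs[arc]^2 - cc^2 + params$R_device^2
    tt <- cc * cs[arc] + sqrt(pmax(disc, 0))
    tt[disc < 0] <- Inf
    # the crossing must be on the far (attack-end) side of the circle
    bad <- is.finite(tt) & (tt * cs[arc] > cc + 1e-9)
    tt[bad] <- Inf
    dist[arc] <- tt
    x[arc] <- tt * cs[arc]
    y[arc] <- tt * s[arc]
  }
  list(x = x, y = y, dist = dist)
}

#' Crossing point of the escape path and the safety-zone edge
#'
#' Returns the first intersection (positive ray parameter) of the escape ray
#' from the origin at angle `et_semi` with the boundary of the danger zone:
#' the lateral edge `y = D_width` for `et_semi < theta_corner(params)`, or
#' the end-of-attack arc `(x + D_attack - R_device)^2 + y^2 = R_device^2`
#' otherwise. An ET of exactly 0 (straight at the predator) never exits
#' laterally and is reported as infeasible (`dist = Inf`), not an error.
#'
#' @param et_semi Folded escape trajectory(ies), degrees in `(0, 180]`.
#' @param params A [model_params()] object.
#' @return A data frame with columns `x`, `y` (mm) and `dist`, the distance
#'   from the prey's initial position to the crossing point.
#' @export
crossing_point <- function(et_semi, params) {
  stopifnot(all(et_semi >= 0 & et_semi <= 180))
  cr <- crossing_point_impl(et_semi, params)
  data.frame(x = cr$x, y = cr$y, dist = cr$dist)
}

#' Prey arrival time at the safety zone
#'
#' Time for the whole prey body to clear the danger zone along the folded ET
#' `et_semi`: the fast-start time `T1(|alpha|)` plus the constant-speed time
#' over the remaining distance `||crossing|| - D1 + L_prey`. If the crossing
#' lies inside the fast-start radius the remaining distance is clamped at
#' `L_prey` (the two-phase decomposition silently assumes the crossing lies
#' beyond `D1`).
#'
#' @param abs_alpha Absolute turn angle(s), degrees.
#' @param et_semi Folded ET(s), degrees in `(0, 180]`.
#' @param params A [model_params()] object.
#' @param turn A fitted or constructed [turn_model()] for `T1(|alpha|)`.
#' @return Time(s) in ms; `Inf` where the crossing is infeasible.
#' @export
t_prey <- function(abs_alpha, et_semi, params, turn) {
  cr <- crossing_point_impl(et_semi, params)
  predict_t1(turn, abs_alpha) +
    (pmax(cr$dist - params$D1, 0) + params$L_prey) / params$U_prey
}

#' Predator arrival time at the crossing point
#'
#' Time for the relevant edge of the capture device to reach the crossing
#' point: `(D_initial + D2 - x_cross) / U_pred` for lateral crossings, and the
#' constant `(D_initial + D_attack) / U_pred` for crossings on the
#' end-of-attack arc (which the device reaches exactly when the attack ends).
#'
#' @param et_semi Folded ET(s), degrees.
#' @param x_cross x coordinate(s) of the crossing point, mm (from
#'   [crossing_point()]).
#' @param params A [model_params()] object.
#' @return Time(s) in ms.
#' @export
t_pred <- function(et_semi, x_cross, params) {
  thc <- theta_corner(params)
  ifelse(et_semi < thc,
         (params$D_initial + sagitta_d2(params) - x_cross) / params$U_pred,
         (params$D_initial + params$D_attack) / params$U_pred)
}

## Core vectorised evaluation of the relative time difference on folded ETs.
## Relative means: the alpha,beta-independent constant
## D_initial/U_pred + D1/U_prey - L_prey/U_prey has been dropped.
tdiff_rel_fold <- function(et_fold, abs_alpha, params, turn) {
  cr <- crossing_point_impl(et_fold, params)
  thc <- theta_corner(params)
  pred_rel <- ifelse(et_fold < thc,
                     (sagitta_d2(params) - cr$x) / params$U_pred,
                     params$D_attack / params$U_pred)
  out <- pred_rel - predict_t1(turn, abs_alpha) - cr$dist / params$U_prey
  out[!is.finite(cr$dist)] <- -Inf
  out
}

#' Relative survival time margin of an escape choice
#'
#' Evaluates the relative time difference `T_diff'` between predator and prey
#' arrival at the crossing point, for a signed turn angle `alpha` and initial
#' orientation `beta` (the ET is `alpha + beta`, folded onto the semicircle).
#' `T_diff'` equals the absolute margin ([t_diff_abs()]) minus the
#' alpha,beta-independent constant
#' `D_initial/U_pred + D1/U_prey - L_prey/U_prey`, so rankings and argmaxes
#' are unaffected by `D_initial`, `D1` and `L_prey`.
#'
#' @param alpha Signed turn angle(s), degrees (positive = away, negative =
#'   toward the predator).
#' @param beta Initial orientation(s), degrees in `[0, 180]`.
#' @param params A [model_params()] object.
#' @param turn A [turn_model()] for `T1(|alpha|)`.
#' @return Relative time margin(s) in ms; `-Inf` marks infeasible rays and
#'   `NA` marks turn angles outside `[alpha_min, alpha_max]`.
#' @export
t_diff_rel <- function(alpha, beta, params, turn) {
  out <- tdiff_rel_fold(fold_et(alpha + beta), abs(alpha), params, turn)
  out[abs(alpha) < params$alpha_min - 1e-9 |
        abs(alpha) > params$alpha_max + 1e-9] <- NA_real_
  out
}

#' Absolute survival time margin
#'
#' `T_diff = T_pred - T_prey` with all constants retained (Eqs. of the
#' straight-attack model evaluated literally). Positive values mean the prey
#' clears the danger zone before the predator's capture device arrives.
#'
#' @inheritParams t_diff_rel
#' @return Time margin(s) in ms.
#' @export
t_diff_abs <- function(alpha, beta, params, turn) {
  et <- fold_et(alpha + beta)
  cr <- crossing_point_impl(et, params)
  t_pred(et, cr$x, params) - (predict_t1(turn, abs(alpha)) +
    (pmax(cr$dist - params$D1, 0) + params$L_prey) / params$U_prey)
}

## ---- T_diff profile over the feasible ET grid --------------------------

## run-aware local maxima: collapse plateaus to their central point; a run is
## a local max if strictly greater than both neighbouring runs (ends of the
## branch compare against their single neighbour).
local_max_idx <- function(v) {
  n <- length(v)
  if (n == 0) return(integer(0))
  r <- rle(v)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1], -Inf)
  is_max <- r$values > left & r$values > right & is.finite(r$values)
  floor((starts[is_max] + ends[is_max]) / 2)
}

#' Relative time-difference profile over all reachable escape trajectories
#'
#' Evaluates `T_diff'` on the full feasible ET grid for one initial
#' orientation: the away branch `beta + [alpha_min, alpha_max]` and the
#' toward branch `beta - [alpha_min, alpha_max]`, at `grid_step` resolution.
#' Identifies the optimal ET (global maximum; ties broken toward the smaller
#' `|alpha|`), the suboptimal ET (highest-valued local maximum on a distinct
#' peak) and the optimal-ET advantage (difference between the two peak
#' values).
#'
#' @param beta Initial orientation, degrees in `[0, 180]`.
#' @param params A [model_params()] object.
#' @param turn A [turn_model()] for `T1(|alpha|)`.
#' @return An object of class `tdiff_profile`: a list with `beta`, a data
#'   frame `entries` (columns `et` on the full circle, `alpha`, `branch`,
#'   `t_diff_rel`, `feasible`), `optimal_et`, `suboptimal_et` (or `NA`),
#'   `advantage` (ms, or `NA`) and the generating `params`.
#' @examples
#' pr <- et_profile(75, pagrus_params(), default_turn_model())
#' pr$optimal_et
#' @export
et_profile <- function(beta, params, turn) {
  stopifnot(length(beta) == 1, beta >= 0, beta <= 180)
  a_away <- seq(params$alpha_min, params$alpha_max, by = params$grid_step)
  alpha <- c(a_away, -a_away)
  branch <- rep(c("away", "toward"), each = length(a_away))
  et <- beta + alpha
  td <- t_diff_rel(alpha, beta, params, turn)
  build_profile(beta, et, alpha, branch, td, params)
}

## shared profile assembly: peak detection on the feasible grid
build_profile <- function(beta, et, alpha, branch, td, params) {
  feasible <- is.finite(td)
  entries <- data.frame(et = et, alpha = alpha, branch = branch,
                        t_diff_rel = td, feasible = feasible,
                        stringsAsFactors = FALSE)

  optimal_et <- suboptimal_et <- advantage <- NA_real_
  if (any(feasible)) {
    best_val <- max(td[feasible])
    cand <- which(feasible & td == best_val)
    opt_i <- cand[which.min(abs(alpha[cand]))]
    optimal_et <- et[opt_i]

    # local maxima branch-wise, in grid (= et) order within each branch
    lm_idx <- integer(0)
    for (b in c("away", "toward")) {
      sel <- which(branch == b)
      sel <- sel[order(et[sel])]
      v <- ifelse(feasible[sel], td[sel], -Inf)
      lm_idx <- c(lm_idx, sel[local_max_idx(v)])
    }
    # drop the peak containing the optimum: any local max equal in value and
    # contiguous with opt_i is the same plateau; identify by position
    same_peak <- vapply(lm_idx, function(i) {
      branch[i] == branch[opt_i] && abs(td[i] - best_val) < 1e-12 &&
        all(td[seq(min(i, opt_i), max(i, opt_i))] >= best_val - 1e-12)
    }, logical(1))
    others <- lm_idx[!same_peak]
    if (length(others)) {
      sub_i <- others[which.max(td[others])]
      suboptimal_et <- et[sub_i]
      advantage <- best_val - td[sub_i]
    }
  }
  structure(list(beta = beta, entries = entries, optimal_et = optimal_et,
                 suboptimal_et = suboptimal_et, advantage = advantage,
                 params = params),
            class = "tdiff_profile")
}

#' @method print tdiff_profile
#' @export
print.tdiff_profile <- function(x, ...) {
  cat(sprintf("T_diff' profile at beta = %g deg: %d grid ETs (%d feasible)\n",
              x$beta, nrow(x$entries), sum(x$entries$feasible)))
  cat(sprintf("  optimal ET %g deg", x$optimal_et))
  if (!is.na(x$suboptimal_et))
    cat(sprintf("; suboptimal ET %g deg (advantage %.2f ms)",
                x$suboptimal_et, x$advantage))
  cat("\n")
  invisible(x)
}

#' Export a profile's feasible grid as a data frame
#'
#' @param profile A [et_profile()] result.
#' @param feasible_only Drop infeasible grid points (default `TRUE`).
#' @return A data frame with `beta`, `et`, `alpha`, `branch`, `t_diff_rel`.
#' @export
profile_table <- function(profile, feasible_only = TRUE) {
  e <- profile$entries
  if (feasible_only) e <- e[e$feasible, ]
  data.frame(beta = profile$beta, e[c("et", "alpha", "branch", "t_diff_rel")],
             row.names = NULL)
}
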