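## Adjustable-path (pursuit) predator.
##
## The predator approaches straight along the axis, sweeping with its
## capture device, until its tip is within D_react of the prey's initial
## position.  From there it can adjust its path with a minimum turning
## radius R_turn (straight + single arc + straight, i.e. a Dubins CS path of
## the tip), under a total path-length budget of D_initial + D_attack.
##
## The danger zone is the union of
##   (i)  the pre-reaction device sweep: the lateral strip |y| <= D_width
##        ahead of the device face at the reaction moment, and
##   (ii) the post-reaction tip-reachable set: points with an admissible
##        CS path within the remaining budget.
## The interiors of the two minimum-radius turning discs are not reachable
## by the tip, so they are safety zones (the Corcoran-style safe region
## inside the predator's turning radius), as is the far region beyond the
## path budget (the safety zone opposite the predator's incoming direction).
##
## An infinite turning radius removes the ability to adjust altogether, in
## which case the pursuit predator IS the straight-attack predator: with
## R_turn = Inf (and any D_react) the danger zone and arrival times are
## those of the base model.  This implements the stated containment of the
## straight-attack construction in the adjustable-path one; for large but
## finite R_turn the pointised post-reaction predator keeps a thin swept
## corridor, so the correspondence is exact only at R_turn = Inf (see the
## methods vignette).

## shortest circle-straight path length from the turn-initiation point
## (D_react, 0), heading -x, to targets (x, y); Inf where the target lies
## inside either minimum-radius turning disc
dubins_cs_len <- function(x, y, p) {
  R <- p$R_turn
  one_circle <- function(cy, cw) {
    dx <- x - p$D_react
    dy <- y - cy
    d2 <- dx^2 + dy^2
    ok <- d2 >= R^2 * (1 - 1e-12)
    Lt <- sqrt(pmax(d2 - R^2, 0))
    psi <- atan2(dy, dx)
    eta <- acos(pmin(pmax(R / sqrt(pmax(d2, R^2)), -1), 1))
    phiP <- if (cw) -pi / 2 else pi / 2   # start point angle on the circle
    res <- rep(Inf, length(x))
    for (sgn in c(1, -1)) {
      phiQ <- psi + sgn * eta
      tx <- if (cw) sin(phiQ) else -sin(phiQ)   # departure tangent direction
      ty <- if (cw) -cos(phiQ) else cos(phiQ)
      qx <- p$D_react + R * cos(phiQ)
      qy <- cy + R * sin(phiQ)
      darc <- if (cw) (phiP - phiQ) %% (2 * pi) else (phiQ - phiP) %% (2 * pi)
      darc[darc > 2 * pi - 1e-9] <- 0   # zero arcs that rounded up to 2*pi
      # a strike adjustment is at most a half-turn: paths that would loop
      # more than 180 degrees are not admissible, which preserves the
      # safety pocket inside each turning disc
      good <- ok & ((x - qx) * tx + (y - qy) * ty > -1e-9) & darc <= pi + 1e-9
      res[good] <- pmin(res[good], (darc * R + Lt)[good])
    }
    res
  }
  pmin(one_circle(R, TRUE), one_circle(-R, FALSE))
}

## device-edge lag behind the tip at lateral offset y (the sagitta at |y|)
device_lag <- function(y, p) {
  p$R_device - sqrt(pmax(p$R_device^2 - y^2, 0))
}

## arrival time of the straight-attack (base-model) predator at (x, y);
## Inf outside the straight device sweep.  budget_x is the lowest tip
## position the straight phase reaches (-D_attack for the base model,
## +D_react for the pre-reaction segment of the pursuit model).
straight_arrival <- function(x, y, p, tip_floor) {
  lag <- device_lag(y, p)
  ok <- abs(y) <= p$D_width & (x - lag) >= tip_floor
  ifelse(ok, (p$D_initial + lag - x) / p$U_pred, Inf)
}

#' Predator arrival time under the adjustable-path model
#'
#' Earliest arrival of the pursuing predator at target point(s): via the
#' pre-reaction straight device sweep where that covers the target, or via a
#' straight + minimum-radius arc + straight path of the tip from the
#' reaction point, within the total path budget `D_initial + D_attack`.
#' Targets inside the minimum-radius turning discs, or beyond the budget,
#' are unreachable and reported as `Inf` (safe). With `R_turn = Inf` the
#' predator cannot adjust at all and this reduces exactly to the
#' straight-attack arrival times of the base model.
#'
#' @param x,y Target coordinates, mm (prey initial position at the origin,
#'   predator approaching along +x).
#' @param p A [pursuit_params()] object.
#' @return Arrival time(s) in ms; `Inf` where the target is unreachable.
#' @export
pursuit_t_pred <- function(x, y, p) {
  if (is.infinite(p$R_turn))
    return(straight_arrival(x, y, p, -p$D_attack))
  pre <- straight_arrival(x, y, p, p$D_react)
  len <- dubins_cs_len(x, y, p)
  turn <- ifelse(len <= p$D_attack + p$D_react + 1e-9,
                 (p$D_initial - p$D_react + len) / p$U_pred, Inf)
  pmin(pre, turn)
}

## membership of points in the pursuit danger zone
pursuit_danger <- function(x, y, p) {
  is.finite(pursuit_t_pred(x, y, p))
}

#' Relative time-difference profile under the adjustable-path predator
#'
#' As [et_profile()], but the danger zone is the pursuit reachable set: for
#' each grid ET the prey's crossing point is the first point along the
#' escape ray outside the reachable set (located by coarse marching plus
#' bisection), and the predator's arrival there comes from
#' [pursuit_t_pred()]. The same additive constant as in the base model
#' (`D_initial/U_pred + D1/U_prey - L_prey/U_prey`) is dropped, so with
#' `R_turn = Inf` the profile coincides with [et_profile()].
#'
#' @param beta Initial orientation, degrees in `[0, 180]`.
#' @param p A [pursuit_params()] object.
#' @param turn A [turn_model()].
#' @param coarse_step Marching step along the escape ray, mm. Safe pockets
#'   thinner than this may be skipped.
#' @return A `tdiff_profile` object (see [et_profile()]).
#' @export
pursuit_profile <- function(beta, p, turn, coarse_step = 2) {
  stopifnot(inherits(p, "pursuit_params"), length(beta) == 1,
            beta >= 0, beta <= 180)
  a_away <- seq(p$alpha_min, p$alpha_max, by = p$grid_step)
  alpha <- c(a_away, -a_away)
  branch <- rep(c("away", "toward"), each = length(a_away))
  et <- beta + alpha
  ef <- fold_et(et)
  th <- deg2rad(ef)
  cs <- cos(th); sn <- sin(th)

  # upper bound on the exit distance: lateral strip exit or turning budget
  lat_cap <- p$D_width / pmax(sn, 1e-6) + 2 * coarse_step
  turn_cap <- if (is.infinite(p$R_turn)) p$D_attack + coarse_step
              else p$D_attack + 2 * p$D_react + coarse_step
  s_cap <- pmax(pmin(lat_cap, 5000), turn_cap)
  s_max <- max(s_cap)
  s_grid <- seq(0, s_max, by = coarse_step)

  m <- length(et)
  feas <- ef > 1e-9
  dist <- rep(Inf, m)
  # coarse march in chunks of steps, dropping rays once they have exited
  first_out <- rep(NA_integer_, m)
  alive <- which(feas)
  chunk <- 32L
  i0 <- 1L
  n_s <- length(s_grid)
  while (length(alive) && i0 <= n_s) {
    i1 <- min(i0 + chunk - 1L, n_s)
    ss <- s_grid[i0:i1]
    X <- outer(cs[alive], ss)
    Y <- outer(sn[alive], ss)
    outside <- matrix(!pursuit_danger(as.vector(X), as.vector(Y), p),
                      nrow = length(alive))
    any_out <- rowSums(outside) > 0
    if (any(any_out)) {
      j <- max.col(outside, ties.method = "first")[any_out]
      first_out[alive[any_out]] <- i0 - 1L + j
      alive <- alive[!any_out]
    }
    # rays past their own cap cannot exit any more; drop them (stay Inf)
    alive <- alive[s_grid[i1] <= s_cap[alive]]
    i0 <- i1 + 1L
  }
  hit <- which(feas & !is.na(first_out) & first_out > 1)
  lo <- s_grid[pmax(first_out[hit] - 1, 1)]
  hi <- s_grid[first_out[hit]]
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    inside <- pursuit_danger(mid * cs[hit], mid * sn[hit], p)
    lo[inside] <- mid[inside]
    hi[!inside] <- mid[!inside]
  }
  dist[hit] <- (lo + hi) / 2
  tp <- rep(Inf, m)
  tp[hit] <- pursuit_t_pred(lo * cs[hit], lo * sn[hit], p)

  td <- tp - predict_t1(turn, abs(alpha)) - dist / p$U_prey -
    p$D_initial / p$U_pred
  td[!feas | !is.finite(dist)] <- -Inf
  td[is.na(td)] <- -Inf
  build_profile(beta, et, alpha, branch, td, p)
}
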