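#' Geometric and kinematic model parameters
#'
#' Bundles the constants of the escape-geometry model. Units are millimetres
#' and milliseconds throughout, so speeds are mm/ms and a speed printed as
#' 1.54 m s^-1 enters unchanged as `1.54`.
#'
#' @param D_width Half-width of the predator's capture device (mouth), mm.
#' @param R_device Radius of the arc approximating the capture device at the
#'   moment of attack, mm. Must satisfy `D_width <= R_device`.
#' @param D1 Displacement at which the prey's fast-start phase (turn plus
#'   acceleration) is assumed to end, mm.
#' @param U_prey Prey speed after the fast-start phase, mm/ms.
#' @param U_pred Predator speed, assumed constant, mm/ms.
#' @param D_attack Distance from the prey's initial position to the tip of the
#'   capture device at the end of the attack, mm.
#' @param L_prey Length of the prey body posterior to its centre of mass, mm.
#'   The whole body must clear the danger zone, so this length is added to the
#'   prey's travel distance.
#' @param D_initial Predator-prey distance at escape onset (flight initiation
#'   distance), mm.
#' @param alpha_min,alpha_max Bounds on the absolute turn angle \eqn{|\alpha|}
#'   the prey can produce, degrees.
#' @param grid_step Resolution of the escape-trajectory grid, degrees.
#' @param attack_endpoint Logical; if `FALSE` the attack has no endpoint (the
#'   predator sweeps forever) and the safety zone reduces to the lateral
#'   strips only. This is the classic straight-attack null construction.
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(D_width = 18, R_device = 199, D_attack = 34.73,
#'                   U_prey = 1.04, U_pred = 1.54)
#' sagitta_d2(p)
#' @export
model_params <- function(D_width = 18, R_device = 199, D1 = 15,
                         U_prey = 1.04, U_pred = 1.54, D_attack = 34.73,
                         L_prey = 30, D_initial = 60,
                         alpha_min = 9, alpha_max = 147, grid_step = 1,
                         attack_endpoint = TRUE) {
  stopifnot(D_width >= 0, R_device > 0, D1 > 0, U_prey > 0, U_pred > 0,
            D_attack > 0, L_prey >= 0, D_initial > 0, grid_step > 0)
  if (D_width > R_device)
    stop("D_width must not exceed R_device (arcsine in the sagitta is undefined)")
  if (!(alpha_min > 0 && alpha_min < alpha_max && alpha_max <= 180))
    stop("need 0 < alpha_min < alpha_max <= 180")
  n_steps <- (alpha_max - alpha_min) / grid_step
  if (abs(n_steps - round(n_steps)) > 1e-8)
    stop("grid_step must divide the feasible |alpha| range evenly")
  structure(list(D_width = D_width, R_device = R_device, D1 = D1,
                 U_prey = U_prey, U_pred = U_pred, D_attack = D_attack,
                 L_prey = L_prey, D_initial = D_initial,
                 alpha_min = alpha_min, alpha_max = alpha_max,
                 grid_step = grid_step,
                 attack_endpoint = isTRUE(attack_endpoint)),
            class = "model_params")
}

#' Default parameters for the juvenile red sea bream experiment
#'
#' Returns the measured/calibrated constants of the dummy-predator experiment
#' on juvenile *Pagrus major*: mouth half-width 18 mm, device radius 199 mm,
#' fast-start cutoff 15 mm, prey speed 1.04 mm/ms, calibrated attack endpoint
#' 34.73 mm and predator speed 1.54 mm/ms, observed turn-angle bounds 9-147
#' degrees. `L_prey` (30 mm) and `D_initial` (60 mm) follow the worked
#' example used to illustrate the corner mechanism.
#'
#' @param ... Overrides passed on to [model_params()].
#' @return A `model_params` object.
#' @export
pagrus_params <- function(...) {
  defaults <- list(D_width = 18, R_device = 199, D1 = 15, U_prey = 1.04,
                   U_pred = 1.54, D_attack = 34.73, L_prey = 30,
                   D_initial = 60, alpha_min = 9, alpha_max = 147,
                   grid_step = 1)
  do.call(model_params, utils::modifyList(defaults, list(...)))
}

#' @method print model_params
#' @export
print.model_params <- function(x, ...) {
  cat("Escape-geometry model parameters (mm, ms, mm/ms):\n")
  num <- vapply(x[names(x) != "attack_endpoint"], as.numeric, numeric(1))
  print(round(num, 4))
  if (!x$attack_endpoint)
    cat("attack endpoint disabled (infinite straight attack)\n")
  invisible(x)
}

#' Parameters for the adjustable-path (pursuit) predator
#'
#' Extends [model_params()] with a predator that can bend its approach path:
#' it travels straight until within `D_react` of the prey's initial position
#' and may then turn with a minimum turning radius `R_turn`. Its total path
#' length is budgeted at `D_initial + D_attack`.
#'
#' @inheritParams model_params
#' @param R_turn Minimum turning radius of the predator, mm.
#' @param D_react Reaction distance: distance from the prey's initial position
#'   at which the predator may start turning, mm. `0 <= D_react <= D_initial`.
#' @param ... Other arguments passed to [model_params()].
#' @return An object of class `c("pursuit_params", "model_params")`.
#' @export
pursuit_params <- function(R_turn = 12, D_react = 70, ...) {
  p <- model_params(...)
  stopifnot(R_turn > 0, D_react >= 0)
  if (D_react > p$D_initial) stop("D_react must not exceed D_initial")
  p$R_turn <- R_turn
  p$D_react <- D_react
  class(p) <- c("pursuit_params", "model_params")
  p
}
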