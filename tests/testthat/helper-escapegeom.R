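# Shared fixtures: built once per test run, in code (no stored data files).

pm <- pagrus_params()
tm_default <- default_turn_model()

# one synthetic cohort at the calibrated truth, reused across files
ev264 <- synth_events(seed = 2)

# spec of the generating truth used for recovery experiments: the
# changepoint-recovery world (flat 15 ms, slope 0.2 ms/deg, break at 44 deg)
recovery_turn <- turn_model(level = 15, slope = 0.2, changepoint = 44)

# random parameter draws for the geometry oracle; the stated world keeps the
# fast-start radius inside the device half-width and attack distance so the
# two-phase time decomposition applies at every crossing
draw_oracle_params <- function(n) {
  dw <- runif(n, 5, 40)
  rd <- pmax(dw, runif(n, 50, 300))
  da <- runif(n, 20, 120)
  data.frame(D_width = dw, R_device = rd, D_attack = da,
             D_initial = runif(n, 30, 150),
             D1 = runif(n, 3, pmin(dw, da) * 0.8),
             L_prey = runif(n, 0, 40),
             U_prey = runif(n, 0.5, 2), U_pred = runif(n, 0.3, 3),
             T1 = runif(n, 5, 40),
             beta = runif(n, 0, 180),
             alpha = sample(c(-1, 1), n, TRUE) * runif(n, 9, 147))
}

# modes of the mirror-symmetrised (folded) circular KDE, highest first
folded_modes <- function(ets, bw = 50) {
  m <- circ_modes(c(fold_et(ets), -fold_et(ets)), bw = bw)
  m$mode <- fold_et(m$mode)
  m[!duplicated(m$mode), , drop = FALSE]
}

# max T_diff' per folded degree: collapses mirror-duplicate grid entries
folded_profile <- function(profile) {
  e <- profile$entries[profile$entries$feasible, ]
  tapply(e$t_diff_rel, round(fold_et(e$et)), max)
}

n_local_maxima <- function(v) {
  n <- length(v)
  sum(vapply(2:(n - 1), function(i) v[i] > v[i - 1] && v[i] > v[i + 1],
             logical(1)))
}
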