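test_that("fold_et maps the full circle onto the symmetric semicircle", {
  expect_equal(fold_et(c(190, -80, 100)), c(170, 80, 100))
  set.seed(1)
  et <- runif(200, -400, 400)
  f <- fold_et(et)
  expect_true(all(f >= 0 & f <= 180))
  expect_equal(fold_et(f), f)                 # idempotent
  expect_equal(fold_et(-et), f)               # sign symmetry
  expect_equal(fold_et(360 - et), f)          # mirror about the axis
})

test_that("sagitta_d2 matches direct evaluation and its limits", {
  expect_equal(sagitta_d2(pm), 199 * (1 - cos(asin(18 / 199))))
  expect_equal(sagitta_d2(pm), 0.8157, tolerance = 1e-3)
  # small-sagitta approximation D_width^2 / (2 R)
  expect_equal(sagitta_d2(pm), 18^2 / (2 * 199), tolerance = 3e-3)
  expect_equal(sagitta_d2(model_params(D_width = 1e-9)), 0, tolerance = 1e-8)
  expect_equal(sagitta_d2(model_params(D_width = 50, R_device = 50)), 50)
  expect_error(model_params(D_width = 200, R_device = 199), "R_device")
})

test_that("theta_corner partitions lateral and arc crossings", {
  thc <- theta_corner(pm)
  expect_equal(thc, 152.04, tolerance = 1e-2)
  # the ray at theta_corner passes through the corner (D2 - D_attack, D_width)
  d2 <- sagitta_d2(pm)
  expect_equal(atan2(pm$D_width, d2 - pm$D_attack) * 180 / pi, thc)
  # corner directly abeam when D_attack equals the sagitta
  p_ab <- model_params(D_attack = sagitta_d2(pm))
  expect_equal(theta_corner(p_ab), 90)
  # large attack distances push the corner toward 180
  expect_gt(theta_corner(model_params(D_attack = 1e6, R_device = 1e6,
                                      D_width = 18)), 179.9)
})

test_that("crossing_point lies on the ray and on the boundary", {
  cr <- crossing_point(c(180, 90), pm)
  expect_equal(cr$x, c(-34.73, 0), tolerance = 1e-9)
  expect_equal(cr$y, c(0, 18), tolerance = 1e-9)

  # frozen from the marching oracle (1e-3 mm steps along the ray)
  oracle_170 <- march_crossing(170, pm$D_width, pm$R_device, pm$D_attack)
  expect_equal(crossing_point(170, pm)$dist, oracle_170, tolerance = 2e-3)
  expect_equal(crossing_point(170, pm)$dist, 35.17, tolerance = 1e-2)

  set.seed(42)
  for (i in 1:50) {
    p <- model_params(D_width = runif(1, 2, 40),
                      R_device = runif(1, 50, 300),
                      D_attack = runif(1, 5, 120))
    et <- runif(1, 1, 180)
    cr <- crossing_point(et, p)
    # on the escape ray
    expect_equal(atan2(cr$y, cr$x) * 180 / pi, et, tolerance = 1e-9)
    # on the defining boundary, to 1e-9 mm
    if (et < theta_corner(p)) {
      expect_equal(cr$y, p$D_width, tolerance = 1e-9)
    } else {
      expect_equal((cr$x + p$D_attack - p$R_device)^2 + cr$y^2,
                   p$R_device^2, tolerance = 1e-6)
    }
  }

  # ET exactly 0 is infeasible, not an error
  expect_equal(crossing_point(0, pm)$dist, Inf)
})

test_that("t_prey follows the two-phase decomposition", {
  # crossing at 170 deg has ||crossing|| = 35.17; T1 = 20 gives
  # 20 + (35.17 - 15 + 30) / 1.04
  tmc <- turn_model("constant", level = 20)
  d <- crossing_point(170, pm)$dist
  expect_equal(t_prey(95, 170, pm, tmc), 20 + (d - 15 + 30) / 1.04)
  # fast start exactly reaching the edge, no body length: T_prey = T1
  p0 <- model_params(D1 = 18, L_prey = 0)
  expect_equal(t_prey(50, 90, p0, tmc), 20)
  # doubling U_prey halves the post-turn term only
  p2 <- pm; p2$U_prey <- 2 * pm$U_prey
  expect_equal(t_prey(95, 170, p2, tmc) - 20,
               (t_prey(95, 170, pm, tmc) - 20) / 2)
})

test_that("t_pred uses the lateral and endpoint-arc branches", {
  p <- pagrus_params(D_initial = 60)
  expect_equal(t_pred(170, crossing_point(170, p)$x, p),
               (60 + 34.73) / 1.54, tolerance = 1e-9)
  expect_equal(t_pred(90, 0, p), (60 + sagitta_d2(p)) / 1.54)
  # constant above the corner
  ets <- seq(ceiling(theta_corner(p)), 180, 1)
  tp <- t_pred(ets, crossing_point(ets, p)$x, p)
  expect_true(all(abs(tp - tp[1]) < 1e-12))
})

test_that("t_diff_rel drops only alpha/beta-independent constants", {
  set.seed(7)
  a <- sample(c(-1, 1), 50, TRUE) * runif(50, 9, 147)
  b <- runif(50, 0, 180)
  base <- t_diff_rel(a, b, pm, tm_default)
  for (mod in list(c("D_initial", 200), c("L_prey", 5), c("D1", 10))) {
    p2 <- pm; p2[[mod[1]]] <- as.numeric(mod[2])
    shifted <- t_diff_rel(a, b, p2, tm_default)
    expect_equal(order(shifted), order(base))        # argmax invariant
  }
  # absolute margin differs from the relative one by the stated constant
  const <- pm$D_initial / pm$U_pred + pm$D1 / pm$U_prey - pm$L_prey / pm$U_prey
  expect_equal(t_diff_abs(a, b, pm, tm_default) - base, rep(const, 50))
  # alpha outside the feasible band is flagged
  expect_true(is.na(t_diff_rel(5, 90, pm, tm_default)))
})

test_that("t_diff_rel folding symmetry and speed monotonicity", {
  set.seed(8)
  a <- sample(c(-1, 1), 40, TRUE) * runif(40, 9, 147)
  b <- runif(40, 0, 180)
  # depends on alpha only through |alpha| and the folded ET
  direct <- t_diff_rel(a, b, pm, tm_default)
  via_fold <- escapegeom:::tdiff_rel_fold(fold_et(a + b), abs(a), pm,
                                          tm_default)
  expect_equal(direct, via_fold)

  # speed monotonicity holds for the absolute margin wherever the predator
  # still has ground to cover (non-negative travel to the crossing)
  abs_base <- t_diff_abs(a, b, pm, tm_default)
  cr <- crossing_point(fold_et(a + b), pm)
  ok <- is.finite(cr$dist) & cr$x <= pm$D_initial
  slow_pred <- pm; slow_pred$U_pred <- pm$U_pred * 0.7
  fast_prey <- pm; fast_prey$U_prey <- pm$U_prey * 1.3
  expect_true(all(t_diff_abs(a, b, slow_pred, tm_default)[ok] >=
                    abs_base[ok] - 1e-12))
  expect_true(all(t_diff_abs(a, b, fast_prey, tm_default)[ok] >=
                    abs_base[ok] - 1e-12))
})

test_that("profile reproduces the published peak structure", {
  # mid initial orientations: optimal 100-140, suboptimal near 170
  pr75 <- et_profile(75, pm, tm_default)
  expect_true(pr75$optimal_et >= 100 && pr75$optimal_et <= 140)
  expect_lt(abs(pr75$suboptimal_et - 170), 15)

  # head-on: optimal near 100 away, suboptimal its toward mirror near -100
  pr15 <- et_profile(15, pm, tm_default)
  expect_lt(abs(pr15$optimal_et - 100), 20)
  expect_lt(abs(pr15$suboptimal_et + 100), 20)
  expect_true(pr15$optimal_et > 0 && pr15$suboptimal_et < 0)

  # attacked from behind: peaks near 170-180 and near 140
  pr165 <- et_profile(165, pm, tm_default)
  expect_true(fold_et(pr165$optimal_et) >= 165)
  expect_lt(abs(fold_et(pr165$suboptimal_et) - 140), 15)

  # entries satisfy et = alpha + beta and the |alpha| bounds exactly
  e <- pr75$entries
  expect_equal(e$et, e$alpha + 75)
  expect_true(all(abs(e$alpha) >= 9 & abs(e$alpha) <= 147))
  # optimal attains the feasible maximum; advantage is the peak gap
  expect_equal(max(e$t_diff_rel[e$feasible]),
               e$t_diff_rel[e$et == pr75$optimal_et])
  expect_gte(pr75$advantage, 0)
})

test_that("a corner-adjacent local minimum separates straddling peaks", {
  thc <- theta_corner(pm)
  for (b in seq(60, 130, 10)) {
    pr <- et_profile(b, pm, tm_default)
    fp <- folded_profile(pr)
    f <- as.numeric(names(fp))
    lo <- which(f >= 130 & f < floor(thc))
    hi <- which(f > ceiling(thc) & f <= 180)
    if (!length(lo) || !length(hi)) next
    if (max(fp[lo]) > fp[which.min(abs(f - thc))] &&
        max(fp[hi]) > fp[which.min(abs(f - thc))]) {
      sel <- which(f >= 140 & f <= 180)
      i_min <- sel[which.min(fp[sel])]
      expect_lte(abs(f[i_min] - thc), 1 + pm$grid_step)
    }
  }
})

test_that("profile plateaus collapse to a single central local maximum", {
  v <- c(-5, -1, -1, -1, -4, -2, -6)
  expect_equal(escapegeom:::local_max_idx(v), c(3, 6))
  expect_equal(escapegeom:::local_max_idx(c(1, 1, 1)), 2)
})

test_that("analytic times agree in sign with the stepping oracle", {
  set.seed(11)
  d <- draw_oracle_params(100)
  ana <- dist <- numeric(100)
  for (i in 1:100) {
    p <- model_params(D_width = d$D_width[i], R_device = d$R_device[i],
                      D1 = d$D1[i], U_prey = d$U_prey[i],
                      U_pred = d$U_pred[i], D_attack = d$D_attack[i],
                      L_prey = d$L_prey[i], D_initial = d$D_initial[i])
    tmc <- turn_model("constant", level = d$T1[i])
    ana[i] <- t_diff_abs(d$alpha[i], d$beta[i], p, tmc)
    dist[i] <- crossing_point(fold_et(d$alpha[i] + d$beta[i]), p)$dist
  }
  orc <- stepping_tdiff(fold_et(d$alpha + d$beta), d$T1, d$D_width,
                        d$R_device, d$D_attack, d$D_initial, d$D1,
                        d$L_prey, d$U_prey, d$U_pred)
  use <- is.finite(dist) & dist < 1500 & abs(ana) > 0.01
  expect_gt(sum(use), 80)
  expect_equal(sign(ana[use]), sign(orc[use]))
})
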