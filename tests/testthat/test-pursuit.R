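pp_frog <- pursuit_params(R_turn = 12, D_react = 70, D_attack = 400,
                          D_initial = 130)

test_that("pursuit arrival times have the stated anchors", {
  # on-axis target ahead of the predator: straight-line time
  expect_equal(pursuit_t_pred(40, 0, pp_frog), (130 - 40) / 1.54,
               tolerance = 1e-9)
  # deep inside a minimum-radius turning disc: unreachable (safe)
  expect_equal(pursuit_t_pred(70, 12, pp_frog), Inf)
  expect_equal(pursuit_t_pred(70, -12, pp_frog), Inf)
  # far behind the prey, beyond the path budget: safe (the safety zone
  # opposite the predator's incoming direction)
  expect_equal(pursuit_t_pred(-(400 + 70 + 10), 0, pp_frog), Inf)
  # but moderately behind is reachable
  expect_true(is.finite(pursuit_t_pred(-50, 0, pp_frog)))
})

test_that("CS path lengths match a dense tangency-search oracle", {
  # oracle: discretise the arc angle, keep headings consistent with the
  # straight leg, take the shortest admissible arc+line path
  cs_oracle <- function(x, y, p) {
    best <- Inf
    for (side in c(1, -1)) {
      cy <- side * p$R_turn
      phiP <- -side * pi / 2
      for (phi in seq(0, pi, length.out = 20001)) {
        ang <- phiP - side * phi          # cw for upper circle
        qx <- p$D_react + p$R_turn * cos(ang)
        qy <- cy + p$R_turn * sin(ang)
        hx <- side * sin(ang); hy <- -side * cos(ang)
        vx <- x - qx; vy <- y - qy
        L <- sqrt(vx^2 + vy^2)
        if (L < 1e-9) { best <- min(best, phi * p$R_turn); next }
        if (abs(vx / L - hx) < 2e-4 && abs(vy / L - hy) < 2e-4)
          best <- min(best, phi * p$R_turn + L)
      }
    }
    best
  }
  set.seed(11)
  pts <- data.frame(x = runif(6, -150, 150), y = runif(6, -120, 120))
  len <- escapegeom:::dubins_cs_len(pts$x, pts$y, pp_frog)
  for (i in seq_len(nrow(pts))) {
    o <- cs_oracle(pts$x[i], pts$y[i], pp_frog)
    if (is.finite(len[i])) {
      expect_equal(len[i], o, tolerance = 1e-2)
      # never shorter than the straight-line distance from the turn point
      expect_gte(len[i], sqrt((pts$x[i] - 70)^2 + pts$y[i]^2) - 1e-9)
    } else {
      expect_gt(o, 1e6)
    }
  }
})

test_that("infinite turning radius reproduces the straight-attack model", {
  pinf <- pursuit_params(R_turn = Inf, D_react = 0, D_attack = 34.73,
                         D_initial = 60)
  base_p <- pagrus_params(D_initial = 60)
  for (b in c(15, 75, 140)) {
    base <- et_profile(b, base_p, tm_default)
    purs <- pursuit_profile(b, pinf, tm_default)
    f <- base$entries$feasible
    expect_equal(purs$entries$feasible, base$entries$feasible)
    expect_lt(max(abs(purs$entries$t_diff_rel[f] -
                        base$entries$t_diff_rel[f])), 1e-6)
  }
})

test_that("shrinking the turning radius never helps the prey", {
  mk <- function(r) pursuit_params(R_turn = r, D_react = 70, D_attack = 400,
                                   D_initial = 130)
  pr6 <- pursuit_profile(90, mk(6), tm_default)
  pr12 <- pursuit_profile(90, mk(12), tm_default)
  pr24 <- pursuit_profile(90, mk(24), tm_default)
  f <- is.finite(pr6$entries$t_diff_rel) &
    is.finite(pr12$entries$t_diff_rel) & is.finite(pr24$entries$t_diff_rel)
  expect_true(all(pr12$entries$t_diff_rel[f] >=
                    pr6$entries$t_diff_rel[f] - 1e-9))
  expect_true(all(pr24$entries$t_diff_rel[f] >=
                    pr12$entries$t_diff_rel[f] - 1e-9))
})

test_that("the pursuit safe pockets shape the profile", {
  # rays through the turning-disc window (folded ET below ~19 deg) exit the
  # danger zone close to the predator and score far better than mid-angle
  # rays that must outrun the whole reachable set
  pr <- pursuit_profile(90, pp_frog, tm_default)
  e <- pr$entries[pr$entries$feasible, ]
  fold <- fold_et(e$et)
  disc <- fold > 2 & fold < 18
  mid <- fold > 45 & fold < 100
  expect_gt(min(e$t_diff_rel[disc]), max(e$t_diff_rel[mid]))
  # a large-angle local peak exists as well (second escape route)
  expect_gt(max(e$t_diff_rel[fold > 150]), max(e$t_diff_rel[mid]))
})
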