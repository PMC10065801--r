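# synthetic turn-time data with known structure
gen_turn_data <- function(n = 263, cp = 44, level = 15, slope = 0.2,
                          noise = 2, fish_sd = 2, n_fish = 23, seed = 1,
                          shape = "flat-then-rise") {
  set.seed(seed)
  a <- runif(n, 9, 147)
  fish <- sample(sprintf("f%02d", 1:n_fish), n, TRUE)
  offs <- rnorm(n_fish, 0, fish_sd)
  names(offs) <- sprintf("f%02d", 1:n_fish)
  truth <- turn_model(level = level, slope = slope, changepoint = cp,
                      shape = shape)
  y <- predict_t1(truth, a) + offs[fish] + rnorm(n, 0, noise)
  list(a = a, y = unname(y), fish = fish, truth = truth)
}

test_that("noise-free piecewise input is recovered exactly", {
  a <- rep(seq(10, 140, 5), 3)
  truth <- turn_model(level = 12, slope = 0.15, changepoint = 50)
  fit <- fit_changepoint(a, predict_t1(truth, a))
  expect_equal(fit$changepoint, 50)
  expect_equal(fit$level, 12, tolerance = 1e-8)
  expect_equal(fit$slope, 0.15, tolerance = 1e-8)
})

test_that("changepoint is recovered within 5 degrees under realistic noise", {
  d <- gen_turn_data(seed = 3)
  fit <- fit_changepoint(d$a, d$y, d$fish)
  expect_lt(abs(fit$changepoint - 44), 5)
  expect_equal(fit$level, 15, tolerance = 0.15 * 15)
  expect_equal(fit$slope, 0.2, tolerance = 0.3 * 0.2)
  # rise-then-flat shape (the velocity curve) recovers too
  dv <- gen_turn_data(cp = 46, level = 1.01, slope = 0.01, noise = 0.05,
                      fish_sd = 0, seed = 4, shape = "rise-then-flat")
  fitv <- fit_changepoint(dv$a, dv$y, dv$fish, shape = "rise-then-flat")
  expect_lt(abs(fitv$changepoint - 46), 5)
})

test_that("predictions follow the fitted curve", {
  m <- turn_model(level = 11.5, slope = 0.08, changepoint = 44)
  expect_equal(predict_t1(m, c(10, 30, 44)), rep(11.5, 3))
  expect_equal(predict_t1(m, 54), 11.5 + 10 * 0.08)
  aa <- seq(0, 180, 2)
  expect_true(all(diff(predict_t1(m, aa)) >= 0))   # monotone non-decreasing
  expect_true(all(predict_t1(m, aa) >= 0))
  # individual offsets enter only when asked for
  m$individual_offsets <- c(f1 = 2, f2 = -1)
  expect_equal(predict_t1(m, 20), 11.5)
  expect_equal(unname(predict_t1(m, 20, fish_id = "f1")), 13.5)
  # removing offsets changes predictions by at most the largest |offset|
  expect_lte(abs(predict_t1(m, 20, fish_id = "f2") - predict_t1(m, 20)),
             max(abs(m$individual_offsets)))
})

test_that("model comparison picks the generating shape", {
  d <- gen_turn_data(seed = 5)
  tab <- compare_turn_models(d$a, d$y, d$fish)
  expect_equal(tab$model[tab$best], "piecewise")
  expect_true(all(tab$delta_aic[tab$model != "piecewise"] > 0))

  set.seed(6)
  a <- runif(263, 9, 147)
  y_lin <- 10 + 0.1 * a + rnorm(263, 0, 2)
  tab_lin <- compare_turn_models(a, y_lin)
  expect_lte(tab_lin$delta_aic[tab_lin$model == "linear"], 2)

  y_const <- rnorm(263, 15, 2)
  tab_c <- compare_turn_models(a, y_const)
  expect_equal(tab_c$model[tab_c$best], "constant")
})

test_that("matched T1 and v0 changepoints differ around zero", {
  diffs <- vapply(1:6, function(sd) {
    d1 <- gen_turn_data(cp = 45, seed = 20 + sd)
    d2 <- gen_turn_data(cp = 45, level = 0.55, slope = 0.01, noise = 0.05,
                        fish_sd = 0, seed = 40 + sd, shape = "rise-then-flat")
    fit_changepoint(d1$a, d1$y, d1$fish)$changepoint -
      fit_changepoint(d2$a, d2$y, d2$fish, shape = "rise-then-flat")$changepoint
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 6)
})

test_that("degenerate inputs fail loudly and bootstrap summarises spread", {
  expect_error(fit_changepoint(rep(45, 20), rnorm(20)), "degenerate")
  d <- gen_turn_data(n = 120, seed = 9)
  fit <- fit_changepoint(d$a, d$y, d$fish, n_boot = 20)
  expect_true(is.finite(fit$cp_se) && fit$cp_se >= 0)
})
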