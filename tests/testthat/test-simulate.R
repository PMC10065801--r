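test_that("sample_et follows the truncated-normal ranking rule", {
  pr <- et_profile(75, pm, tm_default)
  # vanishing choice scale: always the optimal ET
  set.seed(1)
  d0 <- sample_et(pr, choice_dist(1e-9), 50)
  expect_true(all(d0$et == pr$optimal_et))
  # empirical standardised ranks of many draws match the truncated normal
  ord <- escapegeom:::rank_order_profile(pr)
  N <- nrow(ord)
  key <- paste(ord$et, ord$alpha)
  set.seed(2)
  d <- sample_et(pr, choice_dist(0.33), 2e4)
  ranks <- (match(paste(d$et, d$alpha), key) - 1) / (N - 1)
  ks <- suppressWarnings(stats::ks.test(ranks,
                                        function(q) ptrunc_choice(q, choice_dist(0.33))))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("simulate_experiment is seeded, sized and reproducible", {
  betas <- c(20, 20, 75, 140)
  s1 <- simulate_experiment(betas, pm, tm_default, choice_dist(0.33),
                            n_reps = 3, seed = 7)
  s2 <- simulate_experiment(betas, pm, tm_default, choice_dist(0.33),
                            n_reps = 3, seed = 7)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), length(betas) * 3)
  expect_equal(as.integer(table(s1$sim_id)), rep(length(betas), 3))
  s3 <- simulate_experiment(betas, pm, tm_default, choice_dist(0.33),
                            n_reps = 1, seed = 7)
  expect_equal(nrow(s3), length(betas))
})

test_that("pooled theoretical ETs show the observed peak structure", {
  sims <- simulate_experiment(ev264$beta, pm, tm_default, choice_dist(0.33),
                              n_reps = 100, seed = 3)
  expect_equal(nrow(sims), nrow(ev264) * 100)
  m <- circ_modes(sims$et, bw = 50)
  top2 <- sort(m$mode[1:2])
  expect_true(top2[1] >= 105 && top2[1] <= 140)   # large peak ~110-130
  expect_true(top2[2] >= 160 && top2[2] <= 185)   # large peak ~170-180
})

test_that("kuiper statistic matches a direct ECDF computation", {
  # independent oracle: V over all rotations of the pooled support
  kuiper_oracle <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    x <- sort(unique(c(a, b) %% 360))
    F1 <- vapply(x, function(t) mean((a %% 360) <= t), numeric(1))
    F2 <- vapply(x, function(t) mean((b %% 360) <= t), numeric(1))
    max(c(F1 - F2, 0)) + max(c(F2 - F1, 0))
  }
  set.seed(4)
  for (i in 1:10) {
    a <- runif(30, 0, 360); b <- runif(25, 0, 360)
    expect_equal(kuiper_two_sample(a, b, "asymptotic")$V, kuiper_oracle(a, b))
  }
  expect_equal(kuiper_two_sample(a, a, "asymptotic")$V, 0)
  # rotation invariance of the circular statistic
  expect_equal(kuiper_two_sample((a + 37) %% 360, (b + 37) %% 360,
                                 "asymptotic")$V,
               kuiper_two_sample(a, b, "asymptotic")$V)
})

test_that("kuiper p-values behave at both sample-size regimes", {
  set.seed(5)
  kt <- suppressWarnings(kuiper_two_sample(runif(4, 0, 360),
                                           runif(4, 0, 360)))
  expect_equal(kt$method, "permutation")
  expect_true(kt$p > 0 && kt$p <= 1)
  # clearly different distributions are detected
  a <- rnorm(264, 90, 10) %% 360
  b <- rnorm(264, 270, 10) %% 360
  expect_lt(kuiper_two_sample(a, b)$p, 1e-6)
})

test_that("same-distribution rejection rate is near the nominal level", {
  # scaled-down version of the full acceptance check (300 pairs here)
  sims <- simulate_experiment(ev264$beta, pm, tm_default, choice_dist(0.33),
                              n_reps = 20, seed = 6)
  pool <- sims$et
  set.seed(7)
  rej <- mean(vapply(1:300, function(i)
    kuiper_two_sample(sample(pool, 264, TRUE), sample(pool, 264, TRUE),
                      "asymptotic")$p < 0.05, logical(1)))
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.09)
})

test_that("gmm_modes recovers well-separated components", {
  set.seed(8)
  x <- c(rnorm(60, -80, 8), rnorm(120, 125, 8), rnorm(84, 175, 8))
  # BIC selection: the AIC is prone to overcounting mixture components
  g <- gmm_modes(x, k_max = 6, ic = "bic")
  expect_equal(g$best_k, 3)
  expect_lt(max(abs(sort(g$means) - c(-80, 125, 175))), 10)
  expect_true(all(g$aic_table$converged))
  # the AIC column is reported alongside and never prefers fewer components
  aic_k <- which.min(g$aic_table$aic)
  expect_gte(aic_k, g$best_k)
  # the three generating means survive under the AIC pick as well
  g_aic <- gmm_modes(x, k_max = 6, ic = "aic")
  for (mu in c(-80, 125, 175))
    expect_lt(min(abs(g_aic$means - mu)), 10)
  g1 <- gmm_modes(rnorm(264, 120, 20), k_max = 5, ic = "bic")
  expect_equal(g1$best_k, 1)
})

test_that("variant comparison favours the generating full model", {
  tab <- variant_comparison(ev264, pm, tm_default, n_sims = 100, seed = 42)
  expect_setequal(tab$variant, c("full", "attack_only", "turn_only", "null"))
  full <- tab[tab$variant == "full", ]
  expect_true(all(full$rate_p_gt_05 >= tab$rate_p_gt_05))
  expect_true(all(full$median_V <= tab$median_V))
  expect_true(is.na(tab$D_attack[tab$variant %in% c("turn_only", "null")][1]))
  # the null construction has a unimodal folded profile at P. major values
  vs <- escapegeom:::variant_setup("null", pm, tm_default)
  for (b in c(30, 90, 150))
    expect_equal(n_local_maxima(folded_profile(et_profile(b, vs$params,
                                                          vs$turn))), 1)
})
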