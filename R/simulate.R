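## Monte Carlo generation of theoretical escape-trajectory distributions
## under the truncated-normal ranking-choice rule, and the circular
## statistics used to compare them with observed distributions.

## rank-ordered feasible grid for one profile: ETs (full circle), branch and
## signed alpha sorted by decreasing T_diff'
rank_order_profile <- function(profile) {
  e <- profile$entries[profile$entries$feasible, ]
  e[order(-e$t_diff_rel, abs(e$alpha)), c("et", "alpha", "branch")]
}

#' Draw escape trajectories from a profile under the stochastic choice rule
#'
#' Draws `n` ranking indices from the truncated normal and returns, for each,
#' the feasible grid ET whose standardised rank is nearest the draw (rank 0 =
#' optimal, 1 = worst).
#'
#' @param profile A [et_profile()] result.
#' @param choice A [choice_dist()].
#' @param n Number of draws.
#' @return A data frame with `et`, `alpha`, `branch` for each draw.
#' @export
sample_et <- function(profile, choice, n = 1) {
  ord <- rank_order_profile(profile)
  N <- nrow(ord)
  stopifnot(N > 0)
  r <- rtrunc_choice(n, choice)
  idx <- pmin(pmax(round(r * (N - 1)) + 1, 1), N)
  out <- ord[idx, ]
  rownames(out) <- NULL
  out
}

#' Monte Carlo simulation of theoretical escape-trajectory distributions
#'
#' For each initial orientation in `betas`, the `T_diff'` profile is computed
#' once and `n_reps` escape trajectories are drawn under the stochastic
#' ranking rule, giving `n_reps` independent samples each of size
#' `length(betas)` (replicate `i` uses the `i`-th draw of every orientation).
#'
#' @param betas Initial orientations, degrees (typically the observed ones,
#'   or `0:180` for parameter sweeps).
#' @param params A [model_params()] object.
#' @param turn A [turn_model()].
#' @param choice A [choice_dist()].
#' @param n_reps Number of simulation replicates.
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame in long format: `sim_id`, `beta`, `et`, `alpha`,
#'   `branch`.
#' @export
simulate_experiment <- function(betas, params, turn, choice, n_reps = 1000,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ub <- unique(betas)
  draws <- vector("list", length(ub))
  names(draws) <- as.character(ub)
  counts <- table(factor(as.character(betas), levels = as.character(ub)))
  for (i in seq_along(ub)) {
    pr <- et_profile(ub[i], params, turn)
    k <- counts[[i]]
    d <- sample_et(pr, choice, n = n_reps * k)
    d$beta <- ub[i]
    d$pos <- rep(seq_len(k), n_reps)
    d$sim_id <- rep(seq_len(n_reps), each = k)
    draws[[i]] <- d
  }
  out <- do.call(rbind, draws)
  out <- out[order(out$sim_id, out$beta), c("sim_id", "beta", "et", "alpha",
                                            "branch")]
  rownames(out) <- NULL
  out
}

## ---- two-sample Kuiper test on circular data ---------------------------

## V statistic: max(F1 - F2) + max(F2 - F1) over the pooled support, with
## tied values processed as one block; rotation-invariant by construction.
kuiper_V <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  x <- c(a %% 360, b %% 360)
  w <- c(rep(1 / n1, n1), rep(-1 / n2, n2))
  o <- order(x)
  x <- x[o]; w <- w[o]
  grp <- cumsum(c(TRUE, diff(x) > 0))          # tie blocks
  d <- cumsum(vapply(split(w, grp), sum, numeric(1)))
  max(d, 0) - min(d, 0)
}

kuiper_p_asym <- function(V, n_eff) {
  lambda <- (sqrt(n_eff) + 0.155 + 0.24 / sqrt(n_eff)) * V
  if (lambda < 0.4) return(1)
  j <- 1:120
  p <- 2 * sum((4 * j^2 * lambda^2 - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kuiper test for circular data
#'
#' Computes the rotation-invariant Kuiper statistic `V = D+ + D-` of the two
#' circular empirical distribution functions (angles mod 360) and its
#' p-value from the standard asymptotic series with effective sample size
#' `n1 * n2 / (n1 + n2)`. For small samples (`n_eff < 20`, or on request) a
#' permutation p-value is used instead.
#'
#' @param a,b Samples of angles in degrees.
#' @param p_method `"asymptotic"`, `"permutation"`, or `"auto"` (permutation
#'   when `n_eff < 20`).
#' @param n_perm Number of permutations for the permutation p-value.
#' @return An object of class `kuiper_test`: list with `V`, `p`, `n1`, `n2`,
#'   `method`.
#' @export
kuiper_two_sample <- function(a, b, p_method = c("auto", "asymptotic",
                                                 "permutation"),
                              n_perm = 999) {
  p_method <- match.arg(p_method)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  stopifnot(length(a) > 0, length(b) > 0)
  n1 <- length(a); n2 <- length(b)
  n_eff <- n1 * n2 / (n1 + n2)
  if (min(n1, n2) < 5)
    warning("sample size < 5; using permutation p-value only")
  use_perm <- p_method == "permutation" ||
    (p_method == "auto" && (n_eff < 20 || min(n1, n2) < 5))
  V <- kuiper_V(a, b)
  if (use_perm) {
    pool <- c(a, b)
    Vp <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n1 + n2, n1)
      kuiper_V(pool[idx], pool[-idx])
    }, numeric(1))
    p <- (1 + sum(Vp >= V - 1e-12)) / (n_perm + 1)
    method <- "permutation"
  } else {
    p <- kuiper_p_asym(V, n_eff)
    method <- "asymptotic"
  }
  structure(list(V = V, p = p, n1 = n1, n2 = n2, method = method),
            class = "kuiper_test")
}

#' @method print kuiper_test
#' @export
print.kuiper_test <- function(x, ...) {
  cat(sprintf("Two-sample Kuiper test (%s): V = %.4f, p = %.4f (n1 = %d, n2 = %d)\n",
              x$method, x$V, x$p, x$n1, x$n2))
  invisible(x)
}

## ---- circular kernel density and modes ---------------------------------

#' Circular kernel density estimate
#'
#' Von Mises kernel density on the circle; the bandwidth is the kernel
#' concentration parameter (larger = narrower kernels), matching the
#' convention of circular-statistics packages where escape-trajectory
#' histograms are smoothed with a bandwidth of 50.
#'
#' @param theta Angles in degrees.
#' @param bw Von Mises concentration of the kernel.
#' @param n Number of grid points over `[0, 360)`.
#' @return A list with `grid` (degrees) and `density` (per degree).
#' @export
circ_kde <- function(theta, bw = 50, n = 360) {
  th <- deg2rad(theta %% 360)
  grid <- seq(0, 360 - 360 / n, length.out = n)
  gr <- deg2rad(grid)
  # exponentially-scaled kernel avoids overflow at large concentrations;
  # constants drop out in the numerical normalisation below
  dens <- vapply(gr, function(g) mean(exp(bw * (cos(g - th) - 1))), numeric(1))
  dens <- dens / (sum(dens) * 360 / n)   # integrates to 1 over degrees
  list(grid = grid, density = dens)
}

#' Modes of a circular sample
#'
#' Local maxima of the circular kernel density estimate, sorted by density.
#'
#' @inheritParams circ_kde
#' @param min_prop Discard modes whose density is below this fraction of the
#'   highest mode.
#' @return A data frame with `mode` (degrees) and `density`, highest first.
#' @export
circ_modes <- function(theta, bw = 50, n = 360, min_prop = 0.05) {
  k <- circ_kde(theta, bw, n)
  d <- k$density
  nn <- length(d)
  left <- d[c(nn, 1:(nn - 1))]
  right <- d[c(2:nn, 1)]
  is_max <- d > left & d >= right
  out <- data.frame(mode = k$grid[is_max], density = d[is_max])
  out <- out[out$density >= min_prop * max(out$density), ]
  out[order(-out$density), , drop = FALSE]
}

## ---- Gaussian mixture mode counting ------------------------------------

## one EM run for a k-component univariate Gaussian mixture
gmm_em <- function(x, k, init_means, equal_var = TRUE, tol = 1e-6,
                   max_iter = 500) {
  n <- length(x)
  mu <- init_means
  s2 <- rep(stats::var(x) / k, k)
  w <- rep(1 / k, k)
  # variance floor at 1% of the data range: forbids spike components
  floor_s2 <- (diff(range(x)) * 0.01)^2 + 1e-12
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:k, function(j) w[j] * stats::dnorm(x, mu[j], sqrt(s2[j])),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    if (any(rowsum_d <= 0) || any(!is.finite(rowsum_d))) return(NULL)
    ll <- sum(log(rowsum_d))
    R <- dens / rowsum_d
    nk <- colSums(R)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(R * x) / nk
    s2 <- colSums(R * (outer(x, mu, "-")^2)) / nk
    if (equal_var) s2 <- rep(sum(nk * s2) / n, k)
    s2 <- pmax(s2, floor_s2)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(loglik = ll, means = mu, sd = sqrt(s2), weights = w, k = k,
       equal_var = equal_var)
}

#' Count escape-trajectory modes with Gaussian mixtures
#'
#' Fits univariate Gaussian mixtures with 1 to `k_max` components to the
#' escape trajectories on the linear (unwrapped) angle scale and selects the
#' most parsimonious model by AIC. By default the components share one
#' width (`equal_var = TRUE`): equal-width Gaussian curves are the robust
#' choice for counting modes, since the AIC badly overfits the component
#' count when every component has its own variance. Each `k` is fitted from
#' quantile, k-means and random starts; non-converging fits are recorded
#' and excluded from selection.
#'
#' @param ets Escape trajectories, degrees on the unwrapped scale (the
#'   model's reachable range is about -147 to 327).
#' @param k_max Maximum number of components.
#' @param n_start Random restarts per `k`.
#' @param equal_var Share a single component variance (default) or give
#'   every component its own.
#' @param ic Information criterion used to select `best_k`: `"aic"`
#'   (default, as in the original mode-counting analysis) or `"bic"`, which
#'   is markedly more robust against the well-known tendency of the AIC to
#'   overcount mixture components.
#' @return A list with `best_k`, `means` (sorted, of the best model),
#'   `aic_table` (data frame `k`, `aic`, `bic`, `converged`) and
#'   `best_fit`.
#' @export
gmm_modes <- function(ets, k_max = 9, n_start = 5, equal_var = TRUE,
                      ic = c("aic", "bic")) {
  ic <- match.arg(ic)
  x <- ets[is.finite(ets)]
  stopifnot(length(x) > k_max * 3)
  tab <- data.frame(k = 1:k_max, aic = NA_real_, bic = NA_real_,
                    converged = FALSE)
  fits <- vector("list", k_max)
  for (k in 1:k_max) {
    best <- NULL
    km <- if (k > 1)
      tryCatch(sort(stats::kmeans(x, k, nstart = 5)$centers[, 1]),
               error = function(e) NULL)
    else NULL
    starts <- c(list(stats::quantile(x, probs = (1:k) / (k + 1), names = FALSE)),
                if (!is.null(km)) list(km),
                lapply(seq_len(n_start - 1), function(i) sort(sample(x, k))))
    for (m0 in starts) {
      f <- tryCatch(gmm_em(x, k, m0, equal_var = equal_var),
                    error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$loglik > best$loglik)) best <- f
    }
    if (!is.null(best)) {
      n_par <- if (equal_var) 2 * k else 3 * k - 1
      tab$aic[k] <- 2 * n_par - 2 * best$loglik
      tab$bic[k] <- log(length(x)) * n_par - 2 * best$loglik
      tab$converged[k] <- TRUE
      fits[[k]] <- best
    }
  }
  ok <- which(tab$converged)
  best_k <- ok[which.min(tab[[ic]][ok])]
  list(best_k = best_k, means = sort(fits[[best_k]]$means), aic_table = tab,
       best_fit = fits[[best_k]])
}

## ---- four-variant model comparison -------------------------------------

variant_setup <- function(variant, params, turn) {
  p <- params
  tm <- turn
  if (variant %in% c("attack_only", "null"))
    tm <- turn_model("constant", level = turn_curve(turn, 0),
                     shape = turn$shape)
  if (variant %in% c("turn_only", "null"))
    p$attack_endpoint <- FALSE
  list(params = p, turn = tm)
}

#' Compare the full model against its reduced variants
#'
#' Builds the four model variants — `full` (attack endpoint and
#' alpha-dependent turn time), `attack_only` (turn time constant),
#' `turn_only` (no attack endpoint: infinite straight attack) and `null`
#' (neither) — calibrates each independently on the observed events
#' (re-optimising `U_pred`, and `D_attack` where the variant has one), refits
#' the choice scale, and compares `n_sims` Monte Carlo ET samples per variant
#' against the observed ETs with the two-sample Kuiper test.
#'
#' @param events Observed events (columns `beta`, `et`).
#' @param params Template [model_params()].
#' @param turn Fitted [turn_model()].
#' @param variants Subset of the four variant names.
#' @param n_sims Number of Monte Carlo samples per variant.
#' @param seed Integer seed.
#' @param ... Passed to [optimize_params()] (e.g. search bounds, `grid_n`).
#' @return A data frame with one row per variant: calibrated `D_attack`,
#'   `U_pred`, `sd_choice`, `mean_ranking`, `median_V`, `median_p`,
#'   `rate_p_gt_05`. Attribute `"calibrations"` keeps the per-variant fits.
#' @export
variant_comparison <- function(events, params, turn,
                               variants = c("full", "attack_only",
                                            "turn_only", "null"),
                               n_sims = 1000, seed = 1, ...) {
  events <- as.data.frame(events)
  variants <- match.arg(variants, several.ok = TRUE)
  rows <- list(); calib <- list()
  for (v in variants) {
    vs <- variant_setup(v, params, turn)
    opt <- optimize_params(events, vs$params, vs$turn, ...)
    ri <- ranking_index(events, opt$params, vs$turn)
    ch <- fit_choice_sd(ri)
    sims <- simulate_experiment(events$beta, opt$params, vs$turn, ch,
                                n_reps = n_sims,
                                seed = seed + match(v, variants))
    ks <- vapply(split(sims$et, sims$sim_id), function(s) {
      kt <- kuiper_two_sample(s, events$et, p_method = "asymptotic")
      c(kt$V, kt$p)
    }, numeric(2))
    rows[[v]] <- data.frame(variant = v, D_attack = opt$D_attack,
                            U_pred = opt$U_pred, sd_choice = ch$sd_choice,
                            mean_ranking = opt$mean_ranking,
                            median_V = stats::median(ks[1, ]),
                            median_p = stats::median(ks[2, ]),
                            rate_p_gt_05 = mean(ks[2, ] > 0.05),
                            stringsAsFactors = FALSE)
    calib[[v]] <- list(opt = opt, choice = ch, turn = vs$turn)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "calibrations") <- calib
  out
}
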