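## CSV readers/writers, flat-file configuration and the command-line
## pipeline tying the stages together.
##
## Canonical event CSV schema: fish_id, trial_id, beta_deg, alpha_deg,
## et_deg, direction, predator_speed_mps, t1_ms, v0_mps (+ optional side).
## Internally the angle columns are called beta, alpha, et and speeds/times
## keep mm/ms and ms units (numerically identical to m/s).

canonical_map <- c(fish_id = "fish_id", trial_id = "trial_id",
                   beta = "beta_deg", alpha = "alpha_deg", et = "et_deg",
                   direction = "direction",
                   predator_speed = "predator_speed_mps",
                   t1_obs = "t1_ms", v0_obs = "v0_mps", side = "side")

#' Read an escape-event table
#'
#' Reads a per-event CSV, maps its columns onto the canonical schema,
#' validates the angle invariants (`et = alpha + beta` within `tol`; `beta`
#' in `[0, 180]`; directionality consistent with the sign of `alpha`) and
#' pools left-side attacks onto the right side (negating `alpha` and
#' recomputing `et`) when a `side` column is present. Rows failing
#' validation are dropped with a diagnostic naming their line numbers.
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping internal names
#'   (`fish_id`, `beta`, `alpha`, `et`, `direction`, ...) to the file's
#'   column names. Defaults to the canonical schema.
#' @param tol Tolerance for the `et = alpha + beta` check, degrees.
#' @return A validated event data frame with internal column names.
#' @export
read_events <- function(path, column_map = canonical_map, tol = 0.5) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  map <- canonical_map
  map[names(column_map)] <- column_map
  required <- c("fish_id", "beta", "alpha", "et", "direction")
  missing <- required[!(map[required] %in% names(raw))]
  if (length(missing))
    stop("missing required columns: ",
         paste(map[missing], collapse = ", "))
  pick <- function(key) if (map[[key]] %in% names(raw)) raw[[map[[key]]]] else NULL
  ev <- data.frame(fish_id = as.character(pick("fish_id")),
                   beta = as.numeric(pick("beta")),
                   alpha = as.numeric(pick("alpha")),
                   et = as.numeric(pick("et")),
                   direction = as.character(pick("direction")),
                   stringsAsFactors = FALSE)
  for (opt in c("trial_id", "predator_speed", "t1_obs", "v0_obs", "side"))
    if (!is.null(pick(opt))) ev[[opt]] <- pick(opt)
  if (anyNA(ev$beta) || anyNA(ev$alpha) || anyNA(ev$et))
    stop("non-numeric angle values in ",
         paste(which(is.na(ev$beta) | is.na(ev$alpha) | is.na(ev$et)) + 1,
               collapse = ", "))

  # pool left-side attacks onto the right side
  if (!is.null(ev$side)) {
    left <- ev$side == "left"
    ev$alpha[left] <- -ev$alpha[left]
    ev$et[left] <- ev$beta[left] + ev$alpha[left]
    ev$side <- NULL
  }

  bad_sum <- abs(ev$et - (ev$alpha + ev$beta)) > tol
  bad_beta <- ev$beta < 0 | ev$beta > 180
  bad_dir <- (ev$alpha > 0 & ev$direction == "toward") |
    (ev$alpha < 0 & ev$direction == "away")
  bad <- bad_sum | bad_beta | bad_dir
  if (any(bad)) {
    warning(sprintf("dropping %d invalid row(s) (file lines %s): %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1, 10), collapse = ", "),
                    paste(c(if (any(bad_sum)) "et != alpha + beta",
                            if (any(bad_beta)) "beta outside [0,180]",
                            if (any(bad_dir)) "direction/alpha sign mismatch"),
                          collapse = "; ")))
    ev <- ev[!bad, ]
  }
  ev$et <- ev$alpha + ev$beta   # enforce exact identity after validation
  rownames(ev) <- NULL
  ev
}

#' Write an event table in the canonical CSV schema
#'
#' @param events Event data frame (internal column names).
#' @param path Output CSV path.
#' @export
write_events <- function(events, path) {
  out <- events
  nm <- names(out)
  names(out) <- ifelse(nm %in% names(canonical_map), canonical_map[nm], nm)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read a flat key/value configuration file
#'
#' Accepts a minimal YAML/INI dialect: one `key: value` (or `key = value`)
#' per line, `#` comments, blank lines ignored. Values that parse as numbers
#' become numeric; `true`/`false` become logical.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:=]+)[:=](.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (tolower(val) %in% c("true", "false"))
                    tolower(val) == "true"
                  else val
  }
  out
}

config_to_params <- function(cfg) {
  keys <- intersect(names(cfg), names(formals(model_params)))
  p <- do.call(model_params, cfg[keys])
  if (!is.null(cfg$R_turn) || !is.null(cfg$D_react)) {
    pk <- c(keys, "R_turn", "D_react")
    p <- do.call(pursuit_params, cfg[intersect(names(cfg), pk)])
  }
  p
}

config_turn <- function(cfg) {
  if (!is.null(cfg$t1_level))
    turn_model(level = cfg$t1_level,
               slope = if (is.null(cfg$t1_slope)) 0 else cfg$t1_slope,
               changepoint = if (is.null(cfg$t1_changepoint)) 44
                             else cfg$t1_changepoint)
  else default_turn_model()
}

run_log <- function(out_dir, cfg_path, cfg, seed) {
  lines <- c(sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             sprintf("config: %s", cfg_path),
             sprintf("config_hash: %s",
                     sum(utf8ToInt(paste(deparse(cfg), collapse = "")))),
             sprintf("seed: %d", seed),
             vapply(names(cfg), function(k)
               sprintf("  %s: %s", k, paste(cfg[[k]], collapse = " ")),
               character(1)))
  writeLines(lines, file.path(out_dir, "run_log.txt"))
}

#' Command-line pipeline
#'
#' Subcommand dispatcher for the analysis pipeline, intended for
#' `Rscript -e 'escapegeom::escape_cli()' <command> --config <file> ...`.
#' Commands: `synth` (generate events), `fit-turn`, `calibrate`, `simulate`,
#' `compare-variants`, `choice`, `pursuit`. Each reads a flat config file
#' (model parameter keys as in [model_params()], plus `seed`, `events`,
#' pipeline-specific keys), writes its artifacts into `--out-dir` and a run
#' log with a config hash and the seed.
#'
#' @param args Character vector of CLI arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the main result of the command. Calls `stop()` (hence
#'   a non-zero exit under `Rscript`) on validation failure.
#' @export
escape_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: escape_cli <synth|fit-turn|calibrate|simulate|",
                 "compare-variants|choice|pursuit> --config FILE",
                 "[--out-dir DIR] [--seed N]")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  opt <- list(config = NULL, `out-dir` = ".", seed = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option: ", args[i], call. = FALSE)
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  if (is.null(opt$config)) stop(usage, call. = FALSE)
  cfg <- read_config(opt$config)
  out_dir <- opt$`out-dir`
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(if (!is.null(opt$seed)) opt$seed
                     else if (!is.null(cfg$seed)) cfg$seed else 1)
  set.seed(seed)
  params <- config_to_params(cfg)
  turn <- config_turn(cfg)
  run_log(out_dir, opt$config, cfg, seed)
  events_path <- if (!is.null(cfg$events)) cfg$events
                 else file.path(out_dir, "events.csv")

  result <- switch(cmd,
    "synth" = {
      ev <- synth_events(true_params = params, turn_truth = turn,
                         sd_choice = if (is.null(cfg$sd_choice)) 0.33
                                     else cfg$sd_choice,
                         n_fish = if (is.null(cfg$n_fish)) 23 else cfg$n_fish,
                         n_events = if (is.null(cfg$n_events)) 264
                                    else cfg$n_events,
                         seed = seed)
      write_events(ev, file.path(out_dir, "events.csv"))
      truth <- attr(ev, "truth")
      jsonlite::write_json(list(sd_choice = truth$sd_choice,
                                D_attack = truth$params$D_attack,
                                U_pred = truth$params$U_pred,
                                t1_level = truth$turn$level,
                                t1_slope = truth$turn$slope,
                                t1_changepoint = truth$turn$changepoint),
                           file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      ev
    },
    "fit-turn" = {
      ev <- read_events(events_path)
      if (is.null(ev$t1_obs)) stop("events file has no t1_ms column")
      cut <- if (is.null(cfg$cutoff_mm)) 15 else cfg$cutoff_mm
      fit <- fit_changepoint(abs(ev$alpha), ev$t1_obs, ev$fish_id)
      cmp <- compare_turn_models(abs(ev$alpha), ev$t1_obs, ev$fish_id)
      utils::write.csv(cmp, file.path(out_dir, "turn_model_comparison.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(kind = fit$kind, changepoint = fit$changepoint,
                                level = fit$level, slope = fit$slope,
                                aic = fit$fit_ic, cutoff_mm = cut),
                           file.path(out_dir, "turn_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      fit
    },
    "calibrate" = {
      ev <- read_events(events_path)
      opt2 <- optimize_params(ev, params, turn)
      ri <- ranking_index(ev, opt2$params, turn)
      ch <- fit_choice_sd(ri)
      utils::write.csv(data.frame(ev, ranking_index = ri),
                       file.path(out_dir, "ranking.csv"), row.names = FALSE)
      jsonlite::write_json(list(D_attack = opt2$D_attack,
                                U_pred = opt2$U_pred,
                                sd_choice = ch$sd_choice,
                                mean_ranking = opt2$mean_ranking),
                           file.path(out_dir, "calibration.json"),
                           auto_unbox = TRUE, digits = NA)
      opt2
    },
    "simulate" = {
      ev <- read_events(events_path)
      ch <- choice_dist(if (is.null(cfg$sd_choice)) 0.33 else cfg$sd_choice)
      n_reps <- if (is.null(cfg$n_reps)) 1000 else cfg$n_reps
      sims <- simulate_experiment(ev$beta, params, turn, ch,
                                  n_reps = n_reps, seed = seed)
      utils::write.csv(sims, file.path(out_dir, "simulated_ets.csv"),
                       row.names = FALSE)
      sims
    },
    "compare-variants" = {
      ev <- read_events(events_path)
      n_sims <- if (is.null(cfg$n_sims)) 1000 else cfg$n_sims
      tab <- variant_comparison(ev, params, turn, n_sims = n_sims,
                                seed = seed)
      utils::write.csv(tab, file.path(out_dir, "variant_comparison.csv"),
                       row.names = FALSE)
      tab
    },
    "choice" = {
      ev <- read_events(events_path)
      cl <- classify_choice(ev, params, turn)
      used <- cl$choice != "excluded"
      fit <- logistic_choice_fit(cl$advantage[used],
                                 cl$choice[used] == "optimal",
                                 cl$fish_id[used])
      utils::write.csv(cl, file.path(out_dir, "choice_classification.csv"),
                       row.names = FALSE)
      jsonlite::write_json(fit[c("slope", "intercept", "chisq", "p", "n",
                                 "method")],
                           file.path(out_dir, "choice_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      fit
    },
    "pursuit" = {
      if (!inherits(params, "pursuit_params"))
        stop("pursuit command needs R_turn and D_react in the config")
      ch <- choice_dist(if (is.null(cfg$sd_choice)) 0.23 else cfg$sd_choice)
      betas <- seq(0, 180, by = if (is.null(cfg$beta_step)) 1 else cfg$beta_step)
      n_per <- if (is.null(cfg$n_per_beta)) 100 else cfg$n_per_beta
      draws <- lapply(betas, function(b) {
        pr <- pursuit_profile(b, params, turn)
        d <- sample_et(pr, ch, n_per)
        data.frame(beta = b, et = d$et)
      })
      sims <- do.call(rbind, draws)
      utils::write.csv(sims, file.path(out_dir, "pursuit_ets.csv"),
                       row.names = FALSE)
      modes <- circ_modes(sims$et, bw = 50)
      utils::write.csv(modes, file.path(out_dir, "pursuit_modes.csv"),
                       row.names = FALSE)
      sims
    },
    stop("unknown command: ", cmd, "\n", usage, call. = FALSE))
  invisible(result)
}
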