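default_run_config <- function() {
  # the unit-count key is spelled n_units: a bare `N` is parsed as a
  # boolean by YAML
  list(n_units = 400, dt = 10, tau = 50, delta = 120, phi = "relu",
       alpha = 0.001, batch_size = 20, weight_reg = 0.001,
       activity_reg = 0.002, grad_clip_norm = 0.2,
       epochs = c(100, 500, 500),
       eta = 2e-5, update_stride = 5,
       rotation_deg = 30,
       trials_baseline = 200, trials_perturbation = 500,
       trials_washout = 200,
       seed = 1, out_dir = ".")
}

#' Load a run configuration
#'
#' Reads a YAML configuration and fills unset keys with the standard
#' defaults (dt 10 ms, tau 50 ms, delay 120 ms, N 400, ReLU, Adam 0.001,
#' batch 20, weight penalty 0.001, activity penalty 0.002, plasticity rate
#' 2e-5, 300-step trials). Unknown keys are rejected and the delay must be
#' an integer multiple of dt. Overridden keys are listed in the
#' `overrides` attribute for provenance.
#'
#' @param path YAML file; an empty or missing-path call returns pure
#'   defaults.
#' @return a named list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_run_config()
  overrides <- character(0)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
      for (nm in names(user)) {
        if (!is.character(cfg[[nm]]) && !is.numeric(user[[nm]]))
          stop("config key '", nm, "' must be numeric")
        cfg[[nm]] <- user[[nm]]
      }
      overrides <- names(user)
    }
  }
  if (abs(cfg$delta / cfg$dt - round(cfg$delta / cfg$dt)) > 1e-9)
    stop("delta must be an integer multiple of dt")
  if (length(cfg$epochs) != 3) stop("epochs must have three blocks")
  attr(cfg, "overrides") <- overrides
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration
#'
#' @param config a `run_config`.
#' @param path destination YAML file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[names(default_run_config())], path)
  invisible(path)
}

#' Write an adaptation session to a directory
#'
#' Writes the tidy per-trial log (CSV), the baseline and final recurrent
#' weights plus all snapshots (CSV, one file per snapshot), a session
#' manifest with the protocol and per-trial specs (JSON), and a provenance
#' block (seed, plasticity settings, package version).
#'
#' @param log an `adaptation_log`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_session <- function(log, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(log$trials, file.path(dir, "trial_log.csv"),
                   row.names = FALSE)
  wdir <- file.path(dir, "weights")
  dir.create(wdir, showWarnings = FALSE)
  for (nm in names(log$snapshots))
    utils::write.csv(log$snapshots[[nm]],
                     file.path(wdir, sprintf("W_trial_%s.csv", nm)),
                     row.names = FALSE)
  manifest <- list(
    protocol = list(seed = log$protocol$seed,
                    go_time = log$protocol$go_time,
                    phases = log$protocol$phases),
    plasticity = unclass(log$config),
    snapshot_trials = log$snapshot_trials,
    n_trials = nrow(log$trials),
    network = list(N = log$params_baseline$N, dt = log$params_baseline$dt,
                   tau = log$params_baseline$tau,
                   delta = log$params_baseline$delta),
    package_version = as.character(utils::packageVersion("fbmotor")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read an adaptation session from a directory
#'
#' Inverts [write_session()] for all scalar fields: the trial log, the
#' weight snapshots, and the manifest. Missing components raise an
#' integrity error naming the file.
#'
#' @param dir session directory.
#' @return list with `trials`, `snapshots`, `snapshot_trials`, `manifest`.
#' @export
read_session <- function(dir) {
  for (f in c("trial_log.csv", "manifest.json"))
    if (!file.exists(file.path(dir, f)))
      stop("corrupt session: missing ", f)
  trials <- utils::read.csv(file.path(dir, "trial_log.csv"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  snaps <- list()
  for (nm in as.character(manifest$snapshot_trials)) {
    f <- file.path(dir, "weights", sprintf("W_trial_%s.csv", nm))
    if (!file.exists(f)) stop("corrupt session: missing ", basename(f))
    snaps[[nm]] <- as.matrix(utils::read.csv(f))
  }
  list(trials = trials, snapshots = snaps,
       snapshot_trials = manifest$snapshot_trials, manifest = manifest)
}

#' Write network weights to a directory of CSV files
#'
#' @param params a `network_params`.
#' @param dir destination directory.
#' @export
write_weights <- function(params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("W", "W_in", "W_out", "F", "mask_W", "mask_F"))
    utils::write.csv(params[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(data.frame(b = params$b), file.path(dir, "b.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(b_out = params$b_out),
                   file.path(dir, "b_out.csv"), row.names = FALSE)
  jsonlite::write_json(list(N = params$N, dt = params$dt, tau = params$tau,
                            delta = params$delta, phi = params$phi),
                       file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read network weights written by [write_weights()]
#'
#' @param dir weights directory.
#' @return a `network_params`.
#' @export
read_weights <- function(dir) {
  arch <- jsonlite::read_json(file.path(dir, "architecture.json"),
                              simplifyVector = TRUE)
  p <- network_params(N = arch$N, dt = arch$dt, tau = arch$tau,
                      delta = arch$delta, seed = 0)
  for (nm in c("W", "W_in", "W_out", "F", "mask_W", "mask_F")) {
    m <- as.matrix(utils::read.csv(file.path(dir, paste0(nm, ".csv"))))
    dimnames(m) <- NULL
    p[[nm]] <- m
  }
  p$b <- utils::read.csv(file.path(dir, "b.csv"))$b
  p$b_out <- utils::read.csv(file.path(dir, "b_out.csv"))$b_out
  p
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `fbmotor` script: subcommands `train`
#' (initial gradient training, weights written as CSV), `adapt` (rotation
#' adaptation session on stored weights), `experiment` (one of the
#' scripted behavioural experiments), and `demo` (a scaled-down end-to-end
#' train + adapt pipeline). Returns an exit code rather than quitting, so
#' it is testable in-process.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code (0 success, 2 usage error).
#' @export
fbm_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fbmotor <subcommand> [options]",
    "  train      --out DIR [--config FILE] [--seed S] [--no-feedback] [--no-recurrence]",
    "  adapt      --weights DIR --out DIR [--rotation DEG] [--trials B,P,W] [--eta E] [--seed S]",
    "  experiment <vr|remap|generalize|variability|stimulate|clamp> --weights DIR --out DIR [--seed S]",
    "  demo       --out DIR [--seed S]", sep = "\n")
  if (length(argv) == 0) { message(usage); return(2L) }
  cmd <- argv[1]
  opts <- parse_opts(argv[-1])
  get <- function(nm, default = NULL) {
    if (!is.null(opts[[nm]])) opts[[nm]] else default
  }
  tryCatch({
    switch(cmd,
      train = {
        out <- get("out"); if (is.null(out)) stop("train requires --out")
        cfg <- load_config(get("config"))
        if (!is.null(get("seed"))) cfg$seed <- as.integer(get("seed"))
        tc <- training_config(alpha = cfg$alpha, batch_size = cfg$batch_size,
                              weight_reg = cfg$weight_reg,
                              activity_reg = cfg$activity_reg,
                              grad_clip_norm = cfg$grad_clip_norm,
                              epochs = cfg$epochs, seed = cfg$seed,
                              N = cfg$n_units, dt = cfg$dt, tau = cfg$tau,
                              delta = cfg$delta)
        p <- train_initial(tc, feedback = is.null(opts[["no-feedback"]]),
                           recurrent = is.null(opts[["no-recurrence"]]),
                           verbose = TRUE)
        write_weights(p, out)
        utils::write.csv(attr(p, "history"),
                         file.path(out, "training_curve.csv"),
                         row.names = FALSE)
        message("weights written to ", out)
        0L
      },
      adapt = {
        wdir <- get("weights"); out <- get("out")
        if (is.null(wdir) || is.null(out))
          stop("adapt requires --weights and --out")
        p <- read_weights(wdir)
        counts <- as.integer(strsplit(get("trials", "200,500,200"),
                                      ",")[[1]])
        log <- vr_adaptation_session(
          p, rotation_deg = as.numeric(get("rotation", 30)),
          counts = counts, seed = as.integer(get("seed", 1)),
          config = plasticity_config(eta = as.numeric(get("eta", 2e-5))))
        write_session(log, out)
        message("session written to ", out)
        0L
      },
      experiment = {
        kind <- argv[2]
        opts <- parse_opts(argv[-(1:2)])
        wdir <- opts[["weights"]]; out <- opts[["out"]]
        if (is.null(kind) || is.null(wdir) || is.null(out))
          stop("experiment requires a kind, --weights and --out")
        p <- read_weights(wdir)
        seed <- as.integer(if (!is.null(opts[["seed"]])) opts[["seed"]] else 1)
        res <- switch(kind,
          vr = vr_adaptation_session(p, seed = seed),
          remap = policy_remap_experiment(p, seed = seed),
          generalize = generalization_experiment(p, seed = seed),
          variability = variability_experiment(p, seed = seed),
          stimulate = stimulation_experiment(p, seed = seed),
          clamp = error_clamp_experiment(p, seed = seed),
          stop("unknown experiment: ", kind))
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        log <- if (inherits(res, "adaptation_log")) res else res$log
        write_session(log, out)
        summ <- summarise_experiment(kind, res)
        jsonlite::write_json(summ, file.path(out, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
        message("experiment written to ", out)
        0L
      },
      demo = {
        out <- get("out"); if (is.null(out)) stop("demo requires --out")
        seed <- as.integer(get("seed", 1))
        tc <- training_config(N = 60, epochs = c(10, 30, 40), seed = seed)
        p <- train_initial(tc)
        log <- vr_adaptation_session(p, counts = c(40, 120, 40),
                                     seed = seed)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_session(log, out)
        e <- abs(log$trials$takeoff_error_deg[log$trials$phase == "perturbation"])
        summ <- list(seed = seed, n_units = tc$N,
                     early_error_deg = mean(utils::head(e, 20)),
                     late_error_deg = mean(utils::tail(e, 20)))
        jsonlite::write_json(summ, file.path(out, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
        message(sprintf("demo: early |error| %.1f deg -> late %.1f deg",
                        summ$early_error_deg, summ$late_error_deg))
        0L
      },
      { message("unknown subcommand: ", cmd); message(usage); 2L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 2L })
}

parse_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      opts[[key]] <- args[i + 1]; i <- i + 2
    } else {
      opts[[key]] <- TRUE; i <- i + 1
    }
  }
  opts
}

summarise_experiment <- function(kind, res) {
  switch(kind,
    vr = {
      e <- abs(res$trials$takeoff_error_deg[res$trials$phase == "perturbation"])
      list(early_error_deg = mean(utils::head(e, 80)),
           late_error_deg = mean(utils::tail(e, 80)))
    },
    remap = list(mean_abs_shift_deg = res$mean_abs_shift),
    generalize = list(reduction_by_distance =
                        res$generalization[, c("angular_distance", "reduction")]),
    variability = list(asymptote = res),
    stimulate = list(summary = res$summary),
    clamp = list(clamp_drift_deg = res$clamp_drift,
                 weights_frozen = res$weights_frozen))
}

#' Write a trial's full time series to a directory
#'
#' One directory per trial: per-step datasets (`y`, `v`, `v_eff`, `p`,
#' `p_star`, `epsilon`, plus `x` and `r` when recorded) as CSV, and an
#' attributes file (seed, trial metadata, go step, dt).
#'
#' @param result a `trial_result`.
#' @param dir destination directory.
#' @return the directory, invisibly.
#' @export
write_trial_series <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("y", "v", "v_eff", "p", "p_star", "epsilon", "x", "r")) {
    if (!is.null(result[[nm]]))
      utils::write.csv(result[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = result$seed, go_step = result$go_step, dt = result$dt,
         takeoff_error_deg = result$takeoff_error,
         endpoint_error_cm = result$endpoint_error,
         target_index = result$trial$target_index,
         rotation_deg = result$trial$rotation_deg,
         go_time = result$trial$go_time),
    file.path(dir, "attributes.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trial time series written by [write_trial_series()]
#'
#' @param dir trial directory.
#' @return list of per-step matrices plus the attribute list.
#' @export
read_trial_series <- function(dir) {
  out <- list()
  for (nm in c("y", "v", "v_eff", "p", "p_star", "epsilon", "x", "r")) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) {
      m <- as.matrix(utils::read.csv(f))
      dimnames(m) <- NULL
      out[[nm]] <- m
    }
  }
  out$attributes <- jsonlite::read_json(file.path(dir, "attributes.json"),
                                        simplifyVector = TRUE)
  out
}
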