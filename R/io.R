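#' Read a neuron-model configuration file
#'
#' Model parameters are stored as structured YAML (or JSON, which YAML
#' parses): scalar fields of [neuron_model()] at the top level, gates as
#' mappings with `ss: {v_half, v_slope}` and `tau: {v_half, v_slope, tau_min,
#' tau_max}`, and the Kv4.3 block under `kv4`. Omitted fields keep their
#' calibrated defaults.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A [neuron_model()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  scalars <- c("f_s", "cm", "g_leak", "e_leak", "g_na", "e_na", "g_kdr", "e_k",
               "g_cal", "e_ca", "g_sk", "ks_sk", "g_hcn", "e_hcn",
               "ca_rest", "ca_tau", "ca_in")
  for (s in intersect(scalars, names(cfg))) args[[s]] <- cfg[[s]]
  mk_gate <- function(g) gate(boltzmann_params(g$ss$v_half, g$ss$v_slope),
                              tau_params(g$tau$v_half, g$tau$v_slope,
                                         g$tau$tau_min, g$tau$tau_max))
  for (gn in intersect(c("na_m", "na_h", "kdr_n", "cal_a", "hcn_h"), names(cfg))) {
    args[[gn]] <- mk_gate(cfg[[gn]])
  }
  if ("kv4" %in% names(cfg)) {
    k <- cfg$kv4
    kargs <- list()
    for (s in intersect(c("g_max", "f_s", "e_k"), names(k))) kargs[[s]] <- k[[s]]
    if ("activation" %in% names(k)) {
      kargs$activation <- boltzmann_params(k$activation$v_half, k$activation$v_slope)
    }
    if ("inactivation" %in% names(k)) {
      kargs$inactivation <- boltzmann_params(k$inactivation$v_half, k$inactivation$v_slope)
    }
    for (tn in intersect(c("tau_slow", "tau_fast", "activation_tau"), names(k))) {
      kargs[[tn]] <- tau_params(k[[tn]]$v_half, k[[tn]]$v_slope,
                                k[[tn]]$tau_min, k[[tn]]$tau_max)
    }
    args$kv4 <- do.call(kv4_params, kargs)
  }
  do.call(neuron_model, args)
}

#' Write a voltage trace or spike train as CSV
#'
#' @param x A [voltage_trace()] (columns `time_ms`, `v_mv`, `i_pa`) or a
#'   [spike_train()] (written as a one-column `spike_ms` table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  if (inherits(x, "spike_train")) {
    utils::write.csv(data.frame(spike_ms = x$times), path, row.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read/write behavioral session tables
#'
#' CSV schema: `subject`, `session`, `phase`, `trial`, `pct_time_in_port`,
#' `latency_s`.
#'
#' @param path CSV path.
#' @return For `read_session_csv`, a list of [session_series()] (one per
#'   subject).
#' @export
read_session_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject" %in% names(df)) df$subject <- 1
  lapply(split(df, df$subject), session_series)
}

#' @rdname read_session_csv
#' @param series A [session_series()] or list of them.
#' @export
write_session_csv <- function(series, path) {
  if (inherits(series, "session_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' A JSON-serializable record sufficient to re-execute a run: command,
#' configuration snapshot, master seed, package version, output files and
#' timestamp.
#'
#' @param command Command name.
#' @param config Configuration list (snapshot).
#' @param seed Master seed.
#' @param outputs Character vector of output files.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, config, seed, outputs) {
  structure(list(
    command = command,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("kv4rebound")),
    outputs = outputs,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    class = "run_manifest")
}

write_manifest <- function(manifest, dir) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Dispatch a named analysis command
#'
#' Thin programmatic entry point mirroring the command-line interface.
#' Commands: `simulate-rebound`, `sweep`, `voltage-clamp`, `balanced-state`,
#' `fit-behavior`, `generate-fixtures`, `proteomics-normalize`. Every run
#' writes tidy CSV outputs plus a JSON manifest into `out_dir`.
#'
#' @param name Command name.
#' @param config Optional list of command options (see details per command in
#'   the vignette), or a path to a YAML file of them.
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @return The [run_manifest()], invisibly.
#' @export
run_command <- function(name, config = NULL, seed = 1L, out_dir = ".") {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  get_opt <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  model_of <- function(fs) {
    if (!is.null(config$model_config)) {
      m <- read_model_config(config$model_config)
      m$kv4$f_s <- fs
      m
    } else neuron_model(f_s = fs)
  }
  outputs <- character(0)
  if (name == "simulate-rebound") {
    fs <- get_opt("f_s", 0.56)
    pr <- step_protocol(step_ms = get_opt("step_ms", 1000),
                        target_vmin_mv = get_opt("target_vmin_mv", -80),
                        window_ms = get_opt("window_ms", 15000))
    r <- measure_rebound_delay(model_of(fs), pr)
    out <- file.path(out_dir, "rebound.csv")
    utils::write.csv(data.frame(f_s = fs, v_min_mv = r$v_min, amp_pa = r$amp_pa,
                                delay_ms = r$delay_ms, censored = r$censored),
                     out, row.names = FALSE)
    outputs <- out
  } else if (name == "sweep") {
    fs <- get_opt("f_s", c(0.56, 0.22))
    models <- stats::setNames(lapply(fs, model_of), paste0("f_s_", fs))
    tab <- generate_rebound_dataset(
      models, vmin_grid = get_opt("vmin_grid", c(-90, -80, -70)),
      duration_grid = get_opt("duration_grid", c(100, 400, 1000)),
      noise_sd = get_opt("noise_sd", 0), seed = seed)
    out <- file.path(out_dir, "sweeps.csv")
    utils::write.csv(tab, out, row.names = FALSE)
    outputs <- out
  } else if (name == "voltage-clamp") {
    kv4 <- kv4_params(f_s = get_opt("f_s", 0.56))
    tr <- simulate_voltage_clamp(kv4, vc_activation_protocol())
    rec <- recovery_curve(kv4, get_opt("intervals_ms", c(25, 50, 100, 1000)))
    out1 <- file.path(out_dir, "vc_traces.csv")
    out2 <- file.path(out_dir, "vc_recovery.csv")
    utils::write.csv(as.data.frame(tr), out1, row.names = FALSE)
    utils::write.csv(rec, out2, row.names = FALSE)
    outputs <- c(out1, out2)
  } else if (name == "balanced-state") {
    models <- list(ctrl = model_of(0.56), ex3d = model_of(0.22))
    sp <- get_opt("scale_pairs",
                  data.frame(glut_scale = c(0.75, 1, 1.25),
                             gaba_scale = c(1.25, 1, 0.75)))
    sw <- sweep_ei_ratio(models, as.data.frame(sp),
                         n_inputs_grid = get_opt("n_inputs_grid", c(10, 20)),
                         n_trials = get_opt("n_trials", 50), master_seed = seed)
    out1 <- file.path(out_dir, "ei_grid.csv")
    out2 <- file.path(out_dir, "ei_diff.csv")
    utils::write.csv(sw$grid, out1, row.names = FALSE)
    utils::write.csv(sw$diff, out2, row.names = FALSE)
    outputs <- c(out1, out2)
  } else if (name == "fit-behavior") {
    if (is.null(config$sessions_csv)) stop("fit-behavior needs sessions_csv", call. = FALSE)
    series <- read_session_csv(config$sessions_csv)
    rows <- lapply(series, function(s) {
      f <- fit_learning_rates(s)
      data.frame(subject = s$subject[1], alpha_p = f$alpha_p, alpha_n = f$alpha_n,
                 residual = f$residual, v0 = f$bounds$v0, v_min = f$bounds$v_min,
                 v_max = f$bounds$v_max, converged = f$converged)
    })
    out <- file.path(out_dir, "rw_fits.csv")
    utils::write.csv(do.call(rbind, rows), out, row.names = FALSE)
    outputs <- out
  } else if (name == "generate-fixtures") {
    series <- generate_behavior_sessions(
      rw_params(get_opt("alpha_p", 0.3), get_opt("alpha_n", 0.1)),
      rw_bounds(get_opt("v0", 5), get_opt("v_min", 5), get_opt("v_max", 75)),
      noise_sd = get_opt("noise_sd", 5),
      n_subjects = get_opt("n_subjects", 5), seed = seed)
    out <- file.path(out_dir, "sessions.csv")
    write_session_csv(series, out)
    outputs <- out
  } else if (name == "proteomics-normalize") {
    if (is.null(config$peptides_csv)) stop("proteomics-normalize needs peptides_csv", call. = FALSE)
    pep <- peptide_table(utils::read.csv(config$peptides_csv, stringsAsFactors = FALSE))
    aa <- unlist(config$accessible_aa)
    tab <- tetramer_normalize(protein_abundance_table(pep, aa))
    out <- file.path(out_dir, "abundance.csv")
    utils::write.csv(tab, out, row.names = FALSE)
    outputs <- out
  } else {
    stop("unknown command: ", name, call. = FALSE)
  }
  man <- run_manifest(name, config, seed, outputs)
  write_manifest(man, out_dir)
  invisible(man)
}
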