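# Scenario configuration, presets and structured outputs.

.scenario_schema <- list(
  name = NULL, mode = NULL, seed = NULL, initial = NULL,
  tradeoff = c("gamma", "budget"),
  environment = c("supply", "monod_K", "decay", "death_rate",
                  "uptake_exponent"),
  dilution = c("rho0", "c_init", "c_fin", "n_batches"),
  evolution = c("mutation_sigma", "mutations_per_epoch", "epoch_duration",
                "epoch_batches", "mutant_fraction", "max_epochs",
                "rng_seed", "stop_window", "stop_mean_tol",
                "stop_var_factor"),
  control = c("rel_tol", "abs_tol", "max_time", "extinction_threshold",
              "checkpoint_interval", "stationarity_tol", "max_steps"),
  output = c("dir", "formats"))

.check_keys <- function(x, schema) {
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(x)) {
    allowed <- schema[[k]]
    if (is.null(allowed)) next
    bad <- setdiff(names(x[[k]]), allowed)
    if (length(bad))
      stop("unknown configuration key(s): ",
           paste(paste0(k, ".", bad), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' List bundled scenario presets
#'
#' Presets encode the reference parameterizations of the model
#' (symmetric supply `s = 1`, `mu * K = 0.1` realised as `K = 1`,
#' `mu = 0.1`, death rates 0.25 or 1, tradeoff exponents 0.9 / 1 / 1.1,
#' and the serial-dilution regimes `c(0)` in `{0.1 K, K, 10 K}` with
#' `rho0 = 1e-3`, `c_fin = 1e-8`).
#'
#' @return Character vector of preset names usable with
#'   [load_scenario()].
#' @export
crevo_presets <- function() {
  files <- list.files(system.file("presets", package = "crevo"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}

#' Load and validate a scenario configuration
#'
#' Reads a YAML or JSON scenario file (or a bundled preset), rejects
#' unknown keys (the error names the offending key path), fills
#' defaults, and builds the corresponding model objects.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @param preset Name of a bundled preset (see [crevo_presets()]);
#'   ignored when `path` is given.
#' @return Object of class `"scenario_config"`: a list with `raw` (the
#'   fully-resolved configuration list), `spec` ([tradeoff_spec()]),
#'   `env` ([environment_spec()]), `protocol` ([dilution_protocol()] or
#'   `NULL`), `evo` ([evolution_params()] or `NULL`), `ctrl`
#'   ([integration_control()]), `initial`, `mode`, `seed` and `name`.
#' @export
load_scenario <- function(path = NULL, preset = NULL) {
  if (is.null(path)) {
    if (is.null(preset))
      stop("either `path` or `preset` must be given", call. = FALSE)
    path <- system.file("presets", paste0(preset, ".yaml"),
                        package = "crevo")
    if (path == "")
      stop("unknown preset: ", preset, "; see crevo_presets()",
           call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  .check_keys(raw, .scenario_schema)

  if (is.null(raw$environment$supply))
    stop("missing configuration key: environment.supply", call. = FALSE)
  if (is.null(raw$tradeoff$gamma))
    stop("missing configuration key: tradeoff.gamma", call. = FALSE)
  p <- length(raw$environment$supply)
  mode <- if (is.null(raw$mode)) "chemostat" else raw$mode
  if (!mode %in% c("chemostat", "dilution"))
    stop("invalid value for key: mode (expected chemostat or dilution)",
         call. = FALSE)
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)

  spec <- tradeoff_spec(raw$tradeoff$gamma, p = p,
                        budget = if (is.null(raw$tradeoff$budget)) 1
                                 else raw$tradeoff$budget)
  env <- do.call(environment_spec, raw$environment)
  protocol <- NULL
  if (mode == "dilution") {
    if (is.null(raw$dilution))
      stop("missing configuration key: dilution (required when ",
           "mode = dilution)", call. = FALSE)
    protocol <- do.call(dilution_protocol, raw$dilution)
  }
  evo <- NULL
  if (!is.null(raw$evolution)) {
    args <- raw$evolution
    if (is.null(args$rng_seed)) args$rng_seed <- seed
    evo <- do.call(evolution_params, args)
  }
  ctrl <- do.call(integration_control,
                  if (is.null(raw$control)) list() else raw$control)
  initial <- if (is.null(raw$initial)) {
    singular_point(env$supply, spec, env$uptake_exponent)
  } else {
    project_to_constraint(as.numeric(raw$initial), spec)
  }

  resolved <- raw
  resolved$mode <- mode
  resolved$seed <- seed
  resolved$initial <- as.numeric(initial)
  structure(list(raw = resolved, spec = spec, env = env,
                 protocol = protocol, evo = evo, ctrl = ctrl,
                 initial = initial, mode = mode, seed = seed,
                 name = if (is.null(raw$name)) basename(path) else raw$name),
            class = "scenario_config")
}

#' Tabulate an evolutionary trajectory
#'
#' Flattens the snapshots of a [run_evolution()] result into one row per
#' (snapshot, strain): time, strain id, allocation components, simplex
#' coordinates and density.
#'
#' @param traj An `"evolution_trajectory"`.
#' @param spec The [tradeoff_spec()] of the run (defaults to the one
#'   stored in the trajectory).
#' @return A data frame.
#' @export
trajectory_table <- function(traj, spec = traj$spec) {
  p <- spec$p
  rows <- lapply(traj$snapshots, function(st) {
    sx <- simplex_coordinates(st$alpha, spec)
    df <- data.frame(time = st$time, strain_id = st$ids)
    for (j in seq_len(p)) df[[paste0("alpha", j)]] <- st$alpha[, j]
    for (j in seq_len(p)) df[[paste0("share", j)]] <- sx[, j]
    df$density <- st$density
    df
  })
  do.call(rbind, rows)
}

#' Write structured outputs of a run
#'
#' Writes, into `dir`: the per-snapshot strain table as CSV
#' (`trajectory.csv`, full double precision, round-trippable), the final
#' cluster summary as JSON (`clusters.json`), the event log as
#' line-delimited JSON (`events.ndjson`) and the fully-resolved
#' configuration (`config.yaml`).
#'
#' @param traj An `"evolution_trajectory"` from [run_evolution()].
#' @param config The `"scenario_config"` the run was built from.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named character vector of files written.
#' @export
write_outputs <- function(traj, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(trajectory = file.path(dir, "trajectory.csv"),
             clusters = file.path(dir, "clusters.json"),
             events = file.path(dir, "events.ndjson"),
             config = file.path(dir, "config.yaml"))
  tab <- trajectory_table(traj, config$spec)
  # doubles serialized with 17 significant digits: bitwise round-trip
  fmt <- tab
  for (col in names(fmt)) {
    if (is.double(fmt[[col]])) fmt[[col]] <- sprintf("%.17g", fmt[[col]])
  }
  utils::write.csv(fmt, files[["trajectory"]], row.names = FALSE,
                   quote = FALSE)
  cs <- cluster_phenotypes(traj$final, config$spec)
  jsonlite::write_json(list(cutoff = cs$cutoff, clusters = cs$clusters,
                            centers = cs$centers),
                       files[["clusters"]], digits = NA, auto_unbox = TRUE)
  con <- file(files[["events"]], open = "wt")
  jsonlite::stream_out(traj$events, con, verbose = FALSE)
  close(con)
  yaml::write_yaml(config$raw, files[["config"]])
  invisible(files)
}
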