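#' Assemble and validate a run configuration
#'
#' A `run_config` bundles everything a simulation run needs -- host
#' parameterisation, circuit topology with gene kinetics and controller
#' parameters, mutation scheme settings, batch protocol, solver/output
#' settings and a seed -- so that any run can be reproduced from its
#' configuration alone. Unknown keys are rejected.
#'
#' @param config A named list (typically from [read_run_config()]) with
#'   blocks `topology`, `genes`, `params`, `host`, `mutation`, `protocol`,
#'   `solver`, `seed`, `n_B`.
#' @return A validated `run_config` object with materialised component
#'   objects attached (`$circuit`, `$host_params`, `$scheme`,
#'   `$batch_protocol`).
#' @export
run_config <- function(config) {
  known <- c("topology", "genes", "params", "host", "mutation", "protocol",
             "solver", "seed", "n_B", "sweep", "reference", "optimize",
             "robustness")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$topology)) stop("config needs a `topology`", call. = FALSE)

  host <- do.call(host_params, config$host %||% list())
  genes <- purrr::imap(config$genes %||% list(), function(g, nm) {
    if (nm == "C") do.call(srna_spec, g) else do.call(gene_spec, g)
  })
  params <- do.call(controller_params, config$params %||% list())
  circuit <- build_circuit(config$topology, genes, params)
  mut <- config$mutation %||% list()
  scheme <- mutation_scheme(circuit$n_mutable,
                            base_rate = mut$base_rate %||% 5e-5,
                            attenuation = mut$attenuation %||% 0.1)
  protocol <- do.call(batch_protocol, config$protocol %||% list())
  structure(
    list(raw = config, circuit = circuit, host_params = host,
         scheme = scheme, batch_protocol = protocol,
         record_every = (config$solver %||% list())$record_every %||% 20,
         seed = config$seed %||% 1),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A `run_config` (or raw list).
#' @export
write_run_config <- function(config, path) {
  raw <- if (inherits(config, "run_config")) config$raw else config
  yaml::write_yaml(raw, path, precision = 17L)
  invisible(config)
}

#' Miniature test-scale configuration
#'
#' A toy system for fast tests and examples: the standard host, a modest
#' process (`omega_A = 5`), short 8-hour batch days, a small substrate
#' bolus, a fast mutation clock and a 4-day horizon, so that a full
#' evolution run completes in seconds while exhibiting the same qualitative
#' behaviour (day-scale output decay, mutant takeover) as the full-scale
#' protocol.
#'
#' @param topology `"OL"` (default) or `"CLpATL"` for a controller-bearing
#'   toy.
#' @return A `run_config`.
#' @export
fixture_toy_system <- function(topology = c("OL", "CLpATL")) {
  topology <- match.arg(topology)
  base <- list(
    topology = topology,
    genes = list(A = list(omega = 5)),
    host = list(),
    mutation = list(base_rate = 1e-3, attenuation = 0.1),
    protocol = list(day_length = 480, sample_size = 500,
                    substrate_reset = 2e11, max_days = 4,
                    stop_fraction = 0.01),
    solver = list(record_every = 40),
    seed = 1
  )
  if (topology == "CLpATL") {
    base$genes <- list(A = list(omega = 5), B = list(n_aa = 300),
                       C = list(omega = 100))
    base$params <- list(k_B = 500, k_seq = 0.1)
  }
  run_config(base)
}

#' Run an evolution simulation from a configuration
#'
#' @param config A `run_config`.
#' @return An `evolution_trace` (see [run_evolution()]).
#' @export
simulate_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  run_evolution(config$circuit, config$host_params, scheme = config$scheme,
                protocol = config$batch_protocol,
                record_every = config$record_every, seed = config$seed)
}

## ---- results serialisation -------------------------------------------------

#' Write run artifacts to a directory
#'
#' Writes the tidy trace CSV (`time, strain, species, value`), the
#' day-endpoint CSV, the mutation transition matrix CSV (for audit), the
#' metrics CSV and a JSON run manifest (configuration, seed, solver
#' settings, package version, wall time) into `dir`.
#'
#' @param run An `evolution_trace`.
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` to embed in the manifest.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir, config = NULL) {
  stopifnot(inherits(run, "evolution_trace"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- run$trace |>
    tidyr::pivot_longer(cols = c("N", "p_A", "lambda", "T_L_A", "s_X"),
                        names_to = "species", values_to = "value") |>
    dplyr::select("day", "time", "strain", "species", "value")
  utils::write.csv(long, file.path(dir, "trace.csv"), row.names = FALSE)
  utils::write.csv(dplyr::select(run$days, -"strain_N"),
                   file.path(dir, "days.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$scheme$matrix),
                   file.path(dir, "mutation_matrix.csv"))
  utils::write.csv(design_metrics(run), file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  manifest <- list(
    topology = run$circuit$topology,
    P0 = run$P0,
    days = nrow(run$days),
    protocol = unclass(run$protocol),
    mutation = list(base_rate = run$scheme$base_rate,
                    attenuation = run$scheme$attenuation),
    config = if (!is.null(config)) config$raw,
    config_hash = if (!is.null(config)) config_hash(config),
    package_version = as.character(utils::packageVersion("evostab")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_run
#' @export
config_hash <- function(config) {
  raw <- if (inherits(config, "run_config")) config$raw else config
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(raw, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

## ---- command-line driver ---------------------------------------------------

#' Command-line driver
#'
#' The entry point behind the `inst/cli/evostab.R` script:
#' `evostab_cli(c("simulate", "--config", "cfg.yaml", "--out", "runs/x"))`.
#' Commands: `simulate` (evolution run -> trace + manifest), `metrics`
#' (metrics of a run config), `sweep` (grid sweep from the config's `sweep`
#' block), `reference` (open-loop reference sweep), `optimize` (NSGA-II
#' from the `optimize` block), `robustness` (from the `robustness` block).
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the primary result object of the command.
#' @export
evostab_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    stop("usage: evostab <simulate|metrics|sweep|reference|optimize|robustness> --config <yaml> --out <dir> [--seed <int>]",
         call. = FALSE)
  }
  command <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  out_dir <- opt("--out", "evostab-out")
  seed <- as.integer(opt("--seed", "1"))
  cfg_path <- opt("--config")
  if (is.null(cfg_path)) stop("--config is required", call. = FALSE)
  config <- read_run_config(cfg_path)
  config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  result <- switch(command,
    simulate = {
      run <- simulate_config(config)
      write_run(run, out_dir, config)
      run
    },
    metrics = {
      run <- simulate_config(config)
      met <- design_metrics(run)
      utils::write.csv(met, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
      met
    },
    sweep = {
      blk <- config$raw$sweep %||% stop("config needs a `sweep` block",
                                        call. = FALSE)
      grid <- tibble::as_tibble(purrr::map(blk$grid, unlist))
      tab <- sweep_designs(config$raw$topology, tidyr::crossing(!!!grid),
                           n_B = config$raw$n_B %||% 300,
                           host = config$host_params, scheme = config$scheme,
                           protocol = config$batch_protocol,
                           record_every = config$record_every)
      utils::write.csv(tab, file.path(out_dir, "sweep.csv"), row.names = FALSE)
      tab
    },
    reference = {
      blk <- config$raw$reference %||% list()
      tab <- sweep_openloop(n = blk$n %||% 30,
                            range = unlist(blk$range %||% c(0.1, 1000)),
                            host = config$host_params, scheme = config$scheme,
                            protocol = config$batch_protocol,
                            record_every = config$record_every)
      utils::write.csv(tab, file.path(out_dir, "reference.csv"),
                       row.names = FALSE)
      build_openloop_reference(tab)
    },
    optimize = {
      blk <- config$raw$optimize %||% list()
      ga <- do.call(ga_settings, blk$ga %||% list(pop_size = 40,
                                                  generations = 30))
      pf <- pareto_optimize(config$raw$topology,
                            n_B = config$raw$n_B %||% 300, settings = ga,
                            seed = seed, host = config$host_params,
                            scheme = config$scheme,
                            protocol = config$batch_protocol,
                            record_every = config$record_every)
      utils::write.csv(pf$front, file.path(out_dir, "pareto_front.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(topology = pf$topology, n_B = pf$n_B, seed = pf$seed,
             n_eval = pf$n_eval, settings = unclass(pf$settings),
             config_hash = config_hash(config)),
        file.path(out_dir, "optimize_manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      pf
    },
    robustness = {
      blk <- config$raw$robustness %||% stop(
        "config needs a `robustness` block with a `front` CSV path",
        call. = FALSE)
      front <- tibble::as_tibble(utils::read.csv(blk$front))
      rep <- robustness_analysis(front, topology = config$raw$topology,
                                 n_B = config$raw$n_B %||% 300,
                                 X = unlist(blk$X %||% c(10, 25)),
                                 n = blk$n %||% 100, seed = seed,
                                 host = config$host_params,
                                 scheme = config$scheme,
                                 protocol = config$batch_protocol,
                                 record_every = config$record_every)
      utils::write.csv(rep$per_design,
                       file.path(out_dir, "robustness_per_design.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(front = rep$front,
             excluded_designs = rep$excluded_designs,
             config_hash = config_hash(config)),
        file.path(out_dir, "robustness_summary.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      rep
    },
    stop(sprintf("unknown command `%s`", command), call. = FALSE)
  )
  invisible(result)
}
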