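default_run_config <- function() {
  list(
    protocol = "cv",
    condition = "control",
    internode_length = 100,
    n_nodes = 7,
    affected_inrs = NULL,
    gamma = 0.1,
    preset = "methods",
    beta_m = "repaired",
    lt_site = "JP",
    aoe1_scaling = "area",
    max_lambda_fraction = 0.1,
    dt = 0.001,
    t_stop = 4,
    settle_time = 20,
    settle_dt = 0.1,
    v_init = -63,
    record = "nodes",
    record_currents = FALSE,
    stimulus = list(amplitude = 0.2, duration = 0.2, onset = 0, site_node = 0),
    # protocol-specific
    lengths = seq(50, 300, by = 25),
    ks = NULL,
    from = "distal",
    amplitudes = seq(0.2, 1, by = 0.2),
    pulse_ms = 200,
    record_node = 3,
    tol = 0.01
  )
}

validate_run_config <- function(cfg) {
  chk <- function(ok, key, msg) {
    if (!ok) rlang::abort(sprintf("config key `%s`: %s", key, msg))
  }
  chk(cfg$condition %in% c("control", "AOE1", "AOE2"), "condition",
      "must be one of control, AOE1, AOE2")
  chk(is.numeric(cfg$dt) && cfg$dt > 0, "dt", "must be a positive number (ms)")
  chk(is.numeric(cfg$t_stop) && cfg$t_stop > 0, "t_stop", "must be positive (ms)")
  chk(is.numeric(cfg$settle_time) && cfg$settle_time >= 0, "settle_time",
      "must be non-negative (ms)")
  chk(is.numeric(cfg$internode_length) && cfg$internode_length > 0,
      "internode_length", "must be positive (um)")
  chk(is.numeric(cfg$n_nodes) && cfg$n_nodes >= 2, "n_nodes", "must be >= 2")
  chk(is.numeric(cfg$gamma) && cfg$gamma >= 0 && cfg$gamma <= 1, "gamma",
      "must lie in [0, 1]")
  chk(is.numeric(cfg$stimulus$duration) && cfg$stimulus$duration > 0,
      "stimulus.duration", "must be positive (ms)")
  chk(is.finite(cfg$stimulus$amplitude), "stimulus.amplitude",
      "must be finite (nA)")
  chk(cfg$protocol %in% c("cv", "simulate", "inl-sweep", "aoe-sweep",
                          "gna-sweep", "fi-curve", "leak-trace", "describe"),
      "protocol", "unknown protocol")
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML configuration file, merges it over the package defaults,
#' rejects unknown keys, and validates ranges. An empty file yields the full
#' default (control) configuration.
#'
#' @param path Path to a YAML file.
#' @return A named list of class `run_config` with every key resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defs <- default_run_config()
  unknown <- setdiff(names(user), names(defs))
  if (length(unknown)) {
    rlang::abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(user$stimulus)) {
    bad <- setdiff(names(user$stimulus), names(defs$stimulus))
    if (length(bad)) {
      rlang::abort(sprintf("unknown stimulus key(s): %s", paste(bad, collapse = ", ")))
    }
    user$stimulus <- utils::modifyList(defs$stimulus, user$stimulus)
  }
  cfg <- utils::modifyList(defs, user)
  structure(validate_run_config(cfg), class = "run_config")
}

#' Build model objects from a run configuration
#'
#' @param cfg A [load_config()] list (or the default configuration).
#' @return A list with `params` ([channel_params()]), `cable` (discretized),
#'   and `sim` ([sim_config()]).
#' @export
resolve_config <- function(cfg = default_run_config()) {
  params <- channel_params(gamma = cfg$gamma, preset = cfg$preset,
                           beta_m = cfg$beta_m)
  spec <- axon_spec(cfg$condition, internode_length = cfg$internode_length,
                    n_nodes = cfg$n_nodes, affected_inrs = cfg$affected_inrs,
                    params = params, aoe1_scaling = cfg$aoe1_scaling,
                    lt_site = cfg$lt_site)
  cable <- discretize(spec, max_lambda_fraction = cfg$max_lambda_fraction)
  sim <- sim_config(dt = cfg$dt, t_stop = cfg$t_stop,
                    settle_time = cfg$settle_time, settle_dt = cfg$settle_dt,
                    v_init = cfg$v_init, record = cfg$record,
                    record_currents = isTRUE(cfg$record_currents),
                    stimulus = stimulus_spec(
                      amplitude = cfg$stimulus$amplitude,
                      duration = cfg$stimulus$duration,
                      onset = cfg$stimulus$onset,
                      site_node = cfg$stimulus$site_node))
  list(params = params, spec = spec, cable = cable, sim = sim)
}

result_table <- function(result) {
  if (inherits(result, "axon_trace")) {
    tidyr::pivot_wider(result, names_from = "node", values_from = dplyr::any_of(
      c("v", "i_na", "i_ht", "i_lt", "i_leak")), names_prefix = "node_")
  } else if (inherits(result, "cv_result") || inherits(result, "block_threshold")) {
    generics::glance(result)
  } else {
    tibble::as_tibble(result)
  }
}

#' Write a protocol result to disk
#'
#' Writes the result's tidy table as `<name>.csv` and, when available, a
#' resolved-configuration sidecar `<name>_config.yaml`. File contents are
#' deterministic: identical runs produce byte-identical files.
#'
#' @param result A trace, sweep, `cv_result`, `block_threshold`, `fi_curve`
#'   or plain data frame.
#' @param out_dir Output directory (created if needed).
#' @param name Base file name (default derived from the result class).
#' @param config Optional configuration list echoed to the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, out_dir, name = NULL, config = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(name)) name <- class(result)[1]
  paths <- character(0)
  tab <- result_table(result)
  csv <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(tab, csv, row.names = FALSE)
  paths <- c(paths, csv)
  if (inherits(result, "cv_result")) {
    spikes_csv <- file.path(out_dir, paste0(name, "_spikes.csv"))
    utils::write.csv(result$spikes, spikes_csv, row.names = FALSE)
    paths <- c(paths, spikes_csv)
  }
  if (!is.null(config)) {
    side <- file.path(out_dir, paste0(name, "_config.yaml"))
    yaml::write_yaml(unclass(config), side)
    paths <- c(paths, side)
  }
  invisible(paths)
}

new_axon_spec <- function(df, condition, internode_length = NA_real_,
                          n_nodes = 0L, params = channel_params(), ra = 70) {
  structure(tibble::as_tibble(df),
            class = c("axon_spec", class(tibble::tibble())),
            condition = condition, internode_length = internode_length,
            n_nodes = n_nodes, affected_inrs = integer(0), ra = ra,
            params = params, lt_site = "JP", aoe1_scaling = "area")
}

#' Miniature axon specifications for testing
#'
#' * `"single-node"` — one control nodal region (full channel set), for
#'   single-compartment ODE checks.
#' * `"passive-uniform"` — a 2000 um uniform cylinder with bare passive
#'   membrane and no voltage-gated channels (length constant ~472 um), for
#'   analytic cable checks.
#' * `"mini-3node"` — a 3-node / 2-internode control axon.
#'
#' @param name Fixture name.
#' @return An `axon_spec`.
#' @export
make_fixture <- function(name = c("single-node", "passive-uniform", "mini-3node")) {
  known <- c("single-node", "passive-uniform", "mini-3node")
  if (!is.character(name) || !name[1] %in% known) {
    rlang::abort(sprintf("unknown fixture `%s`; available: %s",
                         name[1], paste(known, collapse = ", ")))
  }
  name <- name[1]
  p <- channel_params()
  switch(name,
    "single-node" = new_axon_spec(
      tibble::tibble(kind = "node", node = 0L, inr = NA_integer_, aoe = FALSE,
                     length = 1.3, diameter = 0.8, cm_specific = 1,
                     g_leak = 0.2, g_na = p$g_na, g_ht = p$g_ht, g_lt = 0),
      condition = "fixture-single-node", n_nodes = 1L, params = p),
    "passive-uniform" = new_axon_spec(
      tibble::tibble(kind = "axon", node = NA_integer_, inr = NA_integer_,
                     aoe = FALSE, length = 2000, diameter = 1.25,
                     cm_specific = 1, g_leak = 0.2,
                     g_na = 0, g_ht = 0, g_lt = 0),
      condition = "fixture-passive-uniform", params = p),
    "mini-3node" = axon_spec("control", n_nodes = 3)
  )
}
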