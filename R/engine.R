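#' Current-injection stimulus
#'
#' A rectangular current pulse injected into one compartment (by default the
#' central compartment of node 0). `onset` is measured from the end of the
#' settle phase.
#'
#' @param amplitude Pulse amplitude, nA.
#' @param duration Pulse duration, ms.
#' @param onset Pulse onset, ms.
#' @param site_node Node number whose central compartment receives the
#'   current (ignored when `site_comp` is given).
#' @param site_comp Optional explicit compartment index (1-based).
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(amplitude = 0.2, duration = 0.2, onset = 0,
                          site_node = 0, site_comp = NULL) {
  if (!is.finite(amplitude)) rlang::abort("stimulus `amplitude` must be finite.")
  if (duration <= 0) rlang::abort("stimulus `duration` must be positive.")
  if (onset < 0) rlang::abort("stimulus `onset` must be non-negative.")
  structure(list(amplitude = amplitude, duration = duration, onset = onset,
                 site_node = site_node, site_comp = site_comp),
            class = "stimulus_spec")
}

#' Simulation settings
#'
#' @param dt Integration time step for the stimulus window, ms. The default
#'   0.001 ms resolves the microsecond-scale inter-node delays of this cable;
#'   conduction velocity changes by under 1 percent when it is halved.
#' @param t_stop Duration of the recorded (post-settle) window, ms.
#' @param settle_time Stimulus-free relaxation run before recording, ms.
#' @param settle_dt Time step used during the settle phase, ms (backward
#'   Euler is unconditionally stable, so the settle phase can take large
#'   steps).
#' @param v_init Initial membrane potential, mV; gates start at their
#'   steady state for this voltage. The true resting potential emerges
#'   during the settle phase.
#' @param record `"nodes"` (default: the central compartment of every node)
#'   or `"all"` compartments.
#' @param record_currents Also record the four ionic current components at
#'   the recorded sites (nA).
#' @param settle_tol Maximum |dV/dt| (mV/ms) accepted at the end of the
#'   settle phase; a larger residual raises a warning.
#' @param stimulus A [stimulus_spec()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.001, t_stop = 4, settle_time = 20,
                       settle_dt = 0.1, v_init = -63,
                       record = c("nodes", "all"), record_currents = FALSE,
                       settle_tol = 1e-3,
                       stimulus = stimulus_spec()) {
  record <- match.arg(record)
  if (dt <= 0) rlang::abort("`dt` must be positive.")
  if (t_stop <= 0) rlang::abort("`t_stop` must be positive.")
  if (settle_time < 0) rlang::abort("`settle_time` must be non-negative.")
  structure(list(dt = dt, t_stop = t_stop, settle_time = settle_time,
                 settle_dt = settle_dt, v_init = v_init, record = record,
                 record_currents = record_currents, settle_tol = settle_tol,
                 stimulus = stimulus),
            class = "sim_config")
}

# Engine argument block shared by the C++ and reference steppers.
cable_arrays <- function(cable, gna_scale = 1) {
  stopifnot(inherits(cable, "axon_cable"))
  p <- attr(cable, "params")
  list(
    C = cable$c_nF, gL = cable$g_leak_uS,
    gNa = cable$g_na_uS * gna_scale, gHT = cable$g_ht_uS, gLT = cable$g_lt_uS,
    ga = 1 / cable$r_axial_MOhm[-nrow(cable)],
    gate_k = as.matrix(p$gates[, c("k_alpha", "eta_alpha", "k_beta", "eta_beta")]),
    gamma = p$gamma, v_na = p$v_na, v_ht = p$v_ht, v_lt = p$v_lt,
    v_leak = p$v_leak,
    lt_exp_l = unname(p$lt_exponents[["l"]]), lt_exp_r = unname(p$lt_exponents[["r"]]),
    node_comp = attr(cable, "node_comp")
  )
}

gate_steady_matrix <- function(gate_k, v) {
  n <- length(v)
  G <- matrix(0, n, 6)
  for (j in 1:6) {
    a <- gate_k[j, 1] * exp(gate_k[j, 2] * v)
    b <- gate_k[j, 3] * exp(gate_k[j, 4] * v)
    G[, j] <- a / (a + b)
  }
  G
}

engine_call <- function(arr, v, G, dt, n_steps, stim_comp = -1, stim_amp = 0,
                        stim_from = 0, stim_to = 0, record = integer(0),
                        record_currents = FALSE, backend = "cpp") {
  f <- if (identical(backend, "r")) run_cable_reference else run_cable_engine
  f(arr$C, arr$gL, arr$gNa, arr$gHT, arr$gLT, arr$ga, arr$gate_k, arr$gamma,
    arr$v_na, arr$v_ht, arr$v_lt, arr$v_leak, arr$lt_exp_l, arr$lt_exp_r,
    v, G, dt, as.integer(n_steps), as.integer(stim_comp - 1), stim_amp,
    as.integer(stim_from), as.integer(stim_to), as.integer(record - 1L),
    record_currents)
}

#' Settle a cable to its resting state
#'
#' Starts every compartment at `v_init` with gates at their local steady
#' state, then integrates stimulus-free for `settle_time` so the resting
#' potential can emerge from the full channel complement. The residual
#' max |dV/dt| over a final probe step is reported; if it exceeds
#' `settle_tol` a warning is raised.
#'
#' @param cable An [discretize()]d cable.
#' @param config A [sim_config()].
#' @param gna_scale Scale factor applied to every compartment's Nav
#'   conductance (used by the block-threshold protocol).
#' @param backend `"cpp"` (default) or `"r"` (pure-R reference stepper).
#' @return A list with `v` (mV per compartment), `gates` (N x 6 matrix),
#'   and `residual` (mV/ms).
#' @export
settle_cable <- function(cable, config = sim_config(), gna_scale = 1,
                         backend = "cpp") {
  arr <- cable_arrays(cable, gna_scale)
  v <- rep(config$v_init, nrow(cable))
  G <- gate_steady_matrix(arr$gate_k, v)
  n_settle <- round(config$settle_time / config$settle_dt)
  residual <- NA_real_
  if (n_settle > 0) {
    res <- engine_call(arr, v, G, config$settle_dt, n_settle, record = 1L,
                       backend = backend)
    v <- res$v_final; G <- res$gates_final
    probe <- engine_call(arr, v, G, config$settle_dt, 1L, record = 1L,
                         backend = backend)
    residual <- max(abs(probe$v_final - v)) / config$settle_dt
    if (residual > config$settle_tol) {
      rlang::warn(sprintf(
        "cable not settled after %g ms: residual |dV/dt| = %.3g mV/ms (tolerance %g)",
        config$settle_time, residual, config$settle_tol))
    }
  }
  list(v = v, gates = G, residual = residual)
}

#' Run a cable simulation
#'
#' Settles the cable ([settle_cable()]), then integrates the stimulus window
#' with the backward-Euler cable solver and exponential gating updates. The
#' model is fully deterministic: identical inputs give identical traces.
#'
#' @inheritParams settle_cable
#' @param state Optional pre-settled state (from [settle_cable()]) to reuse
#'   across runs of the same cable.
#' @return A tibble of class `axon_trace` in long format: `time` (ms from
#'   stimulus-window start), `node` (node number, or compartment index when
#'   `record = "all"`), `v` (mV), and, when `config$record_currents` is set,
#'   `i_na`, `i_ht`, `i_lt`, `i_leak` (nA). Attributes: `config`, `cable`
#'   metadata, `node_comp`, `settle_residual`.
#' @examples
#' \donttest{
#' cable <- axon_spec("control") |> discretize()
#' tr <- simulate_cable(cable, sim_config(dt = 0.01, t_stop = 2))
#' dplyr::filter(tr, node == 6, v > 0)
#' }
#' @export
simulate_cable <- function(cable, config = sim_config(), gna_scale = 1,
                           state = NULL, backend = "cpp") {
  arr <- cable_arrays(cable, gna_scale)
  if (is.null(state)) state <- settle_cable(cable, config, gna_scale, backend)

  stim <- config$stimulus
  stim_comp <- stim$site_comp
  if (is.null(stim_comp)) {
    nodes <- arr$node_comp
    if (stim$site_node + 1 > length(nodes)) {
      rlang::abort(sprintf("stimulus site node %d does not exist.", stim$site_node))
    }
    stim_comp <- nodes[stim$site_node + 1]
  }
  rec <- switch(config$record,
                nodes = arr$node_comp,
                all = seq_len(nrow(cable)))
  n_steps <- round(config$t_stop / config$dt)
  res <- engine_call(arr, state$v, state$gates, config$dt, n_steps,
                     stim_comp = stim_comp, stim_amp = stim$amplitude,
                     stim_from = round(stim$onset / config$dt),
                     stim_to = round((stim$onset + stim$duration) / config$dt),
                     record = rec, record_currents = config$record_currents,
                     backend = backend)

  time <- seq_len(n_steps) * config$dt
  site_label <- if (config$record == "nodes") {
    sort(unique(stats::na.omit(cable$node)))
  } else rec
  out <- tibble::tibble(
    time = rep(time, times = length(rec)),
    node = rep(site_label, each = n_steps),
    v = as.vector(res$V)
  )
  if (config$record_currents) {
    out$i_na <- as.vector(res$I_Na); out$i_ht <- as.vector(res$I_HT)
    out$i_lt <- as.vector(res$I_LT); out$i_leak <- as.vector(res$I_L)
  }
  structure(out,
            class = c("axon_trace", class(tibble::tibble())),
            config = config, node_comp = arr$node_comp,
            node_position = cable$position[arr$node_comp],
            condition = attr(cable, "condition"),
            internode_length = attr(cable, "internode_length"),
            n_comp = nrow(cable),
            stim_comp = stim_comp,
            settle_residual = state$residual)
}

# Pure-R twin of the C++ stepper; identical algorithm, used as an in-package
# cross-check and as a readable statement of the numerical scheme.
run_cable_reference <- function(C, gL, gNa, gHT, gLT, ga, gate_k, gamma,
                                v_na, v_ht, v_lt, v_leak, lt_exp_l, lt_exp_r,
                                v0, gates0, dt, n_steps, stim_comp0, stim_amp,
                                stim_from, stim_to, record0, record_currents) {
  N <- length(C)
  v <- as.numeric(v0); G <- gates0
  rec <- record0 + 1L; stim_comp <- stim_comp0 + 1L
  V_out <- matrix(0, n_steps, length(rec))
  IL <- INa <- IHT <- ILT <- if (record_currents) matrix(0, n_steps, length(rec)) else NULL
  for (it in seq_len(n_steps)) {
    for (j in 1:6) {
      a <- gate_k[j, 1] * exp(gate_k[j, 2] * v)
      b <- gate_k[j, 3] * exp(gate_k[j, 4] * v)
      jinf <- a / (a + b)
      G[, j] <- jinf + (G[, j] - jinf) * exp(-dt * (a + b))
    }
    w <- 1 - gamma + gamma * G[, 4]
    gna <- gNa * G[, 1]^3 * G[, 2]
    ght <- gHT * G[, 3]^3 * w
    glt <- gLT * G[, 5]^lt_exp_l * G[, 6]^lt_exp_r
    gion <- gna + ght + glt + gL
    eion <- gna * v_na + ght * v_ht + glt * v_lt + gL * v_leak
    diag <- C / dt + gion
    rhs <- C / dt * v + eion
    if (it - 1 >= stim_from && it - 1 < stim_to && stim_comp >= 1) {
      rhs[stim_comp] <- rhs[stim_comp] + stim_amp
    }
    if (N > 1) {
      diag[-N] <- diag[-N] + ga
      diag[-1] <- diag[-1] + ga
      cp <- numeric(N - 1); dp <- numeric(N)
      cp[1] <- -ga[1] / diag[1]; dp[1] <- rhs[1] / diag[1]
      for (i in 2:N) {
        den <- diag[i] + ga[i - 1] * cp[i - 1]
        if (i < N) cp[i] <- -ga[i] / den
        dp[i] <- (rhs[i] + ga[i - 1] * dp[i - 1]) / den
      }
      v[N] <- dp[N]
      for (i in (N - 1):1) v[i] <- dp[i] - cp[i] * v[i + 1]
    } else {
      v <- rhs / diag
    }
    V_out[it, ] <- v[rec]
    if (record_currents) {
      IL[it, ] <- gL[rec] * (v[rec] - v_leak)
      INa[it, ] <- gna[rec] * (v[rec] - v_na)
      IHT[it, ] <- ght[rec] * (v[rec] - v_ht)
      ILT[it, ] <- glt[rec] * (v[rec] - v_lt)
    }
  }
  out <- list(V = V_out, v_final = v, gates_final = G)
  if (record_currents) {
    out$I_L <- IL; out$I_Na <- INa; out$I_HT <- IHT; out$I_LT <- ILT
  }
  out
}
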