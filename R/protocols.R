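#' Detect action-potential peaks in a trace
#'
#' A spike is a local maximum of the membrane potential exceeding
#' `threshold` (default 0 mV). Peak times and amplitudes are refined by
#' quadratic interpolation through the three samples around each maximum,
#' giving sub-time-step resolution.
#'
#' @param trace An [simulate_cable()] trace.
#' @param nodes Optional subset of recorded sites.
#' @param threshold Peak detection threshold, mV.
#' @return A tibble with columns `node`, `time` (ms), `peak_v` (mV),
#'   time-ordered within each node. Zero rows where no spike occurred.
#' @export
detect_spikes <- function(trace, nodes = NULL, threshold = 0) {
  stopifnot(inherits(trace, "axon_trace"))
  df <- if (is.null(nodes)) trace else dplyr::filter(trace, .data$node %in% nodes)
  dplyr::group_by(df, .data$node) |>
    dplyr::group_modify(function(d, key) {
      v <- d$v; tv <- d$time; n <- length(v)
      if (n < 3) return(tibble::tibble(time = numeric(0), peak_v = numeric(0)))
      mid <- 2:(n - 1)
      loc <- mid[v[mid] > v[mid - 1] & v[mid] >= v[mid + 1] & v[mid] > threshold]
      if (!length(loc)) return(tibble::tibble(time = numeric(0), peak_v = numeric(0)))
      dt <- tv[2] - tv[1]
      y1 <- v[loc - 1]; y2 <- v[loc]; y3 <- v[loc + 1]
      den <- y1 - 2 * y2 + y3
      off <- ifelse(den == 0, 0, 0.5 * (y1 - y3) / den)
      tibble::tibble(time = tv[loc] + off * dt,
                     peak_v = y2 - 0.25 * (y1 - y3) * off)
    }) |>
    dplyr::ungroup()
}

#' Conduction velocity between two nodes
#'
#' Velocity is the axial centre-to-centre distance between the two nodes
#' divided by the delay between their first action-potential peaks. The
#' measurement is flagged `blocked` when either node shows no spike;
#' a non-positive delay (possible in this electrotonically compact cable
#' when firing is near-synchronous) is flagged `invalid`.
#'
#' @param trace An [simulate_cable()] trace recorded at nodes.
#' @param from_node,to_node Node numbers (defaults 0 and 6).
#' @param threshold Spike detection threshold, mV.
#' @return A list of class `cv_result`: `velocity` (m/s, NA when not
#'   measurable), `blocked`, `valid`, `distance_um`, `delay_ms`, `spikes`
#'   (first-spike table for every recorded node), `amplitude_nA`,
#'   `condition`.
#' @export
conduction_velocity <- function(trace, from_node = 0, to_node = 6,
                                threshold = 0) {
  stopifnot(inherits(trace, "axon_trace"))
  sp <- detect_spikes(trace, threshold = threshold) |>
    dplyr::group_by(.data$node) |>
    dplyr::slice_min(.data$time, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  pos <- attr(trace, "node_position")
  nodes <- sort(unique(stats::na.omit(trace$node)))
  pos_of <- function(nd) pos[match(nd, nodes)]
  t_from <- sp$time[sp$node == from_node]
  t_to <- sp$time[sp$node == to_node]
  blocked <- length(t_from) == 0 || length(t_to) == 0
  delay <- if (blocked) NA_real_ else t_to - t_from
  valid <- !blocked && delay > 0
  dist <- abs(pos_of(to_node) - pos_of(from_node))
  structure(list(
    velocity = if (valid) dist * 1e-3 / delay else NA_real_,
    blocked = blocked, valid = valid,
    distance_um = dist, delay_ms = delay,
    spikes = sp,
    amplitude_nA = attr(trace, "config")$stimulus$amplitude,
    condition = attr(trace, "condition"),
    from_node = from_node, to_node = to_node,
    n_comp = attr(trace, "n_comp")
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", x$condition, "\n")
  if (x$blocked) {
    cat(sprintf("  conduction BLOCK: no spike at node %d (stimulus %.3g nA)\n",
                x$to_node, x$amplitude_nA))
  } else if (!x$valid) {
    cat(sprintf("  invalid measurement: non-positive delay %.4g ms (near-synchronous firing)\n",
                x$delay_ms))
  } else {
    cat(sprintf("  CV = %.3f m/s over %.1f um (delay %.4g ms, stimulus %.3g nA)\n",
                x$velocity, x$distance_um, x$delay_ms, x$amplitude_nA))
  }
  invisible(x)
}

#' Measure conduction velocity with automatic stimulus escalation
#'
#' Applies the default brief pulse (0.2 nA, 0.2 ms at node 0) and, when that
#' fails to produce a valid node-to-node measurement (sub-threshold for the
#' enlarged AOE node, or a non-positive peak delay), doubles the amplitude on
#' a dyadic ladder until the measurement is valid. The enlarged AOE node has
#' 7.5 times the control capacitance, so no single absolute amplitude can
#' serve every condition; the dyadic ladder keeps the stimulus minimal
#' without per-condition hand tuning.
#'
#' @param cable A [discretize()]d cable.
#' @param config A [sim_config()]; its stimulus amplitude seeds the ladder.
#' @param from_node,to_node Measurement nodes.
#' @param max_doublings Ladder length.
#' @param gna_scale Nav conductance scale (see [find_block_threshold()]).
#' @param escalate Set `FALSE` to run only the configured amplitude.
#' @return A `cv_result` (see [conduction_velocity()]); attribute
#'   `amplitudes_tried` lists the ladder.
#' @export
measure_cv <- function(cable, config = sim_config(), from_node = 0,
                       to_node = attr(cable, "n_nodes") - 1,
                       max_doublings = 5, gna_scale = 1, escalate = TRUE) {
  state <- settle_cable(cable, config, gna_scale)
  amp0 <- config$stimulus$amplitude
  tried <- numeric(0)
  res <- NULL
  for (k in 0:(if (escalate) max_doublings else 0)) {
    amp <- amp0 * 2^k
    tried <- c(tried, amp)
    cfg <- config
    cfg$stimulus$amplitude <- amp
    tr <- simulate_cable(cable, cfg, gna_scale = gna_scale, state = state)
    res <- conduction_velocity(tr, from_node, to_node)
    if (res$valid) break
  }
  attr(res, "amplitudes_tried") <- tried
  res
}

build_condition_cable <- function(condition, internode_length = 100,
                                  n_nodes = 7, affected_inrs = NULL,
                                  params = channel_params(),
                                  max_lambda_fraction = 0.1, ...) {
  axon_spec(condition, internode_length = internode_length, n_nodes = n_nodes,
            affected_inrs = affected_inrs, params = params, ...) |>
    discretize(max_lambda_fraction = max_lambda_fraction)
}

#' Conduction-velocity experiment for one condition
#'
#' Builds the condition's cable and measures CV between the first and last
#' node with the standard stimulus policy ([measure_cv()]).
#'
#' @param condition `"control"`, `"AOE1"` or `"AOE2"`.
#' @param internode_length Node-to-node spacing, um.
#' @param n_nodes Number of nodes.
#' @param affected_inrs Internodes carrying AOE geometry (see [axon_spec()]).
#' @param params A [channel_params()] object.
#' @param config A [sim_config()].
#' @param ... Passed to [axon_spec()].
#' @return A `cv_result`.
#' @examples
#' \donttest{
#' cv_experiment("control")$velocity
#' }
#' @export
cv_experiment <- function(condition = "control", internode_length = 100,
                          n_nodes = 7, affected_inrs = NULL,
                          params = channel_params(), config = sim_config(), ...) {
  cable <- build_condition_cable(condition, internode_length, n_nodes,
                                 affected_inrs, params, ...)
  measure_cv(cable, config)
}

sweep_row <- function(res) {
  tibble::tibble(velocity = res$velocity, blocked = res$blocked,
                 valid = res$valid, delay_ms = res$delay_ms,
                 distance_um = res$distance_um, amplitude_nA = res$amplitude_nA)
}

#' Conduction velocity as a function of internode length
#'
#' Rebuilds the control cable at each internode length and measures CV with
#' the standard stimulus policy. Longer internodes slow this cable down;
#' the curve flattens towards 300 um.
#'
#' @param lengths Internode lengths, um.
#' @param condition Condition to sweep (default control).
#' @param config A [sim_config()].
#' @param ... Passed to [axon_spec()].
#' @return A tibble of class `axon_sweep`: `internode_length`, `velocity`
#'   (m/s), `blocked`, `valid`, `delay_ms`, `distance_um`, `amplitude_nA`.
#' @export
sweep_internode_length <- function(lengths = seq(50, 300, by = 25),
                                   condition = "control",
                                   config = sim_config(), ...) {
  rows <- purrr::map(lengths, function(L) {
    cable <- build_condition_cable(condition, internode_length = L, ...)
    dplyr::bind_cols(tibble::tibble(internode_length = L),
                     sweep_row(measure_cv(cable, config)))
  })
  structure(dplyr::bind_rows(rows),
            class = c("axon_sweep", class(tibble::tibble())),
            sweep_param = "internode_length", condition = condition)
}

#' Conduction velocity as dysmyelination spreads along the axon
#'
#' Applies the AOE geometry to `k` adjacent internodes (counted from the
#' distal end, so the stimulated node 0 keeps control geometry until the
#' whole axon is affected; `k = 0` is exactly the control cable) and
#' measures CV per `k` with the standard stimulus policy.
#'
#' @param condition `"AOE1"` or `"AOE2"`.
#' @param ks Numbers of affected internodes (default 0..n_inr).
#' @param from `"distal"` (default) or `"proximal"`: end from which affected
#'   internodes are counted.
#' @param n_nodes Number of nodes.
#' @param config A [sim_config()].
#' @param ... Passed to [axon_spec()].
#' @return A tibble of class `axon_sweep` with `n_affected` plus the
#'   standard sweep columns.
#' @export
sweep_affected_inrs <- function(condition = c("AOE1", "AOE2"), ks = NULL,
                                from = c("distal", "proximal"), n_nodes = 7,
                                config = sim_config(), ...) {
  condition <- match.arg(condition)
  from <- match.arg(from)
  n_inr <- n_nodes - 1
  if (is.null(ks)) ks <- 0:n_inr
  rows <- purrr::map(ks, function(k) {
    aff <- if (k == 0) integer(0) else if (from == "distal")
      (n_inr - k + 1):n_inr else 1:k
    cable <- build_condition_cable(condition, n_nodes = n_nodes,
                                   affected_inrs = aff, ...)
    dplyr::bind_cols(tibble::tibble(n_affected = k),
                     sweep_row(measure_cv(cable, config)))
  })
  structure(dplyr::bind_rows(rows),
            class = c("axon_sweep", class(tibble::tibble())),
            sweep_param = "n_affected", condition = condition)
}

#' Sodium-conductance fraction at which conduction fails
#'
#' Scales the Nav conductance of every node by a fraction of its control
#' value and tests whether an action potential evoked at node 0 still
#' reaches the last node. A descending coarse grid brackets the transition
#' (erroring if the block/propagate pattern is not monotone), then bisection
#' narrows it to `tol`. The stimulus is the configured pulse, fixed across
#' the sweep.
#'
#' @param cable Cable to test (default: control).
#' @param config A [sim_config()].
#' @param grid Coarse descending fractions used for bracketing.
#' @param tol Bisection tolerance on the fraction (default 0.01 = 1 point).
#' @param to_node Propagation target node.
#' @return A list of class `block_threshold`: `threshold` (largest fraction
#'   at which conduction fails), `threshold_percent`, `history` (tibble of
#'   every fraction tested with `conducts` and `velocity`).
#' @export
find_block_threshold <- function(cable = NULL, config = sim_config(),
                                 grid = seq(1, 0.05, by = -0.05), tol = 0.01,
                                 to_node = NULL) {
  if (is.null(cable)) cable <- build_condition_cable("control")
  if (is.null(to_node)) to_node <- attr(cable, "n_nodes") - 1
  target_comp <- attr(cable, "node_comp")[to_node + 1]

  conducts_at <- function(f) {
    state <- settle_cable(cable, config, gna_scale = f)
    tr <- simulate_cable(cable, config, gna_scale = f, state = state)
    sp <- detect_spikes(tr, nodes = to_node)
    res <- conduction_velocity(tr, to_node = to_node)
    list(conducts = nrow(sp) > 0, velocity = res$velocity)
  }

  hist <- purrr::map(grid, conducts_at)
  history <- tibble::tibble(
    fraction = grid,
    conducts = purrr::map_lgl(hist, "conducts"),
    velocity = purrr::map_dbl(hist, "velocity"),
    phase = "grid"
  )
  if (!history$conducts[1]) {
    rlang::abort("conduction already fails at 100% of control gNa.")
  }
  flips <- sum(diff(history$conducts) != 0)
  if (flips != 1) {
    rlang::abort(sprintf(
      "non-monotone block/propagate pattern over the coarse grid (%d transitions).",
      flips))
  }
  lo <- max(history$fraction[!history$conducts])  # fails
  hi <- min(history$fraction[history$conducts])   # conducts
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    r <- conducts_at(mid)
    history <- dplyr::bind_rows(history,
      tibble::tibble(fraction = mid, conducts = r$conducts,
                     velocity = r$velocity, phase = "bisect"))
    if (r$conducts) hi <- mid else lo <- mid
  }
  structure(list(threshold = lo, threshold_percent = 100 * lo,
                 bracket = c(fails = lo, conducts = hi),
                 history = dplyr::arrange(history, dplyr::desc(.data$fraction)),
                 n_comp = nrow(cable)),
            class = "block_threshold")
}

#' @export
print.block_threshold <- function(x, ...) {
  cat("<block_threshold>\n")
  cat(sprintf("  conduction fails at %.1f%% of control gNa (conducts at %.1f%%)\n",
              x$threshold_percent, 100 * x$bracket[["conducts"]]))
  invisible(x)
}

#' Firing frequency versus injected current
#'
#' Injects a long current pulse (default 200 ms) at node 0 and counts
#' action-potential peaks at a mid-axon node for each amplitude and
#' condition. Frequency is the spike count divided by the pulse duration;
#' `isi_cv` is the coefficient of variation of the inter-spike intervals
#' (NA with fewer than three spikes).
#'
#' @param amplitudes Injected currents, nA.
#' @param conditions Conditions to test.
#' @param pulse_ms Pulse duration, ms.
#' @param record_node Node whose spikes are counted (default 3, mid-axon).
#' @param dt Time step, ms (the long window does not need the microsecond
#'   resolution of the CV protocols).
#' @param ... Passed to [axon_spec()].
#' @return A tibble of class `fi_curve`: `condition`, `amplitude`,
#'   `n_spikes`, `frequency_hz`, `isi_cv`.
#' @export
fi_curve <- function(amplitudes = seq(0.2, 1, by = 0.2),
                     conditions = c("control", "AOE1", "AOE2"),
                     pulse_ms = 200, record_node = 3, dt = 0.0025, ...) {
  rows <- purrr::map(conditions, function(cond) {
    cable <- build_condition_cable(cond, ...)
    cfg <- sim_config(dt = dt, t_stop = pulse_ms + 20,
                      stimulus = stimulus_spec(amplitude = 0, duration = pulse_ms))
    state <- settle_cable(cable, cfg)
    purrr::map(amplitudes, function(a) {
      cfg$stimulus$amplitude <- a
      tr <- simulate_cable(cable, cfg, state = state)
      sp <- detect_spikes(tr, nodes = record_node)
      isi <- diff(sp$time)
      tibble::tibble(condition = cond, amplitude = a, n_spikes = nrow(sp),
                     frequency_hz = nrow(sp) / (pulse_ms / 1000),
                     isi_cv = if (length(isi) >= 3)
                       stats::sd(isi) / mean(isi) else NA_real_)
    }) |> dplyr::bind_rows()
  })
  structure(dplyr::bind_rows(rows),
            class = c("fi_curve", class(tibble::tibble())),
            record_node = record_node, pulse_ms = pulse_ms)
}

#' Nodal leak current during a propagated action potential
#'
#' Runs the standard conduction protocol for each condition with current
#' recording enabled and returns the leak-current time series at one node,
#' overlaid across conditions.
#'
#' @param conditions Conditions to overlay.
#' @param node Recording node.
#' @param config A [sim_config()] (current recording is switched on
#'   internally).
#' @param ... Passed to [axon_spec()].
#' @return A tibble of class `leak_trace`: `condition`, `time`, `v`,
#'   `i_leak` (nA), `amplitude_nA`.
#' @export
nodal_leak_trace <- function(conditions = c("control", "AOE1", "AOE2"),
                             node = 3, config = sim_config(), ...) {
  rows <- purrr::map(conditions, function(cond) {
    cable <- build_condition_cable(cond, ...)
    # find the working amplitude with the standard policy, then re-run
    # recording currents
    res <- measure_cv(cable, config)
    cfg <- config
    cfg$stimulus$amplitude <- res$amplitude_nA
    cfg$record_currents <- TRUE
    tr <- simulate_cable(cable, cfg)
    dplyr::filter(tr, .data$node == !!node) |>
      dplyr::transmute(condition = cond, time = .data$time, v = .data$v,
                       i_leak = .data$i_leak, amplitude_nA = res$amplitude_nA)
  })
  structure(dplyr::bind_rows(rows),
            class = c("leak_trace", class(tibble::tibble())),
            node = node)
}
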