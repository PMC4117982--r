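#' Voltage-gated channel gating-rate parameters
#'
#' Rate constants for the six Hodgkin-Huxley gating variables of the model:
#' `m`, `h` (Nav activation / inactivation), `n`, `p` (Kv3.1 high-threshold
#' activation / modulatory gate) and `l`, `r` (Kv1.1 low-threshold activation /
#' inactivation). Each gate relaxes according to
#' \deqn{dj/dt = \alpha_j(V)\,(1 - j) - \beta_j(V)\, j}
#' with voltage-dependent rates
#' \deqn{\alpha_j(V) = k_{\alpha j}\exp(\eta_{\alpha j} V), \qquad
#'       \beta_j(V)  = k_{\beta j}\exp(\eta_{\beta j} V).}
#'
#' The published rate table gives `k_beta` for the `m` gate as 0.0381 ms^-1.
#' With that value the alpha/beta ratio places sodium half-activation near
#' -95 mV, the channel is open at rest, and the axon cannot hold a resting
#' potential: it is a decimal misprint. The default table therefore carries
#' the repaired value 3.81 ms^-1, which restores half-activation to -37.5 mV
#' (the standard value for auditory brainstem sodium channels), keeps the
#' activation time constant in the tens-of-microseconds range, and yields a
#' stable rest near the leak reversal. Set `beta_m = "printed"` to recover
#' the literal published table.
#'
#' @param beta_m `"repaired"` (default) uses k_beta(m) = 3.81 ms^-1;
#'   `"printed"` uses the published 0.0381 ms^-1.
#' @return A tibble with one row per gate: `gate`, `current`, `role`,
#'   `k_alpha` (ms^-1), `eta_alpha` (mV^-1), `k_beta` (ms^-1),
#'   `eta_beta` (mV^-1).
#' @examples
#' gating_rate_table()
#' gating_rate_table(beta_m = "printed")
#' @export
gating_rate_table <- function(beta_m = c("repaired", "printed")) {
  beta_m <- match.arg(beta_m)
  tbl <- tibble::tribble(
    ~gate, ~current, ~role,           ~k_alpha, ~eta_alpha, ~k_beta, ~eta_beta,
    "m",   "I_Na",   "activation",     76.4,     0.037,      3.81,   -0.043,
    "h",   "I_Na",   "inactivation",    0.00013, -0.1216,    1.999,   0.0384,
    "n",   "I_HT",   "activation",      0.2719,   0.04,      0.1974,  0,
    "p",   "I_HT",   "modulation",      0.00713, -0.1942,    0.0935,  0.0058,
    "l",   "I_LT",   "activation",      1.2,      0.03512,   0.2248, -0.0319,
    "r",   "I_LT",   "inactivation",    0.0438,  -0.0053,    0.0562, -0.0047
  )
  if (beta_m == "printed") tbl$k_beta[tbl$gate == "m"] <- 0.0381
  tbl
}

#' Voltage-dependent opening and closing rates
#'
#' Evaluates \eqn{\alpha_j = k_{\alpha j} e^{\eta_{\alpha j} V}} and
#' \eqn{\beta_j = k_{\beta j} e^{\eta_{\beta j} V}} for every gate in
#' `gates` at every voltage in `v`.
#'
#' @param gates A gating-parameter tibble, usually [gating_rate_table()],
#'   optionally filtered to a subset of gates.
#' @param v Membrane potential(s), mV. Must be finite.
#' @return A tibble with columns `gate`, `v`, `alpha`, `beta` (ms^-1),
#'   one row per gate-voltage combination.
#' @examples
#' gating_rate_table() |> rate_constants(v = 0)
#' @export
rate_constants <- function(gates, v) {
  stopifnot(is.data.frame(gates))
  if (!all(is.finite(v))) {
    rlang::abort("`v` must be finite (membrane potential in mV).")
  }
  tidyr::crossing(gates[, c("gate", "k_alpha", "eta_alpha", "k_beta", "eta_beta")],
                  v = as.numeric(v)) |>
    dplyr::mutate(
      alpha = .data$k_alpha * exp(.data$eta_alpha * .data$v),
      beta  = .data$k_beta * exp(.data$eta_beta * .data$v)
    ) |>
    dplyr::select("gate", "v", "alpha", "beta")
}

#' Gating-variable steady state and time constant
#'
#' Closed form of the gating ODE at equilibrium:
#' \eqn{j_\infty = \alpha/(\alpha+\beta)}, \eqn{\tau = 1/(\alpha+\beta)}.
#'
#' @inheritParams rate_constants
#' @return A tibble with columns `gate`, `v`, `alpha`, `beta`, `j_inf`
#'   (dimensionless, in (0,1)) and `tau` (ms).
#' @examples
#' gating_rate_table() |> gate_steady_state(v = c(-63, 0))
#' @export
gate_steady_state <- function(gates, v) {
  rate_constants(gates, v) |>
    dplyr::mutate(
      j_inf = .data$alpha / (.data$alpha + .data$beta),
      tau   = 1 / (.data$alpha + .data$beta)
    )
}

#' Time derivative of a gating variable
#'
#' \eqn{dj/dt = \alpha(V)(1-j) - \beta(V)\,j}. Zero exactly at
#' \eqn{j = j_\infty(V)}.
#'
#' @inheritParams rate_constants
#' @param j Current gate value(s), each in \[0, 1\]. Recycled against `v`.
#' @return A tibble with columns `gate`, `v`, `j`, `djdt` (ms^-1).
#' @export
gate_derivative <- function(gates, j, v) {
  if (any(!is.finite(j)) || any(j < 0) || any(j > 1)) {
    rlang::abort("gate values `j` must lie in [0, 1].")
  }
  n <- max(length(j), length(v))
  pairs <- tibble::tibble(j = rep_len(as.numeric(j), n), v = rep_len(as.numeric(v), n))
  tidyr::crossing(gates[, c("gate", "k_alpha", "eta_alpha", "k_beta", "eta_beta")], pairs) |>
    dplyr::mutate(
      alpha = .data$k_alpha * exp(.data$eta_alpha * .data$v),
      beta  = .data$k_beta * exp(.data$eta_beta * .data$v),
      djdt  = .data$alpha * (1 - .data$j) - .data$beta * .data$j
    ) |>
    dplyr::select("gate", "v", "j", "djdt")
}

#' Maximal conductance densities and reversal potentials
#'
#' The default (`preset = "methods"`) uses the explicit conductance values of
#' the channel equations: gNa = 50, gHT = 15, gLT = 2 mS cm^-2, with
#' VNa = +50 mV, VHT = VLT = -80 mV, and leak gL = 0.2 mS cm^-2 at
#' VL = -63 mV. The alternative `preset = "nodal_kanemasa"` carries the
#' capacitance-referenced density set also quoted for the nodal region
#' (gNa = 6.6, gHT = 1.98, gLT = 2.13 mS cm^-2); note that set equals the
#' default densities multiplied by the control/AOE nodal area ratio, i.e. it
#' describes channel-number-conserving redistribution over the enlarged node.
#'
#' `gamma` weights the modulatory `p` gate inside the high-threshold current,
#' \eqn{I_{HT} = g_{HT} n^3 (1-\gamma+\gamma p)(V - V_{HT})}; the source
#' model constrains it to (0, 1) without giving a value, so it is exposed
#' here with default 0.1.
#'
#' @param gamma Dimensionless weight of the `p` gate in I_HT, in \[0, 1\].
#' @param preset `"methods"` (default) or `"nodal_kanemasa"`.
#' @param lt_exponents Integer powers applied to the `l` and `r` gates in
#'   I_LT (default `c(l = 1, r = 1)`, exactly as published).
#' @param beta_m Passed to [gating_rate_table()].
#' @return A list of class `channel_params`: conductance densities
#'   (mS cm^-2), reversal potentials (mV), `gamma`, `lt_exponents`, and the
#'   gating-rate tibble.
#' @examples
#' channel_params()
#' channel_params(gamma = 0.5)$gamma
#' @export
channel_params <- function(gamma = 0.1,
                           preset = c("methods", "nodal_kanemasa"),
                           lt_exponents = c(l = 1, r = 1),
                           beta_m = c("repaired", "printed")) {
  preset <- match.arg(preset)
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0 || gamma > 1) {
    rlang::abort("`gamma` must be a single number in [0, 1].")
  }
  dens <- switch(preset,
    methods        = c(g_na = 50,  g_ht = 15,   g_lt = 2),
    nodal_kanemasa = c(g_na = 6.6, g_ht = 1.98, g_lt = 2.13)
  )
  structure(list(
    g_na = unname(dens["g_na"]), g_ht = unname(dens["g_ht"]),
    g_lt = unname(dens["g_lt"]), g_leak = 0.2,
    v_na = 50, v_ht = -80, v_lt = -80, v_leak = -63,
    gamma = gamma,
    lt_exponents = lt_exponents,
    preset = preset,
    gates = gating_rate_table(beta_m = match.arg(beta_m))
  ), class = "channel_params")
}

#' @export
print.channel_params <- function(x, ...) {
  cat("<channel_params>\n")
  cat(sprintf("  preset: %s   gamma: %g\n", x$preset, x$gamma))
  cat(sprintf("  densities (mS/cm2): gNa %g, gHT %g, gLT %g, leak %g\n",
              x$g_na, x$g_ht, x$g_lt, x$g_leak))
  cat(sprintf("  reversals (mV): VNa %g, VHT %g, VLT %g, Vleak %g\n",
              x$v_na, x$v_ht, x$v_lt, x$v_leak))
  invisible(x)
}

#' Ionic membrane current densities
#'
#' Evaluates the four current densities at given gate values and voltage:
#' \deqn{I_{Na} = g_{Na} m^3 h (V - V_{Na})}
#' \deqn{I_{HT} = g_{HT} n^3 (1-\gamma+\gamma p)(V - V_{HT})}
#' \deqn{I_{LT} = g_{LT}\, l\, r\, (V - V_{LT})}
#' \deqn{I_{L}  = g_{L} (V - V_{L})}
#' Currents whose channel is absent from `channels` are exactly zero.
#'
#' @param state A data frame with columns `m`, `h`, `n`, `p`, `l`, `r`
#'   (gate values in \[0,1\]) and `v` (mV), one row per evaluation point.
#' @param params A [channel_params()] object.
#' @param channels Character vector naming the currents present; any of
#'   `"I_Na"`, `"I_HT"`, `"I_LT"`, `"I_L"`.
#' @return The input tibble with added columns `i_na`, `i_ht`, `i_lt`,
#'   `i_leak` and `i_total` (mA cm^-2: mS cm^-2 times mV gives uA cm^-2,
#'   reported here as uA cm^-2).
#' @export
ionic_current_density <- function(state, params = channel_params(),
                                  channels = c("I_Na", "I_HT", "I_LT", "I_L")) {
  stopifnot(is.data.frame(state))
  need <- c("m", "h", "n", "p", "l", "r", "v")
  missing <- setdiff(need, names(state))
  if (length(missing)) {
    rlang::abort(paste0("`state` lacks columns: ", paste(missing, collapse = ", ")))
  }
  gv <- state[, c("m", "h", "n", "p", "l", "r")]
  if (any(gv < 0 | gv > 1)) rlang::abort("gate values must lie in [0, 1].")
  el <- params$lt_exponents
  tibble::as_tibble(state) |>
    dplyr::mutate(
      i_na = if ("I_Na" %in% channels)
        params$g_na * .data$m^3 * .data$h * (.data$v - params$v_na) else 0,
      i_ht = if ("I_HT" %in% channels)
        params$g_ht * .data$n^3 * (1 - params$gamma + params$gamma * .data$p) *
          (.data$v - params$v_ht) else 0,
      i_lt = if ("I_LT" %in% channels)
        params$g_lt * .data$l^el[["l"]] * .data$r^el[["r"]] * (.data$v - params$v_lt) else 0,
      i_leak = if ("I_L" %in% channels)
        params$g_leak * (.data$v - params$v_leak) else 0,
      i_total = .data$i_na + .data$i_ht + .data$i_lt + .data$i_leak
    )
}
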