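test_that("a channel-free cable rests exactly at the leak reversal", {
  cab <- discretize(make_fixture("passive-uniform"))
  st <- settle_cable(cab, sim_config(settle_time = 50, v_init = -63))
  expect_equal(st$v, rep(-63, nrow(cab)), tolerance = 1e-12)
  # and stays flat when simulated without stimulus
  cfg <- sim_config(dt = 0.01, t_stop = 2, settle_time = 5, record = "all",
                    stimulus = stimulus_spec(amplitude = 0, site_comp = 1))
  tr <- simulate_cable(cab, cfg)
  expect_lt(max(abs(tr$v + 63)), 1e-9)
})

test_that("the settled full cable is a fixed point of the dynamics", {
  cab <- control_cable()
  st <- settle_cable(cab, sim_config())
  expect_lt(st$residual, 1e-3)   # mV/ms
  # a further stimulus-free millisecond moves no compartment visibly
  cfg <- sim_config(dt = 0.001, t_stop = 1,
                    stimulus = stimulus_spec(amplitude = 0))
  tr <- simulate_cable(cab, cfg, state = st)
  drift <- max(abs(tr$v - rep(st$v[attr(cab, "node_comp")], each = 1000)))
  expect_lt(drift, 1e-3)
  # resting potential of the control axon (regression constant, emerges from
  # the full channel complement; below the leak reversal because the
  # low-threshold K+ conductance is partly open at rest)
  expect_equal(st$v[attr(cab, "node_comp")[1]], -68.45682873, tolerance = 1e-6)
})

test_that("single passive compartment follows the RC closed form", {
  spec <- passive_single_spec()
  cab <- discretize(spec)
  R <- 1 / cab$g_leak_uS[1]          # MOhm
  C <- cab$c_nF[1]
  tau <- R * C                       # ms
  amp <- 0.001
  for (dt in c(0.02, 0.005)) {
    cfg <- sim_config(dt = dt, t_stop = 5, settle_time = 10, record = "all",
                      stimulus = stimulus_spec(amplitude = amp, duration = 5,
                                               site_comp = 1))
    tr <- simulate_cable(cab, cfg)
    pred <- -63 + amp * R * (1 - exp(-tr$time / tau))
    err <- max(abs(tr$v - pred))
    # backward Euler is first order: error shrinks ~linearly with dt
    if (dt == 0.02) err_coarse <- err else expect_lt(err, err_coarse / 2.5)
  }
  expect_lt(err_coarse, 0.5)
})

test_that("single compartment with the full channel set matches an adaptive ODE oracle", {
  skip_if_not_installed("deSolve")
  cab <- discretize(make_fixture("single-node"))
  cfg <- sim_config(dt = 0.001, t_stop = 5, settle_time = 0, record = "all",
                    stimulus = stimulus_spec(amplitude = 0.1, duration = 5,
                                             site_comp = 1))
  tr <- suppressWarnings(simulate_cable(cab, cfg))

  p <- channel_params()
  gk <- as.matrix(p$gates[, c("k_alpha", "eta_alpha", "k_beta", "eta_beta")])
  C <- cab$c_nF[1]
  gNa <- cab$g_na_uS[1]; gHT <- cab$g_ht_uS[1]; gLk <- cab$g_leak_uS[1]
  deriv <- function(t, y, parms) {
    v <- y[1]; g <- y[-1]
    a <- gk[, 1] * exp(gk[, 2] * v)
    b <- gk[, 3] * exp(gk[, 4] * v)
    w <- 1 - p$gamma + p$gamma * g[4]
    ion <- gNa * g[1]^3 * g[2] * (v - p$v_na) + gHT * g[3]^3 * w * (v - p$v_ht) +
      gLk * (v - p$v_leak)
    list(c((0.1 - ion) / C, a * (1 - g) - b * g))
  }
  a0 <- gk[, 1] * exp(gk[, 2] * -63); b0 <- gk[, 3] * exp(gk[, 4] * -63)
  ref <- deSolve::lsoda(c(-63, a0 / (a0 + b0)), c(0, unique(tr$time)), deriv,
                        rtol = 1e-9, atol = 1e-9)
  expect_lt(max(abs(ref[-1, 2] - tr$v)), 1)   # mV
})

test_that("the C++ engine and the pure-R reference stepper agree", {
  cab <- discretize(make_fixture("mini-3node"))
  cfg <- sim_config(dt = 0.005, t_stop = 2)
  a <- simulate_cable(cab, cfg, backend = "cpp")
  b <- simulate_cable(cab, cfg, backend = "r")
  expect_equal(a$v, b$v, tolerance = 1e-12)
})

test_that("identical runs give identical traces and gates stay bounded", {
  cab <- discretize(make_fixture("mini-3node"))
  cfg <- sim_config(dt = 0.002, t_stop = 2)
  a <- simulate_cable(cab, cfg)
  b <- simulate_cable(cab, cfg)
  expect_identical(a$v, b$v)

  arr <- axonwave:::cable_arrays(cab)
  st <- settle_cable(cab, cfg)
  res <- axonwave:::engine_call(arr, st$v, st$gates, 0.002, 1000,
                                stim_comp = attr(cab, "node_comp")[1],
                                stim_amp = 0.5, stim_from = 0, stim_to = 100,
                                record = 1L)
  expect_true(all(res$gates_final >= 0 & res$gates_final <= 1))
})

test_that("steady point injection decays as exp(-x/lambda) away from source and ends", {
  cab <- discretize(long_passive_spec(6000))
  mid <- round(nrow(cab) / 2)
  cfg <- sim_config(dt = 0.05, t_stop = 300, settle_time = 5, record = "all",
                    stimulus = stimulus_spec(amplitude = 0.01, duration = 300,
                                             site_comp = mid))
  tr <- simulate_cable(cab, cfg)
  vss <- tr$v[tr$time == max(tr$time)]
  dv <- vss + 63
  lam_um <- length_constant(0.625e-4, 1 / 0.2e-3, 70) * 1e4
  x <- cab$position - cab$position[mid]
  sel <- which(x > 150 & x < 1300)   # interior window, >3.8 lambda from the end
  pred <- dv[mid] * exp(-x[sel] / lam_um)
  expect_lt(max(abs(dv[sel] - pred) / pred), 0.05)
})

test_that("membrane charge equals integrated current in a leak-free cable", {
  spec <- axonwave:::new_axon_spec(
    tibble::tibble(kind = "axon", node = NA_integer_, inr = NA_integer_,
                   aoe = FALSE, length = rep(50, 10), diameter = 1.25,
                   cm_specific = 1, g_leak = 0, g_na = 0, g_ht = 0, g_lt = 0),
    condition = "leakless")
  cab <- suppressWarnings(discretize(spec))
  cfg <- sim_config(dt = 0.01, t_stop = 2, settle_time = 0, record = "all",
                    stimulus = stimulus_spec(amplitude = 0.05, duration = 1.2,
                                             site_comp = 3))
  tr <- suppressWarnings(simulate_cable(cab, cfg))
  v_end <- tr$v[tr$time == max(tr$time)]
  dq <- sum(cab$c_nF * (v_end + 63))        # nF * mV = pC
  expect_equal(dq, 0.05 * 1.2, tolerance = 1e-10)  # nA * ms = pC
})

test_that("a too-large step on an active cable aborts with a diagnostic", {
  cab <- control_cable()
  cfg <- sim_config(dt = 5, t_stop = 50,
                    stimulus = stimulus_spec(amplitude = 10, duration = 40))
  # dt = 5 ms cannot resolve the spike; the solve must either stay finite or
  # abort cleanly -- it must never return NaN silently
  out <- tryCatch(simulate_cable(cab, cfg), error = function(e) e)
  if (inherits(out, "error")) {
    expect_match(conditionMessage(out), "dt too large|overflow")
  } else {
    expect_true(all(is.finite(out$v)))
  }
})
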