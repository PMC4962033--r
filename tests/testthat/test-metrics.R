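dense_exp_waveform <- function(tau, t_end = 1.2, dt = 1e-4, tv = 1) {
  tt <- seq(0, t_end, by = dt)
  structure(list(times = tt, v = tv * exp(-tt / tau)),
            class = "volume_waveform")
}

test_that("volume waveforms integrate midpoint flows with a zero baseline", {
  p <- ventilation_protocol()
  expect_equal(volume_waveform(rep(0, 16), p)$v, rep(0, 17))
  # +10 uL/s for the whole 0.15 s inspiration, then a decaying outflow
  fl <- c(rep(10, 5), 10 * 1 / 3, rep(-2, 10))  # frame 6 spans the switch
  vw <- volume_waveform(fl, p)
  expect_equal(max(vw$v) - min(vw$v), tidal_volume(vw))
  expect_equal(min(vw$v), 0)
  # rectangle integration: 5 full + 1 third interval at 10 uL/s
  expect_equal(max(vw$v), 10 * (5 + 1 / 3) * 0.45 / 16 - min(0),
               tolerance = 1e-12)
})

test_that("tidal volume is the waveform excursion and flags non-ventilation", {
  vw <- structure(list(times = 0:4, v = c(0, 2, 5, 3, 0)),
                  class = "volume_waveform")
  expect_equal(tidal_volume(vw), 5)
  p <- ventilation_protocol()
  m <- endpoint_metrics_table(
    structure(list(flows = matrix(0, 1, 16), times = interval_midpoints(p),
                   endpoint_ids = 1L, missing = FALSE), class = "flow_set"),
    v_ee = 10, protocol = p)
  expect_equal(m$tv, 0)
  expect_true(m$nonventilated)
})

test_that("peak expiratory flow takes the largest outward flow in the expiration window", {
  p <- ventilation_protocol()
  fl <- c(rep(5, 5), 2, -8, -4, -2, -1, rep(-0.5, 6))
  pef <- peak_expiratory_flow(fl, p)
  expect_equal(as.numeric(pef), 8)
  expect_false(attr(pef, "flagged"))
  pef0 <- peak_expiratory_flow(rep(0, 16), p)
  expect_equal(as.numeric(pef0), 0)
  expect_true(attr(pef0, "flagged"))
})

test_that("the expiratory time constant is exact for densely sampled exponentials", {
  p <- ventilation_protocol()
  tau <- expiratory_time_constant(dense_exp_waveform(0.10), p)
  expect_equal(as.numeric(tau), 0.10, tolerance = 2e-3)
  expect_false(attr(tau, "censored"))
  # expelled fraction at one time constant is 63% to the nearest percent
  vw <- dense_exp_waveform(0.10)
  i <- which.min(abs(vw$times - 0.10))
  expelled <- (max(vw$v) - vw$v[i]) / tidal_volume(vw)
  expect_equal(round(100 * expelled), 63)
  expect_equal(100 * expelled, 100 * (1 - exp(-1)), tolerance = 0.05)
})

test_that("16-frame sampling recovers tau = 0.12 s within 0.01 s", {
  p <- ventilation_protocol()
  dt <- 0.45 / 16
  tt <- seq(0, 0.45, by = dt)
  vw <- structure(list(times = tt, v = exp(-tt / 0.12)),
                  class = "volume_waveform")
  est <- as.numeric(expiratory_time_constant(vw, p))
  # closed-form oracle: crossing time of the continuous exponential at the
  # threshold fraction of the *measured* excursion
  tvm <- 1 - exp(-0.45 / 0.12)
  oracle <- uniroot(function(t) (1 - exp(-t / 0.12)) - (1 - exp(-1)) * tvm,
                    c(0.01, 0.4), tol = 1e-10)$root
  expect_lt(abs(est - oracle), 0.003)      # linear-interpolation error bound
  expect_lt(abs(est - 0.12), 0.01)
})

test_that("tau_exp is invariant to tidal volume scaling", {
  p <- ventilation_protocol()
  v1 <- dense_exp_waveform(0.14, tv = 1)
  v2 <- dense_exp_waveform(0.14, tv = 37.5)
  expect_equal(as.numeric(expiratory_time_constant(v1, p)),
               as.numeric(expiratory_time_constant(v2, p)))
})

test_that("regions that fail to expel the threshold are censored at the expiration time", {
  p <- ventilation_protocol()
  tt <- seq(0, 0.45, by = 0.45 / 16)
  # deepest point early in the cycle, maximum at end-inspiration, then a
  # shallow decline: less than 63% of the full excursion is expelled
  v <- c(0, 0.1, 0.2, 0.4, 0.7, 1.0, rep(0.95, 11) - 0.005 * 0:10)
  vw <- structure(list(times = tt, v = v), class = "volume_waveform")
  tau <- expiratory_time_constant(vw, p)
  expect_equal(as.numeric(tau), p$t_exp)
  expect_true(attr(tau, "censored"))
})

test_that("the global time constant of a bi-exponential matches a root-finding oracle", {
  p <- ventilation_protocol()
  tt <- seq(0, 2, by = 1e-4)
  v <- 0.5 * exp(-tt / 0.1) + 0.5 * exp(-tt / 0.2)
  vw <- structure(list(times = tt, v = v), class = "volume_waveform")
  est <- as.numeric(global_time_constant(vw, p))
  oracle <- uniroot(function(t) 0.5 * exp(-t / 0.1) + 0.5 * exp(-t / 0.2) - exp(-1),
                    c(0.01, 1), tol = 1e-10)$root
  expect_equal(est, oracle, tolerance = 2e-3)
  # identical compartments: the global constant equals the common one
  v1 <- dense_exp_waveform(0.13, t_end = 2)
  expect_equal(as.numeric(global_time_constant(v1, p)),
               as.numeric(expiratory_time_constant(v1, p)))
})

test_that("the metrics table computes normalized measures and flags", {
  p <- ventilation_protocol()
  # construct a flow waveform with TV = 2 uL and PEF = 10 uL/s
  dt <- 0.45 / 16
  fl <- c(rep(2 / (5 * dt), 5), 0, -10, rep(-(2 - 10 * dt) / (9 * dt), 9))
  flows <- structure(list(flows = rbind(fl), times = interval_midpoints(p),
                          endpoint_ids = 3L, missing = FALSE),
                     class = "flow_set")
  m <- endpoint_metrics_table(flows, v_ee = 40, protocol = p)
  expect_equal(m$tv, 2, tolerance = 1e-9)
  expect_equal(m$pef, 10)
  expect_equal(m$pef_norm, 5, tolerance = 1e-9)
  expect_equal(m$tv_norm, 0.05, tolerance = 1e-9)
  # a missing waveform propagates NA metrics with the flag set
  flows$flows[1, ] <- NA; flows$missing <- TRUE
  m2 <- endpoint_metrics_table(flows, v_ee = 40, protocol = p)
  expect_true(m2$missing)
  expect_true(is.na(m2$tv))
})

test_that("phantom endpoint metrics track the planted mechanics", {
  e2e <- fx_e2e()
  comp <- e2e$ph$mechanics$compartments
  m <- e2e$metrics
  o <- match(comp$endpoint_id, m$endpoint_id)
  # tidal volumes within 5% of the compartment ODE
  tv_true <- apply(e2e$ph$mechanics$volumes, 1, function(v) max(v) - min(v))
  expect_lt(max(abs(m$tv[o] - tv_true) / tv_true), 0.05)
  # estimated tau ranks the planted tau = RC (monotone recovery)
  expect_gt(cor(m$tau_exp[o], comp$tau, method = "spearman"), 0.9)
  # integrated volume waveforms match the ODE cycle within 5% of TV
  for (i in c(1, 8, 16)) {
    vw <- volume_waveform(e2e$flows$flows[i, ], e2e$protocol)
    row <- which(comp$endpoint_id == e2e$flows$endpoint_ids[i])
    vt <- e2e$ph$mechanics$volumes[row, ]
    expect_lt(max(abs(vw$v - (vt - min(vt)))) / tv_true[row], 0.05)
  }
  # global trachea tidal volume is the sum of endpoint tidal volumes
  # (all compartments driven in phase by the square wave)
  trach <- volume_waveform(e2e$seg_flows[e2e$ph$tree$root, ], e2e$protocol)
  expect_equal(tidal_volume(trach), sum(m$tv), tolerance = 0.02 * sum(m$tv))
})
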