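test_that("presets encode calibrated group ground truths", {
  p <- make_preset("FT")
  expect_s3_class(p, "psq_preset")
  expect_equal(p$iv$vm_mV, -25.1)
  expect_equal(p$iv$km_mV, 7.4)
  expect_equal(p$boltzmann$vhalf_mV, -11)
  expect_equal(p$boltzmann$k_mV, 8.9)
  expect_true(p$release$tau_fast_ms < p$release$tau_slow_ms)
  expect_gt(p$release$n_fast, 0)
  expect_gt(p$release$n_slow, 0)

  ## calibration contract: ground-truth 3 ms cumulative equals the fast
  ## pool target and refill-corrected 30 ms cumulative the total target
  rec30 <- simulate_release(p, pool_protocol(30))
  c_at <- function(t) stats::approx(rec30$time_ms, rec30$cumulative, t)$y
  on <- rec30$protocol$onset_ms
  expect_equal(c_at(on + 3), p$release$fast_target, tolerance = 1e-6)
  expect_equal(c_at(on + 30) - 10 * 30, p$release$total_target,
               tolerance = 1e-6)

  ## true I(V) extremum equals the group's maximal current
  vg <- seq(-60, 44, by = 0.02)
  env <- eval_iv_model(vg, list(gamma = p$iv$gamma_scale, e_rev_mV = 45,
                                vm_mV = p$iv$vm_mV, km_mV = p$iv$km_mV))
  expect_equal(max(abs(env)), 925, tolerance = 1e-3)

  d16 <- make_preset("D2016")
  expect_equal(d16$release$fast_target, 357)
  expect_equal(d16$release$total_target, 1061)

  expect_error(make_preset("nope"), "available")
})

test_that("simulated calcium currents reach the analytic steady state", {
  p <- make_preset("FT")

  ## step to the reversal potential: steady-state current ~ 0
  tr <- simulate_ca_current(p, iv_protocol(45, duration_ms = 10))
  tt <- trace_time(tr)
  expect_equal(tr$samples[which.min(abs(tt - 11.9))], 0, tolerance = 1e-6)

  ## strong depolarization: steady state equals Gamma*d(V)*minf^4
  v <- -10
  tr2 <- simulate_ca_current(p, iv_protocol(v, duration_ms = 10))
  minf <- 1 / (1 + exp(-(v - p$iv$vm_mV) / p$iv$km_mV))
  expected <- eval_iv_model(v, list(gamma = p$iv$gamma_scale, e_rev_mV = 45,
                                    vm_mV = p$iv$vm_mV, km_mV = p$iv$km_mV))
  i_ss <- tr2$samples[which.min(abs(trace_time(tr2) - 11.9))]
  expect_equal(i_ss, expected, tolerance = abs(expected) * 0.001)

  ## the I(V) family peaks at the voltage maximizing the model envelope
  volts <- seq(-50, 50, by = 5)
  sweeps <- lapply(volts, function(v) simulate_ca_current(p, iv_protocol(v)))
  ser <- measure_iv_series(sweeps)
  vg <- seq(-50, 50, by = 0.01)
  dense <- eval_iv_model(vg, list(gamma = p$iv$gamma_scale, e_rev_mV = 45,
                                  vm_mV = p$iv$vm_mV, km_mV = p$iv$km_mV))
  v_star <- vg[which.max(abs(dense))]
  expect_equal(ser$step_mV[which.max(abs(ser$peak_pA))],
               volts[which.min(abs(volts - v_star))])

  expect_error(simulate_ca_current(p, iv_protocol(90)), "voltages")
})

test_that("two-pool release obeys single-pool closed form and conservation", {
  prot <- pool_protocol(30)
  ## refill = 0 and a huge slow time constant: single-pool exponential
  rel <- list(n_fast = 1000, n_slow = 1e-9, tau_fast_ms = 1,
              tau_slow_ms = 1e9, latency_ms = 1, refill_SV_per_ms = 0)
  p <- make_preset("FT"); p$release <- rel
  rec <- simulate_release(p, prot)
  t_rel <- 10   # ms after release onset
  idx <- which.min(abs(rec$time_ms - (prot$onset_ms + rel$latency_ms + t_rel)))
  expect_equal(rec$cumulative[idx], 1000 * (1 - exp(-t_rel / 1)),
               tolerance = 1e-6)

  ## conservation with refill = 0: cumulative never exceeds the pools
  rel2 <- list(n_fast = 800, n_slow = 600, tau_fast_ms = 0.5,
               tau_slow_ms = 5, latency_ms = 0.5, refill_SV_per_ms = 0)
  p$release <- rel2
  rec2 <- simulate_release(p, prot)
  expect_true(all(diff(rec2$cumulative) >= -1e-12))
  expect_lte(max(rec2$cumulative), 800 + 600 + 1e-9)
  ## a 30 ms stimulus releases nearly everything (slow pool ~ 6 tau)
  expect_equal(max(rec2$cumulative), 800 + 600, tolerance = 0.005)

  ## with refill: bounded by pools + refill * stimulation time
  p$release <- list(n_fast = 800, n_slow = 600, tau_fast_ms = 0.5,
                    tau_slow_ms = 5, latency_ms = 0.5,
                    refill_SV_per_ms = 10)
  rec3 <- simulate_release(p, prot)
  expect_lte(max(rec3$cumulative), 800 + 600 + 10 * 30)
})

test_that("EPSC rendering is linear, causal, and reproduces the impulse response", {
  p <- make_preset("FT")
  kern <- p$kernel
  prot <- pool_protocol(3)
  rec <- simulate_release(p, prot)

  ## causality: strictly zero before release onset (noiseless)
  tr <- render_epsc(rec, kern)
  before <- trace_time(tr) < prot$onset_ms + p$release$latency_ms
  expect_true(all(tr$samples[before] == 0))

  ## superposition: render(x1 + x2) = render(x1) + render(x2)
  rec1 <- rec; rec2 <- rec
  set.seed(5)
  rec2$rate <- stats::runif(length(rec$rate), 0, 50)
  rec12 <- rec; rec12$rate <- rec1$rate + rec2$rate
  s12 <- render_epsc(rec12, kern)$samples
  s1 <- render_epsc(rec1, kern)$samples
  s2 <- render_epsc(rec2, kern)$samples
  expect_equal(s12, s1 + s2, tolerance = 1e-9)

  ## zero release renders a zero trace
  rec0 <- rec; rec0$rate <- rec$rate * 0
  expect_true(all(render_epsc(rec0, kern)$samples == 0))

  ## single released vesicle: peak ~ q (the residual adds a slow tail of
  ## a few percent at most near the mEPSC peak)
  imp <- rec0
  i1 <- which(rec$time_ms >= 5)[1]
  imp$rate[i1] <- 1 / imp$dt   # one vesicle in one sample interval
  one <- render_epsc(imp, kern)
  expect_equal(max(abs(one$samples)), kern$q_pA, tolerance = 0.05)
  ## and its total, deconvolved back, integrates to 1 SV (see deconv tests)
})

test_that("generators are reproducible under a fixed seed", {
  p <- make_preset("FT")
  em <- make_preset("control-EM")
  f1 <- simulate_em_field(em, 5, seed = 42)
  f2 <- simulate_em_field(em, 5, seed = 42)
  expect_identical(f1, f2)

  set.seed(9); a <- simulate_ca_current(p, pool_protocol(3), noiseless = FALSE)
  set.seed(9); b <- simulate_ca_current(p, pool_protocol(3), noiseless = FALSE)
  expect_identical(a, b)
})

test_that("EM fields respect preset geometry and rates", {
  em <- make_preset("control-EM")

  ## docked_mean = 0: no vesicle with edge distance < 5 nm
  em0 <- em; em0$docked_mean_per_AZ <- 0
  fields <- simulate_em_field(em0, 50, seed = 1)
  docked <- docked_summary(fields)
  expect_equal(docked$mean, 0)

  ## expected background count per AZ ~ density * length * 195 (Poisson)
  em_bg <- em; em_bg$docked_mean_per_AZ <- 0
  fields2 <- simulate_em_field(em_bg, 400, seed = 2)
  counts <- vapply(fields2, function(f) nrow(f$vesicles), numeric(1))
  lens <- vapply(fields2, az_length, numeric(1))
  expected <- em_bg$background_density * mean(lens) * 195
  se <- sqrt(mean(counts)) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.5)

  ## AZ lengths truncated above 50 nm
  expect_true(all(lens > 50))
})
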