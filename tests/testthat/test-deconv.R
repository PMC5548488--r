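make_ft <- function() {
  p <- make_preset("FT")
  list(p = p, cfg = deconv_config(p$kernel))
}

test_that("deconvolution inverts impulses and zero traces exactly", {
  ft <- make_ft()
  prot <- pool_protocol(3)
  rec <- simulate_release(ft$p, prot)

  ## single rendered mEPSC (+ residual): recovered release integrates to 1
  imp <- rec; imp$rate <- rec$rate * 0
  imp$rate[which(rec$time_ms >= 5)[1]] <- 1 / imp$dt
  epsc <- render_epsc(imp, ft$p$kernel)
  est <- deconvolve(epsc, ft$cfg)
  expect_equal(sum(est$rate) * est$dt, 1, tolerance = 1e-3)

  ## zero EPSC gives zero release
  z <- new_trace(rep(0, 500), dt = 0.02, protocol = prot)
  est0 <- deconvolve(z, ft$cfg)
  expect_true(all(est0$rate == 0))
  expect_true(all(est0$cumulative == 0))
})

test_that("forward-inverse round trip recovers the release rate", {
  ft <- make_ft()
  prot <- pool_protocol(30)
  rec <- simulate_release(ft$p, prot)
  epsc <- render_epsc(rec, ft$p$kernel)
  est <- deconvolve(epsc, ft$cfg)
  l1 <- sum(abs(est$rate - rec$rate)) / sum(rec$rate)
  expect_lt(l1, 0.02)

  ## cumulative is non-decreasing; corrected never exceeds uncorrected
  expect_true(all(diff(est$cumulative) >= -1e-9))
  expect_true(all(est$cumulative_corrected <= est$cumulative + 1e-9))
})

test_that("the O(n) recursion equals the literal triangular solve", {
  ft <- make_ft()
  prot <- pool_protocol(3)
  rec <- simulate_release(ft$p, prot)
  epsc <- render_epsc(rec, ft$p$kernel)
  fast <- deconvolve(epsc, ft$cfg)
  dense <- deconvolve(epsc, ft$cfg, dense = TRUE)
  expect_equal(fast$rate, dense$rate, tolerance = 1e-9)
})

test_that("deconvolution is linear in the EPSC", {
  ft <- make_ft()
  rec <- simulate_release(ft$p, pool_protocol(3))
  epsc <- render_epsc(rec, ft$p$kernel)
  est1 <- deconvolve(epsc, ft$cfg)
  epsc3 <- epsc; epsc3$samples <- 3 * epsc$samples
  est3 <- deconvolve(epsc3, ft$cfg)
  expect_equal(est3$rate, 3 * est1$rate, tolerance = 1e-9)
})

test_that("quantal-size mismatch propagates reciprocally into pools", {
  ft <- make_ft()
  rec <- simulate_release(ft$p, pool_protocol(3))
  epsc <- render_epsc(rec, ft$p$kernel)
  k_off <- ft$p$kernel; k_off$q_pA <- 1.1 * ft$p$kernel$q_pA
  cfg_off <- deconv_config(k_off)
  fast_true <- pool_sizes(deconvolve(epsc, ft$cfg), ft$cfg)$fast_SV
  fast_off <- pool_sizes(deconvolve(epsc, cfg_off), cfg_off)$fast_SV
  expect_equal(fast_off / fast_true, 1 / 1.1, tolerance = 0.01)
})

test_that("pool sizes follow the analytic constant-rate example", {
  ## constant 100 SV/ms over a 30 ms stimulus, refill 10 SV/ms:
  ## fast = 300 SV, total = 3000 - 300 = 2700 SV
  prot <- step_protocol(-80, 0, onset_ms = 2, duration_ms = 30)
  tt <- seq(0, 36, by = 0.02)
  rate <- ifelse(tt >= 2 & tt < 32, 100, 0)
  est <- structure(list(time_ms = tt, rate = rate,
                        cumulative = cumsum(rate) * 0.02,
                        cumulative_corrected = NULL, dt = 0.02,
                        protocol = prot),
                   class = "psq_release_estimate")
  cfg <- deconv_config(mepsc_kernel(q_pA = 10))
  pools <- pool_sizes(est, cfg)
  expect_equal(pools$fast_SV, 300, tolerance = 0.01)
  expect_equal(pools$total_SV, 2700, tolerance = 0.01)

  ## zero release: fast 0 and the negative corrected total clamps to 0
  est0 <- est; est0$rate <- rate * 0; est0$cumulative <- est$cumulative * 0
  p0 <- pool_sizes(est0, cfg)
  expect_equal(p0$fast_SV, 0)
  expect_equal(p0$total_SV, 0)
  expect_true(any(grepl("clamped", p0$flags)))

  ## stimulus shorter than the fast-pool clock is flagged
  prot3 <- step_protocol(-80, 0, onset_ms = 2, duration_ms = 2)
  est3 <- est; est3$protocol <- prot3
  expect_true(any(grepl("shorter", pool_sizes(est3, cfg)$flags)))
})

test_that("normalized cumulative release ends at 1 and matches closed forms", {
  ft <- make_ft()
  rec <- simulate_release(ft$p, pool_protocol(30))
  est <- deconvolve(render_epsc(rec, ft$p$kernel), ft$cfg)
  nc <- normalized_cumulative(est)
  end_idx <- which.min(abs(nc$time_ms - (4 + 30)))
  expect_equal(nc$fraction[end_idx], 1, tolerance = 1e-3)

  ## single-exponential release normalizes to 1 - exp(-t/tau)
  prot <- step_protocol(-80, 0, onset_ms = 2, duration_ms = 30)
  tt <- seq(0, 36, by = 0.02)
  tau <- 2
  rate <- ifelse(tt >= 2 & tt < 32, exp(-(pmax(tt - 2, 0)) / tau), 0) * 500
  est1 <- structure(list(time_ms = tt, rate = rate,
                         cumulative = cumsum(rate) * 0.02, dt = 0.02,
                         protocol = prot),
                    class = "psq_release_estimate")
  nc1 <- normalized_cumulative(est1)
  sel <- tt > 2 & tt < 20
  expected <- (1 - exp(-(tt[sel] - 2) / tau)) / (1 - exp(-30 / tau))
  expect_equal(nc1$fraction[sel], expected, tolerance = 0.01)

  est1$cumulative <- est1$cumulative * 0
  expect_error(normalized_cumulative(est1), "zero total")

  ## larger fast fraction puts the FT curve above D2016 at 3 ms
  d16 <- make_preset("D2016")
  est16 <- deconvolve(
    render_epsc(simulate_release(d16, pool_protocol(30)), d16$kernel),
    deconv_config(d16$kernel))
  at3 <- function(e) {
    nce <- normalized_cumulative(e)
    stats::approx(nce$time_ms, nce$fraction, 4 + 3)$y
  }
  expect_gt(at3(est), at3(est16))
})

test_that("pool report reproduces group ground truths and ratio conventions", {
  ft <- make_ft()
  s3 <- simulate_pool_sweep(ft$p, 3)
  s30 <- simulate_pool_sweep(ft$p, 30)
  rep <- build_pool_report(s3$ica, s3$epsc, s30$ica, s30$epsc, ft$cfg)
  expect_equal(rep$fast_pool_SV, 1505, tolerance = 0.01)
  expect_equal(rep$total_pool_SV, 2152, tolerance = 0.01)
  expect_equal(rep$epsc_amp_3ms_nA, 8.54, tolerance = 0.01)

  ## identical sweeps for both protocols: amplitude ratio exactly 1
  rep_same <- build_pool_report(s3$ica, s3$epsc, s3$ica, s3$epsc, ft$cfg)
  expect_equal(rep_same$ratio_3_30, 1)

  ## fast-pool deficit lowers the mutant ratio below control
  d16 <- make_preset("D2016")
  cfg16 <- deconv_config(d16$kernel)
  m3 <- simulate_pool_sweep(d16, 3)
  m30 <- simulate_pool_sweep(d16, 30)
  rep16 <- build_pool_report(m3$ica, m3$epsc, m30$ica, m30$epsc, cfg16)
  expect_lt(rep16$ratio_3_30, rep$ratio_3_30)

  ## missing sweep yields a flagged partial report
  part <- build_pool_report(s3$ica, s3$epsc, NULL, NULL, ft$cfg)
  expect_true(any(grepl("30 ms", part$flags)))
  expect_true(is.na(part$total_pool_SV))
  expect_equal(part$fast_pool_SV, 1505, tolerance = 0.01)
})

test_that("non-negativity clamp and smoothing behave as configured", {
  ft <- make_ft()
  rec <- simulate_release(ft$p, pool_protocol(3))
  set.seed(77)
  epsc <- render_epsc(rec, ft$p$kernel, noiseless = FALSE, noise_sd = 20)
  cfg_nn <- deconv_config(ft$p$kernel, nonneg = TRUE)
  est <- deconvolve(epsc, cfg_nn)
  expect_true(all(est$rate >= 0))

  cfg_sm <- deconv_config(ft$p$kernel, smoothing_lambda = 10)
  est_sm <- deconvolve(epsc, cfg_sm)
  est_raw <- deconvolve(epsc, deconv_config(ft$p$kernel))
  expect_lt(sum(diff(est_sm$rate)^2), sum(diff(est_raw$rate)^2))
})
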