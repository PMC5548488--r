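## GHK open-channel driving force d(V), continuous at V = 0 via the
## analytic limit: d(V) = V * (1 - exp(-(V-Erev)/25)) / (1 - exp(-V/25));
## lim_{V->0} d(V) = 25 * (1 - exp(Erev/25)).  The 25 mV constant is the
## thermal voltage printed in the model and is never fitted.  Negative
## (inward) below the reversal potential, zero at V = Erev.
ghk_drive <- function(v_mV, e_rev_mV, thermal_mV = 25) {
  out <- numeric(length(v_mV))
  small <- abs(v_mV) < 1e-9
  out[small] <- thermal_mV * (1 - exp(e_rev_mV / thermal_mV))
  vb <- v_mV[!small]
  out[!small] <- vb * (1 - exp(-(vb - e_rev_mV) / thermal_mV)) /
    (1 - exp(-vb / thermal_mV))
  out
}

#' Evaluate the I(V) channel model
#'
#' Hodgkin-Huxley formalism with four independent activation gates on a
#' Goldman-Hodgkin-Katz open-channel driving force:
#' \deqn{I(V) = \Gamma \; d(V) \; \left[1 + e^{-(V - V_m)/k_m}\right]^{-4}}
#' where \eqn{d(V) = V\,(1 - e^{-(V-E_{rev})/25})/(1 - e^{-V/25})} (thermal
#' constant fixed at 25 mV), continuous at \eqn{V = 0} via its analytic
#' limit.  Returns signed current in pA: inward (negative) below the
#' reversal potential for \eqn{\Gamma > 0}.
#'
#' @param v_mV Voltage(s) in mV.
#' @param params List or `psq_iv_fit` with `gamma`, `e_rev_mV`, `vm_mV`,
#'   `km_mV`.
#' @return Current(s) in pA, signed.
#' @export
eval_iv_model <- function(v_mV, params) {
  gate <- (1 + exp(-(v_mV - params$vm_mV) / params$km_mV))^(-4)
  params$gamma * ghk_drive(v_mV, params$e_rev_mV) * gate
}

#' Assemble an I(V) series
#'
#' @param step_mV Step voltages (mV), strictly increasing and unique.
#' @param peak_pA Signed peak currents (pA, inward negative).
#' @param ca_mM External calcium concentration annotation.
#' @return A data frame of class `psq_iv_series`.
#' @export
iv_series <- function(step_mV, peak_pA, ca_mM = 1) {
  stopifnot(length(step_mV) == length(peak_pA),
            !is.unsorted(step_mV, strictly = TRUE))
  structure(data.frame(step_mV = step_mV, peak_pA = peak_pA),
            ca_mM = ca_mM, class = c("psq_iv_series", "data.frame"))
}

#' Measure an I(V) family from simulated or recorded sweeps
#'
#' Takes the signed peak current during the step window of each sweep.
#'
#' @param sweeps List of `psq_trace` objects with protocols attached.
#' @return A `psq_iv_series`.
#' @export
measure_iv_series <- function(sweeps) {
  v <- vapply(sweeps, function(s) s$protocol$step_mV, numeric(1))
  pk <- vapply(sweeps, function(s) {
    p <- s$protocol
    ## strictly inside the step so the repolarization tail is excluded
    win <- c(p$onset_ms, p$onset_ms + p$duration_ms - s$dt / 2)
    tt <- trace_time(s)
    base <- trace_baseline(s)
    sel <- tt >= win[1] & tt <= win[2]
    dev <- s$samples[sel] - base
    dev[which.max(abs(dev))]
  }, numeric(1))
  ord <- order(v)
  iv_series(v[ord], pk[ord])
}

## jitter offsets for multi-start fitting (fixed, no RNG)
.fit_jitter <- rbind(c(0, 0, 0, 0),
                     c(5, 2, 10, 0.3),
                     c(-5, -2, -10, -0.3),
                     c(8, 4, -15, 0.5),
                     c(-8, -4, 15, -0.5))

#' Fit the I(V) channel model
#'
#' Least-squares fit of [eval_iv_model()] to signed (voltage, peak current)
#' pairs by Levenberg-Marquardt with multi-start initialization: the
#' half-activation voltage is seeded from the half-maximum of the
#' normalized gating envelope, the reversal potential from linear
#' extrapolation of the zero crossing beyond the I(V) minimum, the slope
#' from a standard value, and the scale from the peak magnitude; five
#' deterministic jittered restarts are tried and the best residual sum of
#' squares wins.
#'
#' @param series A `psq_iv_series` with at least 6 points.
#' @param init Optional list with starting values `gamma`, `e_rev_mV`,
#'   `vm_mV`, `km_mV`.
#' @return An object of class `psq_iv_fit`: `gamma`, `e_rev_mV`, `vm_mV`,
#'   `km_mV`, `thermal_mV` (fixed 25), `rss`, and `imax_pA`, the
#'   fitted-curve extremum magnitude on a dense voltage grid.
#' @export
fit_iv <- function(series, init = NULL) {
  stopifnot(inherits(series, "psq_iv_series"))
  if (nrow(series) < 6) stop("need at least 6 I(V) points")
  v <- series$step_mV; y <- series$peak_pA
  if (all(y == 0)) stop("degenerate I(V) series: all peaks zero")

  if (is.null(init)) {
    ## reversal potential: zero crossing extrapolated from the outermost
    ## rising limb beyond the current minimum
    i_min <- which.min(y)
    erev0 <- if (i_min < length(v)) {
      ii <- seq.int(max(i_min, length(v) - 2L), length(v))
      if (length(ii) >= 2 && stats::sd(y[ii]) > 0) {
        cf <- stats::coef(stats::lm(y[ii] ~ v[ii]))
        max(min(-cf[1] / cf[2], 70), v[length(v)] + 5)
      } else 45
    } else 45
    ## gating envelope: I / d(V), normalized; half-max -> vm
    drv <- ghk_drive(v, erev0)
    gate <- ifelse(abs(drv) > 1e-6, y / drv, NA)
    gate <- gate / max(gate, na.rm = TRUE)
    above <- which(gate >= 0.5)
    vm0 <- if (length(above)) v[above[1]] else -20
    init <- list(gamma = max(abs(y)) / max(abs(drv)) * 2, e_rev_mV = erev0,
                 vm_mV = vm0, km_mV = 8)
  }

  best <- NULL
  for (j in seq_len(nrow(.fit_jitter))) {
    st <- list(gamma = init$gamma * (1 + .fit_jitter[j, 4] / 2),
               e_rev_mV = init$e_rev_mV + .fit_jitter[j, 3],
               vm_mV = init$vm_mV + .fit_jitter[j, 1],
               km_mV = max(init$km_mV + .fit_jitter[j, 2], 1))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ eval_iv_model(v, list(gamma = gamma, e_rev_mV = e_rev_mV,
                                  vm_mV = vm_mV, km_mV = km_mV)),
        start = st,
        lower = c(gamma = 1e-6, e_rev_mV = 0, vm_mV = -80, km_mV = 0.5),
        upper = c(gamma = Inf, e_rev_mV = 100, vm_mV = 40, km_mV = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("I(V) fit failed to converge from all starts")
  cf <- as.list(stats::coef(best$fit))
  pars <- list(gamma = cf$gamma, e_rev_mV = cf$e_rev_mV, vm_mV = cf$vm_mV,
               km_mV = cf$km_mV)
  vg <- seq(min(v), max(cf$e_rev_mV - 0.1, max(v)), by = 0.05)
  imax <- max(abs(eval_iv_model(vg, pars)))
  structure(c(pars, list(thermal_mV = 25, rss = best$rss, imax_pA = imax)),
            class = "psq_iv_fit")
}

#' @export
print.psq_iv_fit <- function(x, ...) {
  cat(sprintf(
    "<psq_iv_fit> Vm = %.2f mV, km = %.2f mV, Erev = %.1f mV, Gamma = %.3g\n",
    x$vm_mV, x$km_mV, x$e_rev_mV, x$gamma))
  cat(sprintf("  |I|max = %.1f pA, rss = %.3g\n", x$imax_pA, x$rss))
  invisible(x)
}

#' Extract tail-current amplitudes from a sweep family
#'
#' For each sweep, the baseline is the steady level well after the tail
#' has deactivated and the tail amplitude is the extremum magnitude within
#' 1 ms after repolarization, minus baseline (signed, inward negative).
#'
#' @param sweeps List of `psq_trace` objects (protocol attached).
#' @param repol_ms Repolarization time; defaults to each sweep's step end.
#' @return Data frame `(step_mV, tail_pA)` sorted by voltage.
#' @export
extract_tail_amplitudes <- function(sweeps, repol_ms = NULL) {
  res <- lapply(sweeps, function(s) {
    p <- s$protocol
    rp <- if (is.null(repol_ms)) p$onset_ms + p$duration_ms else repol_ms
    tt <- trace_time(s)
    if (rp >= tt[length(tt)]) stop("repolarization time beyond trace end")
    win <- tt >= rp & tt <= rp + 1
    if (!any(win)) stop("empty tail window")
    late <- tt >= rp + 4 & tt <= rp + 5
    if (!any(late)) late <- tt >= tt[length(tt)] - 1
    base <- mean(s$samples[late])
    dev <- s$samples[win] - base
    data.frame(step_mV = p$step_mV, tail_pA = dev[which.max(abs(dev))])
  })
  out <- do.call(rbind, res)
  out[order(out$step_mV), , drop = FALSE]
}

#' Fit a Boltzmann activation curve to tail currents
#'
#' Least-squares fit of
#' \deqn{I_{tail}(V) = I_{base} + I_{min} / (1 + e^{-(V - V_{1/2})/k})}
#' performed on tail-current magnitudes (with the saturating amplitude
#' constrained positive); the sign of the base and saturating amplitudes
#' is restored on report so inward tails are negative.
#'
#' @param points Data frame with `step_mV` and `tail_pA` (signed), at
#'   least 5 points.
#' @return An object of class `psq_boltzmann_fit`: `ibase_pA`, `imin_pA`,
#'   `vhalf_mV`, `k_mV`, `rss`.
#' @export
fit_tail_boltzmann <- function(points) {
  stopifnot(all(c("step_mV", "tail_pA") %in% names(points)))
  if (nrow(points) < 5) stop("need at least 5 tail points")
  v <- points$step_mV
  sgn <- if (sum(points$tail_pA) <= 0) -1 else 1
  m <- abs(points$tail_pA)
  if (stats::sd(m) == 0)
    stop("degenerate tail series: constant amplitudes, slope unidentifiable")
  span <- max(m) - min(m)
  vh0 <- v[which.min(abs(m - (min(m) + span / 2)))]
  best <- NULL
  for (j in seq_len(nrow(.fit_jitter))) {
    st <- list(ibase = min(m), imin = span * (1 + .fit_jitter[j, 4] / 2),
               vhalf = vh0 + .fit_jitter[j, 1],
               k = max(8 + .fit_jitter[j, 2], 0.5))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        m ~ ibase + imin / (1 + exp(-(v - vhalf) / k)),
        start = st,
        lower = c(ibase = -Inf, imin = 0, vhalf = -100, k = 0.1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("Boltzmann tail fit failed to converge")
  cf <- as.list(stats::coef(best$fit))
  structure(list(ibase_pA = sgn * cf$ibase, imin_pA = sgn * cf$imin,
                 vhalf_mV = cf$vhalf, k_mV = cf$k, rss = best$rss),
            class = "psq_boltzmann_fit")
}

#' @export
print.psq_boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<psq_boltzmann_fit> V1/2 = %.2f mV, k = %.2f mV, Imin = %.1f pA\n",
    x$vhalf_mV, x$k_mV, x$imin_pA))
  invisible(x)
}

#' Evaluate a fitted Boltzmann curve
#' @param v_mV Voltage(s) in mV.
#' @param fit A `psq_boltzmann_fit` (or compatible list).
#' @return Signed tail current(s) in pA.
#' @export
eval_boltzmann <- function(v_mV, fit) {
  fit$ibase_pA + fit$imin_pA / (1 + exp(-(v_mV - fit$vhalf_mV) / fit$k_mV))
}
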