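#' Uniformly sampled current trace
#'
#' The common currency of all electrophysiology stages: a uniformly sampled
#' current time series in pA (inward currents negative) together with its
#' sampling interval, start time and, optionally, the stimulus protocol that
#' produced it.
#'
#' @param samples Numeric vector of current values in pA, inward negative.
#' @param dt Sampling interval in ms (default 0.02 ms, i.e. 50 kHz).
#' @param t0 Time of the first sample in ms.
#' @param label Free-text label.
#' @param protocol A [step_protocol()] object or `NULL`.
#' @return An object of class `psq_trace`.
#' @export
new_trace <- function(samples, dt = 0.02, t0 = 0, label = "", protocol = NULL) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop("'samples' must be a numeric vector of length >= 2")
  if (!all(is.finite(samples))) stop("all samples must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("'dt' must be > 0")
  structure(
    list(samples = as.numeric(samples), dt = dt, t0 = t0,
         label = as.character(label)[1L], protocol = protocol),
    class = "psq_trace")
}

#' @export
print.psq_trace <- function(x, ...) {
  cat(sprintf("<psq_trace> %s: %d samples, dt = %g ms, t = [%g, %g] ms\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$samples), x$dt, x$t0,
              x$t0 + (length(x$samples) - 1L) * x$dt))
  invisible(x)
}

#' Time axis of a trace
#' @param trace A `psq_trace`.
#' @return Numeric vector of sample times in ms.
#' @export
trace_time <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) * trace$dt
}

#' Step-depolarization stimulus protocol
#'
#' Describes a voltage-clamp step: holding potential, step potential, step
#' onset and duration, and an optional brief pre-depolarization immediately
#' preceding the step (used by the vesicle-pool protocols, where a 2 ms jump
#' to a potential near the calcium reversal potential opens channels with
#' minimal influx before the release-triggering 0 mV step).
#'
#' @param holding_mV Holding potential (mV).
#' @param step_mV Step potential (mV).
#' @param onset_ms Start time of the main step (ms).
#' @param duration_ms Duration of the main step (ms), > 0.
#' @param pre_pulse Optional `list(level_mV=, duration_ms=)`; the pre-pulse
#'   ends exactly at `onset_ms`.
#' @return An object of class `psq_protocol`.
#' @export
step_protocol <- function(holding_mV, step_mV, onset_ms, duration_ms,
                          pre_pulse = NULL) {
  if (duration_ms <= 0) stop("'duration_ms' must be > 0")
  if (onset_ms < 0) stop("'onset_ms' must be >= 0")
  if (!is.null(pre_pulse)) {
    stopifnot(is.list(pre_pulse), pre_pulse$duration_ms > 0,
              pre_pulse$duration_ms <= onset_ms)
  }
  structure(list(holding_mV = holding_mV, step_mV = step_mV,
                 onset_ms = onset_ms, duration_ms = duration_ms,
                 pre_pulse = pre_pulse),
            class = "psq_protocol")
}

#' Vesicle-pool stimulation protocol
#'
#' The standard pool-depleting stimulus: from a holding potential of -80 mV,
#' a 2 ms pre-depolarization to +70 mV followed by a step to 0 mV for 3 ms
#' (fast pool) or 30 ms (total releasable pool).
#'
#' @param duration_ms Duration of the 0 mV step, usually 3 or 30.
#' @return A `psq_protocol`.
#' @export
pool_protocol <- function(duration_ms = 3) {
  step_protocol(holding_mV = -80, step_mV = 0, onset_ms = 4,
                duration_ms = duration_ms,
                pre_pulse = list(level_mV = 70, duration_ms = 2))
}

#' Current-voltage protocol
#'
#' A single 10 ms step from -80 mV used to build I(V) families.
#'
#' @param step_mV Step potential (mV).
#' @param duration_ms Step duration (ms).
#' @return A `psq_protocol`.
#' @export
iv_protocol <- function(step_mV, duration_ms = 10) {
  step_protocol(holding_mV = -80, step_mV = step_mV, onset_ms = 2,
                duration_ms = duration_ms)
}

## time at which the voltage first leaves holding (pre-pulse start if any)
stim_start <- function(protocol) {
  if (is.null(protocol)) stop("trace has no protocol attached")
  if (!is.null(protocol$pre_pulse))
    protocol$onset_ms - protocol$pre_pulse$duration_ms
  else protocol$onset_ms
}

## mean current over the 2 ms immediately preceding the first voltage
## excursion (or an explicit interval)
trace_baseline <- function(trace, baseline_window = NULL) {
  tt <- trace_time(trace)
  if (is.null(baseline_window)) {
    s <- stim_start(trace$protocol)
    baseline_window <- c(max(trace$t0, s - 2), s)
  }
  sel <- tt >= baseline_window[1] & tt < baseline_window[2]
  if (!any(sel)) sel <- seq_len(min(10L, length(tt)))
  mean(trace$samples[sel])
}

## linear interpolation of the earliest upward crossing of `level` by `y`
## between consecutive samples restricted to indices [i1, i2]
interp_crossing <- function(tt, y, level, i1, i2) {
  idx <- seq.int(i1, i2 - 1L)
  hit <- which(y[idx] < level & y[idx + 1L] >= level)
  if (length(hit) == 0L) return(NA_real_)
  i <- idx[hit[length(hit)]]  # last crossing before the peak: rising phase
  frac <- (level - y[i]) / (y[i + 1L] - y[i])
  tt[i] + frac * (tt[i + 1L] - tt[i])
}

#' Peak amplitude of a trace
#'
#' Baseline-subtracted extremum magnitude within a window.  The baseline is
#' the mean over the 2 ms immediately preceding stimulus onset (or an
#' explicit interval).  Inward deflections are reported as positive
#' magnitudes; ties are broken by the earliest sample.
#'
#' @param trace A `psq_trace`.
#' @param window Numeric length-2 time interval in ms; default is from
#'   stimulus onset to the end of the trace.
#' @param baseline_window Optional explicit baseline interval in ms.
#' @return `list(amplitude, time_ms, baseline)`; amplitude in pA, positive.
#' @export
peak_amplitude <- function(trace, window = NULL, baseline_window = NULL) {
  tt <- trace_time(trace)
  if (is.null(window)) {
    window <- c(if (!is.null(trace$protocol)) trace$protocol$onset_ms
                else trace$t0, tt[length(tt)])
  }
  if (window[1] < trace$t0 - 1e-9 || window[2] > tt[length(tt)] + 1e-9)
    stop("'window' outside trace extent")
  base <- if (is.null(trace$protocol) && is.null(baseline_window)) 0
          else trace_baseline(trace, baseline_window)
  sel <- which(tt >= window[1] & tt <= window[2])
  dev <- abs(trace$samples[sel] - base)
  if (max(dev) == 0)
    return(list(amplitude = 0, time_ms = window[1], baseline = base))
  i <- sel[which.max(dev)]
  list(amplitude = abs(trace$samples[i] - base), time_ms = tt[i],
       baseline = base)
}

#' 10-90% rise time
#'
#' Time between the 10% and 90% crossings of the baseline-subtracted peak
#' amplitude on the rising phase, each located by linear interpolation
#' between samples.
#'
#' @param trace A `psq_trace` containing a well-defined peak.
#' @param window Optional search window (ms) passed to [peak_amplitude()].
#' @param baseline_window Optional baseline interval (ms).
#' @return Rise time in ms.
#' @export
rise_time_10_90 <- function(trace, window = NULL, baseline_window = NULL) {
  pk <- peak_amplitude(trace, window, baseline_window)
  if (pk$amplitude <= 0) stop("trace has no peak; rise time undefined")
  tt <- trace_time(trace)
  dev <- abs(trace$samples - pk$baseline)
  ipk <- which.min(abs(tt - pk$time_ms))
  t10 <- interp_crossing(tt, dev, 0.10 * pk$amplitude, 1L, ipk)
  t90 <- interp_crossing(tt, dev, 0.90 * pk$amplitude, 1L, ipk)
  if (is.na(t10) || is.na(t90))
    stop("threshold crossing not found; rise time undefined")
  t90 - t10
}

## onset of a current: first time after stimulus onset at which the
## baseline-subtracted magnitude exceeds 5% of its eventual peak, refined by
## linear interpolation
current_onset <- function(trace, frac = 0.05) {
  pk <- peak_amplitude(trace)
  if (pk$amplitude <= 0) stop("flat trace: onset undetectable")
  tt <- trace_time(trace)
  dev <- abs(trace$samples - pk$baseline)
  i0 <- which(tt >= trace$protocol$onset_ms)[1L]
  ipk <- which.min(abs(tt - pk$time_ms))
  if (dev[i0] >= frac * pk$amplitude) return(tt[i0])
  on <- interp_crossing(tt, dev, frac * pk$amplitude, i0, ipk)
  if (is.na(on)) stop("onset undetectable")
  on
}

#' Synaptic delay
#'
#' Duration between the onset of the presynaptic calcium current (first time
#' its magnitude exceeds 5% of its eventual peak after stimulus onset) and
#' the time at which the EPSC reaches 50% of its maximum on the rising
#' phase.
#'
#' @param ica Presynaptic calcium-current trace with a protocol attached.
#' @param epsc Postsynaptic EPSC trace on the same time base.
#' @return Delay in ms.
#' @export
synaptic_delay <- function(ica, epsc) {
  if (abs(ica$dt - epsc$dt) > 1e-12)
    stop("traces must share a common time base")
  on <- current_onset(ica)
  pk <- peak_amplitude(epsc)
  if (pk$amplitude <= 0) stop("flat EPSC: 50% crossing undefined")
  tt <- trace_time(epsc)
  dev <- abs(epsc$samples - pk$baseline)
  ipk <- which.min(abs(tt - pk$time_ms))
  t50 <- interp_crossing(tt, dev, 0.5 * pk$amplitude, 1L, ipk)
  if (is.na(t50)) stop("EPSC 50% crossing not found")
  t50 - on
}

#' Charge transfer of a current
#'
#' Trapezoidal integral of the baseline-subtracted current from current
#' onset (5% of peak) to the last time at which at least 10% of the peak
#' remains.  If the current never decays below 10% within the trace the
#' integral runs to the trace end and is flagged as truncated.
#'
#' @param trace A `psq_trace` with protocol attached.
#' @return `list(charge_pC, t_on, t_off, truncated)`; charge is a positive
#'   magnitude in pC.
#' @export
integrate_charge <- function(trace) {
  pk <- peak_amplitude(trace)
  if (pk$amplitude <= 0) stop("flat trace: no peak, charge undefined")
  tt <- trace_time(trace)
  dev <- trace$samples - pk$baseline
  on <- current_onset(trace)
  above <- which(abs(dev) >= 0.10 * pk$amplitude & tt >= on)
  i_end <- above[length(above)]
  truncated <- i_end == length(tt)
  t_off <- if (truncated) tt[i_end] else {
    ## interpolate the downward 10% crossing after the last above-sample
    lvl <- 0.10 * pk$amplitude
    a <- abs(dev[i_end]); b <- abs(dev[i_end + 1L])
    tt[i_end] + (a - lvl) / (a - b) * trace$dt
  }
  sel <- tt >= on & tt <= t_off
  ts <- tt[sel]; ys <- abs(dev[sel])
  q_fC <- sum(diff(ts) * (ys[-1] + ys[-length(ys)]) / 2)
  list(charge_pC = q_fC / 1000, t_on = on, t_off = t_off,
       truncated = truncated)
}

#' Series-resistance compensation configuration
#'
#' @param rs_MOhm Residual series resistance (MOhm), >= 0.
#' @param cm_pF Membrane capacitance (pF), > 0.
#' @param e_rev_mV Synaptic reversal potential (mV).
#' @param v_hold_mV Holding potential (mV).
#' @return An object of class `psq_rs_config`.
#' @export
rs_config <- function(rs_MOhm, cm_pF, e_rev_mV = 0, v_hold_mV = -60) {
  stopifnot(rs_MOhm >= 0, cm_pF > 0)
  structure(list(rs_MOhm = rs_MOhm, cm_pF = cm_pF, e_rev_mV = e_rev_mV,
                 v_hold_mV = v_hold_mV), class = "psq_rs_config")
}

#' Offline series-resistance compensation
#'
#' First-order single-compartment correction of a voltage-clamp current for
#' residual uncompensated series resistance: each sample is rescaled by the
#' driving-force ratio \eqn{(V_h - E_{rev}) / (V_h - E_{rev} - I R_s)} and a
#' capacitive correction \eqn{C_m \, d(I R_s)/dt} is added.  With
#' `rs_MOhm = 0` the trace is returned unchanged.
#'
#' @param trace A `psq_trace` (current in pA).
#' @param cfg A [rs_config()].
#' @return A corrected `psq_trace`; if the voltage error approached the
#'   driving force the scale factor is clamped and the attribute
#'   `"rs_clamped"` is set to `TRUE`.
#' @export
compensate_rs_offline <- function(trace, cfg) {
  stopifnot(inherits(cfg, "psq_rs_config"))
  if (cfg$rs_MOhm == 0) return(trace)
  i_pA <- trace$samples
  v_err <- i_pA * cfg$rs_MOhm * 1e-3           # mV
  df <- cfg$v_hold_mV - cfg$e_rev_mV           # mV
  denom <- df - v_err
  clamped <- FALSE
  bad <- abs(v_err) >= abs(df) | sign(denom) != sign(df)
  if (any(bad)) {
    clamped <- TRUE
    denom[bad] <- sign(df) * 0.05 * abs(df)
    warning("Rs correction divergence: |I*Rs| approached the driving force; ",
            "scale factor clamped")
  }
  scale <- df / denom
  dverr <- c(diff(v_err) / trace$dt, 0)        # mV/ms
  out <- trace
  out$samples <- i_pA * scale + cfg$cm_pF * dverr
  attr(out, "rs_clamped") <- clamped
  out
}

## digital 4-pole Bessel low-pass (bilinear transform of the analog
## prototype, frequency pre-warped), returned as an Arma filter
bessel4_coefs <- function(cutoff_kHz, dt_ms) {
  ## poles of the 4th-order Bessel prototype, -3 dB frequency 1 rad/s
  p <- c(complex(real = -0.6572112, imaginary =  0.8301614),
         complex(real = -0.6572112, imaginary = -0.8301614),
         complex(real = -0.9047588, imaginary =  0.2709187),
         complex(real = -0.9047588, imaginary = -0.2709187))
  fs <- 1 / dt_ms                               # kHz
  wc <- 2 * fs * tan(pi * cutoff_kHz / fs)      # pre-warped cutoff
  ps <- p * wc
  zp <- (1 + ps / (2 * fs)) / (1 - ps / (2 * fs))
  poly_from_roots <- function(r) {
    cf <- 1
    for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
    cf
  }
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(rep(-1 + 0i, 4L)))
  signal::Arma(b = b * sum(a) / sum(b), a = a)
}

#' Zero-phase low-pass filter
#'
#' Forward-backward (zero-phase) application of a 4-pole Bessel low-pass
#' filter with unit DC gain, emulating the analog bandwidth limit of the
#' recording chain.
#'
#' @param trace A `psq_trace`.
#' @param cutoff_kHz Cutoff frequency in kHz; must be below Nyquist.
#' @return The filtered `psq_trace`.
#' @export
lowpass_filter <- function(trace, cutoff_kHz = 6) {
  nyq <- 1 / (2 * trace$dt)
  if (cutoff_kHz >= nyq) stop("cutoff must be below the Nyquist frequency")
  flt <- bessel4_coefs(cutoff_kHz, trace$dt)
  ## edge-replicate padding suppresses filtfilt startup transients
  x <- trace$samples
  npad <- min(length(x) - 1L, 300L)
  xp <- c(rep(x[1L], npad), x, rep(x[length(x)], npad))
  yp <- as.numeric(signal::filtfilt(flt, xp))
  out <- trace
  out$samples <- yp[(npad + 1L):(npad + length(x))]
  out
}

#' Write / read a trace as two-column text
#'
#' Tabular interchange format: a header line and two comma-separated columns
#' `time_ms,current_pA`, values written with six significant digits.
#'
#' @param trace A `psq_trace`.
#' @param path File path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `psq_trace` (without protocol metadata).
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_ms = format(trace_time(trace), digits = 6),
                   current_pA = format(trace$samples, digits = 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_ms", "current_pA") %in% names(df)))
  dt <- stats::median(diff(df$time_ms))
  new_trace(df$current_pA, dt = dt, t0 = df$time_ms[1L],
            label = basename(path))
}
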