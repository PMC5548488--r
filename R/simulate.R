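## piecewise-constant command voltage for a protocol, on the trace grid
protocol_voltage <- function(protocol, tt) {
  v <- rep(protocol$holding_mV, length(tt))
  if (!is.null(protocol$pre_pulse)) {
    p0 <- protocol$onset_ms - protocol$pre_pulse$duration_ms
    v[tt >= p0 & tt < protocol$onset_ms] <- protocol$pre_pulse$level_mV
  }
  v[tt >= protocol$onset_ms &
    tt < protocol$onset_ms + protocol$duration_ms] <- protocol$step_mV
  v
}

#' Simulate a presynaptic calcium-current sweep
#'
#' Forward model of the calcium current under a step protocol:
#' \eqn{I(t) = \Gamma\, d(V(t))\, m(t)^4} with the GHK open-channel driving
#' force \eqn{d(V)} (see [eval_iv_model()]) and first-order activation
#' gating \eqn{dm/dt = (m_\infty(V) - m)/\tau_{act}},
#' \eqn{m_\infty(V) = 1/(1+\exp(-(V-V_m)/k_m))}.  The gate is integrated
#' exactly (per-segment exponential relaxation), so steady states are
#' analytic fixed points; deactivation upon repolarization produces tail
#' currents.  With `noiseless = FALSE` Gaussian noise is added and the
#' trace is low-pass filtered at 6 kHz.
#'
#' @param preset A `psq_preset` from [make_preset()].
#' @param protocol A `psq_protocol`.
#' @param noiseless If `TRUE` (default) no noise and no filtering.
#' @param dt Sampling interval (ms).
#' @param tail_ms Trace padding after the step end (ms).
#' @return A `psq_trace` with the protocol attached.
#' @export
simulate_ca_current <- function(preset, protocol, noiseless = TRUE,
                                dt = 0.02, tail_ms = 8) {
  iv <- preset$iv
  volts <- c(protocol$holding_mV, protocol$step_mV,
             if (!is.null(protocol$pre_pulse)) protocol$pre_pulse$level_mV)
  if (any(volts <= -100 | volts >= 80))
    stop("protocol voltages must lie within (-100, +80) mV")
  t_end <- protocol$onset_ms + protocol$duration_ms + tail_ms
  tt <- seq(0, t_end, by = dt)
  v <- protocol_voltage(protocol, tt)
  minf <- 1 / (1 + exp(-(v - iv$vm_mV) / iv$km_mV))
  ## exact exponential relaxation towards the (piecewise-constant) target
  m <- numeric(length(tt))
  m[1] <- minf[1]
  decay <- exp(-dt / iv$tau_act_ms)
  for (i in 2:length(tt))
    m[i] <- minf[i] + (m[i - 1] - minf[i]) * decay
  i_pA <- iv$gamma_scale * ghk_drive(v, iv$e_rev_mV) * m^4
  out <- new_trace(i_pA, dt = dt, t0 = 0,
                   label = paste0(preset$name, "_ICa"), protocol = protocol)
  if (!noiseless) {
    out$samples <- out$samples +
      stats::rnorm(length(tt), 0, preset$noise_sd_pre_pA)
    out <- lowpass_filter(out, 6)
  }
  out
}

## closed-form two-pool release record on a time grid; release runs from
## (onset + latency) to (onset + duration); refill feeds the slow pool
## during release and continues (capped at n_slow) afterwards
release_record <- function(release, protocol, dt = 0.02, tail_ms = 8) {
  t_end <- protocol$onset_ms + protocol$duration_ms + tail_ms
  tt <- seq(0, t_end, by = dt)
  s <- protocol$onset_ms + release$latency_ms       # release onset
  e <- protocol$onset_ms + protocol$duration_ms     # release offset
  tf <- release$tau_fast_ms; ts <- release$tau_slow_ms
  r <- release$refill_SV_per_ms
  nf0 <- release$n_fast; ns0 <- release$n_slow
  tau_rel <- pmin(pmax(tt - s, 0), max(e - s, 0))   # time spent releasing
  nf <- nf0 * exp(-tau_rel / tf)
  ns <- (ns0 - r * ts) * exp(-tau_rel / ts) + r * ts
  cum <- nf0 * (1 - exp(-tau_rel / tf)) +
    (ns0 - r * ts) * (1 - exp(-tau_rel / ts)) + r * tau_rel
  ## rate samples are interval averages of the analytic cumulative so that
  ## piecewise-constant (zero-order-hold) rendering and plain cumulative
  ## summation reproduce the closed form exactly at sample boundaries
  tau_next <- pmin(pmax(tt + dt - s, 0), max(e - s, 0))
  cum_next <- nf0 * (1 - exp(-tau_next / tf)) +
    (ns0 - r * ts) * (1 - exp(-tau_next / ts)) + r * tau_next
  rate <- (cum_next - cum) / dt
  ## after release ends the slow pool refills towards its initial size
  post <- tt > e
  if (any(post)) {
    ns_end <- (ns0 - r * ts) * exp(-max(e - s, 0) / ts) + r * ts
    ns[post] <- pmin(ns0, ns_end + r * (tt[post] - e))
  }
  structure(list(time_ms = tt, rate = rate, n_fast = nf, n_slow = ns,
                 cumulative = cum, dt = dt, protocol = protocol,
                 release = release),
            class = "psq_release_record")
}

#' Simulate ground-truth quantal release
#'
#' Two-pool depletion model with constant refilling of the slow pool,
#' solved in closed form (exact exponentials, no ODE solver).  During the
#' release window (step onset + latency until step end) the release rate is
#' \eqn{\xi(t) = N_f(t)/\tau_f + N_s(t)/\tau_s} with
#' \eqn{dN_f/dt = -N_f/\tau_f} and \eqn{dN_s/dt = -N_s/\tau_s + r};
#' outside the window \eqn{\xi = 0} and refilling continues into the slow
#' pool, capped at its initial size.
#'
#' @param preset A `psq_preset` with release parameters.
#' @param protocol A `psq_protocol` (typically [pool_protocol()]).
#' @param dt Sampling interval (ms).
#' @return A `psq_release_record`: time, rate (SV/ms), pool occupancies,
#'   cumulative release.
#' @export
simulate_release <- function(preset, protocol, dt = 0.02) {
  if (is.null(preset$release))
    stop("preset '", preset$name, "' has no release model")
  release_record(preset$release, protocol, dt = dt)
}

## discretized convolution kernel: A_k = mean of g over the k-th sample
## interval (zero-order-hold), where g(t) = sum_i cs_i exp(-t/tau_i); this
## matched discretization keeps the deconvolution minimum-phase
kernel_discrete <- function(kernel, dt, n) {
  comp <- kernel_components(kernel)
  tk <- (seq_len(n) - 1L) * dt
  A <- numeric(n)
  for (i in seq_along(comp$taus)) {
    ti <- comp$taus[i]
    A <- A + comp$cs[i] * (ti / dt) * (1 - exp(-dt / ti)) * exp(-tk / ti)
  }
  A
}

## discrete ZOH convolution of a rate with the kernel, evaluated by the
## exact sum-of-exponentials state recursion (strictly causal: output is
## identically zero until the first non-zero rate sample)
apply_kernel <- function(xi, kernel, dt) {
  comp <- kernel_components(kernel)
  rho <- exp(-dt / comp$taus)
  w <- comp$cs * (comp$taus / dt) * (1 - rho)
  n <- length(xi)
  y <- numeric(n)
  s <- numeric(length(rho))
  for (i in seq_len(n)) {
    s <- rho * s + xi[i]
    y[i] <- sum(w * s)
  }
  y * dt
}

## render on the grid of a release record; returns a psq_trace (EPSC,
## inward negative)
render_epsc_raw <- function(record, kernel, noiseless = TRUE,
                            noise_sd = 20) {
  xi <- record$rate
  n <- length(xi)
  y <- apply_kernel(xi, kernel, record$dt)
  out <- new_trace(-y, dt = record$dt, t0 = record$time_ms[1L],
                   label = "EPSC", protocol = record$protocol)
  if (!noiseless) {
    out$samples <- out$samples + stats::rnorm(n, 0, noise_sd)
    out <- lowpass_filter(out, 6)
  }
  out
}

#' Render an EPSC from a release record
#'
#' Strictly linear, causal forward model: the release rate is convolved
#' with the discretized quantal kernel (bi-exponential mEPSC plus
#' residual-current pathway, see [mepsc_kernel()]); the result is an inward
#' (negative) postsynaptic current.  With `noiseless = FALSE` Gaussian
#' noise (`preset` postsynaptic noise SD, or `noise_sd`) is added and the
#' trace is filtered at 6 kHz.
#'
#' @param record A `psq_release_record`.
#' @param kernel A `psq_kernel`.
#' @param noiseless If `TRUE` (default) no noise and no filtering.
#' @param noise_sd Postsynaptic noise SD in pA (used when
#'   `noiseless = FALSE`).
#' @return A `psq_trace`.
#' @export
render_epsc <- function(record, kernel, noiseless = TRUE, noise_sd = 20) {
  stopifnot(inherits(record, "psq_release_record"),
            inherits(kernel, "psq_kernel"))
  render_epsc_raw(record, kernel, noiseless = noiseless,
                  noise_sd = noise_sd)
}

#' Simulate paired pool-measurement sweeps for a group
#'
#' Convenience wrapper producing the calcium current and EPSC for one
#' pool-depleting protocol.
#'
#' @param preset A `psq_preset`.
#' @param duration_ms 0 mV step duration (3 or 30).
#' @param noiseless If `TRUE` no noise/filtering.
#' @param dt Sampling interval (ms).
#' @return `list(ica=, epsc=, record=)`.
#' @export
simulate_pool_sweep <- function(preset, duration_ms = 3, noiseless = TRUE,
                                dt = 0.02) {
  prot <- pool_protocol(duration_ms)
  rec <- simulate_release(preset, prot, dt = dt)
  list(ica = simulate_ca_current(preset, prot, noiseless = noiseless,
                                 dt = dt),
       epsc = render_epsc(rec, preset$kernel, noiseless = noiseless,
                          noise_sd = preset$noise_sd_post_pA),
       record = rec)
}

#' Simulate synthetic active-zone fields
#'
#' Each field is a straight active-zone (AZ) membrane segment in the
#' section plane with surrounding vesicles.  AZ length is Normal
#' (truncated above 50 nm); docked vesicles (count Poisson with the preset
#' mean) get membrane-to-membrane (edge) distances Uniform(0, 5) nm;
#' background vesicles are placed with uniform density in the 5-200 nm
#' band.  Each field is randomly rotated and translated.
#'
#' @param em_preset A `psq_em_preset` from [make_preset()].
#' @param n_AZ Number of fields, >= 1.
#' @param seed Optional integer seed.
#' @return A list of `psq_az_field` objects (see [az_field()]).
#' @export
simulate_em_field <- function(em_preset, n_AZ, seed = NULL) {
  stopifnot(inherits(em_preset, "psq_em_preset"), n_AZ >= 1)
  if (!is.null(seed)) set.seed(seed)
  rad <- em_preset$vesicle_radius_nm
  lapply(seq_len(n_AZ), function(k) {
    len <- 0
    while (len <= 50)
      len <- stats::rnorm(1, em_preset$az_length_mean_nm,
                          em_preset$az_length_sd_nm)
    n_dock <- stats::rpois(1, em_preset$docked_mean_per_AZ)
    n_bg <- stats::rpois(1, em_preset$background_density * len * 195)
    place <- function(n, dmin, dmax) {
      if (n == 0)
        return(matrix(numeric(0), 0, 3,
                      dimnames = list(NULL, c("x", "y", "radius"))))
      edge <- stats::runif(n, dmin, dmax)
      cbind(x = stats::runif(n, 0, len),
            y = sample(c(-1, 1), n, replace = TRUE) * (edge + rad),
            radius = rad)
    }
    ves <- rbind(place(n_dock, 0, 5), place(n_bg, 5, 200))
    ## random rigid motion so fields are not axis-aligned
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    off <- stats::runif(2, 0, 1000)
    seg <- t(R %*% t(rbind(c(0, 0), c(len, 0)))) +
      rep(off, each = 2)
    if (nrow(ves) > 0) {
      xy <- t(R %*% t(ves[, 1:2, drop = FALSE])) + rep(off, each = nrow(ves))
      ves[, 1:2] <- xy
    }
    az_field(az_id = k, p1 = seg[1, ], p2 = seg[2, ], vesicles = ves)
  })
}
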