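## shared fixture builders (all generated in code, nothing stored)

## a bare trace with no protocol: baseline is taken as 0
flat_trace <- function(n = 500, dt = 0.02, value = 0) {
  new_trace(rep(value, n), dt = dt)
}

## rectangular inward pulse of `amp_pA` (negative) over [on, off] ms
rect_pulse_trace <- function(amp_pA = -100, on = 2, off = 12,
                             t_end = 20, dt = 0.02,
                             protocol = step_protocol(-80, 0, on, off - on)) {
  tt <- seq(0, t_end, by = dt)
  x <- ifelse(tt >= on & tt < off, amp_pA, 0)
  new_trace(x, dt = dt, protocol = protocol)
}

## single-exponential rising EPSC-like trace (magnitude grows to amp)
exp_rise_trace <- function(amp = -100, tau = 1, t_end = 15, dt = 0.02) {
  tt <- seq(0, t_end, by = dt)
  new_trace(amp * (1 - exp(-tt / tau)), dt = dt)
}

## a small AZ field built by hand
simple_field <- function(vesicles, p1 = c(0, 0), p2 = c(300, 0), id = 1) {
  az_field(id, p1, p2, vesicles)
}

## wrap arbitrary release parameters in a preset so the public generator
## surface can simulate them
release_record_for_test <- function(rel, prot, dt = 0.02) {
  p <- make_preset("FT")
  p$release <- rel
  simulate_release(p, prot, dt = dt)
}

## random two-pool release parameter set (for round-trip properties)
random_release <- function() {
  list(n_fast = stats::runif(1, 200, 2000),
       n_slow = stats::runif(1, 200, 2000),
       tau_fast_ms = stats::runif(1, 0.4, 1.5),
       tau_slow_ms = stats::runif(1, 10, 40),
       latency_ms = stats::runif(1, 0.5, 1.5),
       refill_SV_per_ms = stats::runif(1, 0, 15))
}
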