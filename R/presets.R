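#' mEPSC kernel for rendering and deconvolution
#'
#' The quantal-event model shared by the EPSC renderer and the
#' deconvolution routine: a bi-exponential miniature EPSC of unit peak
#' scaled to `q_pA`, plus a residual-current pathway representing delayed
#' glutamate clearance in the synaptic cleft (each released vesicle adds
#' `a` units to a residual state that decays with `tau_clear_ms`; the
#' residual state contributes a current of `w_frac * q_pA` per unit, i.e.
#' the residual is carried by the same receptors as the quantal events and
#' scales with the quantal size).
#'
#' @param q_pA Quantal peak amplitude (pA), > 0.
#' @param tau_rise_ms,tau_decay_ms mEPSC time constants (ms),
#'   `tau_rise_ms < tau_decay_ms`.
#' @param residual `list(a=, tau_clear_ms=, w_frac=)`, all >= 0.
#' @return An object of class `psq_kernel`.
#' @export
mepsc_kernel <- function(q_pA, tau_rise_ms = 0.2, tau_decay_ms = 1.0,
                         residual = list(a = 1, tau_clear_ms = 40,
                                         w_frac = 0.05)) {
  stopifnot(q_pA > 0, tau_rise_ms > 0, tau_decay_ms > tau_rise_ms,
            residual$a >= 0, residual$tau_clear_ms > 0,
            residual$w_frac >= 0)
  structure(list(q_pA = q_pA, tau_rise_ms = tau_rise_ms,
                 tau_decay_ms = tau_decay_ms, residual = residual),
            class = "psq_kernel")
}

## peak value of exp(-t/td) - exp(-t/tr), used to normalise the mEPSC shape
biexp_peak_norm <- function(tr, td) {
  tpk <- log(td / tr) * tr * td / (td - tr)
  exp(-tpk / td) - exp(-tpk / tr)
}

## kernel as a sum of exponentials: amplitudes cs, time constants taus, so
## that g(t) = sum_i cs[i] * exp(-t/taus[i]); g is the current (pA) evoked
## per released vesicle
kernel_components <- function(kernel) {
  hn <- biexp_peak_norm(kernel$tau_rise_ms, kernel$tau_decay_ms)
  list(
    taus = c(kernel$tau_decay_ms, kernel$tau_rise_ms,
             kernel$residual$tau_clear_ms),
    cs = c(kernel$q_pA / hn, -kernel$q_pA / hn,
           kernel$q_pA * kernel$residual$w_frac * kernel$residual$a))
}

## table of group-level electrophysiological parameters; IV and Boltzmann
## entries are the printed group means, pool targets are the group mean
## fast (3 ms) and refill-corrected total (30 ms) cumulative release
ephys_group_table <- function() {
  list(
    FT = list(vm = -25.1, km = 7.4, imax = 925, vhalf = -11.0, bk = 8.9,
              fast = 1505, total = 2152, tau_f = 0.6, tau_s = 25,
              latency = 1.0, epsc3_nA = 8.54),
    WT = list(vm = -24.6, km = 8.0, imax = 911, vhalf = -10.6, bk = 8.3,
              fast = 1505, total = 2152, tau_f = 0.6, tau_s = 25,
              latency = 1.0, epsc3_nA = 8.99),
    CKO = list(vm = -22.3, km = 12.6, imax = 464, vhalf = -1.7, bk = 10.3,
               fast = NA, total = NA, tau_f = NA, tau_s = NA,
               latency = NA, epsc3_nA = NA),
    D2042 = list(vm = -25.1, km = 7.4, imax = 925, vhalf = -11.0, bk = 8.9,
                 fast = 430, total = 1292, tau_f = 1.5, tau_s = 30,
                 latency = 1.5, epsc3_nA = 3.38),
    D2016 = list(vm = -23.3, km = 8.2, imax = 744, vhalf = -8.9, bk = 7.2,
                 fast = 357, total = 1061, tau_f = 1.5, tau_s = 30,
                 latency = 1.5, epsc3_nA = 2.49))
}

em_group_table <- function() {
  list(
    `control-EM` = list(docked = 1.39, az_mean = 280.6, az_sd = 89.8),
    `D2042-EM`   = list(docked = 0.77, az_mean = 267.1, az_sd = 88.7),
    `D2016-EM`   = list(docked = 0.63, az_mean = 268.0, az_sd = 79.0))
}

## Solve for initial pool sizes (n_fast, n_slow) such that the model's
## ground-truth observables equal the group targets:
##   cumulative release 3 ms after step onset            = fast target
##   cumulative at 30 ms  -  refill * 30 ms              = total target
## Release runs from (onset + latency); during release
##   Nf' = -Nf/tau_f,  Ns' = -Ns/tau_s + r,
## giving cumulative C(t) = nf*(1-e^(-t/tf)) + (ns - r*ts)*(1-e^(-t/ts)) + r*t
## with t measured from release onset.  Linear 2x2 system in (nf, ns - r*ts).
calibrate_pools <- function(fast, total, tau_f, tau_s, latency,
                            refill = 10, t_fast = 3, t_total = 30) {
  t1 <- t_fast - latency
  t2 <- t_total - latency
  stopifnot(t1 > 0, t2 > t1)
  a <- c(1 - exp(-t1 / tau_f), 1 - exp(-t1 / tau_s))
  b <- c(1 - exp(-t2 / tau_f), 1 - exp(-t2 / tau_s))
  rhs <- c(fast - refill * t1,
           (total + refill * t_total) - refill * t2)
  sol <- solve(matrix(c(a[1], b[1], a[2], b[2]), 2, 2), rhs)
  nf <- sol[1]
  ns <- sol[2] + refill * tau_s
  if (nf <= 0 || ns <= 0)
    stop("pool calibration produced non-positive pool sizes")
  c(n_fast = nf, n_slow = ns)
}

## cache for the quantal-size calibration (shared across presets)
.psq_cache <- new.env(parent = emptyenv())

#' Named synthetic-experiment preset
#'
#' Returns a fully populated parameter set for one experimental group.
#' Electrophysiology groups (`"FT"`, `"WT"`, `"CKO"`, `"D2042"`, `"D2016"`)
#' carry I(V)-model parameters (GHK scale calibrated so the true I(V)
#' extremum magnitude equals the group's maximal current), Boltzmann
#' tail-activation parameters, and a two-pool release model whose initial
#' pool sizes are calibrated so that the ground-truth 3 ms cumulative
#' release and refill-corrected 30 ms cumulative release equal the group's
#' fast-pool and total-pool values.  EM groups (`"control-EM"`,
#' `"D2042-EM"`, `"D2016-EM"`) carry active-zone field parameters.
#'
#' The quantal amplitude of the mEPSC kernel is calibrated once, on the FT
#' group, so that the rendered noiseless 3 ms EPSC peak equals the FT group
#' mean EPSC amplitude; all groups share that quantal size.
#'
#' @param group_name One of the names above.
#' @return A list of class `psq_preset` (or `psq_em_preset` for EM groups).
#' @export
make_preset <- function(group_name) {
  eph <- ephys_group_table()
  emg <- em_group_table()
  if (group_name %in% names(emg)) {
    g <- emg[[group_name]]
    return(structure(list(
      name = group_name,
      az_length_mean_nm = g$az_mean, az_length_sd_nm = g$az_sd,
      docked_mean_per_AZ = g$docked,
      background_density = 2.5e-4,     # vesicles per nm AZ per nm depth
      vesicle_radius_nm = 20), class = "psq_em_preset"))
  }
  if (!group_name %in% names(eph))
    stop("unknown group '", group_name, "'; available: ",
         paste(c(names(eph), names(emg)), collapse = ", "))
  g <- eph[[group_name]]

  ## GHK scale: true extremum magnitude of the I(V) envelope = imax
  env_max <- max(abs(eval_iv_model(seq(-60, 44.9, by = 0.05),
                                   list(gamma = 1, e_rev_mV = 45,
                                        vm_mV = g$vm, km_mV = g$km))))
  iv <- list(gamma_scale = g$imax / env_max, e_rev_mV = 45,
             vm_mV = g$vm, km_mV = g$km, tau_act_ms = 0.3,
             imax_target_pA = g$imax)
  boltz <- list(ibase_pA = 0, imin_pA = -1850, vhalf_mV = g$vhalf,
                k_mV = g$bk)

  release <- NULL
  if (!is.na(g$fast)) {
    pools <- calibrate_pools(g$fast, g$total, g$tau_f, g$tau_s, g$latency)
    release <- list(n_fast = unname(pools["n_fast"]),
                    n_slow = unname(pools["n_slow"]),
                    tau_fast_ms = g$tau_f, tau_slow_ms = g$tau_s,
                    latency_ms = g$latency, refill_SV_per_ms = 10,
                    fast_target = g$fast, total_target = g$total)
  }

  kernel <- mepsc_kernel(q_pA = quantal_size_FT())
  structure(list(name = group_name, iv = iv, boltzmann = boltz,
                 release = release, kernel = kernel,
                 noise_sd_pre_pA = 5, noise_sd_post_pA = 20),
            class = "psq_preset")
}

## quantal size such that the FT noiseless 3 ms EPSC peak is 8540 pA
quantal_size_FT <- function() {
  if (!is.null(.psq_cache$q_FT)) return(.psq_cache$q_FT)
  g <- ephys_group_table()$FT
  pools <- calibrate_pools(g$fast, g$total, g$tau_f, g$tau_s, g$latency)
  rel <- list(n_fast = unname(pools["n_fast"]),
              n_slow = unname(pools["n_slow"]),
              tau_fast_ms = g$tau_f, tau_slow_ms = g$tau_s,
              latency_ms = g$latency, refill_SV_per_ms = 10)
  prot <- pool_protocol(3)
  rec <- release_record(rel, prot, dt = 0.02)
  k1 <- mepsc_kernel(q_pA = 1)
  tr <- render_epsc_raw(rec, k1, noiseless = TRUE)
  pk1 <- peak_amplitude(tr)$amplitude
  q <- g$epsc3_nA * 1000 / pk1
  .psq_cache$q_FT <- q
  q
}
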