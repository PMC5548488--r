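#' Experiment manifest
#'
#' Declarative description of a full synthetic "paper run": which groups
#' to simulate and analyse, the master seed (all stage seeds are derived
#' from it), and optional output directory.
#'
#' @param groups Electrophysiology groups to analyse.
#' @param em_groups EM groups to analyse.
#' @param seed Master integer seed.
#' @param n_cells Cells per group for the noisy replicate comparison.
#' @param n_az Active zones per EM group.
#' @param out_dir Optional directory for JSON reports.
#' @return A list of class `psq_manifest`.
#' @export
experiment_manifest <- function(groups = c("FT", "D2042", "D2016"),
                                em_groups = c("control-EM", "D2042-EM",
                                              "D2016-EM"),
                                seed = 1, n_cells = 6, n_az = 120,
                                out_dir = NULL) {
  structure(list(groups = groups, em_groups = em_groups, seed = seed,
                 n_cells = n_cells, n_az = n_az, out_dir = out_dir),
            class = "psq_manifest")
}

## noiseless single-cell analysis of one group: IV + tail fits and the
## paired-pool deconvolution report
analyse_group <- function(group) {
  preset <- make_preset(group)
  cfg <- deconv_config(preset$kernel)
  s3 <- simulate_pool_sweep(preset, 3)
  s30 <- simulate_pool_sweep(preset, 30)
  rep <- build_pool_report(s3$ica, s3$epsc, s30$ica, s30$epsc, cfg)
  iv_sweeps <- lapply(seq(-50, 50, by = 5), function(v)
    simulate_ca_current(preset, iv_protocol(v)))
  ivfit <- fit_iv(measure_iv_series(iv_sweeps))
  vb <- seq(-50, 50, by = 5)
  tails <- data.frame(step_mV = vb,
                      tail_pA = eval_boltzmann(vb, preset$boltzmann))
  bfit <- fit_tail_boltzmann(tails)
  list(group = group,
       iv = list(vm_mV = ivfit$vm_mV, km_mV = ivfit$km_mV,
                 imax_pA = ivfit$imax_pA, e_rev_mV = ivfit$e_rev_mV),
       boltzmann = list(vhalf_mV = bfit$vhalf_mV, k_mV = bfit$k_mV),
       pools = list(fast_SV = rep$fast_pool_SV,
                    total_SV = rep$total_pool_SV,
                    ratio_3_30 = rep$ratio_3_30,
                    epsc_amp_3ms_nA = rep$epsc_amp_3ms_nA,
                    rise_3ms_ms = rep$rise_3ms_ms,
                    delay_3ms_ms = rep$delay_3ms_ms,
                    ca_charge_3ms_pC = rep$ca_charge_3ms_pC),
       targets = list(fast_SV = preset$release$fast_target,
                      total_SV = preset$release$total_target))
}

#' Run the full synthetic analysis suite
#'
#' Generates synthetic data for every group in the manifest and runs all
#' analysis stages: noiseless I(V) and tail-current fits, paired 3/30 ms
#' pool deconvolution, a noisy replicate comparison of fast-pool sizes
#' across groups (one-way ANOVA with Dunnett's test against the first
#' group), and docked-vesicle morphometry with unpaired t-tests of each
#' EM group against the first.  Fully deterministic for a given manifest.
#'
#' @param manifest A [experiment_manifest()].
#' @return A nested list (class `psq_suite_report`) of recovered values
#'   next to the preset ground-truth targets; written as JSON to
#'   `out_dir` if set.
#' @export
run_paper_suite <- function(manifest = experiment_manifest()) {
  stopifnot(inherits(manifest, "psq_manifest"))
  ephys <- lapply(manifest$groups, analyse_group)
  names(ephys) <- manifest$groups

  ## noisy replicates: per-cell fast pools, compared against the control
  stats_block <- NULL
  if (length(manifest$groups) >= 2 && manifest$n_cells >= 3) {
    reps <- lapply(manifest$groups, function(g) {
      preset <- make_preset(g)
      cfg <- deconv_config(preset$kernel)
      vals <- vapply(seq_len(manifest$n_cells), function(i) {
        set.seed(manifest$seed + 1000L * match(g, manifest$groups) + i)
        sw <- simulate_pool_sweep(preset, 3, noiseless = FALSE)
        pool_sizes(deconvolve(sw$epsc, cfg), cfg)$fast_SV
      }, numeric(1))
      group_sample(g, vals, units = "SV")
    })
    cmp <- anova_dunnett(reps, control_label = manifest$groups[1])
    stats_block <- list(fast_pool_comparison = list(
      omnibus_p = cmp$omnibus_p,
      table = cmp$table))
  }

  em <- NULL
  if (length(manifest$em_groups) > 0) {
    em_res <- lapply(seq_along(manifest$em_groups), function(i) {
      g <- manifest$em_groups[i]
      preset <- make_preset(g)
      fields <- simulate_em_field(preset, manifest$n_az,
                                  seed = manifest$seed + 77L * i)
      ds <- docked_summary(fields)
      lens <- vapply(fields, az_length, numeric(1))
      list(group = g, docked_mean = ds$mean, docked_sem = ds$sem,
           n = ds$n, az_length_mean = mean(lens),
           target_docked = preset$docked_mean_per_AZ, counts = ds$counts)
    })
    names(em_res) <- manifest$em_groups
    ttests <- NULL
    if (length(em_res) >= 2) {
      ctrl <- group_sample(em_res[[1]]$group, em_res[[1]]$counts)
      ttests <- lapply(em_res[-1], function(r) {
        tst <- ttest_unpaired(ctrl, group_sample(r$group, r$counts))
        list(group = r$group, t = tst$t, p = tst$p)
      })
    }
    em <- list(groups = lapply(em_res, function(r)
      r[setdiff(names(r), "counts")]), ttests = ttests)
  }

  report <- structure(list(manifest = manifest[c("groups", "em_groups",
                                                 "seed", "n_cells", "n_az")],
                           ephys = ephys, stats = stats_block, em = em),
                      class = "psq_suite_report")
  if (!is.null(manifest$out_dir)) {
    dir.create(manifest$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(manifest$out_dir, "suite_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.psq_suite_report <- function(x, ...) {
  cat("<psq_suite_report>\n")
  for (g in names(x$ephys)) {
    e <- x$ephys[[g]]
    cat(sprintf(
      "  %-8s Vm %.1f mV, km %.2f mV, |I|max %.0f pA; fast %.0f SV (target %s), total %.0f SV (target %s), ratio %.3f\n",
      g, e$iv$vm_mV, e$iv$km_mV, e$iv$imax_pA, e$pools$fast_SV,
      format(e$targets$fast_SV), e$pools$total_SV,
      format(e$targets$total_SV), e$pools$ratio_3_30))
  }
  if (!is.null(x$em))
    for (g in names(x$em$groups)) {
      r <- x$em$groups[[g]]
      cat(sprintf("  %-12s docked %.2f +/- %.2f per AZ (n = %d, target %.2f)\n",
                  g, r$docked_mean, r$docked_sem, r$n, r$target_docked))
    }
  invisible(x)
}
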