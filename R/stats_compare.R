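#' Group sample container
#'
#' @param label Group label.
#' @param values Numeric measurements, n >= 2.
#' @param units Optional unit annotation.
#' @return A list of class `psq_group`.
#' @export
group_sample <- function(label, values, units = "") {
  stopifnot(is.numeric(values), length(values) >= 2)
  structure(list(label = as.character(label), values = as.numeric(values),
                 units = units), class = "psq_group")
}

significance_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 1e-2, "**",
                       ifelse(p < 0.05, "*", "n.s."))))
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk normality p-value per group and a Bartlett test of
#' variance homogeneity across groups.  Groups with fewer than 3 values
#' or zero variance are flagged and skipped for the normality test.
#'
#' @param groups List of [group_sample()] objects.
#' @return `list(normality_p (named), homogeneity_p, flags)`.
#' @export
check_assumptions <- function(groups) {
  flags <- character(0)
  norm_p <- vapply(groups, function(g) {
    if (length(g$values) < 3 || stats::sd(g$values) == 0) {
      flags <<- c(flags, paste0(g$label,
        ": normality test skipped (undersized or constant)"))
      return(NA_real_)
    }
    stats::shapiro.test(g$values)$p.value
  }, numeric(1))
  names(norm_p) <- vapply(groups, `[[`, character(1), "label")
  vals <- lapply(groups, `[[`, "values")
  hom_p <- if (length(vals) >= 2 &&
               all(vapply(vals, stats::sd, numeric(1)) > 0))
    stats::bartlett.test(vals)$p.value
  else {
    if (length(vals) >= 2)
      flags <- c(flags, "homogeneity test skipped (constant group)")
    NA_real_
  }
  list(normality_p = norm_p, homogeneity_p = hom_p, flags = flags)
}

#' One-way ANOVA with Dunnett's post hoc test
#'
#' Omnibus one-way ANOVA across all groups, followed by Dunnett's
#' many-to-one comparisons of every non-control group against the
#' designated control with family-wise (single-step) adjusted p-values.
#' Significance stars: * p < 0.05, ** p < 0.01, *** p < 0.001,
#' **** p < 0.0001.
#'
#' @param groups List of [group_sample()] objects.
#' @param control_label Label of the control group.
#' @return A list of class `psq_comparison`: per-group descriptives
#'   (mean, SEM, n), omnibus `F` and `p`, adjusted p-value and stars per
#'   non-control group, and the assumption checks.
#' @export
anova_dunnett <- function(groups, control_label) {
  labels <- vapply(groups, `[[`, character(1), "label")
  if (!control_label %in% labels)
    stop("control group '", control_label, "' not among: ",
         paste(labels, collapse = ", "))
  if (length(groups) < 2) stop("need at least 2 groups")
  df <- do.call(rbind, lapply(groups, function(g)
    data.frame(group = g$label, value = g$values)))
  df$group <- stats::relevel(factor(df$group), ref = control_label)
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  dn <- summary(multcomp::glht(fit,
                               linfct = multcomp::mcp(group = "Dunnett")))
  padj <- as.numeric(dn$test$pvalues)
  comp_labels <- sub(" - .*$", "", names(dn$test$coefficients))
  desc <- data.frame(
    group = labels,
    mean = vapply(groups, function(g) mean(g$values), numeric(1)),
    sem = vapply(groups, function(g)
      stats::sd(g$values) / sqrt(length(g$values)), numeric(1)),
    n = vapply(groups, function(g) length(g$values), numeric(1)))
  desc$p_adjusted <- NA_real_
  desc$p_adjusted[match(comp_labels, desc$group)] <- padj
  desc$stars <- ifelse(is.na(desc$p_adjusted), "control",
                       significance_stars(desc$p_adjusted))
  structure(list(control_label = control_label, table = desc,
                 omnibus_F = an[["F value"]][1],
                 omnibus_p = an[["Pr(>F)"]][1],
                 assumptions = check_assumptions(groups)),
            class = "psq_comparison")
}

#' @export
print.psq_comparison <- function(x, ...) {
  cat(sprintf("<psq_comparison> control: %s; omnibus F = %.2f, p = %.4g\n",
              x$control_label, x$omnibus_F, x$omnibus_p))
  tb <- x$table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-12s %8.3g +/- %.3g (%d)  %s%s\n", tb$group[i],
                tb$mean[i], tb$sem[i], tb$n[i],
                ifelse(is.na(tb$p_adjusted[i]), "",
                       sprintf("p = %.4g ", tb$p_adjusted[i])),
                tb$stars[i]))
  invisible(x)
}

#' Unpaired two-sample t-test
#'
#' Classical (equal-variance) two-sided unpaired t-test, the procedure
#' used for the EM group comparisons.
#'
#' @param a,b [group_sample()] objects.
#' @return `list(t, p, df, flag)`.
#' @export
ttest_unpaired <- function(a, b) {
  if (stats::sd(c(a$values - mean(a$values), b$values - mean(b$values))) == 0)
    return(list(t = NA_real_, p = NA_real_,
                df = length(a$values) + length(b$values) - 2,
                flag = "zero pooled variance"))
  tst <- stats::t.test(a$values, b$values, var.equal = TRUE)
  list(t = unname(tst$statistic), p = tst$p.value,
       df = unname(tst$parameter), flag = NULL)
}
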