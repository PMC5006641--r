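# Downstream biomarker statistics: nuclear staining-intensity aggregation,
# group comparisons of the percent of strongly (3+) stained nuclei, a
# logistic-model ROC for case/control discrimination, the two-group power
# calculation used to size validation cohorts, droplet-digital-PCR QC and
# mutant fractions, and cohort carrier summaries.

#' Aggregate per-nucleus intensity calls into case-level percentages
#'
#' Nuclei are scored 0 (no signal), 1 (weak), 2 (moderate) or 3 (strong);
#' the case-level readout is the percentage of nuclei in each bin.
#'
#' @param intensities Integer vector of per-nucleus scores in `0:3`.
#' @param case_id,group Identifiers attached to the output row.
#' @return One-row `data.frame(case_id, group, pct0, pct1, pct2, pct3)`;
#'   the four percentages sum to 100.
#' @export
aggregate_nuclear_scores <- function(intensities, case_id = "case",
                                     group = NA_character_) {
  if (length(intensities) == 0L) stop("no nuclei scored", call. = FALSE)
  if (!all(intensities %in% 0:3))
    stop("intensity calls must be 0, 1, 2 or 3", call. = FALSE)
  counts <- tabulate(intensities + 1L, nbins = 4L)
  pct <- 100 * counts / length(intensities)
  data.frame(case_id = case_id, group = group,
             pct0 = pct[1], pct1 = pct[2], pct2 = pct[3], pct3 = pct[4],
             stringsAsFactors = FALSE)
}

#' Compare percent-3+ staining across groups
#'
#' One-way analysis of variance on the chosen readout followed by Tukey's
#' honest-significant-difference pairwise comparisons (studentized-range
#' adjusted p-values).
#'
#' @param scores Case-level score table with a `group` column.
#' @param value Column name of the readout (default `"pct3"`, the percent
#'   of strongly stained nuclei).
#' @return Object of class `ihc_comparison`: list with `anova_f`,
#'   `anova_p`, `df`, `tukey` (pairwise table with adjusted p-values) and
#'   the fitted `aov` object.
#' @export
group_comparison <- function(scores, value = "pct3") {
  stopifnot(is.data.frame(scores), "group" %in% names(scores),
            value %in% names(scores))
  g <- factor(scores$group)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("need >= 2 cases per group", call. = FALSE)
  y <- scores[[value]]
  if (stats::var(y) == 0)
    stop("degenerate readout: zero variance", call. = FALSE)
  fit <- aov(y ~ g)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(anova_f = an$`F value`[1], anova_p = an$`Pr(>F)`[1],
                 df = c(an$Df[1], an$Df[2]), tukey = tukey, fit = fit,
                 value = value),
            class = "ihc_comparison")
}

#' @export
print.ihc_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA on %s: F(%d, %d) = %.3f, p = %.3g\n",
              x$value, x$df[1], x$df[2], x$anova_f, x$anova_p))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$tukey, row.names = FALSE, digits = 4)
  invisible(x)
}

# Rank (Mann-Whitney) AUC with midrank tie handling.
rank_auc <- function(x, label) {
  n1 <- sum(label); n0 <- sum(!label)
  r <- rank(x)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Logistic model and ROC curve for case/control discrimination
#'
#' Fits a maximum-likelihood binomial GLM of the case/control label on the
#' percent of strongly stained nuclei, sweeps every threshold of the
#' predictor to obtain the ROC curve, and reports the area under the curve
#' by the trapezoidal rule (identical to the rank statistic with midrank
#' ties).  Complete separation is reported with a flag; the AUC remains
#' defined.
#'
#' @param scores Case-level score table.
#' @param case_group,control_group Group labels coded 1 and 0.
#' @param predictor Readout column (default `"pct3"`).
#' @return Object of class `logistic_roc`: list with `fit` (the glm),
#'   `coefficients`, `roc` (`data.frame(threshold, fpr, tpr)`), `auc`,
#'   `auc_rank`, `separation` flag and counts.
#' @export
logistic_roc <- function(scores, case_group = "hgsoc_fte",
                         control_group = "benign", predictor = "pct3") {
  stopifnot(is.data.frame(scores), "group" %in% names(scores),
            predictor %in% names(scores))
  keep <- scores$group %in% c(case_group, control_group)
  x <- scores[[predictor]][keep]
  label <- scores$group[keep] == case_group
  if (sum(label) == 0L || sum(!label) == 0L)
    stop("both classes must be present", call. = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(label ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  thresholds <- c(Inf, sort(unique(x), decreasing = TRUE))
  tpr <- vapply(thresholds, function(t) mean(x[label] >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(x[!label] >= t), numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fit = fit, coefficients = coef(fit),
                 roc = data.frame(threshold = thresholds, fpr = fpr, tpr = tpr),
                 auc = auc, auc_rank = rank_auc(x, label),
                 separation = separation,
                 n_case = sum(label), n_control = sum(!label),
                 predictor = predictor),
            class = "logistic_roc")
}

#' @export
print.logistic_roc <- function(x, ...) {
  cat(sprintf("Binomial GLM of case status on %s (%d cases, %d controls)\n",
              x$predictor, x$n_case, x$n_control))
  co <- summary(x$fit)$coefficients
  cat(sprintf("  slope %.4f, Wald p = %.3g%s\n", co[2, 1], co[2, 4],
              if (x$separation) " [complete separation]" else ""))
  cat(sprintf("  ROC AUC = %.3f\n", x$auc))
  invisible(x)
}

#' @param x A `logistic_roc` object.
#' @param ... Passed to [graphics::plot()].
#' @rdname logistic_roc
#' @export
plot.logistic_roc <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate", ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Per-group sample size for a two-group mean comparison
#'
#' Normal-approximation formula with unpooled variances:
#' `n = (z[1 - alpha/2] + z[power])^2 (sd1^2 + sd2^2) / delta^2`,
#' rounded to the nearest integer.  With the discovery-set staining
#' estimates (means 3 and 14, sds 4 and 10, 90% power, two-sided 5% level)
#' this gives ten cases per group.
#'
#' @param mean1,sd1,mean2,sd2 Group means and standard deviations
#'   (`sd > 0`).
#' @param power Target power in (0, 1).
#' @param alpha Two-sided significance level.
#' @return Integer sample size per group.
#' @examples
#' sample_size_two_groups(3, 4, 14, 10)  # 10
#' @export
sample_size_two_groups <- function(mean1, sd1, mean2, sd2,
                                   power = 0.90, alpha = 0.05) {
  if (sd1 <= 0 || sd2 <= 0) stop("sds must be > 0", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)", call. = FALSE)
  delta <- mean2 - mean1
  if (delta == 0) stop("group means are equal; no effect to detect",
                       call. = FALSE)
  n <- (qnorm(1 - alpha / 2) + qnorm(power))^2 * (sd1^2 + sd2^2) / delta^2
  as.integer(round(n))
}

#' Droplet-digital-PCR QC and mutant allele fraction
#'
#' Wells with fewer than `min_droplets` total droplets fail QC and are
#' excluded; the per-sample mutant fraction is mutant-positive droplets
#' over all allele-positive droplets, pooled over passing wells.
#'
#' @param wells `data.frame(sample_id, mutant, wildtype, total)`; counts
#'   must satisfy `total >= mutant + wildtype >= 0`.
#' @param min_droplets QC threshold on total droplets (default 7000; a
#'   6,999-droplet well is excluded, a 7,000-droplet well included).
#' @return List with `wells` (input plus `qc_pass`) and `samples`
#'   (`data.frame(sample_id, n_wells, n_pass, mutant, wildtype,
#'   fraction)`); samples without passing wells get `NA` fraction.
#' @export
ddpcr_fraction <- function(wells, min_droplets = 7000) {
  stopifnot(is.data.frame(wells),
            all(c("sample_id", "mutant", "wildtype", "total") %in% names(wells)))
  if (any(wells$mutant < 0 | wells$wildtype < 0))
    stop("negative droplet counts", call. = FALSE)
  if (any(wells$total < wells$mutant + wells$wildtype))
    stop("total droplets below mutant + wildtype", call. = FALSE)
  wells$qc_pass <- wells$total >= min_droplets
  samples <- do.call(rbind, lapply(split(wells, wells$sample_id), function(w) {
    p <- w[w$qc_pass, , drop = FALSE]
    mut <- sum(p$mutant); wt <- sum(p$wildtype)
    data.frame(sample_id = w$sample_id[1], n_wells = nrow(w),
               n_pass = nrow(p), mutant = mut, wildtype = wt,
               fraction = if (nrow(p) == 0L) NA_real_
                          else if (mut + wt == 0L) NA_real_
                          else mut / (mut + wt),
               stringsAsFactors = FALSE)
  }))
  rownames(samples) <- NULL
  list(wells = wells, samples = samples)
}

#' Summarize region carriers in a patient cohort
#'
#' Counts the patients carrying at least one variant inside a region (and
#' the subset whose variants are somatic) and reports percentages of the
#' cohort rounded to one decimal, the precision at which such cohort
#' fractions are conventionally quoted (e.g. 16 of 33 patients is 48.5%).
#'
#' @param variants Variant table for the cohort.
#' @param region Target region.
#' @param cohort_size Total number of patients in the cohort.
#' @return Object of class `carrier_summary`: list with `n_variants`,
#'   `n_carriers`, `carrier_pct`, `n_somatic_variants`,
#'   `n_somatic_carriers`, `somatic_carrier_pct`, `cohort_size`.
#' @export
region_carrier_summary <- function(variants, region, cohort_size) {
  region <- as_region(region)
  variants <- validate_variants(variants)
  if (cohort_size < 1) stop("cohort_size must be >= 1", call. = FALSE)
  inside <- variants$chrom == region$chrom &
    variants$pos >= region$start & variants$pos <= region$end
  v <- variants[inside, , drop = FALSE]
  som <- v[v$somatic_status == "somatic", , drop = FALSE]
  pct <- function(n) round(100 * n / cohort_size, 1)
  structure(list(
    region = region, cohort_size = as.integer(cohort_size),
    n_variants = length(unique(variant_key(v))),
    n_carriers = length(unique(v$sample_id)),
    carrier_pct = pct(length(unique(v$sample_id))),
    n_somatic_variants = length(unique(variant_key(som))),
    n_somatic_carriers = length(unique(som$sample_id)),
    somatic_carrier_pct = pct(length(unique(som$sample_id)))),
    class = "carrier_summary")
}

#' @export
print.carrier_summary <- function(x, ...) {
  cat("Region ")
  print(x$region)
  cat(sprintf("  %d variants in %d/%d patients (%.1f%%)\n",
              x$n_variants, x$n_carriers, x$cohort_size, x$carrier_pct))
  cat(sprintf("  somatic: %d variants in %d/%d patients (%.1f%%)\n",
              x$n_somatic_variants, x$n_somatic_carriers, x$cohort_size,
              x$somatic_carrier_pct))
  invisible(x)
}
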