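# Regional rare-variant enrichment scan.  A 2 Mb target region is tiled
# with overlapping windows (40 kb spaced every 100 bp by default); each
# window's observed count of distinct rare variants in the cancer cohort is
# compared against (i) the expected common-SNP density obtained by
# simulating cohort genotypes under Hardy-Weinberg equilibrium from panel
# allele frequencies, (ii) the same ratio statistic recomputed on resampled
# control-cohort subsets (order-statistic p-value), and (iii) a uniform-rate
# Poisson model for local hotspots.

#' Rare-variant filter configuration
#'
#' The discovery filter keeps single-nucleotide substitutions that are seen
#' in fewer than `max_samples` distinct samples (strict comparison: a
#' variant in exactly five samples is excluded when `max_samples = 5`),
#' absent from the reference allele-frequency panel, and flagged with a
#' high-quality caller flag.
#'
#' @param max_samples Recurrence cutoff; keep variants in strictly fewer
#'   distinct samples (default 5).
#' @param allowed_flags Caller flags that pass the quality gate.
#' @return A list of class `rare_filter_config`.
#' @export
rare_filter_config <- function(max_samples = 5,
                               allowed_flags = c("pass", "allele_bias")) {
  if (max_samples < 1) stop("max_samples must be >= 1", call. = FALSE)
  structure(list(max_samples = as.integer(max_samples),
                 allowed_flags = allowed_flags),
            class = "rare_filter_config")
}

#' Window-scan configuration
#'
#' Defaults reproduce the published scan design: 40 kb windows advanced by
#' 100 bp, a 33-sample cohort, 1000 genotype simulations for the expected
#' common-SNP profile, and 100 resampled control subsets for the
#' order-statistic p-value.
#'
#' @param window_size Window width in bp.
#' @param step Spacing between successive window starts, `1 <= step <=
#'   window_size`.
#' @param n_sim Number of Hardy-Weinberg genotype simulations.
#' @param cohort_size Individuals per simulated cohort and per control
#'   subset.
#' @param n_control_subsets Number of control subsets resampled for the
#'   order-statistic p-value.
#' @param density_mode `"carriers"` counts non-reference genotype calls
#'   summed over individuals (the published "heterozygotes or non-reference
#'   homozygotes across the profiles"); `"sites"` counts segregating sites
#'   instead.
#' @param seed Seed for the simulation null.
#' @return A list of class `window_scan_config`.
#' @export
window_scan_config <- function(window_size = 40000, step = 100,
                               n_sim = 1000, cohort_size = 33,
                               n_control_subsets = 100,
                               density_mode = c("carriers", "sites"),
                               seed = NULL) {
  if (step < 1 || window_size < step)
    stop("need window_size >= step >= 1", call. = FALSE)
  if (n_sim < 1 || n_control_subsets < 1)
    stop("n_sim and n_control_subsets must be >= 1", call. = FALSE)
  structure(list(window_size = as.integer(window_size), step = as.integer(step),
                 n_sim = as.integer(n_sim), cohort_size = as.integer(cohort_size),
                 n_control_subsets = as.integer(n_control_subsets),
                 density_mode = match.arg(density_mode), seed = seed),
            class = "window_scan_config")
}

#' Filter a cohort's calls down to high-quality rare variants
#'
#' @param variants Variant table with sample ids and quality flags.
#' @param panel An allele-frequency panel ([read_panel()]) or `NULL`.
#' @param config A [rare_filter_config()].
#' @return The rows of `variants` whose variant passes all three gates
#'   (recurrence, panel absence, quality).  Rows that are not
#'   single-nucleotide substitutions are removed first.
#' @export
filter_rare_variants <- function(variants, panel = NULL,
                                 config = rare_filter_config()) {
  stopifnot(inherits(config, "rare_filter_config"))
  variants <- validate_variants(variants, allow_non_snv = TRUE)
  if (nrow(variants) == 0L) return(empty_variant_table())
  variants <- variants[is_snv(variants), , drop = FALSE]
  ok_flag <- variants$quality_flag %in% config$allowed_flags
  key <- variant_key(variants)
  n_samples <- vapply(split(variants$sample_id, key),
                      function(s) length(unique(s)), integer(1))
  ok_rec <- n_samples[key] < config$max_samples
  ok_panel <- if (is.null(panel) || nrow(panel) == 0L) TRUE else
    !(key %in% paste(panel$chrom, panel$pos, panel$ref, panel$alt, sep = ":"))
  out <- variants[ok_flag & ok_rec & ok_panel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate scan windows over a region
#'
#' The first window starts at the region start; each subsequent window
#' advances by `step`; the last window ends at or before the region end, so
#' the number of windows is `floor((L - window_size)/step) + 1`.
#'
#' @param region Target region.
#' @param config A [window_scan_config()].
#' @return `data.frame(start, end)` of 1-based inclusive windows, in
#'   scan order.
#' @export
enumerate_windows <- function(region, config = window_scan_config()) {
  region <- as_region(region)
  L <- interval_length(region)
  if (L < config$window_size)
    stop("region shorter than one window", call. = FALSE)
  starts <- seq(region$start, region$end - config$window_size + 1,
                by = config$step)
  data.frame(start = starts, end = starts + config$window_size - 1)
}

# Distinct-variant count per window.  Positions of duplicated variant keys
# are counted once; windows may overlap, so counting uses cumulative order
# statistics rather than a partition.
count_in_windows <- function(pos, windows) {
  pos <- sort(pos)
  findInterval(windows$end, pos) - findInterval(windows$start - 1, pos)
}

count_rare_in_windows <- function(variants, windows) {
  uniq <- variants[!duplicated(variant_key(variants)), , drop = FALSE]
  count_in_windows(uniq$pos, windows)
}

# Window sums of a per-site quantity.
window_site_sums <- function(site_pos, site_value, windows) {
  o <- order(site_pos)
  cs <- c(0, cumsum(site_value[o]))
  sp <- site_pos[o]
  cs[findInterval(windows$end, sp) + 1L] -
    cs[findInterval(windows$start - 1, sp) + 1L]
}

#' Expected common-SNP density per window from genotype simulation
#'
#' For each of `n_sim` simulations, cohort genotypes are drawn under
#' Hardy-Weinberg equilibrium at every panel site with MAF above 5% inside
#' the region, and the non-reference genotype calls (individuals carrying
#' at least one alternate allele) are summed per window; the expectation is
#' the mean profile over simulations.  Per-site carrier counts are drawn as
#' Binomial(cohort, 2p(1-p) + p^2), which is exactly the distribution of
#' the carrier count in a simulated genotype matrix.
#'
#' @param panel Allele-frequency panel (or `data.frame` with `pos`, `maf`).
#' @param region Target region.
#' @param config A [window_scan_config()].
#' @param windows Optional precomputed windows (defaults to
#'   [enumerate_windows()]).
#' @param seed Optional seed (defaults to `config$seed`).
#' @return `data.frame(start, end, expected, variance)`; `expected` is the
#'   mean simulated count per window and `variance` the across-simulation
#'   variance, kept for diagnostics.  If no panel site with MAF > 5% falls
#'   in the region the expectation is all zero and flagged with a warning
#'   and attribute `"empty_panel"`.
#' @export
expected_common_density <- function(panel, region, config = window_scan_config(),
                                    windows = NULL, seed = NULL) {
  region <- as_region(region)
  windows <- windows %||% enumerate_windows(region, config)
  sites <- panel[panel$maf > 0.05 & panel$pos >= region$start &
                   panel$pos <= region$end, , drop = FALSE]
  if ("chrom" %in% names(sites))
    sites <- sites[sites$chrom == region$chrom, , drop = FALSE]
  out <- data.frame(start = windows$start, end = windows$end)
  if (nrow(sites) == 0L) {
    warning("no common (MAF > 5%) panel sites in region; expectation is zero")
    out$expected <- 0
    out$variance <- 0
    attr(out, "empty_panel") <- TRUE
    return(out)
  }
  p_carrier <- 2 * sites$maf * (1 - sites$maf) + sites$maf^2
  ns <- nrow(sites)
  sims <- with_seed(seed %||% config$seed, {
    m <- matrix(rbinom(ns * config$n_sim, config$cohort_size,
                       rep(p_carrier, config$n_sim)),
                nrow = ns, ncol = config$n_sim)
    if (config$density_mode == "sites") m <- (m > 0L) + 0L
    m
  })
  site_mean <- rowMeans(sims)
  site_var <- apply(sims, 1L, stats::var)
  out$expected <- window_site_sums(sites$pos, site_mean, windows)
  # sites are independent, so window variance is the sum of site variances
  out$variance <- window_site_sums(sites$pos, site_var, windows)
  attr(out, "site_means") <- data.frame(pos = sites$pos, mean = site_mean)
  out
}

#' Window ratio statistic
#'
#' The scan statistic is observed rare-variant count over expected
#' common-SNP count.  Windows with zero expectation but a positive
#' observation get an infinite sentinel (with a warning) and are excluded
#' from ranking; zero observed over zero expected is reported as 0.
#'
#' @param observed,expected Aligned per-window vectors.
#' @return Numeric vector of ratios.
#' @export
window_statistic <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected lengths differ", call. = FALSE)
  ratio <- ifelse(expected > 0, observed / expected,
                  ifelse(observed > 0, Inf, 0))
  if (any(is.infinite(ratio)))
    warning(sum(is.infinite(ratio)),
            " window(s) with observed > 0 but zero expectation; ",
            "ratio set to Inf and excluded from ranking")
  ratio
}

#' Order-statistic p-values from resampled control cohorts
#'
#' Repeatedly samples `n_control_subsets` subsets of `cohort_size`
#' individuals (without replacement within a subset, independently across
#' subsets) from a control population, recomputes the rare-variant filter
#' and the ratio statistic per window on each subset, and reports per
#' window the fraction of control statistics at least as large as the
#' observed one (ties count against significance).  Windows where no
#' control statistic reaches the observation are reported as censored at
#' `1/N` ("< 1/N") rather than zero.
#'
#' @param observed_ratio Per-window observed ratio statistic.
#' @param control_variants Variant table for the control population.
#' @param expected Per-window expected counts (denominator, shared with the
#'   observed statistic).
#' @param windows Window table.
#' @param config A [window_scan_config()].
#' @param filter A [rare_filter_config()] applied within each subset.
#' @param panel Optional panel for the subset-level rare filter.
#' @param seed Optional seed.
#' @return `data.frame(order_p, order_p_censored, n_exceed)`; `order_p` is
#'   `n_exceed / N`, floored at `1/N` when `n_exceed` is zero with
#'   `order_p_censored = TRUE`.
#' @export
control_order_statistic_p <- function(observed_ratio, control_variants,
                                      expected, windows,
                                      config = window_scan_config(),
                                      filter = rare_filter_config(),
                                      panel = NULL, seed = NULL) {
  control_variants <- validate_variants(control_variants)
  ids <- unique(control_variants$sample_id)
  if (length(ids) < config$cohort_size)
    stop("control population smaller than cohort_size", call. = FALSE)
  if (length(observed_ratio) != nrow(windows))
    stop("observed_ratio does not match windows", call. = FALSE)
  N <- config$n_control_subsets
  with_seed(seed %||% config$seed, {
    n_exceed <- integer(nrow(windows))
    for (b in seq_len(N)) {
      sub_ids <- sample(ids, config$cohort_size)
      sub <- control_variants[control_variants$sample_id %in% sub_ids, ,
                              drop = FALSE]
      sub_rare <- filter_rare_variants(sub, panel, filter)
      obs_b <- count_rare_in_windows(sub_rare, windows)
      stat_b <- suppressWarnings(window_statistic(obs_b, expected))
      n_exceed <- n_exceed + (stat_b >= observed_ratio)
    }
    data.frame(order_p = pmax(n_exceed, 1L) / N,
               order_p_censored = n_exceed == 0L,
               n_exceed = n_exceed)
  })
}

#' Poisson model of local variant enrichment
#'
#' Under the null hypothesis of uniform variant occurrence, the count in a
#' window of width `w` follows a Poisson distribution whose rate is the
#' global rate over the region times `w`.  The reported p-value is the
#' upper tail `P(X >= observed)`, the probability of observing at least
#' this many variants.
#'
#' @param variants Variant table (distinct variants are counted).
#' @param region Target region; the global rate is total / region length.
#' @param config A [window_scan_config()] (only the window geometry is
#'   used).
#' @param windows Optional precomputed window table.
#' @return `data.frame(start, end, observed, lambda, poisson_p)`.
#' @export
poisson_local_enrichment <- function(variants, region,
                                     config = window_scan_config(),
                                     windows = NULL) {
  region <- as_region(region)
  windows <- windows %||% enumerate_windows(region, config)
  uniq <- variants[!duplicated(variant_key(variants)), , drop = FALSE]
  uniq <- uniq[uniq$pos >= region$start & uniq$pos <= region$end, , drop = FALSE]
  total <- nrow(uniq)
  if (total < 1) stop("need at least one variant in the region", call. = FALSE)
  lambda <- total / interval_length(region) * (windows$end - windows$start + 1)
  observed <- count_in_windows(uniq$pos, windows)
  data.frame(start = windows$start, end = windows$end, observed = observed,
             lambda = lambda,
             poisson_p = ppois(observed - 1, lambda, lower.tail = FALSE))
}

#' Annotate variants with regulatory-track overlap
#'
#' Flags each variant for containment in each supplied interval track
#' (e.g. digital genomic footprints, DNaseI hypersensitive sites, ChIP-seq
#' peaks).  Intervals are 1-based inclusive: a variant at either interval
#' boundary overlaps.
#'
#' @param variants Variant table.
#' @param tracks Named list of interval `data.frame`s (`chrom`, `start`,
#'   `end`), e.g. from [read_bed()].
#' @return `variants` with one logical column per track plus
#'   `any_regulatory`; a summary count table is attached as attribute
#'   `"summary"`.
#' @export
annotate_regulatory_overlap <- function(variants, tracks) {
  stopifnot(is.list(tracks), length(names(tracks)) == length(tracks))
  variants <- validate_variants(variants)
  for (tn in names(tracks)) {
    tr <- tracks[[tn]]
    hit <- logical(nrow(variants))
    for (chr in unique(variants$chrom)) {
      vi <- which(variants$chrom == chr)
      ti <- tr$chrom == chr
      if (!any(ti) || !length(vi)) next
      q <- IRanges::IRanges(start = variants$pos[vi], width = 1L)
      s <- IRanges::IRanges(start = tr$start[ti], end = tr$end[ti])
      hit[vi] <- IRanges::countOverlaps(q, s) > 0L
    }
    variants[[tn]] <- hit
  }
  variants$any_regulatory <- Reduce(`|`, variants[names(tracks)],
                                    accumulate = FALSE) %||% logical(nrow(variants))
  smry <- c(vapply(names(tracks), function(tn) sum(variants[[tn]]), integer(1)),
            any = sum(variants$any_regulatory))
  attr(variants, "summary") <- smry
  variants
}

#' Run the full regional enrichment scan
#'
#' Combines window enumeration, distinct rare-variant counting, the
#' simulated expected common-SNP density, the ratio statistic, the Poisson
#' hotspot p-value and (when a control population is supplied) the
#' control-cohort order-statistic p-value into one result object.
#'
#' No multiple-testing correction is applied across the overlapping
#' windows; the scan is a localization device and neighboring windows are
#' strongly dependent.
#'
#' @param rare_variants Filtered rare-variant table for the case cohort
#'   (see [filter_rare_variants()]).
#' @param panel Allele-frequency panel for the expected-density null.
#' @param region Target region.
#' @param config A [window_scan_config()].
#' @param control_variants Optional control-population variant table.
#' @param filter Rare-variant filter applied within control subsets.
#' @return An object of class `window_scan`: a list with `windows` (the
#'   per-window result table), `region`, `config`, and summary fields.
#' @export
window_scan <- function(rare_variants, panel, region,
                        config = window_scan_config(),
                        control_variants = NULL,
                        filter = rare_filter_config()) {
  region <- as_region(region)
  windows <- enumerate_windows(region, config)
  exp_df <- expected_common_density(panel, region, config, windows)
  observed <- count_rare_in_windows(rare_variants, windows)
  ratio <- suppressWarnings(window_statistic(observed, exp_df$expected))
  pois <- poisson_local_enrichment(rare_variants, region, config, windows)
  res <- data.frame(start = windows$start, end = windows$end,
                    observed = observed, expected = exp_df$expected,
                    expected_var = exp_df$variance, ratio = ratio,
                    lambda = pois$lambda, poisson_p = pois$poisson_p)
  if (!is.null(control_variants)) {
    op <- control_order_statistic_p(ratio, control_variants, exp_df$expected,
                                    windows, config, filter, panel)
    res <- cbind(res, op)
  }
  rankable <- is.finite(res$ratio)
  structure(list(windows = res, region = region, config = config,
                 n_rare = length(unique(variant_key(rare_variants))),
                 top_window = res[rankable, , drop = FALSE][
                   which.max(res$ratio[rankable]), , drop = FALSE]),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat("Regional rare-variant enrichment scan\n  region: ")
  print(x$region)
  cat(sprintf("  %d windows of %s bp every %s bp; %d distinct rare variants\n",
              nrow(x$windows), format(x$config$window_size, big.mark = ","),
              format(x$config$step, big.mark = ","), x$n_rare))
  tw <- x$top_window
  cat(sprintf("  top window %s-%s: observed %d, expected %.1f, ratio %.2f, Poisson p %.3g\n",
              format(tw$start, big.mark = ","), format(tw$end, big.mark = ","),
              tw$observed, tw$expected, tw$ratio, tw$poisson_p))
  if (!is.null(tw$order_p))
    cat(sprintf("  top-window order-statistic p %s%.3g\n",
                if (tw$order_p_censored) "< " else "", tw$order_p))
  cat("  (no multiple-testing correction across overlapping windows)\n")
  invisible(x)
}

#' @export
summary.window_scan <- function(object, n_top = 5L, ...) {
  w <- object$windows[is.finite(object$windows$ratio), , drop = FALSE]
  w <- w[order(-w$ratio, w$poisson_p), , drop = FALSE]
  out <- list(top = utils::head(w, n_top),
              n_windows = nrow(object$windows),
              n_rare = object$n_rare,
              n_infinite = sum(is.infinite(object$windows$ratio)))
  class(out) <- "summary.window_scan"
  out
}

#' @export
print.summary.window_scan <- function(x, ...) {
  cat(sprintf("window scan: %d windows, %d distinct rare variants", x$n_windows,
              x$n_rare))
  if (x$n_infinite)
    cat(sprintf(" (%d windows with zero expectation excluded)", x$n_infinite))
  cat("\ntop windows by ratio statistic:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @param x A `window_scan` object.
#' @param what Which per-window series to plot.
#' @param ... Passed to [graphics::plot()].
#' @rdname window_scan
#' @export
plot.window_scan <- function(x, what = c("ratio", "observed", "poisson_p"), ...) {
  what <- match.arg(what)
  w <- x$windows
  mid <- (w$start + w$end) / 2
  y <- w[[what]]
  if (what == "poisson_p") y <- -log10(y)
  plot(mid, y, type = "l", xlab = paste0(x$region$chrom, " position"),
       ylab = if (what == "poisson_p") "-log10 Poisson p" else what, ...)
  invisible(x)
}

#' Extract the highest-ranking windows of a scan
#'
#' @param x A `window_scan` object.
#' @param n Number of windows.
#' @return The per-window rows with the largest finite ratio statistic.
#' @export
top_windows <- function(x, n = 10L) {
  stopifnot(inherits(x, "window_scan"))
  w <- x$windows[is.finite(x$windows$ratio), , drop = FALSE]
  utils::head(w[order(-w$ratio, w$poisson_p), , drop = FALSE], n)
}
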