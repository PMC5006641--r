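test_that("rare-variant filter applies recurrence, panel and quality gates", {
  # recurrence is strict: a variant in exactly 5 samples is excluded
  rec5 <- fixture_variants(rep(100L, 5), samples = paste0("s", 1:5))
  rec4 <- fixture_variants(rep(200L, 4), samples = paste0("s", 1:4))
  expect_equal(nrow(filter_rare_variants(rec5)), 0)
  expect_equal(nrow(filter_rare_variants(rec4)), 4)

  # hand-built table: 6 distinct variants; 2 too recurrent, 1 in the panel,
  # 1 with a failing flag -> 2 survive
  tab <- rbind(
    fixture_variants(rep(10L, 5), paste0("s", 1:5)),          # recurrent
    fixture_variants(rep(20L, 6), paste0("s", 1:6)),          # recurrent
    fixture_variants(30L, "s1"),                              # in panel
    fixture_variants(40L, "s1", flag = "other"),              # bad flag
    fixture_variants(50L, "s2"),                              # survives
    fixture_variants(60L, "s3", flag = "allele_bias"))        # survives
  panel <- fixture_panel(pos = 30L, maf = 0.2, ref = "A", alt = "G")
  kept <- filter_rare_variants(tab, panel)
  expect_setequal(kept$pos, c(50L, 60L))

  # non-SNV rows are removed up front
  messy <- tab[tab$pos == 50, ]
  messy$ref <- "AT"
  expect_equal(nrow(suppressWarnings(
    filter_rare_variants(rbind(tab[tab$pos == 60, ], messy)))), 1)
})

test_that("window enumeration matches the closed-form count", {
  cfg <- window_scan_config(window_size = 40000, step = 100, n_sim = 1)
  w <- enumerate_windows(genomic_interval("chr1", 1, 2e6), cfg)
  expect_equal(nrow(w), 19601)  # floor((2e6 - 4e4)/100) + 1
  expect_equal(w$start[1], 1)
  expect_equal(w$end[nrow(w)], 2e6)
  expect_true(all(w$end - w$start + 1 == 40000))
  expect_true(all(diff(w$start) == 100))

  cfg2 <- window_scan_config(window_size = 100, step = 10, n_sim = 1)
  expect_equal(nrow(enumerate_windows(genomic_interval("chr1", 1, 1000), cfg2)),
               91)
  # region exactly one window long
  cfg3 <- window_scan_config(window_size = 500, step = 500, n_sim = 1)
  expect_equal(nrow(enumerate_windows(genomic_interval("chr1", 1, 500), cfg3)), 1)
  expect_error(enumerate_windows(genomic_interval("chr1", 1, 499), cfg3),
               "shorter")
})

test_that("expected common-SNP density matches the carrier closed form", {
  region <- genomic_interval("chr1", 1, 40000)
  cfg <- window_scan_config(window_size = 40000, step = 40000,
                            n_sim = 2000, cohort_size = 33, seed = 5)
  # single site, maf 0.5: carrier expectation 33 * (2*0.25 + 0.25) = 24.75
  panel <- data.frame(pos = 1000L, maf = 0.5)
  e <- expected_common_density(panel, region, cfg)
  mc_se <- sqrt(e$variance / cfg$n_sim)
  expect_lt(abs(e$expected - 24.75), 3 * mc_se)

  # several sites: MC mean converges to sum of per-site carrier means
  panel2 <- data.frame(pos = c(100L, 5000L, 39000L), maf = c(0.08, 0.2, 0.45))
  analytic <- sum(33 * (2 * panel2$maf * (1 - panel2$maf) + panel2$maf^2))
  e2 <- expected_common_density(panel2, region, cfg)
  expect_lt(abs(e2$expected - analytic), 3 * sqrt(e2$variance / cfg$n_sim))

  # no common site in the region: zero expectation, flagged
  expect_warning(e0 <- expected_common_density(data.frame(pos = 1L, maf = 0.01),
                                               region, cfg),
                 "no common")
  expect_equal(e0$expected, 0)
  expect_true(isTRUE(attr(e0, "empty_panel")))
})

test_that("segregating-site density mode bounds the carrier mode", {
  region <- genomic_interval("chr1", 1, 10000)
  panel <- data.frame(pos = c(1000L, 4000L), maf = c(0.3, 0.1))
  base <- window_scan_config(window_size = 10000, step = 10000, n_sim = 1000,
                             cohort_size = 33, seed = 8)
  sites_cfg <- base; sites_cfg$density_mode <- "sites"
  e_car <- expected_common_density(panel, region, base)
  e_sit <- expected_common_density(panel, region, sites_cfg)
  expect_lte(e_sit$expected, e_car$expected)
  expect_lte(e_sit$expected, 2 + 1e-9)  # at most one count per site
})

test_that("the ratio statistic handles zero expectations by convention", {
  expect_equal(window_statistic(c(0, 5), c(2, 2)), c(0, 2.5))
  expect_warning(r <- window_statistic(c(3, 0), c(0, 0)), "zero expectation")
  expect_identical(r, c(Inf, 0))
  expect_error(window_statistic(1:3, 1:2), "lengths differ")
})

test_that("order-statistic p-values count control exceedances with >=", {
  region <- genomic_interval("chr1", 1, 10000)
  cfg <- window_scan_config(window_size = 5000, step = 5000, n_sim = 10,
                            cohort_size = 3, n_control_subsets = 100, seed = 2)
  windows <- enumerate_windows(region, cfg)
  expected <- c(10, 10)
  # control population large enough for many distinct subsets
  set.seed(13)
  ctrl <- do.call(rbind, lapply(1:12, function(i)
    fixture_variants(sample.int(10000, 20), sprintf("c%02d", i))))
  # observed below any control statistic -> p = 1
  p_lo <- control_order_statistic_p(c(0, 0), ctrl, expected, windows, cfg)
  expect_equal(p_lo$order_p, c(1, 1))
  # observed above all -> censored "< 1/N"
  p_hi <- control_order_statistic_p(c(99, 99), ctrl, expected, windows, cfg)
  expect_equal(p_hi$order_p, c(0.01, 0.01))
  expect_true(all(p_hi$order_p_censored))
  expect_equal(p_hi$n_exceed, c(0L, 0L))
  expect_error(control_order_statistic_p(c(0, 0), ctrl, expected, windows,
                                         window_scan_config(cohort_size = 99)),
               "smaller than cohort_size")
})

test_that("order-statistic p equals a direct exceedance count", {
  # one window; engineered controls where the per-subset statistic is the
  # subset's variant count over an expectation of 1
  region <- genomic_interval("chr1", 1, 100)
  cfg <- window_scan_config(window_size = 100, step = 100, n_sim = 1,
                            cohort_size = 1, n_control_subsets = 400, seed = 4)
  windows <- enumerate_windows(region, cfg)
  # 10 controls: half carry 2 in-window variants, half only out-of-window
  ctrl <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      fixture_variants(c(10L, 20L) + i, sprintf("hot%02d", i)))),
    fixture_variants(200L + 1:5, sprintf("cold%02d", 1:5)))
  p <- control_order_statistic_p(1.5, ctrl, expected = 1, windows, cfg)
  # subsets are single individuals: stat is 2 (hot) or 0 (cold); half exceed
  expect_lt(abs(p$order_p - 0.5), 0.1)
})

test_that("Poisson hotspot tail matches term-by-term summation", {
  # published global rate: 113 variants over 2 Mb, 40 kb windows
  lambda <- 113 / 2e6 * 40000
  direct_tail <- function(k, lam) 1 - sum(exp(-lam) * lam^(0:(k - 1)) /
                                            factorial(0:(k - 1)))
  set.seed(99)
  tab <- fixture_variants(sample.int(2e6, 113), "s1")
  scan <- poisson_local_enrichment(tab, genomic_interval("chr1", 1, 2e6),
                                   window_scan_config())
  expect_equal(scan$lambda[1], lambda)
  i8 <- which(scan$observed == max(scan$observed))[1]
  expect_equal(scan$poisson_p[i8],
               direct_tail(scan$observed[i8], lambda), tolerance = 1e-10)
  # observed 0 -> p = 1; monotone decreasing in the observed count
  expect_equal(ppois(-1, lambda, lower.tail = FALSE), 1)
  expect_true(all(diff(ppois(0:20 - 1, lambda, lower.tail = FALSE)) < 0))
})

test_that("regulatory-track overlap agrees with a linear scan", {
  tracks <- list(
    dnase = data.frame(chrom = "chr1", start = c(100, 500), end = c(199, 520)),
    tfbs = data.frame(chrom = "chr1", start = 150, end = 600))
  v <- fixture_variants(c(100L, 199L, 200L, 519L, 521L, 50L),
                        samples = "s1")
  ann <- annotate_regulatory_overlap(v, tracks)
  expect_equal(ann$dnase, c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(ann$tfbs, c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(attr(ann, "summary")["any"]), 5L)

  # randomized agreement with a brute-force containment scan
  set.seed(3)
  tr <- data.frame(chrom = "chr1",
                   start = sort(sample.int(10000, 30)))
  tr$end <- tr$start + sample.int(300, 30)
  v2 <- fixture_variants(sample.int(10000, 200), "s1")
  ann2 <- annotate_regulatory_overlap(v2, list(t = tr))
  brute <- vapply(v2$pos, function(p) any(p >= tr$start & p <= tr$end),
                  logical(1))
  expect_identical(ann2$t, brute)
})

test_that("order-statistic p-values are conservative under the null", {
  # cancer cohort drawn from the same population model as the controls
  region <- genomic_interval("chr1", 1, 2e5)
  model <- population_model(region, rare_site_rate = 4e-4)
  cases <- simulate_rare_variant_cohort(model, 20, seed = 51)
  ctrl <- simulate_rare_variant_cohort(model, 80, seed = 52,
                                       sample_prefix = "ctrl")
  cfg <- window_scan_config(window_size = 2000, step = 2000, n_sim = 10,
                            cohort_size = 20, n_control_subsets = 100, seed = 53)
  windows <- enumerate_windows(region, cfg)
  obs <- regionburden:::count_rare_in_windows(
    filter_rare_variants(cases), windows)
  expected <- rep(1, nrow(windows))
  stat <- window_statistic(obs, expected)
  p <- control_order_statistic_p(stat, ctrl, expected, windows, cfg)
  ks <- suppressWarnings(
    stats::ks.test(p$order_p, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_gte(min(p$order_p), 1 / cfg$n_control_subsets)
})

test_that("the assembled scan object is coherent", {
  region <- genomic_interval("chr1", 1, 1e5)
  model <- population_model(region,
                            simulate_common_sites(region, 80, seed = 61),
                            rare_site_rate = 3e-4,
                            enrichment_windows = data.frame(start = 40001,
                                                            end = 50000,
                                                            fold = 8))
  cases <- simulate_rare_variant_cohort(model, 33, seed = 62)
  al <- with_seed(63, regionburden:::random_alleles(nrow(model$common_sites)))
  panel <- allele_frequency_panel(
    data.frame(chrom = "chr1", pos = model$common_sites$pos, ref = al$ref,
               alt = al$alt, maf = model$common_sites$maf))
  cfg <- window_scan_config(window_size = 10000, step = 1000, n_sim = 100,
                            cohort_size = 33, seed = 64)
  scan <- window_scan(filter_rare_variants(cases, panel), panel, region, cfg)
  expect_s3_class(scan, "window_scan")
  w <- scan$windows
  expect_equal(nrow(w), 91)
  expect_true(all(w$observed >= 0) && all(w$expected >= 0))
  expect_true(all(w$poisson_p > 0 & w$poisson_p <= 1))
  # the 8-fold window region should hold the top ratio
  expect_true(scan$top_window$start >= 30001 && scan$top_window$start <= 50001)
  expect_output(print(scan), "top window")
  expect_output(print(summary(scan)), "top windows")
  expect_equal(nrow(top_windows(scan, 3)), 3)
})

test_that("an enriched window is recovered at window-scale resolution", {
  # a single 5-fold enriched 40 kb window at study-scale variant rates:
  # the top-ranked window overlaps it (the ratio argmax can drift up to
  # half a window toward low common-SNP-density neighborhoods), and the
  # count-based Poisson ranking localizes to within a few kb
  region <- genomic_interval("chr3", 181214714, 183214713)
  cfg <- window_scan_config(seed = 71)
  windows <- enumerate_windows(region, cfg)
  enr_start <- region$start + 1200000
  enr_idx <- which(windows$start == enr_start)
  common <- simulate_common_sites(region, 1600, seed = 72)
  model <- population_model(region, common, rare_site_rate = 26 / 2e6,
                            enrichment_windows = data.frame(
                              start = enr_start, end = enr_start + 39999,
                              fold = 5))
  exp_df <- expected_common_density(common, region, cfg, windows)
  hit_overlap <- hit_count <- 0L
  for (s in 1:50) {
    cohort <- simulate_rare_variant_cohort(model, cfg$cohort_size,
                                           seed = 7000 + s)
    obs <- regionburden:::count_rare_in_windows(cohort, windows)
    ratio <- window_statistic(obs, exp_df$expected)
    # top ratio window shares ground with the enriched window
    hit_overlap <- hit_overlap + (abs(which.max(ratio) - enr_idx) < 400L)
    # top count window (equivalently, smallest Poisson p) within 10 kb
    hit_count <- hit_count + (abs(which.max(obs) - enr_idx) <= 100L)
  }
  expect_gte(hit_overlap, 48)
  expect_gte(hit_count, 48)
})
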