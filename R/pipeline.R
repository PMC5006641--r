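# End-to-end orchestration: simulate -> ancestor filter -> window scan ->
# ontology enrichment -> biomarker statistics, from a single configuration,
# with one global seed deterministically deriving per-stage seeds so a rerun
# with the same configuration is bit-identical.

PIPELINE_STAGES <- c("simulate", "root_filter", "window_scan",
                     "enrichment", "biomarker")

# Per-stage seeds derived from the global seed; kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  (as.numeric(seed) + 1000003 * match(stage, PIPELINE_STAGES)) %% 2147483647
}

#' Pipeline configuration
#'
#' Collects every stage's parameters.  Any subset of stages can be
#' enabled; later stages consume the outputs of earlier ones, so enabling
#' a stage implies its inputs were produced in the same run.
#'
#' @param seed Global seed; per-stage seeds are derived from it
#'   deterministically.
#' @param region Target region (string or [genomic_interval()]).
#' @param stages Character vector of stages to run, a subset of
#'   `simulate`, `root_filter`, `window_scan`, `enrichment`, `biomarker`.
#' @param n_common_sites Common SNP sites simulated over the region.
#' @param rare_per_sample Expected rare variants per cohort sample.
#' @param cohort_size Number of cancer patients.
#' @param control_size Number of control individuals.
#' @param enriched_window Optional `c(start, end)` of a fold-enriched
#'   window.
#' @param enrichment_fold Rare-rate multiplier inside `enriched_window`.
#' @param islets An [islet_model()].
#' @param scan A [window_scan_config()].
#' @param filter A [rare_filter_config()].
#' @param ancestor An [ancestor_call_config()].
#' @param n_genes,ontology_sizes Gene annotation simulated for the
#'   enrichment stage.
#' @param n_perm Permutations for the ontology test.
#' @param ihc An [ihc_model()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            region = "chr3:181214714-183214713",
                            stages = PIPELINE_STAGES,
                            n_common_sites = 1600,
                            rare_per_sample = 26,
                            cohort_size = 33,
                            control_size = 100,
                            enriched_window = NULL,
                            enrichment_fold = 5,
                            islets = islet_model(),
                            scan = window_scan_config(),
                            filter = rare_filter_config(),
                            ancestor = ancestor_call_config(),
                            n_genes = 60,
                            ontology_sizes = c(5, 15, 30),
                            n_perm = 2000,
                            ihc = ihc_model()) {
  stages <- if (length(stages)) match.arg(stages, PIPELINE_STAGES,
                                          several.ok = TRUE) else character()
  structure(list(seed = seed, region = as_region(region), stages = stages,
                 n_common_sites = n_common_sites,
                 rare_per_sample = rare_per_sample,
                 cohort_size = cohort_size, control_size = control_size,
                 enriched_window = enriched_window,
                 enrichment_fold = enrichment_fold,
                 islets = islets, scan = scan, filter = filter,
                 ancestor = ancestor, n_genes = n_genes,
                 ontology_sizes = ontology_sizes, n_perm = n_perm,
                 ihc = ihc),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; nested
#' mappings `islets`, `scan`, `filter`, `ancestor` and `ihc` are passed to
#' the corresponding constructors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("seed", "region", "stages", "n_common_sites",
                        "rare_per_sample", "cohort_size", "control_size",
                        "enrichment_fold", "n_genes", "ontology_sizes",
                        "n_perm"))]
  if (!is.null(y$enriched_window))
    args$enriched_window <- unlist(y$enriched_window)
  if (!is.null(y$islets)) args$islets <- do.call(islet_model, y$islets)
  if (!is.null(y$scan)) args$scan <- do.call(window_scan_config, y$scan)
  if (!is.null(y$filter)) args$filter <- do.call(rare_filter_config, y$filter)
  if (!is.null(y$ancestor))
    args$ancestor <- do.call(ancestor_call_config, y$ancestor)
  if (!is.null(y$ihc)) {
    ihc <- y$ihc
    # the YAML 1.1 parser reads a bare `n:` key as a boolean
    names(ihc)[names(ihc) %in% c("FALSE", "no")] <- "n"
    args$ihc <- ihc_model(as.data.frame(ihc, stringsAsFactors = FALSE))
  }
  do.call(pipeline_config, args)
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[regionburden:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order, writes per-stage TSV
#' tables and a JSON summary under `output_dir`, and logs progress to the
#' message stream.  A rerun with the same configuration produces
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Output directory (created if needed), or `NULL` to
#'   skip writing files.
#' @return The report bundle, invisibly: a list with one element per
#'   executed stage plus `summary` (the JSON-serializable summary list).
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(output_dir) && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  out <- list()
  summary <- list(seed = config$seed,
                  region = with(config$region,
                                sprintf("%s:%.0f-%.0f", chrom, start, end)),
                  stages = config$stages)
  region <- config$region
  L <- interval_length(region)
  emit <- function(name, x) {
    if (!is.null(output_dir))
      write.table(x, file.path(output_dir, paste0(name, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  sim <- NULL
  if ("simulate" %in% config$stages) {
    s <- stage_seed(config$seed, "simulate")
    pipeline_log("simulate", "seed %d", s)
    common <- simulate_common_sites(region, config$n_common_sites, seed = s)
    rate <- config$rare_per_sample / L
    ew <- if (!is.null(config$enriched_window))
      data.frame(start = config$enriched_window[1],
                 end = config$enriched_window[2],
                 fold = config$enrichment_fold)
    model <- population_model(region, common, rare_site_rate = rate,
                              enrichment_windows = ew)
    cancer <- simulate_rare_variant_cohort(model, config$cohort_size,
                                           seed = s + 1,
                                           somatic_status = "somatic",
                                           sample_prefix = "case")
    # the injected enrichment is a tumor signal; controls carry background only
    null_model <- population_model(region, common, rare_site_rate = rate)
    controls <- simulate_rare_variant_cohort(null_model, config$control_size,
                                             seed = s + 2,
                                             sample_prefix = "ctrl")
    islets <- simulate_islet_callsets(config$islets, region, seed = s + 3)
    al <- with_seed(s + 4, random_alleles(nrow(common)))
    panel <- allele_frequency_panel(
      data.frame(chrom = region$chrom, pos = common$pos, ref = al$ref,
                 alt = al$alt, maf = common$maf, stringsAsFactors = FALSE),
      provenance = "simulated")
    ihc <- simulate_ihc_scores(config$ihc, seed = s + 5)
    sim <- list(model = model, panel = panel, cancer = cancer,
                controls = controls, islets = islets, ihc = ihc)
    out$simulate <- sim
    emit("cancer_variants", cancer)
    emit("control_variants", controls)
    emit("panel", as.data.frame(panel))
    emit("ihc_scores", ihc)
    summary$simulate <- list(n_cancer_variants = nrow(cancer),
                             n_control_variants = nrow(controls),
                             n_panel_sites = nrow(panel))
    pipeline_log("simulate", "%d cancer calls, %d control calls",
                 nrow(cancer), nrow(controls))
  }

  if ("root_filter" %in% config$stages) {
    if (is.null(sim)) stop("[root_filter] requires the simulate stage",
                           call. = FALSE)
    anc <- identify_ancestor_variants(sim$islets$islets, sim$islets$normal,
                                      config$ancestor)
    out$root_filter <- anc
    emit("ancestor_variants", as.data.frame(anc))
    summary$root_filter <- list(n_ancestor = nrow(anc),
                                threshold = config$ancestor$islet_presence_threshold)
    pipeline_log("root_filter", "%d ancestor variants (threshold %.2f)",
                 nrow(anc), config$ancestor$islet_presence_threshold)
  }

  if ("window_scan" %in% config$stages) {
    if (is.null(sim)) stop("[window_scan] requires the simulate stage",
                           call. = FALSE)
    s <- stage_seed(config$seed, "window_scan")
    cfg <- config$scan
    cfg$seed <- s
    rare <- filter_rare_variants(sim$cancer, sim$panel, config$filter)
    scan <- window_scan(rare, sim$panel, region, cfg,
                        control_variants = sim$controls,
                        filter = config$filter)
    out$window_scan <- scan
    emit("window_scan", scan$windows)
    top <- top_windows(scan, 5L)
    if (!is.null(output_dir))
      write_bed(data.frame(chrom = region$chrom, start = top$start,
                           end = top$end),
                file.path(output_dir, "top_windows.bed"))
    summary$window_scan <- list(
      n_windows = nrow(scan$windows), n_rare = scan$n_rare,
      top_window = as.list(scan$top_window[c("start", "end", "observed",
                                             "expected", "ratio",
                                             "poisson_p")]))
    pipeline_log("window_scan", "top window %d-%d ratio %.2f",
                 scan$top_window$start, scan$top_window$end,
                 scan$top_window$ratio)
  }

  if ("enrichment" %in% config$stages) {
    if (is.null(sim)) stop("[enrichment] requires the simulate stage",
                           call. = FALSE)
    s <- stage_seed(config$seed, "enrichment")
    ann <- simulate_gene_annotation(config$n_genes, L,
                                    config$ontology_sizes, seed = s,
                                    chrom = region$chrom)
    ann$genes$tss <- ann$genes$tss + region$start - 1
    domains <- assign_regulatory_domains(ann$genes)
    islet_union <- do.call(rbind, sim$islets$islets)
    fg <- islet_union[!duplicated(variant_key(islet_union)) &
                        islet_union$somatic_status == "somatic", , drop = FALSE]
    bg <- sim$cancer
    enr <- ontology_enrichment(fg, bg, ann$gene_sets, domains,
                               n_perm = config$n_perm, seed = s + 1)
    out$enrichment <- enr
    emit("ontology_enrichment", as.data.frame(enr))
    summary$enrichment <- list(n_sets = nrow(enr), n_hits = sum(enr$hit))
    pipeline_log("enrichment", "%d sets tested, %d hits", nrow(enr),
                 sum(enr$hit))
  }

  if ("biomarker" %in% config$stages) {
    if (is.null(sim)) stop("[biomarker] requires the simulate stage",
                           call. = FALSE)
    cmp <- group_comparison(sim$ihc)
    roc <- logistic_roc(sim$ihc,
                        case_group = setdiff(unique(sim$ihc$group), "benign")[1],
                        control_group = "benign")
    n_val <- sample_size_two_groups(3, 4, 14, 10)
    out$biomarker <- list(comparison = cmp, roc = roc,
                          validation_group_size = n_val)
    emit("ihc_tukey", cmp$tukey)
    emit("roc_points", roc$roc)
    summary$biomarker <- list(anova_f = cmp$anova_f, anova_p = cmp$anova_p,
                              auc = roc$auc,
                              validation_group_size = n_val)
    pipeline_log("biomarker", "ANOVA F %.2f, AUC %.3f", cmp$anova_f, roc$auc)
  }

  out$summary <- summary
  if (!is.null(output_dir)) {
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    pipeline_log("done", "report written to %s", output_dir)
  }
  invisible(out)
}
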