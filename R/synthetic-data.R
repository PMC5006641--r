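# Synthetic-data generators.  These emulate the statistical structure of the
# study inputs -- cohort genotypes at common SNPs under Hardy-Weinberg
# equilibrium, rare variants scattered over a target region, tumor-islet call
# sets sharing a founding clone, gene annotations, and per-case IHC intensity
# scores -- so that the whole pipeline can be exercised and calibrated
# without controlled-access patient data.

#' Population model for a target region
#'
#' Describes the variation expected in one contiguous genomic region: the
#' common SNPs (reference-panel sites with minor allele frequency above 5%)
#' and a homogeneous rare-variant process, optionally with fold-enriched
#' sub-windows.
#'
#' @param region A [genomic_interval()], region string, or list with
#'   `chrom`, `start`, `end`.
#' @param common_sites `data.frame` with columns `pos` and `maf`; all
#'   positions inside `region`, all `maf` in (0.05, 0.5].
#' @param rare_site_rate Expected rare variants per base pair per individual
#'   (>= 0).  The cohort-level density is `rare_site_rate * n_individuals`.
#' @param enrichment_windows Optional `data.frame` with columns `start`,
#'   `end`, `fold` (`fold >= 1`): sub-intervals whose rare-variant rate is
#'   multiplied by `fold`.
#' @param seed Default seed used by generators when they are not given one.
#' @return An object of class `population_model`.
#' @seealso [simulate_common_sites()] to draw a plausible `common_sites`
#'   table, [simulate_cohort_genotypes()], [simulate_rare_variant_cohort()].
#' @export
population_model <- function(region, common_sites = NULL,
                             rare_site_rate = 0, enrichment_windows = NULL,
                             seed = NULL) {
  region <- as_region(region)
  if (is.null(common_sites))
    common_sites <- data.frame(pos = numeric(), maf = numeric())
  stopifnot(is.data.frame(common_sites),
            all(c("pos", "maf") %in% names(common_sites)))
  if (nrow(common_sites)) {
    if (any(common_sites$pos < region$start | common_sites$pos > region$end))
      stop("common sites outside region", call. = FALSE)
    if (any(common_sites$maf <= 0.05 | common_sites$maf > 0.5))
      stop("common-site MAFs must lie in (0.05, 0.5]", call. = FALSE)
    if (anyDuplicated(common_sites$pos))
      stop("duplicated common-site positions", call. = FALSE)
    common_sites <- common_sites[order(common_sites$pos), , drop = FALSE]
    rownames(common_sites) <- NULL
  }
  if (!is.null(enrichment_windows)) {
    stopifnot(is.data.frame(enrichment_windows),
              all(c("start", "end", "fold") %in% names(enrichment_windows)))
    if (any(enrichment_windows$fold < 1))
      stop("enrichment fold must be >= 1", call. = FALSE)
    if (any(enrichment_windows$start < region$start |
            enrichment_windows$end > region$end |
            enrichment_windows$start > enrichment_windows$end))
      stop("enrichment windows must lie inside the region", call. = FALSE)
  }
  if (rare_site_rate < 0) stop("rare_site_rate must be >= 0", call. = FALSE)
  structure(list(region = region, common_sites = common_sites,
                 rare_site_rate = rare_site_rate,
                 enrichment_windows = enrichment_windows, seed = seed),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population model\n  region: ")
  print(x$region)
  cat(sprintf("  common SNPs (MAF > 5%%): %d\n", nrow(x$common_sites)))
  cat(sprintf("  rare-variant rate: %.3g /bp/individual\n", x$rare_site_rate))
  ew <- x$enrichment_windows
  if (!is.null(ew) && nrow(ew))
    cat(sprintf("  enriched windows: %d (fold %s)\n", nrow(ew),
                paste(unique(ew$fold), collapse = ", ")))
  invisible(x)
}

#' Draw a set of common SNP sites with random frequencies
#'
#' Convenience generator for the `common_sites` slot of a
#' [population_model()]: site positions uniform over the region, minor
#' allele frequencies uniform on (0.05, 0.5].
#'
#' @param region Target region.
#' @param n_sites Number of sites.
#' @param seed Optional seed.
#' @return `data.frame(pos, maf)` sorted by position.
#' @export
simulate_common_sites <- function(region, n_sites, seed = NULL) {
  region <- as_region(region)
  with_seed(seed, {
    pos <- sort(sample.int(interval_length(region), n_sites)) + region$start - 1
    data.frame(pos = pos, maf = runif(n_sites, 0.05 + 1e-9, 0.5))
  })
}

#' Simulate cohort genotypes at common sites under Hardy-Weinberg equilibrium
#'
#' Each site is treated independently (no linkage disequilibrium); a
#' genotype at a site with alternate-allele frequency `p` is the number of
#' alternate alleles in two independent draws, i.e. 0/1/2 with probabilities
#' (1-p)^2, 2p(1-p), p^2.
#'
#' @param model A [population_model()] (its `common_sites` are used), or a
#'   `data.frame(pos, maf)`.
#' @param n_individuals Cohort size (>= 1).
#' @param seed Optional seed (defaults to the model seed).
#' @return Integer matrix, individuals x sites, entries 0/1/2; column names
#'   are site positions.
#' @export
simulate_cohort_genotypes <- function(model, n_individuals, seed = NULL) {
  sites <- if (inherits(model, "population_model")) model$common_sites else model
  stopifnot(is.data.frame(sites), all(c("pos", "maf") %in% names(sites)))
  if (n_individuals < 1) stop("n_individuals must be >= 1", call. = FALSE)
  if (any(sites$maf < 0 | sites$maf > 1))
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  seed <- seed %||% (if (inherits(model, "population_model")) model$seed)
  ns <- nrow(sites)
  with_seed(seed, {
    g <- matrix(rbinom(n_individuals * ns, 2L,
                       rep(sites$maf, each = n_individuals)),
                nrow = n_individuals, ncol = ns,
                dimnames = list(sprintf("ind%04d", seq_len(n_individuals)),
                                as.character(sites$pos)))
    g
  })
}

# Piecewise-constant rare-variant intensity over the region: background rate
# everywhere, multiplied by `fold` inside enrichment windows.  Returns
# segment table (start, end, fold) covering the region exactly.
rare_rate_segments <- function(model) {
  region <- model$region
  ew <- model$enrichment_windows
  if (is.null(ew) || nrow(ew) == 0L)
    return(data.frame(start = region$start, end = region$end, fold = 1))
  ew <- ew[order(ew$start), , drop = FALSE]
  if (any(ew$start[-1] <= ew$end[-nrow(ew)]))
    stop("enrichment windows must not overlap", call. = FALSE)
  starts <- region$start
  segs <- list()
  cur <- region$start
  for (i in seq_len(nrow(ew))) {
    if (ew$start[i] > cur)
      segs[[length(segs) + 1L]] <- c(cur, ew$start[i] - 1, 1)
    segs[[length(segs) + 1L]] <- c(ew$start[i], ew$end[i], ew$fold[i])
    cur <- ew$end[i] + 1
  }
  if (cur <= region$end)
    segs[[length(segs) + 1L]] <- c(cur, region$end, 1)
  out <- as.data.frame(do.call(rbind, segs))
  names(out) <- c("start", "end", "fold")
  out
}

#' Simulate a cohort's rare variants
#'
#' Rare variants are modeled as independent singleton events per individual:
#' each individual receives a Poisson number of variants with mean
#' `rare_site_rate` per base pair (multiplied by `fold` inside enrichment
#' windows), placed uniformly within each intensity segment, at positions
#' distinct from the model's common SNP sites.
#'
#' @inheritParams simulate_cohort_genotypes
#' @param somatic_status Value for the `somatic_status` column (all rows).
#' @param sample_prefix Prefix for generated sample ids.
#' @return A variant table (see [variant_table()]); `genotype` is 1 and
#'   `quality_flag` `"pass"` for all simulated calls.
#' @export
simulate_rare_variant_cohort <- function(model, n_individuals, seed = NULL,
                                         somatic_status = "unknown",
                                         sample_prefix = "case") {
  stopifnot(inherits(model, "population_model"))
  if (n_individuals < 1) stop("n_individuals must be >= 1", call. = FALSE)
  if (model$rare_site_rate <= 0 &&
      (is.null(model$enrichment_windows) || nrow(model$enrichment_windows) == 0L))
    if (model$rare_site_rate < 0) stop("negative rate", call. = FALSE)
  seed <- seed %||% model$seed
  segs <- rare_rate_segments(model)
  seg_len <- segs$end - segs$start + 1
  seg_mass <- seg_len * segs$fold * model$rare_site_rate
  total_mean <- sum(seg_mass)
  common_pos <- model$common_sites$pos
  with_seed(seed, {
    n_per_ind <- rpois(n_individuals, total_mean)
    total <- sum(n_per_ind)
    if (total == 0L) return(empty_variant_table())
    seg_idx <- sample.int(nrow(segs), total, replace = TRUE,
                          prob = seg_mass / sum(seg_mass))
    pos <- segs$start[seg_idx] +
      floor(runif(total) * seg_len[seg_idx])
    # keep rare positions disjoint from the common-SNP stratum
    for (i in 1:20) {
      clash <- pos %in% common_pos
      if (!any(clash)) break
      si <- seg_idx[clash]
      pos[clash] <- segs$start[si] + floor(runif(sum(clash)) * seg_len[si])
    }
    al <- random_alleles(total)
    out <- data.frame(
      chrom = model$region$chrom,
      pos = as.integer(pos),
      ref = al$ref, alt = al$alt,
      sample_id = rep(sprintf("%s%04d", sample_prefix, seq_len(n_individuals)),
                      n_per_ind),
      genotype = 1L, quality_flag = "pass",
      somatic_status = somatic_status,
      stringsAsFactors = FALSE)
    # an individual carries a variant at most once
    out <- out[!duplicated(out[c("sample_id", "pos")]), , drop = FALSE]
    out <- out[order(out$pos, out$sample_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Tumor-islet clonal model
#'
#' Parameters of the simulated microdissection experiment: a founding
#' ("root") clone whose variants appear in a high fraction of islets,
#' islet-private variants, and germline variants shared with the matched
#' normal.
#'
#' @param n_islets Number of microdissected tumor islets (>= 1).
#' @param root_variants Number of variants in the founding clone.
#' @param root_presence Probability that an islet carries any given root
#'   variant; the discovery design targets >= 0.9.
#' @param private_rate Expected number of variants private to each islet.
#' @param germline_variants Number of variants shared by all islets and the
#'   matched normal.
#' @param seed Default seed for [simulate_islet_callsets()].
#' @return An object of class `islet_model`.
#' @export
islet_model <- function(n_islets = 30, root_variants = 750,
                        root_presence = 0.95, private_rate = 10,
                        germline_variants = 100, seed = NULL) {
  if (n_islets < 1) stop("n_islets must be >= 1", call. = FALSE)
  if (root_presence <= 0 || root_presence > 1)
    stop("root_presence must lie in (0, 1]", call. = FALSE)
  if (root_variants < 0 || private_rate < 0 || germline_variants < 0)
    stop("counts and rates must be >= 0", call. = FALSE)
  structure(list(n_islets = as.integer(n_islets),
                 root_variants = as.integer(root_variants),
                 root_presence = root_presence,
                 private_rate = private_rate,
                 germline_variants = as.integer(germline_variants),
                 seed = seed),
            class = "islet_model")
}

#' Simulate per-islet variant call sets and a matched normal
#'
#' Draws distinct loci for root, germline and islet-private variants inside
#' `region`; each root variant is carried by a Bernoulli(`root_presence`)
#' subset of islets, germline variants by every islet and the matched
#' normal, and private variants by exactly one islet.
#'
#' @param model An [islet_model()].
#' @param region Region in which loci are placed.
#' @param seed Optional seed (defaults to the model seed).
#' @return A list with components `islets` (named list of variant tables),
#'   `normal` (variant table) and `truth` (list of the generated root,
#'   germline and private variant keys, for validation).
#' @export
simulate_islet_callsets <- function(model,
                                    region = genomic_interval("chr3", 181214714, 183214713),
                                    seed = NULL) {
  stopifnot(inherits(model, "islet_model"))
  region <- as_region(region)
  seed <- seed %||% model$seed
  with_seed(seed, {
    n_private <- rpois(model$n_islets, model$private_rate)
    n_total <- model$root_variants + model$germline_variants + sum(n_private)
    if (n_total > interval_length(region))
      stop("region too short for requested variant counts", call. = FALSE)
    pos <- sample.int(interval_length(region), n_total) + region$start - 1
    al <- random_alleles(n_total)
    base <- data.frame(chrom = region$chrom, pos = as.integer(pos),
                       ref = al$ref, alt = al$alt, stringsAsFactors = FALSE)
    idx_root <- seq_len(model$root_variants)
    idx_germ <- seq_len(model$germline_variants) + model$root_variants
    idx_priv <- split(
      seq_len(sum(n_private)) + model$root_variants + model$germline_variants,
      rep(seq_len(model$n_islets), n_private))
    carried <- matrix(runif(model$root_variants * model$n_islets) <= model$root_presence,
                      nrow = model$root_variants)
    mk <- function(rows, sample_id, status) {
      if (!length(rows)) {
        out <- empty_variant_table()
      } else {
        out <- base[rows, , drop = FALSE]
        out$sample_id <- sample_id
        out$genotype <- 1L
        out$quality_flag <- "pass"
        out$somatic_status <- status
        rownames(out) <- NULL
      }
      out
    }
    islets <- lapply(seq_len(model$n_islets), function(i) {
      rows_i <- c(idx_root[carried[, i]], idx_germ,
                  idx_priv[[as.character(i)]] %||% integer())
      tab <- mk(sort(rows_i), sprintf("islet%02d", i),
                rep("unknown", length(rows_i)))
      tab$somatic_status <- ifelse(tab$pos %in% base$pos[idx_germ],
                                   "germline", "somatic")
      tab
    })
    names(islets) <- sprintf("islet%02d", seq_len(model$n_islets))
    normal <- mk(idx_germ, "normal", "germline")
    list(islets = islets, normal = normal,
         truth = list(root = variant_key(base[idx_root, , drop = FALSE]),
                      germline = variant_key(base[idx_germ, , drop = FALSE]),
                      private = variant_key(base[unlist(idx_priv), , drop = FALSE])))
  })
}

#' Simulate a gene annotation table and gene-set memberships
#'
#' Places `n_genes` transcription start sites uniformly at random on one
#' chromosome (sorted), assigns random strands, and samples one gene set of
#' each requested size without replacement.
#'
#' @param n_genes Number of genes (>= 1).
#' @param region_length Length in bp of the annotated stretch.
#' @param ontology_sizes Integer vector of gene-set sizes; each must be
#'   `<= n_genes`.
#' @param seed Optional seed.
#' @param chrom Chromosome name used for all genes.
#' @return List with `genes` (`data.frame(gene_id, chrom, tss, strand)`,
#'   sorted by `tss`) and `gene_sets` (named list of gene-id vectors).
#' @export
simulate_gene_annotation <- function(n_genes, region_length,
                                     ontology_sizes = integer(), seed = NULL,
                                     chrom = "chr1") {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (any(ontology_sizes > n_genes))
    stop("ontology size exceeds number of genes", call. = FALSE)
  with_seed(seed, {
    tss <- sort(sample.int(region_length, n_genes))
    genes <- data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
                        chrom = chrom, tss = tss,
                        strand = sample(c("+", "-"), n_genes, replace = TRUE),
                        stringsAsFactors = FALSE)
    gene_sets <- lapply(ontology_sizes, function(k) sample(genes$gene_id, k))
    names(gene_sets) <- sprintf("set%02d", seq_along(gene_sets))
    list(genes = genes, gene_sets = gene_sets)
  })
}

#' IHC cohort model
#'
#' Group-wise distribution of the percent of nuclei scored at the strongest
#' (3+) staining intensity.  Defaults follow the discovery-set estimates
#' used for the validation power calculation: benign mean 3 / sd 4 and
#' HGSOC mean 14 / sd 10 percent, with cohort sizes matching the first
#' validation set (46 benign, 42 HGSOC).
#'
#' @param groups `data.frame` with columns `group`, `mean`, `sd`, `n`
#'   (`sd > 0` unless exactly 0 is requested for degenerate checks,
#'   `n >= 2`).
#' @param seed Optional default seed.
#' @return An object of class `ihc_model`.
#' @export
ihc_model <- function(groups = data.frame(
                        group = c("benign", "hgsoc_fte"),
                        mean = c(3, 14), sd = c(4, 10), n = c(46, 42)),
                      seed = NULL) {
  stopifnot(is.data.frame(groups),
            all(c("group", "mean", "sd", "n") %in% names(groups)))
  if (any(groups$sd < 0)) stop("sds must be >= 0", call. = FALSE)
  if (any(groups$n < 2)) stop("need n >= 2 per group", call. = FALSE)
  structure(list(groups = groups, seed = seed), class = "ihc_model")
}

# Censored-normal draw on [lo, hi]: mass outside the bounds collapses onto
# them.  For percent-positive IHC readouts the resulting point mass at 0 is
# the realistic feature (many benign tubes have no strong-staining nuclei),
# and rank-based AUC with midrank ties stays at the binormal value.
rcensnorm <- function(n, mean, sd, lo = 0, hi = 100) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Simulate per-case IHC intensity scores
#'
#' Draws each case's percent of 3+ (strong) nuclei from its group's normal
#' distribution censored to \[0, 100\] and splits the remaining mass among
#' the 0/1+/2+ bins with random Dirichlet(1,1,1) weights, so the four bin
#' percentages sum to 100 per case.
#'
#' @param model An [ihc_model()].
#' @param seed Optional seed (defaults to the model seed).
#' @return `data.frame(case_id, group, pct0, pct1, pct2, pct3)`.
#' @export
simulate_ihc_scores <- function(model, seed = NULL) {
  stopifnot(inherits(model, "ihc_model"))
  seed <- seed %||% model$seed
  g <- model$groups
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      n <- g$n[i]
      pct3 <- rcensnorm(n, g$mean[i], g$sd[i])
      rem <- 100 - pct3
      w <- matrix(rexp(3 * n), ncol = 3)
      w <- w / rowSums(w)
      pct0 <- rem * w[, 1]
      pct1 <- rem * w[, 2]
      pct2 <- rem - pct0 - pct1   # forces exact conservation
      data.frame(case_id = sprintf("%s_%03d", g$group[i], seq_len(n)),
                 group = g$group[i],
                 pct0 = pct0, pct1 = pct1, pct2 = pct2, pct3 = pct3,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
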