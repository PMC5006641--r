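# GREAT-style regulatory-domain assignment and gene-ontology enrichment of
# non-coding variants, with an empirical permutation null.  Each gene owns a
# basal domain around its TSS (5 kb upstream / 1 kb downstream,
# strand-aware) extended up to 1 Mb per side but never into a neighboring
# gene's basal domain; a variant maps to every gene whose extended domain
# contains it.

#' Assign GREAT-style regulatory domains to genes
#'
#' @param genes `data.frame(gene_id, chrom, tss, strand)`; ids must be
#'   unique.
#' @param basal_up,basal_down Basal domain extent upstream/downstream of
#'   the TSS in transcription direction (defaults 5 kb / 1 kb).
#' @param max_extension Maximum extension per side beyond the basal domain
#'   (default 1 Mb); the extension additionally stops at the nearest
#'   neighboring basal domain and at position 1 / the chromosome end.
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   clipping.
#' @return `data.frame` of class `regulatory_domains` with columns
#'   `gene_id`, `chrom`, `tss`, `strand`, `basal_start`, `basal_end`,
#'   `ext_start`, `ext_end`.
#' @export
assign_regulatory_domains <- function(genes, basal_up = 5000,
                                      basal_down = 1000,
                                      max_extension = 1e6,
                                      chrom_lengths = NULL) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  plus <- genes$strand == "+"
  basal_start <- ifelse(plus, genes$tss - basal_up, genes$tss - basal_down)
  basal_end <- ifelse(plus, genes$tss + basal_down, genes$tss + basal_up)
  basal_start <- pmax(basal_start, 1)
  clip_end <- function(chrom, x) {
    if (is.null(chrom_lengths)) return(x)
    lim <- chrom_lengths[chrom]
    ifelse(is.na(lim), x, pmin(x, lim))
  }
  basal_end <- clip_end(genes$chrom, basal_end)
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    tss = genes$tss, strand = genes$strand,
                    basal_start = basal_start, basal_end = basal_end,
                    ext_start = NA_real_, ext_end = NA_real_,
                    stringsAsFactors = FALSE)
  for (chr in unique(out$chrom)) {
    i <- which(out$chrom == chr)
    bs <- out$basal_start[i]; be <- out$basal_end[i]
    n <- length(i)
    left_block <- right_block <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      # nearest basal boundary the left extension can run into: the
      # largest basal end among genes whose basal starts strictly before
      # this one (an overlapping basal clamps the extension to zero)
      lj <- bs < bs[k] & seq_len(n) != k
      if (any(lj)) left_block[k] <- max(be[lj])
      rj <- be > be[k] & seq_len(n) != k
      if (any(rj)) right_block[k] <- min(bs[rj])
    }
    es <- pmax(bs - max_extension, 1,
               ifelse(is.na(left_block), -Inf, pmin(left_block + 1, bs)))
    ee <- pmin(be + max_extension,
               ifelse(is.na(right_block), Inf, pmax(right_block - 1, be)))
    ee <- clip_end(out$chrom[i], ee)
    out$ext_start[i] <- es
    out$ext_end[i] <- ee
  }
  class(out) <- c("regulatory_domains", class(out))
  out
}

#' Map variants to genes through regulatory domains
#'
#' In `"domain"` mode (the GREAT model) a variant is assigned to every
#' gene whose extended regulatory domain contains it, so one variant may
#' map to several genes; in `"nearest_tss"` mode it is assigned to the
#' single gene with the closest TSS (ties broken toward the first gene in
#' annotation order).  Variants contained in no domain are returned with
#' `gene_id = NA`.
#'
#' @param variants Variant table.
#' @param domains A [assign_regulatory_domains()] table.
#' @param mode Assignment mode.
#' @return `data.frame(chrom, pos, ref, alt, gene_id, in_basal,
#'   distance_to_tss)`, one row per (variant, gene) assignment; distinct
#'   variants only.
#' @export
map_variants_to_genes <- function(variants, domains,
                                  mode = c("domain", "nearest_tss")) {
  mode <- match.arg(mode)
  variants <- validate_variants(variants)
  uniq <- variants[!duplicated(variant_key(variants)),
                   c("chrom", "pos", "ref", "alt"), drop = FALSE]
  rownames(uniq) <- NULL
  if (nrow(uniq) == 0L)
    return(cbind(uniq, gene_id = character(), in_basal = logical(),
                 distance_to_tss = numeric()))
  pieces <- list()
  for (chr in unique(uniq$chrom)) {
    vi <- which(uniq$chrom == chr)
    di <- which(domains$chrom == chr)
    v <- uniq[vi, , drop = FALSE]
    if (!length(di)) {
      pieces[[chr]] <- cbind(v, gene_id = NA_character_, in_basal = FALSE,
                             distance_to_tss = NA_real_)
      next
    }
    d <- domains[di, , drop = FALSE]
    if (mode == "nearest_tss") {
      nearest <- vapply(v$pos, function(p) {
        dist <- abs(d$tss - p)
        which.min(dist)  # ties: first gene in annotation order
      }, integer(1))
      pieces[[chr]] <- cbind(v, gene_id = d$gene_id[nearest],
                             in_basal = v$pos >= d$basal_start[nearest] &
                               v$pos <= d$basal_end[nearest],
                             distance_to_tss = abs(d$tss[nearest] - v$pos))
    } else {
      q <- IRanges::IRanges(start = v$pos, width = 1L)
      s <- IRanges::IRanges(start = d$ext_start, end = d$ext_end)
      ov <- IRanges::findOverlaps(q, s)
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      assigned <- cbind(v[qh, , drop = FALSE],
                        gene_id = d$gene_id[sh],
                        in_basal = v$pos[qh] >= d$basal_start[sh] &
                          v$pos[qh] <= d$basal_end[sh],
                        distance_to_tss = abs(d$tss[sh] - v$pos[qh]))
      un <- setdiff(seq_len(nrow(v)), unique(qh))
      if (length(un))
        assigned <- rbind(assigned,
                          cbind(v[un, , drop = FALSE], gene_id = NA_character_,
                                in_basal = FALSE, distance_to_tss = NA_real_))
      pieces[[chr]] <- assigned
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$pos, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# fraction of distinct variants mapping to >= 1 gene of the set, plus the
# per-variant membership indicator used by the permutation null
set_membership <- function(assignments, gene_set) {
  keys <- paste(assignments$chrom, assignments$pos, assignments$ref,
                assignments$alt, sep = ":")
  hit <- !is.na(assignments$gene_id) & assignments$gene_id %in% gene_set
  tapply(hit, keys, any)
}

#' Permutation p-value for one gene set
#'
#' Samples `n_perm` foreground-sized subsets of the background without
#' replacement, recomputes the enrichment (which, for a fixed background,
#' reduces to the subset's fraction of set-mapped variants over the
#' background fraction), and reports the fraction of permutations with
#' enrichment strictly higher than observed (ties favor the null).  Zero
#' exceedances are reported censored at `1/n_perm`.
#'
#' @param fg_variants,bg_variants Foreground and background variant
#'   tables; the background must be at least as large as the foreground.
#' @param gene_set Character vector of member gene ids.
#' @param domains Regulatory-domain table.
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Optional seed.
#' @param mode Variant-to-gene assignment mode.
#' @return List with `p`, `censored`, `observed_enrichment`, `n_exceed`.
#' @export
permutation_p <- function(fg_variants, bg_variants, gene_set, domains,
                          n_perm = 10000, seed = NULL,
                          mode = c("domain", "nearest_tss")) {
  mode <- match.arg(mode)
  fg_m <- set_membership(map_variants_to_genes(fg_variants, domains, mode),
                         gene_set)
  bg_m <- set_membership(map_variants_to_genes(bg_variants, domains, mode),
                         gene_set)
  n_fg <- length(fg_m); n_bg <- length(bg_m)
  if (n_bg < n_fg) stop("background smaller than foreground", call. = FALSE)
  fg_frac <- mean(fg_m); bg_frac <- mean(bg_m)
  obs <- if (bg_frac > 0) fg_frac / bg_frac else NA_real_
  n_exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b)
      mean(bg_m[sample.int(n_bg, n_fg)]) > fg_frac, logical(1)))
  })
  list(p = max(n_exceed, 1L) / n_perm, censored = n_exceed == 0L,
       observed_enrichment = obs, n_exceed = n_exceed)
}

#' Gene-ontology enrichment of foreground versus background variants
#'
#' For each gene set, computes the ratio of the fraction of foreground
#' variants mapping (through regulatory domains) to genes of the set to
#' the same fraction among background variants, a permutation p-value
#' (foreground-sized resamples of the background, shared across sets),
#' Benjamini-Hochberg q-values across sets, and the hit rule: q < 0.01
#' and more than ten distinct supporting genes.
#'
#' @inheritParams permutation_p
#' @param gene_sets Named list of gene-id vectors.
#' @param q_cutoff,min_genes Hit rule: `q_value < q_cutoff` and
#'   `n_supporting_genes > min_genes`.
#' @return `data.frame` of class `ontology_enrichment` with one row per
#'   set: `set`, `fg_fraction`, `bg_fraction`, `enrichment`,
#'   `n_supporting_genes`, `permutation_p`, `p_censored`, `q_value`,
#'   `hit`.  Sets with zero background fraction get `NA` enrichment.
#' @export
ontology_enrichment <- function(fg_variants, bg_variants, gene_sets, domains,
                                n_perm = 10000, seed = NULL,
                                mode = c("domain", "nearest_tss"),
                                q_cutoff = 0.01, min_genes = 10) {
  mode <- match.arg(mode)
  stopifnot(length(gene_sets) >= 1, !is.null(names(gene_sets)))
  fg_assign <- map_variants_to_genes(fg_variants, domains, mode)
  bg_assign <- map_variants_to_genes(bg_variants, domains, mode)
  if (!nrow(fg_assign) || !nrow(bg_assign))
    stop("foreground and background must be nonempty", call. = FALSE)
  fg_M <- vapply(gene_sets, function(gs) set_membership(fg_assign, gs),
                 logical(length(unique(paste(fg_assign$chrom, fg_assign$pos,
                                             fg_assign$ref, fg_assign$alt,
                                             sep = ":")))))
  bg_M <- vapply(gene_sets, function(gs) set_membership(bg_assign, gs),
                 logical(length(unique(paste(bg_assign$chrom, bg_assign$pos,
                                             bg_assign$ref, bg_assign$alt,
                                             sep = ":")))))
  fg_M <- matrix(fg_M, ncol = length(gene_sets),
                 dimnames = list(NULL, names(gene_sets)))
  bg_M <- matrix(bg_M, ncol = length(gene_sets),
                 dimnames = list(NULL, names(gene_sets)))
  n_fg <- nrow(fg_M); n_bg <- nrow(bg_M)
  if (n_bg < n_fg) stop("background smaller than foreground", call. = FALSE)
  fg_frac <- colMeans(fg_M); bg_frac <- colMeans(bg_M)
  enrich <- ifelse(bg_frac > 0, fg_frac / bg_frac, NA_real_)
  n_support <- vapply(gene_sets, function(gs) {
    hits <- fg_assign$gene_id[!is.na(fg_assign$gene_id) &
                                fg_assign$gene_id %in% gs]
    length(unique(hits))
  }, integer(1))
  # one set of permutation draws shared across sets
  n_exceed <- with_seed(seed, {
    ne <- integer(length(gene_sets))
    for (b in seq_len(n_perm)) {
      s <- sample.int(n_bg, n_fg)
      ne <- ne + (colMeans(bg_M[s, , drop = FALSE]) > fg_frac)
    }
    ne
  })
  p <- pmax(n_exceed, 1L) / n_perm
  out <- data.frame(set = names(gene_sets),
                    fg_fraction = fg_frac, bg_fraction = bg_frac,
                    enrichment = enrich,
                    n_supporting_genes = n_support,
                    permutation_p = p, p_censored = n_exceed == 0L,
                    q_value = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$hit <- out$q_value < q_cutoff & out$n_supporting_genes > min_genes
  rownames(out) <- NULL
  class(out) <- c("ontology_enrichment", class(out))
  attr(out, "n_fg") <- n_fg
  attr(out, "n_bg") <- n_bg
  attr(out, "n_perm") <- n_perm
  out
}

#' @export
print.ontology_enrichment <- function(x, ...) {
  cat(sprintf("Ontology enrichment: %d foreground vs %d background variants, %d permutations\n",
              attr(x, "n_fg"), attr(x, "n_bg"), attr(x, "n_perm")))
  df <- as.data.frame(x)
  df$permutation_p <- ifelse(x$p_censored,
                             paste0("< ", format(x$permutation_p)),
                             format(x$permutation_p))
  print(df[setdiff(names(df), "p_censored")], row.names = FALSE, digits = 3)
  invisible(x)
}
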