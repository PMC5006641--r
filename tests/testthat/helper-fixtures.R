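# Shared fixture builders.  Everything is generated in code; tests that
# need randomness take a fixed seed so the suite is reproducible.

# A hand-sized variant table: one row per (sample, variant).
fixture_variants <- function(pos, samples, chrom = "chr1", ref = "A",
                             alt = "G", flag = "pass", status = "unknown") {
  variant_table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                sample_id = samples, quality_flag = flag,
                somatic_status = status)
}

# Small allele-frequency panel on chr1.
fixture_panel <- function(pos, maf, chrom = "chr1", ref = "A", alt = "C") {
  allele_frequency_panel(data.frame(chrom = chrom, pos = pos, ref = ref,
                                    alt = alt, maf = maf,
                                    stringsAsFactors = FALSE))
}

# Random gene layout for domain tests.
fixture_genes <- function(n, span, seed = NULL, chrom = "chr1") {
  with_seed(seed, {
    data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
               tss = sort(sample.int(span, n)),
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

# Brute-force regulatory-domain oracle: direct pairwise definition of the
# basal domain and the extension clipped at every other gene's basal.
oracle_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                           max_extension = 1e6) {
  n <- nrow(genes)
  bs <- be <- es <- ee <- numeric(n)
  for (i in seq_len(n)) {
    if (genes$strand[i] == "+") {
      bs[i] <- genes$tss[i] - basal_up; be[i] <- genes$tss[i] + basal_down
    } else {
      bs[i] <- genes$tss[i] - basal_down; be[i] <- genes$tss[i] + basal_up
    }
    bs[i] <- max(bs[i], 1)
  }
  for (i in seq_len(n)) {
    lo <- max(bs[i] - max_extension, 1)
    hi <- be[i] + max_extension
    for (j in seq_len(n)) {
      if (j == i || genes$chrom[j] != genes$chrom[i]) next
      # walk the left extension back until it no longer touches basal j
      if (be[j] >= bs[i] && bs[j] < bs[i]) lo <- bs[i]
      else if (be[j] < bs[i]) lo <- max(lo, be[j] + 1)
      if (bs[j] <= be[i] && be[j] > be[i]) hi <- be[i]
      else if (bs[j] > be[i]) hi <- min(hi, bs[j] - 1)
    }
    es[i] <- lo; ee[i] <- hi
  }
  data.frame(gene_id = genes$gene_id, basal_start = bs, basal_end = be,
             ext_start = es, ext_end = ee, stringsAsFactors = FALSE)
}
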