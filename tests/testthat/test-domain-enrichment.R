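test_that("basal and extended domains follow the GREAT constants", {
  # isolated + strand gene: basal [tss-5kb, tss+1kb], extension 1 Mb per side
  g <- data.frame(gene_id = "g1", chrom = "chr1", tss = 2e6, strand = "+")
  d <- assign_regulatory_domains(g)
  expect_equal(d$basal_start, 1995000)
  expect_equal(d$basal_end, 2001000)
  expect_equal(d$ext_start, 995000)
  expect_equal(d$ext_end, 3001000)

  # minus strand mirrors the basal domain
  gm <- data.frame(gene_id = "g1", chrom = "chr1", tss = 2e6, strand = "-")
  dm <- assign_regulatory_domains(gm)
  expect_equal(dm$basal_start, 1999000)
  expect_equal(dm$basal_end, 2005000)

  # two abutting basal domains leave zero extension on the facing sides
  g2 <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                   tss = c(10000, 16001), strand = c("+", "+"))
  d2 <- assign_regulatory_domains(g2)
  # a: basal [5000, 11000]; b: basal [11001, 17001]
  expect_equal(d2$ext_end[1], d2$basal_end[1])
  expect_equal(d2$ext_start[2], d2$basal_start[2])
  expect_error(assign_regulatory_domains(rbind(g2, g2[1, ])), "duplicate")
})

test_that("domain assignment matches the brute-force oracle on random layouts", {
  set.seed(101)
  for (rep in 1:1000) {
    n <- sample(2:8, 1)
    genes <- fixture_genes(n, span = 200000)
    d <- assign_regulatory_domains(genes, max_extension = 30000)
    o <- oracle_domains(genes, max_extension = 30000)
    expect_identical(d$basal_start, o$basal_start)
    expect_identical(d$basal_end, o$basal_end)
    expect_equal(d$ext_start, o$ext_start)
    expect_equal(d$ext_end, o$ext_end)
    # structural invariants
    expect_true(all(d$ext_start <= d$basal_start))
    expect_true(all(d$ext_end >= d$basal_end))
    expect_true(all(d$basal_start - d$ext_start <= 30000))
    expect_true(all(d$ext_end - d$basal_end <= 30000))
    for (i in seq_len(n)) {
      others <- d[-i, , drop = FALSE]
      left <- d$ext_start[i] <= others$basal_end &
        d$basal_start[i] - 1 >= others$basal_start
      right <- d$ext_end[i] >= others$basal_start &
        d$basal_end[i] + 1 <= others$basal_end
      expect_false(any(left & others$basal_end < d$basal_start[i]))
      expect_false(any(right & others$basal_start > d$basal_end[i]))
    }
  }
})

test_that("variants map to every containing extended domain", {
  genes <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                      tss = c(50000, 70000), strand = c("+", "+"))
  d <- assign_regulatory_domains(genes)
  # inside a's basal only -> a alone
  v_basal <- fixture_variants(46000L, "s1")
  m1 <- map_variants_to_genes(v_basal, d)
  expect_equal(m1$gene_id, "a")
  expect_true(m1$in_basal)
  # between the genes, in both extended domains -> both genes
  v_mid <- fixture_variants(60000L, "s1")
  m2 <- map_variants_to_genes(v_mid, d)
  expect_setequal(m2$gene_id, c("a", "b"))
  # nearest-TSS mode assigns a single gene
  m2n <- map_variants_to_genes(v_mid, d, mode = "nearest_tss")
  expect_equal(m2n$gene_id, "a")
  # far outside every domain -> unassigned
  v_far <- fixture_variants(9000000L, "s1")
  expect_true(is.na(map_variants_to_genes(v_far, d)$gene_id))

  # randomized agreement with a linear containment scan
  genes_r <- fixture_genes(12, span = 500000, seed = 7)
  dr <- assign_regulatory_domains(genes_r, max_extension = 50000)
  vr <- with_seed(8, fixture_variants(sample.int(500000, 300), "s1"))
  mr <- map_variants_to_genes(vr, dr)
  got <- split(mr$gene_id[!is.na(mr$gene_id)], mr$pos[!is.na(mr$gene_id)])
  for (p in unique(vr$pos)) {
    want <- dr$gene_id[dr$ext_start <= p & dr$ext_end >= p]
    if (length(want)) expect_setequal(got[[as.character(p)]], want)
    else expect_null(got[[as.character(p)]])
  }
})

test_that("enrichment ratios and the hit rule follow their definitions", {
  genes <- fixture_genes(20, span = 1e6, seed = 11)
  d <- assign_regulatory_domains(genes, max_extension = 10000)
  # identical fg and bg -> enrichment exactly 1 wherever defined
  v <- with_seed(12, fixture_variants(sample.int(1e6, 200), "s1"))
  sets <- list(setA = genes$gene_id[1:6], setB = genes$gene_id[7:20])
  enr <- ontology_enrichment(v, v, sets, d, n_perm = 50, seed = 13)
  defined <- !is.na(enr$enrichment)
  expect_true(all(enr$enrichment[defined] == 1))

  # arithmetic example: fg 4/10 mapped, bg 10/100 mapped -> enrichment 4
  g1 <- data.frame(gene_id = "hub", chrom = "chr1", tss = 5000, strand = "+")
  dh <- assign_regulatory_domains(g1, max_extension = 0)   # domain = basal only
  fg <- fixture_variants(c(seq(1000L, 4000L, by = 1000L),          # 4 inside
                           seq(100000L, 105000L, by = 1000L)), "s1")  # 6 out
  bg <- fixture_variants(c(seq(1000L, 5500L, by = 500L),           # 10 inside
                           seq(200000L, 289000L, by = 1000L)), "s1")  # 90 out
  eh <- ontology_enrichment(fg, bg, list(s = "hub"), dh, n_perm = 10, seed = 1)
  expect_equal(eh$fg_fraction, 0.4)
  expect_equal(eh$bg_fraction, 0.1)
  expect_equal(eh$enrichment, 4)

  # hit rule needs q < 0.01 AND more than ten supporting genes
  expect_false(eh$hit)  # only one supporting gene regardless of p
})

test_that("permutation p matches exhaustive enumeration on a tiny background", {
  gene <- data.frame(gene_id = "g", chrom = "chr1", tss = 10000, strand = "+")
  d <- assign_regulatory_domains(gene, max_extension = 0)
  # background of 5 variants, 2 inside the domain; foreground of 2, 1 inside
  bg <- fixture_variants(c(6000L, 7000L, 50000L, 60000L, 70000L), "s1")
  fg <- fixture_variants(c(6500L, 80000L), "s1")
  # exhaustive oracle over all choose(5, 2) = 10 subsets
  memb <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  subsets <- utils::combn(5, 2)
  obs_frac <- 0.5
  exact <- mean(apply(subsets, 2, function(s) mean(memb[s]) > obs_frac))
  expect_equal(exact, 0.1)  # only the {1,2} subset exceeds 1/2
  res <- permutation_p(fg, bg, "g", d, n_perm = 4000, seed = 17)
  expect_lt(abs(res$p - exact), 3 * sqrt(exact * (1 - exact) / 4000))
  expect_equal(res$observed_enrichment, 0.5 / 0.4)
  expect_false(res$censored)
  expect_error(permutation_p(bg, fg, "g", d, n_perm = 10),
               "background smaller")
})

test_that("permutation p-values live on [1/n_perm, 1] and censor at zero", {
  gene <- data.frame(gene_id = "g", chrom = "chr1", tss = 10000, strand = "+")
  d <- assign_regulatory_domains(gene, max_extension = 0)
  # foreground fully inside, background mostly outside: no permutation can
  # strictly exceed an observed fraction of 1
  fg <- fixture_variants(c(6000L, 7000L), "s1")
  bg <- fixture_variants(c(6000L, 7000L, 8000L, 50000L, 60000L, 70000L), "s1")
  res <- permutation_p(fg, bg, "g", d, n_perm = 200, seed = 19)
  expect_true(res$censored)
  expect_equal(res$p, 1 / 200)
})
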