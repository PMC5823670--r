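test_that("percent_of_gene reproduces half-up rounding on known counts", {
  expect_equal(percent_of_gene(47, 76), 61.8)
  expect_equal(percent_of_gene(62, 76), 81.6)
  expect_equal(percent_of_gene(0, 10), 0)
  expect_equal(percent_of_gene(1, 8), 12.5)
  expect_equal(percent_of_gene(3, 16), 18.8)  # 18.75 rounds up
  expect_equal(percent_of_gene(10, 10), 100)
  for (n in c(1, 3, 7)) expect_equal(percent_of_gene(n, n), 100)
  expect_error(percent_of_gene(1, 0), "n_gene")
  expect_error(percent_of_gene(5, 4), "n_locus")
})

test_that("gene counts equal hand-computed column sums on a toy matrix", {
  m <- rbind(A = c(1, 0, 1, 1), B = c(1, 1, 1, 1), C = c(0, 0, 0, 0))
  colnames(m) <- paste0("S", 1:4)
  out <- gene_counts(m, n_samples = 4)
  expect_equal(out$gene, c("B", "A"))           # C excluded, B first
  expect_equal(out$sample_count, c(4L, 3L))
  expect_equal(out$sample_freq, c(100, 75))
  expect_error(gene_counts(m, 0), "n_samples")
  expect_error(gene_counts(m[0, , drop = FALSE], 4), "empty")
})

test_that("gene counts agree with brute-force recomputation", {
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(rbinom(100, 1, 0.3), 10, 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:10)))
    out <- gene_counts(m, 10)
    for (j in seq_len(nrow(out))) {
      g <- out$gene[j]
      expect_equal(out$sample_count[j], sum(m[g, ] > 0))
    }
    expect_true(!is.unsorted(rev(out$sample_count)))
  }
})

test_that("length weighting is exactly inverse-proportional to length", {
  m <- rbind(A = c(1, 1, 0, 0), B = c(1, 1, 0, 0), Z = c(0, 1, 1, 1))
  colnames(m) <- paste0("S", 1:4)
  len <- c(A = 1000, B = 2000, Z = 1500)
  out <- weighted_frequency(m, len)
  wa <- out$weighted_freq[out$gene == "A"]
  wb <- out$weighted_freq[out$gene == "B"]
  expect_equal(wa, 2 * wb)
  expect_equal(wa, 2 / 1 / 4)  # count/(kb)/n_samples
  expect_match(attr(out, "formula"), "length_nt")
  m0 <- rbind(A = c(0, 0, 0, 0))
  colnames(m0) <- paste0("S", 1:4)
  expect_equal(weighted_frequency(m0, len)$weighted_freq, 0)
  expect_error(weighted_frequency(m, c(A = 0, B = 2000, Z = 1)), "length")
})

test_that("weighted frequency matches a hand-computed 5-gene table", {
  m <- matrix(0, 5, 10, dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  cnt <- c(8, 5, 5, 2, 0)
  for (i in 1:5) if (cnt[i]) m[i, seq_len(cnt[i])] <- 1
  len <- c(g1 = 8797 * 3, g2 = 567, g3 = 1182, g4 = 300, g5 = 900)
  out <- weighted_frequency(m, len)
  want <- cnt / (len / 1000) / 10
  expect_equal(out$weighted_freq[match(paste0("g", 1:5), out$gene)],
               unname(want))
  # short gene with equal count outranks the long one
  expect_lt(match("g2", out$gene), match("g3", out$gene))
})

test_that("exon burden assigns variants to exon ranks", {
  models <- list(exons = gene_model("X", c(90, 150, 60), tx_start = 1000L))
  # codon 40 lies in exon 2; two samples there, one sample in exon 3 (codon 90)
  co <- aa_to_genomic(models, "X", c(40, 40, 90))
  v <- data.frame(sample_id = c("S1", "S2", "S1"), chrom = co$chrom,
                  pos = co$pos)
  out <- exon_burden(v, models)
  expect_equal(out$exon, c("2/3", "3/3"))
  expect_equal(out$sample_count, c(2L, 1L))
  v_bad <- rbind(v, data.frame(sample_id = "S3", chrom = "chr1", pos = 1L))
  expect_error(exon_burden(v_bad, models), "annotation mismatch")
})

test_that("single-exon genes report rank 1/1 with the gene's sample count", {
  spec <- cohort_spec(n_genes = 1, gene_codons = 200, exons_per_gene = 1,
                      hotspots = list(), seed = 2)
  m <- generate_gene_models(spec)
  co <- aa_to_genomic(m, "G001", c(5, 7, 100))
  v <- data.frame(sample_id = c("S1", "S2", "S3"), chrom = co$chrom,
                  pos = co$pos)
  out <- exon_burden(v, m)
  expect_equal(out$exon, "1/1")
  expect_equal(out$sample_count, 3L)
})

test_that("position burden counts distinct samples per codon", {
  models <- list(exons = gene_model("X", 300))
  co <- aa_to_genomic(models, "X", c(5, 5, 20, 30))
  v <- data.frame(sample_id = c("S1", "S2", "S3", "S4"), chrom = co$chrom,
                  pos = co$pos)
  out <- position_burden(v, models)
  top <- out[out$aa_pos == 5, ]
  expect_equal(top$sample_count, 2L)
  expect_equal(top$pct_of_gene, 50)
  one_codon <- position_burden(v[v$sample_id %in% c("S1", "S2"), ], models)
  expect_equal(one_codon$pct_of_gene, 100)
})

test_that("per-exon sample counts are at least the gene-level count", {
  co <- generate_cohort(quick_spec(seed = 37))
  s <- co$variants[co$variants$origin == "somatic", ]
  eb <- exon_burden(s, co$models)
  gene_n <- vapply(split(s$sample_id, s$gene),
                   function(x) length(unique(x)), integer(1))
  per_gene <- vapply(split(eb$sample_count, eb$gene), sum, numeric(1))
  expect_true(all(per_gene[names(gene_n)] >= gene_n))
})

test_that("a planted hotspot surfaces in the position table at its codon", {
  spec <- cohort_spec(n_patients = 200, seed = 41,
                      hotspots = list(planted_hotspot("G001", 600L, 0.2, 1)))
  co <- generate_cohort(spec)
  s <- co$variants[co$variants$origin == "somatic", ]
  pb <- position_burden(s, co$models)
  hs <- pb[pb$gene == "G001" & pb$aa_pos == 600, ]
  expect_gte(hs$sample_count, qbinom(0.005, 200, 0.2))
  expect_lte(hs$sample_count, qbinom(0.995, 200, 0.2))
  expect_equal(pb$gene[1], "G001")
})
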