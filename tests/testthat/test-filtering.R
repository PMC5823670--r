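flagged <- function(...) assign_flags(make_call(...))

test_that("database filter removes CO-flagged records only", {
  keep <- flagged(depth = 100, alt_counts = 50)
  drop_g5 <- flagged(depth = 100, alt_counts = 50, af_kg = 0.3, pos = 2L)
  drop_co <- flagged(depth = 100, alt_counts = c(30, 30),
                     af_dk = c(0.3, NA), af_eur = c(NA, 0.2), pos = 3L)
  v <- rbind(keep, drop_g5, drop_co)
  out <- database_filter(v)
  expect_equal(out$pos, c(100L))
})

test_that("impact filter keeps moderate/high and drops unflagged records", {
  v <- rbind(flagged(alt_counts = 50, impact = "modifier", pos = 1L),
             flagged(alt_counts = 50, impact = "low", pos = 2L),
             flagged(alt_counts = 50, impact = "moderate", pos = 3L),
             flagged(alt_counts = 50, impact = "high", pos = 4L),
             flagged(alt_counts = 2, impact = "high", pos = 5L))  # LF, no I flag
  expect_equal(impact_filter(v)$pos, c(3L, 4L))
})

test_that("retained fraction under impact filtering is binomially consistent", {
  set.seed(7)
  p_keep <- 0.85
  imp <- sample(c("modifier", "low", "moderate", "high"), 2000, TRUE,
                prob = c(0.05, 0.10, 0.55, 0.30))
  v <- data.frame(sample_id = "S1", chrom = "chr1", pos = seq_along(imp),
                  ref = "A", alt = "C", qual = 100, hq_depth = 100L,
                  hq_alt_count = 50L, rsid = NA_character_, impact = imp,
                  af_kg = NA_real_, af_dk = NA_real_, af_exac = NA_real_,
                  af_eur = NA_real_, stringsAsFactors = FALSE)
  kept <- nrow(impact_filter(assign_flags(v)))
  expect_gte(kept, qbinom(0.005, 2000, p_keep))
  expect_lte(kept, qbinom(0.995, 2000, p_keep))
})

test_that("mask filter is inclusive of interval ends and supports whole genes", {
  masks <- data.frame(chrom = "chr1", start = 100L, end = 200L, gene = "X",
                      reason = "", whole_gene = FALSE)
  v <- data.frame(chrom = "chr1", pos = c(99L, 100L, 200L, 201L),
                  gene = c("A", "A", "A", "A"))
  expect_equal(mask_filter(v, masks)$pos, c(99L, 201L))
  wg <- data.frame(chrom = "chr9", start = NA, end = NA, gene = "A",
                   reason = "", whole_gene = TRUE)
  expect_equal(nrow(mask_filter(v, wg)), 0)
  bad <- data.frame(chrom = "chr1", start = 200L, end = 100L, gene = "X",
                    reason = "", whole_gene = FALSE)
  expect_error(mask_filter(v, bad), "malformed")
})

test_that("the shipped mask table has the four canonical regions", {
  m <- default_masks()
  expect_equal(nrow(m), 4)
  expect_setequal(m$gene, c("TBP", "LURAP1L", "KRTAP4-5", "ERICH6B"))
  expect_equal(sum(m$whole_gene), 1)
  ok <- !m$whole_gene
  expect_true(all(m$start[ok] < m$end[ok]))
})

test_that("groups below four samples are never classified germline", {
  expect_identical(germline_aaf_test(c(0.5, 0.5, 0.5)), "not-classified")
  expect_identical(germline_aaf_test(rep(0.5, 4)), "germline")
})

test_that("the AAF-distribution rule separates germline from somatic groups", {
  set.seed(31)
  germ <- replicate(1000, germline_aaf_test(rbeta(8, 20, 20)))
  expect_gte(mean(germ == "germline"), 0.95)
  som <- replicate(1000, {
    m <- 0.15
    germline_aaf_test(rbeta(8, m * 25, (1 - m) * 25))
  })
  expect_gte(mean(som == "not-classified"), 0.95)
})

test_that("germline_aaf_filter groups by rs-id or position and drops germline", {
  v <- rbind(
    make_call(sample_id = sprintf("S%d", 1:6), depth = 100,
              alt_counts = c(48, 52, 50, 47, 53, 50), pos = 10L,
              rsid = "rs1"),
    make_call(sample_id = sprintf("S%d", 1:6), depth = 100,
              alt_counts = c(15, 18, 12, 16, 14, 17), pos = 20L))
  v$aaf <- v$hq_alt_count / v$hq_depth
  out <- germline_aaf_filter(v)
  expect_equal(unique(out$pos), 20L)
  groups <- attr(out, "groups")
  expect_equal(groups$call[groups$group == "rs1"], "germline")
  expect_equal(groups$call[groups$group == "chr1:20"], "not-classified")
})

test_that("benign filter needs Benign significance and no cancer relation", {
  cv <- data.frame(rsid = c("rs1", "rs2", "rs3"),
                   significance = c("Benign", "Benign", "Pathogenic"),
                   cancer_related = c(TRUE, FALSE, FALSE))
  v <- make_call(sample_id = sprintf("S%d", 1:4), alt_counts = 50,
                 pos = 1:4, rsid = c("rs1", "rs2", "rs3", "rs9"))
  out <- benign_filter(v, cv)
  expect_setequal(out$rsid, c("rs1", "rs3", "rs9"))
  expect_equal(nrow(blocklist_filter(v, c("rs9", "rs3"))), 2)
  expect_identical(blocklist_filter(v, character(0)), v)
})

test_that("gene recurrence boundary keeps 5 and drops 4 mutated samples", {
  m <- rbind(g5 = c(1, 1, 1, 1, 1, 0), g4 = c(1, 1, 1, 1, 0, 0))
  colnames(m) <- paste0("S", 1:6)
  expect_identical(gene_recurrence_filter(m, 5), "g5")
  expect_identical(gene_recurrence_filter(m[0, , drop = FALSE]), character(0))
})

test_that("recurrence filter equals brute-force column sums on random input", {
  set.seed(5)
  for (i in 1:5) {
    v <- data.frame(gene = sample(paste0("g", 1:8), 60, TRUE),
                    sample_id = sample(paste0("S", 1:10), 60, TRUE))
    m <- mutation_matrix(v)
    got <- gene_recurrence_filter(m, 3)
    want <- names(which(vapply(split(v$sample_id, v$gene),
                               function(s) length(unique(s)),
                               integer(1)) >= 3))
    expect_setequal(got, sort(want))
  }
})

test_that("funnel counts are conserved and the disabled funnel is identity", {
  co <- generate_cohort(quick_spec(seed = 23))
  fl <- assign_flags(co$variants)
  res <- run_funnel(fl, funnel_config(mask = FALSE))
  f <- res$funnel
  expect_true(all(diff(f$remaining) <= 0))
  expect_equal(f$removed[-1], -diff(f$remaining))
  off <- funnel_config(technical = FALSE, database = FALSE, impact = FALSE,
                       mask = FALSE, germline_aaf = FALSE, benign = FALSE,
                       recurrence = FALSE)
  ident <- run_funnel(fl, off)
  expect_equal(nrow(ident$variants), nrow(fl))
  expect_equal(ident$funnel$stage, "input")
})

test_that("mask and benign filters commute", {
  co <- generate_cohort(quick_spec(seed = 29))
  v <- assign_flags(co$variants)
  masks <- data.frame(chrom = v$chrom[1], start = v$pos[1] - 5L,
                      end = v$pos[1] + 5L, gene = "X", reason = "",
                      whole_gene = FALSE)
  rs <- unique(v$rsid[!is.na(v$rsid)])[1:10]
  cv <- data.frame(rsid = rs, significance = "Benign", cancer_related = FALSE)
  a <- benign_filter(mask_filter(v, masks), cv)
  b <- mask_filter(benign_filter(v, cv), masks)
  expect_setequal_rows(a, b)
})
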