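fm <- function(m, genes, feats = paste0("f", seq_len(ncol(m)))) {
  dimnames(m) <- list(genes, feats)
  m
}

test_that("gene scores are feature-row sums with COSMIC tie-break", {
  m <- fm(rbind(c(1, 1, 1, 0, 0, 0, 0, 0, 0),
                c(1, 1, 0, 0, 0, 0, 0, 0, 0),
                c(1, 1, 0, 0, 0, 0, 0, 0, 0),
                c(0, 0, 0, 0, 0, 0, 0, 0, 0)),
          c("A", "B", "C", "D"))
  out <- score_genes(m, c(B = 5, C = 12))
  expect_equal(out$score[out$gene == "A"], 3L)
  expect_equal(out$gene, c("A", "C", "B", "D"))  # 12% beats 5% at score 2
  expect_error(score_genes(fm(rbind(c(1, 2)), "A")), "0/1")
})

test_that("ranking is invariant to feature column order and matches brute force", {
  set.seed(3)
  m <- fm(matrix(rbinom(20 * 9, 1, 0.3), 20), paste0("g", sprintf("%02d", 1:20)))
  freq <- setNames(round(runif(20, 0, 20), 1), rownames(m))
  out <- score_genes(m, freq)
  shuffled <- score_genes(m[, sample(ncol(m))], freq)
  expect_identical(out, shuffled)
  o <- order(-rowSums(m), -freq[rownames(m)], rownames(m))
  expect_equal(out$gene, rownames(m)[o])
  expect_equal(out$score, unname(rowSums(m)[o]))
})

test_that("core panel selection applies the strict 7% frequency add-in", {
  ranked <- data.frame(gene = c("A", "B", "C", "D"),
                       score = c(2L, 0L, 0L, 0L),
                       cosmic_freq = c(0, 8, 7, 6.9))
  out <- select_core_panel(ranked)
  expect_setequal(out$gene, c("A", "B"))
  expect_equal(out$provenance[out$gene == "A"], "core-score")
  expect_equal(out$provenance[out$gene == "B"], "freq-addin")
  none <- data.frame(gene = "Z", score = 0L, cosmic_freq = 1)
  expect_equal(nrow(select_core_panel(none)), 0)
})

test_that("co-occurrence p equals the closed-form hypergeometric example", {
  r <- fisher_cooccurrence(5, 0, 0, 5)
  expect_equal(r$p_value, 1 / 252)
  expect_equal(fisher_cooccurrence(0, 10, 0, 10)$p_value, 1)
  # strict threshold: p exactly at alpha is not significant
  p <- fisher_cooccurrence(3, 2, 2, 3)$p_value
  expect_false(fisher_cooccurrence(3, 2, 2, 3, bonferroni_alpha = p)$significant)
  expect_error(fisher_cooccurrence(-1, 0, 0, 0), ">= 0")
})

test_that("co-occurrence p matches fisher.test one-sided on random tables", {
  set.seed(9)
  for (i in 1:25) {
    tb <- matrix(rpois(4, 6), 2)
    mine <- fisher_cooccurrence(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])$p_value
    ft <- stats::fisher.test(tb, alternative = "greater")$p.value
    expect_equal(mine, ft, tolerance = 1e-12)
  }
})

test_that("network filter retains anchors and 10%-connected genes", {
  inter <- data.frame(
    gene_a = c(paste0("X", 1:10), paste0("Y", 1:10), "Z1"),
    gene_b = c(c("A1", paste0("Q", 2:10)), paste0("Q", 11:20), "A1"),
    confidence = c(rep("high", 20), "low"))
  anchors <- c("A1", "A2")
  # X* each have 1 interactor; X1's is an anchor
  expect_identical(network_filter("X1", inter, anchors), "X1")
  g10 <- data.frame(gene_a = "W", gene_b = paste0("P", 1:10),
                    confidence = "high")
  g10$gene_b[1] <- "A1"
  expect_identical(network_filter("W", g10, anchors), "W")      # exactly 10%
  g0 <- data.frame(gene_a = "V", gene_b = paste0("P", 1:10),
                   confidence = "high")
  expect_length(network_filter("V", g0, anchors), 0)
  expect_identical(network_filter("A2", inter, anchors), "A2")  # anchor branch
  expect_length(network_filter("Z1", inter, anchors), 0)        # low confidence
})

test_that("TCGA-style ranking drops low impact and normalizes by length", {
  mt <- data.frame(gene = c(rep("A", 10), rep("B", 10), rep("C", 4)),
                   impact = c(rep("moderate", 10), rep("high", 10),
                              rep("low", 4)))
  out <- tcga_top_genes(mt, c(A = 1000, B = 2000, C = 100), k = 50)
  expect_equal(out, c("A", "B"))  # same counts, shorter gene first; C all low
  expect_length(tcga_top_genes(data.frame(gene = "A", impact = "low"),
                               c(A = 100)), 0)
})

test_that("TCGA-style ranking matches a brute-force sort on random input", {
  set.seed(13)
  genes <- paste0("g", sprintf("%02d", 1:30))
  mt <- data.frame(gene = sample(genes, 400, TRUE),
                   impact = sample(c("modifier", "low", "moderate", "high"),
                                   400, TRUE))
  len <- setNames(sample(300:3000, 30), genes)
  got <- tcga_top_genes(mt, len, k = 10)
  keep <- mt[mt$impact %in% c("moderate", "high"), ]
  cnt <- table(keep$gene)
  rate <- as.vector(cnt) / as.vector(len[names(cnt)])
  want <- head(names(cnt)[order(-rate, -as.vector(cnt), names(cnt))], 10)
  expect_equal(got, want)
})

test_that("panel merging accumulates provenance and is order-independent", {
  core <- data.frame(gene = c("A", "B"), score = c(3L, 1L),
                     provenance = "core-score", stringsAsFactors = FALSE)
  ext <- list(textmining = c("A", "C"), tcga = c("C", "D"),
              handpicked = c("EGFR-like"))
  out <- merge_panel(core, ext)
  expect_setequal(out$gene, c("A", "B", "C", "D", "EGFR-like"))
  expect_equal(out$provenance[out$gene == "A"], "core-score;textmining")
  expect_equal(out$provenance[out$gene == "C"], "tcga;textmining")
  expect_equal(out$score[out$gene == "C"], 0L)
  # order independence and idempotence
  expect_identical(out, merge_panel(core, rev(ext)))
  expect_identical(merge_panel(core, list()), merge_panel(core, list()))
  expect_equal(nrow(merge_panel(core, list())), 2)
  # union cardinality equals brute-force set union
  expect_equal(nrow(out), length(unique(c(core$gene, unlist(ext)))))
})

test_that("case-variant duplicates signal a normalization failure", {
  core <- data.frame(gene = c("ABC", "abc"), score = c(1L, 1L),
                     provenance = "core-score", stringsAsFactors = FALSE)
  expect_error(merge_panel(core), "normalization failure")
  expect_equal(normalize_genes(c("abc", "p53")), c("ABC", "P53"))
  map <- data.frame(synonym = "P53", canonical = "TP53")
  expect_equal(normalize_genes(c("p53", "KRAS"), map), c("TP53", "KRAS"))
})
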