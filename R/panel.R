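#' Score genes by feature membership
#'
#' A gene's score is the number of evidence features it belongs to. Ranking
#' is by descending score; ties are resolved by the higher colorectal-cancer
#' mutation frequency (COSMIC-style), residual ties alphabetically.
#'
#' @param feature_matrix 0/1 matrix or data.frame, genes as rownames,
#'   features as columns.
#' @param cosmic_freq named numeric vector of per-gene CRC mutation
#'   frequencies in percent (missing genes count as 0).
#' @return data.frame `gene`, `score`, `cosmic_freq`, in rank order.
#' @export
score_genes <- function(feature_matrix, cosmic_freq = numeric(0)) {
  m <- as.matrix(feature_matrix)
  if (!all(m %in% c(0, 1)))
    stop("feature matrix must contain 0/1 indicators", call. = FALSE)
  genes <- rownames(m)
  freq <- unname(cosmic_freq[genes])
  freq[is.na(freq)] <- 0
  out <- data.frame(gene = genes, score = as.integer(rowSums(m)),
                    cosmic_freq = freq, stringsAsFactors = FALSE)
  out <- out[order(-out$score, -out$cosmic_freq, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the core gene panel
#'
#' Genes scoring at least `min_score` form the core; genes whose mutation
#' frequency is strictly above `freq_threshold` percent are added regardless
#' of score.
#'
#' @param ranked output of [score_genes()].
#' @param min_score minimum feature score for core membership (default 1).
#' @param freq_threshold mutation-frequency add-in threshold in percent,
#'   strict (default 7).
#' @return data.frame `gene`, `score`, `provenance` (`;`-joined tags from
#'   `core-score`, `freq-addin`).
#' @export
select_core_panel <- function(ranked, min_score = 1, freq_threshold = 7) {
  stopifnot_cols(ranked, c("gene", "score", "cosmic_freq"))
  core <- ranked$score >= min_score
  addin <- ranked$cosmic_freq > freq_threshold
  keep <- ranked[core | addin, , drop = FALSE]
  prov <- ifelse(core & addin, "core-score;freq-addin",
                 ifelse(core, "core-score", "freq-addin"))[core | addin]
  out <- data.frame(gene = keep$gene, score = keep$score, provenance = prov,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Literature co-occurrence enrichment test
#'
#' One-sided (enrichment) Fisher's exact test on the 2x2 abstract-count
#' table of gene mentions vs disease mentions, i.e. the hypergeometric upper
#' tail. Significance is declared below a Bonferroni-corrected threshold
#' (strict `<`).
#'
#' @param n_both abstracts mentioning both the gene and the disease.
#' @param n_gene_only abstracts mentioning the gene only.
#' @param n_disease_only abstracts mentioning the disease only.
#' @param n_neither abstracts mentioning neither.
#' @param bonferroni_alpha significance threshold (default 5e-7).
#' @return list with vectors `p_value` and `significant`.
#' @examples
#' fisher_cooccurrence(5, 0, 0, 5)$p_value # 1/252
#' @export
fisher_cooccurrence <- function(n_both, n_gene_only, n_disease_only,
                                n_neither, bonferroni_alpha = 5e-7) {
  if (any(c(n_both, n_gene_only, n_disease_only, n_neither) < 0))
    stop("counts must be >= 0", call. = FALSE)
  p <- stats::phyper(n_both - 1, n_both + n_gene_only,
                     n_disease_only + n_neither, n_both + n_disease_only,
                     lower.tail = FALSE)
  list(p_value = p, significant = p < bonferroni_alpha)
}

#' Interaction-network relevance filter
#'
#' Retains a gene when it is one of the anchor genes (the most mutated
#' genes), or when at least 10% of its high-confidence protein interactors
#' are anchors. Genes with no high-confidence interactors and no anchor
#' membership are removed.
#'
#' @param candidate_genes character vector to filter.
#' @param interactions data.frame `gene_a`, `gene_b`, `confidence`
#'   (`"high"`/`"low"`); only high-confidence pairs count.
#' @param anchor_set character vector of anchor genes.
#' @param min_fraction inclusive anchor-interactor fraction (default 0.10).
#' @return retained subset of `candidate_genes`.
#' @export
network_filter <- function(candidate_genes, interactions, anchor_set,
                           min_fraction = 0.10) {
  stopifnot_cols(interactions, c("gene_a", "gene_b", "confidence"))
  hi <- interactions[interactions$confidence == "high", , drop = FALSE]
  partners <- function(g) unique(c(hi$gene_b[hi$gene_a == g],
                                   hi$gene_a[hi$gene_b == g]))
  keep <- vapply(candidate_genes, function(g) {
    if (g %in% anchor_set) return(TRUE)
    p <- partners(g)
    length(p) > 0 && mean(p %in% anchor_set) >= min_fraction
  }, logical(1))
  candidate_genes[keep]
}

#' Top genes by length-normalized mutation rate
#'
#' Drops low-impact records (`modifier` and `low`), counts the remaining
#' mutations per gene, normalizes by gene length, and returns the `k`
#' highest-rate genes (ties broken by raw count, then alphabetically).
#'
#' @param mutation_table data.frame `gene`, `impact`.
#' @param gene_lengths named numeric vector of gene lengths (nt), > 0.
#' @param k number of genes to return (default 50).
#' @return character vector of up to `k` genes, highest rate first.
#' @export
tcga_top_genes <- function(mutation_table, gene_lengths, k = 50) {
  stopifnot_cols(mutation_table, c("gene", "impact"))
  m <- mutation_table[!mutation_table$impact %in% c("modifier", "low"), ,
                      drop = FALSE]
  if (!nrow(m)) return(character(0))
  cnt <- table(m$gene)
  len <- gene_lengths[names(cnt)]
  if (any(is.na(len) | len <= 0))
    stop("missing or non-positive gene length", call. = FALSE)
  rate <- as.vector(cnt) / as.vector(len)
  o <- order(-rate, -as.vector(cnt), names(cnt))
  utils::head(names(cnt)[o], k)
}

#' Merge the core panel with extension gene lists
#'
#' Set union with provenance accumulation: a gene appearing in several
#' sources keeps one row and collects every tag. Ordering is deterministic
#' (score descending, then gene name). Gene identifiers must already be
#' normalized; case-variant duplicates signal a normalization failure.
#'
#' @param core data.frame from [select_core_panel()].
#' @param extensions named list of character vectors; names are provenance
#'   tags (e.g. `textmining`, `pathway`, `drugtarget`, `tcga`, `handpicked`,
#'   `network`).
#' @return data.frame `gene`, `score`, `provenance`.
#' @export
merge_panel <- function(core, extensions = list()) {
  stopifnot_cols(core, c("gene", "score", "provenance"))
  if (length(extensions) && is.null(names(extensions)))
    stop("extensions must be a named list", call. = FALSE)
  prov <- stats::setNames(as.list(core$provenance), core$gene)
  score <- stats::setNames(core$score, core$gene)
  for (tag in names(extensions)) {
    for (g in unique(extensions[[tag]])) {
      prov[[g]] <- unique(c(prov[[g]], tag))
      if (is.na(score[g])) score[g] <- 0L
    }
  }
  genes <- names(prov)
  if (anyDuplicated(toupper(genes)))
    stop("normalization failure: case-variant duplicate gene identifiers",
         call. = FALSE)
  out <- data.frame(
    gene = genes, score = as.integer(score[genes]),
    provenance = vapply(prov, function(p)
      paste(sort(unlist(strsplit(p, ";"))), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize gene identifiers with a synonym map
#'
#' Deterministic replacement for interactive symbol checkers: upper-cases
#' identifiers and applies a synonym-to-canonical lookup.
#'
#' @param genes character vector.
#' @param synonym_map optional data.frame `synonym`, `canonical`.
#' @return normalized character vector.
#' @export
normalize_genes <- function(genes, synonym_map = NULL) {
  g <- toupper(genes)
  if (!is.null(synonym_map)) {
    stopifnot_cols(synonym_map, c("synonym", "canonical"))
    i <- match(g, toupper(synonym_map$synonym))
    g[!is.na(i)] <- toupper(synonym_map$canonical[i[!is.na(i)]])
  }
  g
}
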