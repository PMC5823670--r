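#' Percentage of a gene's mutated samples at a locus
#'
#' `100 * n_locus / n_gene`, rounded half-up to one decimal — the "% samples
#' mutated in gene" column of the recurrence tables.
#'
#' @param n_locus samples mutated at the locus (position, exon or interval).
#' @param n_gene samples mutated anywhere in the gene; must be positive and
#'   at least `n_locus`.
#' @return numeric percentage with one decimal.
#' @examples
#' percent_of_gene(47, 76) # 61.8
#' percent_of_gene(62, 76) # 81.6
#' @export
percent_of_gene <- function(n_locus, n_gene) {
  if (any(n_gene <= 0)) stop("n_gene must be > 0", call. = FALSE)
  if (any(n_locus < 0 | n_locus > n_gene))
    stop("n_locus must be in [0, n_gene]", call. = FALSE)
  round_half_up(100 * n_locus / n_gene, 1)
}

#' Ranked per-gene mutation counts and frequencies
#'
#' @param matrix gene-by-sample mutation matrix (see [mutation_matrix()]).
#' @param n_samples denominator for the sample frequency — the number of
#'   analyzed samples, passed explicitly.
#' @return data.frame `gene`, `sample_count`, `sample_freq` (percent, one
#'   decimal), sorted by descending count, ties alphabetical; genes with no
#'   mutated sample are excluded.
#' @export
gene_counts <- function(matrix, n_samples) {
  if (!nrow(matrix)) stop("empty mutation matrix", call. = FALSE)
  if (n_samples <= 0) stop("n_samples must be > 0", call. = FALSE)
  cnt <- rowSums(matrix > 0)
  out <- data.frame(gene = rownames(matrix), sample_count = as.integer(cnt),
                    sample_freq = round_half_up(100 * cnt / n_samples, 1),
                    stringsAsFactors = FALSE)
  out <- out[out$sample_count > 0, , drop = FALSE]
  out <- out[order(-out$sample_count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length-weighted mutation frequency
#'
#' Long genes accumulate mutations by target size alone; this ranks genes by
#' mutated-sample count normalized for coding length. Formula (documented in
#' the output attribute and TSV header):
#' `weighted = sample_count / (length_nt / 1000) / n_samples`, i.e. mutated
#' samples per kilobase of coding sequence per analyzed sample.
#'
#' @param matrix gene-by-sample mutation matrix; `ncol(matrix)` is the
#'   sample denominator.
#' @param lengths_nt named vector of per-gene targeted lengths in
#'   nucleotides.
#' @return data.frame `gene`, `sample_count`, `weighted_freq`, descending;
#'   attribute `"formula"` records the definition.
#' @export
weighted_frequency <- function(matrix, lengths_nt) {
  genes <- rownames(matrix)
  len <- lengths_nt[genes]
  if (any(is.na(len) | len <= 0))
    stop("missing or non-positive length for: ",
         paste(genes[is.na(len) | len <= 0], collapse = ", "), call. = FALSE)
  cnt <- rowSums(matrix > 0)
  wf <- cnt / (len / 1000) / ncol(matrix)
  out <- data.frame(gene = genes, sample_count = as.integer(cnt),
                    weighted_freq = unname(wf), stringsAsFactors = FALSE)
  out <- out[order(-out$weighted_freq, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "formula") <-
    "weighted_freq = sample_count / (length_nt/1000) / n_samples"
  out
}

#' Per-exon mutation burden
#'
#' Counts, for each exon of the canonical transcript, the distinct samples
#' with at least one variant in the exon; the exon is reported as
#' rank/total (e.g. `"16/16"` for the last of 16 exons).
#'
#' @param variants somatic variant data.frame with `sample_id`, `chrom`,
#'   `pos`.
#' @param models gene models ([generate_gene_models()] or [gene_model()]
#'   rows wrapped in a `gene_models` list).
#' @return data.frame `gene`, `exon` (`"rank/total"`), `sample_count`,
#'   descending.
#' @export
exon_burden <- function(variants, models) {
  stopifnot_cols(variants, c("sample_id", "chrom", "pos"))
  ann <- annotate_positions(models, variants$chrom, variants$pos)
  if (anyNA(ann$gene))
    stop("annotation mismatch: variant outside any exon", call. = FALSE)
  key <- paste(ann$gene, ann$exon_rank, ann$n_exons, sep = "\r")
  cnt <- vapply(split(variants$sample_id, key),
                function(s) length(unique(s)), integer(1))
  parts <- do.call(rbind, strsplit(names(cnt), "\r"))
  out <- data.frame(gene = parts[, 1],
                    exon = paste0(parts[, 2], "/", parts[, 3]),
                    sample_count = as.integer(cnt), stringsAsFactors = FALSE)
  out <- out[order(-out$sample_count, out$gene, out$exon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-amino-acid mutation hotspots
#'
#' Distinct-sample counts per (gene, amino-acid position), with the share of
#' the gene's mutated samples hit at the position ([percent_of_gene()]).
#'
#' @param variants somatic variant data.frame with `sample_id`, `chrom`,
#'   `pos` (amino-acid positions are recomputed from the models).
#' @param models gene models.
#' @return data.frame `gene`, `aa_pos`, `sample_count`, `pct_of_gene`,
#'   descending by count.
#' @export
position_burden <- function(variants, models) {
  stopifnot_cols(variants, c("sample_id", "chrom", "pos"))
  ann <- annotate_positions(models, variants$chrom, variants$pos)
  if (anyNA(ann$gene))
    stop("annotation mismatch: variant outside any exon", call. = FALSE)
  gene_n <- vapply(split(variants$sample_id, ann$gene),
                   function(s) length(unique(s)), integer(1))
  key <- paste(ann$gene, ann$aa_pos, sep = "\r")
  cnt <- vapply(split(variants$sample_id, key),
                function(s) length(unique(s)), integer(1))
  parts <- do.call(rbind, strsplit(names(cnt), "\r"))
  out <- data.frame(gene = parts[, 1], aa_pos = as.integer(parts[, 2]),
                    sample_count = as.integer(cnt), stringsAsFactors = FALSE)
  out$pct_of_gene <- percent_of_gene(out$sample_count, gene_n[out$gene])
  out <- out[order(-out$sample_count, out$gene, out$aa_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
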