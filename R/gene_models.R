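#' Build one gene model from explicit exon lengths
#'
#' Low-level constructor used by [generate_gene_models()] and convenient for
#' toy examples in tests. Exon lengths are coding nucleotides in
#' transcription order; the codon count is `sum(exon_lengths) / 3`.
#'
#' @param gene gene identifier.
#' @param exon_lengths integer vector of exon coding lengths (nt), in
#'   transcription order; the total must be a multiple of 3.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`; on `"-"` the transcription order runs from
#'   the highest genomic coordinate downwards.
#' @param tx_start genomic start (1-based) of the leftmost exon.
#' @param intron_lengths integer vector (length `length(exon_lengths) - 1`)
#'   of gap widths between consecutive genomic exons; recycled default 500.
#' @return data.frame of exons with columns `gene`, `chrom`, `strand`,
#'   `exon_rank` (transcription order), `n_exons`, `start`, `end` (1-based
#'   inclusive), `width`, and `coding_offset` (coding nucleotides preceding
#'   the exon in transcription order).
#' @export
gene_model <- function(gene, exon_lengths, chrom = "chr1", strand = "+",
                       tx_start = 10000L, intron_lengths = NULL) {
  n <- length(exon_lengths)
  stopifnot(n >= 1, all(exon_lengths >= 1))
  if (sum(exon_lengths) %% 3L != 0L)
    stop("total coding length must be a multiple of 3", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (is.null(intron_lengths)) intron_lengths <- 500L
  intron_lengths <- rep_len(as.integer(intron_lengths), max(0L, n - 1L))
  exon_lengths <- as.integer(exon_lengths)
  w_gen <- if (strand == "+") exon_lengths else rev(exon_lengths)
  starts <- as.integer(tx_start) +
    cumsum(c(0L, utils::head(w_gen, -1L) + intron_lengths))
  rank_gen <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  offsets <- cumsum(c(0L, utils::head(exon_lengths, -1L)))
  data.frame(gene = gene, chrom = chrom, strand = strand,
             exon_rank = rank_gen, n_exons = n,
             start = starts, end = starts + w_gen - 1L, width = w_gen,
             coding_offset = offsets[rank_gen],
             stringsAsFactors = FALSE)
}

#' Generate synthetic gene models
#'
#' Draws `spec$n_genes` canonical transcripts: one gene per locus, 1-16
#' exons, 150-1500 codons, random strand, non-overlapping genomic placement.
#' The mapping between amino-acid positions and genomic coordinates is
#' deterministic given the spec's seed. Genes named in `spec$hotspots` are
#' guaranteed to be long enough to contain their hotspot.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `gene_models`: a list with `genes` (one row per
#'   gene: `gene`, `chrom`, `strand`, `n_exons`, `codons`, `cds_length`) and
#'   `exons` (as in [gene_model()]).
#' @export
generate_gene_models <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_genes
  if (n < 1) stop("n_genes must be >= 1", call. = FALSE)
  withr::with_seed(spec$seed, {
    genes <- sprintf("G%03d", seq_len(n))
    hs_genes <- vapply(spec$hotspots, `[[`, character(1), "gene")
    missing_hs <- setdiff(hs_genes, genes)
    if (length(missing_hs))
      stop("hotspot gene(s) not in gene models: ",
           paste(missing_hs, collapse = ", "), call. = FALSE)
    codons <- spec$gene_codons %||% sample(150:1500, n, replace = TRUE)
    codons <- as.integer(rep_len(codons, n))
    for (h in spec$hotspots) {
      i <- match(h$gene, genes)
      codons[i] <- max(codons[i], h$aa_position + h$width + 10L)
    }
    n_ex <- spec$exons_per_gene %||% sample(1:16, n, replace = TRUE)
    n_ex <- as.integer(rep_len(n_ex, n))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    chrom <- paste0("chr", ((seq_len(n) - 1L) %% 22L) + 1L)
    slot <- (seq_len(n) - 1L) %/% 22L
    exons <- vector("list", n)
    for (i in seq_len(n)) {
      exons[[i]] <- gene_model(
        genes[i], split_cds(3L * codons[i], n_ex[i]),
        chrom = chrom[i], strand = strand[i],
        tx_start = 100000L + slot[i] * 3000000L,
        intron_lengths = sample(100:5000, max(1L, n_ex[i] - 1L),
                                replace = TRUE))
    }
    exons <- do.call(rbind, exons)
    structure(list(
      genes = data.frame(gene = genes, chrom = chrom, strand = strand,
                         n_exons = n_ex, codons = codons,
                         cds_length = 3L * codons, stringsAsFactors = FALSE),
      exons = exons), class = "gene_models")
  })
}

# split a coding length into n exon lengths, each reasonably sized
split_cds <- function(cds_len, n_exons) {
  if (n_exons == 1L) return(cds_len)
  n_exons <- min(n_exons, cds_len %/% 9L)
  if (n_exons <= 1L) return(cds_len)
  for (try in 1:50) {
    brk <- sort(sample.int(cds_len - 1L, n_exons - 1L))
    lens <- diff(c(0L, brk, cds_len))
    if (all(lens >= 9L)) return(as.integer(lens))
  }
  base <- cds_len %/% n_exons
  lens <- rep(base, n_exons)
  lens[n_exons] <- lens[n_exons] + cds_len - sum(lens)
  as.integer(lens)
}

exons_of_gene <- function(models, gene) {
  ex <- models$exons[models$exons$gene == gene, , drop = FALSE]
  if (!nrow(ex)) stop("gene absent from models: ", gene, call. = FALSE)
  ex[order(ex$exon_rank), , drop = FALSE]
}

#' Exon rank containing an amino-acid position
#'
#' A codon is assigned to the exon containing its first base.
#'
#' @param models a `gene_models` object.
#' @param gene gene identifier.
#' @param aa vector of 1-based amino-acid positions.
#' @return integer vector of exon ranks (transcription order).
#' @export
exon_of_aa <- function(models, gene, aa) {
  ex <- exons_of_gene(models, gene)
  coding <- 3L * (as.integer(aa) - 1L) + 1L
  if (any(coding < 1L | coding > sum(ex$width)))
    stop("amino-acid position outside gene ", gene, call. = FALSE)
  findInterval(coding - 1L, cumsum(ex$width)) + 1L
}

#' Map amino-acid positions to genomic coordinates
#'
#' @param models a `gene_models` object.
#' @param gene gene identifier (scalar).
#' @param aa vector of 1-based amino-acid positions.
#' @param base codon base to report (1, 2 or 3).
#' @return data.frame with `chrom` and `pos` (1-based).
#' @export
aa_to_genomic <- function(models, gene, aa, base = 1L) {
  stopifnot(base %in% 1:3)
  ex <- exons_of_gene(models, gene)
  coding <- 3L * (as.integer(aa) - 1L) + as.integer(base)
  if (any(coding < 1L | coding > sum(ex$width)))
    stop("amino-acid position outside gene ", gene, call. = FALSE)
  r <- findInterval(coding - 1L, cumsum(ex$width)) + 1L
  d <- coding - ex$coding_offset[r]
  pos <- ifelse(ex$strand[r] == "+", ex$start[r] + d - 1L, ex$end[r] - d + 1L)
  data.frame(chrom = ex$chrom[r], pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

#' Annotate genomic positions with gene, amino acid and exon
#'
#' Inverse of [aa_to_genomic()]: for each position, the containing exon (if
#' any) yields the gene, the 1-based amino-acid position on the canonical
#' transcript and the exon rank. Positions outside every exon get `NA`.
#'
#' @param models a `gene_models` object.
#' @param chrom,pos equal-length vectors of coordinates.
#' @return data.frame with columns `gene`, `aa_pos`, `exon_rank`, `n_exons`.
#' @export
annotate_positions <- function(models, chrom, pos) {
  ex <- models$exons
  chrom_ids <- unique(ex$chrom)
  key_ex <- (match(ex$chrom, chrom_ids) - 1) * 1e9 + ex$start
  o <- order(key_ex)
  ex <- ex[o, , drop = FALSE]
  key_q <- (match(chrom, chrom_ids) - 1) * 1e9 + pos
  i <- findInterval(key_q, key_ex[o])
  hit <- !is.na(key_q) & i >= 1L
  hit[hit] <- pos[hit] <= ex$end[i[hit]] & chrom[hit] == ex$chrom[i[hit]]
  out <- data.frame(gene = rep(NA_character_, length(pos)),
                    aa_pos = NA_integer_, exon_rank = NA_integer_,
                    n_exons = NA_integer_, stringsAsFactors = FALSE)
  if (any(hit)) {
    e <- ex[i[hit], , drop = FALSE]
    d <- ifelse(e$strand == "+", pos[hit] - e$start + 1L, e$end - pos[hit] + 1L)
    coding <- e$coding_offset + d
    out$gene[hit] <- e$gene
    out$aa_pos[hit] <- as.integer(ceiling(coding / 3))
    out$exon_rank[hit] <- e$exon_rank
    out$n_exons[hit] <- e$n_exons
  }
  out
}

#' Per-gene coding lengths
#'
#' @param models a `gene_models` object.
#' @return named integer vector of coding lengths (nt).
#' @export
gene_lengths <- function(models) {
  stats::setNames(models$genes$cds_length, models$genes$gene)
}
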