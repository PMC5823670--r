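#' Generate population allele-frequency tables
#'
#' Builds the germline allele registry the cohort generator draws from, with
#' allele frequencies in four populations emulating the reference panels used
#' for tumor-only filtering: a 1000-Genomes-like panel (`af_kg`), a Danish
#' reference panel (`af_dk`), an exome-aggregation global panel (`af_exac`)
#' and its European subset (`af_eur`). Common alleles have frequency >= 5%
#' in at least one population (a configurable share is private to a single
#' population, so positions can be "common" without any single panel
#' agreeing); rare alleles are below 5% in every population where seen.
#' Somatic and hotspot alleles are never present.
#'
#' @param spec a [cohort_spec()].
#' @param models gene models from [generate_gene_models()]; generated from
#'   `spec` when omitted.
#' @return data.frame of class `frequency_db`, one row per allele: `chrom`,
#'   `pos`, `ref`, `alt`, `rsid`, `gene`, `aa_pos`, `origin`
#'   (`germline-common` / `germline-rare`), `impact`, and the four `af_*`
#'   columns (`NA` = allele not observed in that population).
#' @export
generate_frequency_db <- function(spec, models = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(models)) models <- generate_gene_models(spec)
  withr::with_seed(spec$seed + 1L, {
    n_common <- max(40L, ceiling(4 * spec$germline_common_rate))
    n_rare <- max(30L, ceiling(4 * spec$germline_rare_rate))
    n <- n_common + n_rare
    loci <- draw_coding_loci(spec, models, n)
    coord <- map_loci(models, loci)
    ref <- ref_base(coord$pos)
    alt <- other_base(ref)
    origin <- rep(c("germline-common", "germline-rare"), c(n_common, n_rare))
    impact <- sample(impact_levels(), n, replace = TRUE,
                     prob = c(0.55, 0.30, 0.12, 0.03))
    af <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("af_kg", "af_dk", "af_exac", "af_eur")))
    pattern <- sample(c("all", "some", "one"), n_common, replace = TRUE,
                      prob = c(0.7, 0.15, 0.15))
    for (i in seq_len(n_common)) {
      pops <- switch(pattern[i],
                     all = 1:4,
                     some = sample(1:4, sample(2:3, 1)),
                     one = sample(1:4, 1))
      af[i, pops] <- stats::runif(length(pops), 0.05, 0.5)
    }
    for (i in seq_len(n_rare)) {
      pops <- sample(1:4, sample(1:4, 1))
      af[n_common + i, pops] <- stats::runif(length(pops), 5e-4, 0.045)
    }
    db <- data.frame(chrom = coord$chrom, pos = coord$pos, ref = ref,
                     alt = alt,
                     rsid = sprintf("rs%07d", sample.int(9999999L, n)),
                     gene = loci$gene, aa_pos = loci$aa, base = loci$base,
                     origin = origin,
                     impact = impact, stringsAsFactors = FALSE)
    db <- cbind(db, as.data.frame(af))
    class(db) <- c("frequency_db", "data.frame")
    db
  })
}

# draw n distinct coding loci (gene, aa, base), avoiding hotspot codons
draw_coding_loci <- function(spec, models, n) {
  g <- models$genes
  hs_key <- unlist(lapply(spec$hotspots, function(h)
    paste(h$gene, h$aa_position + seq_len(h$width) - 1L)))
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    k <- 2L * (n - if (is.null(out)) 0L else nrow(out)) + 10L
    gi <- sample.int(nrow(g), k, replace = TRUE, prob = g$codons)
    cand <- data.frame(gene = g$gene[gi],
                       aa = as.integer(ceiling(stats::runif(k) * g$codons[gi])),
                       base = sample(1:3, k, replace = TRUE),
                       stringsAsFactors = FALSE)
    cand <- cand[!paste(cand$gene, cand$aa) %in% hs_key, , drop = FALSE]
    out <- unique(rbind(out, cand))
  }
  out[seq_len(n), , drop = FALSE]
}

# vectorized (gene, aa, base) -> genomic coordinates
map_loci <- function(models, loci) {
  chrom <- character(nrow(loci))
  pos <- integer(nrow(loci))
  for (gn in unique(loci$gene)) {
    i <- which(loci$gene == gn)
    # bases may differ within a gene; map per base offset
    for (b in unique(loci$base[i])) {
      j <- i[loci$base[i] == b]
      m <- aa_to_genomic(models, gn, loci$aa[j], base = b)
      chrom[j] <- m$chrom
      pos[j] <- m$pos
    }
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

# deterministic reference base per position keeps ref consistent across
# samples and generator components
ref_base <- function(pos) c("A", "C", "G", "T")[(pos %% 4L) + 1L]

other_base <- function(ref) {
  vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
         character(1), USE.NAMES = FALSE)
}

#' Write the population frequency tables
#'
#' One wide TSV with the four population columns; ground-truth columns
#' (`origin`, `impact`) are dropped unless `keep_truth = TRUE`.
#'
#' @param db a `frequency_db`.
#' @param path output TSV path.
#' @param keep_truth keep generator-only columns.
#' @return `path`, invisibly.
#' @export
write_frequency_db <- function(db, path, keep_truth = FALSE) {
  cols <- c("chrom", "pos", "ref", "alt", "rsid",
            if (keep_truth) c("gene", "aa_pos", "origin", "impact"),
            c("af_kg", "af_dk", "af_exac", "af_eur"))
  utils::write.table(db[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
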