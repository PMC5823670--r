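#' Write one sample's variant calls as VCF 4.2
#'
#' One bi-allelic record per alternative allele, site quality in `QUAL`,
#' high-quality depth and per-allele high-quality support in `INFO` (`DP`,
#' `HQAC`), plus population frequencies (`AF_KG`, `AF_DK`, `AF_EXAC`,
#' `AF_EUR`), `IMPACT`, `GENE` and `AA` when available. When a `flags`
#' column is present it is written as a `FLAGS` INFO key (semicolon-joined
#' names replaced by `|` inside the key, since `;` separates INFO fields).
#'
#' @param variants variant data.frame rows for a single sample.
#' @param path output `.vcf` path.
#' @param sample_id recorded in a `##sample_id` meta line; defaults to the
#'   table's single `sample_id` value.
#' @return `path`, invisibly.
#' @export
write_sample_vcf <- function(variants, path, sample_id = NULL) {
  stopifnot_cols(variants, c("chrom", "pos", "ref", "alt", "qual",
                             "hq_depth", "hq_alt_count"))
  sample_id <- sample_id %||% unique(variants$sample_id)
  if (length(sample_id) != 1L)
    stop("one sample per VCF; got ", length(sample_id), call. = FALSE)
  opt <- function(key, v, fmt = "%s") ifelse(
    is.na(v), "", sprintf(paste0(";", key, "=", fmt), v))
  info <- paste0(
    "DP=", variants$hq_depth, ";HQAC=", variants$hq_alt_count,
    opt("AF_KG", variants$af_kg, "%.6g"), opt("AF_DK", variants$af_dk, "%.6g"),
    opt("AF_EXAC", variants$af_exac, "%.6g"),
    opt("AF_EUR", variants$af_eur, "%.6g"),
    opt("IMPACT", variants$impact), opt("GENE", variants$gene),
    opt("AA", variants$aa_pos, "%d"),
    if ("flags" %in% names(variants))
      opt("FLAGS", gsub(";", "|", variants$flags)) else "")
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##sample_id=", sample_id),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"High-quality base depth\">",
    "##INFO=<ID=HQAC,Number=1,Type=Integer,Description=\"High-quality bases supporting ALT\">",
    "##INFO=<ID=AF_KG,Number=1,Type=Float,Description=\"1000-Genomes-like population AF\">",
    "##INFO=<ID=AF_DK,Number=1,Type=Float,Description=\"Danish reference panel AF\">",
    "##INFO=<ID=AF_EXAC,Number=1,Type=Float,Description=\"Exome aggregation AF\">",
    "##INFO=<ID=AF_EUR,Number=1,Type=Float,Description=\"European exome aggregation AF\">",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Predicted impact on canonical transcript\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=AA,Number=1,Type=Integer,Description=\"Amino-acid position\">",
    "##INFO=<ID=FLAGS,Number=1,Type=String,Description=\"Tumor-only flag set, |-joined\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  o <- order(variants$chrom, variants$pos, variants$alt)
  body <- paste(variants$chrom[o], variants$pos[o],
                ifelse(is.na(variants$rsid[o]), ".", variants$rsid[o]),
                variants$ref[o], variants$alt[o], variants$qual[o], ".",
                info[o], sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a cohort as one VCF per sample
#'
#' @param cohort a `synthetic_cohort` (or any list with a `variants` table).
#' @param dir output directory, created if needed.
#' @return character vector of written paths, invisibly.
#' @export
write_cohort_vcfs <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(split(cohort$variants, cohort$variants$sample_id),
                  function(v) write_sample_vcf(
                    v, file.path(dir, paste0(v$sample_id[1], ".vcf"))),
                  character(1))
  invisible(unname(paths))
}

#' Read a per-sample VCF back into the variant-table layout
#'
#' Parses with `vcfR` and reconstructs the columns the flagging stage needs.
#'
#' @param path VCF path written by [write_sample_vcf()] (or any VCF with
#'   `DP`/`HQAC` INFO keys).
#' @param sample_id overrides the `##sample_id` meta line.
#' @return variant data.frame.
#' @export
read_sample_vcf <- function(path, sample_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(sample_id)) {
    meta <- grep("^##sample_id=", v@meta, value = TRUE)
    sample_id <- if (length(meta)) sub("^##sample_id=", "", meta[1]) else
      sub("\\.vcf$", "", basename(path))
  }
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  num <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = key)))
  chr <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    ifelse(x == "" | is.na(x), NA_character_, x)
  }
  out <- data.frame(
    sample_id = sample_id, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, qual = as.numeric(fix$QUAL),
    hq_depth = as.integer(num("DP")), hq_alt_count = as.integer(num("HQAC")),
    rsid = ifelse(fix$ID == ".", NA_character_, fix$ID),
    impact = chr("IMPACT"), af_kg = num("AF_KG"), af_dk = num("AF_DK"),
    af_exac = num("AF_EXAC"), af_eur = num("AF_EUR"),
    gene = chr("GENE"),
    aa_pos = as.integer(num("AA")), stringsAsFactors = FALSE)
  fl <- chr("FLAGS")
  if (!all(is.na(fl))) out$flags <- gsub("\\|", ";", fl)
  out
}

#' Write exon models as BED (0-based half-open)
#'
#' @param models a `gene_models` object.
#' @param path output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_exon_bed <- function(models, path) {
  ex <- models$exons
  o <- order(ex$chrom, ex$start)
  writeLines(paste(ex$chrom[o], ex$start[o] - 1L, ex$end[o],
                   sprintf("%s:exon%d/%d", ex$gene[o], ex$exon_rank[o],
                           ex$n_exons[o]),
                   0L, ex$strand[o], sep = "\t"), path)
  invisible(path)
}

#' Write mask regions as BED (0-based half-open)
#'
#' Whole-gene masks (no coordinates) are skipped with a warning.
#'
#' @param masks mask data.frame ([read_mask_regions()]).
#' @param path output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_mask_bed <- function(masks, path) {
  skip <- masks$whole_gene & (is.na(masks$start) | is.na(masks$end))
  if (any(skip))
    warning("whole-gene mask(s) without coordinates not written: ",
            paste(masks$gene[skip], collapse = ", "), call. = FALSE)
  m <- masks[!skip, , drop = FALSE]
  writeLines(paste(m$chrom, m$start - 1L, m$end, m$gene, sep = "\t"), path)
  invisible(path)
}

#' Write / read the clinical table
#'
#' Plain TSV round-trip of the per-patient outcome table.
#'
#' @param clinical clinical data.frame.
#' @param path TSV path.
#' @return `path` (writer) or the clinical data.frame (reader).
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_table
#' @export
read_clinical_table <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("died_within_month", "neoadjuvant"))
    if (col %in% names(cl)) cl[[col]] <- as.logical(cl[[col]])
  cl
}

#' Write ground-truth labels
#'
#' @param cohort a `synthetic_cohort`.
#' @param path TSV path for the per-variant origin labels.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cohort, path) {
  utils::write.table(cohort$truth$origins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
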