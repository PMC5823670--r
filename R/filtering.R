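#' Remove database-common variants
#'
#' Drops every record whose position carries the `CO` flag (any qualifying
#' alt common in some population panel). Since `G5`, `DK`, `EG` and `EE`
#' each imply `CO`, this removes all database-flagged variants.
#'
#' @param variants flagged variant data.frame (see [assign_flags()]).
#' @return the retained rows.
#' @export
database_filter <- function(variants) {
  stopifnot_cols(variants, "flags")
  variants[!has_flag(variants$flags, "CO"), , drop = FALSE]
}

#' Retain moderate- and high-impact variants
#'
#' Keeps records flagged `I2` or `I3`. Records with no impact flag (no
#' qualifying alt) cannot be evaluated biologically and are removed.
#'
#' @inheritParams database_filter
#' @return the retained rows.
#' @export
impact_filter <- function(variants) {
  stopifnot_cols(variants, "flags")
  variants[has_flag(variants$flags, "I2") | has_flag(variants$flags, "I3"), ,
           drop = FALSE]
}

#' Read a mask-region table
#'
#' @param path TSV with columns `chrom`, `start`, `end` (1-based inclusive),
#'   `gene`, `reason`, `whole_gene`.
#' @return mask data.frame.
#' @export
read_mask_regions <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(m, c("chrom", "start", "end", "gene", "whole_gene"), "mask table")
  m$whole_gene <- as.logical(m$whole_gene)
  bad <- !m$whole_gene & (is.na(m$start) | is.na(m$end) | m$start > m$end)
  if (any(bad))
    stop("malformed mask region(s): ",
         paste(m$gene[bad], collapse = ", "), call. = FALSE)
  m
}

#' Default mask regions
#'
#' Four regions of strange biological composition that defeat tumor-only
#' filtering: two repeat polymorphisms (a G/S repeat in TBP — whose printed
#' end coordinate is corrected here so the interval is well-formed — and a
#' Q repeat in LURAP1L), the pentameric-repeat gene KRTAP4-5 masked as a
#' whole gene, and an ERICH6B interval carrying in-frame deletions common
#' in European populations.
#'
#' @return mask data.frame shipped in `extdata/mask_regions.tsv`.
#' @export
default_masks <- function() {
  read_mask_regions(system.file("extdata", "mask_regions.tsv",
                                package = "tosca", mustWork = TRUE))
}

#' Remove variants in masked regions
#'
#' Positional masks are 1-based inclusive intervals; whole-gene masks remove
#' every variant annotated to the gene.
#'
#' @param variants variant data.frame with `chrom`, `pos` and (for
#'   whole-gene masks) `gene`.
#' @param regions mask data.frame as from [read_mask_regions()].
#' @return the retained rows.
#' @export
mask_filter <- function(variants, regions) {
  stopifnot_cols(variants, c("chrom", "pos"))
  drop <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(regions))) {
    if (isTRUE(regions$whole_gene[i])) {
      if ("gene" %in% names(variants))
        drop <- drop | (!is.na(variants$gene) &
                          variants$gene == regions$gene[i])
    } else {
      if (is.na(regions$start[i]) || is.na(regions$end[i]) ||
          regions$start[i] > regions$end[i])
        stop("malformed mask region: ", regions$gene[i], call. = FALSE)
      drop <- drop | (variants$chrom == regions$chrom[i] &
                        variants$pos >= regions$start[i] &
                        variants$pos <= regions$end[i])
    }
  }
  variants[!drop, , drop = FALSE]
}

#' Classify one recurrent variant group as germline or not
#'
#' Operationalizes "AAF distributed evenly around 0.5": a group observed in
#' at least `min_samples` samples is called germline when the median AAF
#' falls in `median_range` and at least `central_frac` of the observations
#' lie in `central_range`. Groups below the sample threshold are never
#' classified.
#'
#' @param aaf numeric vector of per-sample AAFs for one rs-id or genomic
#'   position.
#' @param min_samples minimum number of samples before the test is applied
#'   (default 4).
#' @param median_range interval the median AAF must fall in.
#' @param central_range interval counted as "around 0.5".
#' @param central_frac minimum fraction of observations in `central_range`.
#' @return `"germline"` or `"not-classified"`.
#' @export
germline_aaf_test <- function(aaf, min_samples = 4,
                              median_range = c(0.40, 0.60),
                              central_range = c(0.30, 0.70),
                              central_frac = 0.7) {
  if (length(aaf) < min_samples) return("not-classified")
  med <- stats::median(aaf)
  frac <- mean(aaf >= central_range[1] & aaf <= central_range[2])
  if (med >= median_range[1] && med <= median_range[2] &&
      frac >= central_frac) "germline" else "not-classified"
}

germline_group_key <- function(variants) {
  ifelse(!is.na(variants$rsid) & variants$rsid != "" & variants$rsid != ".",
         variants$rsid, paste0(variants$chrom, ":", variants$pos))
}

#' Remove germline-looking recurrent variant groups
#'
#' Groups records by rs-id (genomic position when no rs-id), applies
#' [germline_aaf_test()] to each group's per-sample AAFs, and removes
#' groups classified germline.
#'
#' @param variants flagged variant data.frame with `aaf`, `rsid`, `chrom`,
#'   `pos`, `sample_id`.
#' @param ... passed to [germline_aaf_test()].
#' @return the retained rows, with the per-group classification attached as
#'   attribute `"groups"` (data.frame: `group`, `n_samples`, `median_aaf`,
#'   `call`).
#' @export
germline_aaf_filter <- function(variants, ...) {
  stopifnot_cols(variants, c("sample_id", "chrom", "pos", "aaf"))
  key <- germline_group_key(variants)
  calls <- vapply(split(seq_len(nrow(variants)), key), function(i) {
    # one AAF per distinct sample in the group
    a <- variants$aaf[i][!duplicated(variants$sample_id[i])]
    germline_aaf_test(a, ...)
  }, character(1))
  groups <- data.frame(
    group = names(calls),
    n_samples = vapply(split(variants$sample_id, key),
                       function(s) length(unique(s)), integer(1)),
    median_aaf = vapply(split(variants$aaf, key), stats::median, numeric(1)),
    call = unname(calls), stringsAsFactors = FALSE)
  out <- variants[calls[key] != "germline", , drop = FALSE]
  attr(out, "groups") <- groups
  out
}

#' Remove benign, non-cancer-related variants
#'
#' Removes records whose rs-id is annotated `Benign` in the clinical
#' significance table *and* has no cancer connotation. Benign rs-ids that
#' are cancer-related, and rs-ids absent from the table, are retained.
#'
#' @param variants variant data.frame with `rsid`.
#' @param clinvar_table data.frame with `rsid`, `significance`,
#'   `cancer_related`.
#' @return the retained rows.
#' @export
benign_filter <- function(variants, clinvar_table) {
  stopifnot_cols(variants, "rsid")
  stopifnot_cols(clinvar_table, c("rsid", "significance", "cancer_related"))
  bad <- clinvar_table$rsid[clinvar_table$significance == "Benign" &
                              !clinvar_table$cancer_related]
  variants[is.na(variants$rsid) | !variants$rsid %in% bad, , drop = FALSE]
}

#' Remove blocklisted rs-ids
#'
#' User-supplied list of rs-ids removed for ad-hoc curational reasons.
#'
#' @param variants variant data.frame with `rsid`.
#' @param rsids character vector of rs-ids to drop.
#' @return the retained rows.
#' @export
blocklist_filter <- function(variants, rsids) {
  if (!length(rsids)) return(variants)
  variants[is.na(variants$rsid) | !variants$rsid %in% rsids, , drop = FALSE]
}

#' Gene-by-sample mutation matrix
#'
#' @param variants variant data.frame with `gene` and `sample_id`.
#' @param samples optional full sample universe (columns); defaults to the
#'   samples present.
#' @param counts return per-gene-sample variant counts instead of 0/1
#'   indicators.
#' @return integer matrix, genes as rows, samples as columns.
#' @export
mutation_matrix <- function(variants, samples = NULL, counts = FALSE) {
  stopifnot_cols(variants, c("gene", "sample_id"))
  v <- variants[!is.na(variants$gene), , drop = FALSE]
  samples <- samples %||% sort(unique(v$sample_id))
  genes <- sort(unique(v$gene))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  if (nrow(v)) {
    t <- table(factor(v$gene, genes), factor(v$sample_id, samples))
    m[] <- as.integer(t)
  }
  if (!counts) m[m > 1L] <- 1L
  m
}

#' Retain recurrently mutated genes
#'
#' @param matrix gene-by-sample mutation matrix.
#' @param min_samples minimum number of mutated samples (default 5).
#' @return character vector of retained gene names.
#' @export
gene_recurrence_filter <- function(matrix, min_samples = 5) {
  if (!nrow(matrix)) return(character(0))
  rownames(matrix)[rowSums(matrix > 0) >= min_samples]
}

#' Configure the somatic filter funnel
#'
#' Every stage can be switched off; with all stages disabled [run_funnel()]
#' is the identity.
#'
#' @param technical,database,impact,mask,germline_aaf,benign,recurrence
#'   logical stage switches.
#' @param drop_lq drop `LQ`-flagged records at the technical stage.
#' @param masks mask data.frame (default [default_masks()] when `mask`).
#' @param clinvar clinical-significance table for [benign_filter()] (`NULL`
#'   makes the benign stage a no-op).
#' @param blocklist character vector of rs-ids to drop.
#' @param min_gene_samples recurrence threshold (default 5).
#' @param ... extra arguments for [germline_aaf_filter()].
#' @return list of class `funnel_config`.
#' @export
funnel_config <- function(technical = TRUE, database = TRUE, impact = TRUE,
                          mask = TRUE, germline_aaf = TRUE, benign = TRUE,
                          recurrence = TRUE, drop_lq = TRUE, masks = NULL,
                          clinvar = NULL, blocklist = character(0),
                          min_gene_samples = 5, ...) {
  structure(list(technical = technical, database = database, impact = impact,
                 mask = mask, germline_aaf = germline_aaf, benign = benign,
                 recurrence = recurrence, drop_lq = drop_lq, masks = masks,
                 clinvar = clinvar, blocklist = blocklist,
                 min_gene_samples = min_gene_samples,
                 aaf_args = list(...)),
            class = "funnel_config")
}

#' Run the somatic filter funnel
#'
#' Applies, in order: the technical depth/AAF filter, the database (`CO`)
#' filter, the impact filter (`I2`/`I3`), region masks, the germline
#' AAF-distribution removal, the benign filter, the rs-id blocklist, and the
#' gene-recurrence filter. Emits a per-stage count funnel.
#'
#' @param variants flagged variant data.frame (from [assign_flags()]); the
#'   recurrence stage additionally requires a `gene` column.
#' @param config a [funnel_config()].
#' @return list of class `filter_funnel`: `variants` (the final somatic
#'   set), `funnel` (data.frame `stage`, `remaining`, `removed`), and
#'   `retained_genes` (when the recurrence stage ran).
#' @export
run_funnel <- function(variants, config = funnel_config()) {
  stopifnot(inherits(config, "funnel_config"))
  stages <- list()
  v <- variants
  note <- function(name) stages[[length(stages) + 1L]] <<-
    data.frame(stage = name, remaining = nrow(v), stringsAsFactors = FALSE)
  note("input")
  if (isTRUE(config$technical)) {
    keep <- technical_filter(v)
    if (isTRUE(config$drop_lq) && "flags" %in% names(v))
      keep <- keep & !has_flag(v$flags, "LQ")
    v <- v[keep, , drop = FALSE]
    note("technical")
  }
  if (isTRUE(config$database)) { v <- database_filter(v); note("database") }
  if (isTRUE(config$impact)) { v <- impact_filter(v); note("impact") }
  if (isTRUE(config$mask)) {
    v <- mask_filter(v, config$masks %||% default_masks())
    note("mask")
  }
  if (isTRUE(config$germline_aaf)) {
    v <- do.call(germline_aaf_filter, c(list(v), config$aaf_args))
    attr(v, "groups") <- NULL
    note("germline_aaf")
  }
  if (isTRUE(config$benign) && !is.null(config$clinvar)) {
    v <- benign_filter(v, config$clinvar)
    note("benign")
  }
  if (length(config$blocklist)) {
    v <- blocklist_filter(v, config$blocklist)
    note("blocklist")
  }
  retained_genes <- NULL
  if (isTRUE(config$recurrence)) {
    stopifnot_cols(v, "gene")
    retained_genes <- gene_recurrence_filter(mutation_matrix(v),
                                             config$min_gene_samples)
    v <- v[!is.na(v$gene) & v$gene %in% retained_genes, , drop = FALSE]
    note("gene_recurrence")
  }
  funnel <- do.call(rbind, stages)
  funnel$removed <- c(0L, -diff(funnel$remaining))
  rownames(v) <- NULL
  structure(list(variants = v, funnel = funnel,
                 retained_genes = retained_genes),
            class = "filter_funnel")
}

#' @export
print.filter_funnel <- function(x, ...) {
  cat("somatic filter funnel:\n")
  print(x$funnel, row.names = FALSE)
  invisible(x)
}

#' Audit a funnel result against generator ground truth
#'
#' Reports, for each origin label, how many records entered and how many
#' survived, plus the headline figures: sensitivity of common-germline
#' removal and the somatic fraction (purity) of the final set.
#'
#' @param result a `filter_funnel` from [run_funnel()].
#' @param cohort the `synthetic_cohort` the variants came from.
#' @return list: `by_origin` table, `germline_common_removed` fraction,
#'   `somatic_purity` fraction.
#' @export
audit_funnel <- function(result, cohort) {
  key <- function(v) paste(v$sample_id, v$chrom, v$pos, v$alt)
  tr <- cohort$truth$origins
  surv <- key(result$variants)
  origin_final <- tr$origin[match(surv, key(tr))]
  by_origin <- data.frame(
    origin = names(cohort$truth$counts),
    input = as.integer(cohort$truth$counts),
    surviving = as.integer(table(factor(origin_final,
                                        names(cohort$truth$counts)))))
  gc_in <- by_origin$input[by_origin$origin == "germline-common"]
  gc_out <- by_origin$surviving[by_origin$origin == "germline-common"]
  list(by_origin = by_origin,
       germline_common_removed = if (gc_in > 0) 1 - gc_out / gc_in else NA,
       somatic_purity = if (nrow(result$variants))
         mean(origin_final == "somatic") else NA)
}
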