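#' Load a cohort composition table
#'
#' The package ships the composition of the reference Danish colorectal
#' cancer cohort the generator defaults emulate: per cancer type (colon /
#' rectal) and stage, patient counts for the full discovery cohort (273
#' patients) and for the subset with reliable survival follow-up (the PFS
#' cohort).
#'
#' @param path TSV with columns `cohort`, `cancer_type`, `stage`, `n`;
#'   defaults to the shipped table.
#' @return composition data.frame.
#' @export
read_cohort_composition <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cohort_composition.tsv",
                                package = "tosca", mustWork = TRUE)
  comp <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(comp, c("cohort", "cancer_type", "stage", "n"),
                 "composition table")
  comp
}

#' Pooled per-stage counts for one cohort
#'
#' Sums the per-cancer-type counts, recomputing the pooled column of the
#' composition table.
#'
#' @param comp composition table ([read_cohort_composition()]).
#' @param cohort cohort label (e.g. `"discovery"` or `"pfs"`).
#' @return named integer vector of pooled counts per stage.
#' @export
cohort_stage_counts <- function(comp, cohort) {
  c0 <- comp[comp$cohort == cohort, , drop = FALSE]
  if (!nrow(c0)) stop("unknown cohort: ", cohort, call. = FALSE)
  vapply(split(c0$n, c0$stage), sum, numeric(1))[unique(c0$stage)]
}

#' Total patients in one cohort
#'
#' @inheritParams cohort_stage_counts
#' @param cancer_type optional restriction (`"CC"` / `"RC"`).
#' @return integer count.
#' @export
cohort_size <- function(comp, cohort, cancer_type = NULL) {
  c0 <- comp[comp$cohort == cohort, , drop = FALSE]
  if (!is.null(cancer_type))
    c0 <- c0[c0$cancer_type %in% cancer_type, , drop = FALSE]
  as.integer(sum(c0$n))
}
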