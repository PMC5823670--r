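#' Build a cohort spec from a YAML configuration file
#'
#' Every field of [cohort_spec()] can be set from YAML; `hotspots` entries
#' are mappings with `gene`, `aa_position`, `prevalence`, `hazard_ratio`
#' and optional `width`. Unknown keys error rather than being ignored.
#'
#' @param path YAML file path.
#' @return a [cohort_spec()].
#' @export
cohort_spec_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs",
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- names(formals(cohort_spec))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown cohort_spec field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$hotspots))
    cfg$hotspots <- lapply(cfg$hotspots, function(h)
      planted_hotspot(h$gene, h$aa_position, h$prevalence, h$hazard_ratio,
                      h$width %||% 1L))
  if (!is.null(cfg$stage_probs)) cfg$stage_probs <- unlist(cfg$stage_probs)
  do.call(cohort_spec, cfg)
}

#' Write flagged variants as a flat TSV
#'
#' One row per sample/position/alt with the computed AAF and the position's
#' flag string — the tabular companion to the annotated VCF.
#'
#' @param variants flagged variant data.frame (from [assign_flags()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_flag_table <- function(variants, path) {
  stopifnot_cols(variants, c("sample_id", "chrom", "pos", "ref", "alt",
                             "aaf", "flags"))
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "aaf", "flags")
  out <- variants[, cols]
  out$aaf <- signif(out$aaf, 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
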