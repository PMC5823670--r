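#' Describe a planted prognostic hotspot
#'
#' A hotspot is a short amino-acid interval of a gene at which the generator
#' plants recurrent somatic mutations in a fixed fraction of patients, and
#' whose carriers have their baseline hazard multiplied by `hazard_ratio`.
#' `hazard_ratio = 1` plants a recurrence hotspot with no survival effect
#' (useful as a null covariate).
#'
#' @param gene gene identifier; must exist in the generated gene models.
#' @param aa_position 1-based amino-acid position of the first codon.
#' @param prevalence fraction of patients carrying a mutation in the hotspot,
#'   in (0, 1).
#' @param hazard_ratio multiplicative effect on the event hazard, > 0.
#' @param width number of consecutive codons the hotspot spans (default 1);
#'   a carrier's mutation lands uniformly on one of the codons.
#' @return an object of class `planted_hotspot`.
#' @export
planted_hotspot <- function(gene, aa_position, prevalence, hazard_ratio,
                            width = 1L) {
  stopifnot(is.character(gene), length(gene) == 1L,
            aa_position >= 1, width >= 1)
  if (!(prevalence > 0 && prevalence < 1))
    stop("prevalence must be in (0, 1)", call. = FALSE)
  if (!(hazard_ratio > 0))
    stop("hazard_ratio must be > 0", call. = FALSE)
  structure(list(gene = gene, aa_position = as.integer(aa_position),
                 prevalence = prevalence, hazard_ratio = hazard_ratio,
                 width = as.integer(width)),
            class = "planted_hotspot")
}

#' Default planted hotspots
#'
#' Three hotspots emulating the prognostic intervals recovered in pooled
#' colorectal-cancer cohorts: a common moderate-effect hotspot and two rarer
#' strong-effect hotspots (hazard ratios 2.0, 2.9 and 3.1 at prevalences
#' 9%, 5% and 4%).
#'
#' @return list of [planted_hotspot()] objects.
#' @export
default_hotspots <- function() {
  list(planted_hotspot("G001", 600L, 0.09, 2.0),
       planted_hotspot("G002", 332L, 0.05, 2.9),
       planted_hotspot("G003", 306L, 0.04, 3.1))
}

#' Specify a synthetic tumor-only cohort
#'
#' Collects every tunable parameter of the synthetic study: cohort size and
#' clinical composition, tumor purity, sequencing depth, gene-model shape,
#' per-patient variant rates by origin, planted hotspots, FFPE-artifact
#' noise, survival model and the master seed. Defaults describe a Danish
#' colorectal-cancer discovery cohort: stage composition (8/41/39/12% for
#' stages I-IV) and the colon fraction (63%) follow the reference cohort
#' composition shipped with the package, tumor purity spans 0.3-0.7
#' (specimens below 30% tumor nuclei are excluded from such studies), and
#' exclusion-flag probabilities mirror 24/303 early deaths and 4/303
#' neoadjuvant-treated patients.
#'
#' @param n_patients number of tumors (one sample per patient).
#' @param stage_probs named probability vector over stages I-IV; must sum
#'   to 1.
#' @param cc_fraction probability that a patient has colon (vs rectal)
#'   cancer.
#' @param purity_range interval in (0, 1] from which per-sample tumor purity
#'   is drawn uniformly.
#' @param depth_mean mean high-quality read depth at a variant position.
#' @param n_genes number of genes in the synthetic gene models.
#' @param germline_common_rate expected common germline variants (population
#'   allele frequency >= 5% somewhere) per sample.
#' @param germline_rare_rate expected rare germline variants per sample.
#' @param somatic_rate expected background somatic variants per sample.
#' @param hotspots list of [planted_hotspot()] objects.
#' @param noise_rate expected FFPE-artifact low-AAF calls per sample.
#' @param early_death_prob probability a patient dies within a month of
#'   surgery (excluded from survival analysis).
#' @param neoadjuvant_prob probability a patient received neoadjuvant
#'   therapy (excluded from survival analysis).
#' @param os_base_hazard,pfs_base_hazard baseline exponential hazards per
#'   month for overall and progression-free survival (defaults: median 60
#'   and 45 months).
#' @param censor_range uniform censoring window in months.
#' @param gene_codons optional integer vector (length `n_genes`) fixing each
#'   gene's codon count; otherwise drawn in 150-1500.
#' @param exons_per_gene optional integer vector fixing each gene's exon
#'   count; otherwise drawn in 1-16.
#' @param seed integer master seed; every generator function derives its
#'   randomness from it.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()], [generate_gene_models()],
#'   [generate_frequency_db()]
#' @export
cohort_spec <- function(n_patients = 200L,
                        stage_probs = c(I = 22, II = 112, III = 106, IV = 33) / 273,
                        cc_fraction = 173 / 273,
                        purity_range = c(0.3, 0.7),
                        depth_mean = 200,
                        n_genes = 25L,
                        germline_common_rate = 30,
                        germline_rare_rate = 8,
                        somatic_rate = 12,
                        hotspots = default_hotspots(),
                        noise_rate = 5,
                        early_death_prob = 24 / 303,
                        neoadjuvant_prob = 4 / 303,
                        os_base_hazard = log(2) / 60,
                        pfs_base_hazard = log(2) / 45,
                        censor_range = c(12, 120),
                        gene_codons = NULL,
                        exons_per_gene = NULL,
                        seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (abs(sum(stage_probs) - 1) > 1e-8 || any(stage_probs < 0) ||
      length(stage_probs) != 4L)
    stop("stage_probs must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  if (!(cc_fraction >= 0 && cc_fraction <= 1))
    stop("cc_fraction must be in [0, 1]", call. = FALSE)
  if (length(purity_range) != 2L || purity_range[1] > purity_range[2] ||
      purity_range[1] <= 0 || purity_range[2] > 1)
    stop("purity_range must be an interval within (0, 1]", call. = FALSE)
  rates <- c(germline_common_rate, germline_rare_rate, somatic_rate,
             noise_rate)
  if (any(rates < 0)) stop("variant rates must be >= 0", call. = FALSE)
  stopifnot(all(vapply(hotspots, inherits, logical(1), "planted_hotspot")))
  names(stage_probs) <- c("I", "II", "III", "IV")
  structure(list(
    n_patients = as.integer(n_patients), stage_probs = stage_probs,
    cc_fraction = cc_fraction, purity_range = purity_range,
    depth_mean = depth_mean, n_genes = as.integer(n_genes),
    germline_common_rate = germline_common_rate,
    germline_rare_rate = germline_rare_rate, somatic_rate = somatic_rate,
    hotspots = hotspots, noise_rate = noise_rate,
    early_death_prob = early_death_prob, neoadjuvant_prob = neoadjuvant_prob,
    os_base_hazard = os_base_hazard, pfs_base_hazard = pfs_base_hazard,
    censor_range = censor_range, gene_codons = gene_codons,
    exons_per_gene = exons_per_gene, seed = as.integer(seed)),
    class = "cohort_spec")
}
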