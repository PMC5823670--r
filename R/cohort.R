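#' Generate a synthetic tumor-only cohort with ground truth
#'
#' Simulates the complete study: per-sample variant calls (VCF-serializable,
#' with site quality, high-quality depth and per-allele high-quality counts),
#' the clinical table, and ground-truth labels. Variant origins:
#'
#' * `germline-common` / `germline-rare`: heterozygous, alternative allele
#'   fraction (AAF) drawn Beta(20, 20) — symmetric about 0.5 — then binomially
#'   resampled at the realized read depth; drawn from the allele registry of
#'   [generate_frequency_db()], so recurrent across patients.
#' * `somatic`: AAF drawn from a Beta with mean purity/2 (diploid
#'   heterozygous mutation diluted by tumor content), overdispersion
#'   concentration 25.
#' * `artifact`: FFPE-like noise calls whose realized AAF is always < 5%.
#'
#' Each planted hotspot mutates a Bernoulli(`prevalence`) subset of patients
#' at its codons; carriers have both survival hazards multiplied by the
#' hotspot's hazard ratio. Survival times are exponential with uniform
#' censoring.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort`: list with `spec`, `models`,
#'   `freq_db`, `variants` (one row per sample x position x alt, including
#'   annotation and ground-truth columns), `clinical` (one row per patient),
#'   and `truth` (list: `origins`, `carriers` patient x hotspot matrix,
#'   `counts` realized draws per origin label).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  models <- generate_gene_models(spec)
  freq_db <- generate_frequency_db(spec, models)
  withr::with_seed(spec$seed + 2L, {
    n <- spec$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    purity <- stats::runif(n, spec$purity_range[1], spec$purity_range[2])

    germ <- draw_germline(spec, freq_db, ids)
    som <- draw_somatic(spec, models, ids, purity, attr(germ, "keys"))
    art <- draw_artifacts(spec, models, ids,
                          c(attr(germ, "keys"), attr(som, "keys")))
    variants <- rbind(germ, som, art)
    variants <- variants[order(variants$sample_id, variants$chrom,
                               variants$pos, variants$alt), ]
    rownames(variants) <- NULL

    carriers <- attr(som, "carriers")
    clinical <- draw_clinical(spec, ids, carriers)

    counts <- c(table(factor(variants$origin,
                             levels = c("germline-common", "germline-rare",
                                        "somatic", "artifact"))))
    structure(list(spec = spec, models = models, freq_db = freq_db,
                   variants = variants, clinical = clinical,
                   truth = list(
                     origins = variants[, c("sample_id", "chrom", "pos",
                                            "alt", "origin")],
                     carriers = carriers, counts = counts)),
              class = "synthetic_cohort")
  })
}

variant_row <- function(sample_id, chrom, pos, ref, alt, qual, hq_depth,
                        hq_alt_count, rsid, impact, af, gene, aa_pos, origin) {
  n <- length(pos)
  rsid <- rep_len(rsid, n)
  impact <- rep_len(impact, n)
  origin <- rep_len(origin, n)
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, qual = qual,
             hq_depth = as.integer(hq_depth),
             hq_alt_count = as.integer(hq_alt_count), rsid = rsid,
             impact = impact, af_kg = af[, 1], af_dk = af[, 2],
             af_exac = af[, 3], af_eur = af[, 4], gene = gene,
             aa_pos = as.integer(aa_pos), origin = origin,
             stringsAsFactors = FALSE)
}

site_qual <- function(k, low_frac = 0.02) {
  q <- stats::runif(k, 25, 2000)
  low <- stats::runif(k) < low_frac
  q[low] <- stats::runif(sum(low), 2, 19)
  round(q, 1)
}

draw_germline <- function(spec, freq_db, ids) {
  n <- length(ids)
  pools <- split(seq_len(nrow(freq_db)), freq_db$origin)
  pick <- function(rate, pool) {
    k <- pmin(stats::rpois(n, rate), length(pool))
    data.frame(sample_id = rep(ids, k),
               idx = unlist(lapply(k, function(m) sample(pool, m))),
               stringsAsFactors = FALSE)
  }
  d <- rbind(pick(spec$germline_common_rate, pools[["germline-common"]]),
             pick(spec$germline_rare_rate, pools[["germline-rare"]]))
  a <- freq_db[d$idx, ]
  m <- nrow(d)
  aaf <- stats::rbeta(m, 20, 20)
  depth <- pmax(1L, stats::rpois(m, spec$depth_mean))
  alt_n <- stats::rbinom(m, depth, aaf)
  out <- variant_row(d$sample_id, a$chrom, a$pos, a$ref, a$alt, site_qual(m),
                     depth, alt_n, a$rsid, a$impact,
                     as.matrix(a[, c("af_kg", "af_dk", "af_exac", "af_eur")]),
                     a$gene, a$aa_pos, a$origin)
  attr(out, "keys") <- paste(d$sample_id, a$gene, a$aa_pos, a$base)
  out
}

# k unique coding loci per patient; redraws the rare within-patient collision
draw_unique_loci <- function(spec, models, sample_id, reserved_keys = NULL) {
  loci <- draw_coding_loci(spec, models, length(sample_id))
  key <- function(l) paste(sample_id, l$gene, l$aa, l$base)
  bad <- duplicated(key(loci)) | key(loci) %in% reserved_keys
  while (any(bad)) {
    loci[bad, ] <- draw_coding_loci(spec, models, sum(bad))
    bad <- duplicated(key(loci)) | key(loci) %in% reserved_keys
  }
  loci
}

somatic_aaf <- function(purity, conc = 25) {
  m <- purity / 2
  stats::rbeta(length(purity), m * conc, (1 - m) * conc)
}

draw_somatic <- function(spec, models, ids, purity, reserved = NULL) {
  n <- length(ids)
  hs <- spec$hotspots
  # planted hotspot mutations first
  carriers <- matrix(0L, n, length(hs),
                     dimnames = list(ids, vapply(hs, function(h)
                       sprintf("%s:%d", h$gene, h$aa_position), character(1))))
  hs_rows <- NULL
  for (j in seq_along(hs)) {
    h <- hs[[j]]
    carriers[, j] <- stats::rbinom(n, 1L, h$prevalence)
    ci <- which(carriers[, j] == 1L)
    if (!length(ci)) next
    aa <- h$aa_position + sample.int(h$width, length(ci), replace = TRUE) - 1L
    hs_rows <- rbind(hs_rows, data.frame(
      sample_id = ids[ci], gene = h$gene, aa = aa,
      base = sample(1:3, length(ci), replace = TRUE),
      purity = purity[ci], impact = "moderate", stringsAsFactors = FALSE))
  }
  # background somatic mutations
  k <- stats::rpois(n, spec$somatic_rate)
  sid <- rep(ids, k)
  hs_keys <- if (!is.null(hs_rows))
    paste(hs_rows$sample_id, hs_rows$gene, hs_rows$aa, hs_rows$base)
  bg <- draw_unique_loci(spec, models, sid, c(reserved, hs_keys))
  bg <- data.frame(sample_id = sid, bg, purity = rep(purity, k),
                   impact = sample(impact_levels(), length(sid),
                                   replace = TRUE,
                                   prob = c(0.05, 0.10, 0.55, 0.30)),
                   stringsAsFactors = FALSE)
  all <- rbind(hs_rows, bg)
  m <- nrow(all)
  coord <- map_loci(models, all[, c("gene", "aa", "base")])
  ref <- ref_base(coord$pos)
  depth <- pmax(1L, stats::rpois(m, spec$depth_mean))
  aaf <- somatic_aaf(all$purity)
  out <- variant_row(all$sample_id, coord$chrom, coord$pos, ref,
                     other_base(ref), site_qual(m), depth,
                     stats::rbinom(m, depth, aaf), NA_character_,
                     all$impact, matrix(NA_real_, m, 4), all$gene, all$aa,
                     "somatic")
  attr(out, "carriers") <- carriers
  attr(out, "keys") <- paste(all$sample_id, all$gene, all$aa, all$base)
  out
}

draw_artifacts <- function(spec, models, ids, reserved = NULL) {
  k <- stats::rpois(length(ids), spec$noise_rate)
  sid <- rep(ids, k)
  loci <- draw_unique_loci(spec, models, sid, reserved)
  m <- length(sid)
  coord <- map_loci(models, loci)
  ref <- ref_base(coord$pos)
  depth <- pmax(1L, stats::rpois(m, spec$depth_mean))
  aaf <- stats::runif(m, 0.004, 0.0475)
  # clamp so the realized fraction stays strictly below 5%
  alt_n <- pmin(pmax(1L, as.integer(round(aaf * depth))),
                pmax(as.integer(ceiling(0.05 * depth)) - 1L, 0L))
  variant_row(sid, coord$chrom, coord$pos, ref, other_base(ref),
              round(stats::runif(m, 3, 300), 1), depth, alt_n, NA_character_,
              sample(impact_levels(), m, replace = TRUE,
                     prob = c(0.5, 0.3, 0.15, 0.05)),
              matrix(NA_real_, m, 4), loci$gene, loci$aa, "artifact")
}

draw_clinical <- function(spec, ids, carriers) {
  n <- length(ids)
  hr <- vapply(spec$hotspots, `[[`, numeric(1), "hazard_ratio")
  mult <- if (length(hr)) exp(as.vector(carriers %*% log(hr))) else rep(1, n)
  cens <- stats::runif(n, spec$censor_range[1], spec$censor_range[2])
  t_os <- stats::rexp(n, spec$os_base_hazard * mult)
  t_pfs <- stats::rexp(n, spec$pfs_base_hazard * mult)
  data.frame(
    patient_id = ids,
    sex = sample(c("M", "F"), n, replace = TRUE),
    cancer_type = ifelse(stats::runif(n) < spec$cc_fraction, "CC", "RC"),
    stage = sample(names(spec$stage_probs), n, replace = TRUE,
                   prob = spec$stage_probs),
    os_time = pmax(round(pmin(t_os, cens), 2), 0.01),
    os_event = as.integer(t_os <= cens),
    pfs_time = pmax(round(pmin(t_pfs, cens), 2), 0.01),
    pfs_event = as.integer(t_pfs <= cens),
    died_within_month = stats::runif(n) < spec$early_death_prob,
    neoadjuvant = stats::runif(n) < spec$neoadjuvant_prob,
    stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d patients, %d genes, %d variant records\n",
              x$spec$n_patients, x$spec$n_genes, nrow(x$variants)))
  print(x$truth$counts)
  invisible(x)
}
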