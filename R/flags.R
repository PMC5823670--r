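#' Per-allele alternative allele fraction
#'
#' The AAF of an alternative allele is the number of high-quality bases
#' supporting it divided by the total number of high-quality bases at the
#' position.
#'
#' @param calls data.frame with columns `hq_depth` and `hq_alt_count` (one
#'   row per alternative allele).
#' @return numeric vector of per-row AAFs in \[0, 1\].
#' @export
allele_frequency <- function(calls) {
  stopifnot_cols(calls, c("hq_depth", "hq_alt_count"))
  if (any(calls$hq_depth == 0))
    stop("undefined allele frequency: hq_depth is 0", call. = FALSE)
  if (any(calls$hq_alt_count > calls$hq_depth))
    stop("hq_alt_count exceeds hq_depth", call. = FALSE)
  calls$hq_alt_count / calls$hq_depth
}

#' Which alternative alleles qualify for database and impact flags
#'
#' An alt qualifies when its AAF is at least 5% and it is supported by at
#' least 5 high-quality bases. Only qualifying alts gate the population
#' (G5/DK/EG/EE/CO) and impact (I0-I3) flags.
#'
#' @inheritParams allele_frequency
#' @return logical vector, one element per row of `calls`.
#' @export
qualifying_alts <- function(calls) {
  aaf <- allele_frequency(calls)
  aaf >= 0.05 & calls$hq_alt_count >= 5
}

flag_order <- function() {
  c("CO", "DK", "EE", "EG", "G5", "HF", "I0", "I1", "I2", "I3",
    "LD", "LF", "LQ")
}

#' Test membership of a flag in a semicolon-joined flag string
#'
#' @param flags character vector of `;`-joined flag strings.
#' @param flag single flag name.
#' @return logical vector.
#' @export
has_flag <- function(flags, flag) {
  grepl(paste0("(^|;)", flag, "(;|$)"), flags)
}

#' Assign the tumor-only flag taxonomy
#'
#' Evaluates, jointly over all alternative alleles of each sample/position,
#' the full flag set:
#'
#' * `LQ` — site quality below 20.
#' * `LD` — fewer than 10 high-quality bases at the position.
#' * `HF` — an alt with AAF above 95% that is supported by >= 5 high-quality
#'   reads, or fewer than 5 high-quality non-alternative bases while some alt
#'   has >= 5 supporting reads. Tumor content makes near-100% somatic AAFs
#'   implausible, so such sites are treated as homozygous-germline-like.
#' * `LF` — no alt reaches 5% AAF with >= 5 supporting reads.
#' * `G5` / `DK` / `EG` / `EE` — all qualifying alts are at >= 5% population
#'   frequency in, respectively, the 1000-Genomes-like, Danish, exome
#'   aggregation, or European exome aggregation panel.
#' * `CO` — every qualifying alt is common (>= 5%) in at least one of the
#'   four panels, possibly a different panel per alt, so `CO` can be set
#'   without any of `G5`/`DK`/`EG`/`EE`.
#' * `I0`-`I3` — maximum predicted impact (modifier/low/moderate/high, on
#'   the canonical transcript) among qualifying alts; absent when no alt
#'   qualifies.
#'
#' Rows belonging to the same sample and position must agree on `qual` and
#' `hq_depth`.
#'
#' @param calls data.frame with one row per alternative allele: `sample_id`,
#'   `chrom`, `pos`, `qual`, `hq_depth`, `hq_alt_count`, `impact`, and
#'   population columns `af_kg`, `af_dk`, `af_exac`, `af_eur` (`NA` = allele
#'   absent from that panel).
#' @return `calls` with added columns `aaf`, `qualifying`, and `flags` (the
#'   position's flags, `;`-joined in stable alphabetical order, replicated
#'   on each of its rows).
#' @export
assign_flags <- function(calls) {
  stopifnot_cols(calls, c("sample_id", "chrom", "pos", "qual", "hq_depth",
                          "hq_alt_count", "impact",
                          "af_kg", "af_dk", "af_exac", "af_eur"))
  calls$aaf <- allele_frequency(calls)
  calls$qualifying <- calls$aaf >= 0.05 & calls$hq_alt_count >= 5
  key <- paste(calls$sample_id, calls$chrom, calls$pos, sep = "\r")
  idx <- match(key, unique(key))
  ng <- max(idx)

  first <- !duplicated(idx)
  qual_g <- calls$qual[first][order(idx[first])]
  depth_g <- calls$hq_depth[first][order(idx[first])]
  if (any(stats::ave(calls$qual, idx, FUN = function(v) length(unique(v))) > 1) ||
      any(stats::ave(calls$hq_depth, idx, FUN = function(v) length(unique(v))) > 1))
    stop("rows of one sample/position must share qual and hq_depth",
         call. = FALSE)

  gsum <- function(v) as.vector(rowsum(as.numeric(v), idx))
  n_alt_bases <- gsum(calls$hq_alt_count)
  n_qual <- gsum(calls$qualifying)
  q <- calls$qualifying

  if (any(q & is.na(calls$impact)))
    stop("annotation-incomplete: qualifying alt without impact annotation",
         call. = FALSE)
  bad_impact <- !is.na(calls$impact) & !calls$impact %in% impact_levels()
  if (any(bad_impact))
    stop("unknown impact level: ",
         paste(unique(calls$impact[bad_impact]), collapse = ", "),
         call. = FALSE)

  common_in <- function(af) !is.na(af) & af >= 0.05
  all_q <- function(cond) n_qual > 0 & gsum(q & cond) == n_qual

  f <- data.frame(
    LQ = qual_g < 20,
    LD = depth_g < 10,
    HF = gsum(calls$aaf > 0.95 & calls$hq_alt_count >= 5) > 0 |
      (depth_g - n_alt_bases < 5 & gsum(calls$hq_alt_count >= 5) > 0),
    LF = n_qual == 0,
    G5 = all_q(common_in(calls$af_kg)),
    DK = all_q(common_in(calls$af_dk)),
    EG = all_q(common_in(calls$af_exac)),
    EE = all_q(common_in(calls$af_eur)),
    CO = all_q(common_in(calls$af_kg) | common_in(calls$af_dk) |
                 common_in(calls$af_exac) | common_in(calls$af_eur)))

  imp_num <- ifelse(q, match(calls$impact, impact_levels()), NA_integer_)
  max_imp <- rep(NA_integer_, ng)
  have <- !is.na(imp_num)
  if (any(have)) {
    mx <- tapply(imp_num[have], idx[have], max)
    max_imp[as.integer(names(mx))] <- as.integer(mx)
  }

  parts <- cbind(
    ifelse(f$CO, "CO", NA), ifelse(f$DK, "DK", NA), ifelse(f$EE, "EE", NA),
    ifelse(f$EG, "EG", NA), ifelse(f$G5, "G5", NA), ifelse(f$HF, "HF", NA),
    ifelse(is.na(max_imp), NA, impact_flag(impact_levels()[max_imp])),
    ifelse(f$LD, "LD", NA), ifelse(f$LF, "LF", NA), ifelse(f$LQ, "LQ", NA))
  flags_g <- apply(parts, 1, function(r) paste(r[!is.na(r)], collapse = ";"))
  calls$flags <- flags_g[idx]
  calls
}

#' Technical filter on depth and allele fraction
#'
#' A position passes when it has at least 10 high-quality bases and at least
#' one alternative allele with AAF in the closed interval \[0.05, 0.95\].
#'
#' @inheritParams assign_flags
#' @return logical vector, one element per row (a position-level decision
#'   replicated on each of its rows).
#' @export
technical_filter <- function(calls) {
  stopifnot_cols(calls, c("sample_id", "chrom", "pos", "hq_depth",
                          "hq_alt_count"))
  aaf <- allele_frequency(calls)
  key <- paste(calls$sample_id, calls$chrom, calls$pos, sep = "\r")
  idx <- match(key, unique(key))
  in_range <- as.vector(rowsum(as.numeric(aaf >= 0.05 & aaf <= 0.95),
                               idx)) > 0
  pass_g <- calls$hq_depth[!duplicated(idx)][order(idx[!duplicated(idx)])] >= 10 &
    in_range
  pass_g[idx]
}
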