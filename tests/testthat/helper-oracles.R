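# Independent oracles and small constructors shared across tests.

# Straight-line re-statement of the flag rules, written scalar-by-scalar and
# kept independent of the vectorized implementation in the package.
straight_line_flags <- function(rows) {
  flags <- character(0)
  qual <- rows$qual[1]
  depth <- rows$hq_depth[1]
  aaf <- rows$hq_alt_count / depth
  if (qual < 20) flags <- c(flags, "LQ")
  if (depth < 10) flags <- c(flags, "LD")
  hf <- FALSE
  for (i in seq_len(nrow(rows)))
    if (aaf[i] > 0.95 && rows$hq_alt_count[i] >= 5) hf <- TRUE
  if (depth - sum(rows$hq_alt_count) < 5 && any(rows$hq_alt_count >= 5))
    hf <- TRUE
  if (hf) flags <- c(flags, "HF")
  qualifies <- aaf >= 0.05 & rows$hq_alt_count >= 5
  if (!any(qualifies)) flags <- c(flags, "LF")
  if (any(qualifies)) {
    qr <- rows[qualifies, , drop = FALSE]
    in_db <- function(af) !is.na(af) & af >= 0.05
    if (all(in_db(qr$af_kg))) flags <- c(flags, "G5")
    if (all(in_db(qr$af_dk))) flags <- c(flags, "DK")
    if (all(in_db(qr$af_exac))) flags <- c(flags, "EG")
    if (all(in_db(qr$af_eur))) flags <- c(flags, "EE")
    if (all(in_db(qr$af_kg) | in_db(qr$af_dk) | in_db(qr$af_exac) |
              in_db(qr$af_eur)))
      flags <- c(flags, "CO")
    imp <- max(match(qr$impact, c("modifier", "low", "moderate", "high")))
    flags <- c(flags, c("I0", "I1", "I2", "I3")[imp])
  }
  paste(sort(flags), collapse = ";")
}

# one sample-position with one row per alt; vector arguments recycle
make_call <- function(qual = 100, depth = 100, alt_counts = 50,
                      af_kg = NA_real_, af_dk = NA_real_,
                      af_exac = NA_real_, af_eur = NA_real_,
                      impact = "moderate", sample_id = "S1",
                      chrom = "chr1", pos = 100L, rsid = NA_character_) {
  n <- length(alt_counts)
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = "A",
             alt = c("C", "G", "T")[seq_len(n)], qual = qual,
             hq_depth = depth, hq_alt_count = alt_counts, rsid = rsid,
             impact = rep_len(impact, n), af_kg = rep_len(af_kg, n),
             af_dk = rep_len(af_dk, n), af_exac = rep_len(af_exac, n),
             af_eur = rep_len(af_eur, n), stringsAsFactors = FALSE)
}

# exhaustive hypergeometric upper tail by direct enumeration
hyper_p_enum <- function(a, b, c, d) {
  n <- a + b + c + d
  K <- a + b          # gene-mentioning abstracts
  m <- a + c          # disease-mentioning abstracts
  ks <- a:min(K, m)
  sum(choose(K, ks) * choose(n - K, m - ks)) / choose(n, m)
}

# Breslow partial log-likelihood maximized on a grid, for a single binary
# covariate; independent of survival::coxph
cox_grid_hr <- function(time, event, x, betas = seq(-3, 3, by = 0.002)) {
  ll <- vapply(betas, function(b) {
    eta <- b * x
    sum(vapply(which(event == 1), function(i) {
      risk <- time >= time[i]
      eta[i] - log(sum(exp(eta[risk])))
    }, numeric(1)))
  }, numeric(1))
  exp(betas[which.max(ll)])
}

# small fast cohort for unit tests
quick_spec <- function(n_patients = 40, seed = 1, ...) {
  cohort_spec(n_patients = n_patients, n_genes = 10,
              germline_common_rate = 8, germline_rare_rate = 3,
              somatic_rate = 5, noise_rate = 2,
              hotspots = list(planted_hotspot("G001", 100L, 0.2, 1.5)),
              seed = seed, ...)
}

expect_setequal_rows <- function(a, b) {
  key <- function(d) sort(do.call(paste, c(d, sep = "\r")))
  expect_identical(key(a), key(b))
}
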