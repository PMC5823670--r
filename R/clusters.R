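#' Parameters for spatial cluster detection
#'
#' @param seed_min_samples minimum distinct mutated samples at a single
#'   codon for the codon to seed a cluster (default 2).
#' @param max_gap largest codon gap bridged when extending a seed to nearby
#'   mutated positions (default 5).
#' @param min_cluster_fraction drop clusters capturing less than this
#'   fraction of the gene's mutations (default 0, keep all).
#' @param background_source `"synonymous"` uses supplied silent-mutation
#'   positions (falling back to uniform per gene when none are available);
#'   `"uniform"` draws background positions uniformly over the protein.
#' @param n_background background replicates per gene for the null score
#'   distribution (default 199).
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(seed_min_samples = 2L, max_gap = 5L,
                           min_cluster_fraction = 0,
                           background_source = c("uniform", "synonymous"),
                           n_background = 199L) {
  stopifnot(seed_min_samples >= 1, max_gap >= 0, min_cluster_fraction >= 0,
            n_background >= 1)
  structure(list(seed_min_samples = as.integer(seed_min_samples),
                 max_gap = as.integer(max_gap),
                 min_cluster_fraction = min_cluster_fraction,
                 background_source = match.arg(background_source),
                 n_background = as.integer(n_background)),
            class = "cluster_params")
}

# maximal runs of mutated codons with gaps <= max_gap that contain a seed
detect_runs <- function(pos, cnt, seed_min, max_gap) {
  if (!length(pos)) return(NULL)
  o <- order(pos)
  pos <- pos[o]
  cnt <- cnt[o]
  new_run <- c(TRUE, diff(pos) > max_gap)
  id <- cumsum(new_run)
  has_seed <- as.vector(rowsum(as.numeric(cnt >= seed_min), id)) > 0
  runs <- data.frame(aa_start = pos[new_run],
                     aa_end = pos[c(new_run[-1], TRUE)],
                     n_mut = as.vector(rowsum(cnt, id)))
  runs[has_seed, , drop = FALSE]
}

max_run_score <- function(pos, cnt, n, seed_min, max_gap) {
  runs <- detect_runs(pos, cnt, seed_min, max_gap)
  if (is.null(runs) || !nrow(runs)) return(0)
  max(runs$n_mut) / n
}

# background distribution of the max cluster score for one gene
background_max_scores <- function(n_mut, length_aa, params, silent = NULL) {
  use_silent <- params$background_source == "synonymous" &&
    length(silent) >= 3L
  vapply(seq_len(params$n_background), function(b) {
    draw <- if (use_silent) sample(silent, n_mut, replace = TRUE)
            else sample.int(length_aa, n_mut, replace = TRUE)
    r <- rle(sort(draw))
    max_run_score(r$values, r$lengths, n_mut,
                  params$seed_min_samples, params$max_gap)
  }, numeric(1))
}

# randomized rank p: exactly Uniform(0,1) when obs and bg are exchangeable
rank_pvalue <- function(obs, bg) {
  (sum(bg > obs) + stats::runif(1) * (sum(bg == obs) + 1)) /
    (length(bg) + 1)
}

#' Detect spatial mutation clusters along protein coordinates
#'
#' Seed/extend clustering in the style of positional-clustering driver
#' detectors: codons mutated in at least `seed_min_samples` distinct samples
#' seed clusters, which absorb nearby mutated codons while gaps stay within
#' `max_gap`; overlapping extensions merge. A cluster's score is the
#' fraction of the gene's mutations falling inside it. Significance is
#' assessed against a per-gene background: `n_background` replicates of the
#' same number of mutations drawn from the background source (silent
#' mutations when available, else uniform over the protein), each reduced to
#' its maximum cluster score. Each cluster gets a z-score against this
#' distribution and a randomized empirical rank p-value that is exactly
#' calibrated for the gene's top-scoring cluster (conservative for the
#' rest). The p-value uses tie-randomization and therefore consumes random
#' numbers; fix the RNG seed for reproducibility.
#'
#' @param positions data.frame of per-sample mutated codons: `gene`,
#'   `sample_id`, `aa_pos`.
#' @param gene_lengths named vector of protein lengths in codons (e.g. from
#'   `gene_models$genes$codons`); every mutated gene must be present.
#' @param params a [cluster_params()].
#' @param silent_positions optional data.frame (`gene`, `aa_pos`) of silent
#'   mutations used as background when
#'   `params$background_source == "synonymous"`.
#' @return data.frame of clusters sorted by descending `sample_count`:
#'   `gene`, `aa_start`, `aa_end`, `sample_count`, `pct_of_gene`, `score`,
#'   `zscore`, `p_value`; per-gene max-score tests (every gene, including
#'   those without clusters) in attribute `"gene_tests"`.
#' @export
find_clusters <- function(positions, gene_lengths, params = cluster_params(),
                          silent_positions = NULL) {
  stopifnot_cols(positions, c("gene", "sample_id", "aa_pos"))
  stopifnot(inherits(params, "cluster_params"))
  u <- unique(positions[, c("gene", "sample_id", "aa_pos")])
  genes <- sort(unique(u$gene))
  absent <- setdiff(genes, names(gene_lengths))
  if (length(absent))
    stop("gene absent from models: ", paste(absent, collapse = ", "),
         call. = FALSE)
  clusters <- list()
  tests <- list()
  for (g in genes) {
    ug <- u[u$gene == g, , drop = FALSE]
    n_mut <- nrow(ug)
    tab <- table(ug$aa_pos)
    pos <- as.integer(names(tab))
    cnt <- as.integer(tab)
    runs <- detect_runs(pos, cnt, params$seed_min_samples, params$max_gap)
    silent <- if (!is.null(silent_positions))
      silent_positions$aa_pos[silent_positions$gene == g]
    bg <- background_max_scores(n_mut, gene_lengths[[g]], params, silent)
    bg_mean <- mean(bg)
    bg_sd <- stats::sd(bg)
    zs <- function(s) if (isTRUE(bg_sd > 0)) (s - bg_mean) / bg_sd else NA_real_
    if (!is.null(runs) && nrow(runs)) {
      runs$score <- runs$n_mut / n_mut
      runs <- runs[runs$score >= params$min_cluster_fraction, , drop = FALSE]
    }
    obs_max <- if (!is.null(runs) && nrow(runs)) max(runs$score) else 0
    tests[[g]] <- data.frame(gene = g, n_mut = n_mut, max_score = obs_max,
                             zscore = zs(obs_max),
                             p_value = rank_pvalue(obs_max, bg),
                             stringsAsFactors = FALSE)
    if (is.null(runs) || !nrow(runs)) next
    gene_samples <- length(unique(ug$sample_id))
    runs$sample_count <- vapply(seq_len(nrow(runs)), function(i)
      length(unique(ug$sample_id[ug$aa_pos >= runs$aa_start[i] &
                                   ug$aa_pos <= runs$aa_end[i]])),
      integer(1))
    runs$gene <- g
    runs$pct_of_gene <- percent_of_gene(runs$sample_count, gene_samples)
    runs$zscore <- vapply(runs$score, zs, numeric(1))
    runs$p_value <- vapply(seq_len(nrow(runs)), function(i) {
      if (runs$score[i] == obs_max) tests[[g]]$p_value
      else rank_pvalue(runs$score[i], bg)
    }, numeric(1))
    clusters[[g]] <- runs
  }
  out <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(gene = character(), aa_start = integer(), aa_end = integer(),
               n_mut = integer(), score = numeric(), sample_count = integer(),
               pct_of_gene = numeric(), zscore = numeric(),
               p_value = numeric(), stringsAsFactors = FALSE)
  out <- out[order(-out$sample_count, out$gene, out$aa_start), ,
             drop = FALSE]
  out <- out[, c("gene", "aa_start", "aa_end", "sample_count", "pct_of_gene",
                 "score", "zscore", "p_value")]
  rownames(out) <- NULL
  attr(out, "gene_tests") <- do.call(rbind, c(tests, list(
    make.row.names = FALSE)))
  out
}

#' Patient-by-cluster covariate matrix
#'
#' Indicator 1 when the patient has at least one mutation inside the cluster
#' interval (ends inclusive). Clusters mutated in `min_samples` or fewer
#' patients are dropped — the default keeps clusters mutated in *more than*
#' five samples, the covariate rule of the survival stage.
#'
#' @param clusters cluster data.frame from [find_clusters()].
#' @param positions per-sample mutated codons (`gene`, `sample_id`,
#'   `aa_pos`).
#' @param patients character vector of all analyzed patients (matrix rows);
#'   defaults to the samples present in `positions`.
#' @param min_samples drop clusters with `<= min_samples` mutated patients
#'   (default 5); set 0 to keep all.
#' @return integer matrix, patients x clusters; column names
#'   `"gene:start-end"`.
#' @export
cluster_covariates <- function(clusters, positions, patients = NULL,
                               min_samples = 5) {
  stopifnot_cols(positions, c("gene", "sample_id", "aa_pos"))
  patients <- patients %||% sort(unique(positions$sample_id))
  m <- matrix(0L, length(patients), nrow(clusters),
              dimnames = list(patients, sprintf("%s:%d-%d", clusters$gene,
                                                clusters$aa_start,
                                                clusters$aa_end)))
  for (i in seq_len(nrow(clusters))) {
    hit <- positions$gene == clusters$gene[i] &
      positions$aa_pos >= clusters$aa_start[i] &
      positions$aa_pos <= clusters$aa_end[i]
    m[intersect(unique(positions$sample_id[hit]), patients), i] <- 1L
  }
  m[, colSums(m) > min_samples, drop = FALSE]
}
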