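---
title: "Tumor-only somatic variant analysis: models, filters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-only somatic variant analysis: models, filters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tosca)
```

## The problem

Targeted sequencing of archival (FFPE) colorectal tumors often happens
without a matched normal sample: germline variation cannot be subtracted
directly, and somatic mutations must be isolated with population databases
and allele-fraction heuristics. `tosca` implements that workflow end to
end — flagging, filtering, recurrence statistics, spatial hotspot
clustering, penalized Cox survival analysis, and evidence-based panel
scoring — together with a synthetic-cohort generator whose ground-truth
labels make every stage testable.

## The flag taxonomy

For each sample and genomic position, the alternative allele fraction (AAF)
of an alt allele is the number of high-quality bases supporting it divided
by the total high-quality bases at the position. Flags are assigned jointly
over all alts at a position:

* `LQ` (site quality < 20) and `LD` (high-quality depth < 10) mark
  unreliable sites. Both thresholds are strict `<` by a literal reading of
  the rules.
* An alt *qualifies* when its AAF ≥ 5% and it has ≥ 5 supporting bases
  (both inclusive). `LF` is set when nothing qualifies.
* `HF` marks sites whose AAF profile looks homozygous-germline: an alt
  above 95% AAF (strict `>`) with ≥ 5 supporting reads, or fewer than 5
  high-quality non-alternative bases. Because tumor content is far below
  95%, a heterozygous somatic mutation cannot reach such fractions. In the
  non-alternative-base branch the rules do not say which alt must carry the
  5 supporting reads; we require any alt with ≥ 5 reads, the closest
  literal reading.
* `G5`, `DK`, `EG`, `EE` are set when *all* qualifying alts are at ≥ 5%
  frequency in, respectively, a 1000-Genomes-like panel, a Danish reference
  panel, an exome-aggregation panel, or its European subset. `CO` requires
  each qualifying alt to be common in at least one — possibly different —
  panel, so `CO` can hold when no single-panel flag does.
* `I0`–`I3` encode the maximum predicted impact (modifier/low/moderate/high
  on the canonical transcript) among qualifying alts.

The technical filter, applied before any biological reasoning, keeps
positions with depth ≥ 10 and at least one alt with AAF in the closed
interval [0.05, 0.95]; we read "between 0.05 and 0.95" inclusively,
consistent with the inclusive 5% in the flag definitions.

## The filter funnel

`run_funnel()` applies, in order: technical filter (dropping `LQ` records
by default; configurable), database (`CO`) removal, impact restriction to
`I2`/`I3`, region masks, germline AAF-distribution removal, the benign
filter, an optional rs-id blocklist, and a gene-recurrence filter (genes
mutated in ≥ 5 samples). Every stage reports counts; with all stages
disabled the funnel is the identity.

Two stages deserve comment:

* **Region masks.** Four regions with repeat-driven artifactual recurrence
  are masked by default (two repeat polymorphisms, one whole repeat gene,
  one interval of common in-frame deletions). One printed source interval
  had its end coordinate below its start; the shipped table uses the
  corrected end so the interval is well-formed, and the fixture's comment
  column notes the correction.
* **Germline AAF test.** Groups (same rs-id, else same position) observed
  in ≥ 4 samples are called germline when the median across-sample AAF lies
  in [0.40, 0.60] and ≥ 70% of observations lie in [0.30, 0.70]. This
  operationalizes "AAF distributed evenly around 0.5", which in practice is
  often decided by eye on histograms; both windows and the fraction are
  configurable. At the generator's defaults the rule recovers > 95% of
  Beta(20, 20)-distributed germline groups while leaving somatic groups
  (mean AAF = purity/2 ≤ 0.35) untouched.

## Recurrence statistics

Gene-, exon- and codon-level tables count *distinct mutated samples*, not
variant records. Percentages are rounded half-up to one decimal
(`percent_of_gene(47, 76)` = 61.8). The length-weighted ranking uses

```
weighted_freq = sample_count / (coding_length_nt / 1000) / n_samples
```

i.e. mutated samples per coding kilobase per analyzed sample. Published
length-corrected tables of this kind typically cannot be reproduced exactly
because the normalizing length (CDS, targeted region, transcript) is not
stated; we therefore document our formula in the output rather than claim
parity. The sample-frequency denominator is always passed explicitly.

## Spatial hotspot clusters

`find_clusters()` is a positional-clustering driver detector in the spirit
of the silent-mutation-background approach: codons mutated in ≥
`seed_min_samples` samples (default 2) seed clusters, extended across
mutated codons while gaps ≤ `max_gap` (default 5); overlapping extensions
merge. A cluster's score is the fraction of the gene's mutations inside it.
The cited tool's defaults are not restated in its description, so these
values are our own, documented choice; with `seed_min_samples = 1`,
`max_gap = 0` the procedure degenerates to the per-codon table, a useful
sanity link to `position_burden()`.

Significance is measured against a per-gene background: `n_background`
(default 199) replicates of the same number of mutations drawn from silent
mutations when supplied, otherwise uniformly over the protein, each reduced
to its maximum cluster score. We report two quantities per cluster:

* `zscore` — the classical normal-approximation z of the score against the
  background distribution;
* `p_value` — a randomized empirical rank of the observed score among the
  background maxima. For a gene's top cluster this statistic is exchangeable
  with the background replicates under the null and therefore exactly
  Uniform(0, 1); for secondary clusters it is conservative. We made the
  empirical rank the primary p-value because cluster scores are discrete
  and right-skewed at realistic mutation counts, so a normal tail is not
  calibrated — the z-score is kept for comparability. Tie randomization
  consumes random numbers; set the RNG seed for reproducible p-values.

`cluster_covariates()` turns clusters into patient-level indicators and
drops clusters mutated in ≤ 5 patients before model selection (the
"more than five samples" covariate rule). Filtering before selection is our
reading of that rule; passing `min_samples = 0` defers the decision.

## Survival analysis

`apply_exclusions()` removes early post-operative deaths and
neoadjuvant-treated patients. `build_groups()` forms the eight standard
designs: OS pooled I–IV / I–III, and PFS for pooled, colon-only and
rectal-only cohorts in stages I–IV / I–III.

Selection uses an elastic-net Cox model over a regularization path
(`glmnet`; `alpha = 1` is the lasso default, and on well-separated planted
effects the selected support is stable across `alpha` in {0.2, 0.5, 1}).
The penalty is chosen by minimizing `deviance + df * log(n_events)` (a BIC)
along the path. We validated this choice with a calibration simulation
before freezing it: with a planted hazard ratio of 3 at 10% prevalence and
n = 400, the BIC rule selects the true covariate in ~100% of replicates
while selecting ~4% of null (HR = 1) covariates; cross-validated
`lambda.min` admitted ~21% of nulls and `lambda.1se` had essentially no
power at this effect size. Both CV rules remain available
(`lasso_cox(rule = "cv.min" / "cv.1se")`); they use 10-fold partial
likelihood and consume RNG for fold assignment.

Each selected cluster is then refit alone in an unpenalized Cox model for
its hazard ratio, with a two-group log-rank test as the primary p-value (a
Wald p and a Benjamini–Hochberg column are reported for reference only; no
multiplicity correction enters selection). Per-interval refitting — rather
than one multivariable model over all selected intervals — is the literal
reading of "tested in a regular survival analysis"; exactly-duplicated
covariate columns are represented by their first copy so that one member of
a perfectly correlated group carries the signal.

## Panel scoring

Gene evidence is summarized as a 0/1 gene × feature matrix (nine features
in the reference design). The score is the row sum; ties are broken by the
higher CRC mutation frequency, then alphabetically. The core panel takes
genes with score ≥ 1 — "positive score" is read as ≥ 1, since every gene
trivially satisfies ≥ 0 — plus genes above a strict 7% mutation-frequency
add-in. Extensions (text-mining hits below a Bonferroni threshold of
5·10⁻⁷, pathway and drug-target lists, length-normalized top-50 mutation
ranks, hand-picked mismatch-repair/receptor genes) merge by set union with
provenance accumulation. The text-mining test is a one-sided
(enrichment) Fisher exact test; sidedness is not specified in the reference
design, and enrichment is the only direction that supports inclusion. The
interaction filter keeps genes that are anchors or whose high-confidence
interactors are ≥ 10% anchors (inclusive).

## The synthetic cohort

`cohort_spec()` fixes the study conditions; `generate_cohort()` emulates:

* **Gene models** — 25 genes of 150–1500 codons in 1–16 exons on both
  strands, with a deterministic codon ↔ genomic mapping.
* **Germline variants** — drawn from a registry of common (AF ≥ 5%
  somewhere; 15% population-private) and rare alleles, heterozygous AAF ~
  Beta(20, 20) (symmetric about 0.5, matching the assumption behind the
  germline AAF test), then binomially resampled at a Poisson(200) depth.
* **Somatic variants** — AAF ~ Beta with mean purity/2 (diploid
  heterozygous mutation diluted by tumor content, concentration 25); tumor
  purity uniform on [0.3, 0.7], the lower bound reflecting the ≥ 30%
  tumor-nuclei inclusion threshold used for FFPE specimens.
* **Artifacts** — FFPE-like noise calls clamped below 5% realized AAF.
* **Hotspots** — `planted_hotspot()` mutates a Bernoulli(prevalence) subset
  of patients at its codons and multiplies both hazards by its hazard
  ratio. Defaults emulate prognostic intervals seen in pooled CRC cohorts
  (HR 2.0/2.9/3.1 at prevalence 9/5/4%).
* **Outcomes** — exponential baseline hazards (median OS 60 months, PFS 45
  months), uniform censoring on [12, 120] months; exclusion flags at the
  reference cohort's rates (24/303 early deaths, 4/303 neoadjuvant).
  Clinical stage composition follows the shipped reference cohort
  composition table (stages I–IV at 8/41/39/12%, 63% colon).

Per-patient variant counts are Poisson (30 common germline, 8 rare
germline, 12 somatic, 5 artifact calls by default). What the generator does
*not* emulate — copy-number change, subclonality, mapping artifacts,
microsatellite instability, correlated FFPE damage — bounds what green
tests mean: they validate the pipeline's logic and calibration, not its
behavior on every pathology of real data. PFS is drawn independently of OS
rather than coupled to it; only marginal endpoint behavior is modeled.

## Numerical conventions and problem sizes

Printed percentages round half-up to one decimal (an epsilon guard absorbs
binary representation error). Mask intervals are 1-based inclusive
internally and 0-based half-open on BED export. All generator randomness
derives from a single integer seed (gene models, allele registry and cohort
draws use consecutive offsets of it), and identical specs produce
byte-identical cohorts. The test suite exercises the stochastic claims at
the cohort sizes of the reference design — 200 patients for filter
recovery (10 seeds), 200 for cluster detection (20 seeds), 400 for
survival parameter recovery (20 seeds), and 300 simulated genes for null
calibration of cluster p-values.

## A worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_patients = 200, seed = 1)
cohort <- generate_cohort(spec)
flagged <- assign_flags(cohort$variants)
funnel <- run_funnel(flagged, funnel_config(mask = FALSE))
audit_funnel(funnel, cohort)

somatic <- funnel$variants
clusters <- find_clusters(
  data.frame(gene = somatic$gene, sample_id = somatic$sample_id,
             aa_pos = somatic$aa_pos),
  setNames(cohort$models$genes$codons, cohort$models$genes$gene))
covariates <- cluster_covariates(clusters, somatic,
                                 patients = cohort$clinical$patient_id)
run_survival(covariates, cohort$clinical)
```

## Known limitations

Cohort-level published counts (e.g. a specific funnel 152,520 → 3,841 in
266 genes) depend on unavailable patient data and are not reproduction
targets. The cluster detector is a re-implementation of the cited concept,
not a port; numerical parity with the original tool is a non-goal. The
panel's nine evidence features are supplied by the user as named lists —
the scoring algorithm, not the curation behind the features, is what the
package implements.
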