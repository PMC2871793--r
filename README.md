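# castebias

Dual-omics detection of developmental caste bias in primitively eusocial
wasp larvae.

In *Polistes* paper wasps, castes are behavioral rather than
morphological, and the bias toward a worker or reproductive (gyne) fate is
hypothesized to arise during larval development: foundress-reared (FR)
larvae are putatively worker-destined, worker-reared (WR) larvae
putatively gyne-destined. `castebias` implements the full statistical
pipeline for testing that hypothesis from candidate-gene qPCR and
label-free spectral-count proteomics on the same kinds of larvae, together
with the haplodiploid microsatellite sexing needed to restrict analyses to
females, and a synthetic-data generator that makes every stage testable
without access to the original (undeposited) measurements.

## What it computes

* **Sexing** — females are diploid, males haploid: a specimen with a
  heterozygous microsatellite locus is a diploid female, one allele at
  every amplified locus marks a potential male, three alleles at a locus a
  triploid (`classify_ploidy()`, `filter_females()`).
* **qPCR quantification** — standard-curve absolute quantification
  (`Cq = a + b log10 q`), triplicate aggregation, merging of duplicate
  runs/contigs, division by the endogenous control gene followed by log2,
  within-group median imputation.
* **Per-gene tests, from first principles** — exact (full-enumeration,
  tie-aware) Mann–Whitney U, covering the 10 vs 7 design exactly
  (19,448 label assignments); fixed-effects one-way ANOVA F (= t²);
  Pearson correlation.
* **Min-p resampling correction** — group labels are permuted (or
  bootstrap-resampled), all per-feature p-values recomputed, and the
  corrected family cutoff taken as the empirical α-quantile of the
  per-iteration minimum p (Westfall–Young style family-wise control that
  adapts to inter-gene correlation). Genes must pass both the MWU and
  ANOVA family cutoffs (concordance).
* **Classification** — collinearity pruning (explicit drop list or a
  reproducible greedy rule), two-class LDA `w = S⁻¹(μ₂ − μ₁)` with
  optional ridge, and exact-refit leave-one-out cross-validation.
* **Proteomics** — presence filter (count ≥ 3 in ≥ 3 of 5 replicates),
  target-decoy FDR, spike-in (beta-lactoglobulin) + lane-total
  normalization for in-gel data or total-count normalization for
  in-liquid data, and the same MWU + min-p machinery per peptide family.
* **Reporting** — z-transformed heatmap matrices, LD-score histograms,
  five-number abundance summaries, TSV readers/writers that round-trip,
  and `run_caste_pipeline()` which chains all arms and returns an MD5
  manifest (identical config + seed ⇒ identical outputs).

## Worked example

```r
library(castebias)
library(dplyr)

study <- simulate_expression_study(seed = 11)   # 38 genes, 10 FR vs 7 WR
norm <- aggregate_technical_replicates(study$quantities) |>
  normalize_to_control(control_gene = "RSP8") |>
  left_join(study$samples[c("sample_id", "group")], by = "sample_id") |>
  filter(feature_id != "RSP8")
imputed <- impute_group_median(norm)

tests <- run_feature_tests(imputed, unimputed = norm)
co_u <- corrected_cutoff(imputed, "mwu",   n_iterations = 1000, seed = 101)
co_f <- corrected_cutoff(imputed, "anova", n_iterations = 1000, seed = 102)
tests <- apply_cutoff(tests, co_u, "both", anova_correction = co_f)
co_u
#> <resampling_correction> mwu / label_permutation, 38 features, 1000 iterations
#>   alpha = 0.05 -> corrected cutoff p <= 0.00308515

summarise(tests, n_significant = sum(significant),
          all_up_in_worker_reared = all(direction[significant] == "up_in_group2"))
#> # A tibble: 1 × 2
#>   n_significant all_up_in_worker_reared
#>           <int> <lgl>
#> 1            14 TRUE

sig <- filter(tests, significant)
cv <- loocv_lda(filter(imputed, feature_id %in% sig$feature_id),
                r_threshold = 0.9)
cv
#> <caste_loocv> 15/17 correct (accuracy 88.2%), 7 features
```

Fourteen of the 16 truly up-regulated genes clear the corrected cutoff
(p ≤ 0.0031 for the 38-gene family), every significant gene is
up-regulated in worker-reared larvae, and leave-one-out cross-validation
on the significant, pruned gene set classifies 15 of 17 larvae (88%)
correctly. `plot_ld_histogram(cv)` draws the per-group LD-score
histogram; `plot_expression_heatmap(build_heatmap_data(imputed, tests))`
the z-score heatmap.

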