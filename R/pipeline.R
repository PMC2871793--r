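#' Run the full caste-bias analysis pipeline
#'
#' Orchestrates the stages end to end on in-memory study objects: sexing
#' and female filtering (genotype arm), technical-replicate aggregation,
#' control normalization, group-median imputation, per-gene tests, min-p
#' corrected cutoffs, concordance flagging, pruned LDA with LOOCV
#' (expression arm), and spike-in/total-count normalization,
#' presence filtering, decoy FDR and corrected differential abundance
#' (proteomics arm). Every output table is written as TSV into `out_dir`
#' and listed in a manifest with its MD5 content hash; identical inputs and
#' seed give an identical manifest.
#'
#' @param out_dir output directory (created if absent).
#' @param expression an `expression_study` (or `NULL` to skip the arm).
#' @param genotypes a `genotype_study` or genotype tibble (or `NULL`).
#' @param spectral a `spectral_study` (or `NULL`).
#' @param control_gene endogenous control gene id.
#' @param alpha_genes,alpha_peptides family-wise error rates for the two
#'   feature families (each family's cutoff arises from its own resampling
#'   run).
#' @param n_iterations resampling iterations per corrected cutoff.
#' @param seed integer seed driving every resampling stage.
#' @param min_het_loci heterozygous-locus rule for sexing.
#' @param r_threshold,drop feature-pruning configuration for the LDA.
#' @param ridge_lambda,priors LDA configuration.
#' @param min_count,min_replicates presence-filter rule for spectral counts.
#' @return list with `manifest` (tibble `file`, `md5`) and the stage
#'   results (`sexing`, `gene_results`, `gene_corrections`, `loocv`,
#'   `proteomics`, `fdr`).
#' @export
run_caste_pipeline <- function(out_dir,
                               expression = NULL,
                               genotypes = NULL,
                               spectral = NULL,
                               control_gene = "RSP8",
                               alpha_genes = 0.05,
                               alpha_peptides = 0.05,
                               n_iterations = 1000,
                               seed = 1,
                               min_het_loci = 1,
                               r_threshold = 0.9,
                               drop = NULL,
                               ridge_lambda = 0,
                               priors = "empirical",
                               min_count = 3,
                               min_replicates = 3) {
  if (alpha_genes <= 0 || alpha_genes >= 1 || alpha_peptides <= 0 ||
      alpha_peptides >= 1) {
    config_error("alpha_genes and alpha_peptides must lie in (0, 1)")
  }
  if (n_iterations < 1) config_error("n_iterations must be >= 1")
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(x, name, writer = readr::write_tsv) {
    path <- file.path(out_dir, name)
    writer(x, path, na = "")
    files <<- c(files, path)
  }
  out <- list()

  if (!is.null(genotypes)) {
    gt <- if (inherits(genotypes, "genotype_study")) genotypes$genotypes else genotypes
    calls <- classify_ploidy(gt, min_het_loci = min_het_loci)
    sexed <- filter_females(gt, min_het_loci = min_het_loci)
    out$sexing <- list(calls = calls, females = sexed$females,
                       exclusions = sexed$exclusions)
    emit(calls, "ploidy_calls.tsv")
    emit(sexed$exclusions, "exclusions.tsv")
  }

  if (!is.null(expression)) {
    stopifnot(inherits(expression, "expression_study"))
    agg <- aggregate_technical_replicates(expression$quantities)
    norm <- normalize_to_control(agg, control_gene = control_gene)
    norm <- dplyr::left_join(norm,
                             expression$samples[c("sample_id", "group")],
                             by = "sample_id")
    norm <- norm[norm$feature_id != control_gene, ]
    imputed <- impute_group_median(norm)
    results <- run_feature_tests(imputed, unimputed = norm)
    corr_mwu <- corrected_cutoff(imputed, test = "mwu", alpha = alpha_genes,
                                 n_iterations = n_iterations, seed = seed)
    corr_anova <- corrected_cutoff(imputed, test = "anova", alpha = alpha_genes,
                                   n_iterations = n_iterations, seed = seed + 1L)
    results <- apply_cutoff(results, corr_mwu, which_p = "both",
                            anova_correction = corr_anova)
    sig <- results$feature_id[results$significant]
    loocv <- if (length(sig) >= 2) {
      sig_data <- imputed[imputed$feature_id %in% sig, ]
      tryCatch(
        loocv_lda(sig_data, r_threshold = r_threshold, drop = drop,
                  ridge_lambda = ridge_lambda, priors = priors),
        castebias_singularity_error = function(e) NULL
      )
    }
    out$gene_results <- results
    out$gene_corrections <- list(mwu = corr_mwu, anova = corr_anova)
    out$loocv <- loocv
    emit(results, "gene_tests.tsv")
    emit(dplyr::bind_rows(glance(corr_mwu), glance(corr_anova)),
         "gene_corrections.tsv")
    emit(build_heatmap_data(imputed, results), "gene_heatmap.tsv")
    if (!is.null(loocv)) {
      emit(loocv$predictions, "loocv_predictions.tsv")
      if (!is.null(loocv$prune_log)) emit(loocv$prune_log, "prune_log.tsv")
    }
  }

  if (!is.null(spectral)) {
    stopifnot(inherits(spectral, "spectral_study"))
    targets <- spectral$counts[!spectral$counts$is_decoy, ]
    filt <- presence_filter(targets, spectral$samples,
                            min_count = min_count,
                            min_replicates = min_replicates)
    out$fdr <- decoy_fdr(
      dplyr::distinct(spectral$counts, .data$hit_id, .data$is_decoy),
      accepted = c(filt$retained,
                   presence_filter(spectral$counts, spectral$samples,
                                   min_count = min_count,
                                   min_replicates = min_replicates)$retained)
    )
    kept <- targets[targets$hit_id %in% filt$retained, ]
    normalized <- if (spectral$mode == "in_gel") {
      normalize_in_gel(kept, spectral$spikeins)
    } else {
      normalize_in_liquid(kept)
    }
    da <- test_spectral_abundance(
      normalized, spectral$samples,
      protein_groups = dplyr::distinct(spectral$counts, .data$hit_id,
                                       .data$protein_group),
      alpha = alpha_peptides, n_iterations = n_iterations, seed = seed + 2L
    )
    out$proteomics <- list(results = da$results, correction = da$correction,
                           filter_log = filt$log, normalized = normalized)
    emit(da$results, "peptide_tests.tsv")
    emit(filt$log, "peptide_filter_log.tsv")
    emit(summarize_abundance(normalized, spectral$samples) |>
           dplyr::mutate(outliers = vapply(.data$outliers, function(o)
             paste(signif(o, 6), collapse = ","), character(1))),
         "peptide_summaries.tsv")
  }

  out$manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  out
}
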