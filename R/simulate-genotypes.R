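#' Simulate a haplodiploid microsatellite genotype table
#'
#' Generates specimens under the haplodiploid sex system: females carry two
#' alleles per locus (possibly identical), males exactly one, and triploids
#' three draws per locus. Each locus can fail to amplify independently with
#' `amplification_failure_rate`, producing an empty call distinct from a
#' homozygous call. Truth labels are kept for recovery tests.
#'
#' Defaults mirror a worker-reared cohort of 29 larvae genotyped at 6 loci
#' in which 18 were male and one triploid.
#'
#' @param n_specimens number of specimens.
#' @param n_loci number of microsatellite loci.
#' @param allele_freqs list of per-locus named frequency vectors (must sum
#'   to 1); default: 8 equifrequent alleles per locus.
#' @param male_fraction,triploid_fraction expected fractions (their sum must
#'   be <= 1); realized counts are the rounded expectations so the default
#'   reproduces 18 males and 1 triploid out of 29.
#' @param amplification_failure_rate per-locus dropout probability.
#' @param rearing label stored in the `rearing` column.
#' @param seed integer seed, or `NULL`.
#' @return object of class `genotype_study`: list with `genotypes` (tibble
#'   `specimen_id`, `year`, `rearing`, `locus1..K` with `/`-separated
#'   calls, `NA` = failed) and `truth` (tibble `specimen_id`, `sex`
#'   (`female`, `male`, `triploid`), `n_loci_failed`).
#' @export
simulate_genotype_table <- function(n_specimens = 29,
                                    n_loci = 6,
                                    allele_freqs = NULL,
                                    male_fraction = 18 / 29,
                                    triploid_fraction = 1 / 29,
                                    amplification_failure_rate = 0.02,
                                    rearing = "worker_reared",
                                    seed = NULL) {
  if (n_specimens < 1 || n_loci < 1) config_error("need >= 1 specimen and locus")
  if (male_fraction < 0 || triploid_fraction < 0 ||
      male_fraction + triploid_fraction > 1) {
    config_error("male_fraction + triploid_fraction must lie in [0, 1]")
  }
  if (amplification_failure_rate < 0 || amplification_failure_rate >= 1) {
    config_error("amplification_failure_rate must lie in [0, 1)")
  }
  if (is.null(allele_freqs)) {
    allele_freqs <- rep(list(stats::setNames(rep(1 / 8, 8),
                                             as.character(seq(100, 128, by = 4)))),
                        n_loci)
  }
  if (length(allele_freqs) != n_loci) {
    config_error("allele_freqs must supply one frequency vector per locus")
  }
  for (f in allele_freqs) {
    if (abs(sum(f) - 1) > 1e-8 || any(f < 0)) {
      config_error("each allele frequency vector must be non-negative and sum to 1")
    }
  }
  n_male <- round(male_fraction * n_specimens)
  n_tri <- round(triploid_fraction * n_specimens)
  if (n_male + n_tri > n_specimens) config_error("rounded male + triploid counts exceed n_specimens")
  sex <- sample_vec <- c(rep("male", n_male), rep("triploid", n_tri),
                         rep("female", n_specimens - n_male - n_tri))

  with_seed(seed, {
    sex <- sample(sex)
    ids <- sprintf("wr%02d", seq_len(n_specimens))
    draw <- function(locus, k) {
      f <- allele_freqs[[locus]]
      sample(names(f), k, replace = TRUE, prob = f)
    }
    loci_mat <- matrix(NA_character_, n_specimens, n_loci)
    failed <- matrix(runif(n_specimens * n_loci) < amplification_failure_rate,
                     n_specimens, n_loci)
    for (i in seq_len(n_specimens)) {
      k <- switch(sex[i], male = 1L, female = 2L, triploid = 3L)
      for (l in seq_len(n_loci)) {
        if (failed[i, l]) next
        loci_mat[i, l] <- paste(sort(unique(draw(l, k))), collapse = "/")
      }
    }
    genotypes <- tibble::as_tibble(
      stats::setNames(as.data.frame(loci_mat, stringsAsFactors = FALSE),
                      paste0("locus", seq_len(n_loci)))
    )
    genotypes <- dplyr::bind_cols(
      tibble::tibble(specimen_id = ids, year = 2005L, rearing = rearing),
      genotypes
    )
    structure(
      list(genotypes = genotypes,
           truth = tibble::tibble(specimen_id = ids, sex = sex,
                                  n_loci_failed = rowSums(failed))),
      class = "genotype_study"
    )
  })
}

#' @export
print.genotype_study <- function(x, ...) {
  cat(sprintf("<genotype_study> %d specimens, %d loci (truth: %s)\n",
              nrow(x$genotypes), sum(grepl("^locus", names(x$genotypes))),
              paste(sprintf("%s=%d", names(table(x$truth$sex)),
                            as.integer(table(x$truth$sex))), collapse = ", ")))
  invisible(x)
}
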