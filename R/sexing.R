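# Haplodiploid sexing from microsatellite genotypes: females are diploid
# (two alleles per locus, heterozygous loci prove diploidy), males haploid
# (one allele everywhere), and a locus with three alleles marks a triploid.

parse_locus_calls <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    unique(trimws(strsplit(as.character(s), "/", fixed = TRUE)[[1]]))
  })
}

#' Classify specimen ploidy from microsatellite allele calls
#'
#' A specimen is `triploid` if any locus carries three distinct alleles;
#' `unscored` if no locus amplified; `female_diploid` if at least
#' `min_het_loci` loci are heterozygous (a heterozygous locus proves
#' diploidy); otherwise `potential_male` (one allele at every amplified
#' locus -- consistent with haploidy but not proof, since a diploid can be
#' homozygous throughout). Failed loci (empty calls) are excluded from
#' counting.
#'
#' `min_het_loci = 1` follows the rule that one heterozygous locus already
#' proves diploidy; setting 2 reproduces the stricter two-locus convention.
#'
#' @param genotypes tibble with `specimen_id` and one column per locus
#'   (auto-detected as columns named `locus*`, or pass `locus_cols`);
#'   allele calls are `/`-separated labels, empty or `NA` = failed
#'   amplification.
#' @param min_het_loci heterozygous loci required to call a female.
#' @param locus_cols optional character vector of locus column names.
#' @return tibble `specimen_id`, `call` (`female_diploid`,
#'   `potential_male`, `triploid`, `unscored`), `n_heterozygous_loci`,
#'   `n_amplified_loci`.
#' @examples
#' g <- tibble::tibble(specimen_id = c("s1", "s2"),
#'                     locus1 = c("101/105", "101"),
#'                     locus2 = c("88/88", "92"))
#' classify_ploidy(g)
#' @export
classify_ploidy <- function(genotypes, min_het_loci = 1, locus_cols = NULL) {
  stopifnot_cols(genotypes, "specimen_id", "genotypes")
  if (is.null(locus_cols)) {
    locus_cols <- grep("^locus", names(genotypes), value = TRUE)
  }
  if (!length(locus_cols)) {
    abort("no locus columns found (expected names starting with 'locus')",
          class = "castebias_argument_error")
  }
  if (min_het_loci < 1) config_error("min_het_loci must be >= 1")
  purrr::pmap(genotypes[c("specimen_id", locus_cols)], function(specimen_id, ...) {
    calls <- parse_locus_calls(unlist(list(...)))
    n_alleles <- vapply(calls, length, integer(1))
    if (any(n_alleles > 3)) {
      abort(sprintf("specimen '%s' shows >3 alleles at a locus", specimen_id),
            class = "castebias_malformed_record_error")
    }
    amplified <- n_alleles > 0
    n_het <- sum(n_alleles == 2)
    call <- if (any(n_alleles == 3)) {
      "triploid"
    } else if (!any(amplified)) {
      "unscored"
    } else if (n_het >= min_het_loci) {
      "female_diploid"
    } else {
      "potential_male"
    }
    tibble::tibble(specimen_id = specimen_id, call = call,
                   n_heterozygous_loci = n_het,
                   n_amplified_loci = sum(amplified))
  }) |> dplyr::bind_rows()
}

#' Filter a genotype table to diploid females
#'
#' Applies [classify_ploidy()] and splits the table into the female analysis
#' set and an exclusion log recording every removed specimen with its
#' reason, so that retained plus excluded always partition the input.
#'
#' @inheritParams classify_ploidy
#' @return list with `females` (character vector of specimen ids) and
#'   `exclusions` (tibble `specimen_id`, `call`, `reason`).
#' @export
filter_females <- function(genotypes, min_het_loci = 1, locus_cols = NULL) {
  if (!nrow(genotypes)) {
    abort("genotype table is empty", class = "castebias_argument_error")
  }
  calls <- classify_ploidy(genotypes, min_het_loci = min_het_loci,
                           locus_cols = locus_cols)
  excl <- calls[calls$call != "female_diploid", ]
  list(
    females = calls$specimen_id[calls$call == "female_diploid"],
    exclusions = tibble::tibble(
      specimen_id = excl$specimen_id, call = excl$call,
      reason = dplyr::case_match(excl$call,
        "potential_male" ~ "single allele at every amplified locus",
        "triploid" ~ "three alleles at a locus",
        "unscored" ~ "no locus amplified")
    )
  )
}
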