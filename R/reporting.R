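#' Per-feature z-score transform
#'
#' Centers and scales each feature to mean 0, sample SD 1 across samples.
#' Constant features cannot be scaled; they are set to 0 and flagged (in
#' the `flagged_constant` attribute) rather than failing.
#'
#' @param data long tibble `feature_id`, `sample_id`, `value`.
#' @return same tibble with `value` z-transformed; attribute
#'   `flagged_constant` lists constant feature ids.
#' @export
z_transform <- function(data) {
  stopifnot_cols(data, c("feature_id", "sample_id", "value"))
  out <- data |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::mutate(
      .sd = sd(.data$value, na.rm = TRUE),
      value = ifelse(.data$.sd > 0,
                     (.data$value - mean(.data$value, na.rm = TRUE)) / .data$.sd,
                     0)
    ) |>
    dplyr::ungroup()
  flagged <- unique(out$feature_id[!is.na(out$.sd) & out$.sd == 0])
  out <- dplyr::select(out, -".sd")
  attr(out, "flagged_constant") <- flagged
  out
}

#' Heatmap-ready matrix of significant features
#'
#' Z-transforms the significant features and orders samples group-1 block
#' then group-2 block, features by ascending Mann-Whitney p.
#'
#' @param data long tibble `feature_id`, `sample_id`, `group`, `value`.
#' @param results flagged tibble from [apply_cutoff()].
#' @return long tibble `feature_id`, `sample_id`, `group`, `value` with
#'   both ids as ordered factors; empty (zero rows) when nothing is
#'   significant.
#' @export
build_heatmap_data <- function(data, results) {
  stopifnot_cols(results, c("feature_id", "p_mwu", "significant"), "results")
  sig <- results[results$significant, c("feature_id", "p_mwu")]
  sig <- sig[order(sig$p_mwu), ]
  d <- data[data$feature_id %in% sig$feature_id, ]
  if (!nrow(d)) {
    return(tibble::tibble(feature_id = factor(), sample_id = factor(),
                          group = character(), value = numeric()))
  }
  z <- z_transform(d[c("feature_id", "sample_id", "value")])
  z$group <- d$group[match(paste(z$feature_id, z$sample_id),
                           paste(d$feature_id, d$sample_id))]
  sample_order <- unique(d$sample_id[order(d$group, d$sample_id)])
  z$feature_id <- factor(z$feature_id, levels = sig$feature_id)
  z$sample_id <- factor(z$sample_id, levels = sample_order)
  z[order(z$feature_id, z$sample_id), c("feature_id", "sample_id", "group", "value")]
}

#' Five-number abundance summaries per hit and group
#'
#' Median, quartiles (linear-interpolation "type 7" convention), whisker
#' ends and 1.5 IQR outliers of normalized abundance, per feature and
#' group -- the numbers behind a box-style per-hit summary figure.
#'
#' @param normalized tibble `feature_id`, `sample_id`, `value`.
#' @param samples tibble `sample_id`, `group`.
#' @return tibble `feature_id`, `group`, `n`, `q1`, `median`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers` (list column).
#' @export
summarize_abundance <- function(normalized, samples) {
  stopifnot_cols(normalized, c("feature_id", "sample_id", "value"))
  d <- dplyr::left_join(normalized, samples[c("sample_id", "group")],
                        by = "sample_id")
  d |>
    dplyr::group_by(.data$feature_id, .data$group) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      q1 = unname(quantile(.data$value, 0.25, na.rm = TRUE, type = 7)),
      median = median(.data$value, na.rm = TRUE),
      q3 = unname(quantile(.data$value, 0.75, na.rm = TRUE, type = 7)),
      whisker_low = min(.data$value[.data$value >= .data$q1 - 1.5 * (.data$q3 - .data$q1)],
                        na.rm = TRUE),
      whisker_high = max(.data$value[.data$value <= .data$q3 + 1.5 * (.data$q3 - .data$q1)],
                         na.rm = TRUE),
      outliers = list(.data$value[!is.na(.data$value) &
                                    (.data$value < .data$q1 - 1.5 * (.data$q3 - .data$q1) |
                                       .data$value > .data$q3 + 1.5 * (.data$q3 - .data$q1))]),
      .groups = "drop"
    )
}

# ---- TSV readers/writers -------------------------------------------------
# All tables are UTF-8 tab-delimited with '.' decimals and empty fields for
# missing values; writers round-trip losslessly through their readers.

#' Read / write the long qPCR quantity table
#'
#' Columns `gene_id`, `sample_id`, `replicate`, `quantity`; empty quantity
#' = missing (never 0).
#' @param path file path.
#' @param quantities tibble as produced by
#'   `simulate_expression_study()$quantities`.
#' @return the tibble (readers) or `path` invisibly (writers).
#' @export
read_quantities_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), sample_id = readr::col_character(),
    replicate = readr::col_integer(), quantity = readr::col_double()))
}

#' @rdname read_quantities_tsv
#' @export
write_quantities_tsv <- function(quantities, path) {
  readr::write_tsv(quantities, path, na = "")
  invisible(path)
}

#' Read / write the sample-group map
#'
#' Columns `sample_id`, `group`, plus any extra columns (kept as-is).
#' @param path file path.
#' @param samples tibble with at least `sample_id`, `group`.
#' @export
read_samples_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), group = readr::col_character(),
    .default = readr::col_double()))
}

#' @rdname read_samples_tsv
#' @export
write_samples_tsv <- function(samples, path) {
  readr::write_tsv(samples, path, na = "")
  invisible(path)
}

#' Read / write a microsatellite genotype table
#'
#' Columns `specimen_id`, `year`, `rearing`, then `locus1..K` with
#' `/`-separated allele calls; empty = failed amplification.
#' @param path file path.
#' @param genotypes tibble as produced by
#'   `simulate_genotype_table()$genotypes`.
#' @export
read_genotypes_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    specimen_id = readr::col_character(), year = readr::col_integer(),
    rearing = readr::col_character(), .default = readr::col_character()))
}

#' @rdname read_genotypes_tsv
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  readr::write_tsv(genotypes, path, na = "")
  invisible(path)
}

#' Read / write a long spectral-count table
#'
#' Columns `hit_id`, `protein_group`, `is_decoy`, `sample_id`, `band`,
#' `count`.
#' @param path file path.
#' @param counts tibble as produced by `simulate_spectral_study()$counts`.
#' @export
read_spectral_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    hit_id = readr::col_character(), protein_group = readr::col_character(),
    is_decoy = readr::col_logical(), sample_id = readr::col_character(),
    band = readr::col_integer(), count = readr::col_integer()))
}

#' @rdname read_spectral_tsv
#' @export
write_spectral_tsv <- function(counts, path) {
  readr::write_tsv(counts, path, na = "")
  invisible(path)
}

#' Read / write a spike-in standard table
#'
#' Columns `sample_id`, `band`, `spikein_count`.
#' @param path file path.
#' @param spikeins tibble as produced by
#'   `simulate_spectral_study()$spikeins`.
#' @export
read_spikeins_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), band = readr::col_integer(),
    spikein_count = readr::col_integer()))
}

#' @rdname read_spikeins_tsv
#' @export
write_spikeins_tsv <- function(spikeins, path) {
  readr::write_tsv(spikeins, path, na = "")
  invisible(path)
}

#' Read / write a per-feature test-result table
#'
#' The [run_feature_tests()] schema plus any flag columns added by
#' [apply_cutoff()].
#' @param path file path.
#' @param results results tibble.
#' @export
read_results_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(), n1 = readr::col_integer(),
    n2 = readr::col_integer(), df1 = readr::col_integer(),
    df2 = readr::col_integer(), direction = readr::col_character(),
    significant = readr::col_logical(), .default = readr::col_double()))
}

#' @rdname read_results_tsv
#' @export
write_results_tsv <- function(results, path) {
  readr::write_tsv(results, path, na = "")
  invisible(path)
}
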