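#' Normalize in-gel spectral counts (spike-in, then lane total)
#'
#' Two-step normalization for in-gel digested samples: each hit's count is
#' first divided by the spike-in standard count of its (sample, band) to
#' cancel digestion variability, then each spike-normalized value is divided
#' by the sum of such values over all hits and bands of the sample's lane to
#' cancel loading differences, and band contributions are summed per hit.
#' Per-sample abundances therefore sum to 1.
#'
#' @param counts long tibble `hit_id`, `sample_id`, `band`, `count` (raw
#'   integer counts; decoys normally excluded beforehand).
#' @param spikeins tibble `sample_id`, `band`, `spikein_count`; every
#'   (sample, band) containing a nonzero hit count must have a positive
#'   spike-in count.
#' @return tibble `feature_id`, `sample_id`, `value` (relative abundance);
#'   attribute `trace` records the steps applied.
#' @examples
#' counts <- tibble::tibble(hit_id = c("a", "b"), sample_id = "s1",
#'                          band = 1L, count = c(10L, 30L))
#' spikes <- tibble::tibble(sample_id = "s1", band = 1L, spikein_count = 5L)
#' normalize_in_gel(counts, spikes)  # 0.25, 0.75
#' @export
normalize_in_gel <- function(counts, spikeins) {
  stopifnot_cols(counts, c("hit_id", "sample_id", "band", "count"))
  stopifnot_cols(spikeins, c("sample_id", "band", "spikein_count"), "spikeins")
  d <- dplyr::left_join(counts, spikeins, by = c("sample_id", "band"))
  bad <- d[d$count > 0 & (is.na(d$spikein_count) | d$spikein_count <= 0), ]
  if (nrow(bad)) {
    abort(sprintf("zero or missing spike-in count for sample '%s', band %s with nonzero hits",
                  bad$sample_id[1], bad$band[1]),
          class = "castebias_normalization_error")
  }
  d$step1 <- ifelse(d$count == 0, 0, d$count / d$spikein_count)
  d <- d |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(lane_total = sum(.data$step1)) |>
    dplyr::ungroup()
  if (any(d$lane_total == 0)) {
    abort("a lane has zero total spike-normalized count",
          class = "castebias_normalization_error")
  }
  out <- d |>
    dplyr::group_by(feature_id = .data$hit_id, .data$sample_id) |>
    dplyr::summarise(value = sum(.data$step1 / .data$lane_total),
                     .groups = "drop")
  attr(out, "trace") <- c("spike_in_per_band", "lane_total")
  out
}

#' Normalize in-liquid spectral counts (total count only)
#'
#' Each hit's count is divided by its sample's total spectral count, so
#' per-sample values sum to 1.
#'
#' @param counts long tibble `hit_id`, `sample_id`, `count` (a `band`
#'   column, if present, is summed over).
#' @return tibble `feature_id`, `sample_id`, `value`; attribute `trace`.
#' @export
normalize_in_liquid <- function(counts) {
  stopifnot_cols(counts, c("hit_id", "sample_id", "count"))
  d <- counts |>
    dplyr::group_by(feature_id = .data$hit_id, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(total = sum(.data$count)) |>
    dplyr::ungroup()
  if (any(d$total == 0)) {
    bad <- d$sample_id[d$total == 0][1]
    abort(sprintf("sample '%s' has zero total spectral count", bad),
          class = "castebias_normalization_error")
  }
  out <- tibble::tibble(feature_id = d$feature_id, sample_id = d$sample_id,
                        value = d$count / d$total)
  attr(out, "trace") <- "total_count"
  out
}

#' Replicate-presence filter for spectral counts
#'
#' Retains a hit only if its raw per-sample count (summed over bands)
#' reaches `min_count` in at least `min_replicates` samples of at least one
#' group (`scope = "either_group"`, the default -- a hit confidently
#' present in a single group is the most interesting case) or across all
#' samples (`scope = "pooled"`). The filter operates on raw counts, before
#' normalization, and is monotone: increasing any count never removes a
#' retained hit.
#'
#' @param counts long tibble `hit_id`, `sample_id`, `count` (+ optional
#'   `band`, summed over).
#' @param samples tibble `sample_id`, `group`.
#' @param min_count,min_replicates the "count >= 3 in at least 3 of 5
#'   replicates" rule.
#' @param scope `"either_group"` or `"pooled"`.
#' @return list with `retained` (character vector) and `log` (tibble
#'   `hit_id`, `retained`, `n_pass_group1`, `n_pass_group2`).
#' @export
presence_filter <- function(counts, samples, min_count = 3,
                            min_replicates = 3,
                            scope = c("either_group", "pooled")) {
  scope <- match.arg(scope)
  stopifnot_cols(counts, c("hit_id", "sample_id", "count"))
  gv <- group_vector(samples, unique(samples$sample_id))
  sizes <- table(gv$g)
  if (any(sizes < min_replicates)) {
    config_error(sprintf(
      "group sizes (%s) below min_replicates = %d",
      paste(as.integer(sizes), collapse = ", "), min_replicates))
  }
  per_sample <- counts |>
    dplyr::group_by(.data$hit_id, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::left_join(samples[c("sample_id", "group")], by = "sample_id")
  tallies <- per_sample |>
    dplyr::group_by(.data$hit_id) |>
    dplyr::summarise(
      n_pass_group1 = sum(.data$count >= min_count & .data$group == gv$levels[1]),
      n_pass_group2 = sum(.data$count >= min_count & .data$group == gv$levels[2]),
      .groups = "drop"
    )
  tallies$retained <- if (scope == "either_group") {
    tallies$n_pass_group1 >= min_replicates | tallies$n_pass_group2 >= min_replicates
  } else {
    (tallies$n_pass_group1 + tallies$n_pass_group2) >= min_replicates
  }
  list(retained = tallies$hit_id[tallies$retained], log = tallies)
}

#' Target-decoy false discovery rate of an accepted hit set
#'
#' Estimates the identification FDR as accepted decoys over accepted
#' targets (capped at 1): under the target-decoy assumption each accepted
#' decoy stands for one expected false target identification.
#'
#' @param hits tibble `hit_id`, `is_decoy`.
#' @param accepted character vector of accepted hit ids (non-empty).
#' @return single number in `[0, 1]`.
#' @export
decoy_fdr <- function(hits, accepted) {
  stopifnot_cols(hits, c("hit_id", "is_decoy"), "hits")
  if (!length(accepted)) {
    abort("accepted hit set is empty", class = "castebias_argument_error")
  }
  acc <- hits[hits$hit_id %in% accepted, ]
  n_decoy <- sum(acc$is_decoy)
  n_target <- sum(!acc$is_decoy)
  min(1, n_decoy / max(1, n_target))
}

#' Differential abundance of normalized spectral counts
#'
#' Runs the shared per-hit Mann-Whitney U test on normalized abundances,
#' computes the peptide family's own resampling-corrected cutoff, and flags
#' significant hits. Hits mapping to the same protein are reported
#' individually with their `protein_group` carried along (redundancy is
#' reported, not collapsed).
#'
#' @param normalized tibble `feature_id`, `sample_id`, `value` from
#'   [normalize_in_gel()] or [normalize_in_liquid()], already restricted to
#'   presence-filtered target hits.
#' @param samples tibble `sample_id`, `group` (>= 3 per group).
#' @param protein_groups optional tibble `hit_id`, `protein_group`.
#' @param alpha,n_iterations,method,seed passed to [corrected_cutoff()].
#' @return list with `results` (flagged [run_feature_tests()] tibble) and
#'   `correction` (the [corrected_cutoff()] object). Empty input returns
#'   empty results with a warning.
#' @export
test_spectral_abundance <- function(normalized, samples, protein_groups = NULL,
                                    alpha = 0.05, n_iterations = 1000,
                                    method = "label_permutation", seed = NULL) {
  stopifnot_cols(normalized, c("feature_id", "sample_id", "value"))
  if (!nrow(normalized)) {
    warn("no hits survive filtering; returning empty results")
    return(list(results = tibble::tibble(), correction = NULL))
  }
  gv <- group_vector(samples, unique(samples$sample_id))
  if (any(table(gv$g) < 3)) {
    abort("need >= 3 samples per group", class = "castebias_argument_error")
  }
  data <- dplyr::left_join(normalized, samples[c("sample_id", "group")],
                           by = "sample_id")
  results <- run_feature_tests(data)
  correction <- corrected_cutoff(data, test = "mwu", alpha = alpha,
                                 n_iterations = n_iterations,
                                 method = method, seed = seed)
  results <- apply_cutoff(results, correction, which_p = "mwu")
  if (!is.null(protein_groups)) {
    stopifnot_cols(protein_groups, c("hit_id", "protein_group"), "protein_groups")
    results <- dplyr::left_join(
      results,
      dplyr::distinct(protein_groups, .data$hit_id, .data$protein_group),
      by = c(feature_id = "hit_id")
    )
  }
  list(results = results, correction = correction)
}
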