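#' Simulate a label-free spectral-count proteomics study
#'
#' Generates a two-group (5 vs 5 by default) spectral-count table under a
#' Poisson model: the expected count of hit h in sample s (and band b for
#' in-gel data) is `base_intensity[h] * band_weight[h, b] * lane_loading[s]
#' * fold` where the fold applies only to differentially abundant hits in
#' group 2. A spike-in standard (one count per sample and band, emulating a
#' beta-lactoglobulin internal standard) is Poisson with mean
#' `spike_in_mean * lane_loading[s]`, so spike-in normalization cancels the
#' lane-loading factor. Decoy hits are generated at low intensity and are
#' never differentially abundant.
#'
#' @param n_per_group samples per group.
#' @param n_hits number of target (non-decoy) database hits.
#' @param de_hits character ids of differentially abundant hits (up in
#'   group 2), default the first 9.
#' @param fold_change fold applied to DE hits in group 2 (scalar or per
#'   DE hit).
#' @param base_intensity expected baseline count per hit (scalar, vector,
#'   or `NULL` to draw log-uniformly between 2 and 60).
#' @param lane_loading_sd SD of the log-normal per-sample loading factor.
#' @param spike_in_mean expected spike-in count per (sample, band); > 0.
#' @param n_bands gel bands per lane (in-gel mode).
#' @param mode `"in_gel"` or `"in_liquid"`.
#' @param decoy_fraction decoy hits as a fraction of target hits.
#' @param decoy_intensity expected count of a decoy hit.
#' @param seed integer seed, or `NULL`.
#' @return object of class `spectral_study`: list of tibbles `counts`
#'   (`hit_id`, `protein_group`, `is_decoy`, `sample_id`, `band`,
#'   `count`), `spikeins` (`sample_id`, `band`, `spikein_count`),
#'   `samples` (`sample_id`, `group`, `lane_loading`) and `hits` (truth:
#'   `hit_id`, `is_decoy`, `fold_change`, `base_intensity`), plus `mode`.
#' @export
simulate_spectral_study <- function(n_per_group = 5,
                                    n_hits = 60,
                                    de_hits = sprintf("hit%02d", 1:9),
                                    fold_change = 6,
                                    base_intensity = NULL,
                                    lane_loading_sd = 0.2,
                                    spike_in_mean = 20,
                                    n_bands = 5,
                                    mode = c("in_gel", "in_liquid"),
                                    decoy_fraction = 0.1,
                                    decoy_intensity = 0.3,
                                    seed = NULL) {
  mode <- match.arg(mode)
  if (n_per_group < 2) config_error("n_per_group must be >= 2")
  if (spike_in_mean <= 0) config_error("spike_in_mean must be > 0")
  if (n_bands < 1) config_error("n_bands must be >= 1")
  if (decoy_fraction < 0 || decoy_fraction >= 1) {
    config_error("decoy_fraction must lie in [0, 1)")
  }
  hit_ids <- sprintf("hit%02d", seq_len(n_hits))
  de_hits <- as.character(de_hits)
  if (!all(de_hits %in% hit_ids)) {
    config_error("de_hits contains ids outside the generated hit set")
  }
  if (length(fold_change) == 1L) fold_change <- rep(fold_change, length(de_hits))
  if (length(fold_change) != length(de_hits) || any(fold_change <= 0)) {
    config_error("fold_change must be positive, scalar or one per DE hit")
  }
  n_decoy <- round(decoy_fraction * n_hits)
  decoy_ids <- if (n_decoy) sprintf("decoy%02d", seq_len(n_decoy)) else character(0)
  if (mode == "in_liquid") n_bands <- 1L

  with_seed(seed, {
    if (is.null(base_intensity)) {
      base_intensity <- exp(runif(n_hits, log(2), log(60)))
    } else if (length(base_intensity) == 1L) {
      base_intensity <- rep(base_intensity, n_hits)
    }
    if (length(base_intensity) != n_hits || any(base_intensity <= 0)) {
      config_error("base_intensity must be positive, scalar or one per hit")
    }
    all_ids <- c(hit_ids, decoy_ids)
    base <- c(base_intensity, rep(decoy_intensity, n_decoy))
    fold <- stats::setNames(rep(1, length(all_ids)), all_ids)
    fold[de_hits] <- fold_change
    n <- 2 * n_per_group
    sample_ids <- c(sprintf("FR%02d", seq_len(n_per_group)),
                    sprintf("WR%02d", seq_len(n_per_group)))
    group <- rep(c("FR", "WR"), each = n_per_group)
    lane <- exp(rnorm(n, 0, lane_loading_sd))
    # per-hit band profile (Dirichlet(2)); flat for one band
    bw <- matrix(stats::rgamma(length(all_ids) * n_bands, shape = 2),
                 length(all_ids), n_bands)
    bw <- bw / rowSums(bw)
    grid <- tidyr::expand_grid(hit_id = all_ids, sample_id = sample_ids,
                               band = seq_len(n_bands))
    hi <- match(grid$hit_id, all_ids)
    si <- match(grid$sample_id, sample_ids)
    lam <- base[hi] * bw[cbind(hi, grid$band)] * lane[si] *
      ifelse(group[si] == "WR", fold[grid$hit_id], 1)
    grid$count <- rpois(nrow(grid), lam)
    grid$is_decoy <- grepl("^decoy", grid$hit_id)
    grid$protein_group <- sub("^(hit|decoy)", "prot", grid$hit_id)
    spikes <- tidyr::expand_grid(sample_id = sample_ids, band = seq_len(n_bands))
    spikes$spikein_count <- rpois(nrow(spikes),
                                  spike_in_mean * lane[match(spikes$sample_id, sample_ids)])
    structure(
      list(
        counts = grid[, c("hit_id", "protein_group", "is_decoy",
                          "sample_id", "band", "count")],
        spikeins = spikes,
        samples = tibble::tibble(sample_id = sample_ids, group = group,
                                 lane_loading = lane),
        hits = tibble::tibble(hit_id = all_ids,
                              is_decoy = grepl("^decoy", all_ids),
                              fold_change = unname(fold),
                              base_intensity = base),
        mode = mode
      ),
      class = "spectral_study"
    )
  })
}

#' @export
print.spectral_study <- function(x, ...) {
  cat(sprintf("<spectral_study> %s: %d hits (%d decoys) x %d samples, %d band(s)\n",
              x$mode, nrow(x$hits), sum(x$hits$is_decoy),
              nrow(x$samples), max(x$counts$band)))
  invisible(x)
}
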