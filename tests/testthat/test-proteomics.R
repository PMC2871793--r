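test_that("in-gel normalization follows the spike-in then lane-total trace", {
  counts <- tibble::tibble(hit_id = c("a", "b"), sample_id = "s1",
                           band = 1L, count = c(10L, 30L))
  spikes <- tibble::tibble(sample_id = "s1", band = 1L, spikein_count = 5L)
  out <- normalize_in_gel(counts, spikes)
  expect_equal(out$value[out$feature_id == "a"], 0.25)
  expect_equal(out$value[out$feature_id == "b"], 0.75)

  # a lane with a single hit normalizes to 1
  one <- normalize_in_gel(
    tibble::tibble(hit_id = "a", sample_id = "s1", band = 1L, count = 7L),
    spikes)
  expect_equal(one$value, 1)

  # doubling all counts and the spike-in in one lane changes nothing
  sp <- simulate_spectral_study(n_hits = 12, de_hits = character(0),
                                decoy_fraction = 0, seed = 41)
  doubled <- sp
  s1 <- sp$samples$sample_id[1]
  doubled$counts$count <- ifelse(doubled$counts$sample_id == s1,
                                 doubled$counts$count * 2L,
                                 doubled$counts$count)
  doubled$spikeins$spikein_count <- ifelse(doubled$spikeins$sample_id == s1,
                                           doubled$spikeins$spikein_count * 2L,
                                           doubled$spikeins$spikein_count)
  expect_equal(normalize_in_gel(sp$counts, sp$spikeins),
               normalize_in_gel(doubled$counts, doubled$spikeins),
               ignore_attr = TRUE)

  # zero spike-in where hits are present is an error naming the spot
  bad_spikes <- spikes
  bad_spikes$spikein_count <- 0L
  err <- tryCatch(normalize_in_gel(counts, bad_spikes), error = identity)
  expect_s3_class(err, "castebias_normalization_error")
  expect_match(conditionMessage(err), "s1")
})

test_that("in-liquid normalization divides by the sample total", {
  counts <- tibble::tibble(hit_id = c("a", "b"), sample_id = "s1",
                           count = c(5L, 15L))
  out <- normalize_in_liquid(counts)
  expect_equal(sort(out$value), c(0.25, 0.75))
  # per-sample sums are 1 and hit order is immaterial
  sp <- simulate_spectral_study(mode = "in_liquid", seed = 42)
  nrm <- normalize_in_liquid(sp$counts)
  sums <- tapply(nrm$value, nrm$sample_id, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)))
  shuffled <- sp$counts[sample(nrow(sp$counts)), ]
  nrm2 <- normalize_in_liquid(shuffled)
  expect_equal(dplyr::arrange(nrm, feature_id, sample_id),
               dplyr::arrange(nrm2, feature_id, sample_id),
               ignore_attr = TRUE)
  expect_error(
    normalize_in_liquid(tibble::tibble(hit_id = "a", sample_id = "s1",
                                       count = 0L)),
    class = "castebias_normalization_error")
})

test_that("presence filter applies the >=3 in >=3 of 5 rule on raw counts", {
  mk <- function(g1, g2) {
    tibble::tibble(
      hit_id = "h",
      sample_id = sprintf("s%02d", 1:10),
      count = as.integer(c(g1, g2))
    )
  }
  samples <- tibble::tibble(sample_id = sprintf("s%02d", 1:10),
                            group = rep(c("FR", "WR"), each = 5))
  pass <- presence_filter(mk(c(3, 3, 3, 0, 0), c(0, 0, 0, 0, 0)), samples)
  expect_equal(pass$retained, "h")
  fail1 <- presence_filter(mk(c(3, 3, 2, 0, 0), c(3, 3, 2, 0, 0)), samples)
  expect_length(fail1$retained, 0)
  fail2 <- presence_filter(mk(c(10, 0, 0, 0, 0), c(10, 0, 0, 0, 0)), samples)
  expect_length(fail2$retained, 0)
  # pooled scope counts across all samples
  pooled <- presence_filter(mk(c(3, 3, 0, 0, 0), c(3, 0, 0, 0, 0)), samples,
                            scope = "pooled")
  expect_equal(pooled$retained, "h")
  # monotone: increasing a count never removes a retained hit
  base <- mk(c(3, 3, 3, 0, 0), c(0, 0, 0, 0, 0))
  bumped <- base
  bumped$count[4] <- 5L
  expect_true("h" %in% presence_filter(bumped, samples)$retained)
  expect_error(presence_filter(base, samples[c(1:2, 6:7), ]),
               class = "castebias_config_error")
})

test_that("either-group scope retains a superset of the per-group-conjunctive rule", {
  set.seed(43)
  samples <- tibble::tibble(sample_id = sprintf("s%02d", 1:10),
                            group = rep(c("FR", "WR"), each = 5))
  counts <- tidyr::expand_grid(hit_id = sprintf("h%02d", 1:40),
                               sample_id = samples$sample_id)
  counts$count <- rpois(nrow(counts), 3)
  either <- presence_filter(counts, samples, scope = "either_group")$retained
  log <- presence_filter(counts, samples)$log
  conj <- log$hit_id[log$n_pass_group1 >= 3 & log$n_pass_group2 >= 3]
  expect_true(all(conj %in% either))
})

test_that("decoy FDR arithmetic", {
  hits <- tibble::tibble(
    hit_id = c(sprintf("t%03d", 1:100), sprintf("d%03d", 1:10)),
    is_decoy = rep(c(FALSE, TRUE), c(100, 10))
  )
  expect_equal(decoy_fdr(hits, c(sprintf("t%03d", 1:100), "d001")), 0.01)
  expect_equal(decoy_fdr(hits, sprintf("t%03d", 1:50)), 0)
  expect_equal(decoy_fdr(hits, c("t001", sprintf("d%03d", 1:5))), 1)
  expect_error(decoy_fdr(hits, character(0)),
               class = "castebias_argument_error")
})

test_that("decoy FDR decreases as the acceptance threshold tightens", {
  set.seed(44)
  score <- c(rnorm(200, 2), rnorm(100, 0))   # targets score higher
  hits <- tibble::tibble(hit_id = sprintf("h%03d", 1:300),
                         is_decoy = rep(c(FALSE, TRUE), c(200, 100)))
  fdrs <- sapply(c(0, 1, 2, 3), function(thr) {
    acc <- hits$hit_id[score >= thr]
    decoy_fdr(hits, acc)
  })
  expect_true(all(diff(fdrs) <= 1e-9))
})

test_that("an eight-fold enriched hit is flagged as up in group 2", {
  sp <- simulate_spectral_study(n_hits = 25, de_hits = "hit01",
                                fold_change = 8, decoy_fraction = 0,
                                mode = "in_liquid", seed = 45)
  nrm <- normalize_in_liquid(sp$counts)
  da <- test_spectral_abundance(nrm, sp$samples, n_iterations = 500, seed = 46)
  r <- da$results[da$results$feature_id == "hit01", ]
  expect_true(r$significant)
  expect_equal(r$direction, "up_in_group2")
})

test_that("the study fixture recovers all nine enriched hits without spurious up-calls", {
  # power regime: baseline expected count 15 per hit, so a 6-fold shift
  # separates the 5v5 groups completely; lower-abundance hits (counts of a
  # few) would not reach the minimum attainable exact p at this design
  for (s in 1:2) {
    sp <- simulate_spectral_study(base_intensity = 15, seed = 600 + s)
    targets <- sp$counts[!sp$counts$is_decoy, ]
    filt <- presence_filter(targets, sp$samples)
    nrm <- normalize_in_gel(targets[targets$hit_id %in% filt$retained, ],
                            sp$spikeins)
    da <- test_spectral_abundance(nrm, sp$samples, n_iterations = 500,
                                  seed = 700 + s)
    res <- da$results
    truth_de <- sp$hits$hit_id[sp$hits$fold_change > 1]
    expect_true(all(truth_de %in% res$feature_id[res$significant]))
    expect_true(all(res$direction[res$feature_id %in% truth_de] == "up_in_group2"))
    # flagged nulls, if any, carry the compositional (down) signature
    flagged_null <- res$feature_id[res$significant &
                                     !res$feature_id %in% truth_de]
    expect_true(all(res$direction[res$feature_id %in% flagged_null] ==
                      "down_in_group2"))
  }
})

test_that("empty post-filter input warns and returns empty results", {
  expect_warning(
    out <- test_spectral_abundance(
      tibble::tibble(feature_id = character(), sample_id = character(),
                     value = numeric()),
      tibble::tibble(sample_id = sprintf("s%d", 1:10),
                     group = rep(c("FR", "WR"), each = 5))),
    "empty")
  expect_equal(nrow(out$results), 0)
})
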