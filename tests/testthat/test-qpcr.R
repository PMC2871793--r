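test_that("standard curve recovers exact and noisy dilution series", {
  # perfect doubling line
  pts <- tibble::tibble(log10_quantity = 0:4, cq = 35 - 3.3219 * (0:4))
  sc <- fit_standard_curve(pts)
  expect_equal(sc$slope, -3.3219, tolerance = 1e-10)
  expect_equal(sc$intercept, 35, tolerance = 1e-10)
  expect_equal(sc$efficiency, 1, tolerance = 1e-4)
  expect_equal(sc$r_squared, 1)

  # two points -> interpolating line
  two <- tibble::tibble(log10_quantity = c(1, 3), cq = c(30, 24))
  sc2 <- fit_standard_curve(two)
  expect_equal(sc2$slope, -3)
  expect_equal(sc2$intercept, 33)
  expect_equal(sc2$r_squared, 1)

  # noisy series vs closed-form normal equations
  set.seed(4)
  x <- c(0, 1, 2, 3, 4)
  y <- 34 - 3.4 * x + rnorm(5, 0, 0.3)
  sc3 <- fit_standard_curve(tibble::tibble(log10_quantity = x, cq = y))
  sxx <- sum((x - mean(x))^2)
  slope_o <- sum((x - mean(x)) * (y - mean(y))) / sxx
  expect_equal(sc3$slope, slope_o, tolerance = 1e-12)
  expect_equal(sc3$intercept, mean(y) - slope_o * mean(x), tolerance = 1e-12)

  expect_error(fit_standard_curve(tibble::tibble(log10_quantity = c(2, 2),
                                                 cq = c(30, 31))),
               class = "castebias_degenerate_curve_error")
})

test_that("absolute quantity inverts the curve and is monotone", {
  sc <- fit_standard_curve(
    tibble::tibble(log10_quantity = 0:4, cq = 35 - 3.3219 * (0:4)))
  expect_equal(absolute_quantity(sc, sc$intercept), 1)
  expect_equal(absolute_quantity(sc, sc$intercept + sc$slope), 10)
  # round trip through its own fitted points (noiseless)
  expect_equal(absolute_quantity(sc, 35 - 3.3219 * (0:4)), 10^(0:4),
               tolerance = 1e-9)
  q <- absolute_quantity(sc, c(20, 25))
  expect_gt(q[1], q[2])
})

test_that("technical replicates aggregate to the mean with CV flagging", {
  q <- tibble::tibble(
    gene_id = c(rep("a", 3), rep("b", 1), rep("c", 3), rep("d", 3)),
    sample_id = "s1",
    replicate = c(1:3, 1, 1:3, 1:3),
    quantity = c(2, 4, 6, 5, 1, 1, 10, NA, NA, NA)
  )
  out <- aggregate_technical_replicates(q, cv_warn = 0.5)
  expect_equal(out$quantity[out$gene_id == "a"], 4)
  expect_equal(out$quantity[out$gene_id == "b"], 5)
  expect_false(out$flagged[out$gene_id == "b"])
  # {1, 1, 10}: CV = sd/mean = 5.196/4 ~ 1.30 > 0.5
  expect_true(out$flagged[out$gene_id == "c"])
  expect_equal(out$cv[out$gene_id == "c"], sd(c(1, 1, 10)) / 4)
  # all replicates missing propagates as NA, not an error
  expect_true(is.na(out$quantity[out$gene_id == "d"]))
})

test_that("correlated-feature merging averages per sample and flags low r", {
  d <- tibble::tibble(
    gene_id = rep(c("a", "b"), each = 4),
    sample_id = rep(sprintf("s%d", 1:4), 2),
    quantity = c(1, 2, 3, 4, 2, 4, 6, 8)
  )
  m <- merge_correlated_features(d, c("a", "b"), merged_id = "ab")
  expect_equal(m$log$r, 1)
  expect_false(m$log$flagged)
  expect_equal(sort(m$data$quantity), sort(1.5 * c(1, 2, 3, 4)))
  # identical vectors -> merged equals the vector
  d2 <- d; d2$quantity[5:8] <- d2$quantity[1:4]
  m2 <- merge_correlated_features(d2, c("a", "b"))
  expect_equal(sort(m2$data$quantity), c(1, 2, 3, 4))
  # merging is commutative in pair order
  m_ab <- merge_correlated_features(d, c("a", "b"), merged_id = "m")
  m_ba <- merge_correlated_features(d, c("b", "a"), merged_id = "m")
  expect_equal(dplyr::arrange(m_ab$data, gene_id, sample_id),
               dplyr::arrange(m_ba$data, gene_id, sample_id))
  # weak correlation merges but flags
  d3 <- tibble::tibble(gene_id = rep(c("a", "b"), each = 4),
                       sample_id = rep(sprintf("s%d", 1:4), 2),
                       quantity = c(1, 2, 3, 4, 4, 1, 3, 2))
  expect_true(merge_correlated_features(d3, c("a", "b"))$log$flagged)
  expect_error(merge_correlated_features(d[c(1, 2, 5, 6), ], c("a", "b")),
               class = "castebias_insufficient_data_error")
})

test_that("control normalization zeroes the control and cancels sample scaling", {
  d <- tibble::tibble(
    gene_id = rep(c("g1", "RSP8"), each = 2),
    sample_id = rep(c("s1", "s2"), 2),
    quantity = c(10, 20, 2, 4)
  )
  out <- normalize_to_control(d)
  expect_equal(out$value[out$feature_id == "g1"], c(log2(5), log2(5)))
  expect_equal(out$value[out$feature_id == "RSP8"], c(0, 0))
  # scaling one sample's column leaves output unchanged
  d7 <- d; d7$quantity[d7$sample_id == "s2"] <- d7$quantity[d7$sample_id == "s2"] * 7
  expect_equal(normalize_to_control(d7), out)
  # errors: non-positive quantity names gene and sample; missing control fatal
  dneg <- d; dneg$quantity[1] <- -1
  err <- tryCatch(normalize_to_control(dneg), error = identity)
  expect_s3_class(err, "castebias_domain_error")
  expect_match(conditionMessage(err), "g1")
  expect_match(conditionMessage(err), "s1")
  dmiss <- d[d$gene_id != "RSP8", ]
  expect_error(normalize_to_control(dmiss), class = "castebias_fatal_error")
})

test_that("group-median imputation fills gaps and preserves group medians", {
  d <- tibble::tibble(
    feature_id = "g1",
    sample_id = sprintf("s%d", 1:8),
    group = rep(c("FR", "WR"), each = 4),
    value = c(1, 2, NA, 4, 3, 9, NA, NA)
  )
  out <- impute_group_median(d)
  expect_equal(out$value[3], 2)
  expect_equal(out$value[7:8], c(6, 6))
  expect_equal(median(out$value[out$group == "FR"]), 2)
  # no missing -> identity
  expect_equal(impute_group_median(out), out)
  # unimputable: one group entirely missing
  dbad <- d; dbad$value[1:4] <- NA
  expect_error(impute_group_median(dbad),
               class = "castebias_unimputable_error")
})

test_that("normalization removes simulated sample scale factors exactly", {
  study <- simulate_expression_study(
    n_genes = 6, de_genes = "g01", correlation_blocks = list(),
    missing_rate = 0, sample_scale_sd = 0.8, seed = 77)
  # divide the per-sample scale factor back out of the raw quantities:
  # control normalization must make the two versions indistinguishable
  descale <- study$quantities
  sf <- stats::setNames(study$samples$scale_factor, study$samples$sample_id)
  descale$quantity <- descale$quantity / sf[descale$sample_id]
  n1 <- normalize_to_control(aggregate_technical_replicates(study$quantities))
  n2 <- normalize_to_control(aggregate_technical_replicates(descale))
  expect_equal(n1$value, n2$value, tolerance = 1e-12)
})
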