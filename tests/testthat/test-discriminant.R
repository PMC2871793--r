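sim_lda_data <- function(n1 = 10, n2 = 7, p = 4, delta = 0, seed = 1,
                         feature_ids = sprintf("f%02d", seq_len(p))) {
  set.seed(seed)
  m <- matrix(rnorm(p * (n1 + n2)), p, n1 + n2,
              dimnames = list(feature_ids, sprintf("s%02d", seq_len(n1 + n2))))
  m[, (n1 + 1):(n1 + n2)] <- m[, (n1 + 1):(n1 + n2)] + delta
  mat2long(m, rep(c("FR", "WR"), c(n1, n2)))
}

test_that("correlation pruning: override, no-op, and greedy tie rule", {
  d <- sim_lda_data(p = 16, seed = 2,
                    feature_ids = c("Pi3K", "ILP2", "RfaBp", "eELF1a",
                                    sprintf("g%02d", 5:16)))
  pr <- prune_correlated(d, drop = c("Pi3K", "ILP2", "RfaBp", "eELF1a"))
  expect_length(pr$retained, 12)
  expect_equal(pr$log$reason, rep("drop_override", 4))
  expect_error(prune_correlated(d, drop = "absent_gene"),
               class = "castebias_argument_error")

  # independent features: nothing dropped
  pr2 <- prune_correlated(d, r_threshold = 0.9)
  expect_length(pr2$retained, 16)
  expect_equal(nrow(pr2$log), 0)

  # A ~ B at r ~ 0.95, C independent: exactly one of {A, B} dropped, and
  # the tie-break (equal partner count, equal mean r) drops the later id
  set.seed(3)
  z <- rnorm(12)
  m <- rbind(A = sqrt(.95) * z + sqrt(.05) * rnorm(12),
             B = sqrt(.95) * z + sqrt(.05) * rnorm(12),
             C = rnorm(12))
  d3 <- mat2long(m, rep(c("FR", "WR"), c(6, 6)))
  pr3 <- prune_correlated(d3, r_threshold = 0.9)
  expect_setequal(pr3$retained, c("A", "C"))
  expect_equal(pr3$log$dropped, "B")
  expect_equal(pr3$log$partner, "A")
})

test_that("greedy pruning terminates and never drops both members of an isolated pair", {
  for (s in 1:5) {
    set.seed(400 + s)
    n <- 14
    z1 <- rnorm(n); z2 <- rnorm(n)
    m <- rbind(a1 = z1 + 0.1 * rnorm(n), a2 = z1 + 0.1 * rnorm(n),
               b1 = z2 + 0.1 * rnorm(n), b2 = z2 + 0.1 * rnorm(n),
               c1 = rnorm(n))
    d <- mat2long(m, rep(c("FR", "WR"), c(7, 7)))
    pr <- prune_correlated(d, r_threshold = 0.9)
    expect_true(any(c("a1", "a2") %in% pr$retained))
    expect_true(any(c("b1", "b2") %in% pr$retained))
    expect_true("c1" %in% pr$retained)
  }
})

test_that("one-dimensional LDA matches the hand computation", {
  d <- tibble::tibble(
    feature_id = "f1",
    sample_id = sprintf("s%d", 1:4),
    group = c("a", "a", "b", "b"),
    value = c(0, 1, 10, 11)
  )
  fit <- fit_lda(d, priors = "equal")
  # pooled var = 0.5, weight = (10.5 - 0.5) / 0.5 = 20, midpoint 5.5
  expect_equal(unname(fit$weights), 20)
  expect_equal(fit$intercept, -20 * 5.5)
  pred <- predict(fit, tibble::tibble(feature_id = "f1", sample_id = "new",
                                      value = 5))
  expect_equal(pred$predicted_group, "a")
  pred2 <- predict(fit, tibble::tibble(feature_id = "f1", sample_id = "new",
                                       value = 6))
  expect_equal(pred2$predicted_group, "b")
})

test_that("identical class means give zero weights and prior-driven classification", {
  d <- tibble::tibble(
    feature_id = rep("f1", 6),
    sample_id = sprintf("s%d", 1:6),
    group = rep(c("a", "b"), each = 3),
    value = c(1, 2, 3, 1, 2, 3)
  )
  fit <- fit_lda(d, priors = c(0.9, 0.1))
  expect_equal(unname(fit$weights), 0)
  expect_true(all(fit$scores$predicted_group == "a"))
})

test_that("LDA weights match an established reference implementation", {
  skip_if_not_installed("MASS")
  for (s in 1:10) {
    d <- sim_lda_data(p = 5, delta = 1, seed = 500 + s)
    fit <- fit_lda(d)
    m <- t(matrix(d$value, 5, 17,
                  dimnames = list(unique(d$feature_id), unique(d$sample_id))))
    ref <- MASS::lda(m, grouping = rep(c("FR", "WR"), c(10, 7)))
    w1 <- fit$weights / sqrt(sum(fit$weights^2))
    w2 <- ref$scaling[, 1] / sqrt(sum(ref$scaling[, 1]^2))
    if (sum(w1 * w2) < 0) w2 <- -w2
    expect_equal(unname(w1), unname(w2), tolerance = 1e-8)
  }
})

test_that("singularity fails loudly and ridge rescues it", {
  d <- sim_lda_data(p = 16, seed = 20)   # 16 features, 17 samples
  expect_error(fit_lda(d), class = "castebias_singularity_error")
  fit <- fit_lda(d, ridge_lambda = 1)
  expect_true(all(is.finite(fit$weights)))
})

test_that("predictions are invariant to common positive scaling and feature order", {
  d <- sim_lda_data(p = 4, delta = 1.5, seed = 21)
  fit <- fit_lda(d)
  d_scaled <- d
  d_scaled$value <- d$value * 10
  fit_s <- fit_lda(d_scaled)
  expect_equal(fit$scores$predicted_group, fit_s$scores$predicted_group)
  expect_equal(fit$scores$ld_score, fit_s$scores$ld_score, tolerance = 1e-9)
  d_perm <- dplyr::arrange(d, dplyr::desc(feature_id), sample_id)
  fit_p <- fit_lda(d_perm)
  expect_equal(fit$scores$ld_score[order(fit$scores$sample_id)],
               fit_p$scores$ld_score[order(fit_p$scores$sample_id)],
               tolerance = 1e-9)
})

test_that("large ridge shrinks weights toward the mean-difference direction", {
  d <- sim_lda_data(p = 4, delta = 1, seed = 22)
  m <- as.matrix(tidyr::pivot_wider(d, id_cols = "feature_id",
                                    names_from = "sample_id",
                                    values_from = "value")[, -1])
  dmu <- rowMeans(m[, 11:17]) - rowMeans(m[, 1:10])
  fit <- fit_lda(d, ridge_lambda = 1e8)
  w <- fit$weights / sqrt(sum(fit$weights^2))
  v <- dmu / sqrt(sum(dmu^2))
  expect_equal(unname(w), unname(v), tolerance = 1e-4)
})

test_that("LOOCV separates well-separated clusters and rejects degenerate folds", {
  d <- sim_lda_data(p = 4, delta = 6, seed = 23)
  cv <- loocv_lda(d)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$n, 17)
  d2 <- sim_lda_data(n1 = 2, n2 = 2, p = 2, seed = 24)
  expect_error(loocv_lda(d2), class = "castebias_degenerate_fold_error")
})

test_that("pruning scope and fixed priors are honored in LOOCV", {
  d <- sim_lda_data(p = 6, delta = 2, seed = 25)
  cv_full <- loocv_lda(d, r_threshold = 0.9)
  cv_fold <- loocv_lda(d, r_threshold = 0.9, prune_scope = "per_fold")
  expect_s3_class(cv_full, "caste_loocv")
  expect_s3_class(cv_fold, "caste_loocv")
  cv_fixed <- loocv_lda(d, priors = c(10 / 17, 7 / 17))
  expect_equal(nrow(cv_fixed$predictions), 17)
})
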