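# Resampling-based family-wise error correction (min-p scheme): resample
# group labels under the null, recompute every per-feature p-value, record
# the per-iteration minimum, and take the empirical alpha-quantile of those
# minima as the corrected significance cutoff for the whole feature family.

# vectorized per-row two-group F p-values (rows = features)
row_anova_p <- function(mx, my) {
  n1 <- rowSums(!is.na(mx)); n2 <- rowSums(!is.na(my))
  m1 <- rowMeans(mx, na.rm = TRUE); m2 <- rowMeans(my, na.rm = TRUE)
  gm <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- rowSums((mx - m1)^2, na.rm = TRUE) + rowSums((my - m2)^2, na.rm = TRUE)
  df2 <- n1 + n2 - 2
  p <- rep(NA_real_, length(n1))
  zero <- ssw == 0
  p[zero & ssb == 0] <- 1
  p[zero & ssb > 0] <- 0
  ok <- !zero & n1 >= 2 & n2 >= 2
  p[ok] <- pf((ssb[ok] / 1) / (ssw[ok] / df2[ok]), 1, df2[ok], lower.tail = FALSE)
  p
}

# per-row MWU p at a given column split, looping features (handles NA, ties)
row_mwu_p <- function(m, idx1, mode) {
  vapply(seq_len(nrow(m)), function(f) {
    v <- m[f, ]
    x <- v[idx1]; y <- v[-idx1]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) return(NA_real_)
    mann_whitney_u(x, y, mode = mode)$p.value
  }, numeric(1))
}

#' Resampling-corrected family-wise p-value cutoff
#'
#' Computes a single corrected significance cutoff for a family of
#' per-feature two-group tests by the min-p scheme: in each iteration the
#' group labels are resampled under the null (label permutation, or a group
#' bootstrap that resamples individuals with replacement from the pooled set
#' while preserving group sizes), every per-feature p-value is recomputed
#' with the named test, and the minimum over features is recorded. The
#' cutoff is the empirical `alpha`-quantile of these null minima, so that
#' the probability any null feature falls at or below the cutoff is
#' approximately `alpha` (family-wise error control that adapts to
#' inter-feature correlation: perfectly dependent features add no
#' multiplicity).
#'
#' @param data long tibble `feature_id`, `sample_id`, `group`, `value`
#'   (normally the imputed, normalized matrix).
#' @param test `"mwu"` or `"anova"`: the per-feature test whose p-values
#'   define the family.
#' @param alpha nominal family-wise error rate.
#' @param n_iterations number of resampling iterations (default 1000; fewer
#'   than 100 triggers a warning).
#' @param method `"label_permutation"` (default) or `"group_bootstrap"`.
#' @param seed integer seed, or `NULL`.
#' @param mwu_mode passed to [mann_whitney_u()].
#' @return object of class `resampling_correction`: list with `alpha`,
#'   `n_iterations`, `method`, `test`, `scope` (`"family_minp"`), `seed`,
#'   `cutoff`, `null_minp`, `n_features`.
#' @export
corrected_cutoff <- function(data, test = c("mwu", "anova"), alpha = 0.05,
                             n_iterations = 1000,
                             method = c("label_permutation", "group_bootstrap"),
                             seed = NULL, mwu_mode = "auto") {
  test <- match.arg(test)
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) config_error("alpha must lie in (0, 1)")
  if (n_iterations < 100) {
    warn("fewer than 100 resampling iterations gives a poorly estimated cutoff")
  }
  stopifnot_cols(data, c("feature_id", "sample_id", "group", "value"))
  m <- as_feature_matrix(data)
  gv <- group_vector(data, colnames(m))
  g <- gv$g
  n1 <- sum(g == gv$levels[1]); n2 <- sum(g == gv$levels[2])
  if (n1 < 2 || n2 < 2) config_error("need >= 2 samples per group")
  # drop untestable features (one group entirely missing)
  testable <- apply(m, 1, function(v) {
    any(!is.na(v[g == gv$levels[1]])) && any(!is.na(v[g == gv$levels[2]]))
  })
  m <- m[testable, , drop = FALSE]
  if (!nrow(m)) config_error("no testable feature in the family")
  if (all(apply(m, 1, function(v) length(unique(v[!is.na(v)])) == 1))) {
    abort("degenerate data: every feature is constant",
          class = "castebias_degenerate_error")
  }
  n <- ncol(m)
  exact_ok <- !anyNA(m) && choose(n, n1) <= 50000 &&
    (mwu_mode %in% c("auto", "exact"))

  null_minp <- with_seed(seed, {
    if (test == "mwu" && method == "label_permutation" && exact_ok) {
      # fast path: the permutation distribution of U per feature is the full
      # enumeration over label assignments, computed once per feature
      cmb <- mwu_combinations(n, n1)
      k <- ncol(cmb)
      cind <- matrix(0, n, k)
      cind[cbind(as.vector(cmb), rep(seq_len(k), each = n1))] <- 1
      rm_ <- apply(m, 1, rank)                       # n x F
      u_all <- crossprod(cind, rm_) - n1 * (n1 + 1) / 2  # k x F
      mu <- n1 * n2 / 2
      absdev <- abs(u_all - mu)
      it <- sample.int(k, n_iterations, replace = TRUE)
      pit <- vapply(seq_len(ncol(absdev)), function(f) {
        sa <- sort(absdev[, f])
        (k - findInterval(absdev[it, f] - 1e-9, sa)) / k
      }, numeric(n_iterations))
      if (is.null(dim(pit))) pit <- matrix(pit, nrow = n_iterations)
      apply(pit, 1, min, na.rm = TRUE)
    } else {
      vapply(seq_len(n_iterations), function(i) {
        if (method == "label_permutation") {
          mi <- m
          idx1 <- sample.int(n, n1)
        } else {
          mi <- m[, sample.int(n, n, replace = TRUE), drop = FALSE]
          idx1 <- seq_len(n1)
        }
        p <- if (test == "anova") {
          row_anova_p(mi[, idx1, drop = FALSE], mi[, -idx1, drop = FALSE])
        } else {
          row_mwu_p(mi, idx1, mwu_mode)
        }
        min(p, na.rm = TRUE)
      }, numeric(1))
    }
  })
  cutoff <- unname(quantile(null_minp, alpha, type = 1))
  structure(
    list(alpha = alpha, n_iterations = n_iterations, method = method,
         test = test, scope = "family_minp", seed = seed,
         cutoff = cutoff, null_minp = null_minp, n_features = nrow(m)),
    class = "resampling_correction"
  )
}

#' @export
print.resampling_correction <- function(x, ...) {
  cat(sprintf(
    "<resampling_correction> %s / %s, %d features, %d iterations\n  alpha = %g -> corrected cutoff p <= %g\n",
    x$test, x$method, x$n_features, x$n_iterations, x$alpha, x$cutoff))
  invisible(x)
}

#' @export
tidy.resampling_correction <- function(x, ...) {
  tibble::tibble(null_minp = x$null_minp)
}

#' @export
glance.resampling_correction <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, cutoff = x$cutoff, test = x$test,
                 method = x$method, n_iterations = x$n_iterations,
                 n_features = x$n_features)
}

#' Flag significant features at a resampling-corrected cutoff
#'
#' Adds a `significant` flag to a [run_feature_tests()] result. With
#' `which_p = "both"` a feature must pass the corrected cutoff of both the
#' Mann-Whitney and ANOVA families (the concordance criterion); a boundary
#' p equal to the cutoff counts as significant.
#'
#' @param results tibble from [run_feature_tests()].
#' @param correction a [corrected_cutoff()] object (for the MWU family
#'   unless `which_p = "anova"`).
#' @param which_p `"mwu"`, `"anova"` or `"both"`.
#' @param anova_correction optional second correction for the ANOVA family
#'   when `which_p = "both"`; defaults to `correction`.
#' @return `results` with columns `significant`, `cutoff_mwu` and/or
#'   `cutoff_anova`.
#' @export
apply_cutoff <- function(results, correction,
                         which_p = c("mwu", "anova", "both"),
                         anova_correction = NULL) {
  which_p <- match.arg(which_p)
  stopifnot(inherits(correction, "resampling_correction"))
  if (which_p == "mwu") {
    results$cutoff_mwu <- correction$cutoff
    results$significant <- results$p_mwu <= correction$cutoff
  } else if (which_p == "anova") {
    results$cutoff_anova <- correction$cutoff
    results$significant <- !is.na(results$p_anova) &
      results$p_anova <= correction$cutoff
  } else {
    ca <- if (is.null(anova_correction)) correction else anova_correction
    stopifnot(inherits(ca, "resampling_correction"))
    results$cutoff_mwu <- correction$cutoff
    results$cutoff_anova <- ca$cutoff
    results$significant <- results$p_mwu <= correction$cutoff &
      !is.na(results$p_anova) & results$p_anova <= ca$cutoff
  }
  results
}
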