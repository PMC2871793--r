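#' One-way two-group ANOVA F test
#'
#' Fixed-effects one-way analysis of variance for two groups, computed from
#' the between/within sums of squares; equals the squared equal-variance
#' two-sample t statistic with df (1, n1 + n2 - 2).
#'
#' @param x,y numeric vectors, each with >= 2 non-missing values.
#' @return one-row tibble: `statistic` (F), `df1`, `df2`, `p.value`,
#'   `infinite` (TRUE when within-group variance is zero but means differ).
#' @export
one_way_f_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("both groups need >= 2 non-missing values",
          class = "castebias_argument_error")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  gm <- mean(c(x, y))
  ssb <- n1 * (mean(x) - gm)^2 + n2 * (mean(y) - gm)^2
  ssw <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  df1 <- 1L; df2 <- n - 2L
  if (ssw == 0) {
    if (ssb == 0) {
      return(tibble::tibble(statistic = 0, df1 = df1, df2 = df2,
                            p.value = 1, infinite = FALSE))
    }
    return(tibble::tibble(statistic = Inf, df1 = df1, df2 = df2,
                          p.value = 0, infinite = TRUE))
  }
  f <- (ssb / df1) / (ssw / df2)
  tibble::tibble(statistic = f, df1 = df1, df2 = df2,
                 p.value = pf(f, df1, df2, lower.tail = FALSE),
                 infinite = FALSE)
}

#' Pearson product-moment correlation
#'
#' Standard product-moment r with the t-based two-sided p-value
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 df.
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return one-row tibble: `estimate` (r), `statistic` (t), `df`, `p.value`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "castebias_argument_error")
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need >= 3 complete pairs", class = "castebias_argument_error")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant vector",
          class = "castebias_undefined_correlation_error")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    return(tibble::tibble(estimate = r, statistic = Inf * sign(r),
                          df = n - 2L, p.value = 0))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  tibble::tibble(estimate = r, statistic = t, df = n - 2L,
                 p.value = 2 * pt(-abs(t), n - 2))
}

#' Run per-feature two-group tests
#'
#' For every feature, computes the Mann-Whitney U test (on `data`, normally
#' the imputed matrix) and the one-way ANOVA F test (on `unimputed` when
#' supplied, with missing cells dropped -- matching a workflow where
#' imputation precedes the rank test only). Direction is the sign of
#' (group-2 median - group-1 median); group 2 is the second group level in
#' sorted order (e.g. `WR` for `FR`/`WR`).
#'
#' Features with an entire group missing are untestable: they are excluded
#' from the result and recorded in the `untestable` attribute.
#'
#' @param data long tibble `feature_id`, `sample_id`, `group`, `value`.
#' @param unimputed optional long tibble of the same shape for the ANOVA arm.
#' @param mwu_mode passed to [mann_whitney_u()].
#' @return tibble with one row per testable feature: `feature_id`, `n1`,
#'   `n2`, `u_statistic`, `p_mwu`, `f_statistic`, `df1`, `df2`, `p_anova`,
#'   `direction`; attribute `untestable` is a tibble (`feature_id`,
#'   `reason`).
#' @export
run_feature_tests <- function(data, unimputed = NULL, mwu_mode = "auto") {
  stopifnot_cols(data, c("feature_id", "sample_id", "group", "value"))
  gv <- group_vector(data, unique(data$sample_id))
  lev <- gv$levels
  anova_data <- if (is.null(unimputed)) data else unimputed
  feats <- unique(data$feature_id)
  untestable <- list()
  rows <- list()
  for (f in feats) {
    d <- data[data$feature_id == f, ]
    g <- group_vector(data, d$sample_id)$g
    x <- d$value[g == lev[1]]
    y <- d$value[g == lev[2]]
    if (all(is.na(x)) || all(is.na(y))) {
      untestable[[f]] <- tibble::tibble(
        feature_id = f, reason = "all values missing in one group")
      next
    }
    mwu <- mann_whitney_u(x, y, mode = mwu_mode)
    da <- anova_data[anova_data$feature_id == f, ]
    ga <- group_vector(anova_data, da$sample_id)$g
    xa <- da$value[ga == lev[1]]; xa <- xa[!is.na(xa)]
    ya <- da$value[ga == lev[2]]; ya <- ya[!is.na(ya)]
    ft <- if (length(xa) >= 2 && length(ya) >= 2) {
      one_way_f_test(xa, ya)
    } else {
      tibble::tibble(statistic = NA_real_, df1 = NA_integer_,
                     df2 = NA_integer_, p.value = NA_real_, infinite = FALSE)
    }
    dmed <- median(y, na.rm = TRUE) - median(x, na.rm = TRUE)
    rows[[f]] <- tibble::tibble(
      feature_id = f, n1 = mwu$n1, n2 = mwu$n2,
      u_statistic = mwu$statistic, p_mwu = mwu$p.value,
      f_statistic = ft$statistic, df1 = ft$df1, df2 = ft$df2,
      p_anova = ft$p.value,
      direction = if (dmed > 0) "up_in_group2"
                  else if (dmed < 0) "down_in_group2" else "tied"
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "untestable") <- if (length(untestable)) {
    dplyr::bind_rows(untestable)
  } else {
    tibble::tibble(feature_id = character(), reason = character())
  }
  attr(out, "group_levels") <- lev
  out
}
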