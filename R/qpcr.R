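#' Fit a qPCR standard curve
#'
#' Ordinary least-squares line of quantification cycle (Cq) on log10 input
#' quantity, as obtained from a genomic DNA dilution series. The slope gives
#' the amplification efficiency `10^(-1/slope) - 1` (1.0 = perfect doubling).
#'
#' @param points data frame with columns `log10_quantity` and `cq`.
#' @return An object of class `standard_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `n`.
#' @examples
#' pts <- data.frame(log10_quantity = 0:4, cq = 35 - 3.3219 * (0:4))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points) {
  stopifnot_cols(points, c("log10_quantity", "cq"), "standard-curve points")
  points <- points[stats::complete.cases(points[c("log10_quantity", "cq")]), ]
  if (nrow(points) < 2 || length(unique(points$log10_quantity)) < 2) {
    abort("standard curve needs >= 2 points at >= 2 distinct quantities",
          class = "castebias_degenerate_curve_error")
  }
  fit <- stats::lm(cq ~ log10_quantity, data = points)
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0) {
    abort("fitted slope is zero; curve is degenerate",
          class = "castebias_degenerate_curve_error")
  }
  r2 <- if (nrow(points) == 2) 1 else suppressWarnings(summary(fit)$r.squared)
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, efficiency = 10^(-1 / slope) - 1, n = nrow(points)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> Cq = %.4f %+.4f * log10(q)  (R2 = %.4f, efficiency = %.3f)\n",
              x$intercept, x$slope, x$r_squared, x$efficiency))
  invisible(x)
}

#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, efficiency = x$efficiency, nobs = x$n)
}

#' Convert Cq values to absolute quantities via a standard curve
#'
#' @param curve a [fit_standard_curve()] object.
#' @param cq numeric vector of quantification cycles.
#' @return positive quantities, `10^((cq - intercept)/slope)`.
#' @export
absolute_quantity <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Aggregate technical qPCR replicates
#'
#' Collapses the 1-3 technical replicates of each (gene, sample) cell to
#' their arithmetic mean, flagging cells whose replicate coefficient of
#' variation exceeds `cv_warn`. Cells with all replicates missing propagate
#' as `NA` (missing, not zero).
#'
#' @param quantities long tibble with `gene_id`, `sample_id`, `replicate`,
#'   `quantity` (e.g. `simulate_expression_study()$quantities`).
#' @param cv_warn CV threshold above which a cell is flagged.
#' @return tibble `gene_id`, `sample_id`, `quantity`, `cv`, `flagged`.
#' @export
aggregate_technical_replicates <- function(quantities, cv_warn = 0.3) {
  stopifnot_cols(quantities, c("gene_id", "sample_id", "quantity"), "quantities")
  quantities |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::summarise(
      cv = if (sum(!is.na(.data$quantity)) >= 2) {
        sd(.data$quantity, na.rm = TRUE) / mean(.data$quantity, na.rm = TRUE)
      } else NA_real_,
      quantity = if (all(is.na(.data$quantity))) NA_real_ else {
        mean(.data$quantity, na.rm = TRUE)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = !is.na(.data$cv) & .data$cv > cv_warn) |>
    dplyr::select("gene_id", "sample_id", "quantity", "cv", "flagged")
}

#' Merge a pair of correlated features by per-sample averaging
#'
#' Used both for duplicate qPCR runs of the same gene and for distinct
#' contigs found to represent one gene: the pair's values are averaged per
#' sample into a single feature. The pair's Pearson correlation is recorded;
#' if it falls below `min_r` the merge still proceeds but is flagged as
#' low-correlation (the check is advisory, since merging is justified by
#' identity of the underlying gene, not by the observed r).
#'
#' @param data long tibble `gene_id`, `sample_id`, `quantity`.
#' @param pair character vector of the two gene ids to merge.
#' @param merged_id id of the merged feature (default: first of the pair).
#' @param min_r advisory correlation threshold.
#' @return list with `data` (tibble, pair replaced by the merged feature)
#'   and `log` (one-row tibble: `gene_a`, `gene_b`, `merged_id`, `r`,
#'   `n_complete`, `flagged`).
#' @export
merge_correlated_features <- function(data, pair, merged_id = pair[[1]],
                                      min_r = 0.9) {
  stopifnot_cols(data, c("gene_id", "sample_id", "quantity"))
  pair <- as.character(pair)
  if (length(pair) != 2 || !all(pair %in% data$gene_id)) {
    abort("`pair` must name two features present in the data",
          class = "castebias_argument_error")
  }
  wide <- data |>
    dplyr::filter(.data$gene_id %in% pair) |>
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "gene_id",
                       values_from = "quantity")
  a <- wide[[pair[1]]]
  b <- wide[[pair[2]]]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) {
    abort("fewer than 3 samples with both features observed",
          class = "castebias_insufficient_data_error")
  }
  r <- pearson_r(a[ok], b[ok])$estimate
  merged <- tibble::tibble(
    gene_id = merged_id,
    sample_id = wide$sample_id,
    quantity = rowMeans(cbind(a, b), na.rm = FALSE)
  )
  out <- data |>
    dplyr::filter(!.data$gene_id %in% pair) |>
    dplyr::bind_rows(merged)
  list(
    data = out,
    log = tibble::tibble(gene_a = pair[1], gene_b = pair[2],
                         merged_id = merged_id, r = r,
                         n_complete = sum(ok), flagged = r < min_r)
  )
}

#' Normalize absolute quantities to the endogenous control gene
#'
#' Divides every gene's quantity by the control gene's quantity in the same
#' sample, then log-transforms (ratio-then-log, the standard relative
#' quantification convention). The control row becomes exactly zero and any
#' per-sample multiplicative scale factor cancels exactly.
#'
#' @param data long tibble `gene_id`, `sample_id`, `quantity` (aggregated
#'   quantities; missing cells `NA`).
#' @param control_gene id of the control gene; must be observed in every
#'   sample.
#' @param log_base 2 (default), 10, or `exp(1)`.
#' @return tibble `gene_id` (renamed `feature_id`), `sample_id`, `value` on
#'   the log scale; `NA` quantities stay `NA`.
#' @export
normalize_to_control <- function(data, control_gene = "RSP8", log_base = 2) {
  stopifnot_cols(data, c("gene_id", "sample_id", "quantity"))
  if (!log_base %in% c(2, 10) && abs(log_base - exp(1)) > 1e-12) {
    config_error("log_base must be 2, 10 or e")
  }
  ctrl <- data[data$gene_id == control_gene, ]
  samples <- unique(data$sample_id)
  if (nrow(ctrl) == 0 || !all(samples %in% ctrl$sample_id) || anyNA(ctrl$quantity)) {
    abort(sprintf("control gene '%s' must be observed in every sample", control_gene),
          class = "castebias_fatal_error")
  }
  bad <- which(!is.na(data$quantity) & data$quantity <= 0)
  if (length(bad)) {
    abort(sprintf("non-positive quantity for gene '%s' in sample '%s'",
                  data$gene_id[bad[1]], data$sample_id[bad[1]]),
          class = "castebias_domain_error")
  }
  ctrl_q <- stats::setNames(ctrl$quantity, ctrl$sample_id)
  tibble::tibble(
    feature_id = data$gene_id,
    sample_id = data$sample_id,
    value = unname(log(data$quantity / ctrl_q[data$sample_id], base = log_base))
  )
}

#' Impute missing values with the within-group median
#'
#' Replaces each missing cell by the median of the observed values of the
#' same feature within the same sample group. Observed cells are untouched.
#'
#' @param data long tibble `feature_id`, `sample_id`, `group`, `value`.
#' @return same tibble with `NA` values imputed.
#' @export
impute_group_median <- function(data) {
  stopifnot_cols(data, c("feature_id", "sample_id", "group", "value"))
  out <- data |>
    dplyr::group_by(.data$feature_id, .data$group) |>
    dplyr::mutate(
      value = ifelse(is.na(.data$value),
                     median(.data$value, na.rm = TRUE), .data$value)
    ) |>
    dplyr::ungroup()
  if (anyNA(out$value)) {
    bad <- out[is.na(out$value), ]
    abort(sprintf("feature '%s' has no observed value in group '%s'; cannot impute",
                  bad$feature_id[1], bad$group[1]),
          class = "castebias_unimputable_error")
  }
  out
}
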