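# Independent oracles and small fixture builders shared across tests.

# Brute-force Mann-Whitney oracle: U by direct pairwise counting, two-sided
# p by enumerating every label assignment of the pooled data. Deliberately
# uses a different computational route (outer() pair counts) than the
# package's rank-sum enumeration.
oracle_mwu <- function(x, y) {
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n1 <- length(x)
  n2 <- length(y)
  mu <- n1 * n2 / 2
  cmb <- utils::combn(length(pooled), n1)
  u_all <- apply(cmb, 2, function(ix) ustat(pooled[ix], pooled[-ix]))
  u_obs <- ustat(x, y)
  list(u = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# features x samples matrix -> canonical long tibble
mat2long <- function(m, groups, feature_ids = NULL, sample_ids = NULL) {
  if (is.null(feature_ids)) {
    feature_ids <- rownames(m) %||% sprintf("f%02d", seq_len(nrow(m)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(m) %||% sprintf("s%02d", seq_len(ncol(m)))
  }
  tibble::tibble(
    feature_id = rep(feature_ids, times = ncol(m)),
    sample_id = rep(sample_ids, each = nrow(m)),
    group = rep(groups, each = nrow(m)),
    value = as.vector(m)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalized, imputed gene matrix for a simulated expression study
process_study <- function(study, control_gene = "RSP8") {
  agg <- aggregate_technical_replicates(study$quantities)
  norm <- normalize_to_control(agg, control_gene = control_gene)
  norm <- dplyr::left_join(norm, study$samples[c("sample_id", "group")],
                           by = "sample_id")
  norm <- norm[norm$feature_id != control_gene, ]
  list(unimputed = norm, imputed = impute_group_median(norm))
}
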