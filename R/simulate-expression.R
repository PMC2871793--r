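#' Simulate a candidate-gene qPCR expression study
#'
#' Generates a two-group absolute-quantity qPCR study with the statistical
#' structure the downstream pipeline assumes: log-normal biological variation,
#' a multiplicative per-sample technical scale factor (removable by
#' reference-gene normalization), blocks of genes sharing a latent factor so
#' their pairwise Pearson correlation hits a target value, technical
#' triplicates with a given coefficient of variation, sparse missingness, and
#' an endogenous control gene with zero group effect.
#'
#' Defaults mirror the study design the pipeline was built around: 10
#' foundress-reared (`FR`, group 1) vs 7 worker-reared (`WR`, group 2)
#' larvae, 38 candidate genes of which 16 are up-regulated in group 2, and
#' three correlated blocks at r = 0.93 among the differentially expressed
#' genes.
#'
#' @param n_group1,n_group2 samples per group (>= 2 each).
#' @param n_genes number of analysis genes (the control gene is extra).
#' @param de_genes character vector of up-regulated gene ids (subset of the
#'   generated ids `g01`, `g02`, ...).
#' @param log2_effect log2 shift added in group 2, scalar or one value per
#'   DE gene (positive = up in group 2).
#' @param correlation_blocks list of `list(genes = <ids>, r = <target>)`;
#'   each block shares one latent factor with loading `sqrt(r)` so every
#'   within-block pair has correlation `r`. All `r` must be in `[0, 1)` and
#'   the control gene may not appear in a block.
#' @param gene_base_mean baseline mean on the log2-copies scale.
#' @param biological_sd per-gene biological SD on the log2 scale (the
#'   "within-group SD" in which effect sizes are naturally expressed).
#' @param sample_scale_sd SD (log2 scale) of the per-sample technical scale
#'   factor; applied multiplicatively to every gene including the control,
#'   hence exactly removable by control normalization.
#' @param triplicate_cv coefficient of variation of technical replicates
#'   around each true quantity (log-normal noise).
#' @param control_gene id of the endogenous control gene.
#' @param missing_rate probability a (gene, sample) cell is missing (all
#'   three replicates `NA`); never applied to the control gene.
#' @param seed integer seed for reproducibility, or `NULL`.
#'
#' @return An object of class `expression_study`: a list with tibbles
#'   `quantities` (`gene_id`, `sample_id`, `replicate`, `quantity`),
#'   `samples` (`sample_id`, `group`, `scale_factor`) and `genes`
#'   (`gene_id`, `is_control`, `log2_effect`, `block`).
#' @examples
#' study <- simulate_expression_study(seed = 1)
#' dplyr::count(study$samples, group)
#' @export
simulate_expression_study <- function(n_group1 = 10,
                                      n_group2 = 7,
                                      n_genes = 38,
                                      de_genes = sprintf("g%02d", 1:16),
                                      log2_effect = 2.5,
                                      correlation_blocks = list(
                                        list(genes = sprintf("g%02d", 1:3), r = 0.93),
                                        list(genes = sprintf("g%02d", 4:6), r = 0.93),
                                        list(genes = sprintf("g%02d", 7:8), r = 0.93)
                                      ),
                                      gene_base_mean = 10,
                                      biological_sd = 1,
                                      sample_scale_sd = 0.3,
                                      triplicate_cv = 0.1,
                                      control_gene = "RSP8",
                                      missing_rate = 0.003,
                                      seed = NULL) {
  if (n_group1 < 2 || n_group2 < 2) {
    config_error("group sizes must both be >= 2")
  }
  if (n_genes < 1) config_error("n_genes must be >= 1")
  gene_ids <- sprintf("g%02d", seq_len(n_genes))
  if (control_gene %in% gene_ids) {
    config_error("control_gene must not collide with generated gene ids")
  }
  de_genes <- as.character(de_genes)
  if (!all(de_genes %in% gene_ids)) {
    config_error("de_genes contains ids outside the generated gene set")
  }
  if (control_gene %in% de_genes) {
    config_error("control gene must have effect 0 (cannot be in de_genes)")
  }
  if (length(log2_effect) == 1L) {
    log2_effect <- rep(log2_effect, length(de_genes))
  }
  if (length(log2_effect) != length(de_genes)) {
    config_error("log2_effect must be scalar or one value per DE gene")
  }
  block_of <- stats::setNames(rep(NA_integer_, n_genes), gene_ids)
  for (b in seq_along(correlation_blocks)) {
    blk <- correlation_blocks[[b]]
    if (is.null(blk$genes) || is.null(blk$r)) {
      config_error("each correlation block needs `genes` and `r`")
    }
    if (blk$r < 0 || blk$r >= 1) config_error("block correlation r must lie in [0, 1)")
    if (control_gene %in% blk$genes) {
      config_error("control gene may not belong to a correlation block")
    }
    if (!all(blk$genes %in% gene_ids)) {
      config_error("correlation block names a gene outside the generated set")
    }
    if (any(!is.na(block_of[blk$genes]))) {
      config_error("a gene may belong to at most one correlation block")
    }
    block_of[blk$genes] <- b
  }
  if (missing_rate < 0 || missing_rate >= 1) config_error("missing_rate must lie in [0, 1)")
  if (triplicate_cv < 0) config_error("triplicate_cv must be >= 0")

  n <- n_group1 + n_group2
  sample_ids <- c(sprintf("FR%02d", seq_len(n_group1)),
                  sprintf("WR%02d", seq_len(n_group2)))
  group <- rep(c("FR", "WR"), c(n_group1, n_group2))
  all_genes <- c(gene_ids, control_gene)
  eff <- stats::setNames(rep(0, length(all_genes)), all_genes)
  eff[de_genes] <- log2_effect

  with_seed(seed, {
    scale_log2 <- rnorm(n, 0, sample_scale_sd)
    # latent block factors, one per block per sample
    zblk <- matrix(rnorm(length(correlation_blocks) * n), ncol = n)
    log2_true <- matrix(NA_real_, length(all_genes), n,
                        dimnames = list(all_genes, sample_ids))
    for (g in all_genes) {
      b <- if (g == control_gene) NA_integer_ else block_of[[g]]
      z <- if (!is.na(b)) {
        r <- correlation_blocks[[b]]$r
        sqrt(r) * zblk[b, ] + sqrt(1 - r) * rnorm(n)
      } else {
        rnorm(n)
      }
      log2_true[g, ] <- gene_base_mean + eff[[g]] * (group == "WR") +
        biological_sd * z + scale_log2
    }
    miss <- matrix(FALSE, length(all_genes), n, dimnames = dimnames(log2_true))
    if (missing_rate > 0) {
      miss[gene_ids, ] <- runif(length(gene_ids) * n) < missing_rate
    }
    sdlog <- sqrt(log(1 + triplicate_cv^2))
    reps <- 3L
    quantities <- tidyr::expand_grid(
      gene_id = all_genes, sample_id = sample_ids, replicate = seq_len(reps)
    )
    truth <- 2^log2_true[cbind(match(quantities$gene_id, all_genes),
                               match(quantities$sample_id, sample_ids))]
    q <- truth * exp(rnorm(nrow(quantities), -sdlog^2 / 2, sdlog))
    q[miss[cbind(match(quantities$gene_id, all_genes),
                 match(quantities$sample_id, sample_ids))]] <- NA_real_
    quantities$quantity <- q

    structure(
      list(
        quantities = quantities,
        samples = tibble::tibble(
          sample_id = sample_ids, group = group,
          scale_factor = 2^scale_log2
        ),
        genes = tibble::tibble(
          gene_id = all_genes,
          is_control = all_genes == control_gene,
          log2_effect = unname(eff),
          block = c(block_of, stats::setNames(NA_integer_, control_gene))[all_genes]
        )
      ),
      class = "expression_study"
    )
  })
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "<expression_study> %d genes + control, %d samples (%s)\n",
    sum(!x$genes$is_control), nrow(x$samples),
    paste(sprintf("%s n=%d", names(table(x$samples$group)),
                  as.integer(table(x$samples$group))), collapse = ", ")
  ))
  invisible(x)
}
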