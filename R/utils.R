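#' @importFrom rlang abort warn .data
#' @importFrom stats median quantile rnorm rpois runif sd var pf pt pnorm
#' @importFrom utils combn
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.", class = "castebias_config_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

config_error <- function(msg) abort(msg, class = "castebias_config_error")

stopifnot_cols <- function(data, cols, what = "data") {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    abort(
      sprintf("%s is missing required column(s): %s", what,
              paste(miss, collapse = ", ")),
      class = "castebias_argument_error"
    )
  }
}

# Long (feature_id, sample_id, value) -> features x samples matrix with
# stable ordering: features in first-appearance order, samples likewise.
as_feature_matrix <- function(data, value_col = "value") {
  stopifnot_cols(data, c("feature_id", "sample_id", value_col))
  feats <- unique(data$feature_id)
  samps <- unique(data$sample_id)
  m <- matrix(NA_real_, length(feats), length(samps),
              dimnames = list(feats, samps))
  m[cbind(match(data$feature_id, feats), match(data$sample_id, samps))] <-
    data[[value_col]]
  m
}

# Two-level group factor for a set of sample ids; level order = sorted unique
# unless already a factor. Returns list(levels, g) with g indexed like ids.
group_vector <- function(data, sample_ids) {
  stopifnot_cols(data, c("sample_id", "group"))
  map <- data[!duplicated(data$sample_id), c("sample_id", "group")]
  g <- map$group[match(sample_ids, map$sample_id)]
  if (anyNA(g)) {
    abort("every sample must carry a group label", class = "castebias_argument_error")
  }
  lev <- if (is.factor(g)) levels(droplevels(g)) else sort(unique(as.character(g)))
  if (length(lev) != 2L) {
    abort(sprintf("expected exactly 2 groups, found %d", length(lev)),
          class = "castebias_argument_error")
  }
  list(levels = lev, g = factor(as.character(g), levels = lev))
}
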