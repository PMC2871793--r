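#' Prune highly correlated features
#'
#' Either removes an explicit `drop` list, or applies a reproducible greedy
#' rule: while any feature pair has |r| above `r_threshold`, drop the
#' feature with the most above-threshold partners, breaking ties by the
#' larger mean |r| over those partners and then by the lexicographically
#' later id. Used to eliminate the collinearity that makes a small-sample
#' LDA singular.
#'
#' @param data long tibble `feature_id`, `sample_id`, `value` (complete
#'   cases recommended).
#' @param r_threshold absolute Pearson correlation above which a pair is
#'   collinear.
#' @param drop optional character vector: remove exactly these features and
#'   skip the greedy rule.
#' @return list with `retained` (character vector, input order) and `log`
#'   (tibble `dropped`, `partner`, `r`, `n_partners`, `reason`).
#' @export
prune_correlated <- function(data, r_threshold = 0.9, drop = NULL) {
  m <- as_feature_matrix(data)
  feats <- rownames(m)
  if (length(feats) < 2) {
    abort("need >= 2 features to prune", class = "castebias_argument_error")
  }
  if (!is.null(drop) && length(drop)) {
    drop <- as.character(drop)
    missing <- setdiff(drop, feats)
    if (length(missing)) {
      abort(sprintf("drop list names absent feature(s): %s",
                    paste(missing, collapse = ", ")),
            class = "castebias_argument_error")
    }
    return(list(
      retained = setdiff(feats, drop),
      log = tibble::tibble(dropped = drop, partner = NA_character_,
                           r = NA_real_, n_partners = NA_integer_,
                           reason = "drop_override")
    ))
  }
  cm <- abs(stats::cor(t(m), use = "pairwise.complete.obs"))
  diag(cm) <- 0
  keep <- feats
  log <- list()
  for (iter in seq_along(feats)) {
    sub <- cm[keep, keep, drop = FALSE]
    over <- sub > r_threshold
    if (!any(over)) break
    n_part <- rowSums(over)
    cand <- which(n_part == max(n_part))
    if (length(cand) > 1) {
      mean_r <- vapply(cand, function(i) mean(sub[i, over[i, ]]), numeric(1))
      cand <- cand[mean_r == max(mean_r)]
    }
    victim <- names(cand)[order(names(cand), decreasing = TRUE)][1]
    partners <- keep[over[victim, ]]
    top <- partners[which.max(sub[victim, partners])]
    log[[victim]] <- tibble::tibble(
      dropped = victim, partner = top, r = cm[victim, top],
      n_partners = sum(over[victim, ]), reason = "greedy_collinearity"
    )
    keep <- setdiff(keep, victim)
  }
  list(retained = keep,
       log = if (length(log)) dplyr::bind_rows(log) else
         tibble::tibble(dropped = character(), partner = character(),
                        r = numeric(), n_partners = integer(),
                        reason = character()))
}

resolve_priors <- function(priors, counts, levels) {
  if (is.character(priors)) {
    priors <- match.arg(priors, c("empirical", "equal"))
    p <- if (priors == "empirical") counts / sum(counts) else c(0.5, 0.5)
  } else {
    if (length(priors) != 2 || any(priors <= 0)) {
      abort("numeric priors must be two positive values",
            class = "castebias_argument_error")
    }
    p <- priors / sum(priors)
  }
  stats::setNames(as.numeric(p), levels)
}

#' Two-class linear discriminant analysis
#'
#' Fisher/Gaussian LDA built from the pooled within-class covariance:
#' weights `w = S_pooled^-1 (mu2 - mu1)` (optionally ridge-stabilized by
#' adding `ridge_lambda * tr(S)/p` to the diagonal), with the intercept
#' placed at the prior-adjusted midpoint of the projected class means, so a
#' sample is assigned to class 2 when
#' `w'x - w'(mu1 + mu2)/2 + log(pi2/pi1) > 0`.
#'
#' @param data long tibble `feature_id`, `sample_id`, `group`, `value`
#'   (complete; impute first).
#' @param ridge_lambda ridge coefficient (>= 0). With 0 a singular pooled
#'   covariance raises an error advising ridge or more pruning.
#' @param priors `"empirical"` (class frequencies), `"equal"`, or a numeric
#'   pair in class-level order.
#' @return object of class `caste_lda`: weights, intercept, class means,
#'   pooled covariance, priors, classes, and per-sample `scores` tibble
#'   (`sample_id`, `group`, `ld_score`, `predicted_group`).
#' @export
fit_lda <- function(data, ridge_lambda = 0, priors = "empirical") {
  stopifnot_cols(data, c("feature_id", "sample_id", "group", "value"))
  if (ridge_lambda < 0) config_error("ridge_lambda must be >= 0")
  m <- as_feature_matrix(data)
  if (anyNA(m)) {
    abort("LDA requires complete data; impute missing values first",
          class = "castebias_argument_error")
  }
  x <- t(m)                                   # samples x features
  gv <- group_vector(data, rownames(x))
  g <- gv$g
  lev <- gv$levels
  n_k <- table(g)
  if (any(n_k < 2)) {
    abort("each class needs >= 2 samples", class = "castebias_argument_error")
  }
  p <- ncol(x)
  n <- nrow(x)
  if (ridge_lambda == 0 && p > n - 2) {
    abort(sprintf(
      "%d features with only %d samples: pooled covariance is singular; prune more features or set ridge_lambda > 0",
      p, n), class = "castebias_singularity_error")
  }
  x1 <- x[g == lev[1], , drop = FALSE]
  x2 <- x[g == lev[2], , drop = FALSE]
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  s1 <- crossprod(sweep(x1, 2, mu1))
  s2 <- crossprod(sweep(x2, 2, mu2))
  sw <- (s1 + s2) / (n - 2)
  if (ridge_lambda > 0) {
    sw <- sw + ridge_lambda * (sum(diag(sw)) / p) * diag(p)
  }
  w <- tryCatch(
    solve(sw, mu2 - mu1),
    error = function(e) abort(
      "pooled covariance is numerically singular; prune more features or set ridge_lambda > 0",
      class = "castebias_singularity_error")
  )
  pri <- resolve_priors(priors, as.numeric(n_k), lev)
  intercept <- -sum(w * (mu1 + mu2)) / 2 + log(pri[2] / pri[1])
  ld <- drop(x %*% w)
  pred <- ifelse(ld + intercept > 0, lev[2], lev[1])
  structure(
    list(
      features = colnames(x), weights = stats::setNames(w, colnames(x)),
      intercept = unname(intercept), class_means = rbind(mu1, mu2),
      pooled_covariance = sw, ridge_lambda = ridge_lambda,
      priors = pri, classes = lev, n = as.numeric(n_k),
      scores = tibble::tibble(sample_id = rownames(x),
                              group = as.character(g),
                              ld_score = unname(ld),
                              predicted_group = unname(pred))
    ),
    class = "caste_lda"
  )
}

#' @export
print.caste_lda <- function(x, ...) {
  cat(sprintf("<caste_lda> %d features, classes %s (n = %s), ridge = %g\n",
              length(x$features), paste(x$classes, collapse = "/"),
              paste(x$n, collapse = "/"), x$ridge_lambda))
  invisible(x)
}

#' @export
tidy.caste_lda <- function(x, ...) {
  tibble::tibble(feature_id = x$features, weight = unname(x$weights))
}

#' @export
glance.caste_lda <- function(x, ...) {
  tibble::tibble(n = sum(x$n), n_features = length(x$features),
                 ridge_lambda = x$ridge_lambda,
                 training_accuracy = mean(x$scores$predicted_group == x$scores$group))
}

#' Predict group membership from a fitted LDA
#'
#' @param object a [fit_lda()] model.
#' @param newdata long tibble `feature_id`, `sample_id`, `value` covering
#'   all model features.
#' @param ... unused.
#' @return tibble `sample_id`, `ld_score`, `predicted_group`.
#' @export
predict.caste_lda <- function(object, newdata, ...) {
  m <- as_feature_matrix(newdata)
  miss <- setdiff(object$features, rownames(m))
  if (length(miss)) {
    abort(sprintf("newdata lacks model feature(s): %s",
                  paste(miss, collapse = ", ")),
          class = "castebias_argument_error")
  }
  x <- t(m[object$features, , drop = FALSE])
  ld <- unname(drop(x %*% object$weights))
  tibble::tibble(
    sample_id = rownames(x), ld_score = unname(ld),
    predicted_group = ifelse(ld + object$intercept > 0,
                             object$classes[2], object$classes[1])
  )
}

#' Leave-one-out cross-validated LDA classification
#'
#' Each sample is predicted by an LDA fit on the remaining n - 1 samples.
#' By default the feature set is pruned once on the full data before
#' cross-validation (the sequence prune -> LDA -> LOOCV; documented as
#' optimistic since the held-out sample informs the pruning);
#' `prune_scope = "per_fold"` re-prunes inside every fold.
#'
#' @param data long tibble `feature_id`, `sample_id`, `group`, `value`.
#' @param r_threshold,drop passed to [prune_correlated()]; set
#'   `r_threshold = NULL` with `drop = NULL` to skip pruning.
#' @param ridge_lambda,priors passed to [fit_lda()]. Numeric `priors` are
#'   held fixed across folds; `"empirical"` recomputes per fold.
#' @param prune_scope `"full_data"` (default) or `"per_fold"`.
#' @return object of class `caste_loocv`: `predictions` tibble
#'   (`sample_id`, `group`, `predicted_group`, `ld_score`, `correct`),
#'   `accuracy`, `retained_features`, `prune_log`.
#' @export
loocv_lda <- function(data, r_threshold = NULL, drop = NULL,
                      ridge_lambda = 0, priors = "empirical",
                      prune_scope = c("full_data", "per_fold")) {
  prune_scope <- match.arg(prune_scope)
  stopifnot_cols(data, c("feature_id", "sample_id", "group", "value"))
  gv <- group_vector(data, unique(data$sample_id))
  if (any(table(gv$g) < 2)) {
    abort("leave-one-out needs >= 2 samples per class",
          class = "castebias_degenerate_fold_error")
  }
  do_prune <- !is.null(r_threshold) || !is.null(drop)
  prune_log <- NULL
  if (do_prune && prune_scope == "full_data") {
    pr <- prune_correlated(data, r_threshold = if (is.null(r_threshold)) 0.9 else r_threshold,
                           drop = drop)
    data <- data[data$feature_id %in% pr$retained, ]
    prune_log <- pr$log
  }
  samples <- unique(data$sample_id)
  preds <- purrr::map(samples, function(s) {
    train <- data[data$sample_id != s, ]
    gtr <- group_vector(train, unique(train$sample_id))$g
    if (nlevels(droplevels(gtr)) < 2 || any(table(droplevels(gtr)) < 2)) {
      abort("leaving one sample out empties (or degenerates) a class",
            class = "castebias_degenerate_fold_error")
    }
    if (do_prune && prune_scope == "per_fold") {
      pr <- prune_correlated(train,
                             r_threshold = if (is.null(r_threshold)) 0.9 else r_threshold,
                             drop = drop)
      train <- train[train$feature_id %in% pr$retained, ]
    }
    fit <- fit_lda(train, ridge_lambda = ridge_lambda, priors = priors)
    test <- data[data$sample_id == s, c("feature_id", "sample_id", "value")]
    p <- predict(fit, test)
    p$group <- unique(data$group[data$sample_id == s])[1]
    p
  })
  preds <- dplyr::bind_rows(preds)
  preds$group <- as.character(preds$group)
  preds$correct <- preds$predicted_group == preds$group
  preds <- preds[, c("sample_id", "group", "predicted_group", "ld_score", "correct")]
  structure(
    list(predictions = preds, accuracy = mean(preds$correct),
         n_correct = sum(preds$correct), n = nrow(preds),
         retained_features = unique(data$feature_id), prune_log = prune_log),
    class = "caste_loocv"
  )
}

#' @export
print.caste_loocv <- function(x, ...) {
  cat(sprintf("<caste_loocv> %d/%d correct (accuracy %.1f%%), %d features\n",
              x$n_correct, x$n, 100 * x$accuracy, length(x$retained_features)))
  invisible(x)
}

#' @export
tidy.caste_loocv <- function(x, ...) x$predictions

#' @export
glance.caste_loocv <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_correct = x$n_correct, n = x$n,
                 n_features = length(x$retained_features))
}
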