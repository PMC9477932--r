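#' Stratified train/validation split
#'
#' Splits a feature table into training and validation sets at the given
#' ratio with (up to integer rounding) equal class proportions in both
#' parts.  With ratio 3/1, three quarters of each class go to training.
#'
#' @param table feature table with a binary `label` column (1/0).
#' @param ratio train:validation ratio; default 3 (i.e. 3/1).
#' @param seed integer seed controlling the random assignment.
#' @return List with `train` and `validation` data.frames.
#' @export
split_cohort <- function(table, ratio = 3, seed = 1L) {
  stopifnot("label" %in% names(table))
  lab <- table$label
  if (length(unique(lab)) < 2L) stop("both classes must be present")
  if (any(tabulate(lab + 1L, 2L) < 2L))
    stop("each class needs at least 2 members to split")
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (cls in c(1L, 0L)) {
    idx <- which(lab == cls)
    n_tr <- round(length(idx) * ratio / (ratio + 1))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  list(train = table[train_idx, , drop = FALSE],
       validation = table[-train_idx, , drop = FALSE])
}

feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "label", "split"))
}

#' Near-zero-variance filter
#'
#' Removes exactly constant features, plus features that are almost
#' constant: frequency ratio of the most common to the second most common
#' value at least `freq_cut` AND fraction of distinct values at most
#' `unique_cut`.  The defaults (19, i.e. 95/5, and 10%) follow the common
#' machine-learning preprocessing convention.
#'
#' @param table feature table (training split).
#' @param freq_cut frequency-ratio cutoff; default 19.
#' @param unique_cut distinct-value fraction cutoff; default 0.1.
#' @return A `selection_result`: list with `retained` (feature names, in
#'   input order), `eliminated` (data.frame of feature/stage/reason), and
#'   `params`.
#' @export
drop_near_zero_variance <- function(table, freq_cut = 19, unique_cut = 0.1) {
  feats <- feature_columns(table)
  n <- nrow(table)
  if (n < 2L) stop("need at least 2 rows")
  drop <- character(0)
  reason <- character(0)
  for (f in feats) {
    x <- table[[f]]
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) == 1L) {
      drop <- c(drop, f); reason <- c(reason, "constant")
      next
    }
    fr <- tab[1] / tab[2]
    uq <- length(tab) / n
    if (fr >= freq_cut && uq <= unique_cut) {
      drop <- c(drop, f)
      reason <- c(reason, sprintf("freq_ratio=%.3g unique_frac=%.3g", fr, uq))
    }
  }
  if (length(drop) == length(feats))
    warning("near-zero-variance filter removed every feature")
  selection_result(retained = setdiff(feats, drop), eliminated = drop,
                   stage = "near_zero_variance", reason = reason,
                   params = list(freq_cut = freq_cut, unique_cut = unique_cut))
}

#' Pairwise-correlation filter
#'
#' While any pair of remaining features has absolute Pearson correlation
#' at or above the threshold, the member of the worst pair with the larger
#' mean absolute correlation against all remaining features is removed;
#' ties break by column order.  Re-running the filter on its own output
#' changes nothing.
#'
#' @param table feature table (training split).
#' @param threshold absolute correlation cutoff; default 0.9.
#' @return A `selection_result`.
#' @export
drop_correlated <- function(table, threshold = 0.9) {
  feats <- feature_columns(table)
  if (nrow(table) < 3L) stop("need at least 3 rows for correlations")
  x <- as.matrix(table[, feats, drop = FALSE])
  keep <- feats
  drop <- character(0)
  reason <- character(0)
  if (length(feats) >= 2L) {
    cm <- abs(suppressWarnings(stats::cor(x)))
    cm[is.na(cm)] <- 0 # zero-variance columns correlate with nothing
    diag(cm) <- 0
    while (length(keep) >= 2L && max(cm) >= threshold) {
      worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      a <- rownames(cm)[worst[1]]; b <- colnames(cm)[worst[2]]
      mean_a <- mean(cm[a, ]); mean_b <- mean(cm[b, ])
      victim <- if (mean_a > mean_b) a
                else if (mean_b > mean_a) b
                else keep[min(match(c(a, b), keep))] # tie: earlier column
      drop <- c(drop, victim)
      reason <- c(reason,
                  sprintf("|r|=%.4f with %s", max(cm),
                          if (victim == a) b else a))
      keep <- setdiff(keep, victim)
      cm <- cm[keep, keep, drop = FALSE]
      if (length(keep) < 2L) break
    }
  }
  selection_result(retained = keep, eliminated = drop,
                   stage = "correlation", reason = reason,
                   params = list(threshold = threshold))
}

#' Stepwise forward selection under cross-validated AUC
#'
#' Greedy wrapper selection with an unpenalized logistic model: starting
#' from the empty set (cross-validated AUC taken as 0.5), repeatedly add
#' the candidate feature that maximizes the mean stratified k-fold
#' cross-validation AUC of the model on the selected set, and stop when
#' the best candidate improves the running AUC by no more than `delta`
#' (strictly-greater stopping rule) or candidates are exhausted.
#'
#' @param table feature table (training split only).
#' @param k number of stratified CV folds; default 5.
#' @param delta minimum AUC improvement to keep adding; default 0.005.
#' @param seed seed for the fold assignment.
#' @param candidates candidate feature names; defaults to all feature
#'   columns.
#' @return A `selection_result`; `$trace` logs each round's best candidate
#'   and CV AUC.
#' @export
forward_select_cv <- function(table, k = 5L, delta = 0.005, seed = 1L,
                              candidates = NULL) {
  if (is.null(candidates)) candidates <- feature_columns(table)
  y <- table$label
  if (length(candidates) == 0L)
    return(selection_result(character(0), character(0), "forward_cv",
                            character(0),
                            params = list(k = k, delta = delta, seed = seed)))
  folds <- stratified_folds(y, k = k, seed = seed)
  x <- as.matrix(table[, candidates, drop = FALSE])
  selected <- character(0)
  remaining <- candidates
  best_auc <- 0.5
  trace <- list()
  repeat {
    if (length(remaining) == 0L) break
    aucs <- vapply(remaining, function(f) {
      cv_auc_logistic(x[, c(selected, f), drop = FALSE], y, folds)
    }, numeric(1))
    top <- which.max(aucs) # first maximum: deterministic tie-break
    trace[[length(trace) + 1L]] <- list(feature = remaining[top],
                                        cv_auc = aucs[[top]],
                                        improvement = aucs[[top]] - best_auc)
    if (aucs[[top]] - best_auc <= delta) break
    selected <- c(selected, remaining[top])
    best_auc <- aucs[[top]]
    remaining <- remaining[-top]
  }
  res <- selection_result(retained = selected,
                          eliminated = setdiff(candidates, selected),
                          stage = "forward_cv",
                          reason = rep("not selected",
                                       length(candidates) - length(selected)),
                          params = list(k = k, delta = delta, seed = seed))
  res$trace <- trace
  res$cv_auc <- best_auc
  res
}

# Stratified fold assignment: within each class, shuffled indices are
# dealt round-robin so every fold holds both classes whenever possible.
stratified_folds <- function(y, k = 5L, seed = 1L) {
  set.seed(as.integer(seed))
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Mean out-of-fold AUC of an unpenalized logistic fit.
cv_auc_logistic <- function(x, y, folds) {
  k <- max(folds)
  aucs <- numeric(k)
  for (fold in seq_len(k)) {
    te <- folds == fold
    ytr <- y[!te]
    if (length(unique(ytr)) < 2L || length(unique(y[te])) < 2L)
      stop(sprintf("fold %d lacks both classes", fold))
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, x[!te, , drop = FALSE]), ytr,
                     family = stats::binomial()))
    pr <- stats::plogis(cbind(1, x[te, , drop = FALSE]) %*% fit$coefficients)
    aucs[fold] <- auc_rank(pr, y[te])
  }
  mean(aucs)
}

selection_result <- function(retained, eliminated, stage, reason, params) {
  structure(list(retained = retained,
                 eliminated = data.frame(feature = eliminated,
                                         stage = rep(stage,
                                                     length(eliminated)),
                                         reason = reason),
                 stage = stage, params = params),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %s> retained %d, eliminated %d\n",
              x$stage, length(x$retained), nrow(x$eliminated)))
  invisible(x)
}

#' Run the full three-stage selection cascade
#'
#' Near-zero-variance filter, then the pairwise-correlation filter, then
#' forward selection under cross-validated AUC, all on the training split
#' only.
#'
#' @param train training feature table.
#' @param candidates candidate pool; defaults to all feature columns.
#' @param freq_cut,unique_cut near-zero-variance parameters.
#' @param corr_threshold correlation cutoff; default 0.9.
#' @param k,delta,seed forward-selection parameters.
#' @return List with the three `selection_result`s (`nzv`, `corr`,
#'   `forward`) and `selected`, the final feature set.
#' @export
select_features <- function(train, candidates = NULL,
                            freq_cut = 19, unique_cut = 0.1,
                            corr_threshold = 0.9,
                            k = 5L, delta = 0.005, seed = 1L) {
  if (is.null(candidates)) candidates <- feature_columns(train)
  sub <- train[, c("label", candidates), drop = FALSE]
  s1 <- drop_near_zero_variance(sub, freq_cut = freq_cut,
                                unique_cut = unique_cut)
  sub2 <- train[, c("label", s1$retained), drop = FALSE]
  s2 <- if (length(s1$retained) >= 2L)
    drop_correlated(sub2, threshold = corr_threshold)
  else selection_result(s1$retained, character(0), "correlation",
                        character(0), list(threshold = corr_threshold))
  sub3 <- train[, c("label", s2$retained), drop = FALSE]
  s3 <- forward_select_cv(sub3, k = k, delta = delta, seed = seed)
  list(nzv = s1, corr = s2, forward = s3, selected = s3$retained)
}
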