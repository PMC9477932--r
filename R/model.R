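#' Fit an unpenalized logistic-regression classifier
#'
#' Maximum-likelihood fit of `P(label = 1 | x) = plogis(b0 + b'x)` on
#' features standardized to the training mean and SD (the stored
#' standardization is reused verbatim at prediction time).  Coefficients
#' are reported on both the standardized and the original scale.
#' Complete separation is detected (fitted probabilities all numerically
#' at 0/1); in that case a lightly ridge-penalized fit replaces the
#' diverging one and the model is flagged.
#'
#' @param train training feature table with a `label` column.
#' @param features names of the predictor columns.
#' @return An object of class `logistic_model`.
#' @export
fit_logistic <- function(train, features) {
  y <- as.integer(train$label)
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  if (min(tabulate(y + 1L, 2L)) < 2L) stop("need >= 2 rows per class")
  missing <- setdiff(features, names(train))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(train[, features, drop = FALSE])
  if (any(!is.finite(x))) stop("non-finite feature values")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1 # constant column: centered to 0, coefficient forced 0
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, xs), y,
                   family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  p_hat <- fit$fitted.values
  separated <- all(p_hat < 1e-8 | p_hat > 1 - 1e-8) ||
    any(abs(beta[-1]) > 15)
  ridge <- FALSE
  if (separated && length(features) >= 1L) {
    # minimal ridge penalty to stabilize the diverging MLE
    xr <- if (ncol(xs) == 1L) cbind(xs, 0) else xs # glmnet needs >= 2 cols
    gfit <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                           lambda = 1e-3, standardize = FALSE)
    beta <- c(as.numeric(gfit$a0),
              as.numeric(gfit$beta)[seq_len(ncol(xs))])
    names(beta) <- c("(Intercept)", colnames(xs))
    ridge <- TRUE
  }
  coef_orig <- beta[-1] / sdv
  intercept_orig <- beta[1] - sum(beta[-1] * mu / sdv)
  structure(list(features = features,
                 coef_std = beta,
                 coef_original = c(`(Intercept)` = intercept_orig,
                                   coef_orig),
                 center = mu, scale = sdv,
                 converged = isTRUE(fit$converged) || ridge,
                 iterations = fit$iter,
                 separated = separated, ridge = ridge),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> %d feature(s)%s\n", length(x$features),
              if (x$separated) " [separation: ridge-stabilized]" else ""))
  print(round(x$coef_std, 4))
  invisible(x)
}

#' Predict class probabilities
#'
#' Applies the stored training standardization, never statistics of the
#' new data.  A missing feature column is an error (no imputation).
#'
#' @param model a [fit_logistic()] result.
#' @param table feature table to score.
#' @return Numeric vector of probabilities of the positive class.
#' @export
predict_prob <- function(model, table) {
  stopifnot(inherits(model, "logistic_model"))
  missing <- setdiff(model$features, names(table))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(table[, model$features, drop = FALSE])
  if (any(!is.finite(x))) stop("non-finite feature values")
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  as.numeric(stats::plogis(model$coef_std[1] +
                             xs %*% model$coef_std[-1]))
}

#' Run the full three-model study
#'
#' Mirrors the study design: on the training split, fit (a) a
#' conventional model on the PET parameters TBR_mean and TBR_max, (b) a
#' radiomics model on the features retained by the three-stage selection
#' cascade (the PET parameters are kept out of the radiomics pool), and
#' (c) a combined model refit jointly on the union of both sets.  Each
#' model is evaluated on the validation and test splits: AUC with a 95%
#' DeLong interval, plus sensitivity and specificity at the optimal
#' (max sens x spec) cutoff; the validation-derived cutoff is also applied
#' to the test split, since a deployed classifier carries its cutoff with
#' it.
#'
#' Splits must be disjoint in `subject_id`; any overlap is information
#' leakage and is refused.
#'
#' @param train,validation,test feature tables (as from
#'   [extract_cohort_features()]).
#' @param conventional names of the conventional PET parameter columns.
#' @param corr_threshold,k,delta,freq_cut,unique_cut cascade parameters
#'   (see [select_features()]).
#' @param seed seed for fold assignment.
#' @return An object of class `study_report`.
#' @export
run_study <- function(train, validation, test = NULL,
                      conventional = c("tbr_mean", "tbr_max"),
                      corr_threshold = 0.9, k = 5L, delta = 0.005,
                      freq_cut = 19, unique_cut = 0.1, seed = 1L) {
  splits <- list(train = train, validation = validation, test = test)
  splits <- splits[!vapply(splits, is.null, logical(1))]
  if (all(vapply(splits, function(s) "subject_id" %in% names(s),
                 logical(1)))) {
    ids <- lapply(splits, `[[`, "subject_id")
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i < j && length(intersect(ids[[i]], ids[[j]])))
        stop(sprintf("subject leakage between %s and %s splits",
                     names(ids)[i], names(ids)[j]))
    }
  }
  pool <- setdiff(feature_columns(train), conventional)
  cascade <- select_features(train, candidates = pool,
                             freq_cut = freq_cut, unique_cut = unique_cut,
                             corr_threshold = corr_threshold,
                             k = k, delta = delta, seed = seed)
  sets <- list(conventional = conventional,
               radiomics = cascade$selected,
               combined = union(conventional, cascade$selected))
  models <- lapply(sets, function(f) {
    if (length(f) == 0L) NULL else fit_logistic(train, f)
  })
  eval_split <- function(tab, cutoffs = NULL) {
    out <- list()
    for (m in names(models)) {
      if (is.null(models[[m]])) {
        out[[m]] <- list(auc = 0.5, ci = c(NA, NA), empty = TRUE)
        next
      }
      pr <- predict_prob(models[[m]], tab)
      roc <- roc_auc(pr, tab$label)
      ci <- auc_ci(pr, tab$label)
      oc <- optimal_cutoff(roc)
      res <- list(auc = roc$auc, ci_low = ci$low, ci_high = ci$high,
                  cutoff = oc$cutoff, sensitivity = oc$sensitivity,
                  specificity = oc$specificity, roc = roc, empty = FALSE)
      if (!is.null(cutoffs) && !is.null(cutoffs[[m]])) {
        cs <- confusion_at(pr, tab$label, cutoffs[[m]])
        res$sens_at_validation_cutoff <- cs$sensitivity
        res$spec_at_validation_cutoff <- cs$specificity
        res$validation_cutoff <- cutoffs[[m]]
      }
      out[[m]] <- res
    }
    out
  }
  val_eval <- eval_split(validation)
  val_cutoffs <- lapply(val_eval, function(e)
    if (isTRUE(e$empty)) NULL else e$cutoff)
  test_eval <- if (!is.null(test)) eval_split(test, cutoffs = val_cutoffs)
  structure(list(models = models, feature_sets = sets, cascade = cascade,
                 validation = val_eval, test = test_eval,
                 config = list(conventional = conventional,
                               corr_threshold = corr_threshold, k = k,
                               delta = delta, freq_cut = freq_cut,
                               unique_cut = unique_cut, seed = seed)),
            class = "study_report")
}

confusion_at <- function(scores, labels, cutoff) {
  pred <- scores >= cutoff
  pos <- labels == 1L
  list(sensitivity = if (any(pos)) mean(pred[pos]) else NA_real_,
       specificity = if (any(!pos)) mean(!pred[!pos]) else NA_real_)
}

#' @export
print.study_report <- function(x, ...) {
  fmt <- function(e) {
    if (isTRUE(e$empty)) return("  (no features selected: AUC 0.50)")
    sprintf("  AUC %.2f (95%% CI %.2f-%.2f)  sens %3.0f%%  spec %3.0f%%",
            e$auc, e$ci_low, e$ci_high,
            100 * e$sensitivity, 100 * e$specificity)
  }
  for (split in c("validation", "test")) {
    ev <- x[[split]]
    if (is.null(ev)) next
    cat(sprintf("%s dataset\n",
                paste0(toupper(substring(split, 1, 1)), substring(split, 2))))
    for (m in names(ev)) {
      cat(sprintf(" %-32s\n%s\n",
                  c(conventional = "FET PET parameters",
                    radiomics = "Radiomics features",
                    combined = "FET PET parameters + radiomics")[[m]],
                  fmt(ev[[m]])))
    }
  }
  invisible(x)
}
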