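#' Cohort specification
#'
#' Describes a synthetic two-class cohort.  Per-class distributions of the
#' lesion TBR targets and of the intra-lesion texture amplitude are given
#' as `c(mean, sd)` of truncated normals; each subject's phantom is then
#' generated from a per-subject seed drawn deterministically from the
#' master seed.  The defaults emulate the group statistics of a
#' glioma follow-up cohort in which tumor progression (TP) shows higher
#' uptake (TBR_mean 2.1 +/- 0.3, TBR_max 3.7 +/- 0.9) and more
#' heterogeneous texture than treatment-related changes (TRC, TBR_mean
#' 1.9 +/- 0.3, TBR_max 2.8 +/- 0.7), at a 75/25 class prevalence.
#'
#' @param n_tp,n_trc subject counts per class (each >= 1).
#' @param tp,trc per-class distributions: named lists with `tbr_mean`,
#'   `tbr_max`, `texture_amp`, each `c(mean, sd)`.
#' @param phantom a [phantom_spec()] providing the shared geometry,
#'   background and noise settings (its per-subject fields are overridden).
#' @param seed master seed.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tp = 75L, n_trc = 25L,
                        tp = list(tbr_mean = c(2.1, 0.3),
                                  tbr_max = c(3.7, 0.9),
                                  texture_amp = c(0.30, 0.08)),
                        trc = list(tbr_mean = c(1.9, 0.3),
                                   tbr_max = c(2.8, 0.7),
                                   texture_amp = c(0.03, 0.02)),
                        phantom = phantom_spec(),
                        seed = 1L) {
  n_tp <- as.integer(n_tp); n_trc <- as.integer(n_trc)
  if (n_tp < 1L || n_trc < 1L) stop("both class counts must be >= 1")
  for (cls in list(tp, trc))
    stopifnot(all(c("tbr_mean", "tbr_max", "texture_amp") %in% names(cls)))
  structure(list(n_tp = n_tp, n_trc = n_trc, tp = tp, trc = trc,
                 phantom = phantom, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort of phantom subjects
#'
#' Draws per-subject TBR and texture-amplitude targets from the class
#' distributions (rejection-sampled so that `tbr_max >= tbr_mean + 0.05`
#' and `tbr_mean >= 1.65`, keeping every lesion detectable), then
#' generates each phantom from its own derived seed.  TP subjects come
#' first, then TRC, so labels are reproducible from the spec alone.
#'
#' @param cohort a [cohort_spec()].
#'
#' @return A list of subjects, each as returned by [generate_phantom()]
#'   plus `subject_id` and numeric `label` (TP = 1, TRC = 0).
#' @export
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n <- cohort$n_tp + cohort$n_trc
  set.seed(cohort$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  labels <- c(rep(1L, cohort$n_tp), rep(0L, cohort$n_trc))
  targets <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- if (labels[i] == 1L) cohort$tp else cohort$trc
    targets[[i]] <- draw_subject_targets(cls)
  }
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- cohort$phantom
    ps$tbr_mean <- targets[[i]]$tbr_mean
    ps$tbr_max <- targets[[i]]$tbr_max
    ps$texture_amp <- targets[[i]]$texture_amp
    ps$label <- if (labels[i] == 1L) "TP" else "TRC"
    ps$seed <- seeds[i]
    subj <- generate_phantom(ps)
    subj$subject_id <- sprintf("S%03d", i)
    subj$label <- labels[i]
    subjects[[i]] <- subj
  }
  subjects
}

# Rejection-sample one subject's targets from class distributions so the
# phantom constraints hold (detectable lesion, max strictly above mean).
draw_subject_targets <- function(cls) {
  for (attempt in 1:1000) {
    tm <- stats::rnorm(1, cls$tbr_mean[1], cls$tbr_mean[2])
    tx <- stats::rnorm(1, cls$tbr_max[1], cls$tbr_max[2])
    if (tm >= 1.65 && tx >= tm + 0.05) {
      amp <- max(0, stats::rnorm(1, cls$texture_amp[1], cls$texture_amp[2]))
      return(list(tbr_mean = tm, tbr_max = tx, texture_amp = amp))
    }
  }
  stop("could not draw admissible TBR targets; check class distributions")
}

#' Simulate a raw feature table
#'
#' A direct simulator for the feature-selection stages: `n` subjects
#' (balanced classes), `p` base features drawn as equicorrelated standard
#' normals, of which the first `p_informative` are shifted by
#' `effect` in class 1.  Constant and exactly duplicated columns can be
#' injected to exercise the variance and correlation filters.
#'
#' @param n number of subjects (split as evenly as possible, class 1 first).
#' @param p number of base features.
#' @param p_informative how many features carry the class effect
#'   (`0 <= p_informative <= p`).
#' @param effect between-class mean shift, in feature SD units.
#' @param correlation pairwise correlation among base features
#'   (`0 <= correlation < 1`).
#' @param seed integer seed.
#' @param n_constant,n_duplicate numbers of constant / duplicated columns
#'   appended after the base features.
#'
#' @return A data.frame with `subject_id`, `label` (1/0) and feature
#'   columns `feat_001`, ... (duplicates named `dup_*`, constants
#'   `const_*`).
#' @export
generate_feature_table <- function(n, p, p_informative = 0, effect = 0,
                                   correlation = 0, seed = 1L,
                                   n_constant = 0L, n_duplicate = 0L) {
  if (p_informative > p) stop("p_informative must be <= p")
  if (p_informative < 0) stop("p_informative must be >= 0")
  if (abs(correlation) >= 1) stop("|correlation| must be < 1")
  if (correlation < 0) stop("equicorrelated construction requires correlation >= 0")
  set.seed(as.integer(seed))
  n1 <- ceiling(n / 2); n0 <- n - n1
  label <- c(rep(1L, n1), rep(0L, n0))
  z <- matrix(stats::rnorm(n * p), n, p)
  if (correlation > 0) {
    shared <- stats::rnorm(n)
    z <- sqrt(1 - correlation) * z + sqrt(correlation) * shared
  }
  if (p_informative > 0)
    z[label == 1L, seq_len(p_informative)] <-
      z[label == 1L, seq_len(p_informative)] + effect
  colnames(z) <- sprintf("feat_%03d", seq_len(p))
  tab <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                    label = label, z, check.names = FALSE)
  if (n_duplicate > 0L) {
    src <- rep_len(seq_len(p), n_duplicate)
    for (j in seq_len(n_duplicate))
      tab[[sprintf("dup_%03d", j)]] <- z[, src[j]]
  }
  if (n_constant > 0L)
    for (j in seq_len(n_constant))
      tab[[sprintf("const_%03d", j)]] <- 1
  tab
}
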