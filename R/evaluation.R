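#' Subject-level K-fold partition
#'
#' Deterministic seeded partition of unique subjects into `k` folds of size
#' differing by at most one; every subject appears in exactly one fold, so
#' train/test subject sets are disjoint in every rotation.
#'
#' @param subject_ids vector of subject identifiers (duplicates allowed;
#'   folds are assigned per unique subject).
#' @param k number of folds (default 7).
#' @param seed integer seed.
#' @return named integer vector: fold (1..k) per unique subject.
#' @export
kfold_split <- function(subject_ids, k = 7, seed = 0) {
  subjects <- unique(as.character(subject_ids))
  if (length(subjects) < k)
    stopf("need at least k=%d subjects, got %d", k, length(subjects))
  withr::with_seed(derive_seed(seed, "kfold"), {
    ord <- sample(subjects)
    folds <- rep(seq_len(k), length.out = length(ord))
    stats::setNames(folds[match(subjects, ord)], subjects)
  })
}

#' Segment start times of a sliding-window stream
#'
#' Half-open windows `[t, t + segment_s)` every `stride_s` seconds;
#' trailing partial windows are dropped.
#'
#' @param duration_s recording length, seconds.
#' @param segment_s window length (default 10).
#' @param stride_s stride (default 5).
#' @return numeric vector of start times (possibly empty).
#' @export
segment_stream <- function(duration_s, segment_s = 10, stride_s = 5) {
  if (duration_s < segment_s) return(numeric(0))
  seq(0, duration_s - segment_s, by = stride_s)
}

#' Percentile bootstrap confidence interval
#'
#' @param values numeric sample.
#' @param B number of bootstrap resamples (default 2000).
#' @param level confidence level (default 0.95).
#' @param statistic function of a sample (default `mean`; use `median` for
#'   error metrics).
#' @param seed integer seed.
#' @return named numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(values, B = 2000, level = 0.95,
                         statistic = mean, seed = 0) {
  if (B < 1) stopf("B must be >= 1")
  if (length(values) == 0) stopf("empty sample")
  withr::with_seed(derive_seed(seed, "bootstrap"), {
    stats <- vapply(seq_len(B), function(i) {
      statistic(values[sample.int(length(values), replace = TRUE)])
    }, numeric(1))
    a <- (1 - level) / 2
    q <- stats::quantile(stats, c(a, 1 - a), names = FALSE, type = 7)
    c(lower = q[1], upper = q[2])
  })
}

#' Pearson correlation with a two-sided zero-correlation test
#'
#' @param pred,truth aligned numeric vectors (n >= 3 after removing
#'   incomplete pairs).
#' @return list with `r` and `p_value`.
#' @export
correlation_report <- function(pred, truth) {
  keep <- is.finite(pred) & is.finite(truth)
  if (sum(keep) < 3) stopf("need n >= 3 complete pairs")
  ct <- stats::cor.test(pred[keep], truth[keep], alternative = "two.sided",
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(keep))
}

#' One-vs-rest F1 score of class calls
#'
#' @param called,truth character vectors of called and true classes.
#' @param positive the positive class.
#' @return F1 in `[0, 1]` (NA when the class never occurs).
#' @export
f1_score <- function(called, truth, positive) {
  tp <- sum(called == positive & truth == positive)
  fp <- sum(called == positive & truth != positive)
  fn <- sum(called != positive & truth == positive)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}
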