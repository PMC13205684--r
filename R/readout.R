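#' Fit linear factor-to-semantic readouts
#'
#' Ordinary least squares from the 64 semantic factors to each semantic
#' quantity (ventricular rate, PR, QT, ...). When the system is
#' ill-conditioned (n <= latent_dim or rank deficiency) a ridge fallback
#' with penalty `ridge` is engaged.
#'
#' @param z factor matrix (segments x latent_dim).
#' @param targets numeric vector, matrix or data frame of semantic values
#'   (one column per target).
#' @param ridge ridge penalty for the degenerate-fit fallback (default 1e-3).
#' @param subject_ids optional per-row subject identifiers, stored for the
#'   subject-disjointness check in [predict_readout()].
#' @return object of class `linear_readout` (`weights`: (latent_dim + 1) x
#'   targets including intercept row).
#' @export
fit_linear_readout <- function(z, targets, ridge = 1e-3, subject_ids = NULL) {
  z <- as.matrix(z)
  if (is.vector(targets)) targets <- matrix(targets, ncol = 1,
                                            dimnames = list(NULL, "target"))
  targets <- as.matrix(targets)
  if (nrow(z) != nrow(targets)) stopf("rows of z and targets must align")
  keep <- stats::complete.cases(targets) & stats::complete.cases(z)
  zc <- z[keep, , drop = FALSE]
  yc <- targets[keep, , drop = FALSE]
  x1 <- cbind(1, zc)
  use_ridge <- nrow(zc) <= ncol(zc) + 1 || qr(x1)$rank < ncol(x1)
  w <- if (use_ridge) {
    pen <- diag(c(0, rep(ridge, ncol(zc))))
    solve(crossprod(x1) + pen, crossprod(x1, yc))
  } else {
    stats::lm.fit(x1, yc)$coefficients
  }
  w <- as.matrix(w)
  rownames(w) <- c("(intercept)", paste0("f", seq_len(ncol(zc))))
  colnames(w) <- colnames(targets)
  structure(list(weights = w, target_names = colnames(targets),
                 fit_metadata = list(n = sum(keep), ridge = use_ridge,
                                     subjects = unique(subject_ids[keep]))),
            class = "linear_readout")
}

#' Predict semantic quantities from factors with a fitted linear readout
#'
#' If both the model and the call carry subject identifiers, overlapping
#' train/test subjects raise an error: readout evaluation is only
#' meaningful on subject-disjoint folds.
#'
#' @param model a `linear_readout`.
#' @param z factor matrix (segments x latent_dim).
#' @param subject_ids optional per-row identifiers of the segments scored.
#' @return matrix (segments x targets) of predicted semantic values.
#' @export
predict_readout <- function(model, z, subject_ids = NULL) {
  stopifnot(inherits(model, "linear_readout"))
  z <- as.matrix(z)
  if (ncol(z) + 1 != nrow(model$weights))
    stopf("factor dimension mismatch: model expects %d factors",
          nrow(model$weights) - 1)
  if (!is.null(subject_ids) && length(model$fit_metadata$subjects) > 0) {
    overlap <- intersect(unique(subject_ids), model$fit_metadata$subjects)
    if (length(overlap) > 0)
      stopf("subject leakage: %d subject(s) appear in both fit and predict",
            length(overlap))
  }
  cbind(1, z) %*% model$weights
}

#' Fit the linear arrhythmia diagnosis head
#'
#' Multinomial logistic regression (no hidden layers: a linear projection
#' from factors to disease categories) over \{NORMAL, AF, PB\} on
#' per-segment factors.
#'
#' @param z factor matrix (segments x latent_dim).
#' @param labels rhythm class per segment.
#' @param decision_threshold per-class calling threshold on the
#'   recording-mean probability (default 0.5).
#' @param subject_ids optional, stored for leakage checks.
#' @return object of class `diagnosis_model`.
#' @export
fit_diagnosis <- function(z, labels, decision_threshold = 0.5,
                          subject_ids = NULL) {
  z <- as.matrix(z)
  labels <- factor(as.character(labels), levels = RHYTHM_CLASSES)
  present <- levels(droplevels(labels))
  if (length(present) < 2) stopf("single-class training data: need >= 2 classes")
  df <- data.frame(y = droplevels(labels), z)
  fit <- suppressWarnings(nnet::multinom(y ~ ., data = df, trace = FALSE,
                                         maxit = 200, MaxNWts = 5000))
  structure(list(fit = fit, classes = present,
                 feature_sd = apply(z, 2, stats::sd),
                 decision_threshold = decision_threshold,
                 fit_metadata = list(n = nrow(z),
                                     subjects = unique(subject_ids))),
            class = "diagnosis_model")
}

#' Per-recording arrhythmia probabilities and calls
#'
#' Segment-level class probabilities are averaged per recording; a
#' non-normal class is called when its mean probability reaches the
#' decision threshold, otherwise the highest-probability class is called.
#'
#' @param model a `diagnosis_model`.
#' @param z factor matrix (segments x latent_dim).
#' @param recording_ids recording identifier per segment.
#' @param subject_ids optional, for the leakage check.
#' @return data frame with one row per recording: mean probability per
#'   class and the called `class`.
#' @export
predict_diagnosis <- function(model, z, recording_ids,
                              subject_ids = NULL) {
  stopifnot(inherits(model, "diagnosis_model"))
  z <- as.matrix(z)
  if (!is.null(subject_ids) && length(model$fit_metadata$subjects) > 0) {
    overlap <- intersect(unique(subject_ids), model$fit_metadata$subjects)
    if (length(overlap) > 0)
      stopf("subject leakage: %d subject(s) appear in both fit and predict",
            length(overlap))
  }
  df <- data.frame(z)
  colnames(df) <- colnames(stats::model.frame(model$fit))[-1][seq_len(ncol(z))]
  probs <- stats::predict(model$fit, newdata = df, type = "probs")
  if (is.null(dim(probs))) { # two-class fits return P(second level)
    probs <- cbind(1 - probs, probs)
    colnames(probs) <- model$classes
  }
  # normalize to the full class set so outputs are fold-invariant
  full <- matrix(0, nrow(probs), length(RHYTHM_CLASSES),
                 dimnames = list(NULL, RHYTHM_CLASSES))
  full[, colnames(probs)] <- probs
  probs <- full
  agg <- stats::aggregate(probs, by = list(recording = recording_ids), FUN = mean)
  prob_cols <- as.matrix(agg[, -1, drop = FALSE])
  call <- vapply(seq_len(nrow(agg)), function(i) {
    p <- prob_cols[i, ]
    abn <- setdiff(colnames(prob_cols), "NORMAL")
    hit <- abn[p[abn] >= model$decision_threshold]
    if (length(hit) > 0) hit[which.max(p[hit])] else colnames(prob_cols)[which.max(p)]
  }, character(1))
  out <- data.frame(recording = agg$recording, prob_cols, class = call,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-factor attribution of a diagnosis model
#'
#' Decision-pathway view: coefficient x factor-SD per class, so every call
#' can be traced to the semantic factors that drive it.
#'
#' @param model a `diagnosis_model`.
#' @return matrix (classes-1 x factors) of scaled attributions.
#' @export
diagnosis_attribution <- function(model) {
  co <- stats::coef(model$fit)
  if (is.null(dim(co))) co <- matrix(co, 1, dimnames = list(model$classes[2], names(co)))
  co <- co[, -1, drop = FALSE] # drop intercept
  sweep(co, 2, model$feature_sd, "*")
}

#' Index of the factor most correlated with a semantic quantity
#'
#' Largest absolute Pearson correlation; constant factors are excluded
#' (their correlation is undefined); ties break to the lowest index.
#'
#' @param z factor matrix (n x latent_dim, n >= 3).
#' @param values semantic values, length n.
#' @return list with `index` and `correlation`.
#' @export
top_correlated_factor <- function(z, values) {
  z <- as.matrix(z)
  if (nrow(z) < 3) stopf("need n >= 3")
  r <- vapply(seq_len(ncol(z)), function(j) {
    if (stats::sd(z[, j]) < 1e-15) return(NA_real_)
    stats::cor(z[, j], values)
  }, numeric(1))
  if (all(is.na(r))) stopf("all factors constant")
  idx <- which.max(abs(r)) # which.max is tie-stable toward the lowest index
  list(index = idx, correlation = r[idx])
}

#' Decode a factor perturbation sweep through both modalities
#'
#' Replaces one factor of a latent vector by each value in `scales` and
#' decodes through the frozen ECG and radio decoders, visualizing how that
#' factor drives signal patterns in both modalities.
#'
#' @param z a `semantic_factors` (first row used) or latent vector.
#' @param index factor index to sweep (1-based, <= latent_dim).
#' @param scales numeric vector of replacement values.
#' @param ecg_model frozen `ecg_vae`.
#' @param radio_model frozen `radio_model`.
#' @return list (one element per scale) of lists with `scale`, `ecg_view`
#'   (vector, mV) and `radio_view` (voxels x frames).
#' @export
perturb_factor <- function(z, index, scales, ecg_model, radio_model) {
  z <- factors_matrix(z, ecg_model$config$latent_dim)[1, ]
  if (radio_model$config$latent_dim != ecg_model$config$latent_dim)
    stopf("frozen-model latent dimensions do not match")
  if (index < 1 || index > length(z)) stopf("factor index out of range")
  lapply(scales, function(s) {
    zi <- z
    zi[index] <- s
    xm_hat <- nn_forward(radio_model$dec, matrix(zi, 1))$out
    list(scale = s,
         ecg_view = ecg_decode(ecg_model, zi)[1, ],
         radio_view = radio_from_model_space(xm_hat, radio_model$config)[1, , ])
  })
}

#' Serialize / load readout and diagnosis models as JSON
#'
#' @param model a `linear_readout` or `diagnosis_model`.
#' @param path JSON file path.
#' @return `save_model_json` returns `path`; `load_readout_json` returns a
#'   `linear_readout`.
#' @export
save_model_json <- function(model, path) {
  if (inherits(model, "linear_readout")) {
    obj <- list(type = "linear_readout", weights = model$weights,
                target_names = model$target_names)
  } else if (inherits(model, "diagnosis_model")) {
    co <- stats::coef(model$fit)
    obj <- list(type = "diagnosis_model", coefficients = co,
                classes = model$classes,
                decision_threshold = model$decision_threshold)
  } else stopf("unsupported model type")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_readout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "linear_readout")) stopf("not a linear_readout JSON")
  w <- as.matrix(obj$weights)
  colnames(w) <- obj$target_names
  structure(list(weights = w, target_names = obj$target_names,
                 fit_metadata = list()),
            class = "linear_readout")
}
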