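#' Repeated stratified 2-fold cross-validation
#'
#' Per repeat, samples are split into two stratified folds (each class
#' halved at random); the model is fitted on one fold and predicts the
#' other, both ways. Squared prediction errors (PRESS) accumulate over all
#' repeats and `Q2 = 1 - PRESS / (n_repeats x SS(y))` with `y` the centered
#' encoded response. Out-of-fold predictions are averaged per sample over
#' repeats; these averaged predictions feed the ROC.
#'
#' @param B scaled [binned_matrix()] or numeric matrix.
#' @param y two-level class labels aligned with rows.
#' @param n_ortho orthogonal components per fold model.
#' @param n_repeats number of random 2-fold repeats.
#' @param seed integer seed for the fold draws.
#' @return list with `q2`, `predictions` (per-sample averaged out-of-fold
#'   `y_hat`), `labels`, `n_repeats`, `seed`.
#' @export
cross_validate <- function(B, y, n_ortho = 1L, n_repeats = 50L, seed = 1L) {
  X <- if (inherits(B, "binned_matrix")) B$values else as.matrix(B)
  if (is.null(attr(y, "positive"))) y <- encode_classes(y)
  n <- nrow(X)
  cls <- y > 0
  if (sum(cls) < 2L || sum(!cls) < 2L)
    stop_nmropls("each class needs at least 2 samples for 2-fold CV")
  ssy <- sum(y^2)
  press <- 0
  pred_sum <- numeric(n)
  pred_n <- numeric(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 37L))
  for (r in seq_len(n_repeats)) {
    fold <- .stratified_2fold(cls)
    for (f in 1:2) {
      test <- fold == f
      m <- fit_oplsda(X[!test, , drop = FALSE], .subset_y(y, !test),
                      n_ortho = n_ortho)
      ph <- predict(m, X[test, , drop = FALSE])$y_hat
      press <- press + sum((y[test] - ph)^2)
      pred_sum[test] <- pred_sum[test] + ph
      pred_n[test] <- pred_n[test] + 1
    }
  }
  list(q2 = 1 - press / (n_repeats * ssy),
       predictions = stats::setNames(pred_sum / pred_n,
                                     rownames(X) %||% seq_len(n)),
       labels = ifelse(cls, attr(y, "positive"),
                       setdiff(attr(y, "levels"), attr(y, "positive"))),
       n_repeats = n_repeats, seed = seed)
}

# random stratified assignment of each class's samples to folds 1/2
.stratified_2fold <- function(cls, max_retry = 10L) {
  n <- length(cls)
  for (try in seq_len(max_retry)) {
    fold <- integer(n)
    for (v in c(TRUE, FALSE)) {
      idx <- which(cls == v)
      idx <- sample(idx)
      half <- floor(length(idx) / 2)
      # odd class sizes: the extra sample lands in a random fold
      cut <- half + (length(idx) %% 2L) * sample(0:1, 1)
      fold[idx] <- c(rep(1L, cut), rep(2L, length(idx) - cut))
    }
    ok <- all(vapply(1:2, function(f)
      length(unique(cls[fold == f])) == 2L, TRUE))
    if (ok) return(fold)
  }
  stop_nmropls("could not build stratified folds containing both classes")
}

# subset an encoded response, re-centering and keeping encoding attributes
.subset_y <- function(y, keep) {
  raw <- ifelse(y > 0, attr(y, "positive"),
                setdiff(attr(y, "levels"), attr(y, "positive")))
  encode_classes(raw[keep], positive = attr(y, "positive"))
}

#' Model-quality label from Q2
#'
#' Chemometric convention for OPLS-DA models: Q2 above 0.70 is robust,
#' above 0.40 good, otherwise poor (strict inequalities).
#'
#' @param q2 cross-validated Q2.
#' @return `"robust"`, `"good"` or `"poor"`.
#' @export
quality_label <- function(q2) {
  stopifnot(is.numeric(q2), length(q2) == 1L)
  if (q2 > 0.70) "robust" else if (q2 > 0.40) "good" else "poor"
}

#' Label-permutation test with R2/Q2 regression intercepts
#'
#' Refits the model under `n_perm` random permutations of the class labels,
#' recording each permuted model's training R2, cross-validated Q2 and the
#' absolute Pearson correlation of the permuted with the original encoded
#' response. Two ordinary-least-squares lines are fitted through the
#' (correlation, R2) and (correlation, Q2) points, including the unpermuted
#' model at correlation 1; their intercepts at correlation 0 diagnose
#' overfitting. The model is declared valid when the Q2 intercept is below
#' 0.05 and every permuted Q2 falls below the actual Q2.
#'
#' @param B scaled [binned_matrix()] or numeric matrix.
#' @param y two-level class labels.
#' @param n_perm number of permutations (>= 10).
#' @param n_ortho orthogonal components (same for all refits).
#' @param cv_repeats CV repeats used for each permuted Q2.
#' @param seed integer seed.
#' @return list with `records` (data.frame correlation/r2/q2, first row the
#'   unpermuted model), `r2_intercept`, `q2_intercept`, `r2_actual`,
#'   `q2_actual`, `p_value` (empirical, `(1 + #{Q2_perm >= Q2}) /
#'   (n_perm + 1)`), `valid`.
#' @export
permutation_test <- function(B, y, n_perm = 200L, n_ortho = 1L,
                             cv_repeats = 10L, seed = 1L) {
  if (n_perm < 10L) stop_nmropls("n_perm must be >= 10")
  X <- if (inherits(B, "binned_matrix")) B$values else as.matrix(B)
  if (is.null(attr(y, "positive"))) y <- encode_classes(y)
  if (stats::var(y) == 0) stop_nmropls("response has zero variance")
  raw <- ifelse(y > 0, attr(y, "positive"),
                setdiff(attr(y, "levels"), attr(y, "positive")))

  m0 <- fit_oplsda(X, y, n_ortho = n_ortho)
  cv0 <- cross_validate(X, y, n_ortho = n_ortho, n_repeats = cv_repeats,
                        seed = derive_seed(seed, 41L))
  recs <- data.frame(correlation = 1, r2 = m0$r2y, q2 = cv0$q2)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 43L))
  perm_seeds <- sample.int(2^31 - 2, n_perm)
  for (k in seq_len(n_perm)) {
    yp_raw <- sample(raw)
    yp <- encode_classes(yp_raw, positive = attr(y, "positive"))
    mk <- fit_oplsda(X, yp, n_ortho = n_ortho)
    cvk <- cross_validate(X, yp, n_ortho = n_ortho, n_repeats = cv_repeats,
                          seed = perm_seeds[k])
    recs <- rbind(recs, data.frame(
      correlation = abs(stats::cor(as.numeric(y), as.numeric(yp))),
      r2 = mk$r2y, q2 = cvk$q2))
  }
  fit_r2 <- stats::lm(r2 ~ correlation, data = recs)
  fit_q2 <- stats::lm(q2 ~ correlation, data = recs)
  q2_perm <- recs$q2[-1]
  list(records = recs,
       r2_intercept = unname(stats::coef(fit_r2)[1]),
       q2_intercept = unname(stats::coef(fit_q2)[1]),
       r2_actual = m0$r2y, q2_actual = cv0$q2,
       p_value = (1 + sum(q2_perm >= cv0$q2)) / (n_perm + 1),
       valid = unname(stats::coef(fit_q2)[1]) < 0.05 &&
         all(q2_perm < cv0$q2),
       n_perm = n_perm, seed = seed)
}

#' ROC curve and AUROC from prediction scores
#'
#' The ROC is swept over the unique prediction values as thresholds; the
#' AUROC is computed by pair counting (the fraction of (positive, negative)
#' pairs ordered correctly, ties counted one half) — the Mann-Whitney
#' statistic, which equals the trapezoidal area under the swept curve.
#' AUROC 1 is perfect discrimination, 0.5 random classification.
#'
#' @param predictions numeric scores (higher = more positive-like).
#' @param labels class labels aligned with predictions.
#' @param positive label counted as positive (default: the level whose mean
#'   prediction convention follows [encode_classes()], i.e. the second
#'   sorted level).
#' @return list with `roc` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auroc`.
#' @export
roc_auroc <- function(predictions, labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stop_nmropls("ROC needs both classes present, got %d level(s)",
                 length(lev))
  positive <- positive %||% lev[2L]
  pos <- labels == positive
  np <- sum(pos); nn <- sum(!pos)
  # pair counting via midranks: U statistic
  r <- rank(predictions)
  auroc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  thr <- c(Inf, sort(unique(predictions), decreasing = TRUE))
  roc <- data.frame(threshold = thr,
                    fpr = vapply(thr, function(th)
                      sum(predictions[!pos] >= th) / nn, 0),
                    tpr = vapply(thr, function(th)
                      sum(predictions[pos] >= th) / np, 0))
  list(roc = roc, auroc = auroc, positive = positive)
}

#' Full validation report for one comparison
#'
#' Bundles training R2, cross-validated Q2 with quality label, the
#' permutation records and intercepts, and the ROC/AUROC computed from the
#' averaged out-of-fold predictions.
#'
#' @param B scaled [binned_matrix()].
#' @param y two-level class labels.
#' @param n_ortho orthogonal components.
#' @param n_repeats CV repeats for the headline Q2 and the ROC predictions.
#' @param n_perm permutations.
#' @param perm_cv_repeats CV repeats inside the permutation loop.
#' @param seed integer seed.
#' @return a list of class `validation_report`.
#' @export
validate_model <- function(B, y, n_ortho = 1L, n_repeats = 50L,
                           n_perm = 200L, perm_cv_repeats = 10L, seed = 1L) {
  if (is.null(attr(y, "positive"))) y <- encode_classes(y)
  model <- fit_oplsda(B, y, n_ortho = n_ortho)
  cv <- cross_validate(B, y, n_ortho = n_ortho, n_repeats = n_repeats,
                       seed = derive_seed(seed, 3L))
  perm <- permutation_test(B, y, n_perm = n_perm, n_ortho = n_ortho,
                           cv_repeats = perm_cv_repeats,
                           seed = derive_seed(seed, 5L))
  roc <- roc_auroc(cv$predictions, cv$labels,
                   positive = attr(y, "positive"))
  structure(list(
    r2 = model$r2y, q2 = cv$q2, quality = quality_label(cv$q2),
    permutation = perm, roc = roc$roc, auroc = roc$auroc,
    cv = cv, n_repeats = n_repeats, n_perm = n_perm, seed = seed
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> R2 = %.3f, Q2 = %.3f (%s), AUROC = %.3f\n  permutation: Q2 intercept %.3f, p = %.4g, %s\n",
    x$r2, x$q2, x$quality, x$auroc, x$permutation$q2_intercept,
    x$permutation$p_value,
    if (x$permutation$valid) "valid" else "not valid"))
  invisible(x)
}
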