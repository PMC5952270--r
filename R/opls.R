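#' Encode a two-class response
#'
#' Maps a two-level class label vector to the mean-centered +1/-1 encoding
#' used by two-class PLS-DA.
#'
#' @param labels factor or character vector with exactly two levels, both
#'   present.
#' @param positive label to encode as +1 (default: second sorted level).
#' @return numeric vector with attributes `levels` and `positive`.
#' @export
encode_classes <- function(labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stop_nmropls("class vector must have exactly two levels, got %d",
                 length(lev))
  positive <- positive %||% lev[2L]
  if (!positive %in% lev)
    stop_nmropls("positive class '%s' not among levels", positive)
  y <- ifelse(labels == positive, 1, -1)
  y <- y - mean(y)
  attr(y, "levels") <- lev
  attr(y, "positive") <- positive
  y
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures: each orthogonal round
#' computes the PLS weight `w = X'y / ||X'y||`, scores `t = Xw`, loading
#' `p = X't/(t't)`, then the orthogonal weight `w_o = p - (w'p) w`
#' (normalized), orthogonal scores `t_o = X w_o`, orthogonal loading
#' `p_o = X't_o/(t_o't_o)`, and deflates `X <- X - t_o p_o'`. After
#' `n_ortho` rounds a final predictive component is computed on the
#' filtered matrix. With `n_ortho = 0` this reduces to one-component
#' NIPALS PLS1.
#'
#' @param B a centered, pareto-scaled [binned_matrix()] (the `scaled`
#'   provenance flag must be set), or a plain centered numeric matrix.
#' @param y class labels (two levels) aligned with the rows of `B`, or an
#'   [encode_classes()] result.
#' @param n_ortho number of orthogonal components (>= 0).
#' @return an object of class `opls_model` with predictive weights/scores/
#'   loadings, orthogonal triplets, per-bin covariance and correlation with
#'   the predictive scores, and training R2X/R2Y.
#' @export
fit_oplsda <- function(B, y, n_ortho = 1L) {
  if (inherits(B, "binned_matrix")) {
    if (!B$scaled)
      stop_nmropls("OPLS-DA expects a centered/scaled matrix; run center_and_pareto_scale()")
    X <- B$values
    centers <- B$centers
    original_sd <- B$original_sd
  } else {
    X <- as.matrix(B)
    centers <- seq_len(ncol(X))
    original_sd <- rep(1, ncol(X))
  }
  if (is.null(attr(y, "positive"))) y <- encode_classes(y)
  if (length(y) != nrow(X))
    stop_nmropls("response length %d does not match %d samples",
                 length(y), nrow(X))
  if (stats::var(y) == 0) stop_nmropls("response has zero variance")
  rk <- qr(X)$rank
  if (n_ortho >= rk)
    stop_nmropls("n_ortho (%d) must be below the rank of X (%d)", n_ortho, rk)

  X0 <- X
  Wo <- To <- Po <- NULL
  E <- X
  for (k in seq_len(n_ortho)) {
    w <- crossprod(E, y)[, 1]
    w <- w / sqrt(sum(w^2))
    t <- E %*% w
    p <- crossprod(E, t)[, 1] / sum(t^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12)
      stop_nmropls("orthogonal component %d is degenerate (no orthogonal variation left)", k)
    wo <- wo / nwo
    to <- E %*% wo
    po <- crossprod(E, to)[, 1] / sum(to^2)
    E <- E - to %*% t(po)
    Wo <- cbind(Wo, wo); To <- cbind(To, to); Po <- cbind(Po, po)
  }
  w <- crossprod(E, y)[, 1]
  w <- w / sqrt(sum(w^2))
  t <- (E %*% w)[, 1]
  p <- crossprod(E, t)[, 1] / sum(t^2)
  cq <- sum(y * t) / sum(t^2)          # response loading
  yhat <- t * cq
  r2y <- 1 - sum((y - yhat)^2) / sum(y^2)
  ssx <- sum(X0^2)
  expl <- sum((t %*% t(p))^2)
  if (n_ortho > 0)
    expl <- expl + sum(vapply(seq_len(n_ortho), function(k)
      sum((To[, k] %*% t(Po[, k]))^2), 0))
  r2x <- expl / ssx

  # per-bin correlation/covariance of the predictive score with the
  # (unfiltered) data; covariance back-scaled to the pre-pareto scale
  n <- nrow(X)
  sds <- apply(X0, 2, stats::sd)
  covs <- crossprod(X0, t - mean(t))[, 1] / (n - 1)
  corr <- ifelse(sds > 0, covs / (sds * stats::sd(t)), 0)
  cov_back <- covs * sqrt(original_sd)

  structure(list(
    weights = w, scores = t, loadings = p, response_loading = cq,
    ortho_weights = Wo, ortho_scores = To, ortho_loadings = Po,
    n_ortho = n_ortho, r2x = r2x, r2y = r2y,
    correlation = corr, covariance = cov_back,
    centers = centers, original_sd = original_sd,
    degenerate_bins = sds == 0,
    y = as.numeric(y), levels = attr(y, "levels"),
    positive = attr(y, "positive"),
    sample_ids = rownames(X)
  ), class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "<opls_model> 1 predictive + %d orthogonal component(s), %d bins\n  R2X = %.3f, R2Y = %.3f (%s vs %s)\n",
    x$n_ortho, length(x$weights), x$r2x, x$r2y, x$levels[1], x$levels[2]))
  invisible(x)
}

#' Predict scores and class from an OPLS-DA model
#'
#' Removes the model's orthogonal variation from new (identically
#' preprocessed) data, then projects onto the predictive weight. The
#' predicted response is `t_new x response loading`; class by sign.
#'
#' @param object an `opls_model`.
#' @param newdata a [binned_matrix()] or numeric matrix with the model's
#'   columns, preprocessed with the training pipeline's constants.
#' @param ... ignored.
#' @return data.frame with `sample_id`, predictive score `t`, first
#'   orthogonal score `t_ortho` (0 when `n_ortho = 0`), predicted response
#'   `y_hat`, and `class`.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "binned_matrix")) newdata$values
       else as.matrix(newdata)
  if (ncol(X) != length(object$weights))
    stop_nmropls("newdata has %d columns but the model was fitted on %d",
                 ncol(X), length(object$weights))
  E <- X
  t_o1 <- rep(0, nrow(X))
  if (object$n_ortho > 0) {
    for (k in seq_len(object$n_ortho)) {
      to <- E %*% object$ortho_weights[, k]
      if (k == 1L) t_o1 <- to[, 1]
      E <- E - to %*% t(object$ortho_loadings[, k])
    }
  }
  t_new <- (E %*% object$weights)[, 1]
  y_hat <- t_new * object$response_loading
  cls <- ifelse(y_hat >= 0, object$positive,
                setdiff(object$levels, object$positive))
  data.frame(sample_id = rownames(X) %||% seq_len(nrow(X)),
             t = t_new, t_ortho = t_o1, y_hat = y_hat, class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' S-plot table
#'
#' One row per retained bin with the covariance (back-scaled to the
#' pre-pareto intensity scale) and Pearson correlation of the bin with the
#' predictive score. Zero-variance bins carry covariance and correlation 0
#' and are flagged degenerate. High |covariance| with high |correlation|
#' marks reliable, high-magnitude discriminating bins.
#'
#' @param model a fitted `opls_model`.
#' @return data.frame with columns `ppm`, `covariance`, `correlation`,
#'   `degenerate`.
#' @export
splot <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  data.frame(ppm = model$centers,
             covariance = ifelse(model$degenerate_bins, 0, model$covariance),
             correlation = model$correlation,
             degenerate = model$degenerate_bins,
             row.names = NULL)
}

#' Mean score trajectories over collection periods
#'
#' Averages the predictive and first orthogonal scores per (group, period)
#' cell, ordered T1 -> T8, for trajectory plots of longitudinal group
#' movement in score space. Empty cells are omitted with a warning.
#'
#' @param scores data.frame with `sample_id`, `t`, `t_ortho` (e.g. from
#'   [predict.opls_model()] or built from a model's training scores).
#' @param metadata data.frame with `sample_id`, `group`, `period`.
#' @param groups groups to include (default: all in metadata).
#' @param periods period order (default T1..T8 intersected with metadata).
#' @return data.frame `group`, `period`, `t`, `t_ortho`, `n`.
#' @export
trajectory <- function(scores, metadata, groups = NULL, periods = NULL) {
  m <- merge(scores, metadata, by = "sample_id")
  if (nrow(m) < nrow(scores))
    stop_nmropls("samples missing group/period metadata: %s",
                 paste(setdiff(scores$sample_id, metadata$sample_id),
                       collapse = ", "))
  groups <- groups %||% unique(m$group)
  periods <- periods %||% intersect(paste0("T", 1:8), unique(m$period))
  out <- expand.grid(group = groups, period = periods,
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    sel <- m$group == out$group[i] & m$period == out$period[i]
    if (!any(sel)) return(NULL)
    data.frame(group = out$group[i], period = out$period[i],
               t = mean(m$t[sel]), t_ortho = mean(m$t_ortho[sel]),
               n = sum(sel), stringsAsFactors = FALSE)
  })
  empty <- vapply(res, is.null, TRUE)
  if (any(empty))
    warning(sprintf("%d empty (group, period) cell(s) omitted", sum(empty)))
  out <- do.call(rbind, res[!empty])
  out[order(match(out$group, groups), match(out$period, periods)), ,
      drop = FALSE]
}

#' Training scores of a fitted model as a data.frame
#'
#' @param model a fitted `opls_model`.
#' @return data.frame `sample_id`, `t`, `t_ortho`.
#' @export
opls_scores <- function(model) {
  data.frame(sample_id = model$sample_ids %||%
               seq_along(model$scores),
             t = model$scores,
             t_ortho = if (model$n_ortho > 0) model$ortho_scores[, 1]
                       else rep(0, length(model$scores)),
             row.names = NULL, stringsAsFactors = FALSE)
}
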