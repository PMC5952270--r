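# Independent oracles used to freeze expected values; deliberately written
# with different algorithms than the package code paths they check.

# Textbook iterative NIPALS PLS1 (single component), looping u/w/t/c until
# the score vector stabilizes.
pls1_nipals_oracle <- function(X, y, tol = 1e-12, max_iter = 500) {
  X <- as.matrix(X)
  u <- y
  t_old <- rep(Inf, nrow(X))
  for (it in seq_len(max_iter)) {
    w <- crossprod(X, u)[, 1] / sum(u^2)
    w <- w / sqrt(sum(w^2))
    t <- (X %*% w)[, 1]
    c <- sum(y * t) / sum(t^2)
    u <- y * c / c^2
    if (sqrt(sum((t - t_old)^2)) < tol) break
    t_old <- t
  }
  p <- crossprod(X, t)[, 1] / sum(t^2)
  list(w = w, t = t, p = p, c = c)
}

# Trapezoidal area under an ROC polygon given (fpr, tpr) points sorted from
# (0,0) to (1,1).
trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  fpr <- roc$fpr[o]; tpr <- roc$tpr[o]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Brute-force AUROC by explicit enumeration of all (positive, negative)
# pairs, ties counted one half.
pairwise_auc <- function(pred, labels, positive) {
  pos <- pred[labels == positive]
  neg <- pred[labels != positive]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Small two-group cohort used across tests. Effects are planted in group
# "TAA" on spectrally isolated metabolites so window crosstalk cannot blur
# ground truth.
isolated_metabolites <- c("citrate", "alanine", "acetate", "glycine",
                          "formate")

make_two_group_cohort <- function(seed = 1, n_subjects = 3,
                                  periods = paste0("T", 1:4),
                                  fold = 2, metabolites = isolated_metabolites,
                                  noise = noise_model(), ppm_step = 0.004,
                                  groups = c("NC", "TAA")) {
  design <- cohort_design(groups = groups, n_subjects = n_subjects,
                          periods = periods)
  lib <- build_default_library(seed)
  effects <- if (fold == 1 || length(metabolites) == 0) NULL else
    do.call(rbind, lapply(metabolites, function(m)
      effect_spec(m, groups[2], fold, periods)))
  cohort <- generate_cohort(design, lib, effects, noise,
                            ppm_step = ppm_step, seed = seed)
  cohort$library <- lib
  cohort$windows <- metabolite_windows(lib)
  cohort
}

# Flat synthetic spectrum with one Gaussian-free Lorentzian-free triangle
# peak; handy for alignment tests.
triangle_spectrum <- function(ppm, center, halfwidth, height = 1) {
  pmax(0, height * (1 - abs(ppm - center) / halfwidth))
}
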