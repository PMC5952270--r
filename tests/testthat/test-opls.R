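scaled_bm <- function(X) {
  # wrap a plain matrix as a scaled binned_matrix with unit original SDs
  binned_matrix(seq(0, ncol(X) / 10, 0.1), seq_len(ncol(X)) / 10 - 0.05,
                X, normalized = TRUE, scaled = TRUE,
                original_sd = rep(1, ncol(X)),
                column_means = rep(0, ncol(X)))
}

centered <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  scale(X, scale = FALSE)
}

test_that("OPLS-DA with zero orthogonal components equals NIPALS PLS1", {
  X <- centered(20, 15, 1)
  y <- encode_classes(rep(c("A", "B"), each = 10))
  m <- fit_oplsda(X, y, n_ortho = 0)
  o <- pls1_nipals_oracle(X, as.numeric(y))
  expect_equal(m$scores, o$t, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(abs(sum(m$weights * o$w)), 1, tolerance = 1e-8)
  expect_equal(m$loadings, o$p, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(m$response_loading, o$c, tolerance = 1e-8)
})

test_that("the informative column dominates the score correlations", {
  set.seed(2)
  y <- encode_classes(rep(c("A", "B"), each = 12))
  X <- cbind(as.numeric(y) + stats::rnorm(24, 0, 0.1),
             matrix(stats::rnorm(24 * 30), 24, 30))
  X <- scale(X, scale = FALSE)
  m <- fit_oplsda(X, y, n_ortho = 1)
  expect_equal(which.max(abs(m$correlation)), 1L)
})

test_that("fitted models satisfy the orthogonality and normalization identities", {
  for (seed in 1:5) {
    X <- centered(18, 25, seed)
    y <- encode_classes(rep(c("A", "B"), each = 9))
    m <- fit_oplsda(X, y, n_ortho = 2)
    expect_equal(sum(m$weights^2), 1, tolerance = 1e-10)
    for (k in 1:2) {
      expect_equal(sum(m$ortho_weights[, k]^2), 1, tolerance = 1e-10)
      expect_lt(abs(sum(m$scores * m$ortho_scores[, k])), 1e-8)
      expect_lt(abs(sum(as.numeric(y) * m$ortho_scores[, k])), 1e-8)
    }
    expect_true(all(abs(m$correlation) <= 1 + 1e-12))
  }
})

test_that("predict reproduces training scores and respects row duplication", {
  X <- centered(16, 12, 3)
  y <- encode_classes(rep(c("A", "B"), each = 8))
  m <- fit_oplsda(X, y, n_ortho = 1)
  pr <- predict(m, X)
  expect_equal(pr$t, m$scores, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(pr$y_hat, m$scores * m$response_loading, tolerance = 1e-10)
  dup <- X[c(1, 1, 5, 5), ]
  prd <- predict(m, dup)
  expect_equal(prd$t[1], prd$t[2])
  expect_equal(prd$y_hat[3], prd$y_hat[4])
  expect_error(predict(m, X[, 1:5]), "columns")
})

test_that("scores are invariant to column permutation", {
  X <- centered(14, 20, 4)
  y <- encode_classes(rep(c("A", "B"), each = 7))
  m1 <- fit_oplsda(X, y, n_ortho = 1)
  perm <- sample(ncol(X))
  m2 <- fit_oplsda(X[, perm], y, n_ortho = 1)
  expect_equal(m1$scores, m2$scores, tolerance = 1e-8)
  expect_equal(m1$weights[perm], m2$weights, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("adding an orthogonal component never decreases training R2Y", {
  for (seed in 1:4) {
    X <- centered(20, 30, 10 + seed)
    y <- encode_classes(rep(c("A", "B"), each = 10))
    r2 <- vapply(0:3, function(k) fit_oplsda(X, y, n_ortho = k)$r2y, 0)
    expect_true(all(diff(r2) >= -1e-10))
  }
})

test_that("degenerate inputs are rejected", {
  X <- centered(10, 8, 5)
  expect_error(fit_oplsda(X, encode_classes(rep(c("A", "B"), each = 5)),
                          n_ortho = 50), "rank")
  expect_error(encode_classes(rep("A", 10)), "two levels")
  B <- binned_matrix(seq(0, 0.8, 0.1), seq(0.05, 0.75, 0.1),
                     matrix(stats::rnorm(40), 5, 8), normalized = TRUE,
                     scaled = FALSE)
  expect_error(fit_oplsda(B, rep(c("A", "B"), c(2, 3))), "scaled")
})

test_that("the predictive weight recovers a planted discriminant direction", {
  set.seed(6)
  n <- 40; p <- 60
  y <- encode_classes(rep(c("A", "B"), each = n / 2))
  dir <- stats::rnorm(p); dir <- dir / sqrt(sum(dir^2))
  ortho <- stats::rnorm(p); ortho <- ortho - sum(ortho * dir) * dir
  ortho <- ortho / sqrt(sum(ortho^2))
  X <- as.numeric(y) %*% t(dir) * 3 +
    stats::rnorm(n) %*% t(ortho) * 2 +
    matrix(stats::rnorm(n * p, 0, 0.3), n, p)
  X <- scale(X, scale = FALSE)
  m <- fit_oplsda(X, y, n_ortho = 1)
  cosine <- abs(sum(m$weights * dir))
  expect_gt(cosine, 0.95)
})

test_that("S-plot matches per-bin Pearson correlations and flags degenerate bins", {
  X <- centered(16, 10, 7)
  X[, 4] <- 0
  y <- encode_classes(rep(c("A", "B"), each = 8))
  B <- binned_matrix(seq(0, 1, 0.1), seq(0.05, 0.95, 0.1), X,
                     normalized = TRUE, scaled = TRUE,
                     original_sd = rep(2, 10), column_means = rep(0, 10))
  m <- fit_oplsda(B, y, n_ortho = 1)
  sp <- splot(m)
  for (j in setdiff(1:10, 4))
    expect_equal(sp$correlation[j], stats::cor(m$scores, X[, j]),
                 tolerance = 1e-10)
  expect_true(sp$degenerate[4])
  expect_equal(sp$covariance[4], 0)
  expect_equal(sp$correlation[4], 0)
  # with a single column, t is collinear with it and |corr| = 1
  m1 <- fit_oplsda(X[, 1, drop = FALSE], y, n_ortho = 0)
  expect_equal(abs(splot(m1)$correlation[1]), 1, tolerance = 1e-10)
})

test_that("trajectories average scores per (group, period) in period order", {
  sc <- data.frame(sample_id = c("a1", "a2", "b1"),
                   t = c(1, 3, -2), t_ortho = c(2, -2, 5))
  meta <- data.frame(sample_id = c("a1", "a2", "b1"),
                     group = c("G", "G", "H"),
                     period = c("T1", "T1", "T2"))
  expect_warning(tr <- trajectory(sc, meta), "empty")
  expect_equal(tr$t[tr$group == "G" & tr$period == "T1"], 2)
  expect_equal(tr$t_ortho[tr$group == "G" & tr$period == "T1"], 0)
  expect_equal(tr$t[tr$group == "H" & tr$period == "T2"], -2)
})

test_that("a decaying planted effect moves the trajectory toward the control centroid", {
  folds <- c(T1 = 3, T2 = 2.2, T3 = 1.6, T4 = 1)
  eff <- do.call(rbind, lapply(isolated_metabolites, function(m)
    effect_spec(m, "TAA", folds, names(folds))))
  design <- cohort_design(groups = c("NC", "TAA"), n_subjects = 6,
                          periods = names(folds))
  lib <- build_default_library(3)
  coh <- generate_cohort(design, lib, eff, noise_model(),
                         ppm_step = 0.004, seed = 3)
  B <- preprocess_spectra(coh$spectra, align = FALSE)
  m <- fit_oplsda(B, encode_classes(coh$metadata$group, positive = "TAA"),
                  n_ortho = 1)
  tr <- trajectory(opls_scores(m), coh$metadata)
  sep <- vapply(names(folds), function(p)
    abs(tr$t[tr$group == "TAA" & tr$period == p] -
          tr$t[tr$group == "NC" & tr$period == p]), 0)
  expect_gt(sep["T1"], sep["T4"])
  expect_true(all(diff(sep) < 0))
})
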