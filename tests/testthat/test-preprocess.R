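make_sm <- function(ppm, rows) {
  M <- do.call(rbind, rows)
  rownames(M) <- paste0("smp", seq_len(nrow(M)))
  spectral_matrix(ppm, M)
}

test_that("alignment is the identity for self-similar or unshifted input", {
  ppm <- seq(0.5, 9.8, by = 0.01)
  base <- triangle_spectrum(ppm, 3.0, 0.1) + triangle_spectrum(ppm, 7.0, 0.1)
  X <- make_sm(ppm, list(base, base))
  expect_equal(align_spectra(X)$intensities, X$intensities)
  shifted <- c(base[-(1:3)], rep(base[length(base)], 3))
  X2 <- make_sm(ppm, list(base, shifted))
  expect_equal(align_spectra(X2, max_shift_ppm = 0)$intensities,
               X2$intensities)
})

test_that("alignment recovers a known integer-point shift", {
  ppm <- seq(0.5, 9.8, by = 0.01)
  base <- triangle_spectrum(ppm, 3.05, 0.08)
  for (k in c(1L, 2L)) {
    shifted <- c(rep(0, k), base[seq_len(length(base) - k)])
    X <- make_sm(ppm, list(base, shifted))
    al <- align_spectra(X, segment_ppm = 0.6, max_shift_ppm = 0.03,
                        reference = 1)
    # brute-force best lag against the reference over the peak segment
    win <- ppm > 2.7 & ppm < 3.4
    expect_lt(sum((al$intensities[2, win] - base[win])^2),
              sum((X$intensities[2, win] - base[win])^2) / 100)
  }
})

test_that("alignment rejects segments below 3 grid points", {
  ppm <- seq(0.5, 9.8, by = 0.01)
  X <- make_sm(ppm, list(stats::runif(length(ppm))))
  expect_error(align_spectra(X, segment_ppm = 0.02), "3 grid points")
})

test_that("exclusion removes exactly the closed interval and keeps order", {
  ppm <- seq(0.5, 9.8, by = 0.01)
  X <- make_sm(ppm, list(seq_along(ppm), rev(seq_along(ppm))))
  ex <- exclude_regions(X, list(c(4.2, 5.9)))
  expect_false(any(ex$ppm >= 4.2 & ex$ppm <= 5.9))
  expect_true(all(diff(ex$ppm) > 0))
  kept <- !(ppm >= 4.2 & ppm <= 5.9)
  expect_equal(ex$intensities[1, ], X$intensities[1, kept])
  # no-op and degenerate cases
  expect_identical(exclude_regions(X, list()), X)
  expect_error(exclude_regions(X, list(c(0, 10))), "every point")
})

test_that("binning tiles the range with half-open bins and conserves totals", {
  ppm <- seq(0.5, 9.8, by = 0.01)
  set.seed(42)
  X <- make_sm(ppm, list(stats::runif(length(ppm)),
                         stats::runif(length(ppm))))
  B <- bin_spectra(X, c(0.5, 9.8), 0.04)
  # brute-force tiling count: full 0.04 bins inside [0.5, 9.8)
  nb <- 0L; lo <- 0.5
  while (lo + 0.04 <= 9.8 + 1e-9) { nb <- nb + 1L; lo <- lo + 0.04 }
  expect_equal(nb, 232L)
  expect_equal(ncol(B$values), 232L)
  in_range <- ppm >= 0.5 & ppm < 0.5 + 232 * 0.04
  expect_equal(rowSums(B$values), rowSums(X$intensities[, in_range]))
  # constant spectrum with equal points per bin -> equal bin values
  Xc <- make_sm(seq(1, 3, by = 0.01)[1:200], list(rep(2, 200)))
  Bc <- bin_spectra(Xc, c(1, 3), 0.05)
  expect_true(all(abs(Bc$values - Bc$values[1, 1]) < 1e-12))
  expect_error(bin_spectra(X, c(0.5, 9.8), 10), "exceeds")
  expect_error(bin_spectra(X, c(0.5, 9.8), 0), "> 0")
})

test_that("binning after exclusion leaves no bin center in the excluded window", {
  ppm <- seq(0.5, 9.8, by = 0.01)
  X <- make_sm(ppm, list(stats::runif(length(ppm)) + 1,
                         stats::runif(length(ppm)) + 1))
  B <- bin_spectra(exclude_regions(X, list(c(4.2, 5.9))))
  expect_false(any(B$centers >= 4.2 & B$centers <= 5.9))
  expect_true(all(B$centers >= 0.5 & B$centers <= 9.8))
})

test_that("PQN maps proportional rows to a common row and is idempotent", {
  set.seed(7)
  ref <- stats::runif(40) + 0.5
  V <- outer(c(0.5, 1, 2, 4), ref)
  rownames(V) <- paste0("s", 1:4)
  B <- binned_matrix(seq(0, 4, 0.1), seq(0.05, 3.95, 0.1), V)
  N <- pqn_normalize(B)
  for (i in 2:4) expect_equal(N$values[i, ], N$values[1, ])
  # median quotient of every output row vs the reference equals 1
  refrow <- apply(sweep(V, 1, rowSums(V), `/`), 2, stats::median)
  for (i in 1:4)
    expect_equal(stats::median(N$values[i, ] / refrow), 1, tolerance = 1e-10)
  # idempotence
  N2 <- pqn_normalize(binned_matrix(N$edges, N$centers, N$values))
  expect_equal(N2$values, N$values, tolerance = 1e-10)
})

test_that("PQN on a single sample reduces to integral normalization", {
  V <- matrix(stats::runif(30) + 1, 1, dimnames = list("only", NULL))
  B <- binned_matrix(seq(0, 3, 0.1), seq(0.05, 2.95, 0.1), V)
  N <- pqn_normalize(B)
  expect_equal(unname(N$values[1, ]), unname(V[1, ] / sum(V)))
})

test_that("PQN errors on a zero-total sample, naming it", {
  V <- rbind(a = rep(1, 10), b = rep(0, 10))
  B <- binned_matrix(seq(0, 1, 0.1), seq(0.05, 0.95, 0.1), V)
  expect_error(pqn_normalize(B), "b")
})

test_that("PQN recovers planted dilution factors at zero noise", {
  nm0 <- noise_model(noise_sd = 0, baseline_amp = 0, shift_sd = 0,
                     dilution_log_sd = 0.3, conc_log_sd = 0)
  coh <- make_two_group_cohort(seed = 9, fold = 1, noise = nm0,
                               periods = c("T1", "T2"), ppm_step = 0.004)
  B <- preprocess_spectra(coh$spectra, align = FALSE, scale = FALSE)
  expect_gt(stats::cor(attr(B, "pqn_factors"), coh$metadata$dilution), 0.99)
})

test_that("pareto scaling centers, scales by sqrt(SD) and keeps zero-variance columns", {
  V <- cbind(c(1, 2, 3), c(0, 0, 0), c(2, 4, 6))
  rownames(V) <- paste0("s", 1:3)
  B <- binned_matrix(seq(0, 0.3, 0.1), c(0.05, 0.15, 0.25), V,
                     normalized = TRUE)
  S <- center_and_pareto_scale(B)
  expect_equal(unname(S$values[, 1]), c(-1, 0, 1))       # SD = 1 fixed point
  expect_equal(unname(S$values[, 2]), c(0, 0, 0))
  # variance of a scaled column equals its original SD
  expect_equal(stats::var(S$values[, 3]), unname(S$original_sd[3]))
  expect_equal(colMeans(S$values), rep(0, 3), ignore_attr = TRUE)
})

test_that("pipeline stages refuse to run out of order", {
  V <- matrix(stats::runif(20) + 1, 2, dimnames = list(c("a", "b"), NULL))
  B <- binned_matrix(seq(0, 1, 0.1), seq(0.05, 0.95, 0.1), V)
  expect_error(center_and_pareto_scale(B), "pqn_normalize")
  S <- center_and_pareto_scale(pqn_normalize(B))
  expect_error(pqn_normalize(S), "before")
  expect_error(center_and_pareto_scale(S), "already")
  one <- binned_matrix(seq(0, 1, 0.1), seq(0.05, 0.95, 0.1),
                       V[1, , drop = FALSE], normalized = TRUE)
  expect_error(center_and_pareto_scale(one), "2 samples")
})
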