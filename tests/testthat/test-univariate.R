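norm_bm <- function(V, centers) {
  binned_matrix(c(centers - 0.02, max(centers) + 0.02), centers, V,
                normalized = TRUE, scaled = FALSE)
}

test_that("window integration averages the covered bins", {
  V <- rbind(s1 = c(1, 2, 3, 4), s2 = c(5, 6, 7, 8))
  B <- norm_bm(V, c(1.0, 1.1, 1.2, 3.0))
  W <- data.frame(metabolite = c("one_bin", "two_bins", "nowhere"),
                  ppm_low = c(2.9, 1.05, 7.0),
                  ppm_high = c(3.1, 1.25, 7.5))
  iv <- integrate_metabolites(B, W)
  expect_equal(unname(iv$levels[, "one_bin"]), c(4, 8))
  expect_equal(unname(iv$levels[, "two_bins"]), c(2.5, 6.5))
  expect_equal(iv$absent, "nowhere")
  expect_false("nowhere" %in% colnames(iv$levels))
  expect_error(integrate_metabolites(B, W[0, ]), "empty")
})

test_that("integration refuses scaled input and flags unnormalized input", {
  V <- matrix(stats::runif(8) + 1, 2,
              dimnames = list(c("a", "b"), NULL))
  W <- data.frame(metabolite = "m", ppm_low = 0.9, ppm_high = 1.5)
  S <- center_and_pareto_scale(norm_bm(V, c(1, 1.1, 1.2, 1.3)))
  expect_error(integrate_metabolites(S, W), "unscaled")
  raw <- binned_matrix(seq(0.98, 1.38, 0.1), c(1, 1.1, 1.2, 1.3), V)
  expect_warning(integrate_metabolites(raw, W), "dilution")
})

test_that("dilution applied before PQN leaves integrated levels unchanged", {
  nm0 <- noise_model(noise_sd = 0, baseline_amp = 0, shift_sd = 0,
                     dilution_log_sd = 0, conc_log_sd = 0.2)
  coh <- make_two_group_cohort(seed = 17, fold = 1, noise = nm0,
                               periods = "T1", ppm_step = 0.004)
  B1 <- preprocess_spectra(coh$spectra, align = FALSE, scale = FALSE)
  doubled <- coh$spectra
  doubled$intensities[1, ] <- 2 * doubled$intensities[1, ]
  B2 <- preprocess_spectra(doubled, align = FALSE, scale = FALSE)
  iv1 <- integrate_metabolites(B1, coh$windows)
  iv2 <- integrate_metabolites(B2, coh$windows)
  expect_equal(iv1$levels, iv2$levels, tolerance = 1e-8)
})

test_that("relative levels and z-scores follow their definitions", {
  lv <- rbind(matrix(c(8, 10, 12), 3, 1), matrix(c(12, 14, 16), 3, 1))
  rownames(lv) <- paste0("s", 1:6)
  colnames(lv) <- "m"
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     group = rep(c("REF", "TGT"), each = 3),
                     period = "T1")
  rel <- relative_levels(lv, meta, "TGT", "REF", periods = "T1")
  expect_equal(rel$relative_level, 1.4)
  expect_equal(rel$z, 2)                        # (14 - 10) / sd = 2
  # identical groups give z = 0, relative level 1
  lv2 <- lv; lv2[4:6, ] <- lv[1:3, ]
  rel2 <- relative_levels(lv2, meta, "TGT", "REF", periods = "T1")
  expect_equal(rel2$relative_level, 1)
  expect_equal(rel2$z, 0)
  # zero reference SD is flagged, not an error
  lv3 <- lv; lv3[1:3, ] <- 5
  rel3 <- relative_levels(lv3, meta, "TGT", "REF", periods = "T1")
  expect_true(rel3$zero_ref_sd)
  expect_true(is.na(rel3$z))
})

test_that("a planted 2-fold change yields relative level 2 exactly at zero noise", {
  nm0 <- noise_model(noise_sd = 0, baseline_amp = 0, shift_sd = 0,
                     dilution_log_sd = 0.3, conc_log_sd = 0)
  # isolated mini-library: windows contain only their own metabolite
  lib <- list(
    citrate = metabolite_signature("citrate", data.frame(
      center = rep(c(2.54, 2.66), each = 2),
      offset = rep(c(-0.015, 0.015), 2),
      height = 0.5, width = 0.012), 6),
    glycine = metabolite_signature("glycine", data.frame(
      center = 3.56, offset = 0, height = 1, width = 0.012), 2),
    creatinine = metabolite_signature("creatinine", data.frame(
      center = c(3.05, 7.2), offset = 0, height = 1, width = 0.012), 10))
  d <- cohort_design(groups = c("NC", "TAA"), n_subjects = 3,
                     periods = c("T1", "T2"))
  coh <- generate_cohort(d, lib,
                         effect_spec("citrate", "TAA", 2, c("T1", "T2")),
                         nm0, ppm_step = 0.004, seed = 19)
  B <- preprocess_spectra(coh$spectra, align = FALSE, scale = FALSE)
  iv <- integrate_metabolites(B, metabolite_windows(lib))
  rel <- relative_levels(iv$levels, coh$metadata, "TAA", "NC",
                         periods = "all")
  expect_equal(rel$relative_level[rel$metabolite == "citrate"], 2,
               tolerance = 1e-6)
})

test_that("z-scores are invariant to relabeling samples within a group", {
  set.seed(23)
  lv <- matrix(stats::rnorm(24, 10), 12, 2,
               dimnames = list(paste0("s", 1:12), c("m1", "m2")))
  meta <- data.frame(sample_id = paste0("s", 1:12),
                     group = rep(c("A", "B"), each = 6), period = "T1")
  rel1 <- relative_levels(lv, meta, "B", "A", periods = "T1")
  shuf <- c(sample(1:6), sample(7:12))
  lv2 <- lv[shuf, , drop = FALSE]
  rownames(lv2) <- paste0("s", 1:12)
  rel2 <- relative_levels(lv2, meta, "B", "A", periods = "T1")
  expect_equal(rel1$z, rel2$z, tolerance = 1e-12)
  expect_equal(rel1$relative_level, rel2$relative_level, tolerance = 1e-12)
})

test_that("normality gating picks the t-test for normal and Wilcoxon for skewed data", {
  set.seed(29)
  a <- stats::rnorm(12); b <- stats::rnorm(12)
  r1 <- test_metabolite(a, b)
  expect_equal(r1$test, "t-test")
  skew_a <- exp(stats::rnorm(12, 0, 1.5))
  skew_b <- exp(stats::rnorm(12, 0, 1.5))
  # draw until the gate actually rejects normality (log-normal, n = 12)
  for (k in 1:50) {
    if (stats::shapiro.test(skew_a)$p.value <= 0.05) break
    skew_a <- exp(stats::rnorm(12, 0, 1.5))
  }
  r2 <- test_metabolite(skew_a, skew_b)
  expect_equal(r2$test, "Wilcoxon")
})

test_that("a 10-SD shift is detected and all-tied input is degenerate", {
  set.seed(31)
  a <- stats::rnorm(12)
  r <- test_metabolite(a, a + 10)
  expect_lt(r$p_value, 1e-4)
  expect_true(r$significant)
  rd <- test_metabolite(rep(1, 5), rep(1, 6))
  expect_equal(rd$p_value, 1)
  expect_true(rd$degenerate)
  expect_error(test_metabolite(1:2, 1:5), "3 values")
})

test_that("null comparisons are flagged at close to the nominal 5% rate", {
  set.seed(37)
  flags <- vapply(1:400, function(k) {
    if (k %% 2 == 0) {
      a <- stats::rnorm(12); b <- stats::rnorm(12)
    } else {
      a <- exp(stats::rnorm(12)); b <- exp(stats::rnorm(12))
    }
    test_metabolite(a, b)$significant
  }, TRUE)
  rate <- mean(flags)
  mc_sd <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(rate - 0.05), 3 * mc_sd)
})

test_that("reference mapping encodes the study's normalization scheme", {
  rm <- reference_mapping()
  expect_setequal(rm$target[rm$reference == "NC"],
                  c("HLD", "TAA", "BDL", "THC", "BHD"))
  expect_setequal(rm$target[rm$reference == "HLD"], c("THC", "BHD"))
})

test_that("z-score tables clip for color mapping and round-trip through TSV", {
  rel <- data.frame(
    metabolite = rep(c("m1", "m2"), each = 2),
    period = rep(c("T1", "T2"), 2),
    relative_level = c(2, 1, 0.5, 1),
    z = c(5.2, 0, -4.1, 0.3),
    p_value = c(0.004, 0.2, 0.03, 0.9),
    test = "t-test", significant = c(TRUE, FALSE, TRUE, FALSE),
    zero_ref_sd = FALSE)
  zt <- zscore_table(rel, clip = 3)
  expect_equal(zt$z_clipped["m1", "T1"], 3)
  expect_equal(zt$z_clipped["m2", "T1"], -3)
  expect_equal(zt$z["m1", "T1"], 5.2)
  expect_equal(zt$stars["m1", "T1"], "**")
  expect_equal(zt$stars["m2", "T1"], "*")
  expect_equal(zt$stars["m1", "T2"], "")
  f <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(metabolite = rownames(zt$z), zt$z,
                                check.names = FALSE),
                     f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(as.numeric(back$T1), unname(zt$z[, "T1"]), tolerance = 1e-12)
})
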