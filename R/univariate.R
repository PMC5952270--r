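#' Integrate metabolite windows
#'
#' Computes the normalized average integration of area per metabolite: the
#' sum of PQN-normalized bin values whose centers fall inside any of the
#' metabolite's ppm windows, divided by the number of contributing bins.
#' Metabolites whose windows overlap no retained bin are flagged absent.
#'
#' @param B a normalized, unscaled [binned_matrix()].
#' @param windows data.frame `metabolite`, `ppm_low`, `ppm_high` (repeated
#'   rows for multiplets).
#' @return list with `levels` (samples x metabolites matrix), `n_bins`
#'   (contributing bins per metabolite) and `absent` (character vector).
#' @export
integrate_metabolites <- function(B, windows) {
  stopifnot(inherits(B, "binned_matrix"))
  if (B$scaled)
    stop_nmropls("integrate on the normalized, unscaled matrix (scale = FALSE)")
  if (!B$normalized)
    warning("matrix is not PQN-normalized; levels will retain dilution variation")
  if (is.null(windows) || nrow(windows) == 0L)
    stop_nmropls("empty metabolite window table")
  mets <- unique(windows$metabolite)
  levels <- matrix(NA_real_, nrow(B$values), length(mets),
                   dimnames = list(rownames(B$values), mets))
  nb <- stats::setNames(integer(length(mets)), mets)
  for (m in mets) {
    w <- windows[windows$metabolite == m, , drop = FALSE]
    inwin <- rep(FALSE, length(B$centers))
    for (k in seq_len(nrow(w)))
      inwin <- inwin | (B$centers >= w$ppm_low[k] &
                          B$centers <= w$ppm_high[k])
    nb[m] <- sum(inwin)
    if (nb[m] > 0L)
      levels[, m] <- rowSums(B$values[, inwin, drop = FALSE]) / nb[m]
  }
  absent <- mets[nb == 0L]
  list(levels = levels[, nb > 0L, drop = FALSE], n_bins = nb,
       absent = absent)
}

#' Two-group metabolite test with normality gating
#'
#' Shapiro-Wilk normality is checked on each group at `alpha_normality`;
#' when both groups conform, a Welch two-sample t-test is used, otherwise a
#' rank test (unpaired rank-sum by default; a paired signed-rank mode is
#' available for matched designs). Constant groups fail the normality gate;
#' all-tied values across both groups yield p = 1 with a degenerate flag.
#'
#' @param a,b numeric level vectors (>= 3 values each).
#' @param alpha_normality significance level of the normality gate.
#' @param paired use the paired signed-rank / paired t-test variant.
#' @return list with `p_value`, `test` ("t-test" or "Wilcoxon"),
#'   `significant` (at p < 0.05) and `degenerate`.
#' @export
test_metabolite <- function(a, b, alpha_normality = 0.05, paired = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop_nmropls("each group needs at least 3 values")
  if (length(unique(c(a, b))) == 1L)
    return(list(p_value = 1, test = "Wilcoxon", significant = FALSE,
                degenerate = TRUE))
  normal <- function(v) {
    if (length(unique(v)) == 1L) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha_normality
  }
  if (normal(a) && normal(b)) {
    p <- if (paired) stats::t.test(a, b, paired = TRUE)$p.value
         else stats::t.test(a, b, var.equal = FALSE)$p.value
    test <- "t-test"
  } else {
    p <- suppressWarnings(
      if (paired) stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
      else stats::wilcox.test(a, b, exact = FALSE)$p.value)
    test <- "Wilcoxon"
  }
  list(p_value = p, test = test, significant = p < 0.05, degenerate = FALSE)
}

#' Reference-group mapping of the study design
#'
#' All treated and model groups are normalized against the untreated
#' control (NC); the two herbal-treatment groups are additionally
#' normalized against the treated healthy control (HLD) to subtract the
#' treatment's effect on healthy animals.
#'
#' @return data.frame with columns `target`, `reference`.
#' @export
reference_mapping <- function() {
  rbind(
    data.frame(target = c("HLD", "TAA", "BDL", "THC", "BHD"),
               reference = "NC", stringsAsFactors = FALSE),
    data.frame(target = c("THC", "BHD"), reference = "HLD",
               stringsAsFactors = FALSE)
  )
}

#' Relative levels and z-scores of one group against a reference group
#'
#' Per metabolite and collection period (plus a pooled `"all"` row over the
#' requested periods): relative level `mean_target / mean_reference` and
#' `z = (mean_target - mean_reference) / SD_reference`, with the two-group
#' p-value from [test_metabolite()]. Cells with zero reference SD carry an
#' undefined (NA) z and a flag.
#'
#' @param levels samples x metabolites matrix from
#'   [integrate_metabolites()].
#' @param metadata data.frame `sample_id`, `group`, `period`.
#' @param target,reference group labels (both must be present in every
#'   requested period).
#' @param periods periods to evaluate (default: all shared periods); use
#'   `"all"` for the pooled comparison only.
#' @param alpha_normality normality-gate level passed to
#'   [test_metabolite()].
#' @return data.frame `metabolite`, `period`, `relative_level`, `z`,
#'   `p_value`, `test`, `significant`, `zero_ref_sd`.
#' @export
relative_levels <- function(levels, metadata, target, reference,
                            periods = NULL, alpha_normality = 0.05) {
  meta <- metadata[match(rownames(levels), metadata$sample_id), ]
  if (anyNA(meta$group))
    stop_nmropls("samples missing from metadata: %s",
                 paste(rownames(levels)[is.na(meta$group)], collapse = ", "))
  for (g in c(target, reference))
    if (!g %in% meta$group) stop_nmropls("group '%s' absent from data", g)
  shared <- intersect(unique(meta$period[meta$group == target]),
                      unique(meta$period[meta$group == reference]))
  periods <- periods %||% c(intersect(paste0("T", 1:8), shared), "all")
  rows <- list()
  for (per in periods) {
    sel_t <- meta$group == target & (per == "all" | meta$period == per)
    sel_r <- meta$group == reference & (per == "all" | meta$period == per)
    if (!any(sel_t) || !any(sel_r))
      stop_nmropls("group '%s' or '%s' has no samples in period %s",
                   target, reference, per)
    for (m in colnames(levels)) {
      lt <- levels[sel_t, m]; lr <- levels[sel_r, m]
      sd_r <- stats::sd(lr)
      tst <- test_metabolite(lt, lr, alpha_normality = alpha_normality)
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = m, period = per,
        relative_level = mean(lt) / mean(lr),
        z = if (sd_r > 0) (mean(lt) - mean(lr)) / sd_r else NA_real_,
        p_value = tst$p_value, test = tst$test,
        significant = tst$significant,
        zero_ref_sd = !(sd_r > 0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "target") <- target
  attr(out, "reference") <- reference
  out
}

#' Color-ready z-score matrix
#'
#' Reshapes a [relative_levels()] table into a metabolite x period matrix
#' of z-scores clipped to +-`clip` for color mapping, with significance
#' stars (`*` p < 0.05, `**` p < 0.01) overlaid.
#'
#' @param rel a [relative_levels()] table.
#' @param clip clipping bound for the color scale.
#' @param drop_pooled drop the pooled `"all"` column (default TRUE).
#' @return list with `z` (unclipped matrix), `z_clipped`, `stars`
#'   (character matrix) and `clip`.
#' @export
zscore_table <- function(rel, clip = 3, drop_pooled = TRUE) {
  if (nrow(rel) == 0L) stop_nmropls("empty z-score table")
  if (drop_pooled) rel <- rel[rel$period != "all", , drop = FALSE]
  mets <- unique(rel$metabolite)
  pers <- intersect(c(paste0("T", 1:8), "all"), unique(rel$period))
  z <- matrix(NA_real_, length(mets), length(pers),
              dimnames = list(mets, pers))
  stars <- matrix("", length(mets), length(pers),
                  dimnames = list(mets, pers))
  for (i in seq_len(nrow(rel))) {
    z[rel$metabolite[i], rel$period[i]] <- rel$z[i]
    stars[rel$metabolite[i], rel$period[i]] <-
      if (!is.na(rel$p_value[i]) && rel$p_value[i] < 0.01) "**"
      else if (!is.na(rel$p_value[i]) && rel$p_value[i] < 0.05) "*" else ""
  }
  list(z = z, z_clipped = pmin(pmax(z, -clip), clip), stars = stars,
       clip = clip)
}
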