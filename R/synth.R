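#' Metabolite signature
#'
#' A named set of Lorentzian multiplets with a base urinary concentration.
#' Each line of a multiplet is described by the multiplet center, the line
#' offset from that center, a relative line height and a linewidth (full
#' width at half maximum). Chemical-shift jitter is later applied to the
#' multiplet center, moving all lines together, as pH-driven shifts do.
#'
#' @param name metabolite name.
#' @param peaks data.frame with columns `center`, `offset`, `height`,
#'   `width` (all ppm except `height`); one row per multiplet line.
#' @param base_conc base concentration in arbitrary units, > 0.
#' @return an object of class `metabolite_signature`.
#' @export
metabolite_signature <- function(name, peaks, base_conc) {
  stopifnot(is.character(name), length(name) == 1L)
  peaks <- as.data.frame(peaks)
  need <- c("center", "offset", "height", "width")
  if (!all(need %in% names(peaks)))
    stop_nmropls("signature '%s': peaks need columns %s", name,
                 paste(need, collapse = ", "))
  pos <- peaks$center + peaks$offset
  if (any(pos < 0.5 | pos > 9.8))
    stop_nmropls("signature '%s': line positions outside [0.5, 9.8] ppm", name)
  if (any(peaks$height <= 0) || any(peaks$width <= 0))
    stop_nmropls("signature '%s': line heights and widths must be > 0", name)
  if (!is.numeric(base_conc) || base_conc <= 0)
    stop_nmropls("signature '%s': base concentration must be > 0", name)
  structure(list(name = name, peaks = peaks, base_conc = base_conc),
            class = "metabolite_signature")
}

# multiplet helpers: line offsets for common patterns, J in ppm units
.singlet <- function(center, height = 1, width = 0.012)
  data.frame(center = center, offset = 0, height = height, width = width)
.doublet <- function(center, height = 1, width = 0.012, J = 0.012)
  data.frame(center = center, offset = c(-J / 2, J / 2),
             height = height / 2, width = width)
.triplet <- function(center, height = 1, width = 0.012, J = 0.012)
  data.frame(center = center, offset = c(-J, 0, J),
             height = height * c(0.25, 0.5, 0.25), width = width)

#' Build the default synthetic metabolite library
#'
#' A fixture of urinary metabolites with literature-typical chemical shifts
#' (creatinine, citrate, hippurate, 2-oxoglutarate, TMAO, branched-chain
#' amino acids, ...). Peak positions and multiplicities are fixed; the seed
#' perturbs base concentrations log-normally (sd 0.2 on the log scale) so
#' that different seeds give different but reproducible concentration
#' regimes. Urea and allantoin resonate inside the water/urea exclusion
#' window and are present precisely so that the exclusion step has real
#' signal to remove.
#'
#' @param seed integer seed controlling the concentration draw.
#' @return a list of [metabolite_signature()] objects (>= 20 entries,
#'   unique names), class `metabolite_library`.
#' @export
build_default_library <- function(seed = 1L) {
  defs <- list(
    list("creatinine", rbind(.singlet(3.05, 1.0), .singlet(4.06, 0.7)), 10),
    list("creatine", rbind(.singlet(3.04, 1.0), .singlet(3.93, 0.7)), 3),
    list("citrate", rbind(.doublet(2.54, 1, J = 0.030),
                          .doublet(2.66, 1, J = 0.030)), 6),
    list("hippurate", rbind(.doublet(3.97, 0.8), .triplet(7.55, 0.8),
                            .triplet(7.64, 0.4), .doublet(7.84, 0.8)), 5),
    list("2-oxoglutarate", rbind(.triplet(2.44, 1), .triplet(3.01, 1)), 4),
    list("succinate", .singlet(2.41), 2),
    list("fumarate", .singlet(6.52), 0.8),
    list("TMAO", .singlet(3.27), 4),
    list("taurine", rbind(.triplet(3.26, 1), .triplet(3.43, 1)), 3),
    list("glycine", .singlet(3.56), 2.5),
    list("alanine", .doublet(1.48), 2),
    list("lactate", rbind(.doublet(1.33, 1), .singlet(4.11, 0.3)), 2.5),
    list("valine", rbind(.doublet(0.99, 1), .doublet(1.04, 1)), 1.5),
    list("leucine", .triplet(0.96), 1.5),
    list("isoleucine", rbind(.doublet(0.94, 1), .doublet(1.01, 0.6)), 1.2),
    list("acetate", .singlet(1.92), 1.5),
    list("formate", .singlet(8.46), 1),
    list("trigonelline", rbind(.singlet(9.12, 0.6), .singlet(8.84, 0.8),
                               .triplet(8.08, 0.6)), 1.5),
    list("betaine", rbind(.singlet(3.26, 1), .singlet(3.90, 0.25)), 2),
    list("dimethylamine", .singlet(2.72), 2),
    list("glutamate", rbind(.triplet(2.08, 0.8), .triplet(2.35, 0.8)), 2),
    list("phenylalanine", rbind(.doublet(7.32, 0.7), .triplet(7.37, 0.7),
                                .triplet(7.42, 0.7)), 1),
    list("benzoate", rbind(.triplet(7.48, 0.7), .triplet(7.55, 0.4),
                           .doublet(7.87, 0.8)), 0.8),
    list("3-indoxylsulfate", rbind(.triplet(7.19, 0.5), .triplet(7.28, 0.5),
                                   .doublet(7.50, 0.6), .doublet(7.70, 0.6),
                                   .singlet(7.35, 0.5)), 1.2),
    list("1-methylnicotinamide", rbind(.singlet(9.28, 0.6),
                                       .doublet(8.90, 0.6),
                                       .doublet(8.97, 0.6)), 0.8),
    list("N-phenylacetylglycine", rbind(.singlet(3.68, 0.8),
                                        .doublet(3.75, 0.8),
                                        .triplet(7.36, 0.6),
                                        .triplet(7.42, 0.4)), 1.5),
    list("allantoin", .singlet(5.39), 3),
    list("urea", .singlet(5.78, 1, width = 0.05), 40)
  )
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 11L))
  lib <- lapply(defs, function(d) {
    conc <- d[[3]] * exp(stats::rnorm(1, 0, 0.2))
    metabolite_signature(d[[1]], d[[2]], conc)
  })
  names(lib) <- vapply(lib, `[[`, "", "name")
  if (anyDuplicated(names(lib))) stop_nmropls("duplicate metabolite names")
  structure(lib, class = "metabolite_library")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Cohort design
#'
#' Group, subject and collection-period layout of a (synthetic) study.
#' The defaults are the six treatment groups with twelve animals each and
#' eight urine collection windows spanning 0 to 144 h.
#'
#' @param groups character vector of group labels.
#' @param n_subjects subjects per group.
#' @param periods ordered subset of T1..T8.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(groups = c("NC", "HLD", "TAA", "THC", "BDL", "BHD"),
                          n_subjects = 12L,
                          periods = paste0("T", 1:8)) {
  pt <- period_table()
  if (!all(periods %in% pt$period))
    stop_nmropls("unknown periods: %s",
                 paste(setdiff(periods, pt$period), collapse = ", "))
  if (length(groups) < 1L || n_subjects < 1L)
    stop_nmropls("design must contain at least one group and one subject")
  structure(list(groups = groups, n_subjects = as.integer(n_subjects),
                 periods = periods,
                 hours = pt[match(periods, pt$period), ]),
            class = "cohort_design")
}

#' Planted group effect on one metabolite
#'
#' Multiplicative fold-changes applied to a metabolite's concentration in
#' the named groups, per collection period. A fold of 1 is no effect.
#'
#' @param metabolite metabolite name (must exist in the library at
#'   generation time).
#' @param groups affected group labels.
#' @param fold either a single fold-change applied to all `periods`, or a
#'   numeric vector named by period.
#' @param periods periods the effect applies to (default all eight).
#' @return a data.frame with columns `metabolite`, `group`, `period`, `fold`.
#' @export
effect_spec <- function(metabolite, groups, fold, periods = paste0("T", 1:8)) {
  if (length(fold) == 1L && is.null(names(fold)))
    fold <- stats::setNames(rep(fold, length(periods)), periods)
  if (is.null(names(fold)) || !all(names(fold) %in% paste0("T", 1:8)))
    stop_nmropls("fold-changes must be named by period T1..T8")
  if (any(fold <= 0)) stop_nmropls("fold-changes must be > 0")
  expand <- expand.grid(group = groups, period = names(fold),
                        stringsAsFactors = FALSE)
  data.frame(metabolite = metabolite, group = expand$group,
             period = expand$period, fold = fold[expand$period],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Noise model for the synthetic cohort
#'
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units; peak heights are of order 1-40).
#' @param baseline_amp amplitude of a smooth low-frequency baseline.
#' @param shift_sd chemical-shift jitter SD in ppm, applied per sample and
#'   per metabolite (whole multiplets move together).
#' @param dilution_log_sd log-scale SD of the per-sample log-normal dilution
#'   factor (urine concentration varies multiplicatively).
#' @param conc_log_sd log-scale SD of per-sample biological variation in
#'   metabolite concentrations.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(noise_sd = 0.05, baseline_amp = 0.2,
                        shift_sd = 0.002, dilution_log_sd = 0.3,
                        conc_log_sd = 0.2) {
  if (any(c(noise_sd, baseline_amp, shift_sd, dilution_log_sd,
            conc_log_sd) < 0))
    stop_nmropls("noise model parameters must be >= 0")
  structure(list(noise_sd = noise_sd, baseline_amp = baseline_amp,
                 shift_sd = shift_sd, dilution_log_sd = dilution_log_sd,
                 conc_log_sd = conc_log_sd),
            class = "noise_model")
}

# height-normalized Lorentzian added in place over a +-window truncation
.add_lorentzian <- function(y, ppm, center, height, width, trunc = 0.35) {
  i0 <- findInterval(center - trunc, ppm) + 1L
  i1 <- findInterval(center + trunc, ppm)
  if (i1 < i0) return(y)
  idx <- i0:i1
  hw2 <- (width / 2)^2
  y[idx] <- y[idx] + height * hw2 / ((ppm[idx] - center)^2 + hw2)
  y
}

#' Generate a synthetic urine-like NMR cohort
#'
#' One spectrum per (group, subject, period). Each spectrum is
#' `dilution x sum(concentration x Lorentzian multiplets) + baseline +
#' noise`, with per-sample, per-metabolite chemical-shift jitter applied to
#' multiplet centers, per-sample log-normal biological variation of
#' concentrations, and planted multiplicative group effects.
#'
#' @param design a [cohort_design()].
#' @param library a [build_default_library()] result (or compatible list).
#' @param effects a data.frame from [effect_spec()] (row-bind several for
#'   multiple effects), or NULL for a null cohort.
#' @param noise a [noise_model()].
#' @param ppm_step grid resolution in ppm (uniform grid over 0.5-9.8).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a list of class `nmr_cohort` with elements `spectra`
#'   (a [spectral_matrix()]), `metadata` (sample_id, group, subject, period,
#'   dilution) and `truth` (the planted effects table).
#' @export
generate_cohort <- function(design, library = build_default_library(),
                            effects = NULL, noise = noise_model(),
                            ppm_step = 0.001, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  if (!is.null(effects) && nrow(effects)) {
    missing_m <- setdiff(unique(effects$metabolite), names(library))
    if (length(missing_m))
      stop_nmropls("effect names metabolite(s) absent from library: %s",
                   paste(missing_m, collapse = ", "))
  }
  ppm <- seq(0.5, 9.8, by = ppm_step)
  meta <- expand.grid(period = design$periods,
                      subject = seq_len(design$n_subjects),
                      group = design$groups,
                      stringsAsFactors = FALSE)
  meta <- meta[, c("group", "subject", "period")]
  meta$subject <- sprintf("%s%02d", meta$group, meta$subject)
  meta$sample_id <- sprintf("%s_%s", meta$subject, meta$period)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 29L))

  n <- nrow(meta)
  nm <- length(library)
  met_names <- names(library)
  base_conc <- vapply(library, `[[`, 0, "base_conc")

  dilution <- exp(stats::rnorm(n, 0, noise$dilution_log_sd))
  conc <- matrix(exp(stats::rnorm(n * nm, 0, noise$conc_log_sd)), n, nm)
  conc <- sweep(conc, 2, base_conc, `*`)
  colnames(conc) <- met_names
  if (!is.null(effects) && nrow(effects)) {
    for (k in seq_len(nrow(effects))) {
      hit <- meta$group == effects$group[k] & meta$period == effects$period[k]
      conc[hit, effects$metabolite[k]] <-
        conc[hit, effects$metabolite[k]] * effects$fold[k]
    }
  }
  jitter <- matrix(stats::rnorm(n * nm, 0, noise$shift_sd), n, nm)
  # smooth baseline: two random-phase long-period cosines per sample
  phase <- matrix(stats::runif(2 * n, 0, 2 * pi), n, 2)
  noise_mat <- matrix(stats::rnorm(n * length(ppm), 0, noise$noise_sd),
                      n, length(ppm))

  X <- matrix(0, n, length(ppm), dimnames = list(meta$sample_id, NULL))
  for (i in seq_len(n)) {
    y <- numeric(length(ppm))
    for (m in seq_len(nm)) {
      pk <- library[[m]]$peaks
      centers <- pk$center + pk$offset + jitter[i, m]
      for (l in seq_len(nrow(pk)))
        y <- .add_lorentzian(y, ppm, centers[l], conc[i, m] * pk$height[l],
                             pk$width[l])
    }
    if (noise$baseline_amp > 0)
      y <- y + noise$baseline_amp *
        (1 + cos(2 * pi * ppm / 9.3 + phase[i, 1]) / 2 +
           cos(4 * pi * ppm / 9.3 + phase[i, 2]) / 3)
    X[i, ] <- dilution[i] * y + noise_mat[i, ]
  }
  meta$dilution <- dilution
  truth <- if (is.null(effects)) {
    data.frame(metabolite = character(), group = character(),
               period = character(), fold = numeric())
  } else effects
  structure(list(spectra = spectral_matrix(ppm, X),
                 metadata = meta[, c("sample_id", "group", "subject",
                                     "period", "dilution")],
                 truth = truth),
            class = "nmr_cohort")
}

#' Default metabolite integration windows
#'
#' Derives per-metabolite ppm windows from a signature library: one window
#' per multiplet, `center +- halfwidth`, with windows intersecting the
#' excluded solvent region dropped. Windows are what the univariate stage
#' integrates; metabolites whose every multiplet falls in the excluded
#' region (urea, allantoin) drop out of the table.
#'
#' @param library a `metabolite_library`.
#' @param halfwidth window half-width in ppm.
#' @param exclude length-2 ppm interval to avoid (water/urea region).
#' @return a data.frame with columns `metabolite`, `ppm_low`, `ppm_high`.
#' @export
metabolite_windows <- function(library, halfwidth = 0.03,
                               exclude = c(4.2, 5.9)) {
  rows <- lapply(library, function(sig) {
    ctr <- unique(sig$peaks$center)
    span <- vapply(ctr, function(cc) {
      lines <- sig$peaks[sig$peaks$center == cc, ]
      range(cc + lines$offset)
    }, numeric(2))
    data.frame(metabolite = sig$name,
               ppm_low = pmax(span[1, ] - halfwidth, 0.5),
               ppm_high = pmin(span[2, ] + halfwidth, 9.8))
  })
  w <- do.call(rbind, rows)
  keep <- w$ppm_high < exclude[1] | w$ppm_low > exclude[2]
  w <- w[keep, ]
  rownames(w) <- NULL
  w
}
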