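#' Build an analysis configuration
#'
#' Either programmatically or from a YAML/JSON file. Unspecified keys take
#' the documented defaults; the fully resolved configuration is echoed into
#' the run report so a run is self-describing.
#'
#' @param input list with `spectra`, `metadata` and optionally `windows`
#'   file paths; or NULL when `simulate` is given.
#' @param simulate list with simulation parameters (`groups`, `n_subjects`,
#'   `periods`, `effects` data.frame, `ppm_step`, noise-model fields); used
#'   when no input paths are given.
#' @param preprocess list of preprocessing keys (`align`, `segment_ppm`,
#'   `max_shift_ppm`, `exclude`, `bin_width`, `bin_range`,
#'   `pqn_reference`).
#' @param comparisons list of lists, each with `a`, `b` (group labels) and
#'   optional `project` (additional groups projected passively into the
#'   score plane).
#' @param validate list with `n_ortho`, `n_repeats`, `n_perm`,
#'   `perm_cv_repeats`.
#' @param univariate list with `references` (data.frame target/reference;
#'   default [reference_mapping()] filtered to available groups) and
#'   `alpha_normality`.
#' @param stocsy list with `drivers` (numeric ppm vector) and
#'   `r_threshold`.
#' @param output_dir output directory.
#' @param seed global integer seed.
#' @param plots write PNG figures (default TRUE).
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, simulate = NULL,
                            preprocess = list(), comparisons = list(),
                            validate = list(), univariate = list(),
                            stocsy = list(), output_dir = "nmropls_run",
                            seed = 1L, plots = TRUE) {
  pre <- utils::modifyList(list(align = TRUE, segment_ppm = 0.2,
                                max_shift_ppm = 0.02,
                                exclude = list(c(4.2, 5.9)),
                                bin_range = c(0.5, 9.8), bin_width = 0.04,
                                pqn_reference = "median"), preprocess)
  val <- utils::modifyList(list(n_ortho = 1L, n_repeats = 50L,
                                n_perm = 200L, perm_cv_repeats = 10L),
                           validate)
  uni <- utils::modifyList(list(references = NULL, alpha_normality = 0.05),
                           univariate)
  sto <- utils::modifyList(list(drivers = numeric(), r_threshold = 0.8),
                           stocsy)
  for (cmp in comparisons) {
    if (is.null(cmp$a) || is.null(cmp$b) || identical(cmp$a, cmp$b))
      stop_nmropls("each comparison needs two distinct groups 'a' and 'b'")
  }
  structure(list(input = input, simulate = simulate, preprocess = pre,
                 comparisons = comparisons, validate = val,
                 univariate = uni, stocsy = sto, output_dir = output_dir,
                 seed = as.integer(seed), plots = isTRUE(plots)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML (or JSON)
#'
#' @param path configuration file; `.json` files are parsed as JSON,
#'   anything else as YAML.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(raw$simulate$effects))
    raw$simulate$effects <- as.data.frame(raw$simulate$effects)
  if (!is.null(raw$univariate$references))
    raw$univariate$references <- as.data.frame(raw$univariate$references)
  if (!is.null(raw$preprocess$exclude) &&
      !is.list(raw$preprocess$exclude[[1]]))
    raw$preprocess$exclude <- lapply(raw$preprocess$exclude, unlist)
  do.call(analysis_config, raw)
}

.cohort_from_config <- function(config) {
  if (!is.null(config$input)) {
    spectra <- read_spectral_matrix(config$input$spectra)
    metadata <- read_metadata(config$input$metadata)
    missing <- setdiff(metadata$sample_id, sample_ids(spectra))
    if (length(missing))
      stop_nmropls("metadata sample(s) absent from spectra: %s",
                   paste(missing, collapse = ", "))
    windows <- if (!is.null(config$input$windows))
      read_windows(config$input$windows)
    else metabolite_windows(build_default_library(config$seed))
    list(spectra = spectra, metadata = metadata, windows = windows,
         truth = NULL)
  } else {
    sim <- config$simulate %||% list()
    design <- cohort_design(
      groups = sim$groups %||% c("NC", "HLD", "TAA", "THC", "BDL", "BHD"),
      n_subjects = sim$n_subjects %||% 12L,
      periods = sim$periods %||% paste0("T", 1:8))
    lib <- build_default_library(config$seed)
    noise <- noise_model(
      noise_sd = sim$noise_sd %||% 0.05,
      baseline_amp = sim$baseline_amp %||% 0.2,
      shift_sd = sim$shift_sd %||% 0.002,
      dilution_log_sd = sim$dilution_log_sd %||% 0.3,
      conc_log_sd = sim$conc_log_sd %||% 0.2)
    cohort <- generate_cohort(design, lib, effects = sim$effects,
                              noise = noise,
                              ppm_step = sim$ppm_step %||% 0.001,
                              seed = config$seed)
    list(spectra = cohort$spectra, metadata = cohort$metadata,
         windows = metabolite_windows(lib), truth = cohort$truth)
  }
}

.save_plot <- function(p, path, log, width = 6, height = 4) {
  ok <- tryCatch({
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 120)
    TRUE
  }, error = function(e) {
    log(sprintf("plot %s failed: %s", basename(path), conditionMessage(e)))
    FALSE
  })
  if (ok) path else NULL
}

#' Run the full analysis pipeline
#'
#' Preprocesses once, then per declared comparison fits an OPLS-DA model
#' and validates it (CV, permutation test, ROC), runs the univariate
#' reference-normalized z-score stage, and any requested STOCSY drivers.
#' All tables, reports, figures and the resolved configuration are written
#' under the output directory; rerunning with the same configuration and
#' seed reproduces all numeric outputs.
#'
#' @param config an [analysis_config()] (or a path readable by
#'   [read_config()]).
#' @return a list of class `run_report`: per-comparison validation
#'   reports, the univariate tables, the file manifest and a log.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character()
  log_lines <- character()
  log <- function(msg) {
    log_lines[[length(log_lines) + 1L]] <<- msg
    invisible(NULL)
  }
  emit <- function(path) {
    manifest[[length(manifest) + 1L]] <<- path
    invisible(path)
  }
  out <- function(...) file.path(config$output_dir, sprintf(...))

  log("loading inputs")
  dat <- .cohort_from_config(config)
  bad <- setdiff(unlist(lapply(config$comparisons,
                               function(cmp) c(cmp$a, cmp$b, cmp$project))),
                 unique(dat$metadata$group))
  if (length(bad))
    stop_nmropls("comparison group(s) absent from metadata: %s",
                 paste(bad, collapse = ", "))

  emit(write_spectral_matrix(dat$spectra, out("spectra_raw.tsv")))
  emit(write_metadata(dat$metadata, out("metadata.tsv")))

  log("preprocessing")
  pre <- config$preprocess
  B_scaled <- preprocess_spectra(dat$spectra, align = pre$align,
                                 segment_ppm = pre$segment_ppm,
                                 max_shift_ppm = pre$max_shift_ppm,
                                 exclude = pre$exclude,
                                 bin_range = pre$bin_range,
                                 bin_width = pre$bin_width,
                                 pqn_reference = pre$pqn_reference,
                                 scale = TRUE)
  B_norm <- preprocess_spectra(dat$spectra, align = pre$align,
                               segment_ppm = pre$segment_ppm,
                               max_shift_ppm = pre$max_shift_ppm,
                               exclude = pre$exclude,
                               bin_range = pre$bin_range,
                               bin_width = pre$bin_width,
                               pqn_reference = pre$pqn_reference,
                               scale = FALSE)
  bt <- data.frame(ppm = B_norm$centers, t(B_norm$values))
  data.table::fwrite(bt, out("binned_normalized.tsv"), sep = "\t")
  emit(out("binned_normalized.tsv"))

  meta <- dat$metadata
  reports <- list()
  for (i in seq_along(config$comparisons)) {
    cmp <- config$comparisons[[i]]
    tag <- sprintf("%s_vs_%s", cmp$a, cmp$b)
    log(sprintf("comparison %s", tag))
    sel <- meta$group %in% c(cmp$a, cmp$b)
    ids <- meta$sample_id[sel]
    Bi <- B_scaled[match(ids, sample_ids(B_scaled))]
    y <- encode_classes(meta$group[sel], positive = cmp$a)
    rep_i <- validate_model(Bi, y,
                            n_ortho = config$validate$n_ortho,
                            n_repeats = config$validate$n_repeats,
                            n_perm = config$validate$n_perm,
                            perm_cv_repeats = config$validate$perm_cv_repeats,
                            seed = derive_seed(config$seed, 100L + i))
    model <- fit_oplsda(Bi, y, n_ortho = config$validate$n_ortho)
    sc <- opls_scores(model)
    proj_groups <- unlist(cmp$project)
    if (length(proj_groups)) {
      pid <- meta$sample_id[meta$group %in% proj_groups]
      pr <- predict(model, B_scaled[match(pid, sample_ids(B_scaled))])
      sc <- rbind(sc, pr[, c("sample_id", "t", "t_ortho")])
    }
    data.table::fwrite(sc, out("scores_%s.tsv", tag), sep = "\t")
    emit(out("scores_%s.tsv", tag))
    sp <- splot(model)
    data.table::fwrite(sp, out("splot_%s.tsv", tag), sep = "\t")
    emit(out("splot_%s.tsv", tag))
    emit(write_opls_model(model, out("model_%s.json", tag)))
    emit(write_validation_report(rep_i, out("validation_%s.json", tag)))
    if (config$plots) {
      traj <- trajectory(sc, meta)
      for (pl in list(
        list(plot_scores(sc, meta), out("scores_%s.png", tag)),
        list(plot_trajectory(traj), out("trajectory_%s.png", tag)),
        list(plot_splot(sp), out("splot_%s.png", tag)),
        list(plot_loadings(sp), out("loadings_%s.png", tag)),
        list(plot_permutation(rep_i$permutation),
             out("permutation_%s.png", tag)),
        list(plot_roc(rep_i$roc, rep_i$auroc), out("roc_%s.png", tag)))) {
        f <- .save_plot(pl[[1]], pl[[2]], log)
        if (!is.null(f)) emit(f)
      }
    }
    reports[[tag]] <- rep_i
  }

  log("univariate stage")
  uni_tables <- list()
  if (!is.null(dat$windows) && nrow(dat$windows)) {
    integ <- integrate_metabolites(B_norm, dat$windows)
    lv <- data.frame(sample_id = rownames(integ$levels), integ$levels,
                     check.names = FALSE)
    data.table::fwrite(lv, out("metabolite_levels.tsv"), sep = "\t")
    emit(out("metabolite_levels.tsv"))
    refs <- config$univariate$references %||% {
      rm <- reference_mapping()
      gr <- unique(meta$group)
      rm[rm$target %in% gr & rm$reference %in% gr, , drop = FALSE]
    }
    for (k in seq_len(nrow(refs))) {
      tg <- refs$target[k]; rf <- refs$reference[k]
      rel <- relative_levels(integ$levels, meta, tg, rf,
                             alpha_normality = config$univariate$alpha_normality)
      tag <- sprintf("%s_vs_%s", tg, rf)
      data.table::fwrite(rel, out("univariate_%s.tsv", tag), sep = "\t")
      emit(out("univariate_%s.tsv", tag))
      zt <- zscore_table(rel)
      zm <- data.frame(metabolite = rownames(zt$z), zt$z,
                       check.names = FALSE)
      data.table::fwrite(zm, out("zscores_%s.tsv", tag), sep = "\t")
      emit(out("zscores_%s.tsv", tag))
      if (config$plots) {
        f <- .save_plot(plot_zscores(zt), out("zscores_%s.png", tag), log,
                        height = 6)
        if (!is.null(f)) emit(f)
      }
      uni_tables[[tag]] <- rel
    }
  }

  sto_results <- list()
  for (drv in config$stocsy$drivers) {
    log(sprintf("STOCSY driver %.3f ppm", drv))
    res <- run_stocsy(B_norm, drv, config$stocsy$r_threshold)
    tag <- sprintf("stocsy_%0.3f", drv)
    data.table::fwrite(as.data.frame(res), out("%s.tsv", tag), sep = "\t")
    emit(out("%s.tsv", tag))
    if (config$plots) {
      f <- .save_plot(plot_stocsy(res), out("%s.png", tag), log)
      if (!is.null(f)) emit(f)
    }
    sto_results[[tag]] <- res
  }

  cfg_echo <- unclass(config)
  jsonlite::write_json(.jsonable(cfg_echo), out("config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  emit(out("config.json"))
  summary <- list(
    seed = config$seed,
    comparisons = lapply(reports, function(r)
      list(r2 = r$r2, q2 = r$q2, quality = r$quality, auroc = r$auroc,
           q2_intercept = r$permutation$q2_intercept,
           r2_intercept = r$permutation$r2_intercept,
           permutation_p = r$permutation$p_value,
           valid = r$permutation$valid)))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  emit(out("summary.json"))
  writeLines(log_lines, out("run.log"))
  emit(out("run.log"))

  structure(list(reports = reports, univariate = uni_tables,
                 stocsy = sto_results, manifest = manifest,
                 log = log_lines, config = config),
            class = "run_report")
}

.jsonable <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) return(lapply(x, .jsonable))
  x
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d comparison(s), %d file(s) written\n",
              length(x$reports), length(x$manifest)))
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %-14s R2 %.3f  Q2 %.3f (%s)  AUROC %.3f\n", nm, r$r2,
                r$q2, r$quality, r$auroc))
  }
  invisible(x)
}
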