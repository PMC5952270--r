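#' Write / read a spectral matrix as TSV
#'
#' The file has a `ppm` first column and one column per sample (points as
#' rows), the common interchange layout for 1D spectral tables.
#'
#' @param X a [spectral_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectral_matrix <- function(X, path) {
  stopifnot(inherits(X, "spectral_matrix"))
  dt <- data.table::data.table(ppm = X$ppm)
  for (s in sample_ids(X)) dt[[s]] <- X$intensities[s, ]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_spectral_matrix
#' @param check_unique_tol tolerance on axis-step uniformity.
#' @export
read_spectral_matrix <- function(path, check_unique_tol = 1e-9) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(hdr))
    stop_nmropls("%s: duplicate sample ids in header", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!"ppm" %in% names(dt))
    stop_nmropls("%s: missing 'ppm' column", path)
  num_ok <- vapply(dt, is.numeric, TRUE)
  if (!all(num_ok))
    stop_nmropls("%s: non-numeric column(s): %s", path,
                 paste(names(dt)[!num_ok], collapse = ", "))
  ids <- setdiff(names(dt), "ppm")
  if (anyDuplicated(ids))
    stop_nmropls("%s: duplicate sample ids", path)
  ppm <- dt$ppm
  M <- t(as.matrix(dt[, ids, with = FALSE]))
  rownames(M) <- ids
  d <- diff(ppm)
  if (all(d < 0)) { ppm <- rev(ppm); M <- M[, ncol(M):1, drop = FALSE] }
  d <- diff(ppm)
  if (any(d <= 0)) stop_nmropls("%s: ppm axis not strictly monotone", path)
  if (max(d) - min(d) > check_unique_tol)
    stop_nmropls("%s: ppm axis not uniform within %g", path,
                 check_unique_tol)
  spectral_matrix(ppm, M)
}

#' Write / read sample metadata as TSV
#'
#' Columns `sample_id`, `group`, `subject`, `period` (extra columns such as
#' the generator's ground-truth dilution pass through).
#'
#' @param metadata data.frame.
#' @param path file path.
#' @return `path` / the validated data.frame.
#' @export
write_metadata <- function(metadata, path) {
  data.table::fwrite(metadata, path, sep = "\t")
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  m <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("sample_id", "group", "subject", "period")
  if (!all(need %in% names(m)))
    stop_nmropls("%s: metadata needs columns %s", path,
                 paste(need, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop_nmropls("%s: duplicate sample ids", path)
  m
}

#' Read a metabolite window table as TSV
#'
#' Columns `metabolite`, `ppm_low`, `ppm_high`; repeated rows describe
#' multiplets of one metabolite.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_windows <- function(path) {
  w <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("metabolite", "ppm_low", "ppm_high")
  if (!all(need %in% names(w)))
    stop_nmropls("%s: window table needs columns %s", path,
                 paste(need, collapse = ", "))
  if (any(w$ppm_low >= w$ppm_high))
    stop_nmropls("%s: ppm_low must be below ppm_high", path)
  w
}

#' Serialize a fitted OPLS model to JSON
#'
#' Stores weights, loadings, orthogonal triplets, fit statistics and the
#' bin geometry so a model can be re-applied without the training data.
#'
#' @param model an `opls_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_opls_model <- function(model, path) {
  obj <- model[c("weights", "loadings", "response_loading", "n_ortho",
                 "r2x", "r2y", "centers", "original_sd", "levels",
                 "positive")]
  obj$ortho_weights <- if (is.null(model$ortho_weights)) NULL
                       else as.data.frame(model$ortho_weights)
  obj$ortho_loadings <- if (is.null(model$ortho_loadings)) NULL
                        else as.data.frame(model$ortho_loadings)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a validation report to JSON
#'
#' @param report a `validation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  obj <- list(
    r2 = report$r2, q2 = report$q2, quality = report$quality,
    auroc = report$auroc,
    permutation = list(
      n_perm = report$permutation$n_perm,
      r2_intercept = report$permutation$r2_intercept,
      q2_intercept = report$permutation$q2_intercept,
      p_value = report$permutation$p_value,
      valid = report$permutation$valid,
      records = report$permutation$records),
    roc = report$roc,
    cv = list(n_repeats = report$n_repeats, seed = report$seed,
              predictions = as.list(report$cv$predictions)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
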