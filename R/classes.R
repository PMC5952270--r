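#' Spectral matrix container
#'
#' Holds a set of 1D NMR spectra on a shared, uniform chemical-shift axis.
#' The axis is stored ascending internally (display functions flip it to the
#' conventional descending ppm). Rows of `intensities` are samples.
#'
#' @param ppm numeric axis in ppm, strictly monotone and uniform.
#' @param intensities numeric matrix, samples x points, with rownames as
#'   sample ids.
#' @param excluded list of length-2 numeric vectors recording ppm intervals
#'   already removed from the axis (provenance for downstream binning).
#' @return an object of class `spectral_matrix`.
#' @export
spectral_matrix <- function(ppm, intensities, excluded = list()) {
  intensities <- as.matrix(intensities)
  if (length(ppm) != ncol(intensities))
    stop_nmropls("ppm axis has %d points but intensity matrix has %d columns",
                 length(ppm), ncol(intensities))
  if (is.null(rownames(intensities)))
    rownames(intensities) <- paste0("S", seq_len(nrow(intensities)))
  if (anyDuplicated(rownames(intensities)))
    stop_nmropls("duplicate sample ids in spectral matrix")
  d <- diff(ppm)
  if (length(d) && any(d <= 0)) {
    if (all(d < 0)) {            # descending input: reorder ascending
      ppm <- rev(ppm)
      intensities <- intensities[, ncol(intensities):1, drop = FALSE]
    } else {
      stop_nmropls("ppm axis must be strictly monotone")
    }
  }
  structure(list(ppm = as.numeric(ppm), intensities = intensities,
                 excluded = excluded),
            class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("<spectral_matrix> %d samples x %d points, %.3f-%.3f ppm\n",
              nrow(x$intensities), length(x$ppm), min(x$ppm), max(x$ppm)))
  if (length(x$excluded))
    cat("  excluded:", paste(vapply(x$excluded, function(r)
      sprintf("[%.2f, %.2f]", r[1], r[2]), ""), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectral_matrix <- function(x) dim(x$intensities)

sample_ids <- function(x) UseMethod("sample_ids")
#' @export
sample_ids.spectral_matrix <- function(x) rownames(x$intensities)
#' @export
sample_ids.binned_matrix <- function(x) rownames(x$values)

axis_step <- function(x) {
  d <- diff(x$ppm)
  if (length(d) == 0) return(NA_real_)
  if (max(d) - min(d) > 1e-9)
    stop_nmropls("ppm axis is not uniform (step varies by %.3g)",
                 max(d) - min(d))
  mean(d)
}

#' Binned (bucketed) spectral matrix
#'
#' Samples x bins matrix produced by [bin_spectra()], carrying the bin
#' geometry and provenance flags so that the pipeline stages can refuse to
#' run out of order. `original_sd` is filled by [center_and_pareto_scale()]
#' and used for back-scaling covariances in S-plots.
#'
#' @param edges numeric vector of bin edges (length nbins + 1), half-open
#'   bins `[edges[i], edges[i+1])`.
#' @param centers numeric bin centers.
#' @param values numeric matrix samples x bins, rownames are sample ids.
#' @param normalized,scaled logical provenance flags.
#' @param original_sd numeric per-bin standard deviations recorded at
#'   scaling time (NULL before scaling).
#' @param column_means numeric per-bin means recorded at scaling time.
#' @return an object of class `binned_matrix`.
#' @export
binned_matrix <- function(edges, centers, values, normalized = FALSE,
                          scaled = FALSE, original_sd = NULL,
                          column_means = NULL) {
  values <- as.matrix(values)
  if (length(centers) != ncol(values))
    stop_nmropls("bin centers (%d) do not match value columns (%d)",
                 length(centers), ncol(values))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  colnames(values) <- sprintf("%.4f", centers)
  structure(list(edges = edges, centers = as.numeric(centers),
                 values = values, normalized = normalized, scaled = scaled,
                 original_sd = original_sd, column_means = column_means),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("<binned_matrix> %d samples x %d bins%s%s\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) ", PQN-normalized" else "",
              if (x$scaled) ", centered/pareto-scaled" else ""))
  invisible(x)
}

#' @export
dim.binned_matrix <- function(x) dim(x$values)

#' Subset a binned matrix by sample
#'
#' @param x a `binned_matrix`.
#' @param i row (sample) index or sample ids.
#' @param ... ignored.
#' @return a `binned_matrix` with the selected samples, same bins and flags.
#' @export
`[.binned_matrix` <- function(x, i, ...) {
  binned_matrix(x$edges, x$centers, x$values[i, , drop = FALSE],
                normalized = x$normalized, scaled = x$scaled,
                original_sd = x$original_sd, column_means = x$column_means)
}
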