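#' Statistical total correlation spectroscopy (STOCSY)
#'
#' Correlates a driver variable (the bin or point nearest the requested
#' ppm) against every variable of the matrix across samples. Resonances of
#' the same molecule vary in fixed proportion and correlate near 1, so the
#' high-|r| set reveals the driver metabolite's other multiplets. Run on
#' normalized but unscaled data: correlation is scale-free while the
#' covariance trace keeps the spectral line shape.
#'
#' @param B a normalized, unscaled [binned_matrix()] or a
#'   [spectral_matrix()] (>= 3 samples).
#' @param driver_ppm chemical shift of the driver variable; the nearest
#'   retained variable is used and echoed in the result.
#' @param r_threshold |r| at or above which a variable is listed as
#'   connected to the driver.
#' @return an object of class `stocsy_result`: data.frame `ppm`, `r`,
#'   `covariance`, `connected`, plus attributes `driver_ppm` (as used) and
#'   `r_threshold`.
#' @export
run_stocsy <- function(B, driver_ppm, r_threshold = 0.8) {
  if (inherits(B, "binned_matrix")) {
    if (B$scaled)
      stop_nmropls("run STOCSY on normalized, unscaled data")
    V <- B$values; centers <- B$centers
  } else if (inherits(B, "spectral_matrix")) {
    V <- B$intensities; centers <- B$ppm
  } else stop_nmropls("need a binned_matrix or spectral_matrix")
  if (nrow(V) < 3L) stop_nmropls("STOCSY needs at least 3 samples")
  j <- which.min(abs(centers - driver_ppm))
  d <- V[, j]
  if (stats::sd(d) == 0)
    stop_nmropls("driver variable at %.4f ppm has zero variance", centers[j])
  dc <- d - mean(d)
  n <- nrow(V)
  covs <- crossprod(V, dc)[, 1] / (n - 1)
  sds <- apply(V, 2, stats::sd)
  r <- ifelse(sds > 0, covs / (sds * stats::sd(d)), 0)
  out <- data.frame(ppm = centers, r = r, covariance = covs,
                    connected = abs(r) >= r_threshold, row.names = NULL)
  structure(out, class = c("stocsy_result", "data.frame"),
            driver_ppm = centers[j], r_threshold = r_threshold)
}

#' @export
print.stocsy_result <- function(x, ...) {
  cat(sprintf("<stocsy_result> driver %.4f ppm, %d/%d variables with |r| >= %.2f\n",
              attr(x, "driver_ppm"), sum(x$connected), nrow(x),
              attr(x, "r_threshold")))
  invisible(x)
}
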