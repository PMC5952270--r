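#' Segment-wise spectral alignment
#'
#' Corrects small chemical-shift differences between spectra by splitting
#' the axis into fixed-length segments and shifting each segment of each
#' spectrum by the integer-point lag (up to `max_shift_ppm`) that maximizes
#' its cross-correlation with the reference spectrum's segment. Points
#' vacated at segment edges are filled by edge-value extension. The output
#' axis is identical to the input axis.
#'
#' @param X a [spectral_matrix()].
#' @param segment_ppm segment length in ppm.
#' @param max_shift_ppm maximum allowed shift in ppm (>= 0).
#' @param reference `"median"` (default), `"mean"`, or a sample id/index
#'   whose spectrum serves as reference.
#' @return an aligned [spectral_matrix()].
#' @export
align_spectra <- function(X, segment_ppm = 0.2, max_shift_ppm = 0.02,
                          reference = "median") {
  stopifnot(inherits(X, "spectral_matrix"), max_shift_ppm >= 0)
  step <- axis_step(X)
  seg_len <- floor(segment_ppm / step)
  if (seg_len < 3L)
    stop_nmropls("segment length %.4f ppm is shorter than 3 grid points",
                 segment_ppm)
  max_lag <- floor(max_shift_ppm / step)
  if (max_lag == 0L) return(X)

  M <- X$intensities
  ref <- if (identical(reference, "median")) {
    apply(M, 2, stats::median)
  } else if (identical(reference, "mean")) {
    colMeans(M)
  } else {
    M[reference, ]
  }
  np <- ncol(M)
  starts <- seq(1L, np, by = seg_len)
  # merge a short trailing remainder into the previous segment
  if (length(starts) > 1L && np - starts[length(starts)] + 1L < seg_len)
    starts <- starts[-length(starts)]
  ends <- c(starts[-1L] - 1L, np)

  out <- M
  lags <- -max_lag:max_lag
  for (s in seq_along(starts)) {
    idx <- starts[s]:ends[s]
    r <- ref[idx]
    for (i in seq_len(nrow(M))) {
      seg <- M[i, idx]
      best <- 0L; best_score <- -Inf
      for (lg in lags) {
        shifted <- .shift_fill(seg, lg)
        sc <- sum(r * shifted)
        if (sc > best_score + 1e-12 ||
            (abs(sc - best_score) <= 1e-12 && abs(lg) < abs(best))) {
          best_score <- sc; best <- lg
        }
      }
      if (best != 0L) out[i, idx] <- .shift_fill(seg, best)
    }
  }
  spectral_matrix(X$ppm, out, excluded = X$excluded)
}

# shift a vector by k points (positive = toward higher index), filling
# vacated positions with the edge value
.shift_fill <- function(v, k) {
  n <- length(v)
  if (k == 0L) return(v)
  if (k > 0L) c(rep(v[1L], k), v[seq_len(n - k)])
  else c(v[(1L - k):n], rep(v[n], -k))
}

#' Remove ppm regions from a spectral or binned matrix
#'
#' Drops every point (or bin) whose center lies inside any of the given
#' closed intervals; the order of the remainder is preserved. Typical use
#' is removal of the residual water and urea signals at 4.2-5.9 ppm.
#'
#' @param X a [spectral_matrix()] or [binned_matrix()].
#' @param regions list of length-2 numeric ppm intervals (a single interval
#'   may be given as a bare vector).
#' @return object of the same class with the regions removed.
#' @export
exclude_regions <- function(X, regions = list(c(4.2, 5.9))) {
  if (is.numeric(regions) && length(regions) == 2L) regions <- list(regions)
  if (length(regions) == 0L) return(X)
  centers <- if (inherits(X, "spectral_matrix")) X$ppm else X$centers
  drop <- rep(FALSE, length(centers))
  for (r in regions) {
    if (r[1] > r[2]) r <- rev(r)
    drop <- drop | (centers >= r[1] & centers <= r[2])
  }
  if (all(drop))
    stop_nmropls("exclusion removes every point of the axis")
  if (inherits(X, "spectral_matrix")) {
    spectral_matrix(X$ppm[!drop], X$intensities[, !drop, drop = FALSE],
                    excluded = c(X$excluded, regions))
  } else {
    binned_matrix(X$edges, X$centers[!drop],
                  X$values[, !drop, drop = FALSE],
                  normalized = X$normalized, scaled = X$scaled,
                  original_sd = X$original_sd[!drop],
                  column_means = X$column_means[!drop])
  }
}

#' Bin (bucket) a spectral matrix
#'
#' Tiles `[range[1], range[2])` with half-open bins of fixed width; a
#' trailing partial bin is dropped. The bin value is the *sum* of point
#' intensities falling in the bin, so integrals are conserved: the total
#' over retained bins equals the total over retained points. Bins that
#' contain no axis points (e.g. inside a previously excluded region), or
#' whose center falls inside a recorded excluded region, are dropped.
#'
#' @param X a [spectral_matrix()] (align/exclude first).
#' @param range length-2 ppm range to bin.
#' @param width bin width in ppm.
#' @return a [binned_matrix()].
#' @export
bin_spectra <- function(X, range = c(0.5, 9.8), width = 0.04) {
  stopifnot(inherits(X, "spectral_matrix"))
  if (width <= 0) stop_nmropls("bin width must be > 0")
  if (width > diff(range)) stop_nmropls("bin width exceeds the ppm range")
  nb <- floor((range[2] - range[1]) / width + 1e-9)
  edges <- range[1] + width * (0:nb)
  centers <- edges[-length(edges)] + width / 2
  # half-open assignment [edge_i, edge_{i+1})
  bin_of <- findInterval(X$ppm, edges, left.open = FALSE,
                         rightmost.closed = FALSE)
  in_range <- bin_of >= 1L & bin_of <= nb & X$ppm < edges[length(edges)]
  counts <- tabulate(bin_of[in_range], nbins = nb)
  V <- matrix(0, nrow(X$intensities), nb,
              dimnames = list(rownames(X$intensities), NULL))
  for (b in which(counts > 0L)) {
    cols <- in_range & bin_of == b
    V[, b] <- rowSums(X$intensities[, cols, drop = FALSE])
  }
  keep <- counts > 0L
  for (r in X$excluded) {
    if (r[1] > r[2]) r <- rev(r)
    keep <- keep & !(centers >= r[1] & centers <= r[2])
  }
  binned_matrix(edges, centers[keep], V[, keep, drop = FALSE])
}

#' Probabilistic quotient normalization
#'
#' Removes per-sample dilution differences: each row is first divided by its
#' total (integral normalization); the reference is the element-wise median
#' of the integral-normalized matrix (or the median over a chosen sample
#' subset); each row is then divided by the median of its quotients against
#' the reference, taken over bins where the reference is positive. After the
#' transform the median quotient of every row against the same reference
#' is 1.
#'
#' @param B a [binned_matrix()] (not yet scaled).
#' @param reference `"median"` (default) or a vector of sample ids/indices
#'   over which the median reference row is computed (e.g. the control
#'   group).
#' @return a normalized [binned_matrix()]; the estimated per-sample dilution
#'   factors (the median quotients, on the integral-normalized scale) are
#'   attached as attribute `"pqn_factors"`.
#' @export
pqn_normalize <- function(B, reference = "median") {
  stopifnot(inherits(B, "binned_matrix"))
  if (B$scaled)
    stop_nmropls("PQN must run before centering/scaling")
  V <- B$values
  tot <- rowSums(V)
  if (any(tot <= 0))
    stop_nmropls("sample(s) with non-positive total intensity: %s",
                 paste(rownames(V)[tot <= 0], collapse = ", "))
  V <- V / tot
  ref_rows <- if (identical(reference, "median")) seq_len(nrow(V))
              else reference
  ref <- apply(V[ref_rows, , drop = FALSE], 2, stats::median)
  pos <- ref > 0
  if (!any(pos)) stop_nmropls("reference spectrum has no positive bins")
  q <- apply(V[, pos, drop = FALSE], 1,
             function(row) stats::median(row / ref[pos]))
  V <- V / q
  out <- binned_matrix(B$edges, B$centers, V, normalized = TRUE,
                       scaled = FALSE)
  attr(out, "pqn_factors") <- stats::setNames(q * tot, rownames(V))
  out
}

#' Mean-center and pareto-scale
#'
#' Centers each bin to mean zero and divides it by the square root of its
#' sample standard deviation (pareto scaling, the usual compromise for NMR
#' data between no scaling and unit variance). Zero-variance bins are
#' centered and left unscaled. Original per-bin SDs and means are stored on
#' the result for back-scaling of loadings and covariances.
#'
#' @param B a normalized [binned_matrix()] with >= 2 samples.
#' @return a centered, pareto-scaled [binned_matrix()].
#' @export
center_and_pareto_scale <- function(B) {
  stopifnot(inherits(B, "binned_matrix"))
  if (!B$normalized)
    stop_nmropls("scale after normalization: run pqn_normalize() first")
  if (B$scaled) stop_nmropls("matrix is already scaled")
  if (nrow(B$values) < 2L)
    stop_nmropls("scaling needs at least 2 samples")
  mu <- colMeans(B$values)
  sds <- apply(B$values, 2, stats::sd)
  V <- sweep(B$values, 2, mu)
  nz <- sds > 0
  V[, nz] <- sweep(V[, nz, drop = FALSE], 2, sqrt(sds[nz]), `/`)
  binned_matrix(B$edges, B$centers, V, normalized = TRUE, scaled = TRUE,
                original_sd = sds, column_means = mu)
}

#' Full preprocessing pipeline
#'
#' Runs the fixed stage order align -> exclude -> bin -> PQN ->
#' center/pareto on a raw spectral matrix.
#'
#' @param X a raw [spectral_matrix()].
#' @param align run the alignment stage (default TRUE).
#' @param segment_ppm,max_shift_ppm alignment parameters.
#' @param exclude list of ppm intervals to remove (water/urea by default).
#' @param bin_range,bin_width binning parameters.
#' @param pqn_reference reference selector for [pqn_normalize()].
#' @param scale also center and pareto-scale (set FALSE to obtain the
#'   normalized, unscaled matrix used by the univariate and STOCSY stages).
#' @return a [binned_matrix()]; `pqn_factors` attribute as in
#'   [pqn_normalize()].
#' @export
preprocess_spectra <- function(X, align = TRUE, segment_ppm = 0.2,
                               max_shift_ppm = 0.02,
                               exclude = list(c(4.2, 5.9)),
                               bin_range = c(0.5, 9.8), bin_width = 0.04,
                               pqn_reference = "median", scale = TRUE) {
  if (align) X <- align_spectra(X, segment_ppm, max_shift_ppm)
  X <- exclude_regions(X, exclude)
  B <- bin_spectra(X, bin_range, bin_width)
  B <- pqn_normalize(B, pqn_reference)
  if (scale) {
    f <- attr(B, "pqn_factors")
    B <- center_and_pareto_scale(B)
    attr(B, "pqn_factors") <- f
  }
  B
}
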