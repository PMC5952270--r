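#' Derive a stage-local seed from a global seed
#'
#' All randomness in the package flows from a single integer seed; stages
#' derive their own seeds deterministically so that reordering independent
#' stages does not perturb one another's random streams.
#'
#' @param seed integer global seed.
#' @param offset integer stage offset (any small non-negative integer).
#' @return an integer seed strictly below 2^31.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # 2^31 - 1 is a prime; multiplication kept in double precision is exact
  # for these magnitudes
  as.integer((abs(seed) %% 2147483647 * 48271 + offset * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nmropls <- function(...) stop(sprintf(...), call. = FALSE)

#' Collection-period labels and hour ranges
#'
#' The eight urine collection windows of the longitudinal design,
#' in hours after treatment.
#'
#' @return a data.frame with columns `period`, `hours_start`, `hours_end`.
#' @export
period_table <- function() {
  data.frame(
    period      = paste0("T", 1:8),
    hours_start = c(0, 8, 24, 32, 48, 72, 96, 120),
    hours_end   = c(8, 24, 32, 48, 72, 96, 120, 144),
    stringsAsFactors = FALSE
  )
}
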