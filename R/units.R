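# Unit conversions between lattice/Monte-Carlo units and physical units.
# One pixel is 3 um; one MCS is 27 s, derived from a reference displacement of
# 0.3 um per MCS against a 40 um/h peak fibroblast migration speed.

#' Convert Monte-Carlo steps to seconds
#'
#' @param n_mcs Number of Monte-Carlo steps (>= 0).
#' @param p Parameter list (for the configured seconds-per-MCS).
#' @return Seconds.
#' @export
mcs_to_seconds <- function(n_mcs, p = default_params()) {
  if (any(n_mcs < 0)) stop("n_mcs must be >= 0")
  n_mcs * p$units$seconds_per_mcs
}

#' Convert Monte-Carlo steps to days
#' @inheritParams mcs_to_seconds
#' @return Days.
#' @export
mcs_to_days <- function(n_mcs, p = default_params()) mcs_to_seconds(n_mcs, p) / 86400

#' Monte-Carlo steps per simulated day
#' @param p Parameter list.
#' @return MCS per day (3200 at the 27 s default).
#' @export
mcs_per_day <- function(p = default_params()) 86400 / p$units$seconds_per_mcs

#' Convert days to Monte-Carlo steps
#' @param days Simulated days.
#' @param p Parameter list.
#' @return MCS (not rounded).
#' @export
days_to_mcs <- function(days, p = default_params()) days * mcs_per_day(p)

#' Convert pixels to micrometres
#' @param px Lengths in pixels.
#' @param p Parameter list.
#' @return Micrometres.
#' @export
pixels_to_um <- function(px, p = default_params()) px * p$units$pixel_um
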