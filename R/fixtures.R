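# Synthetic calibration curves (stand-ins for literature time courses) and
# delimited time-series I/O.

#' Generate synthetic calibration curves
#'
#' Smooth parameterised curves over days 0-18 carrying the qualitative
#' landmarks of healthy healing: a log-normal-shaped myofibroblast peak near
#' day 4 and senescent-myofibroblast peak near day 7, a macrophage logistic
#' plateau at ~2x the initial level near day 3.5, a rising-then-saturating
#' fibroblast curve, a double-plateau ECM curve and an early-peaked
#' wound-closure rate. These are deliberately synthetic fixtures, not
#' re-digitised literature data.
#'
#' @param spec Optional named list overriding per-observable settings; each
#'   entry may set `peak_day`, `peak_value`, `width` (log-days) for the
#'   peaked curves, or `base`/`top`/`mid`/`rate` for the logistic ones.
#' @param days Sample days (default 0 to 18 by 0.25).
#' @return Long data.frame with columns observable, day, value.
#' @export
generate_calibration_curves <- function(spec = list(),
                                        days = seq(0, 18, by = 0.25)) {
  defaults <- list(
    fibroblasts = list(base = 150, top = 320, mid = 3, rate = 1.2),
    myofibroblasts = list(peak_day = 4, peak_value = 60, width = 0.45),
    senescent = list(peak_day = 7, peak_value = 25, width = 0.4),
    macrophages = list(base = 24, top = 48, mid = 2, rate = 1.6),
    ecm = list(p1 = 14000, p2 = 9000, rise = 1.2, drop_day = 7, drop_rate = 1.0),
    closure_rate = list(peak_day = 1.5, peak_value = 0.08, width = 0.7))
  for (k in names(spec)) defaults[[k]] <- utils::modifyList(defaults[[k]], spec[[k]])
  lognorm_peak <- function(d, s) {
    v <- ifelse(d <= 0, 0,
                exp(-(log(d / s$peak_day))^2 / (2 * s$width^2)))
    s$peak_value * v
  }
  logistic <- function(d, s) s$base + (s$top - s$base) /
    (1 + exp(-s$rate * (d - s$mid)))
  out <- rbind(
    data.frame(observable = "fibroblasts", day = days,
               value = logistic(days, defaults$fibroblasts)),
    data.frame(observable = "myofibroblasts", day = days,
               value = lognorm_peak(days, defaults$myofibroblasts)),
    data.frame(observable = "senescent", day = days,
               value = lognorm_peak(days, defaults$senescent)),
    data.frame(observable = "macrophages", day = days,
               value = logistic(days, defaults$macrophages)),
    data.frame(observable = "ecm", day = days, value = with(defaults$ecm,
               p1 / (1 + exp(-rise * (days - 1))) -
                 (p1 - p2) / (1 + exp(-drop_rate * (days - drop_day))))),
    data.frame(observable = "closure_rate", day = days,
               value = lognorm_peak(days, defaults$closure_rate)))
  out$value <- pmax(out$value, 0)
  out
}

#' Write calibration curves to a delimited file
#' @param curves Long data.frame (observable, day, value).
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  utils::write.table(curves, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read calibration curves
#' @param path Tab-separated file from [write_curves()].
#' @return Long data.frame (observable, day, value).
#' @export
read_curves <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("observable", "day", "value")
  if (!all(need %in% names(out)))
    stop("curve file must have columns: ", paste(need, collapse = ", "))
  for (o in unique(out$observable)) {
    d <- out$day[out$observable == o]
    if (any(diff(d) <= 0)) stop("days must be strictly increasing for ", o)
  }
  if (any(out$value < 0)) stop("curve values must be >= 0")
  out
}

#' Write a simulation time series
#'
#' Tab-separated table with a header (day, mcs, per-type counts, per-field
#' totals, closure fraction and rate, cumulative senescence inductions by
#' mechanism); round-trips losslessly through [read_timeseries()].
#'
#' @param ts Time-series data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation time series
#' @param path File written by [write_timeseries()].
#' @return data.frame.
#' @export
read_timeseries <- function(path) {
  out <- tryCatch(suppressWarnings(utils::read.delim(path, stringsAsFactors = FALSE)),
                  error = function(e)
                    stop("malformed time-series file ", path, ": ",
                         conditionMessage(e)))
  if (!"mcs" %in% names(out))
    stop("malformed time-series file ", path, ": missing 'mcs' column")
  out
}
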