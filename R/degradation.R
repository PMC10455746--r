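#' Construct a degradation time series
#'
#' Timestamped pH and electrical conductivity of one sample group during
#' immersion degradation.
#'
#' @param label sample/group label.
#' @param times days, strictly increasing.
#' @param ph pH values in `[0, 14]`, same length.
#' @param conductivity conductivity, uS/cm, same length.
#' @return object of class `degradation_series`.
#' @export
degradation_series <- function(label, times, ph, conductivity) {
  if (!is.numeric(times) || is.unsorted(times, strictly = TRUE))
    stop_field("times", "must be strictly increasing")
  if (length(ph) != length(times) || length(conductivity) != length(times))
    stop_field("ph/conductivity", "must match the time axis length")
  if (any(!is.finite(times)) || any(!is.finite(ph)) ||
      any(!is.finite(conductivity)))
    stop_field("series", "values must be finite")
  if (any(ph < 0 | ph > 14))
    stop_field("ph", "must lie in [0, 14]")
  structure(
    list(label = label, times = times, ph = ph, conductivity = conductivity),
    class = "degradation_series"
  )
}

#' @export
print.degradation_series <- function(x, ...) {
  cat(sprintf("Degradation series '%s': %d samples over %g-%g days\n",
              x$label, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Read a degradation series CSV
#'
#' CSV with header `time_days,ph,conductivity_uScm`.
#'
#' @param path file path.
#' @param label series label (defaults to the file name).
#' @return a [degradation_series].
#' @export
read_degradation_series <- function(path, label = basename(path)) {
  tab <- utils::read.csv(check_file(path), stringsAsFactors = FALSE)
  need <- c("time_days", "ph", "conductivity_uScm")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("degradation file %s is missing columns: %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  degradation_series(label, tab$time_days, tab$ph, tab$conductivity_uScm)
}

#' Descriptive summary of a degradation series
#'
#' Initial and final value, total change, and maximum per-interval rate
#' of change (finite differences) for both channels. The module is
#' intentionally descriptive — no kinetic model is fitted.
#'
#' @param series a [degradation_series] with >= 2 points.
#' @return data.frame with one row per channel: `initial`, `final`,
#'   `total_change`, `max_rate` (per day, signed by the largest-magnitude
#'   interval change).
#' @export
series_summary <- function(series) {
  stopifnot(inherits(series, "degradation_series"))
  if (length(series$times) < 2L)
    stop("summary needs at least 2 time points", call. = FALSE)
  one <- function(v) {
    rates <- diff(v) / diff(series$times)
    data.frame(initial = v[1L], final = v[length(v)],
               total_change = v[length(v)] - v[1L],
               max_rate = rates[which.max(abs(rates))])
  }
  cbind(channel = c("ph", "conductivity"),
        rbind(one(series$ph), one(series$conductivity)))
}

#' First threshold-crossing time
#'
#' Time at which the channel first crosses the threshold, linearly
#' interpolated between the bracketing samples. Direction defaults to
#' the channel's physical course: downward for pH (acidification),
#' upward for conductivity (ion release). A series already past the
#' threshold at its first sample returns time 0 of that sample.
#'
#' @param series a [degradation_series].
#' @param channel `"ph"` or `"conductivity"`.
#' @param threshold threshold value.
#' @param direction `"below"` or `"above"`; default depends on channel.
#' @return crossing time in days, or `NA` if never crossed.
#' @export
time_to_threshold <- function(series, channel = c("ph", "conductivity"),
                              threshold,
                              direction = NULL) {
  stopifnot(inherits(series, "degradation_series"))
  channel <- match.arg(channel)
  check_number(threshold, "threshold")
  if (is.null(direction))
    direction <- if (channel == "ph") "below" else "above"
  direction <- match.arg(direction, c("below", "above"))
  v <- series[[channel]]
  crossed <- if (direction == "below") v <= threshold else v >= threshold
  if (crossed[1L]) return(series$times[1L])
  i <- which(crossed)[1L]
  if (is.na(i)) return(NA_real_)
  t0 <- series$times[i - 1L]; t1 <- series$times[i]
  v0 <- v[i - 1L]; v1 <- v[i]
  if (v1 == v0) return(t1)
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

#' Compare two degradation series
#'
#' Pointwise differences (a minus b) on the intersection of the two time
#' ranges, linearly interpolated onto a common grid, plus the difference
#' of the per-channel summary statistics.
#'
#' @param a,b [degradation_series] objects with overlapping time ranges.
#' @return list with `grid` (common times), `ph_diff`, `cond_diff`, and
#'   `summary_diff` (a's summary minus b's, per channel).
#' @export
compare_series <- function(a, b) {
  stopifnot(inherits(a, "degradation_series"),
            inherits(b, "degradation_series"))
  lo <- max(min(a$times), min(b$times))
  hi <- min(max(a$times), max(b$times))
  if (lo >= hi)
    stop("series have disjoint time ranges", call. = FALSE)
  grid <- sort(unique(c(a$times[a$times >= lo & a$times <= hi],
                        b$times[b$times >= lo & b$times <= hi])))
  ia_ph <- stats::approx(a$times, a$ph, xout = grid)$y
  ib_ph <- stats::approx(b$times, b$ph, xout = grid)$y
  ia_c <- stats::approx(a$times, a$conductivity, xout = grid)$y
  ib_c <- stats::approx(b$times, b$conductivity, xout = grid)$y
  sa <- series_summary(a); sb <- series_summary(b)
  sd_diff <- sa
  num <- vapply(sa, is.numeric, logical(1))
  sd_diff[num] <- sa[num] - sb[num]
  list(grid = grid, ph_diff = ia_ph - ib_ph, cond_diff = ia_c - ib_c,
       summary_diff = sd_diff)
}
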