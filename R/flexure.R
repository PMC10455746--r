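#' Construct a 3-point flexure specimen
#'
#' A bar tested in 3-point bending: support span, caliper width and
#' thickness triplets (measured at three points along the bar and
#' averaged), and the recorded load-deflection curve. The breaking load
#' is the maximum load of the curve.
#'
#' @param specimen_id label.
#' @param span center-to-center support distance, mm.
#' @param width_mm three caliper width readings, mm.
#' @param thickness_mm three caliper thickness readings, mm.
#' @param deflection crosshead deflection, mm, strictly increasing.
#' @param load load, N, same length as `deflection`.
#' @param meta free-form provenance (ground truth for synthetic curves).
#' @return object of class `flexure_specimen`.
#' @export
flexure_specimen <- function(specimen_id, span, width_mm, thickness_mm,
                             deflection, load, meta = list()) {
  check_number(span, "span", lower = 0, strict_lower = TRUE)
  for (nm in c("width_mm", "thickness_mm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
      stop_field(nm, "must be 3 positive caliper readings")
  }
  if (!is.numeric(deflection) || !is.numeric(load) ||
      length(deflection) != length(load))
    stop_field("curve", "deflection and load must be equal-length numeric")
  if (length(deflection) < 1L) stop_field("curve", "must be non-empty")
  if (any(!is.finite(deflection)) || any(!is.finite(load)))
    stop_field("curve", "must be finite")
  if (is.unsorted(deflection, strictly = TRUE))
    stop_field("deflection", "must be strictly increasing")
  structure(
    list(specimen_id = specimen_id, span = span,
         width_mm = width_mm, thickness_mm = thickness_mm,
         curve = data.frame(deflection_mm = deflection, load_N = load),
         break_load = max(load), meta = meta),
    class = "flexure_specimen"
  )
}

#' @export
print.flexure_specimen <- function(x, ...) {
  cat(sprintf(
    "Flexure specimen '%s': span %g mm, w %.3g mm, b %.3g mm, %d curve points, P = %.4g N\n",
    x$specimen_id, x$span, mean(x$width_mm), mean(x$thickness_mm),
    nrow(x$curve), x$break_load))
  invisible(x)
}

#' Average caliper dimensions
#'
#' Arithmetic mean of the three width and three thickness readings.
#'
#' @param specimen a [flexure_specimen].
#' @return named numeric `c(w = ..., b = ...)`, mm.
#' @export
average_dimensions <- function(specimen) {
  stopifnot(inherits(specimen, "flexure_specimen"))
  c(w = mean(specimen$width_mm), b = mean(specimen$thickness_mm))
}

#' Flexural strength in 3-point bending
#'
#' \deqn{\sigma = \frac{3 P I}{2 w b^2}}
#' with breaking load `P` (N), support span `I` (mm), specimen width `w`
#' and thickness `b` (mm). With these units the result is N/mm^2 = MPa.
#'
#' @param P breaking load, N (>= 0).
#' @param span support span I, mm (> 0).
#' @param w specimen width, mm (> 0).
#' @param b specimen thickness, mm (> 0).
#' @return flexural strength, MPa.
#' @examples
#' flexural_strength(10, 40, 6, 6) # 2.778 MPa
#' @export
flexural_strength <- function(P, span, w, b) {
  check_number(P, "P", lower = 0)
  check_number(span, "span", lower = 0, strict_lower = TRUE)
  check_number(w, "w", lower = 0, strict_lower = TRUE)
  check_number(b, "b", lower = 0, strict_lower = TRUE)
  3 * P * span / (2 * w * b^2)
}

#' Elastic modulus from the linear load-deflection window
#'
#' Ordinary least-squares slope `m` (N/mm) of the load-deflection curve
#' restricted to the quasi-linear window between `window[1]` and
#' `window[2]` of the breaking load (default 20-80 %), converted to the
#' modulus by rectangular-section beam theory:
#' \deqn{E = \frac{m L^3}{4 w b^3}}
#' (equivalent to the midspan deflection \eqn{\delta = P L^3 / (48 E I_m)}
#' with second moment \eqn{I_m = w b^3 / 12}).
#'
#' @param specimen a [flexure_specimen].
#' @param window load window as fractions of the breaking load.
#' @return list with `modulus` (MPa) and `slope` (N/mm).
#' @export
elastic_modulus <- function(specimen, window = c(0.2, 0.8)) {
  stopifnot(inherits(specimen, "flexure_specimen"))
  if (length(window) != 2L || window[1L] >= window[2L] ||
      window[1L] < 0 || window[2L] > 1)
    stop_field("window", "must be increasing fractions within [0, 1]")
  P <- specimen$break_load
  sel <- specimen$curve$load_N >= window[1L] * P &
    specimen$curve$load_N <= window[2L] * P
  if (sum(sel) < 5L)
    stop(sprintf("insufficient data: %d points in the %g-%g%% load window (need >= 5)",
                 sum(sel), 100 * window[1L], 100 * window[2L]), call. = FALSE)
  d <- specimen$curve$deflection_mm[sel]
  if (max(d) - min(d) <= 0 || stats::sd(d) == 0)
    stop("degenerate curve: no deflection spread in the fitting window",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, d), specimen$curve$load_N[sel])
  m <- fit$coefficients[[2L]]
  dims <- average_dimensions(specimen)
  list(modulus = m * specimen$span^3 / (4 * dims[["w"]] * dims[["b"]]^3),
       slope = m)
}

#' Bending elongation at break
#'
#' The crosshead deflection at the curve point carrying the maximum
#' (breaking) load, in mm; not converted to strain.
#'
#' @param specimen a [flexure_specimen].
#' @return deflection at break, mm.
#' @export
elongation_at_break <- function(specimen) {
  stopifnot(inherits(specimen, "flexure_specimen"))
  specimen$curve$deflection_mm[which.max(specimen$curve$load_N)]
}

#' Full analysis of one flexure specimen
#'
#' @param specimen a [flexure_specimen].
#' @param window linear-fit load window, see [elastic_modulus()].
#' @return object of class `flexure_result`: list with `specimen_id`,
#'   `sigma` (MPa), `modulus` (MPa), `elongation_at_break` (mm), `slope`
#'   (N/mm).
#' @export
analyze_flexure <- function(specimen, window = c(0.2, 0.8)) {
  dims <- average_dimensions(specimen)
  em <- elastic_modulus(specimen, window = window)
  structure(
    list(specimen_id = specimen$specimen_id,
         sigma = flexural_strength(specimen$break_load, specimen$span,
                                   dims[["w"]], dims[["b"]]),
         modulus = em$modulus,
         elongation_at_break = elongation_at_break(specimen),
         slope = em$slope),
    class = "flexure_result"
  )
}

#' @export
print.flexure_result <- function(x, digits = 4, ...) {
  cat(sprintf("Flexure result '%s': sigma = %s MPa, E = %s MPa, A_g = %s mm\n",
              x$specimen_id, format(x$sigma, digits = digits),
              format(x$modulus, digits = digits),
              format(x$elongation_at_break, digits = digits)))
  invisible(x)
}

#' Cohort summary of flexure results
#'
#' Mean ± sample SD per mechanical metric over a specimen cohort.
#'
#' @param results list of `flexure_result` objects (>= 2).
#' @return data.frame with one row per metric (`sigma`, `modulus`,
#'   `elongation_at_break`): n, mean, sd.
#' @export
flexure_group_summary <- function(results) {
  if (!is.list(results) ||
      !all(vapply(results, inherits, logical(1), "flexure_result")))
    stop_field("results", "must be a list of flexure_result objects")
  if (length(results) < 2L)
    stop("sample SD undefined for fewer than 2 specimens", call. = FALSE)
  do.call(rbind, lapply(c("sigma", "modulus", "elongation_at_break"),
    function(metric) {
      v <- vapply(results, `[[`, numeric(1), metric)
      data.frame(metric = metric, n = length(v), mean = mean(v),
                 sd = stats::sd(v))
    }))
}

#' Read a load-deflection curve CSV
#'
#' CSV with header `deflection_mm,load_N`; specimen geometry is supplied
#' separately when constructing the [flexure_specimen].
#'
#' @param path file path.
#' @return data.frame with columns `deflection_mm`, `load_N`.
#' @export
read_flexure_curve <- function(path) {
  tab <- utils::read.csv(check_file(path), stringsAsFactors = FALSE)
  if (!all(c("deflection_mm", "load_N") %in% names(tab)))
    stop(sprintf("curve %s needs columns deflection_mm, load_N", path),
         call. = FALSE)
  tab
}
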