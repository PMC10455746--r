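#' Subtract a background spectrum
#'
#' The background (e.g. the glass dish with culture medium) is linearly
#' interpolated onto the spectrum's axis and subtracted pointwise. Axis
#' points outside the background's range use the nearest background value
#' (constant extension); fully disjoint axes are an error.
#'
#' @param spectrum a [raman_spectrum].
#' @param background a [raman_spectrum] with an overlapping axis range.
#' @return background-subtracted [raman_spectrum].
#' @export
subtract_background <- function(spectrum, background) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(background, "raman_spectrum"))
  if (min(background$wavenumber) > max(spectrum$wavenumber) ||
      max(background$wavenumber) < min(spectrum$wavenumber))
    stop("spectrum and background axes are disjoint", call. = FALSE)
  bg <- stats::approx(background$wavenumber, background$intensity,
                      xout = spectrum$wavenumber, rule = 2)$y
  out <- spectrum
  out$intensity <- spectrum$intensity - bg
  out
}

# evaluate polynomial with coefficients in increasing degree order
polyval_inc <- function(coeffs, x) {
  y <- numeric(length(x))
  for (k in seq_along(coeffs)) y <- y + coeffs[k] * x^(k - 1)
  y
}

#' Baseline correction
#'
#' Removes a slowly varying baseline under the Raman bands. Two methods:
#'
#' * `"modpoly"` (default): modified-polynomial fitting. A polynomial of
#'   the given order is least-squares fitted to the spectrum; intensities
#'   above the fit are clipped to it and the fit repeated, so the
#'   polynomial relaxes under the peaks onto the baseline. Iteration stops
#'   when the relative change of the fitted baseline drops below `tol`
#'   or after `max_iter` iterations; non-convergence is flagged on the
#'   result (`meta$baseline_converged`), never silent.
#' * `"endpoint_linear"`: the straight line through the first and last
#'   points of the spectrum, suitable for short windows such as the
#'   900-1000 1/cm apatite region.
#'
#' @param spectrum a [raman_spectrum].
#' @param method `"modpoly"` or `"endpoint_linear"`.
#' @param order polynomial order for `modpoly` (default 3).
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @return baseline-corrected [raman_spectrum]; the estimated baseline is
#'   stored in `meta$baseline`.
#' @export
baseline_correct <- function(spectrum, method = c("modpoly", "endpoint_linear"),
                             order = 3, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  method <- match.arg(method)
  x <- spectrum$wavenumber
  y <- spectrum$intensity
  if (method == "endpoint_linear") {
    n <- length(x)
    slope <- (y[n] - y[1L]) / (x[n] - x[1L])
    base <- y[1L] + slope * (x - x[1L])
    converged <- TRUE
  } else {
    order <- check_number(order, "order", lower = 0)
    if (length(x) < order + 2)
      stop_field("spectrum", sprintf("needs >= %d points for order-%d baseline",
                                     order + 2, order))
    # center/scale the axis for numerical conditioning of the polyfit
    xs <- (x - mean(x)) / stats::sd(x)
    X <- outer(xs, 0:order, `^`)
    qrX <- qr(X)
    work <- y
    scale_ref <- max(abs(y), 1e-12)
    base <- rep(0, length(y))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      new_base <- drop(X %*% qr.coef(qrX, work))
      delta <- max(abs(new_base - base)) / scale_ref
      base <- new_base
      work <- pmin(work, base)  # clip peaks, refit to the lower envelope
      if (delta < tol) { converged <- TRUE; break }
    }
  }
  out <- spectrum
  out$intensity <- y - base
  out$meta$baseline <- base
  out$meta$baseline_method <- method
  out$meta$baseline_converged <- converged
  if (!converged)
    warning(sprintf("modpoly baseline did not converge within %d iterations",
                    max_iter), call. = FALSE)
  out
}

#' Savitzky-Golay smoothing
#'
#' Each intensity is replaced by the value, at that point, of the
#' degree-`order` least-squares polynomial fitted to its centered window
#' of `window` points (defaults: second order, 7 points). Points within
#' half a window of the spectrum ends take the value of the polynomial
#' fitted to the terminal full window.
#'
#' @param spectrum a [raman_spectrum] (equally spaced axis assumed).
#' @param order polynomial order (default 2).
#' @param window window length in points, odd, > `order` (default 7).
#' @return smoothed [raman_spectrum].
#' @export
smooth_sg <- function(spectrum, order = 2, window = 7) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  order <- check_number(order, "order", lower = 0)
  window <- check_number(window, "window", lower = 1)
  if (window %% 2 == 0) stop_field("window", "must be odd")
  if (window <= order) stop_field("window", "must exceed the polynomial order")
  if (length(spectrum$wavenumber) < window)
    stop_field("spectrum", "shorter than the smoothing window")
  out <- spectrum
  out$intensity <- signal::sgolayfilt(spectrum$intensity, p = order, n = window)
  out$meta$sg <- c(order = order, window = window)
  out
}
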