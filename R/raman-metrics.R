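#' Default Raman band definitions
#'
#' The bands quantified in the mineralization workflow. Centers in 1/cm:
#' PLA ester band 874, apatite phosphate nu1 960, phosphate P-O 971,
#' phenylalanine ring breathing 1004, carbonate 1070, nu P-O 1091,
#' amide III 1244, P=O 1374. Peak intensity is searched within
#' `center ± half_window` (default 5 1/cm) so small calibration offsets do
#' not miss the band.
#'
#' @param half_window half-width of the search window, 1/cm (> 0).
#' @return data.frame with columns `name`, `center`, `half_window`.
#' @export
raman_bands <- function(half_window = 5) {
  check_number(half_window, "half_window", lower = 0, strict_lower = TRUE)
  data.frame(
    name = c("pla_874", "ha_960", "po_971", "phe_1004",
             "carbonate_1070", "nu_po_1091", "amide3_1244", "p_o_1374"),
    center = c(874, 960, 971, 1004, 1070, 1091, 1244, 1374),
    half_window = half_window,
    stringsAsFactors = FALSE
  )
}

#' Peak intensity within a band window
#'
#' The maximum intensity of the (preprocessed) spectrum within
#' `[center - half_window, center + half_window]`, i.e. the local band
#' height rather than the value at the exact nominal shift.
#'
#' @param spectrum a [raman_spectrum].
#' @param center band center, 1/cm.
#' @param half_window half-width of the search window, 1/cm (default 5).
#' @return maximum intensity (counts) in the window.
#' @export
peak_intensity <- function(spectrum, center, half_window = 5) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  check_number(center, "center")
  check_number(half_window, "half_window", lower = 0, strict_lower = TRUE)
  sel <- spectrum$wavenumber >= center - half_window &
    spectrum$wavenumber <= center + half_window
  if (!any(sel))
    stop(sprintf("band window %g ± %g 1/cm lies outside the spectrum axis",
                 center, half_window), call. = FALSE)
  max(spectrum$intensity[sel])
}

#' Mineralization metrics of one spectrum
#'
#' Band heights at the named bands plus the mineral-to-matrix and
#' carbonate-to-mineral ratios used to read cell-mediated hydroxyapatite
#' (HA) formation off a spectrum:
#' * `ha_phe` = I(960)/I(1004): HA relative to the phenylalanine protein
#'   reference; rises with mineralization.
#' * `ha_amide3` = I(960)/I(1244): HA relative to amide III; rises with
#'   mineralization.
#' * `carbonate_ha` = I(1070)/I(960): carbonate substitution relative to
#'   phosphate; falls as apatite is deposited.
#' * `pla_874`: the polymer-coating marker band height.
#'
#' @param spectrum a preprocessed [raman_spectrum].
#' @param bands band definitions as from [raman_bands()].
#' @param ha_center which band center is treated as the HA peak in the
#'   ratios, 960 (default) or 971.
#' @return object of class `raman_metrics`: list with `peak_intensities`
#'   (named numeric) and the scalar ratios.
#' @export
compute_ratios <- function(spectrum, bands = raman_bands(), ha_center = 960) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  heights <- vapply(seq_len(nrow(bands)), function(i)
    peak_intensity(spectrum, bands$center[i], bands$half_window[i]),
    numeric(1))
  names(heights) <- bands$name
  get_band <- function(center) {
    i <- which(bands$center == center)
    if (!length(i))
      stop(sprintf("no band defined at %g 1/cm", center), call. = FALSE)
    heights[[i[1L]]]
  }
  ratio <- function(num, den, den_center) {
    if (den <= 0)
      stop(sprintf("undefined ratio: band at %g 1/cm has non-positive intensity",
                   den_center), call. = FALSE)
    num / den
  }
  ha <- get_band(ha_center)
  structure(
    list(
      peak_intensities = heights,
      ha_phe = ratio(ha, get_band(1004), 1004),
      ha_amide3 = ratio(ha, get_band(1244), 1244),
      carbonate_ha = ratio(get_band(1070), ha, ha_center),
      pla_874 = get_band(874)
    ),
    class = "raman_metrics"
  )
}

#' @export
print.raman_metrics <- function(x, digits = 4, ...) {
  cat("Raman mineralization metrics\n")
  cat(sprintf("  HA/Phe       %s\n", format(x$ha_phe, digits = digits)))
  cat(sprintf("  HA/amide III %s\n", format(x$ha_amide3, digits = digits)))
  cat(sprintf("  carbonate/HA %s\n", format(x$carbonate_ha, digits = digits)))
  if (!is.null(x$inv_fwhm))
    cat(sprintf("  1/FWHM       %s cm\n", format(x$inv_fwhm, digits = digits)))
  invisible(x)
}

#' Gaussian fit of the apatite band
#'
#' Fits `A * exp(-(x - mu)^2 / (2 s^2)) + c` to the 900-1000 1/cm window
#' by nonlinear least squares and reports the full width at half maximum,
#' `FWHM = 2 sqrt(2 ln 2) s`, and its inverse. 1/FWHM (in cm) is the
#' crystallinity (crystal-size) index of the 960 1/cm HA peak: narrower
#' bands mean larger, more ordered apatite crystals.
#'
#' Initialization: `mu` at the in-range argmax, `A` at range max minus
#' min, `c` at the range minimum, `s` from the half-maximum crossing
#' distance. A failed or non-converged fit returns `converged = FALSE`
#' with the error message in `diagnostics` rather than an error.
#'
#' @param spectrum a [raman_spectrum].
#' @param range fitting window, 1/cm (default `c(900, 1000)`).
#' @param offset include the constant offset `c` (default TRUE); set
#'   FALSE for an offset-free pure Gaussian.
#' @param tol convergence tolerance on parameters (default 1e-8).
#' @return object of class `gaussian_fit`: list with `mu`, `amplitude`,
#'   `sigma`, `offset`, `fwhm`, `inv_fwhm`, `converged`, `residual_rms`,
#'   `diagnostics`.
#' @export
fit_apatite_gaussian <- function(spectrum, range = c(900, 1000),
                                 offset = TRUE, tol = 1e-8) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (length(range) != 2L || range[1L] >= range[2L])
    stop_field("range", "must be an increasing pair of wavenumbers")
  sel <- spectrum$wavenumber >= range[1L] & spectrum$wavenumber <= range[2L]
  x <- spectrum$wavenumber[sel]
  y <- spectrum$intensity[sel]
  if (length(x) < 8L)
    stop_field("spectrum", "needs >= 8 points in the fitting range")

  i_max <- which.max(y)
  c0 <- min(y)
  A0 <- max(y) - c0
  mu0 <- x[i_max]
  # sigma start: distance from the peak to the half-maximum crossing
  half <- c0 + A0 / 2
  above <- which(y >= half)
  s0 <- if (length(above) > 1L) {
    max((x[max(above)] - x[min(above)]) / (2 * sqrt(2 * log(2))), diff(x)[1L])
  } else diff(range) / 10
  if (A0 <= 0) {
    return(structure(list(mu = NA_real_, amplitude = NA_real_,
                          sigma = NA_real_, offset = NA_real_,
                          fwhm = NA_real_, inv_fwhm = NA_real_,
                          converged = FALSE, residual_rms = NA_real_,
                          diagnostics = "flat window: no peak to fit"),
                     class = "gaussian_fit"))
  }

  form <- if (offset) y ~ A * exp(-(x - mu)^2 / (2 * s^2)) + c
          else y ~ A * exp(-(x - mu)^2 / (2 * s^2))
  start <- if (offset) list(A = A0, mu = mu0, s = s0, c = c0)
           else list(A = A0, mu = mu0, s = s0)
  lower <- if (offset) c(0, range[1L], 1e-3, -Inf) else c(0, range[1L], 1e-3)
  upper <- if (offset) c(Inf, range[2L], diff(range), Inf)
           else c(Inf, range[2L], diff(range))

  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(x = x, y = y), start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        ptol = tol, ftol = tol, maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(mu = mu0, amplitude = A0, sigma = s0,
                          offset = if (offset) c0 else 0,
                          fwhm = NA_real_, inv_fwhm = NA_real_,
                          converged = FALSE, residual_rms = NA_real_,
                          diagnostics = conditionMessage(fit)),
                     class = "gaussian_fit"))
  }
  est <- stats::coef(fit)
  s_hat <- est[["s"]]
  at_bound <- s_hat <= 1e-3 * 1.0001 || s_hat >= diff(range) * 0.9999
  fwhm <- 2 * sqrt(2 * log(2)) * s_hat
  structure(
    list(mu = est[["mu"]], amplitude = est[["A"]], sigma = s_hat,
         offset = if (offset) est[["c"]] else 0,
         fwhm = fwhm, inv_fwhm = 1 / fwhm,
         converged = !at_bound,
         residual_rms = sqrt(mean(stats::residuals(fit)^2)),
         diagnostics = if (at_bound) "sigma at bound" else ""),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Gaussian fit: mu = %s 1/cm, sigma = %s, FWHM = %s 1/cm, 1/FWHM = %s cm%s\n",
    format(x$mu, digits = digits), format(x$sigma, digits = digits),
    format(x$fwhm, digits = digits), format(x$inv_fwhm, digits = digits),
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Per-spectrum metrics and summary of a mapping measurement
#'
#' Applies the full preprocessing chain to every spectrum of a set —
#' background subtraction, baseline correction, Savitzky-Golay smoothing,
#' in that fixed order — then computes band ratios and the apatite
#' Gaussian fit per spectrum, and summarizes each metric as mean ± sample
#' SD over the set. Spectra for which any stage fails are excluded from
#' the summary and counted.
#'
#' @param set a [spectrum_set].
#' @param background optional background [raman_spectrum]; NULL skips the
#'   subtraction stage.
#' @param baseline_method passed to [baseline_correct()].
#' @param baseline_order passed to [baseline_correct()].
#' @param sg_order,sg_window passed to [smooth_sg()].
#' @param bands band definitions as from [raman_bands()].
#' @param ha_center HA band center used in ratios (default 960).
#' @param fit_range apatite Gaussian window (default `c(900, 1000)`).
#' @return object of class `set_metrics`: list with `per_spectrum` (one
#'   row per successful spectrum: ratios, 1/FWHM, PLA band height),
#'   `summary` (mean, sd, n per metric), `n_failed`, `failures`
#'   (per-spectrum error messages) and `config` (the resolved pipeline
#'   fingerprint).
#' @export
set_metrics <- function(set, background = NULL,
                        baseline_method = "modpoly", baseline_order = 3,
                        sg_order = 2, sg_window = 7,
                        bands = raman_bands(), ha_center = 960,
                        fit_range = c(900, 1000)) {
  stopifnot(inherits(set, "spectrum_set"))
  config <- list(order = c("background", "baseline", "smoothing", "metrics"),
                 baseline_method = baseline_method,
                 baseline_order = baseline_order,
                 sg_order = sg_order, sg_window = sg_window,
                 ha_center = ha_center, fit_range = fit_range)
  one <- function(s) {
    if (!is.null(background)) s <- subtract_background(s, background)
    # a baseline that hits the iteration cap is flagged per spectrum
    # below rather than warning once per map point
    s <- suppressWarnings(
      baseline_correct(s, method = baseline_method, order = baseline_order))
    s <- smooth_sg(s, order = sg_order, window = sg_window)
    m <- compute_ratios(s, bands = bands, ha_center = ha_center)
    g <- fit_apatite_gaussian(s, range = fit_range)
    data.frame(ha_phe = m$ha_phe, ha_amide3 = m$ha_amide3,
               carbonate_ha = m$carbonate_ha, pla_874 = m$pla_874,
               inv_fwhm = if (g$converged) g$inv_fwhm else NA_real_,
               fit_converged = g$converged,
               baseline_converged = isTRUE(s$meta$baseline_converged))
  }
  rows <- vector("list", length(set$spectra))
  failures <- character(0)
  for (i in seq_along(set$spectra)) {
    res <- tryCatch(one(set$spectra[[i]]), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("spectrum %d: %s", i, conditionMessage(res)))
    } else {
      res$spectrum_id <- i
      rows[[i]] <- res
    }
  }
  per <- do.call(rbind, rows)
  metric_cols <- c("ha_phe", "ha_amide3", "carbonate_ha", "pla_874", "inv_fwhm")
  summ <- do.call(rbind, lapply(metric_cols, function(mc) {
    v <- per[[mc]]
    v <- v[is.finite(v)]
    data.frame(metric = mc, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_)
  }))
  structure(
    list(label = set$label, per_spectrum = per, summary = summ,
         n_failed = length(failures), failures = failures, config = config),
    class = "set_metrics"
  )
}

#' @export
print.set_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("Raman set metrics '%s' (%d spectra, %d failed)\n",
              x$label, nrow(x$per_spectrum) + x$n_failed, x$n_failed))
  print(cbind(x$summary[1L],
              lapply(x$summary[-1L], function(cl)
                if (is.numeric(cl)) signif(cl, digits) else cl)))
  invisible(x)
}
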