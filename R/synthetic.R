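# Synthetic instrument data with retained ground truth. Each generator is
# a pure function of its model (including the seed): the caller's RNG
# state is never consumed, and the generating parameters travel with the
# output so recovery tests need no side channel.

#' Define one synthetic Raman band
#'
#' @param name band label.
#' @param center band center, 1/cm.
#' @param amplitude peak height, counts (>= 0).
#' @param sigma Gaussian width, 1/cm (> 0).
#' @return a one-row data.frame band specification.
#' @export
band_spec <- function(name, center, amplitude, sigma) {
  check_number(center, "center")
  check_number(amplitude, "amplitude", lower = 0)
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  data.frame(name = as.character(name), center = center,
             amplitude = amplitude, sigma = sigma, stringsAsFactors = FALSE)
}

#' Default synthetic band set
#'
#' The eight bands of the mineralization workflow with amplitudes in a
#' plausible proportion for a cell-seeded calcium-phosphate scaffold: the
#' 960 1/cm apatite phosphate band dominant, moderate polymer (874) and
#' phosphate satellites, weaker organic-matrix bands.
#'
#' @param ha_amplitude amplitude of the 960 1/cm band (default 100).
#' @param ha_sigma width of the 960 1/cm band (default 8).
#' @return data.frame of band specifications.
#' @export
default_band_set <- function(ha_amplitude = 100, ha_sigma = 8) {
  rbind(
    band_spec("pla_874", 874, 40, 6),
    band_spec("ha_960", 960, ha_amplitude, ha_sigma),
    band_spec("po_971", 971, 30, 6),
    band_spec("phe_1004", 1004, 25, 5),
    band_spec("carbonate_1070", 1070, 20, 7),
    band_spec("nu_po_1091", 1091, 18, 7),
    band_spec("amide3_1244", 1244, 15, 10),
    band_spec("p_o_1374", 1374, 12, 9)
  )
}

#' Specify a synthetic spectrum model
#'
#' @param axis wavenumber grid, 1/cm, strictly increasing (default
#'   600-1800 at 1 1/cm, covering every band of the workflow).
#' @param bands data.frame of band specifications ([band_spec()] rows);
#'   all centers must lie within the axis range.
#' @param baseline_coeffs polynomial baseline coefficients in increasing
#'   degree order, intensity vs 1/cm (default none).
#' @param noise_sd additive Gaussian noise SD, counts (default 0).
#' @param seed RNG seed (integer) or NULL.
#' @return object of class `spectrum_model`.
#' @export
spectrum_model <- function(axis = seq(600, 1800, by = 1),
                           bands = default_band_set(),
                           baseline_coeffs = numeric(0),
                           noise_sd = 0, seed = NULL) {
  if (!is.numeric(axis) || length(axis) < 2L || is.unsorted(axis, strictly = TRUE))
    stop_field("axis", "must be a strictly increasing numeric grid")
  if (!is.data.frame(bands) && !is.null(bands))
    stop_field("bands", "must be a data.frame of band specs (or NULL)")
  if (is.null(bands)) bands <- default_band_set()[0, ]
  if (nrow(bands)) {
    if (any(bands$sigma <= 0)) stop_field("sigma", "must be > 0")
    if (any(bands$amplitude < 0)) stop_field("amplitude", "must be >= 0")
    if (any(bands$center < min(axis) | bands$center > max(axis)))
      stop_field("center", "must lie within the axis range")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(axis = axis, bands = bands, baseline_coeffs = baseline_coeffs,
         noise_sd = noise_sd, seed = check_seed(seed)),
    class = "spectrum_model"
  )
}

band_profile <- function(axis, bands) {
  y <- numeric(length(axis))
  for (i in seq_len(nrow(bands)))
    y <- y + bands$amplitude[i] *
      exp(-(axis - bands$center[i])^2 / (2 * bands$sigma[i]^2))
  y
}

#' Generate one synthetic Raman spectrum
#'
#' Sum of Gaussian bands over a polynomial baseline plus additive
#' Gaussian noise; the model (ground truth) is stored in
#' `meta$ground_truth`.
#'
#' @param model a [spectrum_model()].
#' @return a [raman_spectrum].
#' @export
gen_spectrum <- function(model) {
  stopifnot(inherits(model, "spectrum_model"))
  y <- band_profile(model$axis, model$bands)
  if (length(model$baseline_coeffs))
    y <- y + polyval_inc(model$baseline_coeffs, model$axis)
  if (model$noise_sd > 0)
    y <- y + with_seed(model$seed, stats::rnorm(length(model$axis),
                                                sd = model$noise_sd))
  raman_spectrum(model$axis, y, meta = list(ground_truth = model))
}

#' Generate a synthetic mapping measurement
#'
#' `n_spectra` spectra on the identical axis; each spectrum's band
#' amplitudes are jointly scaled by independent `Normal(1, jitter)` draws
#' per band, emulating the spot-to-spot variation of a Raman map.
#'
#' @param model a [spectrum_model()].
#' @param n_spectra number of spectra (>= 1; maps in the study carried
#'   90-148).
#' @param jitter fractional SD of the per-band amplitude scaling
#'   (default 0.05).
#' @param label set label.
#' @return a [spectrum_set]; ground truth in each spectrum's meta.
#' @export
gen_spectrum_set <- function(model, n_spectra, jitter = 0.05, label = "") {
  stopifnot(inherits(model, "spectrum_model"))
  check_number(n_spectra, "n_spectra", lower = 1)
  check_number(jitter, "jitter", lower = 0)
  spectra <- with_seed(model$seed, {
    lapply(seq_len(n_spectra), function(i) {
      b <- model$bands
      if (jitter > 0 && nrow(b))
        b$amplitude <- b$amplitude * stats::rnorm(nrow(b), 1, jitter)
      b$amplitude <- pmax(b$amplitude, 0)
      y <- band_profile(model$axis, b)
      if (length(model$baseline_coeffs))
        y <- y + polyval_inc(model$baseline_coeffs, model$axis)
      if (model$noise_sd > 0)
        y <- y + stats::rnorm(length(model$axis), sd = model$noise_sd)
      raman_spectrum(model$axis, y,
                     meta = list(ground_truth = model, realized_bands = b,
                                 spectrum_id = i))
    })
  })
  spectrum_set(spectra, label = label)
}

#' Specify a synthetic flexure test
#'
#' Linear-elastic loading with brittle failure at `break_load`: the
#' noiseless slope is the beam-theory value `m = 4 E w b^3 / L^3` for a
#' rectangular section in 3-point bending.
#'
#' @param E_true true modulus, MPa.
#' @param span support span, mm.
#' @param width,thickness cross-section, mm.
#' @param break_load failure load, N (> 0).
#' @param noise_sd additive load noise SD, N.
#' @param n_points curve points (default 200).
#' @param seed RNG seed or NULL.
#' @return object of class `flexure_model`.
#' @export
flexure_model <- function(E_true = 900, span = 40, width = 6, thickness = 6,
                          break_load = 18, noise_sd = 0, n_points = 200,
                          seed = NULL) {
  check_number(E_true, "E_true", lower = 0, strict_lower = TRUE)
  check_number(span, "span", lower = 0, strict_lower = TRUE)
  check_number(width, "width", lower = 0, strict_lower = TRUE)
  check_number(thickness, "thickness", lower = 0, strict_lower = TRUE)
  check_number(break_load, "break_load", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(n_points, "n_points", lower = 10)
  structure(
    list(E_true = E_true, span = span, width = width, thickness = thickness,
         break_load = break_load, noise_sd = noise_sd,
         n_points = as.integer(n_points), seed = check_seed(seed)),
    class = "flexure_model"
  )
}

#' Generate a synthetic load-deflection curve
#'
#' Deflection runs from 0 to the failure deflection
#' `break_load / m`; interior loads get additive Gaussian noise, the
#' final point carries exactly `break_load` (brittle failure).
#'
#' @param model a [flexure_model()].
#' @return a [flexure_specimen]; ground truth in `meta`.
#' @export
gen_flexure_curve <- function(model) {
  stopifnot(inherits(model, "flexure_model"))
  m <- 4 * model$E_true * model$width * model$thickness^3 / model$span^3
  d_break <- model$break_load / m
  d <- seq(0, d_break, length.out = model$n_points)
  load <- m * d
  if (model$noise_sd > 0) {
    eps <- with_seed(model$seed, stats::rnorm(model$n_points,
                                              sd = model$noise_sd))
    load <- load + eps
    load[1L] <- 0
  }
  load[model$n_points] <- model$break_load
  # brittle ceramic: noise never carries interior load past failure
  load[-model$n_points] <- pmin(load[-model$n_points],
                                model$break_load * (1 - 1e-9))
  flexure_specimen(
    specimen_id = "synthetic", span = model$span,
    width_mm = rep(model$width, 3), thickness_mm = rep(model$thickness, 3),
    deflection = d, load = load,
    meta = list(ground_truth = model, slope_true = m)
  )
}

#' Generate a synthetic coating mass table
#'
#' Rows with `weight_before` near `base_weight` and
#' `weight_after = weight_before / (1 - true_ce) * Normal(1, noise_sd)`,
#' so the noiseless per-row coating efficiency is exactly `100 * true_ce`
#' and the mean recovered CE converges to it as the batch grows.
#'
#' @param true_ce true coating mass fraction, in `[0, 1)`.
#' @param n_rows number of syringe batches (>= 1).
#' @param base_weight nominal pre-coating weight, g (default 3.5).
#' @param noise_sd fractional multiplicative noise SD (default 0).
#' @param seed RNG seed or NULL.
#' @return a coating batch data.frame (columns `series`, `syringe`,
#'   `n_pieces`, `weight_before_g`, `weight_after_g`) with the generating
#'   parameters in `attr(, "ground_truth")`.
#' @export
gen_mass_table <- function(true_ce, n_rows, base_weight = 3.5,
                           noise_sd = 0, seed = NULL) {
  check_number(true_ce, "true_ce", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(n_rows, "n_rows", lower = 1)
  check_number(base_weight, "base_weight", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  n_rows <- as.integer(n_rows)
  tab <- with_seed(check_seed(seed), {
    wb <- base_weight * stats::rnorm(n_rows, 1, noise_sd)
    wa <- wb / (1 - true_ce) * stats::rnorm(n_rows, 1, noise_sd)
    data.frame(series = "synthetic", syringe = seq_len(n_rows),
               n_pieces = 50L, weight_before_g = wb,
               weight_after_g = pmax(wa, wb))
  })
  attr(tab, "ground_truth") <- list(true_ce = true_ce, n_rows = n_rows,
                                    base_weight = base_weight,
                                    noise_sd = noise_sd, seed = seed)
  tab
}

#' Specify a synthetic degradation experiment
#'
#' Exponential pH decay toward `ph_inf` (lactic-acid release) and a
#' saturating conductivity rise whose initial slope is `cond_rate`.
#'
#' @param ph0 initial pH.
#' @param ph_inf asymptotic pH (<= `ph0`).
#' @param rate pH decay rate, 1/day (>= 0).
#' @param cond0 initial conductivity, uS/cm.
#' @param cond_rate initial conductivity slope, uS/cm per day.
#' @param duration experiment length, days (> 0; default 180, the span of
#'   the long-term degradation monitoring).
#' @param sampling sampling interval, days (default 2).
#' @param noise_sd per-channel additive noise SD (default 0).
#' @param seed RNG seed or NULL.
#' @return object of class `degradation_model`.
#' @export
degradation_model <- function(ph0 = 7, ph_inf = 2, rate = 0.1,
                              cond0 = 1, cond_rate = 20,
                              duration = 180, sampling = 2,
                              noise_sd = 0, seed = NULL) {
  check_number(ph0, "ph0", lower = 0, upper = 14)
  check_number(ph_inf, "ph_inf", lower = 0, upper = 14)
  if (ph_inf > ph0) stop_field("ph_inf", "must be <= ph0")
  check_number(rate, "rate", lower = 0)
  check_number(cond0, "cond0", lower = 0)
  check_number(cond_rate, "cond_rate", lower = 0)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(sampling, "sampling", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(ph0 = ph0, ph_inf = ph_inf, rate = rate, cond0 = cond0,
         cond_rate = cond_rate, duration = duration, sampling = sampling,
         noise_sd = noise_sd, seed = check_seed(seed)),
    class = "degradation_model"
  )
}

#' Generate a synthetic degradation series
#'
#' `pH(t) = ph_inf + (ph0 - ph_inf) exp(-rate t)`;
#' `cond(t) = cond0 + cond_rate * duration * (1 - exp(-t / duration))`
#' (bounded saturation with initial slope `cond_rate`); both plus
#' additive Gaussian noise. pH is clamped to `[0, 14]` after noise.
#'
#' @param model a [degradation_model()].
#' @param label series label.
#' @return a [degradation_series]; ground truth in `attr(, "ground_truth")`.
#' @export
gen_degradation_series <- function(model, label = "synthetic") {
  stopifnot(inherits(model, "degradation_model"))
  t <- seq(0, model$duration, by = model$sampling)
  ph <- model$ph_inf + (model$ph0 - model$ph_inf) * exp(-model$rate * t)
  cond <- model$cond0 +
    model$cond_rate * model$duration * (1 - exp(-t / model$duration))
  if (model$noise_sd > 0) {
    noise <- with_seed(model$seed,
                       matrix(stats::rnorm(2 * length(t), sd = model$noise_sd),
                              ncol = 2))
    ph <- pmin(pmax(ph + noise[, 1L], 0), 14)
    cond <- pmax(cond + noise[, 2L], 0)
  }
  out <- degradation_series(label, t, ph, cond)
  attr(out, "ground_truth") <- model
  out
}
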