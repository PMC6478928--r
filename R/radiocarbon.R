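#' Radiocarbon unit algebra
#'
#' Conversions between per-mil Delta-14C and absolute fraction modern, decay
#' correction to the sampling year, and constant-contamination blank
#' correction with first-order error propagation. All internal model
#' arithmetic in this package runs in absolute (sampling-year) fraction
#' modern; Delta-14C appears only at I/O boundaries, which removes
#' sign and reference-year ambiguity.
#'
#' @name radiocarbon
NULL

#' Godwin mean-life radiocarbon decay constant (per year)
#'
#' The inverse of the 8267-year Godwin mean life of 14C,
#' lambda = 1/8267 = 1.21e-4 per year.
#' @export
lambda_14c <- 1 / 8267

#' Convert per-mil Delta-14C to fraction modern
#'
#' In the absolute (sampling-year) convention, F = Delta/1000 + 1. Values at
#' or below -1000 per mil would imply non-positive radiocarbon activity and
#' are rejected.
#'
#' @param delta14c per-mil Delta-14C, each > -1000.
#' @return fraction modern.
#' @export
delta_to_fm <- function(delta14c) {
  if (any(delta14c <= -1000))
    stop("Delta-14C must exceed -1000 per mil (fraction modern > 0)")
  delta14c / 1000 + 1
}

#' Convert fraction modern to per-mil Delta-14C
#'
#' @param fm fraction modern, each > 0.
#' @return per-mil Delta-14C.
#' @export
fm_to_delta <- function(fm) {
  if (any(fm <= 0)) stop("fraction modern must be positive")
  (fm - 1) * 1000
}

#' Decay-correct a 1950 fraction modern to a later sampling year
#'
#' Applies the radioactive decay undergone between 1950 and the sampling year,
#' as done when correcting oxalic-acid standards measured long after 1950:
#' the returned value is `fm_1950 * exp(-lam * (year - 1950))`.
#'
#' @param fm_1950 fraction modern referenced to 1950.
#' @param year decimal sampling year, >= 1950.
#' @param lam decay constant per year (default [lambda_14c]).
#' @return fraction modern at `year`.
#' @export
decay_correct_to_year <- function(fm_1950, year, lam = lambda_14c) {
  if (any(year < 1950)) stop("`year` must be >= 1950")
  fm_1950 * exp(-lam * (year - 1950))
}

#' A radiocarbon measurement
#'
#' @param delta14c per-mil Delta-14C (> -1000).
#' @param sigma per-mil 1-sigma analytical uncertainty (>= 0).
#' @param sampling_year decimal year of field sampling.
#' @param mass_c carbon mass of the measured aliquot in mg C (optional;
#'   required for blank correction).
#' @return an object of class `rc_measurement`.
#' @export
rc_measurement <- function(delta14c, sigma = 0, sampling_year = 2014.5,
                           mass_c = NA_real_) {
  if (delta14c <= -1000) stop("Delta-14C must exceed -1000 per mil")
  if (sigma < 0) stop("`sigma` must be >= 0")
  structure(list(delta14c = delta14c, sigma = sigma,
                 sampling_year = sampling_year, mass_c = mass_c),
            class = "rc_measurement")
}

#' @export
print.rc_measurement <- function(x, ...) {
  cat(sprintf("Radiocarbon measurement: %.1f +/- %.1f permil (year %.1f)\n",
              x$delta14c, x$sigma, x$sampling_year))
  invisible(x)
}

#' Constant-contamination blank model
#'
#' Describes a constant mass of extraneous carbon of fixed fraction modern
#' added to every sample during processing, the standard AMS mixing model
#' used to correct small gas measurements and widen their uncertainties.
#'
#' @param f_contaminant fraction modern of the contaminant (>= 0).
#' @param m_contaminant contaminant carbon mass in mg C (>= 0).
#' @param sigma_f,sigma_m 1-sigma uncertainties of the two (default 0).
#' @return an object of class `blank_model`.
#' @export
blank_model <- function(f_contaminant = 0.5, m_contaminant = 0.001,
                        sigma_f = 0, sigma_m = 0) {
  if (f_contaminant < 0) stop("`f_contaminant` must be >= 0")
  if (m_contaminant < 0) stop("`m_contaminant` must be >= 0")
  if (sigma_f < 0 || sigma_m < 0) stop("sigmas must be >= 0")
  structure(list(f_contaminant = f_contaminant,
                 m_contaminant = m_contaminant,
                 sigma_f = sigma_f, sigma_m = sigma_m),
            class = "blank_model")
}

#' Blank-correct a radiocarbon measurement
#'
#' Inverts the constant-contamination mixing model. With measured fraction
#' modern `F_m` on total mass `m_m` and a contaminant `(F_c, m_c)`, the sample
#' value is
#' \deqn{F_s = (F_m m_m - F_c m_c) / (m_m - m_c).}
#' The 1-sigma uncertainty is propagated to first order over the
#' uncertainties of `F_m`, `F_c` and `m_c`; the correction widens the
#' uncertainty whenever the blank parameters are themselves uncertain.
#'
#' @param measured an [rc_measurement()] with `mass_c` set (mg C).
#' @param blank a [blank_model()].
#' @return an [rc_measurement()] of the decontaminated sample, same mass
#'   convention (`mass_c` = sample mass `m_m - m_c`).
#' @export
blank_correct <- function(measured, blank) {
  stopifnot(inherits(measured, "rc_measurement"),
            inherits(blank, "blank_model"))
  m_m <- measured$mass_c
  if (is.na(m_m)) stop("`measured$mass_c` is required for blank correction")
  m_c <- blank$m_contaminant
  if (m_m <= m_c)
    stop("sample mass (", m_m, " mg C) must exceed contaminant mass (",
         m_c, " mg C)")
  f_m <- delta_to_fm(measured$delta14c)
  f_c <- blank$f_contaminant
  f_s <- (f_m * m_m - f_c * m_c) / (m_m - m_c)
  if (f_s <= 0)
    stop("blank correction yields non-positive fraction modern")
  # first-order propagation: dFs/dFm, dFs/dFc, dFs/dmc
  d_fm <- m_m / (m_m - m_c)
  d_fc <- -m_c / (m_m - m_c)
  d_mc <- (f_s - f_c) / (m_m - m_c)
  s_fm <- measured$sigma / 1000      # per-mil -> fraction modern
  var_fs <- (d_fm * s_fm)^2 + (d_fc * blank$sigma_f)^2 +
    (d_mc * blank$sigma_m)^2
  rc_measurement(delta14c = fm_to_delta(f_s),
                 sigma = sqrt(var_fs) * 1000,
                 sampling_year = measured$sampling_year,
                 mass_c = m_m - m_c)
}

#' Forward mixing: contaminate a clean sample with a blank
#'
#' The forward counterpart of [blank_correct()], used to build synthetic
#' contaminated measurements: mixes sample carbon `(F_s, m_s)` with
#' contaminant carbon `(F_c, m_c)` by mass balance.
#'
#' @param sample an [rc_measurement()] with `mass_c` set (mg C).
#' @param blank a [blank_model()].
#' @return an [rc_measurement()] of the mixture (`mass_c` = total mass).
#' @export
apply_contamination <- function(sample, blank) {
  stopifnot(inherits(sample, "rc_measurement"),
            inherits(blank, "blank_model"))
  m_s <- sample$mass_c
  if (is.na(m_s)) stop("`sample$mass_c` is required")
  m_c <- blank$m_contaminant
  f_mix <- (delta_to_fm(sample$delta14c) * m_s +
              blank$f_contaminant * m_c) / (m_s + m_c)
  rc_measurement(delta14c = fm_to_delta(f_mix), sigma = sample$sigma,
                 sampling_year = sample$sampling_year, mass_c = m_s + m_c)
}
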