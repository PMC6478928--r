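#' NaOH trap specification
#'
#' Stoichiometric CO2 uptake capacity of an alkali trap. One mole of CO2
#' consumes two moles of NaOH (CO2 + 2 NaOH -> Na2CO3 + H2O), so a trap of
#' `volume_ml` millilitres at `molarity` mol/l can absorb
#' `volume * molarity / 2` mol CO2, i.e. that many moles of carbon. The
#' default 20 ml of 1 M NaOH holds 0.01 mol C = 0.1201 g C. Quantification by
#' conductivity is only linear while the trap is unsaturated; intervals at or
#' above `saturation_frac` of capacity are flagged.
#'
#' @param volume_ml trap volume in ml (default 20).
#' @param molarity NaOH molarity in mol/l (default 1).
#' @param saturation_frac fraction of capacity above which (inclusive) a trap
#'   counts as saturated (default 0.80).
#' @return an object of class `trap_spec` with derived field `capacity_gC`.
#' @export
trap_spec <- function(volume_ml = 20, molarity = 1, saturation_frac = 0.80) {
  if (volume_ml <= 0 || molarity <= 0) stop("trap volume and molarity must be positive")
  if (saturation_frac <= 0 || saturation_frac > 1)
    stop("`saturation_frac` must be in (0, 1]")
  capacity <- volume_ml / 1000 * molarity / 2 * 12.011
  structure(list(volume_ml = volume_ml, molarity = molarity,
                 capacity_gC = capacity, saturation_frac = saturation_frac),
            class = "trap_spec")
}

#' Trap replacement and leaching schedules (days)
#'
#' Default sampling schedules of the 181-day incubation: traps replaced on
#' days 4, 13, 30, 63, 92, 121, 150 and 181; leachates collected on days 4,
#' 13, 30, 63, 121 and 181.
#' @export
trap_schedule_days <- c(4, 13, 30, 63, 92, 121, 150, 181)

#' @rdname trap_schedule_days
#' @export
leach_schedule_days <- c(4, 13, 30, 63, 121, 181)

#' One incubation series
#'
#' Cumulative-by-interval CO2-C and per-leach DOC for one incubated sample,
#' with the initial total organic carbon (TOC) content needed for
#' normalisation.
#'
#' @param site_id site identifier.
#' @param co2c_g numeric, grams of CO2-C trapped in each interval, in
#'   schedule order.
#' @param doc_g numeric, grams of DOC in each leachate.
#' @param toc_initial initial TOC of the soil, g OC per kg dry soil (> 0).
#' @param dry_mass dry soil mass incubated, g (default 40).
#' @param interval_end_days trap-replacement days (default
#'   [trap_schedule_days]).
#' @param leach_days leaching days (default [leach_schedule_days]).
#' @param replicate_id replicate identifier (default 1).
#' @return an object of class `incubation_series`.
#' @export
incubation_series <- function(site_id, co2c_g, doc_g = numeric(0),
                              toc_initial, dry_mass = 40,
                              interval_end_days = trap_schedule_days,
                              leach_days = leach_schedule_days,
                              replicate_id = 1L) {
  if (length(co2c_g) != length(interval_end_days))
    stop("`co2c_g` must have one value per trap interval")
  if (length(doc_g) && length(doc_g) != length(leach_days))
    stop("`doc_g` must have one value per leach day")
  if (any(diff(interval_end_days) <= 0))
    stop("`interval_end_days` must be strictly increasing")
  if (any(co2c_g < 0)) stop("negative CO2-C interval mass")
  if (any(doc_g < 0)) stop("negative DOC entry")
  if (toc_initial <= 0) stop("`toc_initial` must be positive")
  if (dry_mass <= 0) stop("`dry_mass` must be positive")
  structure(list(site_id = site_id, replicate_id = replicate_id,
                 interval_end_days = interval_end_days, co2c_g = co2c_g,
                 leach_days = leach_days, doc_g = doc_g,
                 toc_initial = toc_initial, dry_mass = dry_mass),
            class = "incubation_series")
}

# initial organic-carbon mass of the incubated sample, g
.oc_mass_g <- function(series) series$toc_initial * series$dry_mass / 1000

#' Convert a conductivity change of an NaOH trap to trapped carbon
#'
#' Carbonate formation lowers the conductivity of the alkali solution
#' linearly while the trap is far from saturation; a laboratory calibration
#' (slope in mS/cm per mg C, plus intercept) maps the conductivity change to
#' the trapped CO2-C mass. Slightly negative inferred masses (measurement
#' noise) are clamped to zero with a warning; a deficit beyond 1% of the trap
#' capacity is an error.
#'
#' @param cond_initial,cond_final conductivities in mS/cm.
#' @param slope calibration slope, mS/cm per mg C (non-zero; negative for
#'   NaOH traps since conductivity falls as C is absorbed).
#' @param intercept calibration intercept in mS/cm (default 0).
#' @param cond_range calibrated conductivity range, mS/cm; values outside it
#'   are an error since linearity is not guaranteed.
#' @param trap a [trap_spec()] used for the negative-mass tolerance.
#' @return trapped carbon in g C.
#' @export
conductivity_to_c <- function(cond_initial, cond_final, slope,
                              intercept = 0, cond_range = c(0, Inf),
                              trap = trap_spec()) {
  if (slope == 0) stop("calibration slope must be non-zero")
  conds <- c(cond_initial, cond_final)
  if (any(conds < cond_range[1L] | conds > cond_range[2L]))
    stop("conductivity outside the calibrated range; linearity not guaranteed")
  mg_c <- ((cond_final - intercept) - (cond_initial - intercept)) / slope
  g_c <- mg_c / 1000
  if (g_c < 0) {
    if (g_c < -0.01 * trap$capacity_gC)
      stop("conductivity-derived carbon deficit exceeds 1% of trap capacity")
    warning("slightly negative trapped-carbon mass clamped to 0")
    g_c <- 0
  }
  g_c
}

#' Flag trap saturation in an incubation series
#'
#' `TRUE` when the CO2-C of any single trap interval reaches or exceeds
#' `saturation_frac` of the trap's stoichiometric capacity (>= 80% by
#' default), after which conductivity quantification is unreliable and the
#' trapped CO2 is isotopically fractionated.
#'
#' @param series an [incubation_series()].
#' @param trap a [trap_spec()].
#' @return logical.
#' @export
flag_saturation <- function(series, trap = trap_spec()) {
  stopifnot(inherits(series, "incubation_series"), inherits(trap, "trap_spec"))
  any(series$co2c_g >= trap$saturation_frac * trap$capacity_gC)
}

#' Normalise incubation fluxes to initial organic carbon
#'
#' Expresses cumulative CO2-C and DOC relative to the organic carbon present
#' at the start of the incubation, in g C per kg OC, removing the dependence
#' on the soil mass incubated.
#'
#' @param series an [incubation_series()].
#' @return a list with `co2c_cum_gkg` (cumulative, per trap day),
#'   `doc_cum_gkg` (cumulative, per leach day) and `oc_mass_g`.
#' @export
normalize_to_toc <- function(series) {
  stopifnot(inherits(series, "incubation_series"))
  oc <- .oc_mass_g(series)
  list(co2c_cum_gkg = cumsum(series$co2c_g) / oc * 1000,
       doc_cum_gkg = if (length(series$doc_g))
         cumsum(series$doc_g) / oc * 1000 else numeric(0),
       oc_mass_g = oc)
}

#' Cumulative DOC production over the incubation
#'
#' Total leached dissolved organic carbon, normalised to initial OC.
#'
#' @param series an [incubation_series()].
#' @return g DOC-C per kg OC.
#' @export
cumulative_doc <- function(series) {
  stopifnot(inherits(series, "incubation_series"))
  if (!length(series$doc_g)) return(0)
  sum(series$doc_g) / .oc_mass_g(series) * 1000
}

#' Incubation-based turnover time
#'
#' Under the one-homogeneous-pool assumption, turnover time is the ratio of
#' the total carbon stock to the output flux. The cumulative CO2-C respired
#' over the incubation is annualised linearly (`x 365.25/duration`) and,
#' since the stock per kg OC is 1000 g, `tau_i = 1000 / annual_flux` years.
#' DOC is excluded from the flux by default (it is about 1% of total losses);
#' set `include_doc = TRUE` to add it. Saturated series yield no turnover
#' time: the flux itself is unreliable.
#'
#' @param series an [incubation_series()].
#' @param trap a [trap_spec()] for the saturation check.
#' @param duration_days incubation length in days (default 181).
#' @param include_doc include leached DOC in the output flux (default
#'   `FALSE`).
#' @return a list of class `turnover_incubation` with `tau_i` (years),
#'   `annual_flux` (g C per kg OC per year), `cum_loss_frac` (fraction of
#'   initial OC lost as CO2 + DOC) and `saturated`.
#' @export
tau_incubation <- function(series, trap = trap_spec(), duration_days = 181,
                           include_doc = FALSE) {
  stopifnot(inherits(series, "incubation_series"))
  sat <- flag_saturation(series, trap)
  norm <- normalize_to_toc(series)
  cum_co2 <- sum(series$co2c_g) / norm$oc_mass_g * 1000
  cum_doc <- cumulative_doc(series)
  cum_loss_frac <- (cum_co2 + cum_doc) / 1000
  if (sat)
    stop(structure(class = c("soctau_saturation_error", "error", "condition"),
                   list(message = paste0("site ", series$site_id,
                                         ": trap saturated; tau_i withheld"),
                        call = sys.call())))
  flux_cum <- cum_co2 + if (include_doc) cum_doc else 0
  if (flux_cum <= 0) stop("zero output flux: turnover time is infinite")
  annual_flux <- flux_cum * 365.25 / duration_days
  structure(list(tau_i = 1000 / annual_flux, annual_flux = annual_flux,
                 cum_loss_frac = cum_loss_frac, saturated = sat),
            class = "turnover_incubation")
}
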