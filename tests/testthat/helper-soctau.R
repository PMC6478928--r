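# Shared fixtures, built in code at test time.

# constant-Delta atmospheric curve spanning the whole model era
flat_curve <- function(delta = 0) atm_curve(c(1900, 2020), c(delta, delta))

# a complete synthetic study, warnings about unsampled design cells silenced
quiet_study <- function(config = synth_config(), ...) {
  suppressWarnings(generate_study(config, ...))
}

quiet_analysis <- function(study, ...) {
  suppressWarnings(suppressMessages(
    run_full_analysis(study$sites, study$series, study$curve, ...)))
}

# incubation series of a single-pool soil decaying at rate k_lab (1/yr),
# sampled on the standard trap schedule
decay_series <- function(k_lab, toc = 100, dry_mass = 40, site_id = "s1",
                         days = trap_schedule_days) {
  oc <- toc * dry_mass / 1000
  frac <- exp(-k_lab * c(0, days) / 365.25)
  incubation_series(site_id, oc * (frac[-length(frac)] - frac[-1]),
                    doc_g = numeric(0), toc_initial = toc,
                    dry_mass = dry_mass, interval_end_days = days,
                    leach_days = numeric(0))
}
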