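# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps the generator deterministic without
# touching global state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration of the synthetic-study generator
#'
#' Defines the conditions of a simulated regional gradient study with known
#' ground truth: a candidate population with realistic driver correlations, a
#' stratified 54-site selection, true turnover times in realistic ranges, and
#' forward-simulated observations. The planted effect structure mirrors what
#' a regional soil survey can exhibit: soil pH shortens both turnover times,
#' site moisture lengthens only the incubation turnover, clay and slope
#' suppress DOC production, and temperature has no effect at all — so a
#' correct analysis pipeline must recover exactly that pattern.
#'
#' @param n_sites number of study sites selected (default 54).
#' @param n_population size of the candidate population (default 709).
#' @param seed integer seed; a fixed seed gives identical output.
#' @param beta_ph_taui,beta_moisture_taui,beta_ph_tau14c effect sizes (per
#'   SD of the driver) on the log turnover scores before range mapping;
#'   temperature has no coefficient by design.
#' @param beta_clay_doc,beta_slope_doc effect sizes on the DOC score.
#' @param r_ph_clay,r_ph_dryness target driver correlations (defaults 0.39
#'   and 0.35; dryness is the inverse of moisture, so the latter corresponds
#'   to a moisture-pH correlation of -0.35).
#' @param noise_tau,noise_doc SDs of the Gaussian score noise.
#' @param tau14c_range,taui_range,doc_range ranges (years, years, g per kg
#'   OC) into which the scores are affinely mapped (defaults 67-511, 5-29,
#'   0.1-0.9).
#' @param sigma_ams AMS analytical 1-sigma on observed Delta-14C, per mil
#'   (default 3).
#' @param incubation_noise lognormal sdlog of multiplicative noise on
#'   interval fluxes (default 0.05).
#' @param sampling_year decimal year of simulated field sampling (default
#'   2014.5).
#' @param n_replicates incubation replicates per site (default 1).
#' @param inject_pathologies plant the QC cases a real study contains:
#'   saturated traps at study sites 6 and 24 and one unrealistically old
#'   radiocarbon site (site 40, 1140 years) (default `TRUE`).
#' @param lwf_frac fraction of long-term monitoring sites exempt from the
#'   slope filter (default 0.03).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_sites = 54, n_population = 709, seed = 1L,
                         beta_ph_taui = 1.0, beta_moisture_taui = 0.6,
                         beta_ph_tau14c = 0.7,
                         beta_clay_doc = 0.8, beta_slope_doc = 0.5,
                         r_ph_clay = 0.39, r_ph_dryness = 0.35,
                         noise_tau = 0.6, noise_doc = 0.6,
                         tau14c_range = c(67, 511), taui_range = c(5, 29),
                         doc_range = c(0.1, 0.9), sigma_ams = 3,
                         incubation_noise = 0.05, sampling_year = 2014.5,
                         n_replicates = 1L, inject_pathologies = TRUE,
                         lwf_frac = 0.03) {
  if (sigma_ams < 0 || incubation_noise < 0) stop("noise SDs must be >= 0")
  if (any(tau14c_range <= 0) || any(taui_range <= 0))
    stop("turnover ranges must be positive")
  cfg <- as.list(environment())
  # copula correlation over (temp, dryness, ph, clay, slope)
  r <- diag(5)
  dimnames(r) <- rep(list(c("temp", "dryness", "ph", "clay", "slope")), 2L)
  r["ph", "clay"] <- r["clay", "ph"] <- r_ph_clay
  r["ph", "dryness"] <- r["dryness", "ph"] <- r_ph_dryness
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("driver correlation targets are not positive definite")
  cfg$cor_matrix <- r
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic candidate-site population
#'
#' Draws `n_population` candidate sites from a Gaussian copula that hits the
#' configured driver correlations, with non-Gaussian marginals where the
#' field data are skewed (gamma dryness and slope, log-normal clay, clipped
#' to 0-100%). Orientation is uniform over N/E/S/W (with degrees), and the
#' biogeographical region is assigned with climate-dependent weights that
#' reproduce the gaps a real survey shows (no moist-and-warm sites in the
#' Alps, no moist sites in the Southern Alps).
#'
#' @param config a [synth_config()].
#' @return data frame of candidate sites (`site_id`, `region`, `temp`,
#'   `dryness`, `ph`, `clay`, `slope`, `orientation_deg`, `orientation`,
#'   `is_lwf`).
#' @export
generate_population <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed + 1L, {
    n <- config$n_population
    # whiten the raw draw, then recolor: the latent sample correlation then
    # equals the target exactly, so the driver correlations depend only on
    # the (small, deterministic) attenuation of the marginal transforms
    z <- matrix(stats::rnorm(n * 5L), n, 5L)
    z <- scale(z, center = TRUE, scale = FALSE)
    z <- z %*% solve(chol(stats::cov(z))) %*% chol(config$cor_matrix)
    u <- stats::pnorm(scale(z))
    temp <- stats::qnorm(u[, 1L], mean = 6.5, sd = 3)
    dryness <- round(stats::qgamma(u[, 2L], shape = 2, scale = 6))
    ph <- pmin(pmax(stats::qnorm(u[, 3L], mean = 5.2, sd = 0.9), 3), 8)
    clay <- pmin(pmax(stats::qlnorm(u[, 4L], log(20), 0.45), 0), 100)
    slope <- stats::qgamma(u[, 5L], shape = 1.8, scale = 15)
    orientation_deg <- stats::runif(n, 0, 360)
    orientation <- cut(orientation_deg %% 360,
                       breaks = c(0, 45, 135, 225, 315, 360),
                       labels = c("N", "E", "S", "W", "N"),
                       include.lowest = TRUE, right = FALSE)
    regions <- c("Jura", "Midland", "Pre-Alps", "Alps", "Southern Alps")
    base_w <- c(0.15, 0.25, 0.20, 0.25, 0.15)
    warm <- temp > stats::median(temp)
    moist <- dryness <= stats::median(dryness)
    region <- character(n)
    for (i in seq_len(n)) {
      w <- base_w
      if (warm[i] && moist[i]) w[4L] <- 0      # no moist+warm Alpine sites
      if (moist[i]) w[5L] <- 0                 # no moist Southern-Alps sites
      if (!warm[i]) w[4L] <- w[4L] * 2         # cold sites cluster in the Alps
      region[i] <- sample(regions, 1L, prob = w)
    }
    data.frame(site_id = paste0("pop_", seq_len(n)), region = region,
               temp = temp, dryness = dryness, ph = ph, clay = clay,
               slope = slope, orientation_deg = orientation_deg,
               orientation = factor(orientation,
                                    levels = c("N", "E", "S", "W")),
               is_lwf = stats::runif(n) < config$lwf_frac,
               stringsAsFactors = FALSE)
  })
}

# affine map of a score vector onto [lo, hi] (degenerate scores map to the
# midpoint)
.map_range <- function(s, lo, hi) {
  rng <- range(s)
  if (diff(rng) == 0) return(rep((lo + hi) / 2, length(s)))
  lo + (s - rng[1L]) / diff(rng) * (hi - lo)
}

#' Plant ground-truth responses on a site table
#'
#' Builds true turnover times and DOC production as linear functions of the
#' standardised drivers plus Gaussian noise, affinely mapped into the
#' configured ranges (log scale for the turnover times). Higher pH shortens
#' both turnover times; more dry months (less moisture) shorten the
#' incubation turnover only; clay and slope suppress DOC; temperature enters
#' nowhere. If pathologies are enabled, study site 40 is overwritten with an
#' unrealistically old radiocarbon turnover (1140 years), emulating
#' accidental sampling of deep soil.
#'
#' @param sites a site table (typically the selected study sites, with study
#'   ids).
#' @param config a [synth_config()].
#' @return data frame `site_id`, `tau14c_true`, `taui_true`, `doc_true`
#'   (g per kg OC), `toc_gkg` (g OC per kg soil), with the standardised-score
#'   coefficients attached as `attr(, "coefficients")`.
#' @export
generate_truth <- function(sites, config = synth_config()) {
  stopifnot(is.data.frame(sites), inherits(config, "synth_config"))
  .with_seed(config$seed + 2L, {
    n <- nrow(sites)
    zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
    else rep(0, length(x))
    z_ph <- zs(sites$ph); z_dry <- zs(sites$dryness)
    z_clay <- zs(sites$clay); z_slope <- zs(sites$slope)
    s14 <- -config$beta_ph_tau14c * z_ph +
      stats::rnorm(n, 0, config$noise_tau)
    si <- -config$beta_ph_taui * z_ph - config$beta_moisture_taui * z_dry +
      stats::rnorm(n, 0, config$noise_tau)
    sdoc <- -config$beta_clay_doc * z_clay - config$beta_slope_doc * z_slope +
      stats::rnorm(n, 0, config$noise_doc)
    tau14c <- exp(.map_range(s14, log(config$tau14c_range[1L]),
                             log(config$tau14c_range[2L])))
    taui <- exp(.map_range(si, log(config$taui_range[1L]),
                           log(config$taui_range[2L])))
    doc <- .map_range(sdoc, config$doc_range[1L], config$doc_range[2L])
    toc <- pmin(pmax(stats::rlnorm(n, log(60), 0.4), 5), 250)
    out <- data.frame(site_id = as.character(sites$site_id),
                      tau14c_true = tau14c, taui_true = taui,
                      doc_true = doc, toc_gkg = toc,
                      stringsAsFactors = FALSE)
    if (config$inject_pathologies && "40" %in% out$site_id)
      out$tau14c_true[out$site_id == "40"] <- 1140
    attr(out, "coefficients") <-
      c(ph_taui = -config$beta_ph_taui,
        dryness_taui = -config$beta_moisture_taui,
        ph_tau14c = -config$beta_ph_tau14c,
        clay_doc = -config$beta_clay_doc,
        slope_doc = -config$beta_slope_doc, temp = 0)
    out
  })
}

#' Forward-simulate observations from planted truth
#'
#' Produces what the laboratory would measure: bulk-soil Delta-14C from the
#' single-pool forward model at the true turnover time plus AMS noise, and
#' incubation series from first-order decay at rate `1/taui_true` integrated
#' over the trap schedule with multiplicative noise, DOC spread over the
#' leach days. If pathologies are enabled, the traps of study sites 6 and 24
#' are pushed past saturation.
#'
#' @param truth a [generate_truth()] table.
#' @param sites the matching site table (same ids).
#' @param curve an [atm_curve()] forcing for the forward model.
#' @param config a [synth_config()].
#' @param model_config a [tau14c_config()].
#' @param trap a [trap_spec()].
#' @return list with `sites` (site table plus `delta14c`, `delta14c_sigma`,
#'   `toc_gkg`, `saturated`), `series` (list of [incubation_series()]) and
#'   `incubation` (the same series in long format: `site_id`,
#'   `replicate_id`, `day`, `co2c_g`, `doc_g`).
#' @export
generate_observations <- function(truth, sites, curve = synth_bomb_curve(),
                                  config = synth_config(),
                                  model_config = tau14c_config(),
                                  trap = trap_spec()) {
  stopifnot(is.data.frame(truth), is.data.frame(sites))
  sites$site_id <- as.character(sites$site_id)
  if (!identical(sort(sites$site_id), sort(truth$site_id)))
    stop("truth and site tables must share the same site ids")
  sites <- sites[match(truth$site_id, sites$site_id), , drop = FALSE]
  .with_seed(config$seed + 3L, {
    n <- nrow(truth)
    delta_true <- forward_simulate(1 / truth$tau14c_true, curve, model_config,
                                   end_year = config$sampling_year)
    sites$delta14c <- delta_true + stats::rnorm(n, 0, config$sigma_ams)
    sites$delta14c_sigma <- rep(config$sigma_ams, n)
    sites$toc_gkg <- truth$toc_gkg
    dry_mass <- 40
    days <- trap_schedule_days
    leach_w <- diff(c(0, leach_schedule_days))
    sat_ids <- if (config$inject_pathologies)
      intersect(c("6", "24"), truth$site_id) else character(0)
    series <- list()
    long <- list()
    for (i in seq_len(n)) {
      oc <- truth$toc_gkg[i] * dry_mass / 1000
      k_lab <- 1 / truth$taui_true[i]
      frac <- exp(-k_lab * c(0, days) / 365.25)
      base_co2 <- oc * (frac[-length(frac)] - frac[-1L])
      doc_total_g <- truth$doc_true[i] * oc / 1000
      base_doc <- doc_total_g * leach_w / sum(leach_w)
      for (rep_j in seq_len(config$n_replicates)) {
        co2 <- base_co2 * stats::rlnorm(length(base_co2), 0,
                                        config$incubation_noise)
        doc <- base_doc * stats::rlnorm(length(base_doc), 0,
                                        config$incubation_noise)
        if (truth$site_id[i] %in% sat_ids) {
          # push the busiest interval past the saturation threshold
          j <- which.max(co2)
          co2[j] <- 1.05 * trap$saturation_frac * trap$capacity_gC
        }
        series[[length(series) + 1L]] <-
          incubation_series(truth$site_id[i], co2, doc,
                            toc_initial = truth$toc_gkg[i],
                            dry_mass = dry_mass, replicate_id = rep_j)
        long[[length(long) + 1L]] <-
          data.frame(site_id = truth$site_id[i], replicate_id = rep_j,
                     day = days, co2c_g = co2,
                     doc_g = ifelse(days %in% leach_schedule_days,
                                    doc[match(days, leach_schedule_days)],
                                    NA_real_),
                     stringsAsFactors = FALSE)
      }
    }
    list(sites = sites, series = series, incubation = do.call(rbind, long))
  })
}

#' Generate a complete synthetic study
#'
#' End-to-end wrapper: candidate population, slope filter, climate
#' categories, PCoA, stratified near-orthogonal selection of `n_sites` study
#' sites (renumbered 1..n like a field campaign would), planted truth, and
#' forward-simulated observations. Everything is reproducible from
#' `config$seed`.
#'
#' @param config a [synth_config()].
#' @param curve an [atm_curve()] (default [synth_bomb_curve()]).
#' @param model_config a [tau14c_config()].
#' @return a list of class `synthetic_study`: `population`, `design` (the
#'   [select_orthogonal()] result), `sites` (observed study-site table),
#'   `truth`, `series`, `incubation`, `curve`, `config`.
#' @export
generate_study <- function(config = synth_config(),
                           curve = synth_bomb_curve(),
                           model_config = tau14c_config()) {
  population <- generate_population(config)
  pop <- filter_population(population)
  design <- select_orthogonal(pop, n_target = config$n_sites)
  sel <- design$sites[design$sites$selected, , drop = FALSE]
  sel <- sel[order(sel$site_id), , drop = FALSE]
  sel$pop_id <- sel$site_id
  sel$site_id <- as.character(seq_len(nrow(sel)))   # study numbering 1..n
  truth <- generate_truth(sel, config)
  obs <- generate_observations(truth, sel, curve, config, model_config)
  structure(list(population = population, design = design,
                 sites = obs$sites, truth = truth, series = obs$series,
                 incubation = obs$incubation, curve = curve,
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic gradient study:", nrow(x$sites), "sites selected from a",
      nrow(x$population), "candidate population (seed",
      x$config$seed, ")\n")
  invisible(x)
}
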