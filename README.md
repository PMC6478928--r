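# soctau

Soil organic carbon (SOC) turnover from bomb radiocarbon and laboratory
incubation data, with design-based driver attribution.

Soils hold one of the largest terrestrial carbon pools, and how fast that
carbon turns over — and what controls the rate — is a central uncertainty
in carbon-cycle models. `soctau` is for biogeochemists and soil scientists
who want to estimate per-site turnover times from field and laboratory
measurements and then attribute their variation to climate, soil and
landform drivers over a network of sites whose design de-correlates those
drivers.

## What it computes

**Radiocarbon turnover time (τ₁₄C).** A single homogeneous SOC reservoir
at steady state, incorporating bomb ¹⁴C since 1950, follows the monthly
recursion

    x[t+h] = k·h·x_atm[t+h] + x[t]·(1 − h·(k + λ))

with decomposition rate `k` (yr⁻¹), time step `h = 1/12` yr and
radiocarbon decay constant `λ = 1/8267` yr⁻¹; the turnover time is
`τ = 1/k`. `forward_simulate()` runs the recursion against an atmospheric
Δ¹⁴C curve; `invert_tau()` solves for τ given an observed bulk-soil Δ¹⁴C,
returning the slow-cycling solution after the 1964 bomb peak when the
bomb spike produces two roots.

**Incubation turnover time (τᵢ).** Stock over output flux: cumulative
CO₂-C respired over a 181-day incubation (NaOH traps, conductivity
quantification, ≥80 %-capacity saturation QC), normalised to initial
organic carbon and annualised; `tau_incubation()` returns
`τᵢ = 1000 / annual flux` together with DOC production per kg OC.

**Design and attribution.** `select_orthogonal()` reproduces a
statistics-based site selection (slope filter, median climate categories,
PCoA of soil/landform covariates, stratified near-orthogonal subset);
`sequential_anova()` and `order_consistency()` run blocked Type-I ANOVA
under permuted term orderings and cross out significance that is not
order-consistent. `generate_study()` builds complete synthetic studies
with known ground truth; `run_full_analysis()` glues the whole chain.

## Worked example

```r
library(soctau)

curve <- synth_bomb_curve()                      # bomb-spike forcing
delta <- forward_simulate(1 / 150, curve, tau14c_config(),
                          end_year = 2014.5)
round(delta, 2)
#> [1] 87.27

invert_tau(rc_measurement(delta, sigma = 3, sampling_year = 2014.5), curve)
#> tau = 150.0 yr (k = 0.0066667 /yr, post_peak branch, 2 roots)

oc <- 4                                          # g OC incubated
series <- incubation_series("site1", rep(49.56 * oc / 1000 / 8, 8),
                            toc_initial = 100, dry_mass = 40)
ti <- tau_incubation(series)
sprintf("tau_i = %.1f yr, annual flux = %.1f g C per kg OC",
        ti$tau_i, ti$annual_flux)
#> [1] "tau_i = 10.0 yr, annual flux = 100.0 g C per kg OC"
```

A site whose Δ¹⁴C sits at +87‰ in 2014 is bomb-enriched: the model admits
two turnover times and the slow post-peak branch (150 yr) is adopted. The
incubation example respires 49.56 g C per kg OC in 181 days, an annualised
flux of 100 g C kg⁻¹ OC yr⁻¹, i.e. a 10-year turnover of the labile pool.

An end-to-end synthetic study with known truth:

```r
study <- generate_study(synth_config(seed = 1))
analysis <- run_full_analysis(study$sites, study$series, study$curve,
                              extra_exclusions = list(log_tau14c = "40"))
analysis
#> Regional SOC turnover analysis: 54 sites
#>   tau_14C: 54 estimates, range 67-1158 yr
#>   tau_i:   52 estimates, range 5.2-29.2 yr
#>   log_tau14c: BGR=n.s., MI=n.s., TI=n.s., MI:TI=significant, PCo1=significant, PCo2=n.s.
#>   log_taui: BGR=n.s., MI=significant, TI=n.s., MI:TI=n.s., PCo1=significant, PCo2=n.s.
#>   doc: BGR=n.s., MI=significant, TI=n.s., MI:TI=n.s., PCo1=significant, PCo2=n.s.
```

The 54 estimated τ₁₄C span 67–1158 yr (site 40 carries a planted
unrealistic 1140-yr value that the exclusion rules then drop), τᵢ spans
5.2–29.2 yr over the 52 unsaturated sites, and the consistency-screened
verdicts recover the planted structure: moisture and the soil axis PCo1
(which carries pH) drive the incubation turnover, temperature drives
nothing. `write_analysis()` saves the per-site estimates, every ANOVA
table and the verdicts as CSV.

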