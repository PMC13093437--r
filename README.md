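# reproclines

Analysis pipeline for clinal variation in reproductive modes of a bimodal
viviparous salamander. Fire salamander females are either **larviparous**
(depositing aquatic larvae) or **pueriparous** (bearing terrestrial
juveniles); across a hybrid zone between the two lineages, clutches of
intermediate composition appear. This package implements the full analysis
chain for such a transect, for ecologists and evolutionary biologists
working with staged newborn data:

* **Staging** — closed vocabularies for gill (`L1 L2 P1 P2`) and
  pigmentation (`L LP P`) character stages and the rule mapping each stage
  pair to a `larva` / `mixed` / `juvenile` phenotype.
* **Classification** — clutch and population reproductive modes
  (`larviparous` / `mixed` / `pueriparous`), proportion tables, pooled
  clutch-success rates, and transect ordering.
* **Condition** — Scaled Mass Index via standardized-major-axis allometry:
  `b_SMA = b_OLS / r = sd(ln M) / sd(ln L)`,
  `SMI = M (L0 / L)^b_SMA` with `L0` the mean total length of the filtered
  offspring dataset.
* **Ordination** — Pearson chi-square of gill-pigmentation independence and
  correspondence analysis of population-by-stage tables by SVD of
  standardized residuals (total inertia = chi-square / n), with symmetric
  and asymmetric biplot exports.
* **Model** — REML linear mixed model of log-SMI with random intercepts for
  population and female-within-population and residual SDs varying by
  maternal mode (varIdent-style), plus estimated marginal means with Tukey
  contrasts, adjusted ICC, and marginal/conditional R².
* **Simulation** — a seeded hybrid-zone transect generator (logistic cline,
  stage-coupled latent ontogeny, nested random effects, mode-specific
  residual spread) so the whole pipeline is testable and calibratable
  without the field deposit.

The methods vignette (`vignettes/reproductive-mode-clines.Rmd`) documents
the models, parameter choices, and numerical conventions.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
transect (`Rscript analysis/01_simulate_transect.R`, then `02` … `06`).
In code:

```r
library(reproclines)

# published per-population sampling effort: success-rate accounting
sr <- success_rates(table1_sampling())
sr$overall                      # 27  (percent of collected females with births)
setNames(sr$by_mode$rate_pct, sr$by_mode$group)
#> larviparous  mixed  pueriparous
#>          53     43           10

# simulate a transect and classify it
sim <- simulate_transect(cline_params(seed = 20260930))
sim <- simulate_condition(sim, condition_params(), seed = 20260930)
cl  <- clutch_summaries(sim$offspring)
transect_profile(population_summaries(cl, sim$populations))[, c("population", "mode")]
#> POP01-POP03 larviparous, POP04-POP08 mixed, POP09-POP12 pueriparous

# condition and the heteroscedastic mixed model
off <- add_condition(sim$offspring)     # SMA slope ~3.13, TL0 ~35.8 mm
fit <- reml_fit(prepare_frame(off, sim$females))
round(fit$delta, 4)               # residual-SD multipliers by maternal mode
#> larviparous       mixed pueriparous
#>      1.1608      1.0000      0.6838
round(variance_summary(fit)$icc_adjusted, 3)
#> 0.328
emmeans_tukey(fit, "fem_mode")$contrasts
```

The classification of the simulated transect reads larviparous in the
south, mixed mid-transect, pueriparous in the north, with mixed clutches
peaking centrally and a strongly significant gill-pigmentation association
(chi-square ≈ 1300 on df 6 at the default scale) — the qualitative pattern
the field study reports. `parameter_recovery()` re-fits 200 simulated
transects and recovers the generating residual-SD multipliers
(1.10, 0.65) and variance components to within a few percent.

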