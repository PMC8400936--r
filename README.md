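# micpkin

Kinetic profiling and isolate selection for microbially induced calcium
carbonate precipitation (MICP).

Ureolytic bacteria hydrolyze urea to ammonium and carbonate, alkalinize
their medium, and — given dissolved calcium — drive CaCO₃ precipitation.
Screening programs isolate dozens of candidate strains from alkaline soils
and must answer two questions: *which isolates are worth carrying forward*,
and *how fast does each one actually run the process*. `micpkin` implements
the quantitative core of that workflow for microbiologists and biomineralization
engineers:

1. **Isolate selection by standard score.** Each of nine MICP assay
   variables (sporulation rate SR, pH optimum, urea-agar growth UAG and
   color change UAC, urea-broth turbidity UBT and color change UBC,
   CaCl₂ precipitation UBCA, and CaCO₃ formation on urea and yeast-extract
   media, MUC and MEC) is min–max normalized,

   x̄ᵢ = (xᵢ − min xᵢ) / (max xᵢ − min xᵢ),

   and combined into the weighted standard score
   SS = Σᵢ wᵢ x̄ᵢ (weights default to 1/9 and sum to 1). SS = 1 marks an
   isolate that attains the panel optimum on every assay; ranking is by
   descending SS with stable ties.

2. **Kinetic models.** Three closed forms cover the measured variables:
   - first-order ureolysis at constant viable-cell density c_X:
     c_Urea(t) = c_Urea(0)·exp(−k_Urea·t·c_X), t in hours;
   - the four-parameter sigmoid y(t) = d + (a − d)/(1 + (t/c)^b) for pH,
     log viable cells and precipitate mass (a = initial value, d = final
     asymptote, c = midpoint time, b = Hill slope);
   - first-order free-calcium depletion
     c_Ca(t) = c_Ca(0)·exp(−k_precipitate·t), t in days, proxied 1:1 to
     CaCO₃ formation.

3. **Fitting.** Bounded multistart Levenberg–Marquardt nonlinear least
   squares recovers the parameters from trajectories, with r², RMSE,
   residuals, a truthful convergence flag, and a replicate-based
   lack-of-fit F-test. Exponential fits are seeded by a log-domain
   regression, which keeps very steep decays (k of several per day)
   identifiable from daily sampling.

4. **Synthetic data and pipeline.** A seeded generator produces
   trajectories from built-in kinetic profiles of seven characterized
   strains (the ureolytic reference *Sporosarcina pasteurii* DSM 33, the
   non-ureolytic reference *Bacillus pseudofirmus* DSM 8715 and five soil
   *Bacillus* isolates) plus assay panels with a planted top group, so the
   whole pipeline is validated by parameter recovery; `run_pipeline()`
   orchestrates score → fit → report with full logging.

## Worked example

```r
library(micpkin)

# generate a noiseless urea trajectory for B. licheniformis and refit it
p  <- strain_profiles()[["B. licheniformis"]]$ureolysis
tt <- schedule_ureolysis()                     # 0,1,4,...,72 h
tr <- trajectory("B. licheniformis", "urea_gL", tt, urea_model(tt, p))
fit <- fit_ureolysis(tr)
fit$params
#> < ureolysis_params > k_urea = 0.04, c_urea0 = 19.99, c_x = 1

# how fast does it strip calcium from the medium?
percent_reduction(strain_profiles()[["B. licheniformis"]]$calcium, t = 1)
#> [1] 99.20929
```

The fitted rate k_Urea = 0.04 h⁻¹ (at normalized cell density) and initial
concentration 19.99 g/L match the generating profile exactly, and the
fitted depletion coefficient k_precipitate = 4.84 d⁻¹ implies 99.2 % of
free calcium removed within the first day — the signature of the fastest
precipitator among the seven profiles.

The `analysis/` directory holds the full narrative workflow as numbered
drivers: `01_simulate.R` (synthetic panel + trajectory bundles),
`02_score_isolates.R` (standard-score ranking; the five planted
high-performers occupy the top five ranks, SS 0.955–0.976),
`03_fit_kinetics.R` (42 fits per bundle; every noiseless coefficient is
recovered, max |k_Urea error| ≈ 1e-16) and `04_summaries.R` (per-strain
calcium removal at 24 h, MICP pH rise, residual urea at 72 h). Each writes
its tables under `results/`.

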