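# fluxsample

How many chamber collars does it take to estimate soil CO₂ emission over a
25 km² plot, and how much uncertainty does spatial variability add at a
given sample size? `fluxsample` answers these questions with a Monte Carlo
subsampling analysis of point-scale soil-respiration campaigns. It is aimed
at field ecologists and biogeochemists designing (or re-analysing) chamber
surveys of soil respiration, soil temperature and soil moisture.

## The method

A campaign measures soil respiration `R` (μmol CO₂ m⁻² s⁻¹), soil
temperature `T` (10 cm, °C) and volumetric water content `W` (0–10 cm, %)
at `N` collars. Each collar is collapsed to a scalar — its mean `T`, mean
`W`, or its growing-season CO₂ emission `E` obtained by fitting one of
three empirical response models per collar,

- `R:T`  R = α e^(βT)
- `R:W`  R = α W^β
- `R:T&W`  R = α T^β W^γ,

by nonlinear least squares and integrating the prediction over a continuous
half-hourly driver record. The spatial uncertainty at sample size `k` is
estimated by drawing `M` (default 10,000) random subsamples of size `k`
without replacement, taking each subsample mean `E_i`, and computing

    CV_k = sqrt( (1/(M−1)) Σᵢ (E_i − E_N)² ) / E_N × 100 %

where `E_N` is the full-sample mean. The optimal sample size `n*` is the
smallest `n` where the forward slope of the CV curve rises above −1.0 % per
collar — past that point an extra collar buys less than one percentage
point of precision. First-order total derivatives translate driver
estimation errors into relative flux errors (ΔR/R = βΔT, βΔW/W, or
βΔT/T + γΔW/W for the three models respectively).

Two independent oracles validate the Monte Carlo engine: exhaustive
enumeration of all k-subsets, and the survey-sampling closed form
CV_k = sqrt((S²/k)(1 − k/N))/E_N with S² the sample variance (the
finite-population correction). A seeded synthetic generator emulates an
irrigated oasis maize plot (51 collars, 5 × 5 km², four quadrant subplots,
6-day survey cadence, irrigation-driven moisture sawtooth), so the entire
pipeline is testable without field data.

## Worked example

```r
library(fluxsample)

sim <- generate_campaign(synthetic_config(), seed = 42)
sim$campaign
#> Chamber campaign: 51 collars, 816 observations, 5.0 x 5.0 km plot
#>   collars per subplot (SW,SE,NE,NW): 15/15/12/9
#>   dates: 2012-06-16 .. 2012-09-14

# fit the interactive model at one collar and integrate its season
obs1 <- sim$campaign$obs[sim$campaign$obs$collar_id == "C01", ]
fit <- resp_model(obs1, "RTW")
fit
#> Soil respiration model RTW:  R = alpha * T^beta * W^gamma
#>   alpha    beta   gamma
#> 0.06148 0.74470 0.64390
#> R-squared 0.9042 on 16 observations

integrate_emission(fit, sim$continuous[["C01"]], collar_id = "C01")
#> Seasonal emission (collar C01), model RTW, 2012-06-16 .. 2012-09-20
#>   37.269 mol CO2 m-2 = 447.6 g C m-2 = 1640.2 g CO2 m-2

# CV curve of mean soil temperature and its optimal sample size
s  <- summarize_points(sim$campaign)
cv <- mc_cv_curve(s$mean_T, M = 10000, seed = 1, variable = "T")
optimal_sample_size(cv)
#> Optimal sample size n* = 2 (CV 3.8%) at dCV/dn > -1.0

# propagate sample-size-driven driver errors into flux error
propagate_error(list(model = "RTW", beta = 1.649, gamma = 0.622),
                delta_T = 0.054 * 20, delta_W_rel = 0.095, T_bar = 20)
#> Model RTW: dR/R = 0.1481 (14.81%)
```

Reading: two collars already pin the plot-mean temperature to within a CV
of 3.8 % because temperature is spatially stable; moisture and emission,
being irrigation-driven and heterogeneous, need more collars (run the same
three lines on `s$mean_W` or on per-collar emissions). The last call says
that 5.4 % temperature error and 9.5 % moisture error compound to a ~14.8 %
relative error in modelled respiration under the interactive model.

The whole pipeline — simulate → fit → integrate → CV curves → optimal n per
plot partition — is one call (`run_full_analysis("out/")`) or one shell
command (`exec/fluxsample design --out out/`).

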