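# memkin

Kinetic modelling of circulating memory CD4 T cell maintenance from
division-linked DNA labelling (BrdU) with concurrent Ki67 staining in
busulfan chimeric mice.

Memory CD4 T cells — central memory (T<sub>CM</sub>) and effector memory
(T<sub>EM</sub>) — are maintained by a balance of self-renewal, loss, and a
constitutive influx of newly generated memory cells. `memkin` is for
quantitative immunologists who want to estimate those rates, and to ask
whether a memory subset behaves as one kinetic population or as fast and
slow subpopulations, from the standard experimental readouts:

* BrdU pulse/chase timecourses (21-day pulse, 14-day chase) stratified by
  Ki67 expression and by host/donor origin in busulfan chimeras;
* long-timescale donor-replacement (chimerism) curves, which identify the
  per-capita influx rate and the donor content of the influx;
* fate-reporter validation experiments (heritable-label dilution, and
  transfer of Ki67-labelled cohorts).

## The model

A memory subset contains subpopulations *i* with division rates
&alpha;<sub>i</sub> and loss rates &delta;<sub>i</sub> (per day), fed by a
constant influx &Phi; of Ki67-high cells. Candidate structures: **branched**
(influx splits between independent slow/fast subpopulations), **linear**
(fast entry state maturing into a slow descendant), **burst**
(quiescent/dynamic cycling), and **temporal** (loss tied to Ki67 state).
The labelling dynamics track the 16 compartments
{subpopulation} &times; {Ki67<sup>hi/lo</sup>} &times; {BrdU&plusmn;}
&times; {host/donor}: division removes the parent and makes two Ki67-high
daughters, labelled with per-division efficiency &epsilon; during the
pulse; Ki67-high decays at &beta; = 1/T (T &asymp; 3.1 d); influx enters
Ki67-high with donor fraction f<sub>d</sub> and a parametric BrdU content.
Populations are at quasi-equilibrium: the net loss rate
&lambda; = &delta; &minus; &alpha; sets the *clonal* half-life
ln 2 / &lambda;, and the size-weighted mean of &delta; sets the mean cell
lifespan.

Fitting is Bayesian (logit-normal errors on fractions, log-normal on
counts) with an affine-invariant ensemble sampler, a chimerism-derived
prior on the influx rate, and PSIS-LOO/ELPD model ranking (differences
below 4 are reported as indistinguishable).

## Worked example

Simulate a study-shaped young-cohort T<sub>CM</sub> experiment, fit the
branched model to the host timecourse with a chimerism-derived influx
prior, and summarise lifespans:

```r
library(memkin)

truth <- study_truth("TCM", "young")        # calibrated ground truth
design <- study_design("young")             # 21 d pulse + 14 d chase, 2 mice/point
ds <- generate_labelling_dataset("branched", truth, design, seed = 1)

# influx prior from a donor-replacement curve
cur <- generate_chimerism_dataset(list(phi = 0.015, f_d = 0.85), seed = 1)
rep_fit <- fit_replacement(cur, seed = 1)
fit <- fit_model("branched", ds[ds$lineage == "host", ],
                 priors = influx_prior(rep_fit), seed = 1)
fit
#> <posterior_draws> branched model, 1400 draws, 120 observations [INVALID: R-hat > 1.01]
#>   acceptance 0.26, max R-hat 1.440, min ESS 49
#>                    2.5%         50%       97.5%
#> alpha_A          0.0003      0.0033      0.0100
#> lambda_A         0.0038      0.0131      0.0291
#> alpha_B          0.1775      0.2486      0.3734
#> lambda_B         0.0062      0.0121      0.0180
#> psi              0.2227      0.4554      0.6478
#> beta             0.2849      0.3627      0.5230
#> epsilon          0.3302      0.4941      0.6576
#> phi_rate         0.0125      0.0149      0.0172
#> N0          215334.4038 247567.7311 286363.3762
#> ...

weighted_mean_lifespan(fit)$lifespan
#>     2.5%      50%    97.5%
#> 4.449880 6.450019 8.541472
```

At the default (deliberately light) sampler settings the fit is honest
about its mixing: R-hat above 1.01 flags it, and raising `n_steps` in
`sampler_config` clears the flag without changing the estimates
materially. The fast subpopulation divides roughly every 4 days
(`alpha_B` &asymp; 0.25/d) while the slow one divides every few hundred
days; the Ki67-high lifetime `1/beta` is about 2.8 days; the influx
replaces about 1.5% of the pool per day (pinned by the chimerism-derived
prior). The lifespan summary says host T<sub>CM</sub> cells live about
6–7 days on average once fast and slow subpopulations are weighted by
their sizes — short lifespans despite long-lived clones (fast-cell
clonal half-lives, `clonal_half_life(delta, alpha)`, are here
ln 2 / 0.012 &asymp; 60 days, because self-renewal nearly balances
loss). The quick desk estimator from Ki67
prevalence gives the matching population-level figure:

```r
lifespan_from_ki67(k_tcm = 0.4, k_tem = 0.2, T_ki67 = 3.1,
                   em_cm_ratio = 7.5)$lifespan
#> [1] 26.03481
```

about 26 days for the pooled memory CD4 compartment (T<sub>EM</sub>
dominate the average through their 7.5-fold abundance). Model ranking and
the validation predictions follow the same pattern:

```r
fits <- list(branched = fit,
             linear = fit_model("linear", ds[ds$lineage == "host", ], seed = 1),
             burst = fit_model("burst",  ds[ds$lineage == "host", ], seed = 1))
compare_models(fits)          # |ELPD difference| < 4 -> indistinguishable
simulate_cohort_transfer(fit, with_influx = FALSE)   # Ki67 decline without influx
```

See the methods vignette (`vignettes/memkin-methods.Rmd`) for the model,
priors, numerical choices and limitations.

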