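# saccharify

Stochastic simulation and global sensitivity analysis of the enzymatic
saccharification of lignocellulosic biomass.

## The problem

Plant biomass (corn stover, straw, bagasse) is a composite of cellulose,
hemicellulose and lignin. Biorefineries break the cellulose down into glucose
with a cocktail of cellulases — endoglucanase (EG), cellobiohydrolase (CBH)
and β-glucosidase (BGL), plus xylanase for the hemicellulose sheath — but the
material resists digestion: part of the cellulose is crystalline and far
harder to hydrolyse, lignin adsorbs enzymes non-productively, and the
released sugars themselves inhibit the cellulases. Which of the many kinetic
and structural parameters actually control the 72-hour glucose conversion
yield is the question this package addresses, for modellers fitting
saccharification time-courses and for experimentalists choosing what a
pre-treatment should target.

## The model

A single microfibril is resolved at monomer level: cellulose chains at the
core, sheathed by hemicellulose and lignin layers. Each glycosidic bond is
amorphous or crystalline; a crystalline bond is digested with propensity
scaled by the digestibility ratio `r = d_cryst / d_amorph` (0 < r ≤ 1,
typically 10⁻³–10⁻²), and the crystallinity fraction `X` is the share of
crystalline bonds. Enzyme events — EG cuts of exposed internal bonds, CBH
attachment to chain ends and processive cellobiose release, BGL splitting of
cellobiose, xylanase cuts — fire via an exact Gillespie algorithm with
propensities `p_y = K_y n_y N_y`. Free glucose and cellobiose reduce the
effective cellulase numbers:

```
n_y = n_y0 (1 − Σ_x ω_y^x n_x / (Σ_y n_y0 + n_x)),   x ∈ {glc, cbs}
```

and every `L_adh` exposed monolignols sequester one enzyme. Nineteen
parameters (5 rates, 4 enzyme counts, 2 crystallinity fractions, 2
digestibility ratios, lignin adhesion, 5 inhibition affinities) form the
sensitivity registry.

Two companion analyses ship with the simulator:

* **Characteristic times** (`characteristic_times()`, `limiting_step()`):
  closed forms such as `τ_CBH = 1/(4 K_CBHA n_CBH) + (N/K_CBHD)[1 + X(1/r − 1)]`
  for a chain of DP 2N, proving CBH digestion is the time-limiting step for
  the realistic rate ranges (`K_CBHD ∈ [10,10²]`, `K_EG, K_BGL ∈ [10²,10³]`),
  with the regime boundaries given by quadratic roots in N.
* **Sobol sensitivity pipeline** (`saltelli_sample()`, `run_campaign()`):
  Saltelli-style A/B/AB cross sampling (`N_base·(p+2)` parameter sets),
  replicate-averaged simulation, the curve-difference objective
  `Y = Σᵢ |sim(tᵢ) − ref(tᵢ)|`, and Jansen total-order indices normalised by
  the index of the CBH rate `K_CBHD`.

## Worked example

```r
library(saccharify)

# a desk-scale pre-treated fibril: 12 cellulose chains of DP 100
p  <- default_parameters()           # K_CBHD = 45/h, X = 0.45, r = 5e-3, ...
tc <- simulate_saccharification(p, structure_config(), n_rep = 10, seed = 1)
round(tc$conversion_pct[c(13, 25, 49, 73)], 1)
#> [1] 28.5 39.2 59.8 77.9        # % glucose conversion at 12, 24, 48, 72 h

# CBH is the time-limiting step, by characteristic times
ct <- characteristic_times(N = 50, K_EG = 300, K_CBHA = 300, K_CBHD = 45,
                           K_BGL = 300, n_EG0 = 30, n_CBH0 = 30, n_BGL0 = 30,
                           X = 0.45, r = 0.005)
limiting_step(ct)$limiting
#> [1] "CBH"

# regime roots at K_R = K_EG/K_CBHD = 1
eg_regime_roots(1)$printed
#>    N1    N2
#>  2.53 -0.19
```

The curve shows the two-phase dynamics: a steep amorphous phase, then a slow
crystalline plateau — 77.9% conversion at 72 h for X = 0.45. A scaled-down
sensitivity campaign (`run_campaign()` with `n_base = 64`, 3 replicates,
small fibril, ~20 s) ranks the same five parameters found at full scale:
`X_cellulose`, `r_cellulose`, `K_CBHD`, `n_CBH0`, `omega_CBH_glc`.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("exec","saccharify",package="saccharify"))')
Rscript $CLI fixtures make-ref --anchor 58.2 --out ref.csv
Rscript $CLI simulate --config model.json --tmax 72 --reps 10 --seed 1 --out curve.csv
Rscript $CLI analytic --kr 1 --N 50
Rscript $CLI sobol --config model.json --ref ref.csv --nbase 64 --reps 3 --seed 1 --out campaign/
```

## Vignette

`vignettes/saccharification-methods.Rmd` documents the model assumptions,
parameter defaults and units, the synthetic-data generators, numerical
conventions and known limitations.
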