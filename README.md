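# thermoniche

Thermal performance curves and phylogenetic niche structure for microalgal
strain panels.

## The problem

Benthic marine diatoms such as *Cylindrotheca closterium* occur from the
tropics to the poles, and apparent cosmopolitan species often turn out to be
complexes of (pseudo)cryptic lineages with distinct thermal niches. Deciding
which lineages are vulnerable to coastal warming requires three linked
analyses, each of which this package implements as tested, reusable code:

1. **Growth kinetics** — strains are grown at a temperature gradient
   (typically 0.5–33 °C, four replicates) and monitored by PAM fluorometry;
   the minimum fluorescence yield F₀ proxies biomass, so the specific growth
   rate in divisions/day is the OLS slope of log₂ F₀ against time over the
   exponential phase. Viability after extreme-temperature exposure is
   summarized from live/dead counts.
2. **Thermal response** — the replicate-mean rates μ(T) are fitted with the
   Blanchard unimodal curve

   μ(T) = μ_max · x^β · exp[−β(x − 1)],  x = (T_max − T)/(T_max − T_opt),

   by nonlinear least squares with Jacobian-based standard errors. The curve
   attains μ_max at T_opt and zero at T_max; the *thermal performance range*
   is the interval where predicted growth is ≥ 80 % of μ_max.
3. **Phylogenetic comparative analysis** — the strain phylogeny is made
   ultrametric by penalized-likelihood rate smoothing (smoothing weight
   0.1); phylogenetic signal in T_opt is quantified by Pagel's λ (ML,
   likelihood-ratio test) and Blomberg's K (tip-permutation test); and the
   association between *rbcL* p-distances and great-circle geographic
   distances is tested with a Mantel permutation test. Trait regressions
   (μ_max ~ T_opt "hotter is better", niche width ~ T_opt, T_opt ~ sea
   surface temperature) close the loop.

A seeded synthetic-data generator emulates the whole experiment — a Yule
tree, a λ-structured thermal optimum, Blanchard-shaped growth with
multiplicative lognormal F₀ noise, and site SSTs coupled to the optima — so
every stage is testable end to end without any external download.

## Worked example

```r
library(thermoniche)

# one culture: F0 roughly doubling daily
s <- fluorescence_series("PS10", temperature = 20, replicate = 1,
                         times = 0:5,
                         f0 = c(3000, 5900, 12500, 24200, 47800, 97000))
estimate_growth_rate(s)
#> rate 1.0024 divisions/day, r^2 0.99978, 6 points

# a full synthetic panel through the pipeline
sim <- simulate_panel(panel_spec(seed = 42))      # 24 strains, 7 temps, 4 reps
dir <- tempfile(); write_panel(sim, dir)
cfg <- run_config(f0_csv = file.path(dir, "f0.csv"),
                  tree_nwk = file.path(dir, "tree.nwk"),
                  strains_csv = file.path(dir, "strains.csv"),
                  out_dir = file.path(dir, "out"), seed = 7)
rep <- run_all(cfg)
head(rep$tpc[c("strain_id", "mu_max", "t_opt", "se_t_opt", "t_max", "beta", "width")], 4)
#>   strain_id mu_max t_opt se_t_opt t_max  beta width
#> 1       s01  1.269 20.98    0.118 30.58 2.437 8.259
#> 2       s02  1.037 16.81    0.027 26.97 3.314 7.486
#> 3       s03  1.142 18.87    0.125 28.84 2.860 7.914
#> 4       s04  1.530 26.54    0.125 36.23 1.774 9.786
rep$phylogenetic_signal
#> lambda 0.9923 (LR p 1.4e-07)   K 1.101 (permutation p 0.001)
rep$regressions$mu_pred_vs_topt$slope
#> 0.0508   # hotter is better: divisions/day gained per degC of optimum
```

The fitted table shows, per strain, the predicted maximum growth rate
(`mu_max`, divisions/day), the thermal optimum and maximum (`t_opt`,
`t_max`, °C) with standard errors, the curve shape `beta`, and the 80 %
performance-range width (°C). `lambda` near 1 means related strains share
thermal optima (Brownian-like niche conservatism); the hotter-is-better
slope of ≈ 0.05 divisions/day per °C and the width–optimum slope of
≈ 0.25 °C/°C recover the values the generator encodes.

## Command line

```sh
exec/thermoniche simulate --out data --seed 42
exec/thermoniche growth-rates --f0 data/f0.csv --out rates.csv
exec/thermoniche fit-tpc --rates rates.csv --out tpc.csv
exec/thermoniche run-all --f0 data/f0.csv --tree data/tree.nwk \
    --strains data/strains.csv --out report --seed 7
exec/thermoniche sst --seasonal 10,12,14,16
```

`run-all` also accepts `--config cfg.yaml` (fields mirror `run_config()`)
plus `--fraction`, `--smoothing`, `--n-perm`, `--seed` overrides; the
effective configuration is echoed in `report/report.json`.

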