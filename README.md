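# nichebreadth

Crop wild relatives differ widely in how much climatic variation they
tolerate, and that tolerance shapes both their conservation value and
their usefulness as donors of stress-adaptation alleles in breeding. For
groups such as the wild relatives of potato (*Solanum* sect. *Petota*),
two intrinsic traits plausibly drive niche evolution: the breeding
system (self-incompatible vs self-compatible) and ploidy (diploid vs
polyploid), which interact — polyploidy buffers the inbreeding cost of
selfing, while diploids rely on outcrossing.

`nichebreadth` implements the full inference chain from occurrence
points to that conclusion:

1. **Niche breadth from occurrences.** Each georeferenced record is
   assigned the discrete Köppen–Geiger class of its raster cell; classes
   with three or fewer of a species' records are discarded (guarding
   against by-chance presences); the niche breadth `B_s` is the count of
   retained classes. The bundled legend has the 30 three-tier classes.
2. **Trait coding.** Breeding system × ploidy states are coded as four
   *non-exclusive* 0/1 indicators (`SI_diploid`, `SC_diploid`,
   `SC_polyploid`, `asexual_diploid`); a species with mixed cytotypes or
   populations carries several at once.
3. **Regression.** Ordinary least squares
   (`B_s = Xβ + ε`), and a phylogenetic linear model in which residuals
   follow Brownian motion on a time-calibrated tree plus an independent
   error:

   ```
   y ~ N(Xβ, σ² C + σ²_err I),   C_ij = shared root-to-MRCA branch length
   ```

   fitted by maximum likelihood via a one-dimensional profile over
   γ = σ²_err/σ², with percentile parametric-bootstrap intervals for the
   variance components.
4. **Synthetic data.** A first-class generator (Yule trees, Bernoulli
   trait states, nearest-seed patch rasters, per-species occurrence
   clouds with exact ground-truth breadth, model-drawn responses) makes
   every stage testable offline.

See the vignette (`vignettes/niche-breadth-models.Rmd`) for the model
details, parameter conventions and design decisions.

## Worked example

Simulate a 27-species study, run the occurrence pipeline, and fit the
phylogenetic model:

```r
library(nichebreadth)

scen <- simulate_scenario(simulation_config(n_species = 27, seed = 42))
head(compute_breadth(scen$occurrences, scen$raster), 4)
#>   species_id B_s         retained_classes n_points n_nodata
#> 1         t1   5       Am;BSh;BSk;BWh;Csa       30        0
#> 2        t10   7 Af;Am;Aw;BSh;BSk;BWh;BWk       48        0
#> 3        t11   6    Af;Am;BSk;BWh;BWk;Csa       36        0
#> 4        t12   5        Af;Am;BSh;BSk;Csa       42        0

fit <- fit_pglm_bm_error(scen$X, scen$y, scen$tree)
fit
#> Phylogenetic linear model (Brownian motion + independent error)
#>   n = 27 tips, tree depth = 9.19957, residual df = 22
#>             term             value
#>      (Intercept)    2.785* (1.027)
#>       SI_diploid  3.157*** (0.602)
#>       SC_diploid     0.722 (0.697)
#>     SC_polyploid  2.677*** (0.649)
#>  asexual_diploid  2.376*** (0.583)
#>     observations                27
#>               R2             0.742
#>      adjusted R2             0.695
#>    residual s.e. 0.708 (d.f. = 22)
#>   sigma^2 = 0.408122 (per branch-length unit), sigma^2 error = 0.655683
#>   log-likelihood = -50.6839, gamma = 1.60659

parametric_bootstrap(fit, n_boot = 100, seed = 42, include_beta = FALSE)
#>      parameter  estimate        lower     upper
#> 1       sigma2 0.4081217 1.203648e-08 0.7569142
#> 2 sigma2_error 0.6556834 3.592279e-09 2.5837974
```

Reading: each coefficient is the change in the number of discrete
climate classes occupied, relative to a species carrying none of the
four flags (the intercept, here ≈ 2.8 classes). In this simulated run
the self-incompatible diploid and self-compatible polyploid indicators
raise breadth by ≈ 3.2 and ≈ 2.7 classes (both p < 0.001), the
model explains 74 % of breadth variance on the GLS scale, and the
bootstrap intervals show the Brownian rate σ² is not separable from the
independent error with much precision at n = 27 — its interval reaches
down to the boundary.

The same chain runs from files (occurrence CSV; single-band ESRI ASCII
class grid + `code,label` legend CSV; wide or long trait CSV; Newick
tree) through `run_analysis(run_config(...))`, which writes the breadth
table, both model tables, bootstrap intervals, per-state-combination
breadth summaries and a manifest that names every species dropped at
each join — byte-identical on re-run with the same seed.

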