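# traitrisk

Trait-based modelling of species extinction risk under phylogenetic
control, for red-list analyses of insects (butterflies, odonates) and
similar taxa. The package takes a rooted phylogeny, a table of
morphological and biogeographical traits — optionally measured directly
from dorsal specimen images — and ordinal IUCN red-list categories, and
answers: *which traits predict extinction risk, and is the association
carried by evolutionary history or by recent, species-specific variation?*

## The method

For each trait `y` on a phylogeny with Brownian covariance `C`:

1. **Phylogenetic signal.** Pagel's λ is estimated by maximum likelihood
   over `C_λ = λC + (1−λ)diag(C)`, profiling the mean and rate
   analytically, with a likelihood-ratio test against λ = 0 (χ², 1 df).
2. **Decomposition.** The phylogenetic mixed model
   `y = μ + a + e`, `a ~ N(0, σ²ₐG)`, `e ~ N(0, σ²ₑI)` (G the
   depth-normalised correlation matrix) is fitted by profiling
   `h² = σ²ₐ/(σ²ₐ+σ²ₑ)`; BLUP gives the phylogenetically predicted
   component `P = μ̂ + â` and the species-specific component `S = y − P`
   (exactly additive).
3. **Ordinal regression.** Red-list categories (LC=0 … CR=4) are modelled
   by proportional-odds regression,
   `P(Y ≤ k | x) = logistic(ζₖ − x'β)`, fitted jointly on the four traits
   of each block — S-components, P-components, and raw traits — so every
   effect is controlled for the others, in particular for range size.

Traits from images follow the pixel conventions of insect morphometrics:
body volume as stacked cylindrical discs (`Σ π(n_r·s/2)²·s`), color
lightness as the mean 8-bit RGB gray over body plus the nearest third of
each wing, wing area as pixel count × pixel area, residual wing area as
the log–log size-corrected residual, and range occupancy as the occupied
fraction of an equal-area grid. All inputs have simulators with known
ground truth (`simulate_tree`, `simulate_lambda_trait`,
`simulate_lynch_trait`, `simulate_ordinal_response`,
`render_specimen_image`, `simulate_study`), so the whole pipeline is
testable without any external data.

## Worked example

```r
library(traitrisk)

st  <- simulate_study(n_species = 330, seed = 20220908)  # tree, traits, status
rep <- run_pipeline(list(tree = st$tree, traits = st$traits,
                         out_dir = "results/models", seed = 20220908))
rep$lambda_table
rep$blocks$S
```

The simulated study has strong phylogenetic signal in the morphological
traits, weak signal in range size, and a single true effect: extinction
risk rises as the *species-specific* part of range size shrinks. The
pipeline recovers exactly that pattern:

```
phylogenetic signal (lambda, LR test vs lambda = 0):
           trait lambda  p_value
     body_volume  0.967 5.40e-88
       wing_area  0.891 2.68e-43
 color_lightness  0.775 2.62e-58
 range_occupancy  0.319 2.81e-08

species-specific range-size effect: -0.83 +/- 0.19 (z = -4.39, p = 1.15e-05)
=> extinction risk rises as species-specific range size shrinks
```

while the P-component (evolutionary history) block shows no significant
predictor. The numbered drivers under `analysis/` tell the full story —
`01_simulate_study.R` through `06_replication_experiment.R` generate the
data (including rendered specimen images), extract traits from the images,
estimate signal, decompose, fit the three regression blocks, and repeat
the whole study 40 times to report detection rates; each writes its tables
under `results/`.

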