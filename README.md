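# dtfm — digital traction force microscopy for cell monolayers

Traction force microscopy (TFM) maps the in-plane stress `T(x)` (Pa) that an
adherent cell colony exerts on its substrate. Experimental TFM is accurate
but low-throughput: every map costs bead imaging, cell detachment and an
inverse elasticity reconstruction, and resolution degrades on stiff gels.
`dtfm` builds the digital counterpart for people who study collective cell
mechanics (mechanobiology labs, image-analysis methodologists):

* a **geometry generator** for random, curvature-controlled colony outlines
  from a descriptor `d = (n_s, R̄, r_s, σ_s)` (boundary waves, mean radius,
  fluctuation amplitude, smoothing), rasterized to binary indicators `Ω`;
* a **continuum simulator** for ground-truth tractions: a contractile
  elastic monolayer on an elastic foundation,
  `h ∇·(σ_el + σ_A I) = (E_s/L_s) u` with a traction-free edge and a
  saturating contractility law `σ_A(E_s) = σ_max E_s/(E_half + E_s)`,
  solved by pixel-grid finite elements (exact discrete force balance);
* a **conditional adversarial translator** (U-Net generator + patch
  discriminator, cross-entropy objective
  `L(D,G) = E[log D(T)] + E[log(1 − D(G(Ω,C)))]`, ADAM with lr 2·10⁻⁴,
  β₁ = 0.6, β₂ = 0.95) that paints the traction map from cell geometry and
  substrate properties, with a single factor `α` extrapolating trained maps
  to other contractile cell types;
* an **inverse network** recovering the hidden substrate stiffness field
  `E_s(x)`, its footprint mean `Ē_s`, and the contractility–stiffness
  relation from `(Ω, T)`;
* **analysis tools**: the average pixelwise relative error
  `ε_T = ⟨|T^p − T^t|/|T^t|⟩` over masked pixels, force-balance residuals,
  and durotaxis asymmetry `A = (S⁺ − S⁻)/(S⁺ + S⁻)` of stiff- vs soft-side
  traction under stiffness gradients.

The methods vignette (`vignettes/digital-tfm.Rmd`) documents the models,
defaults, and design decisions.

## Worked example

Simulate a corpus, train a small translator, and evaluate it:

```r
library(dtfm)

# 120 simulated (geometry, stiffness, traction) samples at a 64x64 grid
corpus <- build_corpus(120, seed = 1, n = 64)
corpus
#> <tfm_corpus> 120 samples, 64x64 grid, traction scale 644 Pa
#>  stiffness modes: uniform

split <- split_corpus(corpus, c(train = 100/120, test = 20/120), seed = 1)
model <- train_gan(corpus, split = split,
                   config = train_config(epochs = 40, batch_size = 8, seed = 1,
                                         augment = TRUE))

preds  <- predict_corpus(model, corpus, split$test)
truths <- lapply(split$test, function(i) corpus$samples[[i]]$traction)
epsilon_t(preds, truths)
#> <tfm_error_report> epsilon_T = 0.2355 (23.5%) over 20 samples (mask: |T| > 0.05 max)
```

`epsilon_t()` is the average pixelwise relative traction error over pixels
carrying at least 5% of each map's peak traction: 0.24 means the painted
maps deviate from the simulated ground truth by ~24% of the local traction
magnitude on this deliberately small training corpus (a couple of minutes
of CPU); the scaled-down evaluation below trains on 300 samples and stays
well under 15%. Single predictions come from
`predict_traction(model, geometry, stiffness_field)` and plot with
`autoplot()`; `scale_to_cell_type(tf, alpha)` rescales a map to a more or
less contractile cell type.

The simulator alone reproduces collective durotaxis — traction localizes
on the stiff side of a gradient substrate, more strongly for steeper
gradients and larger colonies:

```r
durotaxis_sweep(gradients = c(25, 50, 100), radii = c(50, 80, 120),
                n_reps = 6, n = 64, seed = 31)
#>   vary     gradient  rbar a_mean   a_sd    a_se n_reps
#> 1 gradient       25    80 0.0276 0.0141 0.00576      6
#> 2 gradient       50    80 0.0354 0.0162 0.00661      6
#> 3 gradient      100    80 0.0735 0.0256 0.01047      6
#> 4 radius         50    50 0.0191 0.0167 0.00680      6
#> 5 radius         50    80 0.0354 0.0162 0.00661      6
#> 6 radius         50   120 0.0685 0.0227 0.00929      6
```

`a_mean` is the stiff-side traction asymmetry A: positive everywhere under
a positive gradient, and growing with both gradient strength and colony
size — the collective-durotaxis signature.

An end-to-end pipeline (corpus → training → inversion → evaluation →
durotaxis) with file artifacts and a checksum manifest:

```r
run_pipeline(smoke_profile("out_dir", seed = 1))
```

and a thin shell interface with the same stages lives at
`inst/cli/dtfm.R` (`Rscript dtfm.R pipeline --out out_dir --seed 1`).

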