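---
title: "Digital traction force microscopy: model, simulator and networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital traction force microscopy: model, simulator and networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 4)
library(dtfm)
```

Traction force microscopy (TFM) measures the in-plane stress a cell colony
exerts on its deformable substrate. It is accurate but slow: each map needs
bead imaging, cell detachment, and an inverse elasticity reconstruction.
`dtfm` implements a *digital* TFM: a continuum simulator manufactures
(geometry, substrate, traction) triples at scale, a conditional adversarial
image-to-image network learns the geometry-to-traction translation, and an
inverse network recovers hidden substrate properties from traction maps.
This vignette records the models, the parameter choices, and the design
decisions, in that order; the README shows the quick-start workflow.

## The forward continuum model

The ground-truth simulator treats the colony as a thin, linearly elastic,
uniformly contractile sheet (thickness $h$, Young modulus $E_c$, Poisson
ratio $\nu_c$, plane stress) coupled to the substrate through an elastic
foundation. With displacement field $u(x)$ on the colony footprint
$\Omega$, mechanical equilibrium reads

$$ h \,\nabla\cdot\big(\sigma_{el}(u) + \sigma_A(E_s(x))\, I\big) = Y(x)\,u,
   \qquad \big(\sigma_{el} + \sigma_A I\big)\cdot n = 0 \ \text{on}\
   \partial\Omega , $$

where $Y(x) = E_s(x)/L_s$ is the foundation stiffness density obtained from
the local substrate Young modulus $E_s$ and an effective coupling depth
$L_s$, and the traction transmitted to the substrate is $T = Y u$ (stored
in the cell-on-substrate convention: contraction gives inward-pointing
vectors). The active stress follows a saturating law of the local
substrate stiffness,

$$ \sigma_A(E_s) = \sigma_{max}\, \frac{E_s}{E_{half} + E_s}, $$

which encodes mechanotransduction: cells pull harder on stiffer substrates,
up to a ceiling. The model has a single emergent length, the localization
length $\ell = \sqrt{h E_c / (Y (1 - \nu_c^2))}$: traction is concentrated
in a boundary layer of width $\sim\ell$ at the colony edge and decays
exponentially toward the interior. For an infinite strip of half-width $w$
the transverse profile is available in closed form,
$T_x = (\sigma_A h/\ell)\sinh(x/\ell)/\cosh(w/\ell)$, which serves as the
solver's analytic oracle (`strip_closed_form()`).

Defaults (`mechanics_params()`): $h = 5\ \mu m$, $E_c = 10$ kPa,
$\nu_c = 0.45$, $L_s = 50\ \mu m$, $\sigma_{max} = 2$ kPa,
$E_{half} = 15$ kPa. Over substrate stiffnesses of 5–40 kPa these give
$\ell \approx 9{-}25\ \mu m$, i.e. boundary layers of a few cell lengths,
and peak tractions of order $10^2$ Pa — the ranges reported for epithelial
monolayers.

**Discretization.** The equilibrium problem is discretized with bilinear
quadrilateral finite elements on the pixel grid itself (one element per
foreground pixel), assembled from the underlying energy functional. This
has two consequences worth the choice: the traction-free edge is the
*natural* boundary condition, so no ghost-cell approximation is needed on
jagged rasterized boundaries, and the discrete net force
$\sum_\Omega T$ vanishes *identically* (to solver round-off, $\sim10^{-15}$
relative), not merely to truncation order. The sparse symmetric
positive-definite system is solved by Cholesky factorization with one step
of iterative refinement, which makes 90°-rotated inputs reproduce rotated
outputs to better than $10^{-8}$ Pa.

```{r strip}
p <- mechanics_params()
ell <- localization_length(5000, p)
g <- cell_geometry({
  ind <- matrix(0, 128, 128); ind[57:72, 3:126] <- 1; ind
}, pixel_size = ell / 10)
s <- make_stiffness_field("uniform", 128, ell / 10, e0 = 5000)
tf <- solve_traction(g, s, p)
force_balance_residual(tf)
```

**What the surrogate does and does not capture.** The simulator reproduces
the monolayer phenomenology that drives the learning problem: exponential
edge localization, stiffness-dependent traction amplitude, stiff-side
localization under stiffness gradients, and exact force balance. It is
still a single-field elastic surrogate: adhesion-molecule transport, edge
and interfacial energies, and stress-fiber anisotropy are not modelled.
One visible consequence is that the association between boundary traction
magnitude and local convex curvature — strong in chemomechanical models
with explicit edge energetics — is present here only as a weak positive
trend (pooled rank correlation $\approx +0.1$ across random colonies),
because lobe tips acquire large tractions chiefly through their distance
from the colony's elastic center. Passing tests therefore validate the
translation machinery on this family of fields, not the full biology of
real monolayers.

## Random colony geometries

Training needs broad coverage of 2-D colony shapes. A boundary is drawn in
polar form from the four-entry descriptor $d = (n_s, \bar R, r_s,
\sigma_s)$: a truncated Fourier series with $n_s$ modes and uniform random
coefficients, rescaled to unit maximum amplitude, applied as a relative
radial fluctuation $r_s$, circularly Gaussian-smoothed over $\sigma_s$
angular samples, and finally rescaled so the enclosed area is exactly
$\pi \bar R^2$. The construction is single-valued in the polar angle, so
every curve is simple; the exact-circle limits ($n_s = 0$ or $r_s = 0$;
$\sigma_s \to \infty$) are test anchors. Default sampling ranges:
$n_s \in [2, 8]$, $\bar R \in [40, 190]\ \mu m$, $r_s \in [0, 0.35]$,
$\sigma_s \in [1, 8]$ samples, with $K = 512$ angular samples for
sub-pixel boundary resolution at the default grids.

Rasterization marks a pixel foreground iff its center lies inside the
curve (for star-shaped curves the even-odd rule reduces to a radius
comparison at the pixel's polar angle); no anti-aliasing, because the
network consumes a strictly binary indicator. The per-sample pixel size is
chosen so the colony diameter fills 80% of the field of view
("fixed-fraction framing"), making 40–190 µm colonies representable at any
grid size; the physical scale is restored to the network through a
conditioning channel (below).

```{r geometry, fig.alt = "random colony indicator"}
geo <- random_cell_geometry(seed = 7, n = 128)
autoplot(geo$geometry)
```

## Corpus, encoding, augmentation

`build_corpus()` draws independent sub-seeded samples, solves each, and
records a manifest (descriptor, stiffness mode, footprint mean stiffness
$\bar E_s$, contractility, traction percentiles). Traction tensors are
normalized by the corpus-wide 99.5th percentile of pixel magnitude —
percentile rather than maximum for robustness to rare solver edge spikes —
and clipped to $[-1, 1]$ with the clipped fraction reported.

The network input is an $n\times n\times 3$ stack with a fixed channel
order: the binary indicator, the min–max normalized stiffness map
$E_s(x)$, and a constant channel carrying the normalized mean radius.
Scalars are broadcast as constant channels rather than injected at the
bottleneck so the generator stays fully convolutional and spatially
varying and uniform substrates are handled identically; the radius channel
restores the physical scale that fixed-fraction framing removes, and the
contractility is implicit in the stiffness channel through the
contractility law.

Augmentation is restricted to the dihedral-4 group (quarter-turn rotations
and axis flips): these are *exact* for binary masks and square-grid vector
fields — components permute and negate with the spatial map, so force
balance and the zero-outside-footprint invariant survive bitwise.
Arbitrary-angle rotation is refused rather than approximated. Splits are
drawn per *base* sample, so augmented variants never straddle
train/validation/test.

## The adversarial translator

The generator is a U-Net: 3×3 convolution + ReLU blocks, 2×2 max-pooling
on the way down, 2×2 up-convolutions on the way up, resolution-matched
skip connections, and a linear 1×1 output convolution to the two traction
channels. The discriminator is a stack of stride-2 convolutions ending in
a per-patch fully connected stage (a 1×1 convolution) and sigmoid — an
$m\times m$ reliability matrix of local validity scores with $m = n/16$ at
the default depth. Both adversaries see the conditioning stack
concatenated with the (real or generated) traction map. The objective is
the adversarial cross-entropy

$$ L(D, G) = \mathbb{E}\,[\log D(T)] +
   \mathbb{E}\,[\log(1 - D(G(\Omega, C)))], \qquad
   \max_D \min_G L(D, G), $$

with gradients for both players evaluated at the same parameter point
(simultaneous updates) and an $\varepsilon = 10^{-7}$ clamp inside the
logarithms; the non-saturating generator variant is available behind a
flag. Optimization is ADAM with learning rate $2\times10^{-4}$ and moment
parameters $\beta_1 = 0.6$, $\beta_2 = 0.95$; the full profile trains 200
epochs.

**Reconstruction anchor.** A pure adversarial objective fixes the
distribution of outputs, not their pixelwise agreement with the paired
target, so a conditional regression of this kind needs a reconstruction
anchor: a masked pixelwise L1 term with weight $\lambda_{rec}$ (default
100; 0 recovers the literal cross-entropy-only game). Generator outputs
are masked to the footprint before both the discriminator and the loss,
so the zero-outside-$\Omega$ contract is enforced during training, not
just at prediction time. A variant weighting the L1 by the inverse local
traction magnitude (to mirror the relative evaluation metric) was
evaluated and *rejected*: it slowed learning of the high-traction rim and
raised the held-out relative error.

**Stabilizers.** Three standard image-translation techniques carry most of
the accuracy at desk scale: instance normalization after every convolution
(without it the short-schedule optimization stalls far from the data);
dihedral-4 augmentation of every training batch (exact on the square grid,
an eightfold effective corpus); and an exponential moving average of the
generator weights (decay 0.998 with a ramp-in so short runs are not
anchored to the initialization), which is what prediction uses. At
prediction time the output is additionally averaged over the dihedral-4
orbit of the inputs (`symmetrize = TRUE`), which removes orientation noise
exactly on the square grid.

**Profiles.** The smoke profile used by the package's own evaluations is a
depth-4 U-Net with 8 base channels at $n = 64$ and a depth-4,
4-base-channel patch discriminator, trained ~40 epochs on 300 simulated
maps with batch size 8 — sizes chosen so a full three-seed evaluation is a
desk-scale computation. Wider and deeper profiles are a `generator_spec()`
call away; nothing in the code is specific to the smoke sizes.

**Evaluation.** The error statistic is the average pixelwise relative
error: per pixel the vector-magnitude ratio
$|T^p - T^t| / |T^t|$, averaged over pixels whose true magnitude exceeds
$\tau = 0.05$ of the per-sample maximum, then over samples. The mask is a
policy decision forced by the mathematics — the pointwise ratio is
undefined wherever $T^t = 0$, i.e. everywhere outside the colony — and is
recorded in every report. Magnitude ratios (not componentwise ratios) are
used because the componentwise form is undefined on the zero crossings of
either component inside the colony.

## The inverse network

Task II reverses the map: from (indicator, normalized traction) recover
the hidden substrate. The same U-Net body emits the normalized stiffness
field; a global-average-pooled linear head on the bottleneck emits the
scalar contractility. Supervision is pixelwise squared error on the
stiffness map *inside the footprint only* — traction carries no stiffness
information elsewhere — plus squared error on the contractility scalar,
with the forward model's optimizer settings, augmentation, weight
averaging and symmetrized prediction. Recovery is hardest at the stiff end
of the range, where the contractility law saturates and the traction
amplitude carries little stiffness information; the shipped 40-epoch
scaled-down training is the point where the stiffness regression clears
a 0.9 correlation on held-out simulated maps (30 epochs sit at 0.88). Recovered stiffness is
reported as missing outside the footprint; an identically zero traction
input triggers an out-of-distribution warning instead of a crash.

Sweeping fresh simulated colonies across uniform stiffness levels and
aggregating the recovered $(\bar E_s, \sigma_A)$ pairs
(`recover_contractility_curve()`) reproduces the saturating
contractility–stiffness relation the simulator was built with — the
"hidden relationship" that is experimentally inaccessible but fully known
here, which is what makes the synthetic recovery a meaningful test.

## Durotaxis analysis

On a substrate with a stiffness gradient the traction pattern loses left–
right symmetry: the stiff side both couples more strongly ($Y$ larger,
$\ell$ shorter) and pulls harder ($\sigma_A$ larger). The analysis module
quantifies this with $\Delta T = T_G - T_0$ (gradient vs uniform substrate
at the matched mean stiffness) and the asymmetry
$A = (S^+ - S^-) / (S^+ + S^-)$, where $S^\pm$ sum $|T_G|$ over the
footprint halves on either side of the footprint *centroid* (not the image
center — colonies are not centered in general), split perpendicular to the
gradient. $A$ is antisymmetric under gradient reversal and, in the
simulator, increases with both gradient strength and colony size — the
collective-durotaxis signature: a bigger colony spans a larger stiffness
difference, so it senses a gradient an isolated cell cannot.

```{r durotaxis, eval = FALSE}
sw <- durotaxis_sweep(gradients = c(25, 50, 100), radii = c(50, 80, 120),
                      n_reps = 6, n = 64, seed = 31)
autoplot(sw)
```

## Numerical choices and degenerate inputs

* Rejection–resampling with deterministic sub-seeds wherever a random draw
  can be invalid (negative radius, multi-component rasterization), with a
  cap of 100 retries and a descriptive error beyond it.
* The solver refuses empty footprints and mismatched grids; zero
  contractility short-circuits to the exact zero field.
* All network arithmetic runs in single precision through the compiled
  im2col kernels (one BLAS `sgemm` per layer per direction); parameters
  and accumulators stay in double precision. Training is deterministic
  given the seed and BLAS; checkpoints reload to bitwise-equal weights.
* Ties in the 2×2 max-pool resolve to the first maximum in column-major
  order, fixed by the compiled kernel.
* `epsilon_t()` errors on an empty mask rather than returning 0: an empty
  mask means the truth field is degenerate and the statistic undefined.

## Problem sizes used by the shipped evaluations

The package's own evaluations (test suite and the acceptance script) run
the forward problem at $n = 64$ with 300 training and 50 held-out
simulated maps, three training seeds at ~40 epochs, and the inverse
problem at the same corpus scale (40 epochs) with mixed
uniform/linear/circular stiffness patterns over 5–40 kPa. These sizes were
chosen as the smallest at which the size- and stiffness-trends of the
error statistic are resolved; the corpus builder streams per-sample writes, so corpora of the
$7\,000$-profile scale used for full training are a `count` argument, not
a code change.

## Known limitations

* At desk scale the held-out relative error is driven primarily by the
  per-sample traction amplitude: small colonies ($\bar R \lesssim 2\ell$,
  no saturated boundary plateau) and soft substrates (low $\sigma_A$ and
  long $\ell$) produce weak tractions, and a relative metric amplifies a
  given absolute network error there. As a result the error is U-shaped in
  colony size (the resolution-loss increase appears only in the upper half
  of the size range) and visibly higher on the softest substrates, rather
  than flat.
* The simulator is a surrogate: no adhesion kinetics, no edge energies, no
  anisotropic stress fibers; its curvature–traction coupling is weak (see
  above). Conclusions about real monolayers require retraining on
  experimental maps, for which the corpus format has an `experimental`
  provenance slot but no bundled data.
* The cell-type extrapolation is a single multiplicative contractility
  scale (`scale_to_cell_type()`); it cannot capture cell types whose
  traction *patterns*, not just amplitudes, differ.
* Networks are resolution-locked: predictions at a grid size other than
  the trained one are refused rather than resampled.
* The inverse network recovers stiffness only where traction carries
  information (inside the footprint); outside values are reported missing
  by design.
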