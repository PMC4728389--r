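# geldiff

Modelling the in vivo fate of an autofluorescent hydrogel depot from
fluorescence images: degradation-driven fluorophore release, Fickian spread
through tissue, and estimation of the apparent diffusivity.

## The problem

A glutaraldehyde cross-linked albumin hydrogel injected subcutaneously is
intrinsically fluorescent, so whole-animal imaging can follow its
degradation non-invasively: the fluorescent spot first brightens as the gel
degrades and releases fluorophores, then fades and broadens as they diffuse
away and clear. `geldiff` is for researchers who want to turn such image
series into physics: it implements the release–diffusion model linking
radiant intensity to fluorophore concentration, solves it analytically,
cross-checks the solution with an independent finite-difference oracle,
generates synthetic image stacks with the study's statistical structure,
extracts radial intensity time series by azimuthal averaging, and fits the
one empirical parameter of the model — the apparent diffusivity *D* — by
bounded nonlinear least squares with bootstrap uncertainty.

## The model

Scaled intensity is treated as fluorophore concentration *c*(*r*, *t*)
(dimensionless, lengths in mm, times in day):

```
∂c/∂t = D (1/r) ∂/∂r (r ∂c/∂r) + S(r, t)
S(r, t) = A · w(t + T; k, λ) · H(R − r)
c(r, 0) = c0 + c1 · exp(−a r^α)
```

where *w* is the Weibull probability density (shape *k*, scale *λ*) — the
growth-then-attenuation of release from the degrading gel — *H*(*R* − *r*)
confines release to the gel disk of radius *R*, *T* aligns the release
onset with the first image, and the initial profile is a stretched
exponential over a constant background *c₀*. The solution is obtained by
the order-zero Hankel transform,

```
c(r,t) = c0 + ∫₀^∞ β J₀(βr) [ û₀(β) e^(−Dβ²t)
         + A (R J₁(βR)/β) ∫₀^t w(τ+T) e^(−Dβ²(t−τ)) dτ ] dβ ,
```

and verified against a conservative Crank–Nicolson solver with mass-balance
audits. Reference parameters (shipped in `inst/extdata/params.toml`):
*A* = 500, *k* = 1.5, *λ* = 10 d, *T* = 1.5 d, *R* = 0.42 mm,
*c*(*r*, 0) = 0.1 + 0.8 exp(−0.16 *r*^1.5), *D* = 4.32 mm²/day — about 5%
of a small molecule's diffusivity in water.

## Worked example

```r
library(geldiff)
p <- gel_params()

# concentration at the innermost reference radius, 10 days post-injection
solve_concentration(2.475, 10, p$source, p$initial, p$transport)
#> [1] 1.012597

# simulate noisy intensity curves at the five reference radii and refit D
obs <- simulate_observations(p$source, p$initial, p$transport,
                             reference_radii(), times = 0:60,
                             noise_rel = 0.05, seed = 11)
fit_diffusivity(obs, p$source, p$initial, init_D = 8.64)
#> Diffusivity fit
#>   D = 4.32386
#>   residual norm = 0.103903, converged = TRUE (9 iterations)
```

The first number says the model intensity at 2.475 mm exceeds the 0.9
centre value of the initial profile at day 10 — released fluorophores
transiently accumulate near the depot before diffusion wins. The fit
recovers the generating diffusivity (4.32 mm²/day) to within 0.1% from a
doubled starting value despite 5% multiplicative noise.

The end-to-end analysis lives in `analysis/`:

| script | what it does |
|---|---|
| `01_forward_model.R` | model curves at the reference radii (analytic and finite-difference); peak-time table of the outward diffusive wave (8 → 10 → 13 → 15 → 19 d across 2.475 → 11.17 mm) |
| `02_validate_solver.R` | inversion identity, 1% oracle equivalence, 0.5% mass balance, peak ordering → `results/validation/validation.json` |
| `03_synthetic_imaging.R` | synthetic 31-frame fluorescence stack (128 px, 0.2 mm/px, 5% noise) → TIFF + sidecar, then azimuthal extraction → CSV |
| `04_fit_diffusivity.R` | fits D to the extracted series (with 90% bootstrap CI) and runs the 50-replicate recovery study (bias 0.03%, RMSE 0.9% at 5% noise) |

Run them in order from the repository root after installing; outputs land
under `results/`.

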