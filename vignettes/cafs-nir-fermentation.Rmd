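---
title: "Wavelength selection for NIR fermentation monitoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength selection for NIR fermentation monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Coffee fermentation degrades the sugar-rich mucilage around the bean;
the accumulating acids push pH down from about 5.6 towards 4.6 and
sugar consumption pulls total soluble solids (TSS) down by a few °Brix.
Both quantities indicate when fermentation should stop, and both leave
signatures in the near-infrared spectrum (overtones of O–H and C–H
bonds: water/acid features near 1451 and 1927 nm, carbohydrate and
lipid features near 1205, 1729 and 1839 nm). A full spectrum at 2 nm
resolution over 1100–2100 nm is 501 collinear variables; portable,
low-cost monitoring hardware wants a model on a few dozen. `cafspec`
implements the pipeline from raw reflectance to such reduced models and
the machinery to compare selection strategies fairly.

# Models and procedures

## Preprocessing

Reflectance is converted to absorbance, *A*(λ) = log₁₀(1/*R*(λ)),
because absorbance is approximately linear in analyte concentration
(Beer–Lambert). Savitzky–Golay smoothing then fits a degree-*q*
polynomial over a sliding window of 2*m* + 1 points by least squares;
the fitted centre value is a fixed convolution whose coefficients come
from the pseudoinverse of the local Vandermonde design and sum to 1.
Edges are mirror-padded so the output length equals the input length
and wavelength indices stay aligned through the whole pipeline; the
alternative (truncation) would silently desynchronize selections.

Two readings of the conventional "second order, three-point" smoothing
setting exist, and they differ materially: with *q* = 2 and a 3-point
window the quadratic interpolates its three points exactly, so the
filter is the identity. We default to `poly_order = 2, window = 3`
(the literal reading, a no-op) and expose both parameters; analyses
here that want real smoothing use `window = 7`. Both readings are
runnable; nothing downstream assumes either.

## PLSR

Single-response partial least squares regression is fit by NIPALS.
With one response the weight vector of each component is closed-form,
`w = X'y / ||X'y||`, so the decomposition involves no iteration and no
random initialization: fits are deterministic to the last bit.
Per component we record the unit-norm weights, scores, X-loadings,
y-loading `q_a`, and the response sum of squares explained,
`SS_a = q_a² t_a't_a`. Coefficients on the original predictors come
from `B = W (P'W)⁻¹ q`, and the stored coefficient path gives
predictions at any component count without refitting.

Centering only (no autoscaling) is the default: absorbance channels
share units, and unit-variance scaling would inflate flat noise
regions. The component count is either fixed by the user or chosen per
training fold by inner cross-validation over 1..15
(`choose_ncomp()`), so held-out folds never influence the choice.

Variable importance in projection is
`v_j = sqrt(p · Σ_a SS_a (w_aj/||w_a||)² / Σ_a SS_a)`, with the
algebraic identity `Σ_j v_j² = p`; the conventional cutoff `v_j > 1`
(strict) defines the VIP selection. An empty VIP selection raises a
typed condition instead of silently falling back to all variables.

## Covering-array feature selection

A covering array CA(*N*; *t*, *k*, *v*) is an *N* × *k* matrix over
*v* symbols in which every choice of *t* columns exhibits all *v*ᵗ
symbol tuples in at least one row. The package builds them with a
seeded one-row-at-a-time greedy: each appended row is the best of a
candidate batch (random rows plus, for *v* = 2, the complement of the
previous row) by number of newly covered tuples, after seeding with
the constant rows. Tuple bookkeeping is explicit enumeration, so
strength is limited to *t* ≤ 3 — all that feature screening needs.
Verification is exhaustive and returns a concrete witness on failure.

CAFS uses a binary CA as a screening design over spectral bands:

1. split the *p* wavelengths into *k* contiguous bands (NIR features
   span adjacent wavelengths, so bands are the natural unit);
2. build CA(*N*; *t*, *k*, 2); row symbol 1 = "band included";
3. fit PLSR per row on the included wavelengths and record K-fold
   cross-validated RMSE (one shared fold assignment across rows);
4. score each band by mean RMSE of excluding rows minus mean RMSE of
   including rows (a main-effects estimate, reported per wavelength
   and usable against a permutation null);
5. retain the bands of the best (lowest-RMSE) row, refit PLSR on them
   with a deliberately small component count, rank the member
   wavelengths by |β| and keep the top `n_final`.

Two choices in step 5 deserve their rationale, because the obvious
alternatives fail in a way that is easy to reproduce with the synthetic
benchmark. First, retention by *positive band score* breaks down when a
chemical feature spans several contiguous bands: almost every CA row
then contains a redundant copy of the feature, single-band main
effects shrink into the CV noise, and the retained set becomes
essentially random (on replicate benchmarks, half the runs retained no
informative band). Whole-subset performance — the best row — still
separates cleanly, so retention goes through it; the scores are kept
as diagnostics. Second, the ranking refit uses `refit_ncomp = 2` by
default: fermentation progress drives one or two latent factors, and
|β| from a low-rank fit concentrates on them, whereas β from a
high-rank fit acquires noise components that can out-rank genuine
signal wavelengths. Both are exposed as parameters.

Defaults: *t* = 2, *k* = 50 bands for 501 wavelengths,
`n_final = 30` (the middle of the 22–47 cardinality range typical of
covering-array selections in this application), screening fits with 10
components and 3 folds. The whole procedure is deterministic given its
seed, and the returned object records the CA dimensions, the best row,
per-row RMSE and per-band scores.

## Evaluation protocol

`run_repeated_kfold()` runs *K* = 5 folds × 30 repetitions by default.
Fold assignment for repetition *r* derives from `base_seed + r − 1`
and is stored, making every report reproducible bit-for-bit. Metrics
on each held-out fold: RMSE; R² = 1 − SSE/SST with the standard
denominator Σ(yᵢ − ȳ)² — the variant normalizing by Σ(ŷᵢ − ȳ)² is
selectable (`r2_method = "predicted-mean"`) for audit, since it
appears in print occasionally but can exceed 1 and contradicts
RPD/R² consistency; and RPD = SD/RMSE with SD taken as the population
(n-divisor) standard deviation of the *full* response vector, so RPD
is comparable across folds. Aggregation is the mean over all
rep × fold cells (the mean-of-folds convention; pooled-prediction
aggregation is a documented alternative we do not use). Degenerate
folds (a single sample, or constant response) report RMSE/RPD with R²
as NA rather than failing, which keeps the leave-one-out limit
runnable. Selection, when part of a recipe, is re-run inside every
training fold — the held-out fold never touches it.

The Kolmogorov–Smirnov statistic is computed exactly on order
statistics: D⁺ = maxᵢ(i/n − Zᵢ), D⁻ = maxᵢ(Zᵢ − (i−1)/n),
D = max(D⁺, D⁻), with Zᵢ the normal CDF at the i-th order statistic.
Parameters default to the maximum-likelihood fit (sample mean,
population SD) of the tested vector — making D invariant under affine
transforms — or can be fixed. For n = 1 with fitted parameters the
convention Z = 0.5 applies. Lilliefors-corrected p-values are out of
scope (they need the raw laboratory data to be meaningful here).

# The synthetic generator

Laboratory fermentation spectra for this problem are not publicly
deposited, so the package carries a generator that emulates the
*structure* the analysis assumes, with planted ground truth:

- **Design**: 3 varieties × 7 times (0–24 h) × 2 subsamples × 50
  profiles = 2100 rows by default.
- **Trajectories**: normalized exponential decay
  `end + (start − end)·(e^{−rt} − e^{−rT})/(1 − e^{−rT})`, which hits
  the configured endpoints exactly at t = 0 and t = T and collapses to
  a step as r → ∞. pH runs 5.60→4.77, 5.43→4.60, 5.57→4.67 per
  variety; TSS starts at 15.87, 15.13, 16.53 °Brix. Decay rates
  (0.22/h for pH, 0.18/h for TSS) put stabilization at 16–20 h,
  matching the observed plateau. TSS drops by 3 °Brix by default — a
  magnitude consistent with response SDs of about 1 °Brix reported for
  fermenting coffee; like the rates, it is a generator choice, not a
  measured value.
- **Spectra**: absorbance = sloping baseline + per-profile drift
  offset + Gaussian bands at 1205, 1451, 1729, 1839, 1927 nm + white
  noise; reflectance = 10^(−A), exercising the conversion in its
  intended direction. Band amplitudes respond linearly to the
  profile's true pH (water/acid bands 1451, 1927) or TSS
  (carbohydrate bands 1205, 1729); 1839 nm is deliberately uncoupled.
  Ground truth (`make_benchmark()$truth`) is the set of wavelength
  indices within two band widths of each coupled centre.
- **Noise model**: profile-level biological jitter enters both the
  response and the spectrum; *measurement* noise (pH 0.06, TSS 0.22,
  realistic meter/refractometer repeatability) enters only the
  recorded reference value and therefore bounds attainable accuracy.
  The measurement SDs were set so the full-spectrum model attains
  cross-validated R² ≈ 0.95 at defaults (measured 0.947), the intended
  operating point of the stated world.

What a green test does establish: the pipeline recovers planted
informative regions, selection beats chance decisively, the protocol
is leak-free and reproducible. What it does not: agreement with any
particular laboratory dataset — real spectra have scatter effects,
variety-specific chemistry beyond five bands, and nonlinear
TSS–spectrum relationships (reported for fermenting matrices) that a
linear band-coupling generator does not emulate. pH and TSS are also
strongly correlated here (both track fermentation progress, r ≈ 0.86
across the default benchmark), so bands coupled to either response are
genuinely informative for both; recovery is therefore assessed against
the union of coupled-band supports.

# Numerical choices and degenerate inputs

- NIPALS stops with an explicit error if `X'y` vanishes before the
  requested component count (effective rank exhausted); the rank bound
  `A ≤ min(n − 1, p)` is enforced up front.
- Ties in |β| rankings break to the lower wavelength index;
  `which.min` ties in the CAFS best row break to the first row — both
  make selections deterministic.
- SG smoothing of reflectance clamps values that exceed 1 after
  convolution; the absorbance path is unaffected.
- Reflectance outside (0, 1] during simulation is clipped with a
  counting warning (defaults never trigger it).
- All randomness is scoped: package functions seed a local RNG and
  restore the caller's state, so seeds recorded in results are
  sufficient to reproduce them and independent computations cannot
  interfere.
- Covering-array tuple bookkeeping is dense enumeration — fine for
  t ≤ 3, k ≤ 60; larger strengths are rejected rather than silently
  slow.

# Limitations

- PLSR is linear; the generator's band-amplitude couplings are linear
  too. Nonlinear response–spectrum relationships (as reported for TSS
  in fermenting products) need kernel or local models outside this
  package's scope.
- The CAFS reconstruction here is one defensible reading of
  "covering-array screening over spectral bands"; its retention and
  ranking rules are versioned parameters precisely so alternative
  readings can be swapped in and compared under the same protocol.
- The greedy CA constructor gives small-but-not-minimal arrays; optimal
  construction, mixed alphabets and post-optimization are out of scope.
- Aggregated CV metrics are means over folds; with 5 × 30 = 150 cells
  the difference from pooled aggregation is negligible for the sample
  sizes used here, but the convention matters for tiny datasets.
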