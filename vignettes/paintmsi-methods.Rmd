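---
title: "Methods: decoding paint stratigraphy from MALDI-MSI data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding paint stratigraphy from MALDI-MSI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and design choices behind
`paintmsi`. It states no empirical result beyond what the package's test
suite and acceptance script themselves compute.

## The problem

A paint cross section is a stack of micrometre-thin layers, each a binder
(the film-forming medium: animal glue, casein, egg tempera, linseed oil)
mixed with pigments (lead white, earth pigments, ultramarine, synthetic
organics). MALDI-MSI of such a section yields one mass spectrum per pixel
(~5 µm pitch, m/z 60–900, Orbitrap-class accuracy). Two analysis routes are
supported, and they complement each other:

1. **Identification chemistry** — exact-mass annotation, isotopic
   patterns, and Kendrick mass defect analysis answer *which molecular
   species* are present.
2. **Supervised composition prediction** — a sparse classifier trained on
   sections of known stratigraphy answers *which binder and pigment class*
   each pixel belongs to, including layers that are optically
   indistinguishable.

## Preprocessing model

**Peak picking.** Local maxima of the per-pixel intensity sequence are
scored by topographic prominence (height above the higher of the two
saddles that connect the peak to taller signal); maxima with prominence
below `min_prominence` (default **500** counts, the operating point for
Orbitrap paint data) are discarded, and retained maxima closer than
`ppm_window` (default **10 ppm**, measured against the larger m/z) are
merged keeping the most intense. The "step size" of the merge is
interpreted as a minimum peak separation: it prevents split centroids while
matching the local-maxima/prominence picker the workflow is built on. The
prominence kernel is compiled (Rcpp); the test suite checks it against an
independent brute-force scanner on 100 random spectra.

**Alignment.** Peaks from all sections being analysed together are binned
on a logarithmic m/z axis with constant relative width `bin_ppm` (default
**10 ppm**), anchored at the global minimum observed m/z. Fixed-grid
binning makes alignment order-invariant and O(n); its known artefact — two
peaks < 10 ppm apart can straddle a bin boundary — is immaterial here
because peak picking already merged sub-window structure per spectrum. A
bin's representative m/z is the intensity-weighted mean of its members,
which stabilises downstream ppm annotation.

**Normalization.** Rows (pixels) are divided by their total ion count;
all-zero pixels are left untouched and reported. Columns (ion images) are
then min–max scaled to [0, 1] — *per ion image, not per spectrum* — so that
LASSO coefficients are comparable across ions and the shrinkage parameter
transfers across datasets. Constant columns map to 0. The order
(normalise, then scale, after alignment) is a documented choice; the
workflow description does not fix it.

## Annotation chemistry

Masses are computed from an embedded IUPAC/CODATA isotope table (27
elements relevant to artist materials). All ions are singly charged
positive species; one electron mass (0.000548580 Da) is subtracted. Under
this convention the six reference ions used as acceptance targets are
reproduced within 0.5 mDa of their printed values, which absorbs the
printed rounding.

Isotopic patterns are computed by convolving elemental isotope
distributions (binary exponentiation per element), aggregating
isotopologues on a 0.5 mDa lattice with abundance-weighted mean masses,
pruning below 10⁻¹⁰, truncating to `top_n` and renormalising to base peak
1. At 0.5 mDa aggregation, fine structure is *resolved*, not summed: the
+2 isotopologue of copper phthalocyanine is the pure ⁶⁵Cu species (the
¹³C₂ cell sits ~8.5 mDa higher), and the fourth isotopologue of the iron
hydroxide-hydrate cluster is the ¹⁸O species, not ⁵⁸Fe. Tests encode these
facts deliberately.

Observed-vs-theoretical agreement is scored by cosine similarity after
greedy nearest-match assignment within a ppm tolerance; unmatched
theoretical peaks contribute zero. Database matching uses **5 ppm** by
default (70k resolving power); every record/adduct within tolerance of a
bin is reported, and bins hit by more than one record are flagged
ambiguous (isobars). Database entries whose printed m/z has no published
formula assignment (ferric oxide 106.943, lead oxide 262.935, PBr23,
PR5, PY64, PY101) are stored as observed-m/z entries and excluded from
formula-based tests.

## Kendrick mass defect analysis

With base unit mass `b` (default CH₂; FeOOH and H₂O are packaged),
`KM = mz · round(b)/b` and `KMD = round(KM) − KM`. Round-to-nearest (not
ceiling) is used so defects are symmetric about zero for metal species
below integer mass; the upstream description does not fix a formula, so
this definition is documented and tested on its own terms. Referenced KMD
divides the KMD offset from a reference point (default: the most intense
peak) by the KMD spacing of one heavy→light isotope substitution, so
isotopologue branches fall on near-integer levels — the "fork" signature
of iron pigments.

`detect_fork()` treats each peak as a candidate principal-isotope species,
requires every isotope with relative abundance ≥ 5% of the principal to be
found within the m/z tolerance, requires found members' intensity ratios
to match natural abundance within `abundance_tol` (default 0.2, absolute
on the principal-normalised scale), and scores the cluster by cosine. The
abundance gate is what rejects coincidental mass matches (e.g. a ⁵⁴Fe
satellite reinterpreted as a principal). `detect_series()` chains peaks
whose consecutive differences equal one unit mass within tolerance
(default 5 ppm); water-loss ladders are the same chains read downward.

## Registration and masks

Manual co-registration is replaced by a reproducible surrogate: the user
supplies corresponding landmark pairs and a similarity transform (uniform
scale, rotation, translation; reflections excluded) is estimated in closed
form (Procrustes/Umeyama). Nearest-neighbour resampling keeps masks
binary; pixels mapping outside the optical image receive a sentinel colour
(magenta) that downstream defines the off-sample **Matrix** class, which
is trained like any other class.

Colour thresholding assigns a pixel to a class when every channel is
within the class tolerance of its colour centre; colour boxes of different
labels may not overlap *within* one problem (binder or pigment), while a
binder and a pigment legitimately share a layer's colour. Optical masks
are then refined by ordinary least squares of the 0/1 mask on all ion
images (one Cholesky factorisation shared across a section's masks, with a
vanishing ridge as numerical guard): fitted values are thresholded at
**0.5**, and refinement may only *remove* pixels. The threshold is a
package choice (none is published); the shrink-only rule prevents
regression artefacts from leaking labels into neighbouring layers, and it
is what drops void pixels that the optical mask overhangs. Balanced
training sets draw `min(n_per_class, class size)` pixels per class without
replacement; the default `n_per_class = 1000` is a desk-scale choice, not
a published value.

## The composition classifier

Per class *k*, with the scaled feature matrix X and the 0/1 indicator y of
the class's sampled pixels, the model solves

    (1/2n) ‖y − b0 − X b‖² + μ ‖b‖₁

(glmnet, `standardize = FALSE`; the explicit 1/2n scaling makes μ
transferable across sample sizes). Choices that were genuinely open, and
how they were resolved:

* **One-vs-rest, two independent models.** Binders (plus Matrix) and
  pigments (plus Matrix) are separate problems sharing one feature matrix:
  a paint pixel has both a binder and a pigment label, so a single
  multiclass model is not well-posed over the union.
* **μ selection.** For each grid value (the canonical ten-value grid is
  the default) a single non-bootstrapped model is trained on the training
  samples and scored by pooled MSE between predicted score images and the
  0/1 validation masks; minimum wins, ties toward the larger (sparser) μ.
  Bootstrapping enters only the final model, which is refit on training
  *plus* validation samples.
* **Bootstrap averaging.** 10 class-balanced resamples with replacement;
  coefficient vectors and intercepts averaged elementwise. Averaging over
  resamples stabilises which of several correlated ion images carries the
  weight.
* **Score model.** One full-covariance Gaussian per class, fit to the
  score vectors of the class's true pixels per *training* section, then
  averaged parameter-wise across sections (covariances regularised by
  +10⁻⁶ on the diagonal). A single component per class suffices because
  scores live in class-score space, where classes are unimodal by
  construction; "averaging the per-section models" is implemented
  literally as parameter averaging.
* **Gating.** Posteriors follow Bayes' rule under uniform priors
  (balanced sampling removed prevalence information); a pixel below the
  **0.95** maximum-posterior threshold is assigned **Uncertain** and
  excluded from all evaluation counts. Argmax ties break toward the
  earlier class in model order.

Evaluation is one-vs-rest per class over pixels that are labelled in the
ground truth and not Uncertain: sensitivity TP/(TP+FN), specificity
TN/(TN+FP), reported in percent.

Models serialise to JSON with full-precision numbers (a text format that
round-trips exactly; chosen over a binary container so artefacts remain
portable and diffable).

## What the synthetic generator does and does not emulate

`generate_dataset()` builds sections that emulate aged multilayer replica
boards: horizontal layers (one binder + one pigment each), a matrix border
of off-sample pixels, voids (random blobs, default 4% of layer area),
15 signature ions per class drawn once uniformly over m/z 60–900,
lognormal pixel-to-pixel intensity variation (σ_log = 0.3), half-normal
additive noise (σ = 40), and ~200 sparse background ions (presence
probability 0.12, exponential intensities with mean 600 — straddling the
prominence cutoff, as real chemical noise does). Metal pigments carry full
isotopic patterns (top 4 isotopologues) and planted cluster series (FeOOH
additions and water losses for ochre; elemental lead for lead white), with
one multiplicative factor per species so isotope ratios survive noise, as
they do physically. Signature m/z are rejection-sampled so that no two
signatures fall within 50 ppm and none lands one FeOOH/H₂O/Fe-isotope
spacing from another — class markers are distinct by design, and
noiseless fixtures cannot contain coincidental series.

The generator does **not** emulate: realistic peak shapes or mass-error
drift (sticks at exact masses; a 10 ppm aligner is not stressed by
calibration error), matrix-cluster chemistry, cross-linking chemistry
between layers, correlated ion suppression, or optical blur (layer colours
are exact, so colour thresholding is unambiguous unless degraded
deliberately). A green benchmark therefore establishes that the *pipeline
machinery* — preprocessing, supervision extraction, selection, averaging,
gating, evaluation — is correct and stable, not that the classifier would
reach the same figures on instrument data. Conversely the benchmark's
near-ceiling specificity/sensitivity is the expected behaviour of a sparse
model on well-separated synthetic classes, and the acceptance bounds
(binder specificity ≥ 95%, pigment ≥ 90%, sensitivity ≥ 60%) are the
published floors, not targets tuned to the generator.

On recovery accounting: the isotopologues of one metal species are
perfectly collinear ion images, and an L1 penalty provably selects a
subset of a collinear group rather than every member. Planted-signature
recovery (`signature_recovery()`) is therefore counted per ion *species*
(isotopologue group), excluding planted isotopologues whose mean intensity
sits below the prominence cutoff (they are never observable).

## Numerical choices and degenerate inputs

* Intensities are written as 32-bit floats, m/z as 64-bit floats (the
  common imzML dialect); m/z round-trips bit-exactly, TICs to ~10⁻⁷
  relative.
* The `.ibd` UUID is derived from the dataset content, so written
  artefacts are byte-reproducible from config + seed.
* Constant spectra have no local maxima; empty spectra yield empty peak
  lists, not errors. All-zero pixels survive TIC normalisation untouched
  and are reported. Constant ion images scale to 0.
* Degenerate landmark sets (coincident source points) raise; similarity
  fits on noiseless landmarks recover parameters to 10⁻⁹ (tested over 100
  random configurations).
* Posterior computation subtracts the per-pixel maximum log-density before
  exponentiation, so far-from-all-classes pixels underflow to a uniform
  posterior and are gated Uncertain rather than producing NaN.
* All randomness flows through per-call seeds; derived child seeds stay
  below 2³¹.

## Known limitations

* Profile-mode spectra are read but not resampled; peak picking assumes
  the discrete sequence is meaningful (centroided sticks or dense
  profiles).
* Fixed-grid alignment can split peak populations that straddle a bin
  boundary between sections; a clustering aligner would remove the
  artefact at O(n log n) cost.
* `detect_series` chains by nearest successor; it does not branch, so two
  interleaved series sharing a member are reported as one chain plus a
  fragment.
* The classifier is linear in the scaled ion images by design (that is
  what makes the weights interpretable as marker ions); non-linear class
  boundaries are out of scope.
* Registration is landmark-driven; no automatic intensity-based or
  deformable registration.
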