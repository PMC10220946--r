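---
title: "Inter-eye asymmetry analysis for glaucoma screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-eye asymmetry analysis for glaucoma screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculasym)
```

## The problem

Glaucoma damages the optic nerve head (ONH) asymmetrically between a
patient's two eyes long before the late, symmetric stage of the disease.
Two routine imaging modalities see this damage from different angles: a
fundus photograph shows the optic disc and the central cup, whose
difference — the neuroretinal rim — thins as ganglion-cell axons die; a
peripapillary OCT B-scan measures the retinal nerve fiber layer (RNFL)
thickness around the ONH directly. `oculasym` implements a screening
pipeline built on a simple idea: rather than comparing one eye against a
normative database, compare the two eyes of the same patient against each
other, sector by sector, and feed the asymmetry into small, interpretable
cost-sensitive classifiers.

## Sector conventions

The peripapillary circle is divided into temporal (T), temporal-superior
(TS), nasal-superior (NS), nasal (N), nasal-inferior (NI) and
temporal-inferior (TI) sectors; T and N span 90°, the oblique sectors 45°.
A pseudo-sector G is the angle-weighted global mean,

$$ w_G = \tfrac{1}{360}\left(90\,w_T + 45\,w_{TS} + 45\,w_{NS}
          + 90\,w_N + 45\,w_{NI} + 45\,w_{TI}\right). $$

Angles are *anatomic*: 0° temporal, 90° superior. Because temporal/nasal
mirror between eyes, the mapping from anatomic angles to image pixels
depends on laterality: with image x rightward and y downward, temporal is
image-left for a right eye and image-right for a left eye; superior is
image-up for both. This convention is declared explicitly (it is usually
only shown pictorially) and is unit-tested by a mirror-symmetry property:
reflecting the contours horizontally and flipping laterality leaves every
sector value unchanged.

## Fundus geometry

Expert contour annotations are noisy point lists, so both the disc and cup
contours are smoothed with a direct least-squares conic fit constrained to
an ellipse (the Halir–Flusser stabilisation of the Fitzgibbon fit):
closed-form, deterministic, and the standard choice for ONH annotation
smoothing. Rim width at an angle is measured along a ray cast from the
**disc-ellipse center**: (distance to the disc boundary) − (distance to
the cup boundary). Using a single, common ray origin even for an eccentric
cup keeps the radial profile single-valued; negative widths (annotation
noise can put the cup marginally outside the disc) are clipped to zero
with a warning rather than an error. The profile is sampled at 360 angles
(1° steps): well below annotation noise and cheap.

Two scalar summaries accompany the sector profile:

* **CDR** (cup-to-disc ratio). The source literature never states which
  diameter it uses, so this package defaults to the clinical convention of
  *vertical* (superior–inferior) diameters, with a mean-diameter variant
  behind `compute_cdr(..., method = "mean")`.
* **RDR** (rim-to-disc ratio): the minimum rim width over the profile,
  normalized by the disc chord through the center at the same meridian;
  the arg-min angle is reported and ties are broken by the first sampled
  angle (with a 1e-9 numeric tolerance so floating-point jitter cannot
  defeat the rule).

Fundus widths are in pixels, OCT thicknesses in µm. A single cohort-level
factor `f = mean(OCT G) / mean(fundus G)` (`calibrate_scale()`) puts the
two on a common scale; on the clinical data this factor is about 0.64.

The geometry is verified against an independent brute-force oracle (dense
polygonal ellipse boundaries + ray–segment intersection) to 1e-4 relative
error, and the identity "angle-weighted sector mean equals G" holds to
1e-9 by construction of the uniform sampling.

## Asymmetry metrics

For sector value $w$ in right ($r$) and left ($l$) eyes of patient $i$:

| column | definition |
|---|---|
| `delta` | $\delta_{S,i} = w^r_{S,i} - w^l_{S,i}$ |
| `absdelta` | $|\delta_{S,i}|$ |
| `rel` | $\Delta_{S,i} = \delta_{S,i} / (w^r_{S,i} + w^l_{S,i})$ |
| `absrel` | $|\Delta_{S,i}|$ |
| `cohortrel` | $\bar\Delta_{S,i} = \delta_{S,i} / (\bar w^r_S + \bar w^l_S)$ |
| `globalrel` | $\bar{\bar\Delta}_{S,i} = \delta_{S,i} / (w^r_{G,i} + w^l_{G,i})$ |

plus $|\Delta CDR|$ and $|\Delta RDR|$. The signed metrics are zero-mean
and near-Gaussian in both classes but with larger variance under glaucoma;
taking the modulus converts that variance difference into a *mean*
difference (a half-normal has mean $\sigma\sqrt{2/\pi}$), which is why the
absolute metrics separate the classes better as features.

The cohort means in `cohortrel` are computed over **all included patients**
(healthy + glaucoma, suspects excluded) before any train/test split. The
alternative — per-class or per-training-fold means — is not what the metric
definition says; we keep the literal definition and note the mild
information-leakage caveat it implies for cross-validated results.
Zero denominators raise errors naming the metric and sector rather than
propagating NaN.

## ISNT rules

Regrouping TI+NI into I and TS+NS into S (simple means: equal 45° spans),
healthy rims typically order I ≥ S ≥ N ≥ T. `check_rules()` evaluates
ISNT, IST (I ≥ S ≥ T) and IS (I ≥ S) with non-strict comparisons and zero
tolerance by default — the rule is taken literally, so exact ties comply; a
`tol` knob exists for sensitivity analysis. The implication chain
ISNT ⇒ IST ⇒ IS is enforced as a property test over 10,000 random
profiles. Compliance is reported per eye and for both eyes simultaneously,
by diagnosis class.

## Classification protocol

* **Stratified 5-fold CV**, folds drawn deterministically from the spec
  seed and shared across every grid point of a hyperparameter sweep so the
  resulting curves are comparable point by point.
* **Pooled (micro-averaged) confusion matrix**: predictions from the k
  test folds are pooled into a single TP/FN/TN/FP table from which
  sensitivity, specificity, precision and accuracy are computed (glaucoma
  positive). Pooling, rather than fold-averaging, is what makes the
  marginals equal the class counts exactly — an invariant the tests check.
* **Cost sensitivity.** A false negative (missed glaucoma) may be
  penalized by C(FN) ≥ 1 with C(FP) = 1. For trees the cost enters as an
  observation weight on the positive class in the weighted-Gini impurity
  and in the leaf decision (cost-weighted majority, ties to positive); for
  SVMs as a per-class penalty multiplier. These are the standard
  realizations of a 2×2 misclassification cost matrix.
* **Trees** are binary CART grown *best-first*: at each step the frontier
  leaf whose best split gives the largest weighted impurity decrease is
  split. This makes the "maximum number of splits" (MNS) cap a bound on
  the number of internal nodes — the semantics of the tooling the protocol
  was designed around — which a depth cap cannot emulate. Growth is fully
  deterministic; ties are broken by feature order then threshold.
* **SVM**: the kernel is unstated in the source protocol, so the default
  is linear, fitted in the primal with a squared hinge loss by BFGS from a
  zero start (deterministic, no QP solver dependency). Features are
  standardized with training-fold statistics only; trees consume raw
  features (scale-invariant).
* **Feature relevance / MSP.** Averaging the normalized split-gain
  relevance over 1000 trees, each trained on an independent stratified 80%
  subsample (how the "1000 different trees" differ is unstated; resampling
  is the natural reading). `select_msp()` takes the top-k features, ties
  broken by the canonical sector order TS, T, TI, NS, N, NI, G.

Trees and the SVM are implemented in this package: no suitable
cost-sensitive best-first tree (or any SVM) implementation is available in
the target environment, and owning the tree also guarantees the MNS
semantics and determinism that the protocol's sweeps rely on.

## The synthetic cohort: what it emulates, and what it does not

With the clinical dataset unavailable offline, `generate_cohort()` stands
in. Its *stated-world* structure:

* per class, per sector: patient mean = class mean + jitter; the glaucoma
  class mean is the healthy mean × (1 − thinning fraction);
* the inter-eye difference δ is zero-mean Gaussian with a class-specific
  SD (larger in glaucoma); right/left = mean ± δ/2, truncated at a 1 µm
  floor so normalized metrics stay defined;
* per-eye G is the angle-weighted sector mean exactly (so the OCT
  G-consistency check flags nothing on generator output);
* fundus rim-width targets are linear in the OCT thicknesses
  (target = (OCT + noise) × slope, default slope 1/0.6425 px/µm, so
  calibration recovers f ≈ 0.6425).

Defaults are this package's choices, documented as such, not values from
any dataset: healthy sector means (TS 132, T 72, TI 140, NS 103, N 75,
NI 110 µm) follow the normative peripapillary double-hump; thinning
fraction 0.25; σ_healthy = 3 µm and σ_glaucoma = 9 µm; 7 µm
between-patient jitter; 2 µm fundus noise; 300 px disc radius; class sizes
default to 161/47 to mirror the clinical cohort's shape.

**Contour synthesis.** The pipeline smooths every contour with an ellipse
fit, so contour files carrying a sharp per-sector modulation would have
that structure destroyed on extraction. The generator therefore writes
*exact* ellipses: the disc is a circle and the cup an offset, rotated
ellipse whose first-order harmonic expansion (constant + first + second
angular harmonics, 5 degrees of freedom) matches the six sector targets in
least squares, followed by a mean-width correction so the realized G hits
its target almost exactly. Each record stores the *realized*
(ellipse-implied) sector widths; extraction reproduces those to machine
precision, and they track the intended targets to first order. Infeasible
geometries (cup escaping the disc) are regenerated with fresh noise, with
a warning, up to a bounded number of retries.

Consequences a user should understand:

* per-sector fundus widths match their linear-in-OCT targets only in
  least squares (an ellipse pair has ~6 geometric degrees of freedom for 6
  targets but not independently); G matches tightly. This mirrors the
  clinical observation that the fundus–OCT relation is convincingly linear
  in G but loose in individual sectors;
* the synthetic healthy class does **not** reproduce clinical ISNT
  compliance rates (the ellipse-realized rim inherits the RNFL double-hump,
  where N can fall below T). The ISNT module is validated by its own exact
  logic and property tests, not by the generator;
* no age/sex effects, no vessel structure, no annotation-style point
  noise on the contours (measurement noise enters through the sector
  targets instead). A green end-to-end test therefore establishes the
  pipeline's arithmetic and protocol, not clinical performance.

## Numerical choices and degenerate inputs

* Ellipse fitting requires ≥ 5 points; collinear or otherwise degenerate
  configurations raise errors naming the offending contour.
* Rays that miss the cup contribute the full disc radius as rim width;
  rim widths are clipped at 0 with a warning.
* OCT rows outside (0, 300) µm or non-numeric are rejected with per-row
  diagnostics; duplicate (patient, laterality) keys are an error. Missing
  single-sector values are not imputed — the patient is excluded from
  analyses needing that sector, with a logged reason (complete-case
  analysis).
* All randomness flows from explicit integer seeds; every model fit is
  deterministic given data and seed, and re-running a pipeline config
  reproduces its outputs byte-identically (modulo the manifest path).

## Known limitations

Beyond the generator caveats above: the CDR definition (vertical) and the
SVM configuration (linear, squared hinge, unit penalty scale) are
documented defaults where the source protocol is silent; suspects are
excluded rather than modeled; and cross-validated performance numbers on
synthetic cohorts say nothing about performance on clinical data — the
package computes only what its tests and acceptance script themselves
compute.
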