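---
title: "Radiobiological plan evaluation with rtOutcome"
author: "rtOutcome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiobiological plan evaluation with rtOutcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtOutcome)
```

## What the package models

`rtOutcome` evaluates external-beam radiotherapy dose distributions in
radiobiological terms. The motivating clinical question is urethral sparing
in focally dose-escalated prostate radiotherapy: when a simultaneous
integrated boost (SIB) raises the dose on an imaging-defined intraprostatic
target, does carving the urethra (or a urethral planning organ-at-risk
volume, PRV) out of the boost volume reduce the predicted urethral toxicity
without compromising predicted tumour control? The package answers such
questions with three dose-response models, a composite plan score, motion
blurring, and a paired nonparametric comparison across plan variants — and
ships a seeded synthetic phantom cohort so the whole chain is testable
without patient data.

All computations are voxel-based: a `DoseGrid` holds total physical dose
(Gy) on an axis-aligned mm grid (axes ordered left-right,
anterior-posterior, cranio-caudal; voxel-centre convention), and
`StructureMask`s are binary occupancy arrays on the same geometry. Binary
occupancy (no partial-volume weights) was chosen deliberately: structure
volume is voxel count times voxel volume, which makes every downstream
quantity exactly reproducible from the masks.

## Isoeffect conversion

All models operate on isoeffective doses. With total dose $D$ delivered in
$N$ fractions of $d = D/N$, the linear-quadratic conversion to a reference
fraction size $x$ is

$$\mathrm{EQD}x = D\,\frac{1 + d/(\alpha/\beta)}{1 + x/(\alpha/\beta)}.$$

`voxelEQD()` applies this per voxel with the voxel's own $d_i = D_i/N$. The
tumour model uses $x = 0$ (the biologically effective dose limit); the
normal-tissue models use EQD2, matching how their published parameters were
derived. A single fraction count is carried per grid; a compound schedule
delivered as one summed plan is treated with the union fraction number (20
by default), since only total-dose matrices are available after planning.

```{r}
eqd(60, 3, abRatio = 1.6)        # 60 Gy in 3 Gy fractions, EQD0
eqd(70, 3.5, abRatio = 1.6, referenceFractionSize = 2)  # boost EQD2
```

## The three dose-response models

**Tumour control (LQ-Poisson).** The expected number of surviving
clonogens in target voxel $i$ is $\rho\, v_i\, e^{-\alpha\,\mathrm{EQD0}_i}$
with clonogen density $\rho$ (default $2.8\times10^8$ cells/cm³) and voxel
volume $v_i$; control is the Poisson probability that none survive,

$$\mathrm{TCP} = \prod_i \exp\!\left(-\rho\, v_i\,
  e^{-\alpha\,\mathrm{EQD0}_i}\right),$$

accumulated as a log-domain sum so extreme doses cannot underflow the
product. $\alpha$ is not taken from tables blindly: `calibrateAlpha()`
re-derives it so that a reference schedule (70% TCP at 60 Gy in 3 Gy
fractions by default) is met on a given set of tumour volumes, either for
the cohort mean TCP (monotone bisection) or per volume (closed form
$\alpha = \ln(\rho V / -\ln T)/\mathrm{EQD0}$). Both aggregations are
offered because "reached in a cohort" is ambiguous between them; the
shipped default $\alpha = 0.12050$ Gy⁻¹ (with $\alpha/\beta = 1.6$ Gy)
corresponds to the mean-TCP reading, and `tcpParameterSets()` carries the
published robustness triplet ($\alpha/\beta \in \{1.2, 1.6, 2.7\}$ Gy).

**Urethra (Lyman-Kutcher-Burman).** A probit response in the generalised
equivalent uniform dose of the EQD2-converted voxel doses,
$\mathrm{NTCP} = \Phi\big((\mathrm{gEUD} - D_{50})/(m D_{50})\big)$ with
$\mathrm{gEUD} = (\sum_i \Delta v_i D_i^{1/n})^n$. Defaults are the
urethral-stricture set $D_{50} = 116.7$ Gy, $m = 0.23$, $n = 0.3$,
$\alpha/\beta = 5$ Gy. Whether the source parameters were meant for EQD2 or
physical dose is not documented; EQD2 is the default and `convert = FALSE`
exposes the alternative. $\Phi$ is the error-function-based normal CDF, not
a lookup table. `lkbUncertaintyScan()` evaluates the model on an inclusive
$(D_{50}, m)$ grid (1 Gy and 0.01 steps by default) for
confidence-interval scans; grid values are built from the lower bound by
integer multiples of the step so endpoint counts never drift with floating
point.

**Bladder and rectum (relative seriality).** The Källman form with
per-voxel Poisson response $P(D) = 2^{-\exp(e\gamma(1 - D/D_{50}))}$ and

$$\mathrm{NTCP} = \Big[1 - \prod_i \big(1 - P(D_i)^s\big)^{\Delta v_i}
  \Big]^{1/s},$$

on EQD2 voxel doses. The exact formula variant used by the literature
chain this parameterisation comes from is not printed in one place, so the
Källman form is isolated in a single internal function for easy
substitution. Defaults: bladder $D_{50} = 80$ Gy EQD2, $\gamma = 2.59$,
$s = 1.3$; rectum $\gamma = 1.79$, $s = 0.75$; $\alpha/\beta = 3$ Gy. The
product is accumulated via `log1p` so that $P \to 0$ or $P \to 1$ stays in
$[0,1]$.

## The composite score P+

The total probability of injury combines the organ NTCPs as
$P_I = 1 - \prod_j w_j (1 - \mathrm{NTCP}_j)$ with clinical-importance
weights $w_j \in (0,1]$, all 1 by default. The formula is implemented
literally — the weights sit inside the product, so any $w_j < 1$ makes
$P_I > 0$ even at zero NTCP; the function flags that case rather than
silently re-normalising. Complication-free tumour control assumes
independence of tumour and normal-tissue response:
$P_+ = P_B (1 - P_I)$. The more general form with an explicit joint
tumour/injury term is not modelled, as no joint distribution is available.

```{r}
probabilityOfInjury(c(0.072, 0.023, 0.009))
pPlus(0.997, probabilityOfInjury(c(0.072, 0.023, 0.009)))
```

## Intrafractional motion

Random intrafractional displacement of the anatomy relative to the dose
matrix is modelled by blurring the *dose* with an anisotropic Gaussian
kernel while the masks stay fixed; convolution is exactly the expectation
of the delivered dose over Gaussian displacements. Default standard
deviations are (0.92, 1.59, 1.54) mm for (LR, AP, CC), the published
prostate motion amplitudes. Numerics: the kernel is truncated at 4σ and
renormalised to unit sum; edges use replicate padding so no dose is
artificially lost at the patient surface; a zero σ is an exact identity.
Because the wording "changing the relative positioning … implementing
Gaussian filtering" also admits a finite-fraction reading, a seeded
`mode = "sample"` draws one rounded displacement per fraction and averages
the shifted matrices; convolution remains the default.

## DVH and geometry metrics

$DX\%$ is computed by exact order statistics (the largest dose received by
at least $X\%$ of the structure), not by binned-DVH interpolation — exact
quantiles are reproducible to the voxel, while planning systems
interpolate, so last-decimal differences against planning-system printouts
are expected. The binned cumulative DVH exists for plotting only.
Constraint checking resolves the generic `PTV3` role to the plan's active
boost volume and reports missing structures as *not evaluable*, never as a
pass. Overlap metrics (Dice, intersection volume, coverage) are voxel
counting; minimum distances are centre-to-centre with anisotropic spacing
respected, which biases surface distances by up to half a voxel —
documented rather than corrected, as it is deterministic and small at the
1.5 mm default grid. Per-slice distances are restricted to axial (CC)
slices, matching step-sectioned histology workflows.

## The synthetic phantom cohort

No patient data are distributed with the study this package operationalises,
so `makePhantom()` / `paintDose()` / `makeCohort()` generate a cohort that
emulates its *statistical structure*:

* a ~48 cm³ ellipsoidal gland with a 3 mm-radius urethra through it and a
  2 mm PRV expansion (the PRV margin follows the clinical convention for
  urethral sparing);
* an imaging-defined GTV-Union (~5 cm³ ellipsoid, clipped to the gland)
  abutting the urethra with a seeded 0–2 mm surface gap — the study found
  urethral contact or near-contact of the imaging target in most patients;
* a ground-truth GTV-Histo at the same centre, volume scaled by
  $0.9245^3 \approx 0.79$, elongated tangentially to the urethra until its
  coverage by GTV-Union matches the 79% target (bisection to ~2%). The
  tangential elongation makes the uncovered part protrude as thin lobes
  hugging the Union surface — a tumour slightly underestimated by imaging —
  rather than drifting into the low-dose bath, which would be
  unrepresentative of co-registered histology;
* boost volumes PTV3_1 = GTV-Union + 2 mm, PTV3_2 = PTV3_1 minus urethra,
  PTV3_3 = PTV3_1 minus PRV, defining plans 1–3;
* SIB dose painting: 60 Gy whole gland, 70 Gy boost, 20 fractions, built
  from Gaussian-blurred indicators (3 mm penumbra σ — a realistic
  80%–20% falloff) of padded paint regions; the paint margins (7 mm base,
  4.5 mm boost) are what an optimizer effectively does to hold the
  prescription at the structure edge; smooth correlated noise (sd 0.3 Gy,
  4 mm correlation length, drawn independently per plan as separately
  optimised plans would be) adds realistic plan-to-plan variability;
* urethral suppression for plans 2/3: the dose is iteratively scaled
  inside a blurred indicator of the spared structure until its D2% is at
  most the 62.4 Gy sparing constraint minus a 2 Gy headroom. The headroom
  is a design constant chosen so the constraint also survives motion
  blurring, which pulls neighbouring boost dose back into the spared
  corridor;
* per-case geometry jitter (10% on semi-axes, seeded gap/angle/offset
  draws) from a single RNG stream, so a cohort is exactly reproducible
  from one seed.

What the phantom does *not* emulate: irregular (non-ellipsoidal) target
shapes, true fluence-based dose calculation, inter-patient variation in
gland anatomy beyond ellipsoid jitter, bladder filling, and
histology-registration uncertainty. Consequently, passing end-to-end tests
demonstrates that the *pipeline* reproduces the qualitative effect
structure (urethral NTCP falls under sparing in every case, TCP is
essentially untouched, bladder/rectum are unaffected, P+ improves, the
sparing plan meets its constraint with and without motion) — not that the
phantom reproduces the patient-level numbers, which depend on real anatomy
and are not recoverable from the publication.

```{r, eval = FALSE}
cohort <- makeCohort(10, phantomSpec(), seed = 1)
records <- evaluateCohort(cohort, kernel = defaultMotionKernel())
summarizeCohort(records, c("tcp", "ntcpUrethra", "pPlus"))
comparePlans(records)
```

## Statistics

Plan variants are compared per endpoint with an exact two-sided paired
Wilcoxon signed-rank test. Zero differences are dropped by default (the
classic convention; the Pratt variant is available by flag since reference
software differs), ties get midranks, and the null distribution of the
positive-rank sum is computed exactly by generating-function convolution
over the (doubled, hence integer) midranks — identical to enumerating all
$2^m$ sign assignments, at polynomial cost, so exactness does not have to
stop at small $m$. $p = \min(1, 2\min(P(W \le w), P(W \ge w)))$. No
multiple-testing correction is applied; the analysis is exploratory and
raw p-values are reported.

## Numerical choices, sizes and limitations

* Probability comparisons in the test suite use 1e−9 absolute tolerance;
  α-calibration bisects to 1e−8; closed-form/voxelized TCP agreement is
  asserted at 1e−10 relative.
* The default phantom grid is 64 × 64 × 80 voxels at 1.5 mm (the
  calculation-grid resolution typical of clinical SIB plans); a 10-case,
  3-plan cohort with motion evaluation runs in about two minutes on one
  core, which is the problem size used by the shipped tests and the
  acceptance script.
* DICOM support is deliberately one dialect: explicit VR little endian,
  identity orientation, uniform frame offsets, 16/32-bit scaled dose.
  Oblique grids are rejected rather than silently resampled; the internal
  JSON + raw-array case bundle is the primary interchange format.
* Whether masks should carry partial-volume weights is an open modelling
  question; binary occupancy was chosen for determinism, and at 1.5 mm it
  biases small-structure volumes by at most a voxel shell.
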