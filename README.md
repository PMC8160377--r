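# rtOutcome

Radiobiological evaluation of radiotherapy treatment plans: voxel-based
tumour control probability (TCP), normal tissue complication probabilities
(NTCP), and the composite complication-free tumour control probability P+,
with intrafractional-motion dose blurring, DVH/geometry metrics, exact
paired Wilcoxon plan comparison, and a seeded synthetic prostate-phantom
cohort generator.

## Who it is for

Medical physicists and radiotherapy researchers who have 3D dose matrices
and structure masks (e.g. from DICOM RT exports) and want to compare plan
variants — typically a focal simultaneous-integrated-boost (SIB) plan with
and without urethral sparing — in outcome-model terms rather than purely
dosimetric ones.

## The models

With total dose `D` in `N` fractions (`d = D/N`) and isoeffect conversion
`EQDx = D (1 + d/(α/β)) / (1 + x/(α/β))`:

* **TCP** — LQ-Poisson on EQD0 voxel doses:
  `TCP = Π_i exp(−ρ v_i exp(−α EQD0_i))`, clonogen density
  `ρ = 2.8e8 /cm³`, `α` calibrated to a reference schedule
  (`calibrateAlpha()`), tumour `α/β = 1.6 Gy` by default.
* **NTCP, urethra** — Lyman-Kutcher-Burman probit in the gEUD of EQD2
  voxel doses: `NTCP = Φ((gEUD − D50)/(m·D50))`,
  `gEUD = (Σ Δv_i D_i^{1/n})^n`; defaults `D50 = 116.7 Gy`, `m = 0.23`,
  `n = 0.3`, `α/β = 5 Gy` (urethral stricture).
* **NTCP, bladder/rectum** — relative seriality (Källman form) on EQD2:
  `NTCP = [1 − Π_i (1 − P(D_i)^s)^{Δv_i}]^{1/s}`,
  `P(D) = 2^{−exp(eγ(1 − D/D50))}`; bladder `(80 Gy, γ 2.59, s 1.3)`,
  rectum `(80 Gy, γ 1.79, s 0.75)`, `α/β = 3 Gy`.
* **P+** — `P_I = 1 − Π_j w_j (1 − NTCP_j)` (weights `w_j = 1` by
  default) and `P+ = TCP · (1 − P_I)` under tumour/OAR independence.
* **Motion** — anisotropic Gaussian blurring of the dose matrix
  (σ = 0.92/1.59/1.54 mm LR/AP/CC), structures fixed.

See `vignettes/plan-evaluation.Rmd` for assumptions, parameter provenance
and numerical choices.

## Worked example

```r
library(rtOutcome)

cohort  <- makeCohort(10, phantomSpec(), seed = 1)   # 10 cases x 3 plans
records <- evaluateCohort(cohort, kernel = defaultMotionKernel())
subset(summarizeCohort(records, c("tcp", "ntcpUrethra", "pPlus")), !motion)
```

```
    plan motion    endpoint   median      q25      q75  n
1  plan1  FALSE         tcp 0.995655 0.994984 0.995916 10
2  plan1  FALSE ntcpUrethra 0.052291 0.050467 0.054087 10
3  plan1  FALSE       pPlus 0.935905 0.934238 0.937281 10
7  plan2  FALSE         tcp 0.995672 0.994645 0.996084 10
8  plan2  FALSE ntcpUrethra 0.019167 0.018911 0.019503 10
9  plan2  FALSE       pPlus 0.970115 0.965531 0.971658 10
13 plan3  FALSE         tcp 0.995643 0.995195 0.996147 10
14 plan3  FALSE ntcpUrethra 0.011648 0.011329 0.012481 10
15 plan3  FALSE       pPlus 0.977207 0.973438 0.978832 10
```

Reading: carving the urethra (plan 2) or its 2 mm PRV (plan 3) out of the
70 Gy boost volume cuts the predicted urethral stricture probability from
about 5% to about 1–2% while the tumour control probability moves by less
than 0.1 percentage points, so the complication-free tumour control P+
rises in every case. `comparePlans(records)` adds exact paired Wilcoxon
p-values per endpoint and plan pair, and `checkConstraints()` verifies the
62.4 Gy urethra/PRV D2% sparing constraints.

The same functions work on real data: `readRTDose()` / `readRTStruct()`
ingest one common DICOM dialect (explicit VR little endian, axis-aligned
grids), and `writeCase()` / `readCase()` provide a lossless internal
bundle (JSON header + raw arrays).

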