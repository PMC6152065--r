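---
title: "Calling HMW glutenin subunit compositions from chromatographic and gel evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling HMW glutenin subunit compositions from chromatographic and gel evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmwgs)
```

## The model

Wheat expresses three to five high-molecular-weight glutenin subunits
(HMW-GS), one x-type and optionally one y-type protein from each of the
*Glu-A1*, *Glu-B1* and *Glu-D1* loci (the Ax y-gene is silent in common
wheat; the Ax x-gene itself may be null). On a reversed-phase column each
expressed subunit produces one peak, and its retention time (RT) is treated
as a draw from a subunit-specific normal distribution `N(mean_s, sd_s)`.
The packaged reference table holds these statistics for the 20 alleles
observed in a 16-cultivar standard panel, estimated from 3–25 replicate
runs each; relative standard deviations are all below 0.38%, i.e. RTs are
reproducible to roughly ±0.1 min.

Classification uses the window `mean_s ± k·sd_s` with default `k = 3`. A
peak apex inside several same-type windows is *ambiguous*; the connected
components of the mean-in-window relation at `k = 3` reproduce exactly the
five ambiguity groups documented for this separation chemistry:
`{Ax1, Ax2*}`, `{Dx2, Dx4}`, `{Dy10, Dy12}`, `{By8*, By9, By18, By20y}`
and `{Bx7, Bx7OE}`. Each group carries the evidence type that resolves it:
gel mobility for the first, second and fourth; relative intensity for
Bx7/Bx7^OE^ (an overexpressed duplicate gene, same RT and mobility, about
double the protein); and Glu-D1 linkage for Dy10/Dy12, exploiting the
strict co-occurrence of Dy10 with Dx5 and of Dy12 with Dx2/Dx2.2/Dx4.

### Assignment and evidence order

Detected peaks are assigned to locus types by exhaustive enumeration of
injective maps, constrained to (a) each peak's window candidates, (b) one
peak per type, (c) a complete Glu-D1 pair, (d) a By peak only alongside a
Bx peak, and (e) at least one allowed Bx–By combination in the pairing
table. Among feasible assignments the minimizer of the summed squared
z-scores is kept; exact ties keep the first assignment in a deterministic
enumeration order (peaks by ascending apex, types in Ax–Dy order), which is
equivalent in practice because ties only arise between symmetric candidate
sets.

Candidate sets are then reduced in a fixed order: **pairing → gel →
intensity → linkage**, mirroring how an analyst works through a
chromatogram and gel side by side. Two asymmetries are deliberate:

* Pairing narrows only the **x-type** set (keep Bx candidates that have an
  allowed partner among the By candidates, or that may occur alone when no
  By peak exists). The y-type is never narrowed from the x-type: a By
  cluster peak alongside an unambiguous Bx17 *could* be inferred as By18
  from the pairing table alone, but the package treats the pairing table as
  a prior over x-alleles rather than as identification evidence for the
  y-peak, so the By locus stays flagged until a gel lane confirms it. This
  keeps "which evidence identified this subunit" honest in the report, at
  the cost of flagging a locus a geneticist might consider implied.
* Linkage runs last and infers Dy from the *final* Dx candidate set; when
  Dx is itself still ambiguous the inference is accepted only if every
  remaining Dx candidate maps to the same Dy (true for `{Dx2, Dx4}`).

A locus still holding several candidates is flagged and reported with its
lowest-|z| candidate as provisional. Glu-A1 null is a call of absence: it
requires zero peaks in any Ax window at the detection threshold, so the
threshold itself participates in the null call. Peaks matching no window
are flagged and excluded from assignment rather than failing the trace,
because a contaminant peak should not invalidate otherwise clean calls; a
trace whose matched peaks admit no consistent assignment raises an
`hmwgs_unassignable` error (CLI exit code 2).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `k` | 3 | SDs | RT window half-width; at 3 the induced ambiguity structure equals the documented one, and a true apex leaves its window with probability ~0.3% |
| `oe_threshold` | 1.5 | ratio | Bx area / median other-peak area at or above which 7^OE^ is called; the simulator's overexpression factor is 2, and observed ratios cluster near 1 and 2, so 1.5 splits them symmetrically |
| `smooth_width` | 0.05 | min | moving-average width, ~5 samples at the default grid; symmetric, so it does not bias apexes |
| `min_height` | 5% of window max | AU | detection threshold; relative, so calls are invariant to absorbance scaling |
| `hmw_window` | 25–42 | min | HMW elution region; LMW glutenins and gliadins elute later |
| `peak_sigma` | 0.15 | min | simulated Gaussian peak SD (see below) |
| `rt_jitter_scale` | 0 | × reference SD | run-to-run RT jitter in simulation; 1 emulates realistic reproducibility |
| `grid_step` | 0.01 | min | simulated sampling interval |

## What the simulator emulates — and what it does not

`simulate_chromatogram()` emits a sum of Gaussians, one per expressed
subunit, centered at `mean_s + jitter · N(0, sd_s)`, equal amplitudes
(×2 for Bx7^OE^), optional white baseline noise, and optional clutter
confined to 43–54 min emulating the LMW region. `simulate_gel()` emits one
band per expressed subunit at its ordinal mobility rank, merging
co-migrating subunits.

Choices made once and kept:

* **Peak shape and width.** Real glutenin peaks are only approximately
  Gaussian and their widths are not published for this separation;
  σ = 0.15 min was chosen so that the closest same-trace reference means
  (Dx2 and By16, 0.409 min apart) remain bimodal at zero jitter while peaks
  stay wide relative to the 0.01-min grid. Under 1×SD jitter that pair
  drops below the 2σ resolvability limit in roughly one draw in five —
  a property of the stated world, visible as occasional unassignable
  Sukang-type replicates in the stochastic tests.
* **Equal amplitudes.** True relative subunit amounts are not published;
  consequently no quantitative claim except the overexpression ratio
  depends on areas.
* **Ordinal gel ranks.** The packaged slowest→fastest order within some
  groups is a convention (only distinguishability, not order, is
  documented); the caller and simulator share it, and it is user-replaceable
  via TSV.

A green round-trip test therefore establishes that the decision logic is
correct *given* the statistical model of RTs and band ranks — it does not
establish robustness to skewed peaks, gradient drift, co-elution with
gliadin contaminants, or lane-to-lane gel distortion.

## Numerical choices

* **Apex refinement.** A quadratic through the three samples around a
  smoothed local maximum; on noise-free Gaussians the apex error is below
  10⁻⁵ min, comfortably under the 0.005-min acceptance bound and the
  0.001-min printing precision. Plateau ties keep the first sample; the
  symmetric three-point formula then still lands on the true center.
* **Baseline.** Linear between the window endpoints. Reference peaks sit
  ≥ 1.4 min inside the window, where a Gaussian tail is numerically zero,
  so the baseline does not bias apexes.
* **Statistics.** Sample SD uses the n−1 denominator; quartiles use linear
  interpolation (R type 7); whiskers are Tukey 1.5·IQR; the CI of the mean
  is the 95% normal approximation. None of these conventions is stated by
  the source data, so they are fixed here and used consistently.
* **Ambiguity derivation** uses mean-in-window *containment*, not interval
  overlap: overlap at `k = 3` would merge Bx6 with Bx7, contradicting the
  documented resolvability of Bx6. The derivation is validated against a
  brute-force pairwise oracle in the tests. No single interval rule
  simultaneously reproduces the visual separation of the Dy10/Dy12
  confidence intervals and their documented indistinguishability, which is
  why the canonical groups (with their resolution mechanisms) are also
  shipped as curated data rather than derived at run time.
* **Stochastic recovery metric.** "≥ 95% of 200 jittered replicates of the
  16 standards" is measured as the fraction of the 3200 per-cultivar calls
  recovered exactly. The per-panel (all-16-exact) reading is unattainable
  in the stated world because of the Sukang peak-merge geometry above
  (~0.82 per panel), while the per-call rate is ~0.97–0.98.

## Known limitations

* Alleles outside the 20-subunit reference are flagged as no-match, never
  force-called to the nearest window.
* Fused peaks are not deconvolved; a merged Dx/By peak makes the trace
  unassignable rather than guessed.
* Calling from a gel lane alone (without a chromatogram) is out of scope,
  as are densitometric quantification and quality-score prediction.
* The acceptance of the Glu-A1 null call depends on the detection
  threshold: a real trace with a very weak Ax peak below 5% of the window
  maximum would be called null.
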