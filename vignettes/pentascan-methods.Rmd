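---
title: "Methods: deviation mapping and dose-response analysis for pentameric proton-gated channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deviation mapping and dose-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentascan)
```

# Scope

`pentascan` implements two analyses used to interpret mutational scans of
homopentameric proton-gated channels such as GLIC: a structural arm that
asks *does this mutation move the backbone more than wild-type structures
differ among themselves?*, and a functional arm that asks *does this
mutation shift the proton sensitivity of the channel?* This vignette
documents the models, the parameters that matter, the numerical choices,
and what the synthetic-data generators do and do not emulate.

# Structural arm

## The 25-alignment scheme

A single global superposition of two pentamers averages away exactly the
quaternary, inter-subunit rearrangements one wants to see. The package
therefore aligns a structure M on a reference in 25 distinct ways
(`alignment_scheme()`): every adjacent two-subunit pair of M (A+B, B+C,
C+D, D+E) upon every such pair of the reference — 16 alignments that
preserve one subunit *interface* each — plus chain E of M on each
reference chain and each M chain on reference chain E (9 further
single-chain alignments after de-duplicating E-on-E, standing in for the
wrapped E+A pair). Pair tasks use positionwise chain correspondence, never
crossed pairings. The task order is fixed (pair tasks row-major, then the
single-chain tasks); it affects logs only, since averaging pools all
samples.

## Superposition contract

Each task is solved by the closed-form least-squares rigid superposition
(Kabsch): SVD of the 3×3 covariance of centered paired coordinates, with a
reflection guard forcing the determinant of the rotation to +1. There is
no iterative outlier rejection; rigid-body alignment of crystal structures
of the same fold does not need it, and a plain contract keeps results
reproducible. Fewer than 3 atom pairs, or collinear fitting atoms (second
singular value below 1e-8 of the largest), raise a degenerate-alignment
error naming the task.

By default only Cα atoms of matched, non-mutated residues drive each fit
(`atom_set = "calpha"`). Substituted positions and residues present in
only one structure are excluded from the fit so a mutated side chain
cannot bias the frame; `"backbone"` and `"all_common"` are available when
a denser fit is wanted.

## Per-residue deviations and averaging

Under each task's transform, every matched residue contributes one sample
per chain pair: the RMSD over its common heavy atoms (computed in the
task's frame, without per-residue re-fitting) and the Cα–Cα distance.
Mutated positions contribute a Cα sample but no RMSD sample (their atom
sets differ by construction). Hydrogens and HETATM records are excluded at
parse time. Pooling all (position, chain-pair) samples across the 25 tasks
with equal weight and taking arithmetic means per position yields
`v_rmsd` and `v_dca` — a position sampled in both chains of a pair task
contributes two samples from that task, 41 per position in a complete run.
Pooling (rather than averaging per-task means) was chosen because chains
appear unequally often across tasks; the choice is recorded in the profile
attributes.

## Normalization and flagging

Two wild-type reference structures solved independently (different
crystals, slightly different conditions) define the measurement floor.
For mutant M against references Wt1, Wt2:

$$\mathrm{ratio}(i) \;=\; \frac{V(M{-}Wt_1)(i) + V(M{-}Wt_2)(i)}
                               {2\, V(Wt_2{-}Wt_1)(i)}$$

applied identically to the RMSD and Cα profiles. The mutated position
itself is excluded; positions with zero control deviation are omitted with
a warning (the ratio is undefined there; this arises only for idealized
noise-free inputs). Positions whose Cα ratio exceeds the fold-change
threshold — default 5, configurable — are flagged as significant local
changes. The threshold is a conservative round fold-change over wild-type
variability; the null calibration below shows its false-positive rate is
far under 5% at the default noise level.

## Alternate conformations and residue matching

Altlocs are collapsed to a single conformer before any distance is
computed: within an atom-name group, a blank-altloc atom is always kept;
otherwise the highest-occupancy conformer wins, ties broken by the lowest
altloc character. Collapsing (rather than deleting altloc-bearing side
chains outright) keeps per-residue profiles gap-free; the rule is
deterministic and idempotent. Residue correspondence is by chain, residue
number, and insertion code — no sequence alignment — with an optional
integer renumbering offset at read time for structures deposited under
shifted numbering conventions.

# Functional arm

## The dose-response model

For one oocyte the two recorded peak currents per pH application are
averaged and fitted with

$$I(\mathrm{pH}) = \frac{I_{max}}{1 + 10^{\,h\,(\mathrm{pH} - \mathrm{pH}_{50})}}$$

with the bottom fixed at 0 and Hill slope $h > 0$ (current grows as pH
drops). Fitting uses bounded Levenberg–Marquardt on the raw mean peaks
(normalization to $I/I_{max}$ is a plotting transform only), with
pH50 ∈ [3, 8], $h$ ∈ [0.05, 10], $I_{max} > 0$. Initial values: pH50 from
linear interpolation of the half-maximum crossing, $h_0 = 1.5$,
$I_{max,0}$ = the maximal observed current; on failure a fixed 4×3 restart
grid over (pH50, $h$) is tried and the lowest-RSS convergent fit kept,
else the fit is marked `fail_convergence`. $R^2 = 1 - SS_{res}/SS_{tot}$
with $SS_{tot}$ about the mean of the fitted series. Recordings with fewer
than 3 distinct pH points or all-zero currents are rejected outright.

## Quality control

A fit passes only with $R^2 \ge 0.9$, $0.6 \le h \le 4$, and
$I_{max} \ge 0.9$ µA — the standard filters for this assay (the Imax floor
guards against endogenous acid-evoked currents; the slope and $R^2$ windows
remove curves that cannot be fitted meaningfully). When several filters
fail, one status is reported with fixed precedence: convergence, then
$R^2$, then Hill slope, then Imax. Boundary values are inclusive.

## Batch correction and classification

Wild-type proton sensitivity drifts between oocyte batches. Each passing
mutant fit is therefore referenced against the mean pH50 of the
QC-passing wild-type oocytes of its *own* batch:
$\Delta \mathrm{pH}_{50} = \mathrm{pH}_{50} - \overline{\mathrm{pH}_{50}^{Wt,\,batch}}$.
Adding any constant to all pH50 values of a batch leaves every shift
unchanged — the correction is exact by construction. Mutant fits in
batches without a passing wild-type oocyte keep their pH50 for aggregation
but contribute no shift (warned about and logged).

A construct is classified **gain** when both its mean ΔpH50 and its mean
pH50 minus the global QC-passing wild-type mean exceed +0.5 pH units
(strict inequality), **loss** when both fall below −0.5, otherwise
**no effect**; fewer than `min_n = 2` passing fits — or no batch-referenced
shift at all — gives **insufficient data**. The global wild-type mean is
used for the pH50 half of the criterion (the shift half carries the batch
correction); the equal-variance two-sided Student t test p value against
the wild-type pH50 values is reported alongside, but the threshold
criterion governs the label, which keeps calls stable for the small
per-mutant n typical of scans. All thresholds live in `qc_criteria()` and
are configurable.

# Synthetic data

## What the generators emulate

`simulate_pentamer_set()` builds a procedural toy fold (parametric helix,
extended strand, or both; 8 heavy atoms per residue), replicates it
five-fold by 72° rotations about a central axis at 25 Å radius, and emits
two wild-type noise realizations plus a mutant with configurable
per-residue displacements (radial or random, applied identically in all
five chains, as a substitution in a homopentamer would), residue
truncations, and optional two-conformer altlocs. `control_noise_sd`
(default 0.2 Å) is the RMS atomic displacement magnitude — the way
coordinate uncertainty is usually quoted for crystal structures — so the
per-axis Gaussian sd is $0.2/\sqrt{3}$.

`simulate_ephys_dataset()` draws, per batch, a wild-type pH50 offset
(Gaussian, sd 0.3 — slightly conservative against the ~0.4 overall spread
typical of large wild-type samples); per oocyte, a Hill slope
(1.5 ± 0.2), a lognormal Imax (median 5 µA, sdlog 0.4), and currents from
the Hill curve with 5% multiplicative Gaussian noise read out as two
independent peaks on the descending pH grid 7.0, 6.5, …, 4.0, 3.7 (the
standard protocol: half-log steps to a minimal pH of 3.7). A configurable
fraction of recordings is deliberately corrupted — flat featureless traces
and sub-threshold-current traces, alternating — to exercise the QC
filters. Both generators are fully deterministic given their seed and
restore the caller's RNG state.

## What they do not emulate

No crystal packing, no anisotropy, no correlated domain motions, no real
side-chain rotamers; no desensitization kinetics, no endogenous currents
with their own pH dependence, no electrode drift. Passing the simulation
suites therefore demonstrates that the *computational contract* is honored
under the stated statistical assumptions — not that any particular real
mutant will reproduce, where refinement software choices and true
experimental noise enter. Reproduction against deposited structures may
also differ slightly because the original analysis used a structural
alignment tool whose outlier-rejection behavior on non-consecutive chain
pairs is not documented; this package deliberately uses the plain
least-squares contract.

# Verification sizes and numerical tolerances

The test-suite and acceptance-script problem sizes are the package's
verification conditions: 40-residue chains (200 residues, 1600 heavy atoms
per pentamer) for the 50-seed null-calibration and detection studies;
6–15-residue chains for exactness checks; 100 seeded rigid transforms
recovered to < 1e-6 Å; 200 simulated oocytes for recovery (median
|pH50 error| < 0.05) and QC false-exclusion (< 5%) checks; 50 seeded
three-construct scans (true shifts ±1.5 and 0) for classification
accuracy. Exact identities (ratio ≡ 1, batch cancellation, midpoint
$I(\mathrm{pH}_{50}) = I_{max}/2$) are asserted at machine precision or
1e-6. The deviation route is cross-checked against an independent
brute-force implementation built on `bio3d::fit.xyz`.

# Known limitations

- Correspondence is strictly by residue number; structures with register
  shifts need the renumbering offset, not an alignment.
- Biphasic or otherwise non-sigmoidal dose-response data are rejected by
  the QC filters (typically `fail_r2` or `fail_convergence`), never
  fitted with a more complex model.
- The per-residue RMSD uses all common heavy atoms; a side-chain-only
  variant is not provided.
- The flagging threshold applies to the Cα ratio only; the RMSD ratio is
  reported but not thresholded, mirroring how such profiles are read.
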