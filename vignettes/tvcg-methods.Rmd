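---
title: "Temporal-vectorcardiogram heartbeat classification: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-vectorcardiogram heartbeat classification: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvcgbeat)
```

## The representation and the model

A two-lead ECG beat is usually classified from its amplitude morphology and
its rhythm context. The temporal vectorcardiogram (TVCG) treats the beat as a
curve in three dimensions — lead A, lead B and time — so that loops which
overlap in the classic two-lead vectorcardiogram are disentangled along the
time axis. The package turns that curve into a complex network: every
retained sample is a vertex, every pair of vertices is weighted by its
Euclidean distance (normalized to `[0, 1]`), and a rising threshold schedule
`T_l = T_0 + l (T_Q - T_0)/(m - 1)` prunes edges heavier than `T_l`. At each
of the `m` thresholds five degree statistics summarize the surviving
topology; tight, slow or premature beats produce visibly different point
clouds and hence different degree profiles.

The classifier is a weighted one-against-one C-SVC with RBF kernel (libSVM
through e1071). Class weights multiply the penalty `C` per class, the
standard device for the extreme imbalance of ambulatory recordings, where
normal beats outnumber ventricular ectopy by more than an order of
magnitude. All feature columns are z-scored with statistics fitted on the
training patients only; the same standardizer object is applied verbatim to
evaluation patients, and `tvcg_svm` stores it inside the fitted model so a
prediction can never silently re-fit it.

Everything is evaluated under the inter-patient paradigm: a record (patient)
contributes beats to exactly one side of any split, and
`evaluate_interpatient()` refuses to run otherwise. Metrics are the AAMI
per-class sensitivity, positive predictivity and false-positive rate plus
overall accuracy; the optimization fitness is the mean per-class F-score,
which balances Se and +P instead of rewarding majority-class accuracy.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| window span | -250 / +450 | ms around R | covers P, QRS, T and the late morphological sampling region with one window |
| `subsample_step` | 2 | samples | bounds the `O(n_v^2)` weight matrix; 253-sample windows give `n_v = 127` |
| `T_0`, `T_Q` | 0.05, 0.5 | normalized distance | stage-1 search box is `[0.001, 0.2] x [0.1, 1]` |
| `m` | 2 | thresholds | 178-feature vector; `m = 1` gives the 173-feature variant |
| `C` | 1 | — | hard-margin-like setting used throughout |
| `gamma` | `1/n_features` | — | the standard RBF default after z-scoring |
| class weights | stage 1 fixes `(6, 100, 15)` | — | stage-2 search box `[1,5] x [10,200] x [5,100]` for (N, S, V) |
| PSO `c1 = c2` | 2.05 | — | the conventional acceleration constants |
| PSO inertia | 0.9 -> 0.4 linear | — | exploration early, exploitation late |
| BPSO `vmax` | 4 | velocity | sigmoid(±4) ≈ 0.982/0.018, keeping bit flips possible |

The search-range assignment for stage 1 deserves a note: thresholds act on
weights normalized to `[0, 1]`, so the only consistent reading of the three
published ranges is `m` as the integer range 1–10, `T_0` in `[0.001, 0.2]`
and `T_Q` in `[0.1, 1]`; `m` is carried as a continuous coordinate and
rounded half-up only at evaluation, and positions with `T_0 > T_Q` are
repaired by swapping the pair.

## What the synthetic generator does and does not emulate

`synth_record()` builds each beat from Gaussian bumps with compact support
(3.5 sd): a P bump (absent for class V), a QRS bump whose width is
class-dependent (V roughly twice as wide as N), and a T bump, on both leads;
class S beats arrive prematurely (RR interval scaled by 0.6). Records get
sinusoidal baseline wander (0.1 mV at 0.3 Hz), white noise (0.02 mV sd) and a
per-record multiplicative morphology offset so that different seeds act like
different patients. Defaults were chosen once as plausible desk-scale
analogues of ambulatory data: 360 Hz sampling, 0.8 s base RR, ~1 mV QRS.

This emulates exactly what the feature extractors consume — class-dependent
QRS width, prematurity, P-wave presence, wander and noise — and nothing
else: no ectopic morphology variability within a class beyond the patient
offset, no rhythm episodes, no lead misplacement, no non-stationary noise
bursts. Passing the end-to-end test therefore shows the pipeline is wired
correctly and separates *separable* classes across patients; it says nothing
about performance on real recordings, where class S in particular overlaps
normal morphology heavily. Fiducials for synthetic data are derived from the
generator configuration (`synth_fiducials()`), standing in for an external
delineator, which the package deliberately does not reimplement; for real
records fiducials are accepted as input.

## Numerical choices and degenerate inputs

* **Rounding.** All ms-to-sample conversions round half up (`floor(x + 0.5)`);
  metric percentages are rounded half up to one decimal at printing only.
* **Threshold schedule.** Computed with `seq(t0, tq, length.out = m)`, which
  pins both endpoints; `m = 1` returns `T_0` (the division-by-zero guard).
* **Edge removal, not vertex removal.** The evolution step is read as
  removing *edges* above the limit, keeping the vertex set fixed — degree
  descriptors would be ill-defined otherwise, and this is the convention of
  the complex-network shape literature.
* **Descriptor normalization.** Mean degree divides by `n_v^2` and maximum
  degree by `n_v`, keeping both in `[0, 1]` across variable point counts.
  The joint-degree statistics are defined over the distribution of unordered
  endpoint-degree pairs of the surviving edges (entropy in bits with
  `0 log 0 = 0`, energy as the squared mass, mean as the expected pair mean
  divided by `n_v`); an empty graph scores all five descriptors 0, and
  coincident point sets give the all-zero weight matrix.
* **Axis normalization.** Each TVCG axis is min–max normalized before
  distances are taken; without it the time axis (in samples) would dominate
  the distance, and the network would only encode time adjacency. A constant
  axis maps to zeros.
* **FIR stages.** The 12-tap low-pass is a Hamming windowed-sinc whose cutoff
  is solved numerically so the realized response is -3 dB at 35 Hz; the 1 Hz
  high-pass is the spectral complement of a 1.5 s linear-phase low-pass
  (forced to exact unit DC gain, so DC is fully rejected) with its cutoff
  solved the same way — a 12-tap FIR cannot place a corner at 1 Hz at ECG
  sampling rates. Group delay is compensated by a forward shift (the even
  tap count leaves a residual half-sample delay, irrelevant to the feature
  extractors); the two-stage median baseline shrinks its windows at the
  record edges.
* **Feature hygiene.** Any non-finite feature becomes 0 after assembly (the
  count is kept in an attribute); zero-variance columns get unit scale in the
  standardizer; relative amplitudes with zero maximum are defined as 0.
* **Interval block.** The 13 interval features are reconstructed as 3 RR
  features + per-lead QRS duration, T duration (QRS offset to T end) and
  P-presence + 4 normalized RR ratios (pre/local, post/local, pre/post,
  mean(pre, post)/local). The T-duration endpoint uses the T-end fiducial —
  the delineation at hand — rather than a T-onset that no fiducial provides.
  The first beat's pre-RR falls back to its post-RR (symmetrically for the
  last), and the local RR averages the pre-RRs of up to 11 beats centered on
  the indexed one, shrinking at record edges.
* **Optimization.** Global-best updates are synchronous (once per full swarm
  evaluation); velocities clamp to half the box width per dimension and
  positions clip to the box; non-finite objective values are demoted to
  `-Inf`; BPSO runs without inertia by default (the variant that selected
  features better in the original study) and starts from the all-ones mask
  with 5% bit-flip noise on all but one particle; all-zero masks score
  `-Inf`. BPSO fitness is memoized by mask, which changes evaluation counts
  but never results. Every stage is exactly reproducible from its seed.

## Deliberately open points, decided here

The published description leaves several things unstated; the package's
choices are: the beat-window span (-250/+450 ms) and TVCG subsampling step
(2) above; per-lead max-absolute normalization for the morphology samples;
the joint-degree descriptor formulas spelled out above; `m = 2` as the
default (the 178-feature configuration, with the 173-feature `m = 1` variant
a parameter away); and record 111 in the evaluation partition (its
conventional membership). The bundled `published_confusion()` matrix is the
reported DS2 evaluation under the common filter; of its published metric
row, the five values that are pure row/column arithmetic on the 3-class
matrix (Se_N, +P_N, +P_S, Se_V, FPR_S) are reproduced exactly by
`aami_metrics()`, while the remaining figures require the fusion/unknown
counts the 3-class matrix does not carry and are therefore not asserted
anywhere.

## Problem sizes used by the shipped checks

The test-suite and acceptance runs use desk-scale sizes chosen as the
package's own defaults for fast, deterministic verification: descriptor
oracle checks on hundreds of random point sets with up to 12 vertices; a 5-D
sphere benchmark with 30 particles and 100 iterations; the planted-feature
study with 20 features, 180 beats per split and 40x60 BPSO; and an
end-to-end corpus of 6 synthetic patients with 100 beats each, split 3/3.
The full three-stage optimization campaign on real data (hundreds of
particles, tens of thousands of beats) is orders of magnitude larger and is
exactly what the stage functions' `n_particles`/`n_iter` arguments scale up
to.

## Known limitations

Class F (fusion) and Q (unknown) beats are mapped and counted but the
synthetic generator and the stage optimizers work with the three majority
superclasses, mirroring the 3-class evaluation scheme. The WFDB reader
covers the two-lead format-212 layout with beat annotations — sufficient for
the arrhythmia database it targets — not the full format zoo. Fiducial
delineation of real signals is out of scope by design. And the headline
published numbers stem from a full-scale optimization campaign on real
recordings; nothing at desk scale reproduces them end-to-end, which is why
the package's checks separate metric arithmetic (exact) from pipeline
behaviour (synthetic, seeded).
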