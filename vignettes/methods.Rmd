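---
title: "Models and methods behind stallox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stallox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stallox)
```

stallox analyzes two-photon phosphorescence lifetime (2PLM) point
measurements of capillary oxygen in the brain: repeated short
excitation/collection cycles at a single capillary yield, simultaneously, a
phosphorescence decay (hence pO2) and an intensity time course whose dips
mark red blood cell (RBC) passages (hence flux and speed). Around these two
primitives the package builds stall-event detection, tissue-pO2 estimation
from the erythrocyte-associated transient (EAT), and vessel-density
geometry from 3D angiograms. A synthetic-data generator produces every
input with known ground truth, so each stage of the pipeline is testable
end to end.

## The acquisition model

A visit to a point consists of `n_cycles` cycles of `excitation_us`
microseconds of excitation followed by `collection_us` of photon counting;
the defaults (1000 cycles of 10 + 290 us) give 300 ms per visit. Points are
revisited every `revisit_interval_s` (default 8 s) for the length of a
session. Photon arrival times are recorded within each cycle and quantized
to `decay_bin_width_us` (default 0.5 us), mirroring time-correlated
photon-counting hardware.

## Oxygen from phosphorescence lifetimes

Collisional quenching by oxygen shortens the probe lifetime according to
the Stern-Volmer relation

$$\frac{1}{\tau} = \frac{1}{\tau_0} + k_q\,\mathrm{pO_2},$$

with the zero-oxygen lifetime $\tau_0$ and quenching constant $k_q$
calibrated per dye batch by an oxygen titration (`fit_stern_volmer()` is a
linear fit of $1/\tau$ on pO2). No literature constants are baked in: the
calibration is always supplied by the user or by the simulator, whose
documented defaults are $\tau_0 = 40\,\mu s$ and
$k_q = 5\times10^{-4}\,(\mu s\cdot mmHg)^{-1}$, giving lifetimes from 40 us
at zero oxygen down to ~15 us at 80 mmHg — a realistic dynamic range for a
two-photon phosphorescent probe.

Per visit, arrival times are re-referenced to the end of the excitation
window, the first 5 us discarded (electro-optic modulator response), and
the remainder pooled into a histogram which `fit_decay()` fits with
$A e^{-t/\tau} + B$. The default objective is the Poisson negative
log-likelihood — the correct noise model for photon counting — with
ordinary least squares as an option; whether the single-exponential fit
should carry a background term is not standardized in this literature, so
`B` is fitted by default and can be disabled. Initialization is
deterministic (background from the tail 10% of bins, lifetime from a
count-weighted log-linear slope, amplitude from the first bin), and the
L-BFGS-B tolerances are set tightly because `factr` is relative to the
objective magnitude, which grows with photon count. Histograms with fewer
than `min_photons` (default 500) photons are flagged rather than fitted;
the number is a package choice, since published pipelines reject
low-signal points without quoting a threshold. Small negative pO2 values
from estimator noise are clipped to zero and flagged; lifetimes beyond
$\tau_0(1+0.05)$ are flagged out of range.

## Flux and speed from dye-exclusion dips

The probe stays in plasma, so an RBC crossing the focal volume produces a
dip in counts per cycle. `binarize_otsu()` labels cycles plasma/RBC by
thresholding the counts-per-cycle trace; flux is the number of RBC
intervals divided by the visit duration and speed is an assumed RBC path
length (default 6 um) over the median dip duration — the path length is an
explicit assumption and is reported with the estimate.

Three numerical choices matter here, all visible in the function
signatures:

* **Smoothing (default 3 cycles).** With dips occupying only a few percent
  of the cycles, Otsu's criterion on raw counts prefers splitting the
  unimodal plasma shot noise over isolating the dip class; a short moving
  average shrinks the plasma variance and restores the valley between the
  classes. The cost is that detected dips widen by about one cycle per
  side, a ~5–10% downward bias on speed.
* **Dip-evidence criteria.** Otsu always produces a split, even on a
  dip-free (stalled) trace. A trace is only binarized when the low class
  sits more than `min_contrast_sd` (default 3) shot-noise standard
  deviations of the smoothed values below the plasma class — this stands in
  for the manual "clear dips" pre-selection used with real data — and the
  operating threshold is kept at least that far below the plasma mean.
  Accepted intervals must additionally reach down toward the dip intensity
  level: noise runs hover just under the threshold and are rejected.
* **Minimum dip length (default 5 cycles, 1.5 ms).** Smoothing correlates
  adjacent cycles, so noise runs as long as the smoothing window are
  common; the shortest credible dip must exceed it. Symmetrically, plasma
  gaps shorter than this between two dips are closed before counting.

`analyze_session()` estimates one threshold per capillary from the pooled
smoothed counts of all its visits rather than per visit: a single 300-ms
visit can contain only a sliver of one dip — too little low-class mass to
threshold on its own — while the pooled session trace is stable. Visits
that claim RBC intervals with weak class separation (below
`min_separation = 0.2`) fail quality control, as do visits whose mean
counts drop below half the capillary's session median (probe drift or
focus loss).

## Tissue pO2 from the EAT

Intravascular pO2 is elevated next to each RBC and relaxes toward the
surrounding tissue value between RBCs (the erythrocyte-associated
transient). `build_eat_profile()` assigns each plasma-phase photon a
distance — time to the nearest RBC interval midpoint multiplied by the RBC
speed — pools photons into 1-um distance bins, and fits a lifetime per bin.
The far-from-RBC plateau is the tissue-pO2 proxy: `estimate_tissue_po2()`
pools all photons beyond a cutoff (the larger of 10 um and half the median
inter-RBC distance, a rule the package fixes because "far from the RBC" is
never quantified in this literature) and fits one decay. The midpoint of
the RBC interval is used as the distance reference, and photons are pooled
across all qc-passing flowing visits of a capillary; both are package
conventions. No diffusion model is implied — the proxy is used as is.

## Stall events and their consequences

A stall is a maximal run of consecutive qc-passing visits with flux
exactly zero (`detect_stalls()`). Consecutive zero-flux visits are one
event even though flow could in principle resume and re-stall between
visits — at an 8-s revisit interval this is unresolvable, so the per-event
visit list is kept for re-analysis. qc-failed visits break runs
conservatively and flag the adjacent events. Stall pO2 is the mean over the
event's visits; `classify_hypoxia()` uses strict thresholds (< 10 mmHg
hypoxic, < 5 mmHg severe, both configurable), 10 mmHg being the level
below which cellular respiration becomes oxygen-limited.

`align_peri_stall()` places each event on a relative-visit axis with the
event collapsed to offset 0 (event-mean pO2, flux 0), producing the
cohort-mean drop-and-recovery picture. `fit_stall_vs_tissue()` is ordinary
least squares of stall pO2 on EAT-estimated tissue pO2, per group label.
`neighbor_effects()` compares each never-stalling capillary's pO2 and flux
between visits concurrent with any detected stall and visits with no
detected stall anywhere in the session; reference windows exclude all
stall-concurrent visits because undetected stalls would otherwise
contaminate the baseline. Concurrency is by visit index (visits are
interleaved within one revisit interval), and distances between
measurement points are 3D Euclidean — in-plane distance is not
distinguishable in the data the pipeline sees.

## Vessel geometry

`crop_subvolume()` extracts 75 voxels in all directions around a
measurement point (151 per axis for interior points; boundary clips are
recorded). `binarize_angiogram()` applies a 3x3x3 median filter and a
global Otsu threshold; `skeletonize_mask()` thins the mask to one-voxel
centerlines by homotopic thinning (simple-point deletion with endpoint
preservation), so the skeleton is a subset of the mask and preserves
connected components. Out-of-volume neighbors are treated by replicate
padding: vessels truncated by a crop boundary are treated as continuing
beyond it, which prevents artificial erosion of their cut ends. Voxel
indices are 1-based (R's array convention) with voxel `(i,j,k)` centered
at `((i,j,k)-1) * voxel_size_um`; anisotropic voxel sizes are honored in
every distance. The vessel-density histogram counts *all* binarized vessel
voxels (not skeleton voxels) in 1-um distance bins from the point — the
skeleton is exposed for inspection but does not enter the density
estimate. Large-vessel (arteriole/venule) labels are taken from an input
label mask; distances to them are measured to the labeled voxels, i.e. the
vessel edge.

Note the median filter erodes the one-voxel surface shell of thin tubes
(a radius-3-um vessel at 1-um voxels loses part of its surface, Dice
~0.84 against truth), an inherent property of median smoothing at this
scale rather than a defect; at radius 5 um the overlap exceeds 0.97.

## The synthetic-data generator

`simulate_point_measurement()` draws, per cycle: RBC occupancy from
scheduled passage intervals (Poisson arrivals at the flux rate by default,
or regular spacing with random phase — inter-RBC interval statistics are
not established, and Poisson is the physiologic default); a local pO2 that
is the stalled equilibrium during a stall and otherwise follows an
exponential EAT gradient from the near-RBC value to the tissue value with
length constant `eat_length_um`; a lifetime through the inverse
Stern-Volmer relation; and a Poisson photon count (plasma or RBC rate,
dye excluded from RBCs) with arrival times from the truncated exponential
decay plus uniform dark counts, quantized to the decay bin width. Stall
onset is an instantaneous step to the stalled equilibrium — the ~8-s
revisit interval cannot resolve the true kinetics, and long stalls are
observed to sit at a lower steady state. `expected_decay()` is the
noiseless counterpart used for exact-fit checks.

The session ledger records, per visit, the true pO2, stall state, raw RBC
count, and a *resolvable* RBC count: the number of passages an ideal
detector could report at the acquisition's cycle resolution (occupancy
runs of at least `min_dip_cycles`, with sub-resolution gaps merged by the
same rule the detector uses). Recovery tests compare detection to the
resolvable count, since passages separated by less than one cycle are
indistinguishable in principle.

`simulate_stall_cohort()` is the package's reference experiment: 32
capillaries, each stalling once, with exactly 13 assigned a hypoxic
stalled equilibrium drawn from U(2, 8) mmHg and the rest from U(14, 32) —
a cohort whose hypoxic fraction (13/32) and mean stall pO2 (~16 mmHg) are
fixed by design, with class margins around the 10-mmHg threshold wide
enough that estimator noise at the simulated photon budget (about 0.9 mmHg
SD at 10 000 photons/visit) contributes negligible misclassification.
Stall durations are mostly single visits (70/20/10% for 1/2/3 visits),
matching the observation that most stalls are brief. The cohort uses
regular RBC arrivals and a clearly detectable dip regime (8 RBC/s, 15-ms
transits, plasma 10 vs RBC 1 counts/cycle): it emulates the *post-QC*
"good points" of a real study — in practice the majority of measured
points are discarded for lacking clear flux contrast — so that the
scheduled stall set coincides exactly with the zero-flux set. With Poisson
arrivals at 8 RBC/s, ~9% of flowing visits would contain zero RBCs in
300 ms and be genuine (unscheduled) stalls, which is a property of real
traffic, not a detector error; the regular-arrival cohort removes that
ambiguity on purpose.

What passing the simulation-based tests does *not* show about real data:
the generator has no probe photobleaching or drift (QC's count-drop rule
is exercised synthetically), no motion artifacts, no multi-exponential
decay components or intravascular/interstitial dye compartments, no
hematocrit phase separation or network flow redistribution, and its EAT
gradient is exactly exponential. Recovery performance on simulated
cohorts is therefore an upper bound on real-data performance, and the
detector settings (contrast criterion, smoothing) matter most exactly
where the simulation is cleanest.

## Problem sizes and determinism

All simulation-backed checks run at sizes chosen to exercise the full
pipeline while staying lightweight: 10 visits per capillary for EAT
recovery (~10^5 far-field photons), 50 capillaries across five pO2 levels
for oxygen recovery, four capillaries at each of four flux levels for flux
recovery, and 32-stall cohorts re-simulated across a couple of hundred
seeds for the event statistics. Every random stage takes an explicit seed,
all thresholds live in `run_config()`, and every pipeline output carries
the configuration and its hash, so any table can be reproduced from its
own metadata. The on-disk formats are deliberately plain: CSV + JSON for
photon containers (lossless, since arrival times are quantized and readr
round-trips doubles at full precision), multi-page TIFF + JSON sidecar
for volumes.

## Known limitations

* Speed estimation rests on an assumed RBC path length and on dip duration
  at cycle resolution; after smoothing it carries a ~5–10% downward bias.
* Per-capillary thresholding assumes dip contrast is stable across a
  session; slow drift in plasma counts is handled only by the QC
  count-drop rule.
* The EAT plateau cutoff rule (max of 10 um and half the median inter-RBC
  distance) leaves a small positive bias (< 1 mmHg at the default gradient
  length constant) from residual gradient photons just beyond the cutoff.
* Very short partial dips at trace edges (under `min_dip_cycles`) are
  invisible to both the detector and the ledger's resolvable count by
  construction.
* Hypoxia classification applies fixed thresholds to estimated stall pO2;
  near-threshold events can be misclassified when photon budgets are low.
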