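# stallox

Capillary stalls — transient interruptions of red blood cell (RBC) flow in
single capillaries — are increasingly implicated in brain pathology, but
their acute effect on local oxygen is hard to quantify. Two-photon
phosphorescence lifetime microscopy (2PLM) can measure both at once: each
point measurement consists of ~1000 cycles of 10 µs excitation and 290 µs
of photon counting (300 ms per visit), yielding simultaneously

* a pooled **phosphorescence decay**, whose lifetime τ encodes oxygen
  partial pressure through the Stern-Volmer relation
  `1/τ = 1/τ0 + kq · pO2`, and
* an **intensity time course** (counts per cycle) in which RBC passages
  appear as dips, because the phosphorescent probe is confined to plasma —
  giving RBC flux and speed from the same photons.

stallox is an R package for analyzing such measurements end to end: decay
pooling and single-exponential lifetime fitting (Poisson likelihood),
calibrated conversion to pO2, Otsu-based dip segmentation into per-visit
flux/speed with quality control, tissue-pO2 estimation from the
erythrocyte-associated transient (EAT — the inter-RBC pO2 plateau far from
any RBC approximates the surrounding tissue), detection and
characterization of stall events (hypoxia classes below 10 and 5 mmHg,
peri-stall alignment, stall-vs-tissue regression, effects on co-measured
neighbor capillaries), and vessel-density geometry from 3D angiogram
volumes (median filtering, binarization, 3D skeletonization, distance
histograms). A synthetic-data generator simulates every input — photon
streams, stall schedules, EAT gradients, tube-network angiograms — with
known ground truth, so every stage is verifiable by recovery tests.

It is intended for microscopists and analysts working with phosphorescent
oxygen probes, and for anyone who wants a transparent, simulation-tested
reference implementation of this analysis chain.

## A worked example

Simulate a small cohort of eight capillaries, each scheduled to stall once
(three with a hypoxic stalled equilibrium), run the per-visit pipeline,
and detect the events:

```r
library(stallox)

ses <- simulate_stall_cohort(seed = 42, n_stalls = 8, n_hypoxic = 3)
ses
#> <stallox_session> 8 capillaries x 7 visits, 542097 photons (13 stall visits)

ts <- analyze_session(ses)   # lifetime fit, pO2, flux, speed, QC per visit
events <- detect_stalls(ts)
dplyr::select(events, capillary_id, start_visit, end_visit,
              duration_s, stall_po2, hypoxia_class)
#> # A tibble: 8 × 6
#>   capillary_id start_visit end_visit duration_s stall_po2 hypoxia_class
#>   <chr>              <int>     <int>      <dbl>     <dbl> <fct>
#> 1 cap01                  6         6          8      5.24 hypoxic
#> 2 cap02                  5         5          8     22.7  normoxic
#> 3 cap03                  4         6         24     24.6  normoxic
#> 4 cap04                  3         3          8     31.5  normoxic
#> 5 cap05                  4         5         16      3.72 severe
#> 6 cap06                  4         5         16     31.1  normoxic
#> 7 cap07                  5         6         16      7.74 hypoxic
#> 8 cap08                  5         5          8     16.7  normoxic
```

All eight scheduled stalls are recovered with their visit boundaries, and
the three hypoxic ones (stall pO2 below 10 mmHg) are classified as such —
`stall_po2` is the fitted mean pO2 over each event's visits, estimated
from the photons alone. Aligning the events on stall onset shows the
drop-and-recovery structure:

```r
summarize_peri_stall(align_peri_stall(events, ts, max_offset = 2))
#> # A tibble: 5 × 6
#>   offset po2_mean po2_sd flux_mean flux_sd n_events
#>    <int>    <dbl>  <dbl>     <dbl>   <dbl>    <int>
#> 1     -2     34.3   8.31      7.08    1.18        8
#> 2     -1     34.0   7.74      8.75    1.73        8
#> 3      0     17.9  11.3       0       0           8
#> 4      1     33.8   7.97      8.33    1.78        8
#> 5      2     37.9   5.63      8.67    1.83        5
```

Oxygen drops by ~16 mmHg at the stall (offset 0, flux exactly zero by
definition of the event) and recovers within one revisit (~8 s) of flow
resuming. `plot_peri_stall()`, `plot_capillary_series()`,
`plot_eat_profile()` and friends render these tables with ggplot2;
`tidy()`/`glance()` methods cover the fitted objects.

The same building blocks are exposed individually —
`build_decay()`/`fit_decay()`, `fit_stern_volmer()`/`lifetime_to_po2()`,
`build_intensity_trace()`/`binarize_otsu()`/`count_flux()`,
`build_eat_profile()`/`estimate_tissue_po2()`,
`crop_subvolume()`/`binarize_angiogram()`/`skeletonize_mask()`/
`density_histogram()` — and a thin command-line front end
(`inst/cli/stallox`, subcommands `simulate` and `report`) drives the whole
pipeline on on-disk photon containers. See `vignette("methods")` for the
models, parameter choices and their rationale.

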