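# sepsync

Synchronization-based topography of somatosensory evoked potentials
(SEPs).

## What it does, and for whom

Dense epidural grids (e.g. 192 electrodes at 0.5 mm pitch) record the
averaged cortical response to peripheral nerve stimulation.  The
traditional way to delineate the cortical representation keeps the
channels whose N1–P1 peak-to-peak amplitude exceeds 60% of the grid
maximum — a rule that throws away low-amplitude channels even when their
activity is tightly synchronized with the response.  `sepsync` is for
electrophysiologists who want the *functional network* instead: the set
of channels that are mutually synchronized, detected objectively and
mapped onto the electrode grid, with the classic amplitude topography
computed alongside for comparison.

## The method

For z-normalized traces `z_i(t_k)` (population SD, so the diagonal is
exactly 1) the equal-time correlation matrix and its eigensystem are

    C_ij = (1/T) Σ_k z_i(t_k) z_j(t_k),     C v_i = λ_i v_i .

Eigenvalues are tested per rank against a surrogate null built by
phase-randomizing every channel independently (N = 100 repetitions,
preserving each channel's power spectrum, destroying inter-channel phase
relations): rank *i* is a synchronized cluster when

    λ_i > λ̄'_i + K·SD_i ,   K = 3   (the 99.7% Gaussian band).

Each channel's participation index `PI_ji = λ_i v_ji²` is mapped onto the
grid; the network boundary is the knee point of the PI-threshold /
channel-count curve (maximum chord distance on the min–max-scaled curve),
followed by 8-connected component labelling; the network area is
`members × pitch²` in mm².  Clusters with maximum PI < 0.2 are flagged
weak.  The classic baseline (N1/P1 latencies, N1–P1 amplitude, inclusive
60%-of-max area) and a pooled Student t-test for group comparisons are
included, as is a synthetic SEP generator with known ground-truth
networks.

## Worked example

```r
library(sepsync)
sim    <- synth_generate(synth_preset("normal", seed = 42))
report <- run_pipeline(sim$traces, sim$grid, list(seed = 42))
report
#> sep_report: 192 channels, 1 synchronized cluster(s) (1 strong)
#>   cluster 1: eigenvalue 23.167, 54 members, 13.50 mm^2
#>   classic 60%-of-max area: 24 members, 6.00 mm^2
```

Reading: the top correlation eigenvalue (23.2) towers over the surrogate
band (mean + 3 SD ≈ 8.3 at rank 1), so exactly one synchronized network
is present.  Its knee-point boundary contains 54 channels = 13.5 mm²,
while the traditional 60%-of-max amplitude area is 24 channels = 6.0 mm²
and lies entirely inside the network — the synchronization view recovers
the low-amplitude fringe that the amplitude rule discards.  Against the
generator's ground truth the recovered member set has Jaccard ≈ 0.89.

The same pipeline is scriptable from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "sepsync", package = "sepsync"))')
Rscript $CLI synth --preset normal --seed 7 --out-traces t.csv --out-layout l.json
Rscript $CLI run   --traces t.csv --layout l.json --seed 7 --out report.json
Rscript $CLI compare --group-a a1.json,a2.json --group-b b1.json,b2.json --field area_mm2
```

`run_pipeline()` accepts a trace CSV (time column + one column per
channel) and a layout (JSON `{channel: [ml_mm, ap_mm]}` or 3-column CSV)
and writes a single self-describing JSON report: eigenvalues, surrogate
band, cluster count, per-cluster PI map, knee threshold, members, area,
weak flags, classic features, full config echo and seed.

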