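---
title: "Synchronization-based topography of somatosensory evoked potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronization-based topography of somatosensory evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsync)
```

## The problem

A somatosensory evoked potential (SEP) is the averaged cortical response
to peripheral nerve stimulation, recorded here on a dense epidural
electrode grid (by default 192 channels at 0.5 mm pitch) over one rat
hemisphere.  The classic way to map the cortical representation is by
amplitude: find each channel's N1 trough and P1 peak and keep the channels
whose N1--P1 amplitude exceeds 60% of the grid maximum.  That rule is
simple but arbitrary — channels with low-amplitude SEPs that are strongly
*synchronized* with the response are discarded.

`sepsync` instead maps the *functional network*: the set of channels whose
traces are mutually synchronized, regardless of their amplitude.

## The model

Let $x_i(t_k)$, $i = 1\dots M$, $k = 1\dots T$ be the traces in an
analysis window after the stimulus.  Each channel is z-normalized,

$$ z_i(t_k) = \frac{x_i(t_k) - \langle x_i \rangle}{\sigma_i}, $$

with $\sigma_i$ the *population* standard deviation (divide by $T$).  This
choice is deliberate: the equal-time correlation matrix

$$ C_{ij} = \frac{1}{T}\sum_k z_i(t_k)\, z_j(t_k) $$

then has an exactly unit diagonal, so $\mathrm{tr}(C) = \sum_i \lambda_i =
M$, which the tests assert.  The eigendecomposition $C v_i = \lambda_i
v_i$ concentrates shared variance: a group of synchronized channels
produces one eigenvalue far above the bulk, and the largest eigenvalue
measures global synchronization (it approaches $M$ when every channel
carries one common waveform).

### Significance: the surrogate null

Whether an eigenvalue is "far above the bulk" is decided against a
surrogate null in which each channel keeps its own power spectrum (hence
autocorrelation) but all *inter-channel* phase relations are destroyed.
Each of $N = 100$ repetitions phase-randomizes every channel
independently, re-z-normalizes, and records the sorted eigenvalues of the
surrogate correlation matrix $R$; the per-rank mean
$\bar\lambda'_i$ and standard deviation $SD_i$ define the band.  Rank $i$
is a synchronized cluster when

$$ \lambda_i > \bar\lambda'_i + K \cdot SD_i, \qquad K = 3, $$

the three-sigma rule, i.e. a 99.7% one-sided confidence band under a
Gaussian null.

Two surrogate constructions are available.  The default, `"ft"`, is the
classic Fourier surrogate: multiply the positive-frequency coefficients by
$e^{i\theta_k}$ with independent uniform phases mirrored
Hermitian-symmetrically ($\theta_{T-k} = -\theta_k$, DC and Nyquist bins
untouched), so the inverse transform is exactly real and the amplitude
spectrum is preserved to machine precision.  The `"aaft"` option is the
amplitude-adjusted variant (Gaussianize by rank, phase-randomize,
rank-remap the original amplitudes), which additionally preserves the
amplitude distribution and is the appropriate null when the traces are
visibly non-Gaussian.  We default to `"ft"` because the stated null —
same power spectrum, random phases — is exactly its construction, and
because averaged evoked potentials (200 sweeps) are close to Gaussian by
the central limit theorem.  Surrogate channels are re-z-normalized before
computing $R$ so that $R$ is a true correlation matrix; for `"ft"` this
is a no-op up to rounding (Parseval), for `"aaft"` it matters.

A diagnostic mode shares one phase vector across all channels within a
repetition; this preserves cross-spectra (and therefore synchrony) and is
useful for verifying that the null machinery itself does not destroy
correlation — it is *not* a null for cluster detection.

### Topography: participation index and knee point

The participation index of channel $j$ in cluster $i$ is

$$ \mathrm{PI}_{ji} = \lambda_i\, v_{ji}^2 , $$

the cluster strength weighted by the channel's squared eigenvector
loading.  When all $M$ components are retained, each channel's PI sums to
$C_{jj} = 1$ — a test-only invariant; reported PI is restricted to
*significant* clusters because within a degenerate eigenvalue subspace the
eigenvector basis (hence PI) is solver-dependent.  Eigenvector signs are
fixed by forcing the largest-magnitude element positive, so reports are
deterministic; PI itself is sign-invariant.

Lowering a PI threshold from the maximum admits more and more channels;
the curve of channel count against threshold rises slowly through the
genuine network and then jumps when the threshold crosses the noise bulk.
The network boundary is placed at the knee of this curve: both axes are
min-max scaled to $[0,1]$ and the point with maximum perpendicular
distance to the chord joining the curve's endpoints is chosen (the
"Kneedle" rule).  This replaces a qualitative "where growth slows"
criterion with a deterministic, parameter-free one.  Ties break toward the
higher PI — the smaller, more conservative network — and a perfectly
linear curve (no knee) falls back to the highest-PI interior point with a
warning.  Curves with fewer than three distinct PI values are degenerate;
the caller falls back to including all channels, again with a warning.

Supra-threshold channels are then segmented by 8-connected component
labelling on the electrode lattice and the component containing the
maximum-PI channel is kept; 8-connectivity avoids fragmenting diagonally
touching blobs at 0.5 mm pitch.  A full level-set segmentation would add
nothing on a 192-node lattice — the procedure reduces to a threshold
plus connected components.  The network area is exactly
`members × pitch_mm²`.  A cluster whose maximum PI is below 0.2 has
fairly small synchronization strength: it is flagged weak and excluded
from the headline network count (both counts are reported).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_start_ms`, `window_end_ms` | 0, 50 | ms post-stimulus | covers N1 (~9.5 ms) and P1 (~21 ms) with margin; the analysis window is a genuine free choice and is always echoed in the report |
| `n_surrogates` | 100 | — | enough repetitions for a stable per-rank mean and SD |
| `surrogate_method` | `"ft"` | — | see above |
| `K` | 3 | SDs | 99.7% Gaussian band |
| `n1_window_ms` | 3–15 | ms | brackets reported rat sciatic N1 latencies (7.6–9.5 ms) |
| `p1_window_ms` | 10–40 | ms | brackets reported P1 latencies (18.5–21 ms) |
| `amplitude_fraction` | 0.6 | — | the classic 60%-of-max rule; inclusive (`>=`) at equality, since "over 60%" and "less than 60%" phrasings conflict exactly at the threshold |
| `weak_pi_max` | 0.2 | PI | weak-network ceiling |
| `seed` | 1 | — | root seed for the surrogate null; recorded in the report |

## The synthetic generator

Because dense epidural SEP grids are not publicly deposited, the package
ships a generator with known ground truth.  Channel $i$ records
$\sum_c g_c(i)\, w_c(t) + \varepsilon_i(t)$ where each cluster $c$ has a
Gaussian spatial gain $g_c(i) = \exp(-d(i, \text{centre})^2 / 2r^2)$
(anisotropic if two radii are given) and an SEP-like waveform $w_c$ — a
negative Gaussian bump (N1) followed by a larger positive one (P1).
Noise is iid Gaussian per channel and sample, defensible because the
input is already a 200-sweep average; an exponential-kernel spatially
correlated noise option exists for robustness checks (default off).
Ground-truth cluster membership is gain ≥ 10% of the peak gain — an
arbitrary but fixed, documented cutoff that the recovery tests are
calibrated against.

Defaults are chosen once to represent the recording conditions: 16 × 12
grid at 0.5 mm pitch spanning −5.5 to +2.0 mm AP (so the grid crosses
bregma) and 1.0–6.5 mm ML; 20 kHz sampling, 50 ms duration (T = 1000);
noise SD 5 µV.  The `"normal"` preset is one compact isotropic cluster
(radius 1.0 mm) posterior to bregma with N1 9.5 ms / P1 21 ms and ~50 µV
N1–P1 amplitude; `"injured"` is larger, AP-elongated (1.05 × 1.55 mm),
shifted toward bregma, with shorter latencies (7.6 / 18.5 ms) and ~94 µV
amplitude — mirroring the reported direction of change after acute
peripheral nerve injury.  `"two_cluster"` places two compact clusters
with different waveform latencies at opposite corners for multi-network
detection tests.

What the generator does **not** emulate: volume conduction and dipole
geometry (gains are phenomenological), trial-to-trial latency jitter,
line noise, electrode drop-out, and spatially structured physiological
background (unless the spatial-noise option is enabled).  Passing the
recovery tests therefore shows the pipeline recovers networks of this
phenomenological form at realistic SNR — not that it is robust to every
artefact of real recordings.

## Numerical choices

* Population-SD normalization (divide by $T$) keeps $C_{jj} = 1$ exactly;
  sample-SD would make the trace identity only approximate.
* $C$ is symmetrized as $(C + C^\top)/2$ before `eigen(symmetric = TRUE)`.
* Per-rank comparison of sorted observed against sorted surrogate
  eigenvalues; if the significant set is ever not a prefix of the ranks a
  warning is emitted (not observed in practice except as rare noise
  exceedances deep in the bulk).
* One root seed drives the surrogate null; draws are consumed in a fixed
  repetition order, so results are bitwise reproducible and the caller's
  RNG state is restored afterwards.
* Zero-variance channels are a hard error everywhere rather than being
  dropped, keeping matrix rows aligned with the electrode layout.

## A worked run

```{r example, eval = FALSE}
sim <- synth_generate(synth_preset("normal", seed = 42))
report <- run_pipeline(sim$traces, sim$grid, list(seed = 42))
report
#> sep_report: 192 channels, 1 synchronized cluster(s) (1 strong)
#>   cluster 1: eigenvalue 23.167, 54 members, 13.50 mm^2
#>   classic 60%-of-max area: 24 members, 6.00 mm^2
```

One eigenvalue (23.2, against a surrogate band topping out near 8.3)
flags a single network; its knee-point boundary holds 54 channels
(13.5 mm²), while the classic 60%-of-max amplitude area is less than
half that (6.0 mm²) and lies inside it — the low-amplitude fringe of the
response is synchronized with the core and only the synchronization view
captures it.

## Validation problem sizes

The statistical checks in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` use: 100 white-noise runs (M = 24, T = 1000,
N = 100 surrogates) for null calibration; 50 runs each of the one- and
two-cluster presets for detection and boundary recovery (Jaccard against
ground truth); and 30 runs per condition for the normal-vs-injured area
comparison.  These sizes give stable empirical rates while keeping a full
validation run in the ten-minute range on a single core.

## Limitations

* The analysis window is not prescribed by the method; different windows
  change the correlation structure and should be reported alongside
  results.
* The knee rule is a deterministic stand-in for a visual criterion; on
  curves with two comparable knees it picks the higher-PI one.
* Equal-time correlation only: lagged coupling, cross-frequency or
  wavelet coherence are out of scope, as is a random-matrix-theory
  (Marchenko–Pastur) analytic null.
* Group comparison uses the pooled-variance Student t-test (a Welch
  option exists); no correction for multiple comparisons across fields.
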