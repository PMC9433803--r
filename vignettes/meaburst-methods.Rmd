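---
title: "Methods: network bursts, learning populations and functional hubs on HD-MEA spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network bursts, learning populations and functional hubs on HD-MEA spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and data model

`meaburst` analyzes spike-train recordings from a high-density CMOS
microelectrode array: a 64 x 64 lattice of 4,096 recording electrodes at
81 um pitch (21 um electrodes), covering cultured cortical networks of
roughly 90,000 neurons — about 22 neurons per electrode. The package
starts from detected spike timestamps (`spike_train_set`): raw-voltage
processing and spike detection are upstream, vendor-side steps and are
out of scope. Timestamps are milliseconds on `[0, duration)`, strictly
increasing per electrode; electrodes are numbered 1..4096 in row-major
order and positions are electrode centers, `((col-1)*pitch,
(row-1)*pitch)`. The stated active area (5.12 x 5.12 mm^2) and 64 x 81
um = 5.184 mm are mildly inconsistent; the pitch is treated as
authoritative, so all distances derive from it.

## Stimulation protocol and evoked responses

The learning paradigm delivers biphasic pulses (negative-first, 200 us
per phase, +/-15 uA — carried as metadata) through one electrode pair at
1 Hz: 8 cycles x 4 trials x 10 stimuli = 320 stimuli over 32 trials,
with 20 s rest per trial and 60 s per cycle. Published timing narratives
(cycle length vs "every 1 min for 60 min") do not add up exactly; the
scheduler treats the counts as authoritative and the rest durations as
configuration, because every downstream analysis is indexed by counts
(32 trials, 320 stimuli), not by wall-clock time. The first 10 ms after
each stimulus are blanked (artifact) and the analysis window is
(10, 200] ms; windows are truncated at the next stimulus when stimuli
are closer than 200 ms, with a warning.

Per stimulus and electrode, a response is flagged when the spike count
in the window *strictly* exceeds the network-average count over active
electrodes for that stimulus. The R/S ratio of a trial is the fraction
of its 10 stimuli that were responses (so it lives on {0, 0.1, ..., 1});
the response time (RT) is the mean latency of the first three in-window
spikes, undefined for empty windows.

## Localizing the learning population

Each electrode's R/S series and mean-RT series over the 32 trials are
fitted with first-order OLS lines against trial index (undefined trials
skipped). The learning population is the intersection: R/S slope > 0 AND
RT slope < 0 AND at least `min_defined_trials` (default 8) trials with a
defined RT.

The sign-only rule is the default, faithful to the published criterion.
It has, however, no specificity under the generator's stated noise: a
non-learning electrode with constant response probability has a
symmetric slope distribution on both axes, so ~25% of non-learning
electrodes pass the sign intersection by chance (we measure precision
~0.07 on a 32 x 32 array with 21 planted learning electrodes). The
optional slope-significance filter (`localize(...,
significance_level = 0.05)`, a two-sided OLS t-test on both slopes)
restores specificity without touching recall — planted trends (R/S 0.2
-> 0.9, RT 150 -> 40 ms over 32 trials) yield |t| well above 7. The
pipeline default and the parameter-recovery acceptance test therefore
enable the filter; the generator and its noise parameters are untouched.

Information content is quantified per electrode as the Shannon entropy
of the binned inter-spike-interval (ISI) distribution, `E = -sum(P_i
log2 P_i)` with `0 log 0 := 0`. The source does not state a binning;
we use linear 10-ms bins on [0, 1000) ms plus one overflow bin, which
separates within-burst ISIs (tens of ms) from background ISIs (seconds)
while keeping the bin count (101) small enough that a few hundred ISIs
populate it. The learning population's entropy share is the sum of
learning-electrode entropies over the sum across all electrodes with a
defined entropy (>= 2 spikes); whether the published share aggregates by
sum or mean is unstated, so both are available (`aggregate = "sum"` is
the headline).

## Network bursts

A network burst is a maximal run of time bins in which strictly more
than 25% of the *active* electrodes (>= 1 spike in the recording, by
default — on a fully active default array the threshold is exactly
1,024 electrodes, matching the published parenthetical) fire at least
one spike. Distinct electrodes, not spikes, are counted per bin. The bin
width is not dictated by the definition; the default 25 ms resolves
onset order within bursts that last a few hundred milliseconds while
keeping counts stable, and is configurable. Supra-threshold runs
separated by at most `merge_gap` (100 ms) are merged and bursts shorter
than `min_duration` (25 ms) are dropped. Burst windows snap to bin
edges; participants' first spikes are raw timestamps inside the window.

## Burst initiation and propagation

Per burst, electrodes are ranked by first-spike time (ties broken by
(row, col), making maps deterministic); the 10 earliest ranks are the
onset electrodes and their mean center position is the initiation site.
Propagation speed is estimated by OLS of first-spike latency (relative
to the burst's earliest first spike; the reference is configurable to
the window start) on distance from the initiation site — for radial
propagation at speed v the slope is 1/v. Distances from initiation
sites to the nearest learning electrode are summarized as cumulative
fractions at inclusive thresholds of one pitch, one diagonal and two
pitches (81, 115, 162 um). Initiation sites are grouped into onset
clusters by single-linkage agglomeration at one pitch radius (no
clustering rule is published; single linkage at the finest spatial
class is the least committal choice and is deterministic after sorting
sites).

Two measurement caveats, quantified on synthetic data: burst windows
snapping to bin edges can exclude the very earliest first spikes, and
background spikes inside a long window can pre-date an electrode's true
recruitment. Both bias the fitted speed upward (10-60% at default
background). The speed-recovery acceptance check therefore runs the
propagation stage on the generator's ground-truth annotations
(`annotated_bursts()`), which isolates the rank/site/fit machinery; the
burst-count recovery check runs on `detect_bursts()` output.

## Functional connectivity

The functional graph is built over learning-population electrodes from
pairwise spike-train cross-correlograms (1-ms lag bins over +/-50 ms, 5
ms coincidence window; both unstated in the source and configurable).
The printed normalization 1/(N_x N_y) is the default; the literature's
1/sqrt(N_x N_y) convention is available via `normalization = "sqrt"`,
with threshold statistics adapting automatically. The detection
threshold is mean + 3 SD of the pairwise peak values; a pair's edge
direction follows its peak-lag polarity (positive lag: first train
leads, edge x -> y; zero lag: reciprocal edges). Two numerical choices:
(i) the comparison is `>=`, so the degenerate all-equal-weights case
(SD = 0) keeps its edges; for continuous weights this is
indistinguishable from `>`; (ii) with a 5-ms coincidence window on 1-ms
bins the maximum is a plateau — its central lag is reported, so
identical trains peak at lag 0 and a +5 ms copy peaks at +5.

Synchrony between two trains is the mean over spikes of
`1 / (1 + dt / tau_s)` (dt = distance to the nearest spike of the other
train, tau_s = 10 ms), averaged over both directions; rate correlation
is the Pearson correlation of 100-ms binned counts.

## Graph metrics

All measures use the binarized, symmetrized adjacency (connection
status), per the unweighted formulations: degree; density
`2l/(n(n-1))`; global efficiency (mean inverse hop distance, 1/Inf = 0);
modularity from the module mixing matrix; betweenness normalized by
`(n-1)(n-2)` over unordered pairs (so a 3-path's middle node scores
0.5); and small-worldness `S = (C/C_rand)/(L/L_rand)` with C the mean
local clustering (degree < 2 contributes 0) and L the characteristic
path length on the largest component, against 20 degree-preserving
rewired nulls (10 x edge-count swaps, seeded). Community detection is
seeded greedy modularity maximization with module labels renumbered by
lowest member index, hence deterministic. Shortest paths, betweenness
counts, clustering and rewiring are delegated to igraph; every metric is
verified against independent pure-R brute-force oracles (BFS distances,
DP path counting, explicit mixing matrices) in the test suite. The
published per-node "degree of modularization" axis is ambiguous between
modularity and degree; node degree is used for that axis and both
regressions are always reported.

## Hub-burst association

For each onset cluster, the predictor is the mean node metric (degree or
betweenness) over learning electrodes within 115 um of the centroid;
the response is the cluster's burst count; OLS slope/r/R^2 are reported
with unlinked clusters excluded and counted. The "top 90%" overlap reads
the published phrasing literally — keep the highest 90% by metric rank
(ties kept), i.e. exclude the bottom decile — with the alternative
top-decile reading available via `percentile_keep = 0.1`; onset
electrodes outside the learning set map to their nearest learning
electrode within 115 um and count as non-overlap if none exists.
Pre/post comparisons use Welch's unequal-variance t-test (the source
says only "t-test"); degenerate zero-variance samples fall back to an
exact-equality report with a flag. No multiple-testing correction is
applied (none is applied in the source; noted in the report).

## The synthetic generator: what it does and does not establish

The generator is phenomenological — Poisson processes and planted
first-order structure, no membrane or synapse dynamics:

- **Background**: independent per-electrode Poisson trains at 0.5 Hz.
- **Bursts**: onsets from a Poisson process (4/min before, 8/min after
  learning), thinned to a >= 1 s onset separation (post-burst network
  refractoriness; also keeps annotated and detected counts comparable);
  a site drawn per burst from the configured site pool; recruitment of
  the electrodes within the 0.6 distance quantile of the site; first
  spikes at `distance / 20 um/ms + N(0, 3 ms)`; ~4 spikes per recruited
  electrode (Poisson) over a 100-300 ms envelope.
- **Learning phase**: response probability of learning electrodes
  interpolated linearly 0.2 -> 0.9 across the 32 trials and mean evoked
  latency 150 -> 40 ms (linear, because the analysis fits first-order
  lines); responses are 3-spike volleys 3 ms apart (RT averages the
  first three spikes), truncated into the analysis window; non-learning
  electrodes respond at a constant 0.15 probability and constant 100 ms
  mean latency (mid-window, uninformative).
- **Post-learning**: the site pool is augmented with hub electrodes and
  the rate doubles; hub-initiated bursts are annotated as new patterns.
- **Disinhibition ("bicuculline-like")**: burst rate x2, envelope x1.5,
  participation x1.3 (capped) — more, longer, wider bursts.

Three RNG streams (background / burst skeleton / burst and response
spikes) are derived from the master seed, so toggling one component
never shifts another's draws; identical seed + config gives
byte-identical spike files. Ground truth (burst onsets, sites, recruited
electrodes, learning mask) is always emitted, never inferred.

A green parameter-recovery test therefore establishes that the analysis
recovers exactly the structure the generator plants — linear trends,
radial propagation, Poisson counts — at realistic noise. It does not
establish performance on real recordings, whose bursts have
non-stationary rates, avalanche-like recruitment, electrode-dependent
noise and correlated background; the published headline statistics
(r = 0.783/-0.906 learning fits, ~75% entropy share, 72/90/98% distance
fractions, r = 0.735 betweenness regression, 29/68/78% overlaps) are
real-data references, not reproduction targets.

## Numerical choices and degenerate inputs

- OLS fits are closed-form; constant series get slope 0 and undefined r;
  fits with fewer than the minimum defined points are undefined, never
  silently extrapolated.
- `rate_correlation` and the regression helpers flag zero-variance
  inputs as undefined (`NA`) with warnings rather than erroring
  mid-pipeline; empty spike trains are hard errors for correlogram and
  synchrony (the quantities are undefined).
- Spike files store timestamps with 17 significant digits so the CSV
  round trip is bit-exact.
- The pipeline's default configuration is desk-scale (16 x 16 grid,
  2-min spontaneous recordings) so that `run-all` completes in seconds;
  the full-array geometry is a configuration change, not a code path.
  With more localized learning electrodes than `connectivity$max_nodes`
  (40), the pipeline keeps the most active ones — an O(n^2) correlogram
  cap, recorded in the output.

## Known limitations

- Direction from peak-lag polarity cannot distinguish common drive from
  direct coupling, and zero-lag peaks yield reciprocal edges by
  convention.
- The burst detector's bin-edge snapping biases detected-burst
  propagation-speed estimates upward (see above); rank order itself is
  unaffected.
- The entropy share depends on the (configurable) ISI binning.
- Weighted graph metrics, transfer entropy / Granger connectivity,
  wave-front velocity fields, and single-channel (ISI-based) burst
  detection are out of scope.
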