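# meaburst

Network-burst and learning-population analysis for high-density
microelectrode array (HD-MEA) spike trains.

## The problem

Cultured cortical networks on 4,096-electrode CMOS arrays (64 x 64
lattice, 81 um pitch) fire spontaneous *network bursts* — brief epochs
in which a large fraction of the array spikes near-synchronously — and
they can be *trained*: repeated low-frequency electrical stimulation
through one electrode pair makes a subset of electrodes respond more
reliably and faster across trials. `meaburst` implements, as a tested
and reusable pipeline, the analysis chain that connects these two
phenomena:

1. **Learning-population localization.** Per electrode and trial, the
   response/stimulus ratio R/S (fraction of a trial's 10 stimuli whose
   evoked spike count exceeds the network average, in [0, 1]) and the
   response time RT (mean latency of the first 3 spikes in the 10-200 ms
   post-stimulus window). First-order fits across the 32 trials; the
   learning population is the intersection {R/S slope > 0} AND
   {RT slope < 0}. ISI Shannon entropy `E = -sum(P_i log2 P_i)`
   quantifies its information share.
2. **Network-burst detection.** A burst is a run of 25-ms bins in which
   strictly more than 25% of active electrodes spike (> 1,024 on a
   fully active default array).
3. **Propagation mapping.** Per burst: first-spike rank order, the 10
   earliest ranks as onset electrodes, their centroid as the initiation
   site, distance-vs-latency regression (slope = 1/speed), and the
   distance from each initiation site to the nearest learning electrode
   (cumulative fractions at 81/115/162 um).
4. **Functional graph and hubs.** Pairwise spike-train cross-correlograms
   `C_xy(tau) = (1/(N_x N_y)) sum` of coincidences in a 5-ms window,
   thresholded at mean + 3 SD of the peak values, directed by peak-lag
   polarity; then degree `k_i = sum_j a_ij`, density `2l/(n(n-1))`,
   global efficiency, modularity `Q = sum_u [e_uu - (sum_v e_uv)^2]`,
   normalized betweenness centrality, and small-worldness
   `S = (C/C_rand)/(L/L_rand)` against degree-preserving nulls.
5. **Hub-burst association.** Regression of onset-cluster burst counts
   on the mean degree/betweenness of learning electrodes within 115 um,
   top-percentile overlap between onset electrodes and high-betweenness
   learning electrodes, and Welch-t pre/post comparisons.

No raw recordings are bundled: a seeded, phenomenological generator
(`simulate_spontaneous()`, `simulate_learning_phase()`,
`simulate_post_learning()`) produces spike trains with exactly the
structure the analyses assume — Poisson background, radially
propagating bursts from configurable sites, linearly improving evoked
responses in a planted learning set, and a disinhibited
("bicuculline-like") regime — together with ground-truth annotations,
so every stage is testable end to end.

## Worked example

```r
library(meaburst)

grid <- electrode_grid(16, 16)                 # desk-scale array
planted <- learning_disc(grid, c(5, 5), 203)   # ~20-electrode learning blob

## learning phase: 8 cycles x 4 trials x 10 stimuli at 1 Hz
cfg <- sim_config(seed = 1, learning_set = planted,
                  burst_sites = matrix(c(12, 12), ncol = 2))
lp  <- simulate_learning_phase(cfg, stim_protocol(), grid)
tbl <- response_table(lp$spikes, lp$log)
map <- localize(tbl, grid, significance_level = 0.05)
found <- map$electrode[map$is_learning]

## spontaneous activity after learning: bursts and propagation
post <- simulate_post_learning(cfg, grid, hub_sites = found[1:3])
bursts <- detect_bursts(post$spikes)
fit <- distance_latency_fit(rank_order_map(bursts[[1]], grid), grid)

## functional graph over the learning population and its hubs
g  <- build_functional_graph(post$spikes, found, sd_multiplier = 1)
gm <- graph_metrics(g, seed = 1)
```

This prints (exact output of the snippet, seed 1):

```
learning electrodes: 21 found / 21 planted (recall 1.00)
bursts: 34 in 5 min (6.8/min)
burst 1 propagation: 25.0 um/ms (r = 0.80)
functional graph: 21 nodes, 33 links, density 0.16, Q 0.34
top hub: electrode 55 (betweenness 0.181)
```

Reading it: all 21 planted learning electrodes are recovered; the
post-learning recording holds 34 network bursts (6.8/min, the planted
post-learning regime); the first burst propagates radially at ~25 um/ms
(planted speed 20 um/ms, estimated from a single burst at 3 ms first-
spike jitter); the thresholded correlogram graph over the learning
population has 33 links and its strongest hub is electrode 55.
(`sd_multiplier = 1` is used here because a 21-node example graph is
sparse at the default mean + 3 SD threshold.)

## Command line

```sh
Rscript inst/exec/meaburst simulate --seed 3 --rows 16 --cols 16 --out spikes.csv --truth truth.json
Rscript inst/exec/meaburst detect-bursts --input spikes.csv --out bursts.csv
Rscript inst/exec/meaburst run-all --seed 7 --out report_dir
```

(After installation the launcher lives at
`system.file("exec", "meaburst", package = "meaburst")`.)
`run-all` executes simulate -> localize -> connect -> metrics ->
detect-bursts (pre/post) -> propagate -> associate and writes a
deterministic CSV/JSON bundle: identical seeds give byte-identical
reports.

## Further reading

The methods vignette (`vignettes/meaburst-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate,
numerical choices and degenerate-input behavior, and known limitations.
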