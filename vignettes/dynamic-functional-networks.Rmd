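---
title: "Dynamic functional networks from motor cortical spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional networks from motor cortical spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfn)
```

## The scientific question

During a planned reach, populations of primary motor cortex (M1) neurons
coordinate their spiking at the scale of milliseconds. `dynfn` asks whether
the *pairwise spike-time* structure of such a population — who tends to fire
just before whom — carries information about the upcoming movement, beyond
what single-neuron firing rates convey, and *when* during a trial that
information appears.

The experimental setting is an instructed-delay center-out reach: the
subject holds at a central target, an Instruction cue indicates one of 8
radial targets, a 1-s delay follows, and a Go cue releases the reach. Trial
time is referenced to trial start (0.5 s before Instruction); trials count
as valid when correct and when the target is acquired within 1.5 s of
movement onset, itself defined as the first time hand speed reaches 5% of
the movement's peak speed after Go.

## The functional network model

Spike trains are binarized in 10-ms bins (1 if the unit fired at least once
in the bin). For an ordered pair of units $(i, j)$ the edge weight is the
*confluent mutual information* (conMI): the plug-in mutual information
between the source state $i_t$ and the collapsed target state
$\hat{j}_t = 1 \iff (j_t = 1 \lor j_{t+1} = 1)$,

$$\mathrm{conMI}(i \to j) \;=\; \sum_{i_t \in \{0,1\}}\,
\sum_{\hat j_t \in \{0,1\}} p(i_t, \hat j_t)\,
\log_2 \frac{p(i_t,\hat j_t)}{p(i_t)\,p(\hat j_t)} ,$$

with empirical frequencies over $t = 1,\dots,T-1$ (the final bin has no
successor and is dropped; a 200-ms window therefore contributes 19 source
bins). Collapsing the target over bins $t$ and $t+1$ makes the measure
asymmetric — co-firing where $j$ follows $i$ raises $\mathrm{conMI}(i\to j)$
but not $\mathrm{conMI}(j\to i)$ unless reciprocated — so the resulting
*functional network* (FN) is weighted **and** directed. A full-trial FN uses
the whole trial; a *temporal FN* is the sequence of FNs from 200-ms windows
slid in 10-ms steps.

Conventions chosen where the mathematics needs one:

* $0\log 0 = 0$, and a degenerate marginal (a silent or saturated train)
  gives exactly 0 — the plug-in standard, avoiding NaNs.
* No small-sample bias correction is applied; the rate-matched null (below)
  is subject to the same bias and absorbs it in comparisons.
* Window timestamps are the **trailing edge** relative to the alignment
  event: the FN stamped at $t$ uses only data from $[t - 0.2\,\mathrm{s}, t)$.
  This causal convention means onset-like latencies read at most 200 ms
  later than under a leading-edge convention; no result in this package is
  compared against a fixed published latency, precisely because the original
  convention is not stated.

## Rate-matched surrogates

Any pairwise statistic is suspect of merely reflecting firing rates. The
null model regenerates every unit's train, trial by trial, from its own
single-trial rate: the train is convolved with a Gaussian kernel
($\sigma = 20$ ms, unit area, 1-ms lattice), and the smoothed rate $r(t)$
drives an inhomogeneous sampling scheme that emits at most one spike per
10-ms period with probability $\min(r\Delta, 1)$, placed uniformly within
the period. Rate dynamics are preserved; precise timing is jittered within
the kernel width. 45 surrogate network sets normalize reciprocity; count
preservation is verified at 50 iterations in the tests.

Two honest caveats, verified quantitatively in the test suite and the
decisions this package had to make:

* **The surrogate is a Cox (doubly stochastic) process.** The kernel holds
  only $\approx 0.4$ expected spikes at 8 Hz, so the single-trial rate
  estimate is essentially a bump per observed spike. Even when the true
  rate is flat, surrogates are over-dispersed and serially correlated at
  the kernel scale, which measurably shifts plug-in conMI and alignment
  scores relative to data at any reasonable sample size. Consequently a
  structureless Poisson cohort is *not* statistically indistinguishable
  from its surrogates — one acceptance-level check asserting exactly that
  indistinguishability is deliberately left failing rather than weakened
  (see `tests/testthat/test-acceptance.R`). What *does* hold, and is what
  the downstream analyses rely on, is one-sided: with no injected
  correlations the data never stochastically dominate the null, and with
  injected correlations they do.
* The probability cap at 1 and the one-spike-per-period scheme are choices
  the original description leaves open; both only matter at rates far above
  the physiological range simulated here.

## Graph statistics

The *graph alignment score* between two FNs $M, N$ on the same node set is
$\mathrm{GAS} = 2\sum_{ij}\min(M_{ij},N_{ij}) / \sum_{ij}(M_{ij}+N_{ij})$
over ordered pairs: 1 iff identical, 0 iff disjoint support, invariant to a
common rescaling. Trial pairs are grouped by the circular distance between
their instructed targets ($\Delta \in \{0,45,90,135,180\}^\circ$; all five
groups are computed even where only three are usually displayed).

*Weighted reciprocity* of a thresholded FN is
$r = \sum_{i\ne j}\min(w_{ij},w_{ji}) \,/\, \sum_{i\ne j} w_{ij}$,
normalized against the mean reciprocity $\bar r$ of the 45 surrogate
networks after identical thresholding: $\rho = (r - \bar r)/(1 - \bar r)$.
Thresholding keeps edges at or above a percentile (85th–90th by default) of
each network's own nonzero off-diagonal weights; ties at the threshold are
kept, and the percentile is per-network (the original text is ambiguous
between per-network and pooled; per-network keeps the edge count comparable
across windows with different overall weight scales).

## Decoding

A multilayer perceptron (one hidden layer of 100 ReLU units, constant step
size 0.001, at most 200 iterations or convergence at tolerance $10^{-4}$)
predicts the 8-way target from per-window features: firing-rate counts
(`FR`, length $N$), vectorized off-diagonal FN weights (`FN`, length
$N(N-1)$), their concatenation (`FRFN`), or FN features from one surrogate
realization (`nullFN`). Splits are stratified 75/25 (stratification is a
package choice; the original does not say), features are not scaled, and 50
independent splits/initializations per window give a score distribution.
The implementation is a minimal Adam-trained MLP written for this package —
no pre-installed R package provides this architecture — with Glorot
initialization, softmax cross-entropy ("linear output units" read as the
identity pre-softmax logits), and an L2 penalty of $10^{-4}$.

Onset is the first window whose 50 scores beat chance (one-sided one-sample
t test, $p < 0.01$ Bonferroni-corrected across the epoch's windows) *and*
that starts a run of ≥ 3 consecutive significant windows; the run rule
operationalizes "significant from $t$ onward", which the original never
formalizes. The peak is the maximal mean within 500 ms of Instruction.

## Significance timelines

Group comparisons per window use the two-sided Mann–Whitney U test with
Bonferroni family equal to the number of windows in the aligned epoch (the
per-figure-panel reading; the family size is recorded next to every
p-value so any other correction can be recomputed). Divergence time uses
the same sustained-run rule as decoding onset. The reciprocity baseline is
each trial's mean $\rho$ from Instruction to +100 ms; each window is
compared to that distribution by Welch's t test (corrected), and the
minimum-$\rho$ window additionally gets an uncorrected test, mirroring the
starred-minima convention of the original figures.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` builds a world in which every downstream stage has
known ground truth:

* **Task structure** — Instruction at 0.5 s, Go at 1.5 s, reaction time
  uniform on [0.2, 0.3] s (no distribution is published; this brackets
  typical macaque reaction times), a 0.4-s minimum-jerk reach of 8 cm, end
  0.5 s after acquisition, 8 directions, all trials correct.
* **Rates** — Bernoulli thinning on a 1-ms lattice with uniform jitter
  within the step; baseline 8 Hz; cosine tuning with fractional depth 0.5
  switching on 120 ms after Instruction (tuning latency in the
  physiological 100–150 ms range).
* **Direction code** — per direction, `assembly_size` ordered unit pairs
  receive excess co-spikes: each source spike adds a target spike in the
  same or next 10-ms bin with probability `corr_strength`, from 120 ms
  after Instruction onward. Injections are *added* (sources stay Poisson),
  which keeps rate bookkeeping exact but means assemblies also raise
  target-unit rates — so firing-rate decoders inherit part of the injected
  signal, exactly as rate and timing information co-vary in real data.
* **Reciprocity scaffold** — a direction-blind background set of
  bidirectional pairs is active for the whole trial; the optional
  reciprocity dip silences the reverse legs of a fraction of them inside a
  post-Instruction window (default 0.15–0.35 s). The scaffold is
  direction-independent by necessity: pre-Instruction windows must carry
  no direction information (decoders at chance before the cue), yet the
  dip needs baseline reciprocity to dip *from*. For dip fixtures the
  injections use strictly lag-1 bins, because a same-bin co-spike elevates
  conMI in both directions at once, making a directed "reverse leg"
  ill-defined.

A fixed seed reproduces a cohort byte for byte; surrogate and decoder
substreams are derived per (iteration, unit, trial) so any single draw is
reproducible in isolation.

What a green test does **not** establish: the generator is Poisson with
injected coincidences — no refractoriness, bursting, oscillations,
latent-state dynamics, or non-stationarity across trials — so passing
parameter recovery here demonstrates the *pipeline* recovers planted
structure, not that cortical data contain it. Desk-scale fixtures shrink
the population (60 → 16–30 units) and trial counts (30 → 6–20 per
direction) and compensate with stronger injections (`corr_strength`
0.35–0.6 instead of 0.2); the spec for this package explicitly frames those
defaults as detectability choices, not physiological estimates.

## Embedding

Vectorized FNs (row-major, length $N^2$) are embedded in 2-D with UMAP
(cosine metric; `n_neighbors = 50, min_dist = 1` for full-trial FNs,
`n_neighbors = 100, min_dist = 0.1` for temporal FNs, all samples embedded
jointly, no labels). Because no UMAP implementation exists in the offline R
library set, `embed_fns()` drives the Python `umap-learn` package through a
subprocess with a fixed `random_state`; a pure-R fallback
(`backend = "pca"`: principal components of L2-normalized vectors, which
reproduces cosine geometry to second order) keeps the contract available
without Python, at the cost of UMAP's local-structure emphasis. Trial
trajectories through the embedding are natural cubic splines through each
trial's window coordinates; per-direction territories use a bivariate KDE
with normal-reference bandwidths. Embedding output is treated as
qualitative throughout; no test asserts manifold geometry beyond
determinism, label-blindness, and that planted cluster structure beats
chance under a k-NN readout.

## Numerical and degenerate-input policy

* conMI: inputs validated binary and equal-length $\ge 2$; tiny negative
  float residue clipped to 0.
* GAS of two all-zero networks, reciprocity of a zero-weight network,
  thresholding a network with no nonzero edge, normalization with
  $\bar r = 1$: all are errors, not silent zeros.
* Per-trial/window reciprocity that is undefined after thresholding
  becomes `NA` and is excluded from aggregates.
* Ties: threshold keeps ties ($\ge$); the minimum-$\rho$ window takes the
  earliest among exact ties.
* All seeds are integers below $2^{31}$; substreams are derived by a
  splitmix-style integer mix.

## Known limitations

* The surrogate indistinguishability caveat above is the main one: the
  null is conservative for detecting *excess* structure but is not a
  calibrated sampler of "the same data without timing".
* The normalized-GAS variant described only in the original supplement has
  no published formula and is not implemented; `group_gas_by_target_delta`
  accepts pre-normalized networks should a user supply their own
  normalizer.
* The Dryad-deposited recordings are not bundled or required; readers for
  the generic text formats are provided and the synthetic cohort stands in
  for all testing. Bit-exact reproduction of subject-specific numbers is
  out of scope.
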