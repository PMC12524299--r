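---
title: "Predicting temporal liking from temporal dominance of sensations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting temporal liking from temporal dominance of sensations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdsliking)
```

This vignette documents the modelling choices behind `tdsliking`: the data
representations, the echo state network and its hyperparameters, the
synthetic panel generator, and the numerical conventions. It is the place
where every genuinely open design decision is recorded.

## Data representations

All curves live on a shared, evenly spaced grid on normalized time
$t \in [0,1]$ ($t = \text{seconds}/\text{trial duration}$), by default 101
points (0.01 resolution — ample for tastings of 10–20 s; `time_grid()`).
A raw trial is an ordered sequence of timestamped button presses
(`trial_record`); sampling it onto the grid is last-event-carried-forward,
with the sentinel `"none"` (TDS) or the value 0 (TL) before the first
press. The TL zero-initialization matters: a liking curve legitimately
starts at 0 even though the buttons only go down to 1, because panelists
have not pressed anything yet.

A `curve_set` pairs, for one condition:

* a 12 × 101 TDS matrix of dominance proportions — the fraction of trials
  in which each attribute was dominant at each grid point;
* a TL curve in $[0, 9]$;
* the residual "none" mass. At every grid point, attribute mass + none
  mass = 1 exactly; this conservation identity is enforced in tests to
  $10^{-12}$. The none channel is bookkeeping only: model inputs stay
  12-dimensional.

Per-panelist curves are built from that panelist's three repetitions
first (proportion for TDS, mean for TL), and only then averaged or
resampled across panelists. The alternative — pooling all 48 trials of a
condition directly — would change the bootstrap unit; resampling operates
on *panelist curve pairs*, so rep-level aggregation has to come first.

## Bootstrap augmentation

A 16-panelist panel yields far too few curve pairs to train a recurrent
model, so each condition is augmented to 100 curve pairs: each replicate
draws 16 panelist curve pairs with replacement and averages them. The TDS
and TL curves of a panelist are drawn *together*, preserving the
within-panelist coupling between sensation and liking that the model is
supposed to learn. Draws are independent across conditions (the seed is
offset per condition). Replicates are pointwise convex combinations of
panelist curves, hence contained in the panel envelope — another tested
invariant, as is the convergence of the replicate grand mean to the panel
mean. This is augmentation, not uncertainty quantification: bootstrap
replicates understate the variability of an independent consumer
population.

## Input encoding

Model inputs are the 12 attribute channels, passed through bit-exactly,
plus one of eight blocks of constant 0/1 auxiliary channels
(`aux_config_names`, auxiliary dimension 0–7, total input 12–19):

* `combo` — one flag: is this a cracker–spread pairing?
* `cracker_spread` — cracker and spread presence; both 1 for pairings.
* `exclusive3` — cracker-only / spread-only / pairing, mutually exclusive.
* `brand` — one flag per product (premium cracker, sesame cracker,
  peanut, strawberry), set by ingredient presence.
* `brand_combo`, `brand_cs`, `brand_all` — the brand block combined with
  the blocks above, inheriting each block's own semantics.

For the 7-flag `brand_all` composite the cracker/spread/combination
sub-block could follow either the exclusive or the both-1 convention; the
exclusive convention is the default (`encoding_config(exclusive_composite
= FALSE)` switches). Flags are constant over the whole sequence: they are
context, not dynamics. A 64-row truth table (8 conditions × 8 encodings)
is kept as a fixture and checked exhaustively.

## The echo state network

`esn()` draws a reservoir once per fit and trains only the readout:

$$x(t) = (1-\alpha)\,x(t-1) + \alpha \tanh(W x(t-1) + W_{in} u(t)),
\qquad x(0)=0,$$

$$\hat y(t) = w \cdot [x(t);\,1].$$

Defaults, all exposed as arguments (only the reservoir sizes to compare
were externally given; the rest are conventional ESN settings):

| parameter | default | role |
|---|---|---|
| `n_neurons` | 128 | reservoir size; 64–256 is the compared range |
| `spectral_radius` | 0.9 | contraction of $W$ after rescaling; $<1$ gives the echo-state property |
| `leak_rate` | 1.0 | leaky-integrator rate in $(0,1]$; 1 = plain tanh update |
| `input_scaling` | 1.0 | half-width of uniform $W_{in}$ |
| `recurrent_density` | 0.1 | fraction of nonzero entries of $W$ |
| `input_density` | 1.0 | fraction of nonzero entries of $W_{in}$ |
| `ridge` | $10^{-6}$ | readout penalty $\lambda$ |
| `washout` | 0 | initial steps dropped per sequence |

Numerical conventions:

* $W$ is drawn sparse-uniform on $[-1,1]$ and rescaled so its largest
  eigenvalue magnitude equals `spectral_radius` exactly (verified to
  $10^{-6}$ by an independent eigenvalue computation in the tests). A
  zero-spectral-radius draw — possible only at tiny size × density — is
  redrawn with an incremented sub-seed, with a message.
* The state is reset to zero at every sequence start and no washout is
  discarded by default: sequences are short (101 steps) and all start
  from the same quiescent state, so early states carry signal rather than
  initialization artifacts.
* The readout is solved in closed form from the pooled normal equations;
  the ridge penalty applies to the bias coefficient too (this matches the
  pooled closed form; it is switchable in principle by centering, and at
  $\lambda = 10^{-6}$ the difference is negligible). Pooling makes the
  fit invariant to training-sequence order, which is tested.
* At $\lambda = 0$ a singular system raises an error advising
  $\lambda > 0$ rather than silently pseudo-inverting.
* Predictions are raw — *not* clipped to $[0,9]$ — and RMSEs are computed
  on raw predictions; `clip = TRUE` is available but off by default, so
  reported errors are not flattered by clamping.

## Evaluation protocol

`evaluate_architecture()` holds out one pairing at a time: a fresh
reservoir, a readout trained on the 700 curve sets of the seven other
conditions, and one RMSE per held-out replicate
($\sqrt{\text{mean}_t (\hat y - y)^2}$, 101 grid points). Summaries are
the median and IQR, using R's default type-7 (linear interpolation)
quantiles — the convention had to be fixed somewhere, and type 7 is what
an R practitioner computes by default; the tests pin it against an
order-statistics oracle.

The headline ranking statistic is the *pooled* median over the
concatenated $4 \times 100$ RMSE values of the four pairings (so the
"all pairs" column carries its own IQR); `pooling = "median_of_medians"`
gives the alternative reading. Ties in the ranking are broken by pooled
IQR width, then architecture label. One reservoir seed per architecture
is the default; pass different seeds to replicate.

## The synthetic panel generator

The generator exists so that every stage — curve building, resampling,
encoding, training, evaluation — is testable end to end. It emulates the
study layout exactly: 16 panelists × 8 conditions (2 crackers, 2 spreads,
4 pairings) × 2 tasks × 3 repetitions = 768 trials, 12 attributes, liking
buttons 1–9, and trial durations lognormal around 20 s for crackers and
pairings and 10 s for spreads with 15% coefficient of variation (only the
means were externally given; the lognormal and its CV are this package's
choice of a realistic positive duration model).

Dominance is generated by a semi-Markov process: episodes with
exponential dwell times (mean `dwell_mean_s`, 1.8–3 s depending on the
condition) whose attribute is drawn from the selection-probability vector
of the *phase* containing the episode's normalized start time. Phases
tile $[0,1]$ and encode the qualitative temporal structure of the study
foods: jam runs sour → wet → sweet with liking above 6 in the sweet
middle phase; crackers are dry/salty/sesame/wheat-like with liking below
6; pairings show spread attributes early and cracker attributes late,
with an earlier, higher liking peak. Liking presses arrive as a Poisson
process on normalized time (rate 10 per trial) after an exponential
initial delay with mean 10% of the duration — so the zero-before-first-
press rule is exercised — and score the hedonic weight of the currently
dominant attribute plus $N(0, 0.7)$ noise, rounded and clipped to 1–9.
Before the companion TDS trial's first press there is no dominant
attribute; the neutral scale midpoint 5 is used.

Two generator caveats. First, because episodes that start in one phase
carry their attribute across a phase boundary, empirical dominance
proportions near boundaries are a dwell-smoothed version of the phase
vectors; the frequency-convergence tests therefore use single-phase
profiles, where the identity is exact. Second, the generator deliberately
omits panelist-specific biases, fatigue, order and carryover effects, and
any chemistry-driven structure: passing tests show the *pipeline* is
correct and that the model can learn a dominance-to-liking map of this
kind — they do not certify prediction accuracy on real panels, and RMSEs
obtained on synthetic data are analogs, not reproductions, of values
measured on human data.

Determinism: one global seed expands to per-trial seeds through a counter
scheme, so a session is a pure function of (design, profiles, seed) and
any single trial can be regenerated in isolation. CSV writers emit
numeric columns with `%.17g`, so files round-trip bit-exactly through
their readers.

## Problem sizes used in the test suite

The suite validates at the study's native scale where that is what is
being claimed — the 768-trial session, 100 bootstrap replicates per
condition, 700-sequence training pools, and the full 32-architecture
sweep — and at reduced scale (4 panelists, 4–12 replicates) for
structural and oracle checks where size adds nothing. Monte-Carlo oracles
use 1 000 trials (selection frequencies, episode counts), 5 000+ presses
(liking histogram) and 5 000 bootstrap replicates (grand-mean
convergence) under fixed seeds.

## Known limitations

* Time normalization discards duration information (a cracker tasting is
  twice as long as a spread tasting); the model sees only normalized
  dynamics.
* Training requires curve data for all *other* pairings; the pipeline
  evaluates transfer across pairings, not prediction of a pairing from
  its components' solo curves.
* Bootstrap replicates recycle the same 16 panelists; they do not model
  an independent consumer population.
* A single readout maps all conditions; there is no per-condition
  recalibration beyond the auxiliary flags.
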