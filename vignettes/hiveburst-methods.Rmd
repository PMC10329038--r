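---
title: "Detecting collective bursts, pioneer bees and information flow in hive tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting collective bursts, pioneer bees and information flow in hive tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiveburst)
```

## The problem

Honeybee colonies intermittently fall into episodes of collectively
elevated locomotion — *bursts* — in which a large fraction of the hive
starts moving at once and then relaxes. `hiveburst` implements a complete
analysis chain for per-second individual tracking data (one row per
detected bee per second: position in pixels and a unit head-direction
vector) that

1. quantifies hive activity as kinetic energy,
2. detects bursts with Kleinberg's burst automaton,
3. detects the behaviors that surround bursts (waggle dances, dance
   following, foraging trips),
4. measures directed information flow between activity, dance and
   out-of-hive time series with effective transfer entropy,
5. extracts the *pioneer bees* that become active before each burst by
   nonnegative matrix factorization (NMF), and
6. asks whether pioneer membership converges over time using Jaccard
   distances, non-metric multidimensional scaling (nMDS) and a
   random-membership null.

Because per-second hive tracking datasets are rarely public, the package
also contains an agent-based synthetic hive (`simulate_hive()`) that
produces tracking tables with known ground truth for every one of those
detectors. All validation in the test suite runs against that generator.

## Activity and burst detection

The locomotor activity of bee $i$ at second $t$ is its squared per-second
displacement

$$K_i(t) = \Delta x^2 + \Delta y^2 \qquad [\mathrm{px^2/s^2}],$$

and hive activity $K_G(t)$ is the unweighted mean of the $K_i(t)$ defined
at $t$. Seconds where a bee is undetected at either endpoint are treated
as *absent*, not as zero: absence is the signal the trip detector feeds
on, and zero-filling would both dilute $K_G$ and invent stationary bees.
The averaging set therefore changes from second to second; we accept that
in exchange for robustness to tag loss and deaths.

The daily activity cycle is removed by subtracting a centered 12-h moving
average (`detrend_diurnal()`, window truncated at the series edges so the
series keeps its full length). Detrended values can be negative, but the
burst machinery interprets activity as an event *rate*, which must be
positive; `clamp_positive()` floors the series at $10^{-6}$ times the
mean of its positive part. The floor only touches values that are
effectively "no activity" and its exact size is immaterial — it exists so
the rate conversion below is defined everywhere.

Kleinberg's method consumes inter-event gaps. A rate series converts to
gaps by inversion: activity 1 is one event per second (gap 1 s), activity
10 an event every 0.1 s. We attach one gap per second ($x_t = 1/K(t)$)
instead of concatenating a realized event train, so the optimal state
sequence stays aligned with the clock — burst periods can then be read
off directly. The automaton itself (`kleinberg_levels()`) has states
$i = 0, 1, \dots$ emitting gaps as $\mathrm{Exp}(\bar\lambda s^i)$ with
$\bar\lambda = N/T$ the baseline rate; raising the level by one costs
$\gamma \ln n$, lowering is free, and the minimum-cost sequence is found
exactly by dynamic programming. We use the conventional $s = 2$ (a level
increment per rate doubling) and $\gamma = 1$. The test suite checks the
DP against exhaustive branch-and-bound minimization on hundreds of random
instances; the dynamic program is exact, so the two must agree to
rounding.

A *burst* is a maximal run with level $\ge 1$; its peak is the maximum of
the detrended series inside the run (earliest second on ties — ties are
measure-zero on real data, so the rule only matters for synthetic
constants). Bursts intersecting a recorded glass-cleaning time
(± 300 s by default) are flagged artificial and excluded from everything
downstream. Inter-burst intervals are peak-to-peak differences of
consecutive spontaneous bursts, because the NMF windows are also anchored
on peaks; `fit_ibi_powerlaw()` fits them with the continuous maximum
likelihood estimator (closed-form exponent per candidate cutoff, cutoff
chosen by minimal Kolmogorov–Smirnov distance, goodness-of-fit by
semi-parametric bootstrap with 1000 replicates by default).

## Behavioral detectors

**Waggle dances.** At 1 Hz, a dancing bee reverses its heading by more
than 90° nearly every second, alternating left and right. A 5-second
window qualifies when all four successive heading dot products are
negative and the signs of the four scalar cross products strictly
alternate; windows merge into events. Five samples give exactly four
products, so "at least four reversals in five seconds" means *all* of
them. A zero cross product (collinear headings) carries no turn
direction and breaks the alternation; numerically, anything below
$10^{-9}$ counts as zero.

**Dance followers.** A follower must stay within 600 px (about one bee
length) of a dancing bee with its head direction within 90° of the
direction to the dancer, for at least 3 consecutive detected seconds.
The containment of every follow event in its dance event is enforced by
construction and re-checked as a test invariant.

**Trips.** The tracking covers only the inside of the hive, so being out
of hive is an absence. A trip is a detection gap of at least 60 s
beginning after the entrance opened; shorter gaps are treated as tracking
dropouts and gaps before opening as tracking loss. This absence rule is
the largest inferential gap relative to an instrumented exit tunnel, and
`min_gap` is deliberately exposed: lowering it recovers shorter trips at
the cost of counting dropouts as trips.

**Foragers and orientation flights.** Young bees make exploratory
orientation flights before they forage. A bee's first *foraging* day is
the first calendar day (wall clock, from the trial metadata) with at
least six trips of which more than 25% departed before noon; all earlier
trips are orientation flights. Note this rule is not monotone under
arbitrary additions of trips — extra afternoon departures can disqualify
a day by diluting its before-noon fraction — so the corresponding
property test only asserts the direction that does hold (before-noon
additions never delay the day). The simpler discard-the-first-six-flights
rule is available as `method = "first_six"`. Per burst, the foragers
$F_b$ are bees re-entering 600–1000 s before the peak (non-orientation
trips only), and dancers $W_b$ / followers $DF_b$ are bees with an event
overlapping the 1000 s before the peak.

## Effective transfer entropy

Directed dependence between binned series is measured with plug-in
Shannon transfer entropy (history lengths $k = l = 1$, base-2 logarithm,
so units are bits). The plug-in estimator is biased upward in finite
samples; the *effective* transfer entropy subtracts the mean TE over 300
surrogates in which the source series is fully time-permuted, and the
empirical p-value uses the add-one convention
$p = (1 + \#\{\text{shuffled} \ge \text{observed}\})/(1 + 300)$.

Real-valued series are symbolized into $q = 3$ equiprobable bins by
empirical quantiles, ties to the lower bin (so a count series with many
zeros keeps all zeros in one symbol; a constant series degenerates to one
symbol and zero TE). The binning is the one knob of this module with no
canonical value; it is exposed as `q` everywhere. Note that quantile
binning spends its resolution where the data mass is: for strongly
bimodal series (long quiet baseline plus rare excursions) the bin edges
fall inside the quiet mode and part of the alphabet encodes noise. This
is a known cost of equiprobable binning and the reason the group-flow
validation scenario uses strong, well-separated activity pulses.

`kdo_scan()` applies this machinery to the K/D/O triple — mean hive
activity, distinct dancers per bin, distinct out-of-hive bees per bin —
across bin widths of 2, 5, 10, 30 and 60 min, reporting net flows
$ETE_{X \to Y} - ETE_{Y \to X}$ with significance stars. `group_flow()`
does the same for mean-activity series of disjoint bee groups (e.g.
foraged pioneers vs. everyone else).

## Pioneer extraction by NMF

For each spontaneous burst, the window matrix $A$ holds $K_i(t)$ for
every bee over `peak ± half_width` seconds. The default half-width is
1000 s, about half the smallest inter-peak interval seen in week-long
trials; the principle — half the minimum inter-peak spacing, so windows
never straddle a neighbouring burst — is what generalizes, and dense
synthetic burst trains use correspondingly smaller windows (170 s for 20
bursts in 2 h).

$A \approx G B$ is factorized with Kullback–Leibler multiplicative
updates ($G$: time courses, columns; $B$: bee memberships, rows),
implemented in C++ for speed, with $\varepsilon$-floored denominators so
all-zero rows and columns are harmless. The updates provably never
increase the loss, and the per-iteration loss trace is returned so tests
can verify it. Defaults follow standard practice for this estimator: 500
iterations, best of 50 uniform-random restarts.

The rank is chosen by consensus clustering: per candidate rank
(2–10), several factorizations from random starts each assign every bee
to its dominant basis; the co-assignment frequencies form a consensus
matrix, and the cophenetic correlation between consensus distances and
their average-linkage dendrogram measures stability. The chosen rank is
the one preceding the first drop of that coefficient (argmax if it never
drops). Because the consensus from finitely many runs is itself noisy,
drops smaller than `tol = 0.005` count as plateau — without this, a
sub-millesimal dip at the true rank truncates the search one rank early.

Pioneers are then: bees whose dominant basis has its time-course maximum
strictly before the burst period's onset, minus any bee whose
reconstructed activity ($GB$ column) never reaches the mean entry of $A$
(the amplitude filter, which removes near-idle bees attached to a
pioneer basis by noise). Two readings of the amplitude reference are
defensible; the matrix mean is the default and a per-bee mean is
available via `amplitude_ref = "bee"`. When several bases peak
pre-onset, all contribute pioneers by default (`earliest_only = TRUE`
restricts to the first).

## Burst similarity and the convergence question

The pioneer-bee binary matrix (bees × bursts) induces Jaccard distances
between bursts, $d(a,b) = 1 - |P_a \cap P_b| / |P_a \cup P_b|$; bursts
with empty pioneer sets are excluded. `nmds_embed()` wraps Kruskal
non-metric MDS (stress-1, monotone regression, via `vegan::monoMDS`)
with random restarts until stress < 0.2; an embedding that misses the
target after all restarts is returned flagged.

"Variance within the MDS space" is made precise as the mean squared
Euclidean distance of a burst subset to its centroid (the sum of
per-coordinate population variances). The null model resamples each
burst's pioneer set uniformly from the roster with its original
cardinality and reruns the *entire* pipeline — distances, a fresh
embedding, dispersion — 500 times. All 500 draws enter the null: random
sets produce near-uniform distance matrices whose attainable stress often
exceeds 0.2, and discarding those draws would bias the null toward its
accidentally structured members (non-convergence counts are reported in
an attribute instead). Observed below the null's 5th percentile is the
operational meaning of "late pioneer membership is more similar than
chance".

Group comparisons use the Brunner–Munzel rank test (no normality or
equal-variance assumptions; Satterthwaite-type degrees of freedom;
reported alongside the stochastic-superiority estimate
$\hat p = P(A<B) + \tfrac12 P(A=B)$). The test suite validates the
t-approximated p against the exact permutation distribution of the
studentized statistic, which for tie-free data depends only on how sorted
positions split between groups and can therefore be fully enumerated.

## The synthetic hive

`simulate_hive()` is a 1-Hz agent-based model on the real arena geometry
(6576 × 4384 px). Its purpose is narrow: to produce data with exactly the
statistical structure the detectors assume, plus ground-truth labels.
Passing tests on it show the pipeline recovers what it is designed to
recover; they do not show the generator reproduces real hive biology.

* **Locomotion.** Agents are correlated random walks: heading turns by a
  Gaussian step each second (SD 0.3 rad quiet, 0.6 rad active) and the
  agent advances by a half-normal step along its heading (scale 2 px/s
  quiet, 30 px/s active — roughly body lengths per second for an excited
  bee, with a bee ≈ 600 px). Persistent headings matter: real bees do
  not reverse orientation by >90° every second, so quiet walkers
  essentially never trigger the dance detector (its false-positive
  budget is 0.01 events per bee-hour).
* **Contact activation.** A quiet agent with at least
  `activation_threshold` active agents within 600 px becomes active with
  probability `p_contact_activation` per second; active agents revert
  after an Exp(60 s) holding time and are then refractory for Exp(300 s).
  The refractory period is what lets cascades die out: without it, any
  reverted agent is instantly re-activable and a single ignition locks
  the colony into permanent activity.
* **Scripted behavior.** Dances are alternating ±(180° − 10°) turns (the
  detector's criteria hold by construction); followers ride at a fixed
  150–400 px offset facing their dancer; trips are literal removals from
  the table with re-insertion at the entrance in an excited state.
  Emitted headings carry small Gaussian jitter so detectors face noise.
* **Planted bursts and pioneers.** A planned event pre-activates a known
  pioneer set `lead` seconds early and then activates a mass of
  currently-quiet agents (an already-active agent cannot be "activated",
  which also keeps the planted pioneers' activity profile peaked in the
  lead window, as a pioneer group's should be).

Five presets (`preset_config()`) cover the validation scenarios: `null`
(nothing happens), `contact_cascade` (rare spontaneous ignitions,
calibrated to 3–8 spontaneous bursts per 2 h at 100 bees),
`forager_driven`, `dance_demo`, and `pioneer_recovery` (20 planned
bursts with 20-bee planted pioneer groups, 60 s lead).

The `forager_driven` preset deserves its own paragraph because it is the
ground truth for the *direction* of information flow. Twelve return
events (~540 s apart, jittered) bring a fixed 15-bee forager group back
to the entrance in an excited state for a fixed 150 s, seeding contact
cascades through the colony. Three choices make the planted coupling
strictly one-way and reliably detectable: the foragers are
contact-immune (otherwise cascades genuinely re-excite them and a
backward channel exists by construction, not by estimator error); their
post-return excitation is fixed rather than exponential (an early
reversion sometimes fails to ignite any cascade); and events are spaced
beyond the refractory tail (closer events meet a colony still recovering,
which both weakens the forward cascade and makes the colony's state
informative about the next return — a real backward signal). Even so,
the "backward flow not significant" check is an $\alpha = 0.05$ test
under a true null and fails for about 1 seed in 20 by design; the
validation criterion (16 of 20 seeds) accommodates that floor.

What the generator does *not* emulate: comb geometry and task zones,
trophallaxis, pheromone fields, circadian modulation of individual state
(a sinusoidal activity modulation is available to exercise the detrend,
off by default), realistic densities (100 agents in the full arena is
much sparser than 1000 bees in a real observation hive), and any
coupling between dancing and subsequent foraging. Conclusions drawn from
it concern the pipeline's recovery ability only.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run simulations of 100 bees
for 7200 s (and smaller), diurnal-detrend windows of 1800 s on those 2-h
series, NMF windows of ±170 s around peaks spaced ~360 s apart, rank
search over 2–5 with 8 runs per rank and 200 iterations, and final
factorizations with 5 restarts and 300 iterations. These sizes were
chosen so the planted structure in each scenario is comfortably
recoverable while a full validation pass stays in the minutes range;
week-long analyses at the 43200-s window, ±1000-s windows, rank 2–10,
500 iterations and 50 restarts are the package defaults and scale
linearly in bursts × restarts × iterations.

Other numerical choices, in one place: heading vectors with norm in
[0.99, 1.01] are renormalized on input, anything else is rejected;
cross products below $10^{-9}$ count as zero turn; the Kleinberg level
cap defaults to $\lceil \log_s(\max_t \lambda_t/\bar\lambda)\rceil + 1$;
the power-law cutoff scan caps candidates at 100 quantile-spaced unique
values; NMF denominators and the KL ratio are floored at $10^{-12}$;
Brunner–Munzel with two internally constant samples returns statistic 0
and $\hat p = 0.5$ (identical constants) or $\pm\infty$ and p = 0
(complete separation).

## Known limitations

* Trip inference from absence cannot distinguish a trip from a 60-s
  tracking dropout; with real data the `min_gap` choice should be
  validated against any available exit instrumentation.
* The discretization feeding transfer entropy is not part of the
  original method's description; net-flow *signs* are robust to the
  choice of `q`, but absolute ETE magnitudes are not comparable across
  different binnings.
* The amplitude filter's reference level ("mean of the window matrix")
  is one of several defensible readings; pioneer counts, though not the
  qualitative structure, depend on it.
* Rank selection is stochastic; with few runs per rank the cophenetic
  curve is noisy, which is why `tol` exists and why validation uses 8+
  runs per rank.
* The nMDS stress target (0.2) is a convention; embeddings of
  near-uniform distance matrices (e.g. random pioneer sets) often cannot
  reach it, which is handled by flagging rather than failing.
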