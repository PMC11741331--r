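---
title: "Simulating detectable IBD segments around a locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating detectable IBD segments around a locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(ibdsegs)
```

## The model

Two haplotypes are identical by descent (IBD) over a segment when they
inherit it from a common ancestor with no intervening recombination on
either lineage. `ibdsegs` simulates the lengths of all IBD segments that
overlap one focal genomic position in a sample of `n` haploids, together
with each pair's time to most recent common ancestor (TMRCA). Two waiting
processes drive everything:

* **Coalescence.** Backward in time, each haploid picks a uniformly random
  parent among the `N(t)` haploids of the previous generation
  (Wright–Fisher reproduction); lineages that pick the same parent merge.
  For a pair, the TMRCA is geometric with success probability `1/N(t)` per
  generation; for `k` lineages the per-generation merger count is
  approximately `Binomial(choose(k,2), 1/N(t))`.
* **Recombination.** Under the homogeneous Poisson (Haldane) crossover
  model, the surviving segment length to one side of the locus after `t`
  meioses is `Exponential(t)` Morgans. Left and right are independent, so a
  pair with TMRCA `t` generations has one-sided shared length
  `Exponential(2t)` and total width `Gamma(2, 2t)` — old ancestry means
  short segments, which is what makes fast simulation possible.

A segment is *detectable* when its length reaches the threshold `w`
Morgans (0.01–0.02 M is typical for IBD detection methods). The simulator
is exact for the set of detectable segments: its output equals the
all-pairs computation on the same endpoint draws, which the test suite
asserts bit-for-bit against an independent path-minimum oracle
(`naive_oracle()`).

## The genealogy: three regimes

`simulate_tree()` switches between three ways of advancing the genealogy,
controlled by `regime_config()`:

1. **Exact Wright–Fisher parent sampling** when `k/N(t) > 0.1`
   (`binomial_max_ratio`). Sampling fractions this large occur in
   biobank-scale samples during the most recent generations, where the
   binomial approximation's neglected terms — of order `(k/N)^3` — are no
   longer negligible. Sibling groups of three or more are resolved into
   sequential binary mergers within the generation; the tree then contains
   zero-length internal branches, which draw no recombination endpoints
   (the `Exponential(rate -> 0)` limit puts a crossover at infinity).
2. **Binomial merger counts** otherwise: `X ~ Binomial(choose(k,2),
   1/N(t))`, truncated at `floor(k/2)`, with the `X` merging pairs drawn
   disjointly from the lineages present at the start of the generation so
   all events are binary. When the expected count drops below
   `binomial_min_expected` (default 1) inside a constant-size epoch, the
   loop skips ahead geometrically to the next generation with at least one
   merger and draws `X` conditional on `X >= 1`; this is distributionally
   identical to looping one generation at a time and much faster.
3. **Kingman tail** (optional, on by default) once
   `choose(k,2)/min_{s>=t} N(s) <= 0.05` (`kingman_max_expected`), i.e.
   coalescence is rare for *all* remaining time: waiting times are drawn as
   `Exponential(choose(k,2))` in rescaled time and mapped back to
   (continuous) generations through the inverse of
   `Lambda(g) = integral_0^g ds/N(s)`, computed in closed form per epoch.

An alternative reading of the switching rule — binomial whenever `k^3` is
*not* much smaller than `N^3` — inverts the validity argument; the package
follows the validity argument and keeps the inverted rule available as
`regime_config(pseudocode_rule = TRUE)` for comparison experiments. All three thresholds are tunable; their defaults
mark the `(k/N)^3 = 10^-3` accuracy scale.

A caveat the tests quantify: on the boundary of the validity region
(e.g. `k = 20`, `N = 200`) the exact-WF merger count includes three-child
sibling groups at rate `choose(k,3)/N^2 ~ 0.03` per generation, which a
binary-pairs binomial cannot produce, so the total-variation gap between
the two laws is ~0.03 there. Well inside the region (`k = 20`, `N = 500`)
the gap is below 0.01. The regime boundary trades this approximation error
against the cost of exact parent sampling, exactly as the hybrid design
intends.

## The IBD engine: shared draws, pruning, merging

`extract_detectable_ibd()` walks coalescent events in time order. Each
surviving lineage carries a record `(la, ra)` of its surviving extent
(Morgans) on each side of the locus, initialised to infinity. At an event
at time `tau`, **one** endpoint pair `(l', r') ~ Exponential(tau - v)` is
drawn per child branch (`v` the child's time) and caps every record under
that branch. Drawing per branch — rather than independently per descendant
— is deliberate: the shared draw is what makes two records' endpoints
*exactly* equal with positive probability, reproducing both the merging
mechanism and the correct dependence of IBD sharing across pairs. The
probability that the shared draw dominates on one side is `v/(2u + v)`
(`shared_endpoint_prob()`), and squares across the two independent sides.

Within an event the order is: update, then

1. **prune** records with `la + ra < w` — every pair such a record could
   join is bounded above by `la + ra`, so nothing detectable is lost;
2. **merge** records under the same child branch with bit-identical
   `(la, ra)` — exact floating-point equality is the correct test because
   equality can only arise by both records holding copies of the same
   shared draw, never by coincidence of independent exponentials;
3. **record** every cross pair (one record per child side), expanding
   merged records to all member pairs, emitting `length = min(la_1, la_2)
   + min(ra_1, ra_2) >= w` with `tmrca = tau`. Cross pairs only, so each
   haploid pair is compared exactly once, at its MRCA.

The walk stops early once at most one active record remains. With pruning
and merging disabled the engine performs exactly `choose(n,2)` record
comparisons, and the expected number of comparisons at the `j`-th
root-ward bifurcation of a random tree is `n(n-1) 4^{-j}`
(`expected_comparisons()`), which is why most comparisons — and hence the
savings — concentrate near the root, where ancestors are old and segments
almost surely undetectable.

Endpoints are unbounded: there are no chromosome edges, so simulated
lengths can exceed any physical chromosome. Physical coordinates, variable
recombination maps and crossover interference are out of scope.

## Demography

A `demography()` is a set of half-open epochs tiling backward time, each
with a starting haploid size and a backward exponential rate
(`N(t) = size * exp(growth * (t - start))`; a forward-growing phase has
negative `growth` here). Sizes may jump at epoch boundaries. The last
epoch must be constant so the cumulative coalescent rate diverges.
`cumulative_rate()` and its inverse use the per-epoch analytic
antiderivative; for a constant epoch the inverse is exactly `N * lambda`.
All sizes are haploid internally; user-facing counts may be diploid and
are doubled on input.

Two built-in scenarios follow their verbal descriptions — a bottleneck
(ancestral 10,000 diploids, fixed exponential growth, instantaneous
reduction 20 generations ago) and three-phase growth (ancestral 5,000
diploids, three increasingly rapid phases). Their exact growth rates and
the reduction factor are not printed anywhere authoritative, so they are
builder parameters with defaults chosen to give a biobank-like present-day
size (~10^6 haploids for the bottleneck, ~10^6 for three-phase growth at
rates 0.10/0.02/0.005 over breaks at 20/100/300 generations); a YAML
demography file is the source of truth for any serious study.

## Selective sweeps

`sweep_trajectory()` models a hard sweep at the focal locus by the
deterministic logistic decay `p(t+1) = p(t)/(p(t) + (1-p(t)) e^s)`
backward from the present-day frequency `p0`, stopping at the first
generation where `p(t) <= 1/N(t)` (one haploid copy; a diploid convention
is available). The functional form is the standard deterministic genic
selection trajectory; a user-supplied table of `p(t)` is accepted since
implementations of sweep coalescents differ in this choice. The structured coalescent
(`simulate_structured_tree()`) then runs two classes with effective sizes
`N(t)p(t)` and `N(t)(1-p(t))` and no cross-class mergers until the
mutation time, where all surviving carrier lineages are forced into a
single ancestor that rejoins the neutral population. By default the number
of sampled carriers is `Binomial(n, p0)`; an explicit split is accepted.
There is no recombination-driven migration between allelic classes — a
deliberate simplification relative to full ancestral-selection-graph
models. `s = 0` bypasses the structure entirely and is distributionally
identical to the neutral simulator.

## Reproducibility and randomness

One seed drives a run. The stream is consumed in a fixed, documented
order: the genealogy first, then one endpoint pair per branch for events
in time order (`child1` before `child2`, left before right). Zero-length
branches consume nothing. Because the draw log is generated identically
regardless of algorithm variant, `fast`, `prune_only`, `merge_only` and
`naive` runs at the same seed produce byte-identical segment tables — the
package's strongest self-check, asserted in the tests over hundreds of
random instances up to `n = 128` with mixed demographies and thresholds.

## What the tests do and do not show

The test suite exercises synthetic genealogies and draws generated by the
package itself under fixed seeds: closed-form values (expected coalescent
times; `(k/N)^3`; `v/(2u+v)`; `n(n-1)4^{-j}` against exhaustive
enumeration at `n = 4`), distributional laws (geometric pairwise TMRCA,
`Gamma(2, 2g)` widths, endpoint tails `e^{-gw}` and `e^{-gw}(1+gw)`, the
1/9 merge frequency in the three-leaf geometry with `u = v`), and the
exactness of pruning/merging. Monte-Carlo checks use 10^3–10^5 replicates
with three-standard-error bands (or stated p-value floors), sized so the
whole suite runs in a few minutes on one core; a separate
`scripts/smoke.R` exercises 8,000 diploids under the bottleneck scenario
(a couple of seconds with the fast algorithm). None of this validates the
model against real genotype data: detection error, phasing switches,
genotyping artefacts and variable recombination rate are all outside the
simulator's scope, and TMRCA accuracy is approximate by construction
wherever the binomial or Kingman approximations are active.

## Known limitations

* Single locus only — no ancestral recombination graph, no genome-wide
  segments.
* Segment lengths ignore chromosome boundaries.
* Genealogy times are approximate in the binomial and Kingman regimes
  (the regime discussion above quantifies where).
* The sweep trajectory is deterministic; stochastic (diffusion)
  trajectories, soft sweeps and background selection are not modelled.
* No migration or demes beyond the sweep's two allelic classes.
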