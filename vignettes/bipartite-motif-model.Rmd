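---
title: "The bipartite thermodynamic binding model behind bmf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bipartite thermodynamic binding model behind bmf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmf)
```

## The model

`bmf` describes an RNA-binding protein (or complex) with two cooperating
binding domains, A and B, each of which contacts a `k`-nucleotide core
(`k = 3` by default). For a sequence `x` of length `L` we sum the
statistical weights of *all* binding configurations — zero, one or many
proteins bound, each placement labelled A or B — rather than scoring only
the best site. This matters for RBPs, whose motifs are short and
degenerate: combinatorially many weak placements can add up to strong
binding, especially on repeat sequences. All energies are in units of
kBT, with kBT set to 1; the unbound configuration has weight 1, so the
partition sum satisfies `Z(x) >= 1` and

    p(bound | x) = 1 - 1/Z(x)

is a proper probability in `[0, 1)`.

Each domain owns a full table of `4^k` k-mer binding energies (no
positional factorization — RBP cores are short enough that the exhaustive
table is both tractable and more expressive than a PWM). Lower energy
means stronger binding; the Boltzmann factor of a placement on k-mer `m`
is `exp(-E(m))`.

Cooperativity is carried by the *effective concentration* of domain B at
distance `d` nucleotides downstream of a bound A:

    cB(d) = cAB + S * NB(d; r, p)

where `NB` is the negative binomial pmf
`choose(d + r - 1, d) p^r (1 - p)^d`, evaluated through log-gamma so that
non-integer `r` is handled stably. The constant `cAB` is the free-protein
concentration; only the ratio `S / cAB` is identifiable, so `cAB` is
fixed to 1 and `(S, r, p)` are learned. A spacer distribution
concentrated at `d = 0` describes a single contiguous motif of length
`2k`; mass at `d > 0` describes genuinely bipartite binding.

## Dynamic programming and its conventions

`forward_partition()` computes `Z(x)` in `O(L^2)` with two state
families: `ZA(i)` (all configurations on the prefix up to `i` whose last
placement is an A ending exactly at `i`) and `ZB(i)` (nothing bound at
`i`, or a B ending at or before `i`). A B immediately following an A is
always that A's partner and is weighted by `cB(d)`; a B following
nothing or another B is a free placement at concentration `cAB`. The
boundary convention `ZA(i) = 0`, `ZB(i) = 1` for all `i < k - 1`
(including negative indices) makes the empty prefix carry weight 1, and
both placements occupy exactly `k` nucleotides, so all recursion offsets
equal the core length.

These conventions imply two grammar corner cases that are worth stating
explicitly: a *free* B never immediately follows an unpaired A, and a
paired A–B admits no third placement between its cores. The brute-force
oracle `enumerate_partition()` enumerates configurations under exactly
this grammar, and the test suite checks DP-vs-enumeration agreement to a
relative `1e-9` on hundreds of random (model, sequence) pairs with
`L <= 14` — small enough that the enumeration (thousands of
configurations) is itself trustworthy.

Numerical choices:

* Arithmetic is in linear space. Initial energies near 12 kBT keep
  Boltzmann factors ~`6e-6`, far from overflow. As a guard for extreme
  trained models or very long inputs, every per-position statistical
  weight is deterministically capped at `1e250`; the `overflow` flag on
  the result reports saturation (capped entries also zero their
  derivative rows). In practice the cap is unreachable during normal
  training.
* Any k-window containing a character outside `ACGU` (after `T -> U`
  mapping and case folding) contributes weight 0 — infinite energy —
  so genomic inputs with `N`s are scoreable rather than rejected.
* The k-mer index is lexicographic base-4 with `A < C < G < U`,
  everywhere, including the model file.

## Likelihood and gradients

With background fractions `p_bg(x)` (empirical multiplicities of the
input library) the probability of observing `x` among the selected
sequences is `p_bg(x) p(bound|x)` normalized over the library, giving

    LL = sum_{x in X+} [ln p_bg(x) + ln(1 - 1/Z(x))]
         - N+ * ln sum_{x'} p_bg(x') (1 - 1/Z(x'))

The `ln p_bg(x)` term is constant in the parameters and is dropped
during optimization (and by default in `log_likelihood()`): enriched
sequences need not occur verbatim in a finite background sample, where
their empirical fraction would be 0. `log_likelihood(...,
include_constant = TRUE)` adds it back when the enriched set is a subset
of the background.

Gradients with respect to every energy and the unconstrained spacer
parameters are obtained by differentiating the DP recursions themselves
and propagating derivative arrays alongside the forward pass
(`model_gradient()`); nothing is numerically differentiated. The suite
verifies analytic gradients against central finite differences (step
`1e-5`, relative tolerance `1e-4`) on random small instances.

## Optimization

Training (`bmf_train()`) is stochastic gradient *ascent* with ADAM at
its defaults (`alpha = 0.01`, `beta1 = 0.9`, `beta2 = 0.999`,
`eps = 1e-8`) and minibatches of 512 sequences, drawn without
replacement within an epoch and reshuffled between epochs. To keep
`r > 0`, `p` in `(0, 1)` and `S >= 0`, the optimizer works on
`rho = ln r`, `pi = logit p` and `ln S`.

The likelihood normalizer is computed over a per-iteration background
minibatch of the same size as the enriched minibatch, with uniform
weights. This is a stochastic approximation of the full-background
normalizer that keeps the iteration cost proportional to the batch size;
reported final likelihoods use the full background.

Initialization: energies i.i.d. Normal(12, 1) kBT (the scale of measured
RBP binding energies, and small Boltzmann factors at the start),
`S = 10^4`, `r ~ U(1, 5)`, `p ~ U(0, 0.5)`.

Stopping: training halts at 1000 iterations, or earlier when the
variation `v = (max - min) / |last|` over the last five *recorded*
values of each of four tracked statistics — the minimum energy of each
core table and the spacer's `r` and `p` — falls below 0.03. Statistics
are recorded every `record_every = 10` iterations: with ADAM's 0.01 step
size a statistic near 12 kBT cannot move by more than ~0.05 across five
*consecutive* iterations, so a per-iteration window would satisfy the
0.03 criterion immediately, far from any optimum; spacing the snapshots
ten iterations apart makes the variation measure the actual plateau. The
absolute value in the denominator keeps the rule meaningful when a
tracked energy crosses zero.

## The synthetic benchmark

`make_benchmark()` emulates an idealized one-round selection on a random
oligomer library, the setting the model is designed for: 2000 background
and 2000 enriched sequences of 40 nt (the library design the method
targets), i.i.d. uniform nucleotides. Each enriched sequence receives
one implant — core A (`AAA`), a gap of `d` untouched background letters
with `d ~ NB(r = 4, p = 0.4)` (mode 4 nt, mean 6 nt; the same family the
binding model assumes, enabling clean parameter-recovery tests), then
core B (`CCC`) — at a uniformly random feasible position, overwriting
the letters so lengths stay fixed. Degenerate motifs are emulated by
passing several core variants, sampled uniformly.

What the generator deliberately does *not* emulate: multiple selection
rounds, PCR/sequencing bias, secondary structure, partial enrichment
(every enriched sequence carries an implant), or heterogeneous sequence
lengths. Passing the recovery tests therefore demonstrates correctness
of the estimator under the model's own assumptions, not robustness to
the many confounders of real selection or CLIP data.

## Post-hoc motif statistics

* `boltzmann_probs()` converts a core's energies to k-mer probabilities
  `exp(-E)` normalized to 1 (computed after subtracting the minimum
  energy); `top_kmers()` renormalizes the top five for display, breaking
  ties lexicographically.
* `spacer_distribution()` reports the normalized NB pmf and
  `P(d > 0) = 1 - p^r`; the constant `cAB` term is free protein, not a
  spacer length, and is excluded. The default tabulation extends to at
  least `d = 100` and always captures all but `< 1e-6` of the mass.
  `classify_bipartite()` thresholds `P(d > 0)` at 0.5 by default.
* `core_similarity()` is the Pearson correlation of the two cores'
  Boltzmann probability vectors (`NA` for a zero-variance vector).
* `motif_entropy()` marginalizes each core's k-mer distribution to
  per-position nucleotide distributions and averages the Shannon entropy
  (bits) over all `2k` positions; it is 2 for uniform cores and 0 for a
  point mass, and invariant under relabeling the alphabet. This
  positional-marginal definition is one of several reasonable
  complexity measures; it is isolated behind this one function so it can
  be swapped without touching anything else.
* `repetitiveness()` takes the 16 repeat units (4 mononucleotide, 12
  ordered dinucleotide), computes per core the probability mass on
  k-mers that are substrings of the unit's infinite repetition, and
  returns the maximum over units of the geometric mean of the two cores'
  masses — 1 when both cores sit entirely on the same repeat, 0 when no
  unit is compatible. Like the entropy, it is a declared definition kept
  behind its own function.
* `random_model_baseline()` draws freshly initialized models and
  records both statistics, giving the null distribution against which
  trained models are compared (random models sit near entropy 2 and low
  repetitiveness).

## Prediction

`predict_scores()` scores arbitrary-length sequences: up to the window
length (default 50 nt) the score is the binding probability of the whole
sequence; longer sequences are cut into windows at stride 20 starting at
position 0, plus a final right-anchored window ending at the last
nucleotide so that coverage is complete (anchoring rather than
truncation, since a shorter final fragment would not be score-comparable
with full windows); the score is the arithmetic mean over windows. The
score is `p(bound | window)` — any ranking metric is unaffected by the
choice between `p` and `Z` since both are monotone in `Z`.

## Problem sizes and reproducibility

The test suite exercises: DP-vs-enumeration on 200 random pairs
(`k` in 2–3, `L <= 14`); gradient checks on 20 random small datasets
(`k = 2`, up to 10 sequences of up to 20 nt); and parameter recovery and
restart robustness on a 500 + 500 benchmark with minibatch 128 — sizes
at which training converges in a few hundred iterations while exhibiting
the same recovery behaviour as the full 2000 + 2000 default, which is
what `scripts/acceptance.R` runs. Every stochastic step (generation,
initialization, minibatch order) is driven by explicit seeds, and
training traces are bitwise reproducible for a fixed seed.

## Known limitations

* Exactly two cooperating domains; higher oligomeric states are only
  captured implicitly through multiple bound proteins.
* No RNA secondary structure: energies depend on sequence alone.
* One selection round is modelled; multi-round enrichment is
  approximated by training input vs. final round.
* The `O(L^2)` DP is exact but quadratic; scoring megabase transcripts
  should go through the windowed predictor rather than whole-sequence
  partition sums.
* Protein concentration is not a free parameter (`cAB = 1`); absolute
  binding probabilities are therefore on a model scale, and only
  comparisons between sequences are meaningful.
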