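# bmf — bipartite motif discovery for RNA-binding proteins

Many RNA-binding proteins (RBPs) contact RNA with two cooperating
RNA-binding domains — either two domains on one chain or a dimer — so
their specificity is not a single motif but a *pair* of short, often
degenerate sequence cores with a preferred linker length between them.
`bmf` learns such bipartite motifs de novo from an enrichment experiment
(e.g. SELEX-type selection): an *enriched* set of bound sequences and a
*background* (input library) set.

## Model

A protein with domains A and B binds a sequence `x` in many alternative
configurations of zero, one or more proteins. Each configuration `c` has a
statistical weight `exp(-F(c))` (energies in units of kBT, kBT = 1); the
unbound configuration has weight 1. The partition sum

```
Z(x) = sum over all configurations of exp(-F(c))
```

is computed exactly by dynamic programming over all placements of
k-nucleotide cores, and the probability that `x` is bound is

```
p(bound | x) = 1 - 1/Z(x).
```

Each domain carries one binding energy per k-mer (two tables of `4^k`
energies, default `k = 3`). Cooperativity enters through the effective
concentration of the downstream domain B at linker distance `d` from a
bound A:

```
cB(d) = cAB + S * NB(d; r, p),   cAB = 1 fixed,
```

a scaled negative binomial whose parameters `(S, r, p)` are learned along
with the energies. Training maximizes the likelihood that the enriched
sequences were drawn from the background by binding-probability-weighted
selection, by stochastic gradient ascent (ADAM) with analytic gradients
propagated through the DP.

## Worked example

Generate a synthetic benchmark with an implanted bipartite motif
(`AAA`, then a negative-binomially distributed gap with mode 4 nt, then
`CCC`), train, and summarize:

```r
library(bmf)
cfg <- synthetic_config(n_enriched = 500, n_background = 500, seed = 11)
dataset <- make_benchmark(cfg)
fit <- bmf_train(dataset, k = 3,
                 config = train_config(minibatch_size = 128, rng_seed = 5))
motif_summary(fit$model)
```

```
Bipartite motif summary (k = 3)
  classification: bipartite (P(d>0) = 0.982)
  core similarity 0.001 | entropy 0.265 bits | repetitiveness 0.111
  core A top k-mers:
    AAA  0.988 ########################################
    CCC  0.004
    CAA  0.003
    CAC  0.003
    GCC  0.003
  core B top k-mers:
    CCC  0.979 #######################################
    AAA  0.013 #
    GCA  0.003
    AAG  0.002
    ACC  0.002
  spacer: mode 4 nt, P(d>0) = 0.982, tail mass 0
```

Both implanted cores are recovered as the minimum-energy k-mer of their
table (energies rendered as Boltzmann probabilities of the top five
k-mers, renormalized to 1), the learned spacer distribution peaks at the
implanted 3–5 nt linker, and the model is called bipartite because the
probability of a spacer longer than 0 is 0.98. The low entropy (0.27 bits
per position vs. ~2 for a random model) reflects the single dominant
k-mer per core.

Trained models score new sequences with `predict_scores()` (sliding
window of 50 nt, stride 20, scores averaged across windows), and persist
losslessly as JSON via `write_model()` / `read_model()`.

## Command line

A launcher is installed at `system.file("exec", "bmf", package = "bmf")`:

```sh
bmf generate --out-enriched enr.fa --out-background bg.fa --seed 1
bmf train    --enriched enr.fa --background bg.fa --out model.json --seed 1
bmf visualize --model model.json
bmf predict  --model model.json --sequences peaks.fa --out scores.tsv
```

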