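---
title: "Scoring gene-set association by network proximity: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gene-set association by network proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`riddler` decides whether two gene sets are functionally associated by
asking whether they sit close to each other in a weighted functional gene
network. This vignette documents the statistical model, every tunable
parameter, the synthetic data the package trains and validates on, and the
design decisions taken where more than one reasonable choice existed.

## The network model and its assumptions

The substrate is an undirected graph over gene identifiers with strictly
positive edge weights interpreted as evidence strength. Self-loops are
dropped at construction and duplicate edges keep their maximum weight, so
the object is invariant to how the edge list was assembled. Genes are
opaque case-sensitive strings; identifier mapping is deliberately out of
scope. A gene set may contain members absent from the network: they are
kept in the set object but excluded from every network computation, and
the `query_coverage` feature reports the loss — the method's accuracy is
intrinsically limited by network coverage.

*Centrality* here always means weighted degree (the sum of incident edge
weights); set centrality is the mean over in-network members.

## Diffusion

Connectivity between a seed set and the rest of the network is measured by
a random walk with restart. With \(\hat W\) the normalized adjacency and
\(Y\) uniform mass \(1/|\text{seed}|\) on the in-network seed genes, the
iteration

\[ F \leftarrow (1-r)\,\hat W F + r\,Y \]

is run to its fixed point, the unique solution of
\((I-(1-r)\hat W)F = rY\). Parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `restart` | 0.5 | fraction of mass re-injected at the seed per step (dimensionless, in (0,1]) |
| `tol` | 1e-9 | max absolute change between iterations at convergence |
| `max_iter` | 1000 | iteration cap; non-convergence is flagged, not hidden |
| `normalization` | `"symmetric"` | \(D^{-1/2} W D^{-1/2}\); `"row"` gives the plain random walk \(D^{-1}W\) |

The restart of 0.5 makes the iteration a contraction with rate 0.5, so the
fixed point is reached in ~30 iterations at the default tolerance; unit
tests verify equality with the direct linear solve to 1e-8 on networks of
up to 200 nodes. Seed mass is uniform per seed gene so profiles are
comparable across seed sizes, and diffusion is exactly linear in the seed
indicator. Genes in components disjoint from the seed score exactly 0 and
tie at the bottom of the ranking.

One subtlety is worth recording. Under *symmetric* normalization,
increasing the weight of the single edge leading to a gene on a bare path
does **not** monotonically increase that gene's score: the \(D^{-1/2}\)
factors cancel the raise and the induced degree imbalance can lower it.
The monotonicity one intuitively expects of "strengthening the only path"
holds for the row-normalized walk, and the package's property test pins it
there. Symmetric normalization remains the default because it is the
standard, well-characterized choice for guilt-by-association diffusion and
is symmetric in seed and terminal roles.

## Recovery statistics and their confounds

Recovery of a terminal set from a diffusion ranking is summarized two
ways. The AUC is computed as the Mann–Whitney statistic on midranks
(identical to the trapezoidal ROC area; ties count one half). Average
precision sorts the \(k\) in-network terminal genes by ascending rank and
takes \(\mathrm{AP} = \frac1k \sum_{i=1}^k i/\mathrm{rank}_i\).

Neither is a neutral measure. On random recovery tests — random seed sets
predicting terminal sets of varying size and centrality — AP rises
strongly with terminal-set size (in the limit where the terminal set is
the whole universe, AP is 1 by construction) while AUC stays at chance;
and AUC rises with terminal-set centrality, because central genes earn
diffusion mass from anywhere. `recovery_confound_survey()` reproduces both
trends on the synthetic world, and the test suite asserts their signs. A
size-normalized AP (`normalize = TRUE`) is available as a diagnostic but
is deliberately not a model feature. Rather than correcting the measures,
the combiner is given size, centrality, and coverage as covariates and
learns their effect.

**Seed-exclusion convention.** When seed and terminal sets overlap, the
shared genes stay in the ranking (they are legitimate recovery targets and
take the top ranks they earn); seed genes *not* in the terminal set are
removed, since they are not candidates. This convention makes
overlapping-subset tests behave sensibly and is pinned by tests; it is the
main place where a different convention would silently change results.

## Local extension

The neighbor score of a gene outside `s1` is the summed weight of its
edges into `s1`. The set is extended by its top-scoring neighbors up to

\[ LE_n = \min(\lfloor \alpha n \rfloor, \beta), \]

with defaults \(\alpha = 0.8\), \(\beta = 100\): proportional to the set's
in-network size \(n\), capped to avoid extending into non-specific hub
neighborhoods. The floor is taken with a small epsilon guard and the
result is floored at one gene. If the gene at the cutoff boundary ties in
score with excluded genes, all tied genes are admitted and the result is
flagged `breached` — membership must not depend on arbitrary tie order.
Within the reported `added` list, order is descending score then
lexicographic gene id, so results are bit-for-bit deterministic. The
extended set is then re-tested against `s2` with the hypergeometric tail
on the network universe; a zero-gene extension reproduces the plain test
exactly.

## The combiner

Each query–pathway pair yields 13 features: the log hypergeometric
p-value; log LE p-values in the forward (query extended) and reverse
(pathway extended) directions; AUC and AP in both diffusion directions;
query, pathway, and overlap sizes (in-network counts); query and pathway
mean centralities; and query coverage. Log p-values are floored at
log(1e-300) to avoid infinities.

These feed a radial-basis SVM with class weights
\(w_1 = 1\) (matched) and \(w_0 = 0.3\) (mismatched — the mismatch class
is several-fold larger), cost \(C = 10^9\), termination tolerance 0.01,
and kernel width \(\gamma = 0.07\). Features are z-scored on the modeling
split before training — an RBF kernel on features spanning twelve orders
of magnitude is meaningless otherwise — and the scaling is stored inside
the model so scoring is reproducible. Data are split 25/25/50 into
modeling, cross-validation, and final validation per class; the reported
accuracy and the score distributions used for the FDR come from the final
validation split only. The association score (RAS) is the signed SVM
decision value, oriented so that higher means more match-like; a
probability calibration was considered and rejected because ranking, not
calibrated probability, is the downstream use.

**Empirical FDR.** With \(\bar P(s)\), \(\bar N(s)\) the fractions of
positive and negative validation scores at or above \(s\) (each
distribution area-normalized to 1, ignoring the much larger prior
probability of a negative match), the raw FDR is
\(\bar N/(\bar N + \bar P)\). Finite validation samples make this ratio
locally non-monotone, so it is smoothed with isotonic regression over the
pooled score grid to be non-increasing in \(s\), clamped to \([0,1]\), and
evaluated as a right-continuous step function; above all observed scores
the FDR is 0, below all of them it is 0.5.

## The synthetic world

Training and benchmarking run on a planted-partition world whose defaults
define the package's study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_modules` | 30 | planted functional modules |
| `module_size` | 25 | genes per module |
| `n_background` | 500 | genes outside every module |
| `p_in` / `p_out` | 0.25 / 0.01 | within/between edge probability |
| weights | log-normal(0, 0.5) | right-skewed positive evidence weights |

This yields roughly 1,250 genes and 10,000 edges — large enough that
the three regimes are statistically non-trivial, small enough that a full
train-and-benchmark cycle runs in well under a minute. Test pairs are
drawn per module under three regimes: *overlap* (two independent draws of
half the module, expected overlap \(n/4\)), *disjoint* (a random
partition into halves differing by at most one gene), and *timesplit* (an
asymmetric 70/30 partition with the query on the small side, emulating
genes annotated only after a cutoff date — the hardest regime, kept as a
distinct tag). Centrality-matched random sets bin all network genes into
10 equal-width (not quantile) centrality bins and replace each template
member by a random draw from its bin, preserving size and approximate
centrality while destroying module structure.

The training corpus contains, per module and regime, one matched pair
(positive); per query, ten mismatched known subsets from other modules;
plus one centrality-matched random set per module paired with a random
real module. All generators are pure functions of their parameters and a
seed.

What the synthetic world does *not* emulate: overlapping/nested pathway
hierarchies (real libraries contain siblings that are legitimately hard to
distinguish), scale-free degree structure, hub genes shared across many
modules, and annotation bias where well-studied genes are both central and
over-annotated. Passing benchmarks here therefore demonstrates the
machinery — that diffusion recovers planted structure, that the combiner
integrates its components correctly and beats each alone on disjoint
splits — not performance levels on real pathway databases, which are
harder in exactly the ways this world is clean.

## Benchmark accounting

In the subset-matching benchmark each module's query is ranked against
every module's known subset by each method: the RAS; the hypergeometric
test (ascending p); LE-only (ascending reverse-direction p); and RD-only
(descending reverse-direction AUC or AP). A module counts as *matched*
only when its own subset's midrank is exactly 1. Midranks matter: in the
disjoint regime every overlap is empty, all hypergeometric p-values tie
at 1, and with midrank accounting the hypergeometric correctly registers
zero perfect matches rather than winning ties by list order. RAS ties in
`rank_pathways()` are broken by pathway id purely for output determinism.

## Numerical choices and degenerate inputs

- Hypergeometric tails are computed in log space via the stable
  distribution-function implementation; `k = 0` returns exactly 1.
- AUC errors out when the terminal set covers all or none of the ranking
  (the quantity is undefined), and AP when no terminal gene is present.
- An empty network after filtering, a gene set with no in-network member,
  and a malformed edge-list or GMT line are errors naming the offender;
  non-positive edge weights are rejected lines with a logged count.
- Weight renormalization before diffusion is exposed via the
  normalization option only; weights are otherwise taken as given.
- All stochastic functions accept a seed and restore the caller's RNG
  state, so library code never perturbs a user's session randomness.

## Known limitations

Association is only measurable for genes the network covers; sets wholly
outside it cannot be scored. The combiner is trained on synthetic worlds
by default — users applying it to a real network should retrain on pairs
drawn from that network (`train_on_world()` generalizes directly) rather
than reuse a shipped model. Extension is single-round by design; iterated
extension drifts toward hubs. And the RAS is a relative score: it orders
candidates within a library, and its absolute scale is only interpretable
through the attached empirical FDR.
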