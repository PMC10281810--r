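---
title: "Testing host-symbiont codiversification with cophylotrace"
author: "cophylotrace authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing host-symbiont codiversification with cophylotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Gut symbionts that are endemic to a host group — the motivating case is
bacteria found only in termite guts — can be transmitted along two routes:
vertically, from parent colonies to daughter colonies (in social insects via
proctodeal trophallaxis), and horizontally, between colonies or from the
environment. Sustained vertical transmission couples the diversification of
symbiont and host and leaves two signatures that can be read off
phylogenies: congruence between the host tree and the symbiont tree, and a
scarcity of host switches when the symbiont gene tree is reconciled with the
host tree. `cophylotrace` implements both readouts, the clade-extraction
step that precedes them, and a simulator that generates data with known
history so that every stage can be validated.

The intended user starts from (i) a rooted, time-calibrated host phylogeny,
(ii) rooted marker-gene trees of the symbionts, annotated per tip with host
species, environment and assembly contig, and (iii) the host-symbiont
association implied by which metagenome each sequence came from.

## Habitat-specific clades (TSCs)

`extractTscs()` reports the maximal clades of a marker-gene tree whose tips
all carry the focal environment label and that span at least `minSpecies`
distinct host species (default 10, inclusive; the threshold is a parameter
because reasonable analyses may count the boundary case either way).
Maximality is enforced top-down, so a reported clade is never nested in
another reported clade; host species are counted as distinct species ids,
not samples, because several samples may come from one species.
`matchTscs()` links clades found with different marker genes through
assembled contigs that carry sequences of both markers, resolving conflicts
by majority contig count and flagging exact ties rather than guessing.

## Three congruence statistics, one permutation scheme

All three tests compare a host tree and a symbiont tree connected by a
binary association; hosts without symbionts in the clade under test are
pruned first, since split-based comparisons require matching leaf sets and
the paired-distance comparison is only defined over linked tips.

**Procrustes residual (PACo-style `m2`).** Both trees are turned into
patristic distance matrices and embedded by principal coordinates
(`pcoa()`); axes with negative eigenvalues — tree metrics need not be
Euclidean-embeddable — are truncated, the simpler of the standard
corrections. One row per association link is drawn from each embedding,
both configurations are centered, and the symbiont configuration is
superimposed on the host configuration by translation, orthogonal
transformation and scale, solved in closed form by singular value
decomposition. The residual sum of squares `m2` is the statistic (small =
congruent). Scaling is one-directional (symbiont onto host), which matches
the asymmetric host-drives-symbiont hypothesis; consequently `m2` is
invariant to rigid motions of either configuration and to rescaling the
symbiont configuration, but rescaling the host configuration rescales `m2`
trivially. The null randomizes the association by a backtracking fill that
preserves the row and column totals (the degree structure of the
interaction), restarting on deadlock.

**Clustering information distance.** An information-based generalization of
Robinson-Foulds: every non-trivial split contributes the entropy of its
bipartition, splits of the two trees are matched one-to-one to maximize
their mutual clustering information, and the distance is
`H(t1) + H(t2) - 2 * matched information` (bits). Similar-but-unequal
splits earn partial credit, which makes the statistic far less brittle than
plain RF on trees with reconstruction noise.

**Nye branch-alignment similarity.** Splits are matched one-to-one on a
Jaccard-type score: a pair of splits `A|A'`, `B|B'` scores the better of
the two side-pairings of `min` Jaccard overlaps. Identical topologies with
`k` non-trivial splits score `k` (1 after normalization).

Both split statistics solve their matching with an exact Hungarian
assignment, never greedily, so that brute-force enumeration on small trees
is reproduced exactly.

**Host-tip splitting.** The two split statistics need a one-to-one leaf
correspondence, but a host usually harbours several symbionts.
`splitHostTips()` replaces each host tip by a fan of zero-branch-length
tips, one per link. The fan is kept as a multifurcation rather than an
arbitrary binary resolution: a zero-length resolution would inject
arbitrary splits into split-based statistics.

**Permutations and p-values.** The null for the split statistics shuffles
which symbiont tips map to which hosts (the symbiont column of the link
list); both tree shapes are preserved and only the mapping is tested,
mirroring the PACo null. The direction of each test follows its statistic
(small `m2`/distance congruent, large similarity congruent), p-values use
the +1-corrected permutation estimator with ties counted as extreme, so the
smallest attainable p is `1/(nPerm+1)`. The user-facing default is 10 000
permutations; each of the three tests draws its own permutation stream.
Which quantity to permute for the split statistics is a genuinely open
design point (tip labels would be an alternative); shuffling the
association was chosen because it tests exactly the datum the association
table contributes, and it keeps all three tests under one null.

## Transfer rates by undated DTL reconciliation

`dtlLikelihood()` scores a symbiont (gene) tree against the host (species)
tree under an undated duplication-transfer-loss model. On each host branch
a gene lineage draws one event with probabilities `pS = 1/q`,
`pD = delta/q`, `pT = tau/q`, `pL = lambda/q`, `q = 1 + delta + tau +
lambda`. A transfer copies the lineage to a branch drawn uniformly among
branches not ancestral to the donor (self excluded, descendants allowed) —
the recipient rule is applied consistently in the extinction equations, the
inside recursion and the simulator. Extinction probabilities are solved by
fixed-point iteration from zero (converging to the minimal solution) to an
absolute residual below 1e-12 with a cap of 100 iterations; the
self-referential speciation-loss, duplication-loss and transfer-loss terms
of the inside probabilities are resolved with 5 Gauss-Seidel sweeps
(parameterized), enough that a truncated enumeration of event histories
reproduces the likelihood to better than 1e-6 at small rates. The gene root
placement is summed over host branches under a uniform prior. Inside rows
are renormalized when they become tiny, with the log correction accumulated
along the gene tree, so large incongruent gene trees do not underflow.
Rates outside the numerically valid regime of the fixed sweep count return
`-Inf` and are thereby excluded from optimization.

`estimateRatesML()` maximizes the likelihood over the three global rates
(per-branch rates are out of scope) with Nelder-Mead on a logistic-log
transform enforcing bounds `[1e-6, 10]`, from 4 seeded restarts. The
reported transfer rate is the fitted `tau`. It is the closest implementable
analogue of the transfer rates printed by ML reconciliation software; exact
numeric equality with any external program's normalization is not claimed.
`reconcileMP()` provides the parsimony counterpart (exact dynamic program
with loss-augmented descent) and is used to cross-check the model: in the
low-rate limit the most probable event assignment agrees with the
parsimony event multiset on congruent and single-transfer fixtures.

**The no-transfer baseline.** Non-recombining genes of the host itself
(mitochondrial genes in the motivating study) share one true history and
experienced no transfer, so any positive rate estimated for them measures
what phylogenetic reconstruction noise alone can produce.
`computeBaseline()` estimates the transfer rate for each replicate gene
tree and records the range; `classifyTsc()` calls a clade
`vertical_dominant` when its rate does not exceed the baseline maximum
(boundary inclusive — a rate of zero is vertical-dominant for any
baseline), and `transfer_elevated` otherwise.

## The simulator

`simulateCophylogeny()` is the package's ground-truth generator. One
symbiont lineage enters at the host root; at each host speciation a
resident lineage codiverges with probability `codivergence` (default 0.9)
or follows one daughter uniformly; along branches, duplication, loss and
host switching fire as Poisson processes (Gillespie next-event sampling
from a single seeded RNG stream; defaults 0.1 per lineage per unit
host-tree time each). A switch leaves a copy in the donor and moves a copy
to a contemporaneous non-ancestral host branch — a move-only switch would
be invisible to reconciliation, so switches are bifurcations, matching the
transfer definition of the estimator. Extant tips are then thinned with
probability `sampling` (default 0.8), emulating bacterial extinction or
insufficient sequencing depth, which real data cannot distinguish.
Reconstruction noise is modelled directly on trees by `perturbTree()`
(random NNI moves plus lognormal branch-length jitter with median 1) rather
than by simulating sequences — the defaults (2 NNI moves, log-sd 0.1)
represent the mild topological uncertainty of a well-supported marker-gene
tree. `makeBaselineReplicates()` applies independent noise to one true tree,
the synthetic analogue of a set of mitochondrial gene trees (15 in the
motivating design).

The defaults above are the package's study conditions; they aim at a
symbiont clade that mostly tracks its host. What the simulator does *not*
emulate: alignment and model misspecification biases (noise is topology- and
length-level only), within-host population processes, correlated sampling
across related hosts, and rate variation across lineages. Passing the
package's tests therefore shows that the statistics behave correctly for
trees whose noise is of this kind, not that any real dataset satisfies the
model.

## Numerical and design choices

- Branch lengths serialize with 10 significant digits; Newick round trips
  are exact at that precision. Trees are rooted throughout.
- Zero-length splits from host-tip expansion stay multifurcations.
- RY recoding maps ambiguity codes that span both purine and pyrimidine
  classes to `?` (only `R` and `Y` themselves resolve within a class) — a
  conservative choice where conventions differ.
- PCoA negative eigenvalues are truncated rather than Cailliez-corrected;
  truncation is the simpler default and the choice is isolated in `pcoa()`.
- The backtracking association randomizer preserves exact row and column
  sums — the strictest reading of "conserving the overall degree of
  interactions"; calibration experiments draw the observed matrix from the
  same filler so that observed and permuted matrices are exchangeable.
- Assignment problems are solved exactly (Hungarian algorithm in C++).
- Parsimony ties are broken in a fixed order (speciation, duplication,
  transfer) so event counts are deterministic.
- All stochastic functions take explicit integer seeds; nothing is
  wall-clock derived. Reports regenerate byte-identically from one config
  and seed on one platform (floating-point mode may differ across BLAS
  builds).

## Problem sizes used by the tests and the acceptance script

The validation experiments are sized for a desk machine and state their
conditions explicitly: host trees of 8-20 tips (rescaled to unit height
where event rates must be comparable across replicates), 999 permutations
per test, 500 null simulations for calibration, a 4-point switch-rate grid
with 30 replicates per point for rate recovery, and 50 replicates of the
15-gene baseline design for the classification experiment. These sizes
make every experiment a property check of the method, not a reproduction of
any real dataset, whose scale (hundreds of metagenomes) is far beyond a
test suite.

## Known limitations

- The undated DTL model ignores branch lengths and dates; transfers are
  constrained only by the non-ancestral rule, not by contemporaneity.
- Gene-tree topologies are taken as given: there is no joint gene-tree
  correction during reconciliation, so reconstruction noise inflates rate
  estimates — which is exactly why the replicate-gene-tree baseline exists.
- With 15 baseline replicates, an exchangeable noise-only clade exceeds the
  baseline maximum about 1/16 of the time; the classification rate reflects
  that order statistic, not an error in the estimator.
- The permutation tests condition on the observed association degree
  structure; they do not test hypotheses about the degrees themselves.
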