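---
title: "Predicting disulfide connectivity from tandem cysteine losses on a phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting disulfide connectivity from tandem cysteine losses on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cysbond)
```

## The problem

A protein with `2d` oxidized cysteines forms `d` intra-chain disulfide
bonds, but which cysteine pairs with which — the *connectivity pattern* —
is a perfect matching on the oxidized positions, one of `(2d-1)!!`
possibilities. Knowing the pattern constrains fold recognition and ab
initio structure prediction, yet for most sequences no experimental
structure exists. `cysbond` predicts the pattern from evolutionary
information alone, taking the oxidation states themselves as known input.

## The model

Two assumptions drive the method. First, the connectivity pattern is
conserved within a protein family: structure outlives sequence, so the
homologs in an alignment share the query's bond topology. Second, within
the sampled family an oxidized cysteine can only be *lost*, not regained —
restoring a fully lost bond would need two coordinated mutations back to
cysteine, a rare event on family timescales. Under these assumptions, the
loss of one member of a bonded pair removes the selective pressure on its
partner, and the partner tends to follow: bonded pairs disappear in
*tandem*, and observing which cysteines vanish together reveals the
pairing.

The observable is a phylogenetic tree whose leaves are the aligned
homologs. Each node carries a binary label over the query's oxidized
columns (1 = cysteine present). Leaf labels are read off the alignment;
ancestral labels are reconstructed by the loss-only parsimony rule: a node
has a cysteine iff any leaf below it does, i.e. each inner node is the
bitwise OR of its children. This is computed in one post-order pass; since
OR is associative, commutative and idempotent, the result equals the
leaf-by-leaf recursive procedure with backtracking and is independent of
child order, and it generalizes unchanged to multifurcating nodes. Along
any root-to-leaf lineage each bit flips at most once (1 to 0), the minimum
number of mutations compatible with the leaves — maximum parsimony under
loss-only evolution. When the query row is in the alignment the root label
is all-ones.

For every leaf, the path of labels to the root is scanned, with an
all-zeros label prepended before the leaf so that the leaf's own retained
set is itself compared. Between adjacent labels, let `mu` be the number of
positions that switch from 0 to 1 (leaf-to-root direction, i.e. cysteines
lost on that edge going forward in time):

* `mu = 0`: nothing happened; no inference.
* `mu = 2`: a clean tandem loss; the corresponding candidate bond gains
  weight 1.
* even `mu > 2`: several bonds fell in one step and the tree's time
  resolution cannot separate them; each of the `mu(mu-1)/2` pairs among
  the `mu` positions gains `2/(mu(mu-1))`, so the step still deposits
  total weight 1.
* odd `mu` (parity breaking): the step confounds tandem pairs with a
  stray single mutation and contributes nothing. (A variant that also
  *penalizes* edges between mutated and conserved cysteines in odd steps
  was considered and rejected: the added complexity does not pay for the
  marginal gain.)

Because every informative step deposits exactly weight 1, the total graph
weight equals the number of informative steps — an exact invariant the
test suite asserts. Steps on a tree edge are counted once per descendant
leaf, which is what the per-leaf path traversal implies; the production
code does a single pass over tree edges multiplying by descendant-leaf
counts, and the literal per-leaf traversal is retained as a cross-check
oracle.

The accumulated weights form a symmetric non-negative matrix over the
`2d` cysteines; the prediction is its maximum-weight perfect matching.

## Pipeline choices

**Parity filter.** Homologs with an odd number of cysteines at the
oxidized columns carry an unresolved single mutation and are removed before
tree building. Zero cysteines is even, so cysteine-free homologs are
retained: the filter keys only on parity, and all-zero labels are harmless
(they add no weight). The query row always survives the filter.

**Distances and tree.** Pairwise p-distances (mismatches over columns
where both rows are non-gap; distance 1 when no column is comparable) feed
a standard Saitou–Nei neighbor-joining implementation. A Kimura protein
correction `d = -ln(1 - p - p^2/5)` (capped at 10 beyond `p = 0.75`) is
available behind a flag but off by default: downstream inference uses only
the topology, and the plain p-distance is the simplest defensible choice.
NJ ties are broken by the lexicographically smallest id pair and negative
branch lengths are clamped to zero with the deficit moved to the sister
branch, so results are bit-reproducible. An externally built Newick tree
can be supplied instead, bypassing these steps.

**Rooting.** The tree is rooted by an outgroup made by randomly shuffling
the query sequence — distant from every homolog by construction, it
attaches outside the family and defines the root consistently. The root is
placed at the midpoint of the outgroup's pendant edge; the outgroup is
machinery, not a homolog: it bypasses the parity filter, is dropped before
labeling, and contributes no leaf path.

**Matching.** The maximum-weight perfect matching is computed exactly by a
dynamic program over vertex subsets (C++ via Rcpp, `O(2^n n)`), guarded at
`n <= 26` cysteines — beyond every practically observed bond count (up to
15 bonds in curated sets). Exactness is trivially auditable, unlike a
blossom-style implementation, and at these sizes speed is a non-issue; an
exhaustive `(n-1)!!` enumeration in R serves as an independent oracle up to
`n = 16`, and the two agree on every random instance tested. Perfectness is
inherent in the DP, so zero-weight cysteines are still matched. Ties are
broken by the lexicographically smallest sorted pair list. When the
parity filter leaves fewer than two rows there is no tree to interpret; the
pattern is then drawn uniformly at random (seeded) and flagged as a
fallback, which keeps evaluations comparable across a dataset.

## Evaluation

`Rb` is the number of correctly predicted bonds over observed bonds,
micro-averaged within a stratum (macro behind a flag); `Qp` is the
fraction of proteins predicted perfectly. A uniform random matching pairs
any cysteine with each of the other `2d-1` equally, giving
`E[Rb] = 1/(2d-1)`, and picks the single correct pattern with probability
`1/(2d-1)!!`. Over a benchmark composition of 100/85/41/37 proteins with
2/3/4/5 bonds the weighted random `Qp` averages 15%. Note that `Qp` is
bounded by the *macro*-averaged `Rb` (an exact protein has all bonds
correct) but can exceed the micro-average when exact proteins have fewer
bonds than wrong ones. Fold-averaged `Qp` (as used with 20-fold splits in
the literature) is supported; with few proteins per fold it is subject to
sampling bias and can differ from the pooled value by a few percent.

## The simulator

Synthetic families make every stage testable without downloads. A random
rooted binary tree (`ape::rtree` topology, exponential branch lengths,
rate 10) carries a root sequence with cysteines exactly at the planted
bond positions and background residues uniform over the 19 non-cysteine
amino acids. Down each branch: background sites substitute independently
with probability `p_sub = 0.05`; each member of an intact bond is lost
with base hazard `p_loss/2`, and when exactly one member falls the partner
is dragged down in the same step with probability `p_tandem`; an orphaned
cysteine keeps the same per-site hazard; lost cysteines restore with
`p_restore = 0` by default, honoring the loss-only model. With
`p_tandem = 0` all losses are therefore i.i.d. across sites and the
simulation carries no pairing signal — the proper chance-level control —
while `p_tandem = 1` is the pure tandem regime. Defaults (64 leaves,
sequence length 100, 3 bonds, `p_loss = 0.3`) give families in which most
lineages lose several bonds, the regime the method is meant for.

The simulation is gap-free, uses no realistic substitution matrix, and
has no rate heterogeneity or indels: the inference only reads
cysteine/non-cysteine states, and these simplifications isolate the
inference logic. Passing recovery tests on simulated families therefore
demonstrates the correctness of the machinery under the model's own
assumptions — not performance on real alignments, where alignment errors,
gaps, uneven sampling and violations of loss-only evolution all intrude.

Under the strong-signal conditions (64 leaves, 3 bonds, `p_loss = 0.3`,
`p_tandem = 1`) the planted pattern is recovered exactly in ≥95% of
replicates. The residual failures are informative: when two whole bonds
happen to fall on the same early branch, the `mu = 4` split assigns equal
weight to all pairings within the quartet, the matching ties, and the
deterministic tie-break picks the planted pairing only a third of the
time — exactly the time-resolution ambiguity the `mu`-split rule encodes.

## Numerical and scale choices

Weights accumulate in double precision; exact-identity assertions on
totals use tolerance 1e-9. Test and acceptance problem sizes — 100
replicates per recovery arm, 1000 random graphs for the matching oracle,
1e5 Monte-Carlo matchings per bond count — were chosen to give stable
statistics at interactive runtimes. All randomness is seeded; every
reported number is reproducible.

## The pair feature encoder

For stacking these unsupervised predictions into a supervised model, the
package implements the standard 523-dimension cysteine-pair encoding: for
each of the two cysteines, a 13-column window (6 each side, clipped
windows zero-padded) of 20-dimensional amino-acid frequency profiles from
the alignment columns (gaps carry no mass), totalling 20 × 2 × 13 = 520;
one dimension for the sequence separation `ln|c_i - c_j|` (log base is not
fixed by convention; natural log here); and two dimensions for the pair's
relative order — the 1-based ranks of the two members among the `n`
oxidized cysteines divided by `n` (the classical formula lists all `n`
ratios, but two dimensions are allotted, so the pair's own two are used).
`append_prediction_bit()` adds the 524th dimension carrying this package's
binary bond prediction. Training the downstream regressor is out of scope:
it requires external benchmark datasets.

## Limitations

* The method needs informative tandem losses: families with few homologs,
  or with all cysteines conserved everywhere, yield flat weight matrices
  and the prediction degrades to the deterministic tie-break.
* Homologs are trusted to share the query's connectivity; families with
  rewired disulfides violate the first assumption.
* The even-parity filter can discard a substantial fraction of homologs
  (one in five in sparse families), which hurts exactly the cases that are
  already homolog-poor.
* The loss-only reconstruction is a parsimony heuristic, not a
  probabilistic model; it cannot express uncertainty in ancestral states.
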