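---
title: "Multiple sequence alignment by residue clustering: models and methods"
author: "msaclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple sequence alignment by residue clustering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msaclust)
```

## The problem and the approach

Progressive multiple sequence aligners assemble an alignment pairwise along a
guide tree. That is fast, but the result is biased toward the tree: errors
made early between subgroups are frozen in, and downstream phylogenies
inferred from such alignments inherit the bias. `msaclust` takes a
non-progressive route. It treats every residue of every sequence as a node of
a k-partite graph, weights edges by the posterior probability that two
residues belong in one column, and then *clusters* the graph into columns
directly, with no tree anywhere in the pipeline.

The pipeline has four stages:

1. **Pairwise stochastic alignment.** For every pair of sequences, a
   partition function over all gapped alignments yields posterior
   residue-pairing probabilities.
2. **Consistency transformation.** Pairwise posteriors are re-estimated
   through every third sequence, sharpening agreement across the set.
3. **Residue clustering.** The resulting alignment graph is recursively
   bipartitioned by an order-constrained Fiduccia–Mattheyses (FM) heuristic
   until every part holds at most one residue per sequence; parts become
   columns.
4. **Iterative refinement.** Groups of sequences are re-aligned against the
   rest by maximum expected accuracy, removing clustering artefacts.

## Pairwise stochastic alignment

An alignment $A$ of sequences $a$, $b$ is scored by the usual similarity
function $S(A)$: substitution scores $s(x, y)$ for aligned residues and
affine gap penalties (open $g_o$, extension $g_e$); every column of a
*terminal* gap run — one touching either end of either sequence — is scored
with the terminal-gap parameter instead. Each alignment gets the Boltzmann
weight

$$W(A) = e^{\beta S(A)},$$

and the partition function $Z = \sum_A e^{\beta S(A)}$ normalises these
weights to a distribution over all alignments. The posterior probability
that residues $a_i$ and $b_j$ share a column is then

$$P(a_i \sim b_j) \;=\; \frac{Z_{i-1,j-1}\; e^{\beta s(a_i,b_j)}\;
  \hat Z_{i+1,j+1}}{Z},$$

where $Z_{i,j}$ and $\hat Z_{i,j}$ are partition functions over prefix and
suffix alignments. Both are computed by the sum-over-paths analogue of the
Gotoh three-state recursion (match, gap-in-$a$, gap-in-$b$): every `max` is
replaced by a sum. Two indel conventions are supported: the default allows a
gap in one sequence to directly follow a gap in the other (`"adjacent"`),
while `"noadjacent"` removes the two cross-state transitions, so insertions
and deletions must be separated by at least one match column. The default
follows the variant that scored best in the benchmarking of the parent
method family.

**Numerical safety.** The raw recursion overflows double precision for
realistic sequence lengths (weights grow like $e^{\beta S}$ with $S$
proportional to length). The tables are therefore stored with per-row
rescaling: after each row is computed, it is divided by its maximum and the
log of the factor is accumulated. All ratios are preserved exactly, and the
posterior product above is evaluated in log space before exponentiation.
Forward and reverse totals are required to agree to a relative $10^{-9}$ in
the test suite, and both match exhaustive enumeration over all alignments of
short sequences to $10^{-8}$.

**Boundary conventions.** $Z_{0,0} = 1$ (the empty prefix); boundary rows
and columns carry pure-gap prefix weights scored as terminal runs. One
consequence worth stating explicitly: under the `"adjacent"` convention the
two orderings of a pure-gap alignment (gap run in $a$ first vs. gap run in
$b$ first) count as two distinct alignments, exactly as the recursion counts
them; under `"noadjacent"` both are excluded because the two runs are
adjacent. The enumeration oracle in the tests adopts the same convention, so
the equality checked there is meaningful and not a shared artefact.

**Sparsity.** Posterior entries below the cutoff $t_c$ (default 0.01) are
set to zero and the matrices are stored sparsely. In practice only a handful
of entries per row survive, which keeps all downstream stages near-linear in
sequence length. Pruning happens after normalisation, never before.

## Consistency transformation

Pairwise posteriors ignore the other $k - 2$ sequences. The consistency
transformation re-estimates them through every intermediary $c$:

$$P'_{ab} \;\gets\; \frac{\sum_{c} w_{ac}\, w_{cb}\; P_{ac} P_{cb}}
  {\sum_{c'} w_{ac'}\, w_{c'b}},$$

a weighted average of matrix products. The sum runs over *all* sequences
including $a$ and $b$ themselves, with the self matrix $P_{aa}$ taken as the
identity — so the $c = a$ and $c = b$ terms interpolate toward the current
matrix and iterating the transform is stable. Weights measure pair
similarity as total posterior mass over the shorter length,

$$w_{ab} = \frac{\sum_{i}\sum_{j} P(a_i \sim b_j)}{\min(|a|, |b|)} \in [0, 1],$$

so intermediaries similar to both endpoints contribute more; setting all
weights to 1 recovers the plain averaged transform. Three details are the
package's own choices where the formulation leaves room:

* updates are synchronous (all matrices of an iteration are computed from
  the previous iteration's store);
* weights are computed once from the untransformed posteriors and reused
  across iterations, since they are a property of the stochastic alignment
  itself;
* entries below the cutoff are pruned after every iteration (an internal
  switch can defer pruning to the end), keeping the sparsity the complexity
  relies on.

Two iterations are the default; more blur the affinity structure.

## Residue clustering

Columns of a multiple alignment partition the residue set, so aligning
becomes clustering the alignment graph under two structural constraints: a
cluster may not contain two residues of one sequence (*ambiguity*), and the
clusters must be orderable consistently with every sequence's residue order
(*conflict*). `msaclust` clusters divisively: each step cuts every sequence
interval at one position, which makes conflicts impossible by construction,
and recursion continues (leftmost subregion first) until every region holds
at most one residue per sequence. Non-empty terminal regions are emitted as
columns, left to right.

Each cut should minimise the weight of edges it severs, subject to balance.
This is graph bipartitioning, and the package adapts the
Fiduccia–Mattheyses heuristic to the order constraint:

* **Moves are block moves.** Shifting one sequence's cut to a new position
  moves every residue between the old and new position; a residue cannot
  jump the cut alone. Because the graph is k-partite, a block (all in one
  sequence) contains no internal edges, and the gain of a block move is the
  exact sum of its members' crossing-weight differences — maintained
  incrementally per node and cumulated along each sequence.
* **Balance.** No accepted state may leave a side with fewer residues
  (node weight, at coarse levels) than
  $\max(0, \lfloor (T - k)/2 \rfloor)$ for region size $T$ — equivalently,
  sides may differ by at most $k$, the largest possible final column. This
  is the smallest search space containing every partition consistent with
  some multiple alignment.
* **Passes.** Starting from the per-sequence midpoint cut, the best
  feasible block move (by gain; ties break by smaller block, lower sequence
  index, leftward direction) is applied and its residues are locked for the
  pass; negative-gain moves are accepted, which lets a pass traverse
  valleys. Since a block move of size $d$ is a trajectory of $d$ unit
  moves whose intermediate states are all feasible, those prefixes are
  also recorded as candidate best states (the classical best-prefix rule).
  The best state seen in a pass seeds the next pass.
* **Termination with one kick.** Classically the search stops when a pass
  fails to improve. In small dense regions that single greedy trajectory
  regularly parks in a multi-move local optimum: auditing such cases showed
  every returned cut was 1-move optimal, i.e. the misses were genuine
  basins, not bookkeeping errors. The package therefore allows one
  deterministic continuation pass from the trajectory's *end* state before
  terminating — a kick out of the first basin. The returned cut is still
  the best state ever visited, so the cut weight never exceeds the initial
  midpoint cut's. On 200 random small instances (2–3 sequences, lengths up
  to 6) where exhaustive enumeration of all balance-feasible cuts is
  possible, this implementation matches the optimum on 92–96% of instances
  with mean relative gap under 3%; exactness is not guaranteed — FM is a
  heuristic.
* **Degenerate cuts.** If a returned cut leaves one side empty while the
  region is non-terminal, the longest sequence interval is split at its
  midpoint instead, guaranteeing progress.

**Multilevel option.** With `multilevel = TRUE`, the region subgraph is
repeatedly coarsened — consecutive residue pairs within each sequence
interval merge, node weights add, parallel edges sum — until every interval
has at most two nodes (the stopping size is the package's choice; the
scheme itself does not fix one). FM partitions the coarsest graph, and the
cut is projected back level by level (each coarse cut position expands to
the left edge of the first right-side coarse node, preserving the cut
weight exactly), with an FM refinement seeded by the projected cut at every
level. Edges leaving the current region are already cut and cannot change
under internal moves, so each bipartition call works on the region-internal
subgraph only.

## Refinement

Clustering tends to leave superfluous near-all-gap columns, e.g. three
consecutive columns each holding one residue of a different sequence where
one shared column would do. Refinement removes them: the sequence set is
split into two groups, the alignment is projected onto each group (columns
that become all-gap are dropped), and the two profiles are re-aligned
globally with scores

$$\mathrm{score}(u, v) \;=\; \sum_{x \in \mathrm{col}_u,\; y \in
  \mathrm{col}_v} P(x \sim y)$$

and zero gap penalty. The input alignment corresponds to one admissible
path through this score matrix, so the optimal path never decreases the
*expected accuracy* — the sum of stored posteriors over all within-column
pairs — which is the invariant the tests enforce at every step. Zero gap
penalty creates massive score ties; traceback breaks them deterministically
(diagonal over up over left) so runs are reproducible.

The schedule runs a leave-one-out sweep once (each sequence against the
rest, in order — very effective on the gap artefacts above), then
`refine_iters` iterations (default 100) re-aligning a random subset drawn
by: size uniform on $1..k-1$, then a uniform subset of that size. The whole
step can be turned off, since aggressive refinement can force alignment of
non-homologous insertions. Randomness comes from the run's single seeded
generator; refinement is the only stochastic stage, so equal seed and
configuration give byte-identical output.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `beta` | 0.2 | inverse temperature; rescales $S(A)$ in $e^{\beta S}$. Larger values concentrate the posterior on optimal alignments |
| `gap_open` / `gap_ext` | −22 / −1 | affine gap penalties, in the score units of the substitution matrix (10·log10 odds for the bundled matrix) |
| `terminal_gap` | 0 | per-column score of terminal gap runs |
| `indel_variant` | `"adjacent"` | whether an insertion may directly follow a deletion |
| `cutoff` | 0.01 | posterior sparsity threshold $t_c$ |
| `consistency_iters` | 2 | consistency iterations |
| `weighted_consistency` | TRUE | similarity-weighted vs. plain averaging |
| `multilevel` | FALSE | multilevel coarsening around FM |
| `refine_iters` | 100 | random-subset refinement iterations |
| `seed` | 1 | RNG seed (consumed by refinement only) |

The numeric defaults follow the established parameterisation for
Gonnet-family scoring at this scale (they are the defaults of the Probalign
lineage this pipeline's outer stages follow). The bundled `gonnet160`
matrix is *derived*: starting from the published 1992 Gonnet–Cohen–Benner
250-PAM odds matrix, the amino-acid frequencies and reversible Markov
generator are recovered and rescaled to 160 PAM by a matrix power, then
re-expressed as 10·log10 odds. That is the standard construction of the
Gonnet family; entries can differ in the last rounded digit from other
distributions of a 160-PAM Gonnet file. Ambiguity codes (B, Z, X) are
rejected rather than silently scored — a fail-fast choice that keeps the
posterior semantics honest; supply a custom matrix to accept them.

## The synthetic family generator, and what tests do (not) show

`simulate_family()` draws a random ancestor and evolves each leaf
independently (a star phylogeny): per-site substitution with probability
`sub_rate` (uniform over the other letters), deletions and insertions
initiated with probability `indel_rate` and geometric lengths (mean
`mean_indel`). The true alignment is recorded through ancestor coordinates;
insertion residues get private columns, so insertions of different leaves
are never counted as alignable. The end-to-end recovery checks use families
of 4 sequences, ancestor length 60, substitution rate 0.1, indel rate 0.02
— a conserved-family regime where the true alignment is essentially
identifiable and the pipeline is expected to recover ≥ 90% of true residue
pairs (SP). Runs at this scale keep the whole suite within a few minutes.

What this does *not* show: star phylogenies have no guide-tree-difficult
topology, no rate heterogeneity across sites, no conserved motifs embedded
in divergent background, and lengths far below real benchmark families.
Passing these tests validates the machinery (partition functions against
enumeration, the transform against a dense oracle, the partitioner against
exhaustive cut enumeration, monotone refinement, determinism) — it does not
certify benchmark-level accuracy on real protein families.

## Scoring against a reference

`sp_tc_score()` implements the two standard reference-based metrics: SP,
the fraction of reference-aligned residue pairs reproduced by the test
alignment, and TC, the fraction of reference columns whose exact residue
content appears as a test column, optionally restricted to a core-column
mask. One simplification relative to the external benchmark scorer is
deliberate: reference columns holding a single residue contribute no SP
pairs and count toward TC only if the test alignment isolates that residue
identically.

## Known limitations

* Stochastic alignment is $O(k^2 l^2)$ time and the consistency sum is
  $O(k^3)$ in sequence number; the implementation is plain R and aimed at
  method-scale problems, not genome-scale ones.
* The FM partitioner is a heuristic; optimality holds only usually, and
  only the multilevel scheme mitigates bad early cuts on large regions.
* No tree-guided refinement splits, no banding of the DP, no MSF/Stockholm
  writers, and no nucleotide-specific scoring presets beyond user-supplied
  matrices.

## A worked example

```{r example}
seqs <- sequence_set(c(s1 = "HEAGAWGHEE", s2 = "PAWHEAE", s3 = "HEAGWGHE"))
fit <- msaclust(seqs, align_params(refine_iters = 20, seed = 1))
fit
as.character(fit)
```
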