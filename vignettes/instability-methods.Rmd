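---
title: "Why progressive alignments depend on input order: methods and design"
author: "msastab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why progressive alignments depend on input order: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msastab)
```

## The phenomenon

Progressive multiple sequence alignment works in two stages: all-against-all
pairwise distances feed a hierarchical clustering that produces a guide
tree, and sequences (then profiles) are aligned in the tree's branching
order. Because the distance stage must run over $N(N-1)/2$ pairs, production
aligners use fast word-based scores: the count of exact $k$-tuple matches
between two sequences, variously scaled by sequence length. Such scores
discard both the positions of the matches and the identities of the
residues matched, so they can take only a small number of distinct values.

For two equal-length sequences of length $L$, a 1-tuple score takes at most
$L + 1$ values (0 matches, 1 match, ..., $L$ matches) and a 6-tuple score
at most $(L - 5) + 1$. As $N$ grows the number of pairs grows quadratically
while the number of available values stays fixed, so the distance matrix
becomes dominated by *ties*. A tie at the minimum of a clustering step
makes the merge order arbitrary: real implementations resolve it by
whichever pair comes first (or last) in their internal scan order, which is
inherited from the order of the sequences in the input file. Reversing the
input file then changes the guide tree, and with it the alignment. This
package implements every piece needed to demonstrate, measure and bound
that effect at desk scale.

## Distance formula families

Five pairwise measures are provided, all symmetric and all returning 0 for
identical inputs:

| method       | score                        | scaling                                      |
|--------------|------------------------------|----------------------------------------------|
| `clustalo1`  | shared 1-tuple count $S_1$   | $1 - S_1/\min(L_a, L_b)$                     |
| `muscle6`    | shared 6-tuple count $S_6$   | $1 - S_6/(\min(L_a, L_b) - 5)$               |
| `kalign_mm`  | approximate tuple matches    | $(1 - S/\text{max poss}) \cdot \min(L)/\max(L)$ |
| `mafft6`     | shared 6-tuple count $S_6$   | $D' = D/f(x, y)$, see below                  |
| `nw`         | alignment identities         | $1 - \text{ident}/\min(L_a, L_b)$            |

The two-stage `mafft6` form is
$D_{ij} = 1 - S_{ij}/\min(S_{ii}, S_{jj})$ with self-scores
$S_{ii} = L_a - 5$, and
$f(x, y) = \frac{y}{x}\cdot 0.1 + \frac{10000}{x + 10000} + 0.01$
where $x \ge y$ are the two lengths. Because *both* lengths enter $f$, a
dataset with $c$ distinct lengths admits up to $c^2$ distinct scaling
factors, which is why this family sustains more unique distances than the
others (and why its closed-form ceiling below carries a squared term).

Design choices worth recording:

* **Multiset tuple counting.** The shared $k$-tuple score is implemented
  as $\sum_w \min(\text{count}_a(w), \text{count}_b(w))$ over distinct
  words $w$. Sequential-scan formulations ("advance and restart after a
  match") can give different answers depending on which sequence drives
  the scan; the multiset form is order-independent, reproduces the
  self-score $L - k + 1$, and is validated in the tests against an
  independent maximum-bipartite-matching oracle over tuple positions.
* **Symmetry by construction.** `kalign_distance` assigns the
  longer/shorter roles by length, breaking equal lengths by lexicographic
  order of the sequences; `nw_distance` aligns each pair in a canonical
  order before counting identities (with co-optimal alignments, a
  deterministic traceback could otherwise report different identity
  counts for the two argument orders). `symmetry_audit()` recomputes every
  pair both ways and returns the worst discrepancy, which is exactly 0
  for all five methods. Real implementations are not always symmetric,
  and an asymmetric distance is a second, independent route to
  input-order-dependent trees — the audit exists to prove this package
  never takes it.
* **Kalign stand-in.** The real program derives distances from
  Muth–Manber approximate string matching; its internals (including a
  quirk that scores very short pairs as distance zero) are not
  replicated. The stand-in counts shorter-sequence 6-tuples that occur in
  the longer sequence with at most one substitution, by brute force. It
  reproduces the *character* of the measure (bounded value set,
  longer-length scaling), not its bit-exact output.
* **Degenerate pairs** (shorter than $k$) get distance 1 with a warning;
  the formulas are undefined there and this choice keeps matrices total.
* Distances are carried at full double precision; the 25-decimal rule
  applies to file output (below).

## Tie census and closed-form ceilings

`count_unique_distances()` rounds the upper-triangle values to a
configurable number of decimals (default 25, matching the file format) and
counts distinct values. The matrix writer emits PHYLIP square format with
25-decimal values so that ties on disk are ties in memory; rounding is
configurable because binary representation can split mathematically tied
values.

`theoretical_max_unique()` evaluates the conservative ceilings

$$\text{MaxUniqueDists} = \text{MaxSeqLength} \times \text{Count(SeqLengths)}$$

for the linear family (`clustalo1`, `kalign_mm`, `muscle6`) and

$$\text{MaxUniqueDists} = \text{MaxSeqLength} \times \text{Count(SeqLengths)}^2$$

for `mafft6`. These deliberately ignore the small per-method adjustments
(the $+1$ for zero matches, the $k$-tuple end correction); the exact
per-method ceilings $L + 1$ and $L - 4$ are what the tests assert on
equal-length sets, and both forms are exposed. Inverting
$N(N-1)/2 = \text{MaxUniqueDists}$ gives `max_stable_sequences()`, the
largest $N$ whose pairs can still all receive distinct values — beyond it,
ties are forced by counting alone. The integer solution
$\lfloor(1 + \sqrt{1 + 8M})/2\rfloor$ is post-corrected with two integer
comparisons to guard against floating-point edge cases at perfect
triangular numbers.

## UPGMA with explicit tie handling

`upgma()` is standard arithmetic-average linkage. At each step the global
minimum is located and every pair within `tol` of it (default `tol = 0`,
exact equality) forms the tie set; if that set has more than one pair a
`tie_event` is recorded and a warning of potential instability is issued —
the run continues, because ties are a property of the data, not an error.
The merged pair is chosen by one of four policies: `input_order_first`
(first tied pair in row-major order over the current cluster order — the
"first pair wins" model of real code), `input_order_last`,
`lexicographic` (smallest pair of sorted member-label tuples — the
mitigation that makes the tree a pure function of the *set* of sequences),
and `random` (seeded). Tie-free matrices give the same tree under every
policy, and the implementation is checked against stock average-linkage
clustering (`hclust`) on tie-free matrices in the tests.

String comparisons in the lexicographic policy and in canonical forms use
radix (byte) order throughout so results cannot depend on the session
locale.

`chained_tree()` builds the caterpillar tree over input order — the
degenerate guide tree that can improve accuracy at scale but maximizes
input-order dependence. `same_topology()` compares canonical forms with
child order and heights ignored.

## The progressive aligner

`pairwise_nw()` is a three-state (Gotoh) affine-gap global aligner in C++;
a gap run of length $g$ costs $\text{open} + (g-1)\cdot\text{extend}$.
Defaults are BLOSUM62, open 11, extend 1, terminal gaps penalized —
standard protein settings. The traceback is deterministic with tie
preference diagonal > up > left; determinism here is a *contract*, so that
any output difference downstream is attributable to the guide tree alone.
The U and O residues, absent from published BLOSUM62, are scored with the
X column.

`profile_profile_align()` runs the same DP over alignment columns, scoring
column $u$ against column $v$ as the average substitution score over all
row pairs with gap-involving pairs contributing 0, and never removing an
existing gap ("once a gap, always a gap"). `progressive_align()` merges
leaves-to-root; at every internal node the two children are ordered
canonically (the child containing the smallest leaf label first). This
canonicalization is a deliberate design decision: it makes the output a
pure function of tree *topology*, so the implication "same forward and
reverse topology ⟹ identical alignment ⟹ identical TC score" holds
exactly and is asserted in the tests, turning the causal claim — the
instability originates in the guide tree — into a checkable invariant.

Both DP scores are validated against exhaustive enumeration over all
global alignments at small sizes (Delannoy-number growth limits this to
lengths ≤ 8, which is ample to exercise every recurrence case).

## TC scoring

`tc_core_score()` computes the total-column score restricted to core
columns of a reference alignment: a reference column is correct when all
of its residues (as sequence-id/residue-ordinal cells, gaps skipped) sit
in one single column of the test alignment. The default mask marks the
gap-free reference columns as core, the natural stand-in when no
structural annotation exists; a column holding a single residue counts as
vacuously correct by default, with a switch to drop such columns from the
denominator (annotation conventions vary on this point). An all-column
variant is available via `columns = "all"`, but core-column scoring is the
default. Scores are compared downstream as exact integer counts of correct
columns, never as floating-point ratios.

## The synthetic family generator

`simulate_family()` evolves a uniform-composition root sequence down a
random-join binary tree with per-site substitutions (probability
`subst_rate` per branch) and geometric-length indels (`indel_rate`,
`mean_indel_len`), recording every indel against a global column registry
so the true alignment is exact by construction. A configurable fraction of
leaves is overwritten with exact copies under their own ids, mirroring
identically-sequenced, differently-labelled entries in large curated
families; the first `n_refs` leaves form the embedded reference.

The generator emulates the features that drive tie formation — sequence
count, divergence, the number of distinct lengths (`indel_rate = 0` forces
a single length, the tie-maximizing regime), and duplicate records. It
does **not** emulate realistic substitution processes (no BLOSUM-like
exchangeabilities, no rate heterogeneity, no domain architecture), and its
uniform root composition makes k-tuple matches rarer than in real
proteins. Passing tests therefore demonstrate the *mechanism* — bounded
value sets, forced ties, order-dependent trees — on families whose tie
structure is realistic in kind; they do not certify the magnitude of
instability on any particular real family, which depends on composition
and length structure the generator does not model.

## Experiment scale and numerical choices

`forward_reverse_experiment()` shuffles a family (seeded), runs distance →
UPGMA → progressive alignment → TC, reverses the shuffled order, repeats,
and reports both scores with tie-event counts and a forward/reverse
topology comparison. The default study conditions used by the package's
own checks are: tie-plateau census at $n = 300$, $L = 120$,
`subst_rate` 0.2; instability runs at $n = 100$, $L = 120$, `subst_rate`
0.3, `indel_rate` 0, 20 shuffle seeds, 5 reference sequences. These sizes
keep a full run in tens of seconds on one core while being comfortably
inside the regime where same-length ties dominate ($44{,}850$ pairs versus
at most 121 distinct values at $L = 120$). Substitution rate 0.3 per
branch produces strongly diverged families in which the aligner actually
opens gaps, so order-dependent trees produce measurably different
alignments; at low divergence every merge is gap-free and forward and
reverse alignments coincide trivially.

Other numerical choices: tie equality defaults to exact double equality
(configurable `tol`); UPGMA heights are half the merge distance; Newick
branch lengths are written with 10 significant digits; all seeded
operations restore the caller's RNG state, and every result is a pure
function of (inputs, configuration, seed).

## Known limitations

* The four real aligner binaries are not wrapped or reproduced; the
  formula families are reimplemented from their published descriptions,
  and the Kalign measure is an explicit stand-in.
* The `nw` distance uses one optimal alignment's identity count;
  co-optimal alignments with different identity counts exist, and the
  canonical-order rule picks one deterministically rather than averaging.
* Guide-tree iteration, consistency scoring and FFT-accelerated matching
  are out of scope; the aligner is meant for hundreds of sequences, not
  tens of thousands.
* The closed-form ceilings are conservative bounds, not sharp maxima; the
  observed unique-distance counts plateau well below them.
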