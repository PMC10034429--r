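---
title: "Comparing metabolic pathways as enzymatic step sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing metabolic pathways as enzymatic step sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essalign)
```

## The idea

Two metabolic pathways can be functionally similar even when their genes are
unrelated: what matters is the *order of catalytic activities* along the
pathway. `essalign` operationalises this by turning each KEGG-style metabolic
map into a set of linear **enzymatic step sequences (ESS)** — ordered lists of
Enzyme Commission (EC) numbers in which each step's product is the next
step's substrate — and then comparing ESS with a global sequence aligner whose
substitution scores come from the EC classification hierarchy rather than
from residue chemistry.

The pipeline has four stages, each exposed as ordinary functions:

1. **Graph construction** (`parse_kgml()`): reactions become nodes, shared
   compounds become edges.
2. **ESS extraction** (`extract_map_ess()`): breadth-first-search trees are
   grown from *initialization nodes* and one sequence is read off per leaf;
   identical sequences across maps and organisms are collapsed into a
   non-redundant set (`make_nonredundant()`, stored with `write_ess_db()`).
3. **Pairwise alignment** (`nw_align()`): a *minimizing* Needleman–Wunsch
   over an entropy-based EC dissimilarity matrix, with a composite score in
   [0, 1] (0 = identical).
4. **Significance** (`significance_report()`): alignment scores are compared
   with those of shuffled databases to find a cutoff below which similarity
   is unlikely to be chance.

## From KGML to a reaction graph

A KGML document lists `entry` elements (genes, enzymes, compounds, linked
maps) and `reaction` elements with `substrate`/`product` children.
`parse_kgml()` creates one node per reaction; entries attached to the same
reaction are merged, so isoenzymes and enzyme complexes form a single node
holding the union of gene identifiers. Four-level EC numbers are read from
`ec:`-prefixed entry name tokens (the convention of KEGG reference maps);
a reaction without any EC token is labelled with the sentinel `9.9.9`.
Resolving organism-specific gene identifiers to EC numbers through the full
KEGG relational data is deliberately out of scope — no network access is
assumed anywhere in the package.

Directionality is a user choice (`directed = TRUE/FALSE`). In the directed
graph, a reaction marked `reversible` mirrors every incident edge, so
traversal can cross it in both directions; the nominal substrate/product
sets are kept as annotated. `relation` elements never contribute edges;
`maplink` relations are read only to mark which reactions touch another map.
Only *strict* metabolic maps (5-digit codes below 01000, `is_strict_map()`)
are meaningful inputs: global overview maps mix pathways and would produce
arbitrary step sequences.

## Extracting step sequences

BFS roots ("initialization nodes") are chosen by two criteria, and their
union is used: (1) reactions none of whose substrates is produced by any
other reaction of the map — the map's entry points; (2) reactions that link
to another map and have fewer than three neighbours, which bounds the number
of sequences a single map can generate. Criterion 1 is evaluated with the
*any* quantifier (no substrate may have an in-map producer) on the nominal
compound sets: a reversible reaction is not counted as "producing" its
canonical substrates, which keeps the criterion independent of the
reversibility annotation. In a pure cycle no node qualifies and the map
yields no sequences.

From each root a BFS tree is grown (forward edges only in directed mode) and
one ESS is read per leaf, reported root-to-leaf so the sequence follows the
metabolic flow. Sequences shorter than two steps are discarded
(`min_length = 2`): a single step carries no order information. When a node
carries several EC numbers, the step label is the lexicographically smallest
three-level EC (with its matching four-level form); the full gene–EC
relations are preserved in the database rather than expanded
combinatorially, which would blow up the output with little information
gain. BFS queue ties are broken by sorted node id, so extraction is
reproducible byte-for-byte.

## Scoring EC dissimilarity

Each three-level EC number is treated as three alignment columns, one per
classification level, and each column is scored with Shannon entropy
(`column_entropy()`): 0 when the symbols agree, 1 when a pair disagrees.
The weighted combination

$$ECS(EC_1, EC_2) = \frac{w_1 H_1 + w_2 H_2 + w_3 H_3}{w_1 + w_2 + w_3},
\qquad (w_1, w_2, w_3) = (15, 10, 1)$$

makes a first-level disagreement (different reaction chemistry) far more
costly than a third-level one. The printed form of the entropy equation in
the method's source omits the minus sign; the standard $-\sum p_i \log_2
p_i$ is used, which the 0/1 pairwise simplification requires. The weights
are a qualitative choice inherited from the original method; they are
configurable but `(15, 10, 1)` is the pinned default.

The pairwise substitution matrix `S` (`build_ec_matrix()`,
`ec_dissimilarity()`) additionally enforces the EC hierarchy: a mismatch at
level 1 scores 1 outright, and a mismatch at level 2 forces level 3 to count
as mismatched, giving the ladder $1 \ge 21/26 \cdots$ in general and, with
the default weights, the concrete values

| pair | value |
|------|-------|
| identical | 0 |
| level-3 mismatch | 1/26 ≈ 0.0385 |
| level-2 mismatch | 11/26 ≈ 0.4231 |
| level-1 mismatch | 1 |
| `9.9.9` vs anything else | 1 |

The matrix is regenerated from whatever EC labels occur in the input
database (the label universe is a property of the data, not a constant) and
can be cached as TSV (`write_ec_matrix()`).

## Alignment and the composite score

`nw_align()` fills the dynamic-programming matrix with the *minimum* of
diagonal + S, left + gap, and up + gap; the gap cost is 1, the maximum
dissimilarity between two EC numbers. Gaps are printed as `-.-.-`. The
composite score of the resulting alignment is

$$score = 0.95\,H + 0.05\,GP$$

where the homogeneity $H$ is the mean per-column dissimilarity (a column
pairing a step with a gap counts 1, terminal gaps included) and the gap
penalization $GP$ is the mean over the two rows of (internal gap blocks) /
(internal gap characters). Terminal gap runs are excluded from $GP$, and a
row without internal gaps contributes 0 — both conventions are forced by the
reference worked example, which this package reproduces exactly:

```{r}
aln <- nw_align("2.7.1:5.3.1:5.3.1:2.7.1:4.1.2:1.2.1", "5.3.1:5.3.1:4.2.1")
aln
c(H = aln$H, GP = aln$GP, score = aln$score)
```

The method's prose description of $GP$ ("the numerator becomes smaller as
the number of gap blocks increases") contradicts its printed formula, under
which concentrated gaps are penalised *less* than scattered ones at fixed
gap count; the printed formula is implemented, since the worked example is
consistent with it. Printed scores are truncated — not rounded — to five
decimals, matching the reference output convention (`0.56698` for the exact
value 0.5669871…).

Two numerical choices deserve note:

* **Traceback determinism and symmetry.** Among co-optimal tracebacks the
  preference is diagonal, then a gap in the second sequence, then in the
  first. Co-optimal alignments can differ in length and gap placement, so
  this order alone would make the reported score depend on argument order.
  `nw_align()` therefore canonicalises the orientation (the
  lexicographically smaller sequence is aligned first and rows are swapped
  back), which makes `score(x, y) == score(y, x)` exact while staying fully
  deterministic.
* **Floating-point ties** in the traceback are compared with tolerance
  1e-9; all substitution values are small rationals (k/26), so this is far
  below the spacing between distinct attainable costs.

`localize_trim()` implements the "local-like" mode: columns outside the
span of the shorter sequence's first and last aligned step are removed and
$H$, $GP$ and the score are recomputed on the trimmed columns (both
components, so a gap that becomes terminal within the window is re-treated
as terminal). This favours finding a short pathway embedded in a longer one.

## Batch alignment and significance

`dbalign()` aligns all unordered pairs within a database (self-pairs
excluded) or all cross pairs between two databases, keeping pairs with
score ≤ threshold (default 0.27). Pair results are computed in a fixed
deterministic order regardless of the worker count, so the output is
identical for `nproc = 1` and `nproc = 8`; rows are sorted by (id1, id2)
and can be streamed to a TSV file.

The null model (`shuffle_ess_db()`) pools every EC token of the whole
database, permutes the pool, and deals tokens back into sequences of the
original lengths: sequence lengths and the database-wide EC composition are
conserved exactly, while within-sequence co-occurrence — the family signal —
is destroyed. A *per-sequence* permutation would preserve each sequence's
own composition and leave family structure largely intact, which is why the
shuffle is global. Replicate $r$ uses seed `base_seed + r`.

`threshold_report()` deliberately avoids inventing a formula for the
qualitative published rule ("higher dispersion of the real data relative to
the mean random scores, with less than 1% of sequences lost"). It emits the
full audit curves — cumulative real and null-mean score densities and the
fraction of partnerless sequences per candidate cutoff — and recommends the
largest cutoff at which the real cumulative density strictly exceeds the
null mean while the loss stays below `loss_cap` (default 1%). The published
rule of thumb 0.27 was derived from a KEGG-wide database that is not
shipped here; it is reported alongside for comparison, never recomputed
from fixtures.

## What the synthetic generators emulate

`make_kgml()` emits minimal valid KGML with four topologies (chain, branch,
cycle, cross-map link) whose expected ESS are known in closed form; these
expectations are the primary oracle for the whole extraction pipeline.
`make_ess_db()` generates families of near-identical sequences: each family
descends from one ancestor by point EC substitutions at a set rate, and
families occupy disjoint EC top-level classes so between-family steps score
the maximal dissimilarity. Defaults (families of ~5 sequences, lengths
5–10 steps, mutation rates 0–0.2) mirror the scale of sequences a single
strict KEGG map yields.

What the fixtures do **not** emulate: realistic KEGG map statistics (hub
compounds such as ATP that create dense spurious connectivity, multi-EC
complexes, partially annotated reactions), the 300-odd EC label universe of
a KEGG snapshot, or database-scale score distributions. Passing tests
therefore demonstrate correctness of the algorithms and contracts, not that
the 0.27 cutoff is optimal for real KEGG data.

## Problem sizes used by the test suite

The suite verifies the aligner against a naive enumeration oracle over all
sequence pairs up to length 3 on a four-label alphabet (3,570 pairs) plus a
seeded sample of 400 pairs at lengths 4–5; score identities are checked on
1,000 random pairs; worker invariance on a 50-sequence family database
(1,225 pairs); and the significance machinery on 10 shuffled replicates of
20-sequence databases. These sizes exercise every code path while keeping
the whole suite around half a minute on one CPU.

## Known limitations

* EC assignment from KGML relies on `ec:` name tokens; organism-specific
  maps that carry only gene identifiers yield `9.9.9` steps unless the
  caller enriches the KGML beforehand.
* Scoring is defined at three EC levels only; four-level labels are stored
  but never scored.
* Gap costs are linear (no affine gaps), and the "local" mode is trimming,
  not true Smith–Waterman.
* `dbalign()` is exhaustive over pairs; there is no indexed pre-filter, so
  all-vs-all over very large databases is quadratic work.
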