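---
title: "Methods: screening metrics, tree classification, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening metrics, tree classification, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hgtphylo` detects candidate horizontal gene transfers (HGT) by combining
similarity-based screening with automatic gene-tree classification. This
vignette documents the model behind each stage, the tunable parameters and
their defaults, the design decisions taken where the method is genuinely
open, and what the synthetic validation does and does not demonstrate.

## Affiliations: Ingroup, Donor, and the exclusion rule

Every subject taxid is resolved against an NCBI-style taxonomy to one of
five affiliations. The user declares an **Ingroup** (the lineage considered
closely related to the query species, e.g. `Metazoa`); every other
resolvable taxon is a potential **Donor**. Two further affiliations exist
for hygiene: `QUERY` for the query species' own taxid (self-hits would
otherwise dominate every metric, so they are excluded from all
computations), and `EXCLUDED` for taxa under any user-listed lineage.
Exclusion takes precedence over everything, including the query taxid: when
scanning for transfers that may be shared with close relatives one excludes
the query's own phylum, and a hit from that phylum must vanish entirely
rather than count as Ingroup. Unresolvable taxids become `UNKNOWN`; they are
ignored by AI/h/AHS and by branch tagging (but reported), since guessing a
side for them would inject noise in exactly the situations — incomplete
taxonomies — where the data are already weakest. `affiliate()` is total: it
never errors on strange input.

## Screening metrics

Let `bestE_side` be the minimum e-value among a query's hits on one side
(ties broken by higher bitscore, then input order — determinism matters for
reproducible reports).

* **Alien Index.** `AI = ln(bestE_ingroup + ε) − ln(bestE_donor + ε)` with
  ε = 1e-200 (configurable). Positive AI: the query is more similar to a
  distant taxon. The log-ratio form is the standard one in the alien-index
  literature; ε guards `log(0)` while staying far below any realistic
  e-value, and the synthetic generator deliberately keeps e-values at or
  above 1e-180 so that ε never saturates the index. A side with no hits
  enters at e-value 1, so "donor homology only" yields a large positive AI.
* **HGT index.** `h = bestBit_donor − bestBit_ingroup`, missing sides
  contributing 0. Bitscores do not underflow, which rescues the case where
  both e-values are exactly 0.
* **outg_pct.** Among the top 10 hits by bitscore (after dropping
  `EXCLUDED`/`QUERY`), the percentage of *distinct* Donor species — species
  identity by name string when the search reports one, by taxid otherwise.
  Ten HSPs from one bacterium are one species. With fewer than 10 usable
  hits the denominator shrinks to the actual count; `top_n` is
  configurable.
* **Aggregate Hit Support.** Each bitscore is normalized against the
  query's highest bitscore `H`: `BitscoreN = b · exp(−10·(H − b)/b)`, and
  `AHS = Σ BitscoreN(Donor) − Σ BitscoreN(Ingroup)` with `H` taken over the
  union of both sides. The exponential makes the weight of a hit collapse
  as it falls behind the leader, so AHS is dominated by the strong end of
  the homology *distribution* rather than by a single (possibly
  mislabelled) best hit. The exponent's denominator is read as the hit's
  own bitscore, which gives the sharper decay; an `alt_denominator` switch
  divides by `H` instead for sensitivity analysis, since the two readings
  are both defensible. `HBitscore` is computed before any per-query hit
  cap, so capping the tree inputs never changes the metric.

Undefined rows (a query with no Donor and no Ingroup hits at all) carry
`AI = NA` and are flagged; `select_candidates()` never selects NA. The
default selection predicate is the permissive `AI > 0 | AHS > 0`; any
boolean combination over the metric columns is accepted (expression, string
or one-sided formula), and thresholds are strict inequalities.

### The F1 threshold scan

Once a first round of tree classification has confirmed a set of HGTs, the
scan `F1(N) = 2·HGT_{AI>N} / (HGT_{AI>0} + Genes_{AI>N})` over a threshold
grid (default 0–40) identifies the AI cutoff that best balances precision
and sensitivity for *this* dataset, rather than inheriting a cutoff
calibrated on another species. The implementation enforces the algebraic
identity with `2PR/(P+R)` and reports the argmax (smallest N on ties).

## Gene-tree classification

Candidates are grouped by single-linkage clustering with an edge wherever
the shared-hit fraction reaches 70%. The denominator of that fraction is the
*smaller* hit set, so a sparsely annotated query fully nested in a richer
one still clusters with it; a Jaccard (union) denominator is available.
Per-query hits are capped at the top 100 by bitscore when building group
FASTAs (a bound on tree size; configurable), headers encode the subject
taxid as `id|taxid` so leaves re-affiliate without the hit table, and groups
with fewer than four sequences skip tree building and are reported
`COMPLEX` with a `too_few_homologs` flag — no phylogeny is possible there.

Each tree is **midpoint rooted**: the root is placed halfway along the
longest leaf-to-leaf path. The diameter pair is found from patristic
distances; ties are broken by the lexicographically smallest label pair so
that rooting is deterministic. The rooted tree satisfies, up to a numeric
tolerance of 1e-6 times the diameter, equality of the two root-side depths.
Optionally, internal edges with support below a user threshold are
contracted into polytomies first; the default threshold is 0 — no collapse
unless requested.

The **sister branch** (SB) of the query leaf is its sibling subtree (in a
polytomy: the union of all co-children); the **ancestral sister branch**
(ASB) is the sibling of the query's parent, and is `NOT_PRESENT` when that
parent is the root. When the sister branch contains only other
query-species sequences (paralogs), the query clade is enlarged to its
parent and the search ascends — without this rule any recently duplicated
transfer would classify against its own paralogs.

Both branches are tagged by their informative leaves (`QUERY`, `EXCLUDED`,
`UNKNOWN` dropped): `DONOR` or `INGROUP` when that side holds ≥ 80% of the
leaves, `BOTH` otherwise, `EMPTY` when nothing informative remains.
Sequences are counted, not distinct species; a branch of ten strains of one
contaminant still *is* taxonomically one-sided, and collapsing them would
hide that. The 80% majority and the "minority above one in five means
mixed" reading are reconciled into the single `majority_threshold` knob
(default 0.8): the two printed rules disagree only for minority fractions
in (1/6, 1/5), and one monotone threshold keeps behaviour predictable. The
tag pair is then looked up in the fixed 12-cell decision matrix (see the
README); two edge cases the matrix does not cover are resolved as: an
`EMPTY` sister branch yields `COMPLEX` with a flag (there is literally no
evidence either way), and an `EMPTY` ancestral sister branch is treated as
`NOT_PRESENT` (no ancestral signal). Per-query results keep full
provenance — tags, leaf lists, flags — and a FigTree-readable NEXUS file
colours every leaf by affiliation.

## Downstream checks

**Origin classification** walks a user-supplied nested rank hierarchy
(coarse → fine, e.g. Bacteria → Proteobacteria) and reports the deepest
rank containing ≥ 80% of the donor leaves' lineages — the same majority
logic as branch tagging — or `"ambiguous"`.

**Topology evaluation** asks whether the data actually prefer the HGT
topology: the alternative is a constrained tree in which the query plus all
Ingroup sequences form one monophyletic group, `((q, i1..im), d1..dk);`.
Constrained inference and the topology-test run are external commands
(IQ-TREE-style) driven by `{placeholder}` templates; the report parser
tolerates whitespace and fails loudly when the AU column is missing. The
decision statistic is the AU test at α = 0.05: the constrained topology
rejected (p < α) means the HGT topology is `STRONG`ly preferred, otherwise
`EQUAL` — the candidate survives but downgraded. Other tests in the report
(KH, SH, wKH, wSH, c-ELW, bp-RELL) are carried through but not decisive;
the AU test is the field's standard for comparing a small set of candidate
topologies.

**Genomic neighborhood score.** For each confirmed candidate with a GFF3
locus, up to `window = 10` genes on each side of it *on the same scaffold*
are collected (rank-based: strand and intergenic distances are ignored) and
their status weights averaged. Defaults: `NO` and `NOT_TESTED` +1 (a
neighbor with Ingroup-dominated homology is the clearest vertical signal),
`COMPLEX` −0.5, `HGT` −1, `NO_HITS` 0; every weight is a config key. Scores
below 0 (configurable) raise a contamination alert, with the standing
caveat that block transfers and post-acquisition duplications also produce
negative scores. A candidate alone on its scaffold has no neighbors and its
score is reported as undefined rather than silently 0.

## The synthetic validation model

The `fixtures` module generates every input with known planted truth:

* **Taxonomies**: two disjoint clades under one root (Metazoa-like ingroup
  with the query species, Bacteria-like donors), emitted as a standard
  nodes+names dump.
* **Hit tables**: planted-HGT queries draw Donor log10 e-values uniformly
  in [−180, −100] and Ingroup in [−50, −5]; native queries the mirror
  image. Bitscores are linear in −log10(e) with small jitter. The gap
  between the two ranges is deliberate: all of AI, h and AHS separate the
  classes with probability 1, so any failure in a pipeline test indicts the
  pipeline, not the generator. Twenty queries with eight hits per side is
  the default scenario size.
* **Gene trees**: topology `(((query, SB), ASB), out)` with a distant
  outgroup on a branch of length 10 against internal edges below 0.5, which
  pins the midpoint onto the outgroup edge and makes the planted (ASB, SB)
  tag pair survive rooting; the `NOT_PRESENT` row puts the query itself on
  the long branch. `BOTH` branches mix donors and ingroup 60/40 — inside
  the mixed band at the 0.8 threshold for any branch of ≥ 2 leaves.
* **Genomes**: native scaffolds of `NO` genes with isolated planted `HGT`
  insertions, plus contaminant scaffolds consisting entirely of `HGT`
  genes. Contamination is modelled as whole alien contigs — the classic
  assembly signature — because a short alien block *embedded* in a native
  scaffold is mathematically invisible to a symmetric rank window at its
  edges (the native flank contributes +w against at most −w from the block
  side), so "every block gene scores negative" is only a fair planted truth
  for standalone contaminant contigs.

Every generator is a pure function of its seed. What passing these tests
shows: the decision matrix, metric algebra, rooting, grouping and scoring
machinery are each correct against independent oracles (direct evaluation,
brute-force path enumeration, union-find components, hand-traced
topologies), and the assembled pipeline preserves planted truth end to end.
What it does not show: behaviour on real homology distributions (overlapping
e-value ranges, paralog interleaving, incomplete taxonomies), real
alignment/inference error, or contamination patterns subtler than whole
contigs. The tree-inference stage itself is mocked in tests — alignment and
likelihood inference are external tools by design, and their correctness is
not this package's claim.

## Numerical choices and problem sizes

ε = 1e-200 for AI; midpoint tolerance 1e-6 × diameter; all best-hit and
diameter ties broken deterministically (e-value, then bitscore, then input
order; lexicographic label pairs for tree diameters); group numbering by
smallest member id. Verdicts serialize as `HGT`/`COMPLEX`/`NO` in TSVs, with
the ✓/?/✗ glyphs reserved for human-readable printing. The validation suite
uses 12 × 5 planted trees, 50 random 20-leaf trees for rooting, 100 random
candidate sets for grouping, 20 planted genomes, and a 30-query end-to-end
workspace — sizes chosen so the full suite and the acceptance script each
run in well under a minute while every property is exercised across its
whole input space.

## Known limitations

Classification counts sequences, not species, when tagging branches;
taxon-sampling bias in the database therefore propagates into tags.
Single-linkage grouping can chain unrelated queries through promiscuous
hits (domain walking). The local score is rank-based and blind to physical
distance. Branch-support values are only honoured when the user sets a
collapse threshold; rerooting tools differ in how they transfer support
labels across the root, which is why the default leaves supports untouched.
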