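---
title: "Functional-family annotation transfer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-family annotation transfer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funfamscan)
```

## The problem

Transferring function annotations to an uncharacterized protein from
its closest BLAST hit is error-prone: paralogs, multifunctional
relatives, multidomain proteins with shuffled domain content and
database misannotations all propagate wrong labels.  A more reliable
strategy first subclassifies each domain superfamily into *functional
families* (FunFams) — groups of domain relatives inferred to share the
same or highly similar function — and then transfers only the
annotations of the one functional family each domain of the query
actually matches.

`funfamscan` implements that annotation-transfer pipeline end to end
for a library of functional families that the user supplies as
alignments plus per-member GO/EC annotations:

1. **Scan**: the query is scored against every family's profile HMM by
   local Viterbi alignment; scores become E-values through a
   per-family Gumbel calibration.
2. **Threshold**: a match is accepted only if its E-value is at or
   below the family's *inclusion threshold* — the worst (maximum)
   E-value obtained by the family's own members against the family
   profile.  This per-family adaptive cutoff is what distinguishes the
   approach from a fixed global E-value cutoff.
3. **Resolve**: accepted matches are collapsed into one consistent
   multidomain architecture (MDA) that maximizes residue coverage
   without overlaps, allowing discontinuous (split) domains.
4. **Transfer**: each matched family contributes its GO terms with a
   confidence equal to the term's frequency among the family's
   *annotated* members.
5. **Propagate**: confidences are pushed up the GO DAG over `is_a` and
   `part_of` edges, each term keeping the maximum score it receives.
6. **Merge**: per-domain sets combine into one nonredundant protein
   set, each term retaining its highest confidence.

The package generates the families it is tested on (the
`sim_config()` / `simulate_library()` / `simulate_queries()` module);
building functional families from real superfamily alignments —
clustering, specificity-determining positions, functional-coherence
scoring — is out of scope.

## The profile model

Each family alignment becomes a simplified Plan7-style profile:
alignment columns with gap fraction < 0.5 are match nodes (the HMMER
convention); match emissions are column residue counts with a Laplace
pseudocount of 1 over the 20 standard residues; per-node transition
probabilities (M→M/I/D, I→M/I, D→M/D) are counted from each row's
observed state path, also with pseudocount 1.  The background model is
uniform (1/20 per residue), so insert states — which emit the
background — contribute 0 bits, and the Viterbi bit score is the
log2-odds of the aligned subsequence under the model versus the
background.  Alignment is local on both the sequence and the model:
entry and exit at any match node are free.  Tie-breaking prefers Match
over Insert over Delete, making scores and paths fully deterministic.
There is no multi-hit (J) state; repeated domains are found by
re-running Viterbi with previously matched residues masked (up to 4
rounds).

Two mechanisms produce discontinuous matches:

* a single Viterbi path that bridges an insertion longer than
  `split_insert` (default 20) residues is split into segments, with
  the bridged insertion excluded and scored as free — without this, a
  split domain A–B–A would be reported as one segment swallowing B;
* masked re-scan matches of the same family are merged when the later
  match continues the earlier one on both the query and the model
  (model overlap up to 5 nodes is tolerated, because local alignment
  ends wobble at a split point).

In both cases the discontinuous match is one hit: its bit score is the
sum of the segment scores and its E-value is recomputed from that sum.

## E-values

Viterbi scores of random sequences follow an extreme-value law, so
each profile is calibrated once against `n_random` (default 200)
seeded i.i.d. background sequences of fixed length (default 150), and
a Gumbel distribution is fitted by the method of moments
(`lambda = pi / (sd sqrt 6)`, `mu = mean − gamma/lambda`).  Then
`E = db_size · (1 − exp(−exp(−lambda (S − mu))))` with `db_size` the
number of families in the library.  No query-length correction is
applied; the calibration length is a package constant chosen near the
typical query length.  On held-out background sequences the empirical
`P(E ≤ 0.1)` lands close to 0.1 (the acceptance script measures it),
which is what the inclusion-threshold logic needs: E-values on a
common, roughly uniform scale.

Alternatively, matches computed externally by `hmmscan` can be
ingested from `--domtblout` files (`parse_domtblout()`), using the
envelope coordinates as segments and the per-domain independent
E-value (i-Evalue) as the match E-value.  The full-sequence E-value
would be the other defensible choice; the independent E-value is used
because thresholds are applied per domain region.

## The inclusion threshold and small families

The inclusion threshold of a family is the maximum E-value any of its
members attains against the family profile
(`compute_inclusion_threshold()`, which takes the scanning function as
an argument).  `build_library()` offers two wirings:

* `threshold_mode = "self"`: each member is scored against the profile
  built from the full alignment — the literal definition.
* `threshold_mode = "jackknife"` (default): each member is scored
  against the profile re-estimated *without* that member, with
  E-values computed on the full profile's calibration.

The default matters for small families.  With a handful of members,
every member's own residues sit in the emission counts, so in-sample
self-scores are optimistically biased by several bits; the in-sample
maximum then underestimates the E-value a genuine *new* family member
would attain, and the threshold rejects most of them.  In a library of
five-member synthetic families the leave-in threshold rejected the
majority of held-out true members, while the jackknifed threshold
accepts essentially all of them and still rejects random sequences by
dozens of orders of magnitude of E-value.  Large, diverse families —
where between-member spread dwarfs the self-inclusion bias — can use
`"self"` to match the literal definition.  Either way each member's
own self-scan E-value is at or below the stored threshold.

## Architecture resolution

`resolve_mda()` selects the accepted matches that maximize total
residue coverage subject to pairwise segment disjointness; ties break
by lower E-value product, then lexicographic family id.  Inputs of
single-segment matches are solved exactly by weighted-interval
scheduling DP; when discontinuous matches are present an exhaustive
subset search is used up to 20 candidates, beyond which a greedy pass
by ascending E-value runs with a warning.  `slack` controls how many
residues two retained matches may share: the function default is the
strict 0, but the annotation pipeline (`annotate_sequence()`) passes
`overlap_slack = 5` and trims contested residues from the weaker
match, because local alignment ends overshoot a few residues into a
neighbouring domain and a strict rule would discard genuinely
adjacent or nested domains.  The reported architecture is always
strictly disjoint.

## Confidence scores and the GO DAG

The confidence of a transferred term is its frequency among the
*annotated* members of the matched family — members with no
annotations do not count in the denominator (a family of 2 annotated
+ 3 unannotated members, both annotated carrying a term, gives
confidence 1.0).  EC numbers are carried and reported with
frequencies exactly like GO terms but are never propagated (EC is not
a DAG here).

Propagation follows the GO-consortium convention: `is_a` and
`part_of` edges both imply annotation of the parent, `regulates`-type
relations are ignored, cross-namespace edges are not followed, and
the operation is `score'(t) = max over annotated descendants` — hence
idempotent, monotone, and distributive over per-domain merging (all
property-tested).  Terms unknown to the ontology and obsolete terms
are dropped with a warning at transfer time; `alt_id`s resolve to
their primary term.  Root terms receive propagated scores but are
excluded from evaluation, per CAFA practice.

## Evaluation

`precision_recall()` implements the CAFA-style definitions on a
101-point threshold grid over [0, 1]: precision at threshold *t*
averages `|P_i(t) ∩ T_i| / |P_i(t)|` over proteins with at least one
prediction scoring ≥ *t* (the CAFA choice for the averaging set);
recall averages `|P_i(t) ∩ T_i| / |T_i|` over *all* benchmark
proteins; `Fmax` is the maximum harmonic mean (0/0 counted as 0).
Root terms are excluded from predictions and truth.

Two baselines mirror common comparators: `blast_baseline()` transfers
all terms of the top local-alignment hit (Smith–Waterman, BLOSUM62) at
confidence exactly 1, and `flat_family_baseline()` runs the same
pipeline over a library collapsed to one family per superfamily,
modelling flat (non-subclassified) domain family resources.  With two
equally sized subfamilies, a subfamily-specific term is diluted to
confidence 0.5 in the flat baseline while the subfamily-aware
pipeline reports 1.0 — the core benefit of functional
subclassification, and the property the acceptance checks assert.
`identity_filter()` supports rollback-style benchmark construction by
removing queries above a sequence-identity cutoff (default 0.5) to any
annotated database sequence; identity is matches over global-alignment
length including internal gaps (denominator over the shorter sequence
is available as an option), and `rollback_targets()` is the
set-difference helper over two annotation snapshots.

## The synthetic generator

`simulate_library()` emulates the structure the pipeline is designed
for: each superfamily descends from one ancestral uniform-random
sequence of `domain_length` (default 80) residues; each subfamily
consensus mutates the ancestor at `2 × mutation_rate` per site; each
of `members_per_subfamily` (default 5) members mutates the consensus
at `mutation_rate` (default 0.05, a realistic within-family divergence
at which ~1 in 20 positions differ).  Substitutions draw uniformly
from the 19 other residues.  Each subfamily carries a distinct leaf
term of the toy ontology plus a term shared across its superfamily,
annotated on `annotated_fraction` (default 0.8) of members, plus a
distinct synthetic EC number.  Synthetic domains are ungapped and
equal-length, so member stacks are valid alignments — alignment
generation is deliberately sidestepped, and a small hand-written
gapped alignment under `inst/extdata/` covers the gap-handling code
paths.  `make_toy_dag()` builds a single-namespace tree (default
depth 4, branching 2) and adds a second, shallower parent to each
non-root term with probability 0.2, keeping the graph acyclic.
`simulate_queries()` emits held-out single-domain mutants (5 per
subfamily), a cross-superfamily two-domain concatenation, one
discontinuous construction (a domain split in half with another
domain inserted between the halves) and random negatives, together
with a ground-truth table of expected families, segments and
propagated terms.

What passing on these fixtures shows — and does not show: the
synthetic families have no indels, no rate heterogeneity across
sites, uniform residue composition and i.i.d. member divergence, so
results quantify the pipeline's internal consistency (self-recovery,
threshold calibration, architecture resolution, score propagation),
not performance on real, compositionally biased, unevenly diverged
protein families.

## Numerical choices and degenerate inputs

* Fixed seeds flow through every stochastic step (`withr::with_seed`);
  regeneration is byte-identical, and scans of identical inputs are
  byte-identical.
* Viterbi tie-breaks: candidate predecessors are examined in the order
  Match, Insert, Delete, fresh-start; the best end cell is the first
  encountered in sequence-then-node order.
* A ragged alignment is a format error; an empty alignment, an empty
  sequence, an all-gap column set (no match columns), fewer than two
  sequences for conservation scoring, duplicate FASTA ids and an empty
  FASTA file are value errors; a zero-variance calibration sample is a
  calibration error; `n_random < 100` is rejected.
* Residues outside the 20-letter alphabet score as a uniform-emission
  wildcard; non-alphabetic characters in a query are an input error.
* Conservation scores (`conservation_scores()`) are the mean over
  residue pairs of a normalized BLOSUM62 similarity
  `max(0, M[a,b] / sqrt(M[a,a] M[b,b]))`, gaps scoring 0 against
  anything, giving scores in [0, 1] with gap-free invariant columns
  exactly 1.  This is a sum-of-pairs stand-in for entropy-based
  conservation scoring; reproducing any particular published scorer is
  a non-goal.

## Problem sizes in the test suite

The shipped tests and the acceptance script run entirely on synthetic
data at sizes a laptop handles in seconds: DP-vs-enumeration on 200
random instances (≤ 4 nodes, ≤ 6 residues), resolver-vs-DP on 500
instances (≤ 15 matches), 100 toy precision–recall benchmarks,
propagation laws on 200 random DAGs, and full pipelines over 2 × 2
superfamily/subfamily libraries with 5–10 members per family.  These
sizes were chosen to exercise every code path with exhaustible
oracles, not to emulate the scale of a production family library.

## Known limitations

* Bit scores and E-values are not comparable to HMMER3's (no Dirichlet
  mixture priors, no sequence weighting, no multihit model, no
  forward-algorithm E-values); within-package comparisons are
  consistent, which is all the threshold logic requires.
* One best match per family per query is reported; tandem repeats of
  the same family appear as a merged discontinuous match or are
  suppressed once four masked rounds are exhausted.
* The Gumbel calibration uses a fixed background length; E-values for
  queries much longer than the calibration length are slightly
  conservative.
* `collapse_to_superfamilies()` requires equal alignment widths within
  a superfamily, which holds for the synthetic libraries; pooling real
  alignments of different widths would require re-alignment, which is
  out of scope.
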