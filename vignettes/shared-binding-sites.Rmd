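---
title: "Methods: shared binding-site detection in exapted SINE families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shared binding-site detection in exapted SINE families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the models and
procedures each stage implements, the assumptions behind them, the
parameters that matter, and the choices we made where the design was
genuinely open. The companion README shows a worked run; nothing stated
here goes beyond what the package's tests and acceptance script themselves
compute.

## The analysis in one paragraph

A SINE family is a set of diverged, mostly 5′-truncated copies of one
master (consensus) sequence. The pipeline asks: *which transcription-factor
motifs occur at the same consensus position in many copies?* Such shared
sites are candidate exaptation-era regulatory elements, inherited from the
master rather than gained independently. The stages are: scan every locus
with position weight matrices on both strands; align every locus to the
consensus; push each motif hit through the alignment into consensus
coordinates, resolving strand; count loci per consensus position, cluster
loci sharing a site location, and test whether sites concentrate in
annotated consensus domains; separately, build an exact maximum-parsimony
tree for orthologous copies of a single locus, rooted on the consensus as
outgroup.

## Motif scanning

PWMs are built from TRANSFAC-style nucleotide count matrices. Column
probabilities use additive smoothing, `P(b|j) = (n_b(j) + ε)/(N_j + 4ε)`,
scores are `log2(P/q_b)` in bits, and a window's score is the column sum.

Tunable parameters:

* `pseudocount` ε (default **0.25** per base) — the conventional ¼-per-base
  smoothing; avoids −∞ columns while barely moving well-populated counts.
* `background` (default **uniform**) — simulated families are uniform-base;
  callers analysing real loci can supply genomic composition.
* `threshold_fraction` f, with threshold `t = min + f·(max − min)`
  (default **0.8**) — a relative threshold is the only option that works
  across matrices of very different information content without fitted
  score distributions. `f = 1` accepts only per-column-optimal windows.

Windows containing `N` are disqualified outright rather than marginalised —
simpler and conservative. Overlapping hits are all reported; deduplication
happens at the locus-counting stage where it is scientifically meaningful.
Minus-strand hits are reported in plus-strand coordinates of the scanned
sequence, and ties in output order are broken by (start, strand) so output
is byte-stable.

The scanner is intentionally exhaustive (every window, both strands); the
test suite holds it equal to an independent brute-force re-scorer to 1e−9
bits.

## Consensus alignment

Copies are aligned to the consensus by a semi-global dynamic program: the
entire locus must align, end gaps on the **consensus** side are free, and
internal gaps carry affine costs (a length-k gap costs `open + k·extend`).
Free consensus end gaps are the right model because SINE copies are
end-truncated, not internally rearranged; a local alignment could fragment
the copy, while a fully global one would penalise genuine truncation.
Defaults `match = +1`, `mismatch = −1`, `gap_open = −4`, `gap_extend = −1`
are ordinary DNA scoring ratios; nothing downstream is sensitive to them at
the divergences we target (≤ 15%). `N` scores as a mismatch against
everything, including `N`.

Both orientations of each locus are aligned and the better kept (ties
favour `+`); stored orientation metadata is advisory only. The dynamic
program is executed by `Biostrings::pairwiseAlignment(type =
"global-local")`, whose traceback is deterministic; optimal tracebacks can
tie (for example, a gap sliding along a run of equal bases), so positions
*within* an indel neighbourhood may map differently than the generating
edit list while the score and all other columns agree. The test suite
accounts for this by requiring ≥95% column agreement with the generator's
true maps at 10% divergence rather than identity.

The product is a bidirectional position map; `map_position()` returns `NA`
(the unaligned flag) for locus positions inside locus-only insertions or
outside the aligned span, and is strictly increasing over aligned
positions.

An open question we had to settle: whether to place sites on the consensus
through per-locus pairwise maps or a family multiple alignment. We chose
pairwise maps — each locus's coordinates are then independent of the rest
of the set, results are stable under adding/removing loci, and no MSA
ambiguity enters the coordinate system. The cost is that two loci can in
principle disagree slightly about a column near an indel; the clustering
tolerance (below) absorbs this.

## Projection, histogram, clusters, enrichment

A hit's consensus interval is the span `[min, max+1)` of the consensus
columns paired with its locus positions. Hits mapping fewer than
`min_aligned_frac` (default **0.8**) of their columns are rejected with a
reason, so stage counts always reconcile exactly (`hits = projected +
rejected`). Consensus strand is the hit strand composed with alignment
orientation.

The position histogram counts **loci**, not hits: a locus contributes at
most 1 per position per motif and strand, whatever its internal hit
structure. Claims of the form "k loci share this site" count loci, so the
data structure does too. Consequently the histogram's conservation
identity is: total mass = Σ over (motif, strand, locus) of the per-locus
covered-interval **union** lengths.

"Sites at similar locations" is operationalised as single-linkage
clustering of projected start positions with linkage distance ≤ `w`
(default **5 nt**) per motif × consensus strand. `w` is the principal free
parameter of the whole analysis — nothing in the underlying biology fixes
it — so it is surfaced in the configuration and CLI; 5 nt covers
projection jitter near indels without merging genuinely distinct sites of
typical 8–12-nt motifs. Clusters report distinct-locus counts and a
representative interval (the modal projected interval, ties leftmost).

Domain enrichment assigns each hit to the domain containing its interval
midpoint (unambiguous and order-independent for boundary-straddling hits)
and compares observed per-domain counts against `M` uniform placements of
each hit over all consensus start positions where it fits. The one-sided
p-value uses the add-one permutation convention, `p = (1 + #{perm ≥ obs}) /
(M + 1)`, so `p ∈ (0, 1]` and the resolution floor at the default `M =
1000` is 1/1001. Benjamini–Hochberg q-values across motif × domain rows
are provided but labelled exploratory — the analysis is descriptive, not a
formal multiple-testing design.

Strand convention: the histogram's forward/reverse split is relative to
the **consensus**, not to each genomic locus. This is the convention under
which the whole analysis is invariant to how loci happen to be stored: the
test suite verifies byte-identical histograms and clusters after
reverse-complementing every input locus.

## Maximum parsimony

Orthologous copies of one locus are analysed with unit-cost Fitch
parsimony. Gaps and `N` are treated as missing data (leaf state set = all
four bases) rather than a fifth state — indels in these alignments are
mostly alignment artefacts of diverged non-coding sequence, and a fifth
state would let a single deletion spanning several columns count multiple
times; the choice is recorded and switchable in principle by recoding the
input. Search is exact: exhaustive stepwise-addition enumeration up to 7
taxa, branch-and-bound (pruning on the monotone partial-tree score) up to
12. All co-optimal topologies are reported — picking one arbitrarily would
overstate resolution. No heuristic search is provided because orthologous
locus sets in this setting are small (≈9 species); the capacity error
says so.

Determinism: topologies are serialised with subtrees sorted by smallest
descendant label, ambiguous Fitch state choices resolve in base order
A<C<G<T, and at the root the state prefers the outgroup side so
substitutions attach to ingroup branches. Branch "lengths" in the output
Newick are per-branch change counts from that single deterministic
most-parsimonious reconstruction. Taxon input order never affects results
(addition order is fixed by sorted labels; the suite checks this).

## The synthetic family generator

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is demonstrated.

What it emulates: a **570-nt** consensus (the canonical length for the
amniote tRNA-derived family modelled here) with four ordered domains —
5S-promoter, tRNA-derived region, Deu-domain, 3′ tail. Only the total
length and domain order are established for the real family; the default
lengths **60/120/150/240 nt** are package choices giving a mid-consensus
Deu-domain of plausible size. The family default is **124 copies**
(matching the size of the classic conserved-locus set), per-site
substitution probability **0.10** and indel initiation **0.005** with
geometric lengths of mean 2 (the literature gives no divergence estimates
for such sets; these are placeholder rates typical of conserved repeat
copies, not inferences), 5′ truncation uniform over `[0, 285]` by default
(copies retain at least the 3′ half; a fixed offset of 256 reproduces
copies retaining exactly `[256, 570)`), and optional random storage
orientation. Substitutions are single-pass per-site uniform over the three
other bases — no back-mutation within a pass, so the expected mismatch
fraction equals the divergence parameter exactly, which is what makes the
generator calibratable by a binomial test.

Embedded motif instances model exaptation-era sites: one ancestral
instance sequence per embedding (per-column argmax of the count matrix, or
a frequency draw), placed at one consensus position on either strand in a
chosen locus subset **before** truncation and mutation. With
`protect_embedded = TRUE` (default) the embedded interval is immune to
substitutions and indels, so recovery experiments measure pipeline error,
not simulation noise; an unprotected mode exists for stress tests. Sites
5′ of a copy's truncation point are flagged as not surviving — partial
truncation destroys a site, so survival requires the full interval.

What it does **not** emulate: rate heterogeneity across sites or branches,
CpG hypermutability, target-site duplications of real retroposition,
selection, or GC-biased composition. Passing tests therefore demonstrate
algorithmic correctness and calibration under a neutral, uniform model —
not performance on real genomic repeats. One property of the uniform model
worth knowing: a random consensus occasionally contains a perfect motif
occurrence by chance, which the whole family then genuinely inherits; the
pipeline correctly reports it as a shared site (it *is* one, by descent),
and recovery experiments must read ground truth accordingly.

## Problem sizes and thresholds used in the checks

The test suite and acceptance script run, as the package's chosen
demonstration sizes: 50 random 500-nt sequences × 3 PWMs against the
brute-force scan oracle; 124-locus × 570-nt families over ten seeds for
embedded-site recovery; 100 random 5-taxon × 30-site alignments against a
Sankoff oracle; twenty 6-taxon × 600-site ortholog simulations at
per-branch substitution probability 0.05 for topology recovery; 10,000
permutations for the enrichment floor check.

Recovery experiments scan at `threshold_fraction = 0.95` rather than the
0.8 default. The reason is analytic: a protected embedded instance scores
the per-column maximum, so it always survives any threshold, while the
expected number of chance windows passing threshold grows rapidly as f
drops (at f ≈ 0.8 an 8-column matrix of this information content admits
one to two mismatches, and a 570-nt random consensus then carries such
windows with appreciable probability, which the family inherits). A
threshold that only accepts per-column-optimal windows makes "the embedded
site" and "what the scanner reports" coincide, which is the property the
recovery experiment is meant to isolate. For exploratory analysis of real
loci the permissive default remains appropriate.

## Degenerate inputs and edge conventions

Empty sequences, non-ACGTN characters, rates outside `[0,1)`,
`divergence + indel_rate ≥ 1`, thresholds outside `[0,1]`, permutation
counts below 100, missing domain annotation for enrichment, and taxon
mismatches all raise immediate, named errors. Sequences shorter than a
motif scan to an empty hit table (not an error). Zero projected hits give
an all-zero histogram and p = 1 everywhere. A whole-consensus domain gives
p = 1 exactly, by construction of the add-one estimator.

## Known limitations

* Projection fidelity degrades near indels; at divergence ≳0.2 the
  per-locus maps become unreliable and no warning is currently raised.
* The enrichment null places hits independently and uniformly; it ignores
  composition bias and alignability differences between domains.
* Branch-and-bound is exact but exponential; beyond ~12 taxa the search
  refuses rather than degrades to a heuristic.
* The permutation and BH machinery is exploratory; the package makes no
  formal inferential claims about domain concentration.
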