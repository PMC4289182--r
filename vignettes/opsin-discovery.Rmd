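---
title: "Mining and classifying opsin genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and classifying opsin genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsinminer)
```

## The problem

Opsins are retinal-binding G-protein-coupled receptors that mediate both
visual and non-visual photoreception.  In non-model invertebrates --
echinoderms such as brittle stars being the motivating case -- the opsin
repertoire must be mined from draft nucleotide assemblies: candidate
loci are found by translated homology search against a reference opsin
panel, validated as opsins (rather than related non-opsin GPCRs), and
classified into the canonical families (ciliary, rhabdomeric, Go,
neuropsin, peropsin, RGR, and basal-branch "echinopsins") by sequence
similarity, diagnostic residues and phylogenetic placement.  Candidate
gene expression is checked against transcriptome sequences, and a
companion module analyses day/night activity counts from a
multi-wavelength photoperiod experiment.

All residue positions in this package use **anchor numbering**: the
coordinates of a 348-residue mammalian rhodopsin, onto which every
candidate is mapped by alignment.  The diagnostic scheme
(`diagnostic_scheme()`) is the single home of those positions:

* **K296** -- the Schiff-base lysine that covalently binds the retinal
  chromophore.  Its presence at the mapped 296-equivalent defines a
  *bona fide* opsin; a covered site with another residue refutes it;
  an uncovered site (incomplete fragment) leaves the status
  indeterminate.
* **113** -- the vertebrate-type counterion site: E is the
  vertebrate-type glutamate, Y the invertebrate-type tyrosine.
* **E181** -- the ancestral counterion, retained by many invertebrate
  and "group 4" opsins.
* **134-136** -- the D(E)RY tripeptide of the ionic lock; "DRY-like"
  variants accept D/E at 134 and a configurable set at 136, with R
  fixed at 135.
* **302-313** -- the NPxxY(x)6F pattern; the call requires N302, P303,
  the Y306-equivalent and the F313-equivalent through the residue map,
  so insertions between mapped sites do not break it.
* **310-312** -- the internal triad: NxQ marks ciliary opsins, HxK
  rhabdomeric ones, HxS a derived state, anything else "other".
* **C110/C187** and **C322/C323** -- the disulfide and palmitoylation
  cysteine pairs.

`validate_scheme()` confirms that the shipped anchor actually carries
every expected residue, so no downstream module ever hard-codes these
positions against an inconsistent reference.

## Reference fixtures are synthetic stand-ins

The real anchor rhodopsin and the nine sea-urchin-style family
exemplars live in online sequence databases.  The panel shipped under
`inst/extdata/reference_panel_synthetic.*` is instead **constructed**
(deterministically, by `build_synthetic_panel()`): a rhodopsin-like
348-residue consensus anchor whose diagnostic sites are canonical by
construction, and nine exemplars derived from that scaffold at 35%
divergence outside the diagnostic sites, each given its
family-diagnostic motif states (the peropsin exemplar, for instance,
lacks the Schiff-base lysine and is the panel's pseudo-opsin).  The Go
pair (3.1/3.2) shares a family template so that within-family
similarity exceeds between-family similarity, which is also why the
leave-one-out family-recovery property is only testable on families
with at least two exemplars.  Conclusions drawn from runs against this
panel are about the *pipeline*, not about any real species' opsins;
`analyse_deposited()` accepts real deposited sequences when they are
available (a network fetch script is provided), and family calls there
are only as faithful as the panel references used.

## Pairwise alignment

All comparisons rest on Needleman-Wunsch (global) and Smith-Waterman
(local) alignment with affine gaps, implemented in C++ and checked in
the test suite against an exhaustive matching-enumeration oracle on
short sequences.

* Substitution matrix: BLOSUM62 (as distributed with Biostrings), with
  the `X` row and column zeroed -- an untranslatable codon neither
  rewards nor penalises any pairing.
* Gap costs: a gap of length $k$ costs $10 + 0.5\,(k-1)$ (EMBOSS-style
  defaults); end gaps are charged in global mode, free in local mode.
* Traceback ties prefer diagonal over a gap in the subject over a gap
  in the query, making every alignment deterministic.
* Identity counts identical columns over *all* aligned columns (gap
  columns stay in the denominator); similarity additionally counts
  columns whose residues share a similarity group, using a
  conservative-substitution partition ({G,A,S,T}, {I,L,V,M}, {F,Y,W},
  {K,R,H}, {D,E,N,Q}, {C}, {P}).  The exact percentages therefore
  depend on this partition and on the local-alignment trimming; only
  the ranking behaviour, not individual cell values, should be
  compared across software.

## Translated search, RBH, and two calibrated thresholds

`translated_search()` aligns all six reading frames of every contig
against every panel protein and reports hits with contig coordinates
back-computed from frame arithmetic.  Two defaults were calibrated
once, against the pipeline's own null behaviour, and then frozen:

* **`min_score = 100`** matrix units.  Measured null maxima of the
  search over desk-scale random assemblies (40 seeds, eight 2.2-kb
  junk contigs against the 10-protein panel) range from 57 to 75, so a
  threshold in the 50s admits spurious loci in essentially every run,
  while the weakest genuine fragment hits in the synthetic study score
  around 400.  At 100 the expected number of random hits per assembly
  is on the order of $10^{-5}$.
* **`trim_rate = 1`** matrix unit per aligned column.  An optimal
  local alignment occasionally extends tens of residues through cheap
  affine gaps into flanking junk translation (every prefix of an
  optimal alignment has positive score, so such extensions are "real"
  but barely).  Terminal segments averaging under 1 unit/column are
  trimmed -- genuine homologous ends accumulate 3-5 units/column even
  at 30% divergence, junk extensions sit near zero.  Without this
  BLAST-HSP-style end trimming, bridged extensions stochastically
  overlapped the reference spans of split-gene fragments (defeating
  the non-overlap merge) and polluted residue mappings.

Reciprocal best hit (`reciprocal_best_hit()`) validates candidates the
way the original searches used an online database: the reverse search
runs against the panel *plus* a decoy database
(`decoy_gpcr_panel()`: a melatonin-receptor-like non-opsin GPCR
template -- the anchor scaffold at 60% divergence without the
Schiff-base lysine -- and unrelated random proteins).  A candidate is
confirmed only if its reverse top hit is an opsin panel member.

Fragments are expected, not errors.  `merge_nonoverlapping_fragments()`
implements the rule that loci sharing a best reference with pairwise
disjoint reference spans are fragments of one gene (suffixed .A/.B in
reference order), while overlapping spans mark putative paralogs, and
different references never merge.

## Transmembrane verification

`predict_tm_helices()` is a Kyte-Doolittle sliding-window hydropathy
caller: window mean $\ge$ threshold marks TM-candidate residues, and
maximal runs of at least `min_helix_len` are helices.  The defaults
(window 19, threshold 1.1, minimum run 6) were chosen by grid search so
that the anchor rhodopsin yields exactly its seven helices, then
frozen; with the textbook starting point (threshold 1.6, run 15) the
anchor yields fewer.  The helix count is recorded on every candidate
but never gates it, since genuine fragments are too short to show all
seven.  Note a generator limitation below: synthetic divergence is
hydrophobicity-blind, so diverged synthetic genes systematically lose
hydropathy signal and their TM counts underestimate what comparable
real sequences would show.

## Residue-frame mapping

Diagnostic calls require a candidate-to-anchor position equivalence.
The obvious single global alignment to the anchor runs at ~48%
identity for realistic candidates and was measured to lose or shift a
diagnostic site in roughly 0.2% of gene/seed combinations.
`diagnose_candidates()` therefore defaults to a **guided** two-step
map (`map_via_reference()`): candidate to its best-scoring panel
reference, reference to anchor, composed -- each leg at much higher
identity.  The direct map remains available (`guide = FALSE`, and
`map_to_anchor()` is unchanged).  Residual single-site mis-calls still
occur (about 2 runs in 40 under the default synthetic study show one
count off by one), always traceable to a chance mutation cluster that
makes a fragment end unalignable or shifts one mapped column; this
mirrors the incomplete-fragment caveat of real repertoire studies and
is within the recovery tolerances the tests assert.

## Classification, naming, and the tree

Family assignment is similarity-first: the family of the
highest-similarity reference on the trimmed local alignment (anchor
and outgroup excluded), with the triad (NxQ supports ciliary, HxK
rhabdomeric) and the nearest-neighbour family on the tree as
corroborating evidence.  Agreement of all non-missing evidence marks
the call `consistent`; disagreement (legitimately common in the minor
groups, which can carry either triad) marks it `ambiguous` without
changing the family.  Naming follows the reference numbering: the base
name is the best reference's number, multiple genes sharing a number
get `.1/.2/...` by descending similarity, and fragments of one merged
gene keep `.A/.B`.

The tree is a deliberate stand-in, used only as corroborating
evidence: maximum-likelihood and Bayesian inference are out of scope.
Sequences are truncated to the conserved 7-TM core by mapping to a
truncation reference (default "Sp-opsin 1", keeping its own positions
68-357, insertions inside the core retained), stacked into an
anchor-indexed pseudo-alignment (residues placed at their mapped
reference columns; insertions dropped -- a deterministic substitute
for a progressive multiple alignment), and joined by neighbor joining
on p-distances (1 minus fractional identity; a Poisson correction is
available but off by default).  Column bootstrap (default 500
replicates, seeded) gives support values as the fraction of replicates
containing each original bipartition; the displayed tree is rooted at
the non-opsin GPCR outgroup.  NJ itself (via ape) recovers topology
and branch lengths exactly on additive matrices, which the tests
assert on random additive trees.

## Expression matching

A gene is flagged as *detected* when some transcript, translated in
six frames, aligns to the gene protein with identity strictly above
99.9% over at least 30 residues.  With windows of ~30 residues a
single mismatch is ~97%, so the strict reading effectively demands a
perfect protein-level match.  The flag is "detected in this transcript
set", not "expressed in vivo": absence cannot distinguish true
non-expression from below-threshold expression, restricted expression
in other tissues or stages, or assembly gaps.

## Behaviour statistics

The experiment emulated: several aquaria, each with 18 animals under
its own daylight colour, arm counts photographed twice per phase for 8
days; an animal extends at most two arms, bounding every count by 36.
Counts are compared between day and night per treatment with the
classic pooled-variance unpaired two-tailed t-test on daily means (the
day is the replication unit; per-observation analysis is available),
annotated with the two-tailed variance F-test (larger variance on top,
so identical groups give F = 1, p = 1; zero-variance groups are
flagged degenerate, not tested) and Shapiro-Wilk normality p-values
(defined for 3-50 observations; constants flagged).  Welch's
correction sits behind a flag.  Alpha is fixed at 0.05 with no
multiple-testing correction across treatments -- a deliberate
limitation, matching common practice for five planned contrasts.

The verdicts table reports the raw two-tailed outcome as
`significant`, but the `sensitive` verdict additionally requires the
day mean to lie below the night mean: spectral sensitivity here means
*daytime suppression* of feeding activity, and a significant
difference in the wrong direction is not evidence of it.  Under the
null this direction qualification also halves the false-positive rate
of the verdict.

## The synthetic study

`default_gene_set()` defines the study conditions: 13 genes -- one
ciliary gene on a short fragment missing the Schiff-base site, two
basal-branch genes, one Go gene, six rhabdomeric genes (one with the
derived HxS triad), one RGR gene split into two disjoint fragments
(anchor 68-205 and 245-292, a 40-residue gap chosen large relative to
alignment end noise, with K296 in neither), and two neuropsins with
the Schiff-base lysine knocked out.  Nine genes carry K296 (and nine
sequences, since neither RGR fragment covers 296), eight carry E181,
four carry the invertebrate Y113, and three genes (one basal-branch,
one rhabdomeric, one neuropsin) emit transcripts.  Defaults: 20%
per-site divergence outside the protected diagnostic sites, three
decoy GPCR contigs, four pure background contigs, uniform random
600-nt flanks.  Behaviour defaults put suppression effects of 0.65,
0.70 and 0.60 on white, green and blue light and none on red light or
darkness, with night counts Binomial(36, 0.25) per observation.

What the generator does *not* emulate -- and what passing tests
therefore do not show about real data: no intron/exon structure (the
merge rule, not spliced alignment, handles multi-fragment genes); no
codon-usage bias (back-translation picks synonymous codons uniformly);
substitutions ignore residue chemistry, so hydropathy degrades faster
than in real homologs; no read-level sequencing artefacts (transcript
noise is a uniform per-base substitution rate); behaviour counts are
exchangeable binomials with no circadian autocorrelation.

Everything is seeded and byte-reproducible; ground truth travels with
every product, and `evaluate_recovery()` scores a mined run against
it through the contig placements.

## Problem sizes used by the tests

The alignment oracle runs 200 random pairs of length up to 8 (the
enumeration oracle maximises over all monotone residue matchings,
scoring gap runs directly by length -- independent of the
dynamic-programming states under test).  End-to-end recovery runs the
full 13-gene study at 30% divergence over 100 seeds; expression
recovery runs 100 zero-noise seeds; NJ recovery 100 random additive
trees; the t-test is checked against its closed form on 100 random
data sets, its type-I rate on 2000 null simulations, and the
five-treatment verdict pattern over 100 seeds.  Unit tests use smaller
versions of the same constructions.

## Known limitations

* Family calls against the synthetic panel validate the pipeline, not
  real taxonomy; with real deposited sequences the calls inherit the
  panel's quality.
* Exact similarity percentages depend on the similarity-group
  partition and local trimming; compare rankings, not cells, across
  tools.
* The NJ placement is corroborative only; do not read its topology as
  a substitute for model-based phylogenetics.
* Single-site diagnostic counts can deviate by one in a few percent of
  seeded runs for alignment-coverage reasons discussed above.
* No multiple-testing correction across the five behaviour
  treatments.
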