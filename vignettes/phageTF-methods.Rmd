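---
title: "Methods: surveying WhiB- and Lsr2-type regulators in phage genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying WhiB- and Lsr2-type regulators in phage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phageTF implements a computational survey of host-derived transcription
factors -- chiefly WhiB-like iron-sulfur-cluster regulators and Lsr2-like
xenogeneic-silencing nucleoid proteins -- across collections of
actinobacteriophage genomes. This vignette is the package's own account of
the methods: what each stage computes, the assumptions behind it, the
parameters that matter, and the numerical choices made where a design was
genuinely open.

## The synthetic collection generator

Every downstream stage is validated against genome collections produced by
`simulate_collection()`, whose ground truth (`SyntheticTruth`) records every
implanted gene, its coordinates, strand, divergence and repeat membership.
The generator emulates the statistical structure the analyses rely on:

* **Cluster-structured relatedness.** One random ancestor per cluster,
  drawn i.i.d. at the cluster's background GC; genomes descend from their
  ancestor by independent per-site substitution (default 0.02/site),
  uniform over the three alternative bases. Between-cluster structure is
  independent ancestors rather than a deep simulated tree: the analyses only
  require cluster-level separability, mirroring the cluster-concordant
  organization of real phage collections.
* **Implanted regulator ORFs.** Each implant is a back-translation of a
  family seed protein mutated to a requested amino-acid divergence
  (0--0.75). Codons are chosen among synonyms with probability proportional
  to the product of base frequencies under the genome's GC bias, so the
  implant does not stand out compositionally. The initiator codon is forced
  to ATG and the initiator residue is never mutated, so the ORF is always
  recoverable by a table-11 ORF caller. Divergence is realized by exact
  positional substitution and verified by global alignment to within five
  percentage points.
* **AT-rich upstream dips.** Each lsr2-like implant gets the window
  immediately upstream (default 300 bp) resampled at background GC minus a
  configured depth (default 0.15), emulating the low-GC regions xenogeneic
  silencers bind.
* **Direct terminal repeats.** With `dtr_length_bp > 0` the genome's first
  and last `dtr_length_bp` bases are identical copies and the first implant
  copy is placed inside the repeat, so it appears twice with 100% protein
  identity -- the signature used to recognize repeat-borne gene copies.
  `dtr_gc` optionally resamples the repeat at a distinct GC to emulate
  GC-rich repeat blocks.
* **Lifestyle labels.** Temperate/virulent labels are Bernoulli draws; the
  log-odds of "temperate" are shifted by `log(lifestyle_odds)` (default 3)
  for implant carriers, giving the carrier--lifestyle association the group
  statistics are meant to detect.

Non-repeat implants keep a 6 kb margin from the genome ends so that 5 kb
context windows are always complete. What the generator does *not* emulate:
realistic phage gene content, genome mosaicism and recombination, indels
(substitutions only), and codon-usage selection. Passing recovery tests
therefore demonstrates correctness of the pipeline's logic under controlled
conditions, not performance on the full messiness of real assemblies.

`emit_domain_hits()` emulates a conserved-domain screen's tabular output:
each true implant is reported by 1--4 "source databases" at identical or
slightly jittered (at most 10 bp) coordinates, because real domain screens
report the same locus redundantly across databases; decoy non-regulator hits
can be added at a configurable rate.

## Domain-screen post-processing

`filter_hits()` keeps hits whose domain id belongs to the regulator catalog
and whose E-value passes the screening threshold (default 0.001, the
conventional domain-screen cutoff). `collapse_overlapping()` removes
cross-database redundancy: within a genome, hits overlapping by at least
half of the shorter interval (configurable) are grouped by single linkage
into one locus, labeled by the family of the lowest-E-value member. The
grouping is re-applied to the collapsed spans until stable, which makes the
operation idempotent and guarantees the output loci are non-overlapping
under the same criterion. `build_matrix()` counts loci per genome and
family and drops families present in fewer than `prevalence_min` genomes
(default 10, interpreted inclusively; the boundary is configurable because
"at least 10" and "more than 10" are both defensible readings of the
original screen). `cooccurrence()` is Pearson correlation on the count
columns; zero-variance columns give NA rather than 0, since an absent
signal is not evidence of independence.

## Alignment-free whole-genome phylogeny

Genomes are summarized by k-mer frequency profiles (`kmer_profile()`,
default k = 6, i.e. 4096 features -- small enough to stay in memory for
thousands of genomes, large enough to separate phage clusters). Windows
containing N are skipped; profiles are computed on the given strand by
default, with a `canonical` flag that folds in the reverse complement.

Profiles are compared by Jensen-Shannon divergence in bits
(`jsd()`: `H(M) - (H(P)+H(Q))/2`, `M = (P+Q)/2`), which is symmetric and
bounded in [0, 1]. **The distance used for tree building is `sqrt(JSD)`**,
not raw JSD. The square root is a true metric, and empirically it matters:
neighbor joining assumes near-additive distances, and raw JSD is strongly
non-additive over the composition range phage clusters span. On generated
collections (4 clusters x 5 genomes, 50 kb, 2%/site within-cluster
divergence, adjacent cluster GC separated by at least 0.05) NJ on raw JSD
misplaces intermediate-GC clusters and recovers only 50--75% of clusters as
clades, whereas NJ on sqrt(JSD) recovers 100% on every seed tried. Raw JSD
remains available via `sqrt_jsd = FALSE`.

`neighbor_joining()` is the Saitou--Nei algorithm with the Studier--Keppler
Q-criterion, written in-package so its numerical behavior is fully
specified: ties in the Q minimization are broken by the lowest (row, column)
pair, and negative branch lengths are clamped to zero with the deficit
transferred to the adjacent branch of the joined pair (their sum is
preserved). On additive matrices the generating topology and path lengths
are recovered to floating-point accuracy (validated against 200 random
additive trees of 5--12 taxa, and cross-checked against an independent NJ
implementation).

`cluster_concordance()` asks, for every cluster with at least two labeled
leaves, whether the cluster's leaf set lies on one side of some edge of the
unrooted tree; leaves without cluster labels are excluded from the
bipartition comparison rather than counted against monophyly.

## Translated homolog detection

The detection pipeline composes five operations:

1. **Translated search** (`translated_search()`): every query protein is
   aligned by Smith--Waterman (BLOSUM62, gap open 11, extend 1) against all
   six reading frames. Raw scores are converted by the Karlin--Altschul
   formula (`bitscore = (lambda*S - ln K)/ln 2`, `E = m*n*2^-bitscore`) with
   the standard gapped constants lambda = 0.267, K = 0.041 and a search
   space of all translated residues (about 2/3 of twice the genome length
   per strand pair). Hits at E <= 1e-5 are reported with frame-aware genome
   coordinates; after each hit the matched region is masked with stop
   symbols and the query re-aligned, so multiple same-frame gene copies are
   all recovered. This engine reproduces the semantics -- not the heuristics
   -- of a seeded translated-BLAST search; exact seeding/X-drop behavior is
   out of scope, and real BLAST tabular output can be substituted upstream
   of the locus operations.
2. **Locus merging** (`merge_loci()`): strand-ignorant single-linkage union
   of overlapping or bookended hit intervals per genome (the merge
   convention of the common interval toolkits), validated against a
   covered-positions oracle.
3. **Extension** (`extend_locus()`): 500 bp padding completes the gene for
   translation and reciprocal filtering; 5 kb padding defines the context
   locus for the synteny/GC analyses. Clamping is linear (no wraparound).
4. **ORF extraction** (`extract_orf_protein()`): table-11 ORFs (ATG/GTG/TTG
   starts, initiator reported as M, stop required) of at least 30 residues
   on both strands. The 30-residue floor avoids spurious micro-ORFs while
   keeping well below the ~80--120 residue regulators of interest.
5. **Reciprocal filter** (`reciprocal_filter()`): each candidate ORF is
   aligned back to the full query library; the best hit is the lowest
   E-value with deterministic tie-breaking (higher raw score, then
   lexicographic query id), a locus passes at E <= 1e-5, and exactly one
   best candidate is retained per locus.

On simulated collections the composition achieves 100% sensitivity at
implant divergences up to 0.3, at least 90% at 0.5, and zero false-positive
loci on non-implanted 50 kb genomes at E <= 1e-5 -- measured by the
acceptance script on 30-genome collections.

## Identity clustering and gene trees

`global_identity()` is Needleman--Wunsch global alignment (same scoring)
with identity defined as identical aligned pairs over the *full* alignment
length including terminal gap columns -- the strict convention of pairwise
sequence demarcation tools, where gaps count as mismatches.
`greedy_cluster()` is the greedy centroid scheme of the classic identity
clusterers: length-descending input order, assignment to the first centroid
at or above the threshold (default 0.90), new centroid otherwise; the
longest member represents each cluster. Greedy centroid anchoring is
deliberately not single linkage: a chain A~B~C with A--C below threshold
yields clusters {A, B} and {C}.

Gene trees are neighbor joining on identity-derived distances:
p-distance `1 - identity` or, by default, the Poisson multiple-hit
correction `-ln(identity)` (capped at 5.0 for zero identities). This
replaces maximum-likelihood inference deliberately: the quantity consumed
downstream -- how many maximal same-source clades a group occupies
(`source_interleaving()`, the "paraphyly index": 1 = monophyletic) -- is a
topology-level statistic for which distance methods are consistent, and the
package stays self-contained. Model selection, bootstrap support and
transfer-event reconciliation are out of scope.

## Genomic context and GC structure

`annotate_locus()` calls ORFs in the 5 kb-extended locus and labels each by
its best hit in a bundled annotation library (accepted at global identity
>= 0.3 and E <= 1e-5, otherwise "hypothetical"); overlapping calls are
resolved annotated-first, then score, then length. The bundled library is a
set of *synthetic* proxy families (integrase, excisionase, ParA/ParB,
helicase, primase, Ku, SSB, ...) generated once and frozen -- stand-ins
that exercise the synteny logic, not curated natural sequences; users
substitute their own FASTA for real annotation. `domain_abundance()`
reports, per cluster, the fraction of loci containing each label, flagged
at a configurable majority threshold (default at least half).

`gc_profile()` computes GC over 100 bp windows (N excluded from numerator
and denominator). `detect_gc_drop()` formalizes the "distinct upstream GC
drop" as: the minimum of a three-window rolling mean over the windows fully
inside the upstream span, at least `drop_min` (default 0.10) below the
locus-wide median; for dip detection the profile is computed with
overlapping windows (step 50), making the statistic a 200 bp span evaluated
on a 50 bp grid. The median baseline is robust to the gene body's own
composition, and the smoothing is essential: with raw 100 bp windows the
binomial sampling standard deviation (~0.05) alone produces spurious
"dips" in roughly a quarter of flat loci, whereas the smoothed overlapping
statistic holds the false-positive rate near 4% while detecting planted
300 bp x 0.15 dips with ~98% power (2000-replicate simulation; both rates
are recomputed per run by the acceptance script).
`dtr_gc_contrast()` reports GC inside a repeat interval versus its
complement.

## Group statistics

`wilcoxon_rank_sum()` is implemented from first principles. Exact mode
(automatic for pooled n <= 12) enumerates all C(n, n_x) group assignments
of the pooled mid-ranks and doubles the smaller tail (capped at 1); normal
mode uses the tie-corrected variance with a 0.5 continuity correction,
matching the conventions of the standard R test, against which both modes
are cross-checked. Identical pooled values give p = 1. The significance
ladder is the figure-legend convention: `****` < 0.0001, `***` < 0.001,
`**` < 0.01, `*` < 0.05, `ns` otherwise, with strict inequalities.

`lifestyle_enrichment()` normalizes carrier counts to lifestyle group size
and excludes genomes without lifestyle information from numerator and
denominator alike. `compare_gc_size()` runs the four carrier-vs-non-carrier
comparisons (GC and genome size, within temperate and within virulent
genomes) with two-sided tests and no multiple-testing correction by default
(stars are reported per panel, as is conventional in this literature);
Benjamini--Hochberg can be applied downstream via `p.adjust` on the
returned p-values.

## Problem sizes and determinism

The validation suite and the acceptance script use desk-scale collections
chosen to exercise every code path at comfortable runtimes: 50 kb genomes,
4--6 clusters of 5 genomes for tree recovery and detection, 10-genome
collections for the high-divergence sensitivity measurement, 200 random
additive matrices for the NJ oracle, 1000 short random pairs for the
alignment oracle, and 100 simulated loci per arm for the GC-dip operating
characteristics. Every stochastic component is seeded: the generator is
byte-deterministic given its seed, and `run_all()` reruns with the same
config and seed produce byte-identical outputs (verified by manifest
checksums).

## Known limitations

* The alignment engine reproduces translated-search semantics, not BLAST's
  heuristics; E-values are calibrated by the Karlin--Altschul constants for
  gapped BLOSUM62 11/1 and will differ numerically from any particular
  BLAST build.
* Frameshifted or spliced genes, and fusion architectures in which the
  regulator is a small domain of a much longer ORF, are reported only as
  whatever ORF the caller recovers; fusion detection is out of scope.
* The identity definition (gaps as mismatches over the full alignment,
  terminal gaps included) is stricter than tools that ignore terminal gaps;
  clustering at 0.90 with a different convention will differ near the
  threshold.
* The GC-dip criterion is a formalization of a visual call; its threshold
  and smoothing are configurable and the defaults are justified only by the
  simulated operating characteristics above.
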