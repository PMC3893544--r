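---
title: "Detecting and validating host-to-parasite horizontal gene transfer"
author: "hgtscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating host-to-parasite horizontal gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtscreen)
```

## The problem

Holoparasitic plants such as *Orobanche* (broomrapes) and *Cuscuta*
(dodders) fuse their vasculature with that of their hosts through
haustoria, creating a symplastic conduit through which nutrients,
RNA, proteins and — occasionally — DNA move.  A gene that jumped from
the host's nuclear genome into the parasite's leaves a recognisable
signature: the parasite's copy resembles the donor clade (for
example Brassicales) far more than it resembles the parasite's own
relatives (Lamiales or Solanales), it nests inside the donor clade
in gene trees with high bootstrap support, and — when the transfer
happened at the DNA level — it carries introns at positions
homologous to the donor's.

`hgtscreen` implements that entire argument as a tested pipeline:
a transcriptome **screen** that proposes candidates, and a set of
**validation** analyses (alignment diagnostics, intron-structure
comparison, phylogenetic placement, functional-divergence and
codon-selection models, expression analysis) that interrogate them.
A simulation module generates every input with known ground truth,
so each stage is testable end to end without any external database.

## The screening model

The screen mirrors the published workflow stage by stage:

1. **Read trimming** (`trimReads`): the first exact adapter
   occurrence and everything 3' of it is removed, then the read is
   truncated at the first base with Phred quality below 25.  The
   truncate-at-first-failure rule is deliberately conservative; the
   tool used in the original study applies a different (window-based)
   rule, so trimmed sets are not base-identical to its output.
2. **Read assignment** (`assignReads`): each fragment (read pair) is
   assigned to the transcript(s) sharing its maximal count of
   matching k-mers (default k = 21, both strands), split 1/t across
   ties.  This replaces a probabilistic multi-mapping estimator
   (RSEM-style EM is out of scope); on error-free simulated reads the
   assignment is exact.
3. **Contamination filter** (`contaminationFilter`): parasites
   transport host mRNA, so any transcript with zero fragments summed
   across the *host-free* life stages (germination stages, before
   attachment) is discarded as host contamination.  We read the rule
   as a union over host-free stages — evidence in any one suffices —
   since the study lists two host-free samples without requiring
   both.
4. **ORF prediction and length gates** (`predictOrf`,
   `lengthGates`): six-frame longest ATG-to-stop ORF; transcripts
   shorter than 300 nt or ORFs shorter than 100 aa are dropped (both
   bounds inclusive).
5. **Alien score ratio** (`alienScore`): hits are partitioned by
   whether the in-group rank name (default "Lamiales") occurs in the
   subject lineage; the statistic is
   best out-group bit score / best in-group bit score, and a
   candidate needs a ratio strictly above 1.2.  Bit scores are used
   because they are length- and database-normalized, which makes the
   ratio portable; the original report says only "score ratio", so
   this is a documented choice (the scoring column is whatever the
   hit table carries).  Self-hits — same identifier, or 100%
   identity with no mismatches or gaps — are removed first.  A query
   with no in-group hit at all gets ratio +Inf and is kept as a
   flagged candidate: the ratio is undefined and phylogenetic
   confirmation is mandatory for it.
6. **Sister-taxon exclusion** (`sisterTaxonFilter`): candidates
   whose best nucleotide-level hit is affiliated with the recipient's
   sister taxon (default *Mimulus guttatus*) are removed; these are
   typically non-coding sequences spuriously translated.

Two invariants are enforced by tests: the ratio is invariant to any
common positive rescaling of a query's scores, and raising the
threshold can only remove candidates.

## Validation analyses

**Gene structure.**  `mapIntrons` aligns a cDNA to its genomic clone
with a spliced-alignment dynamic program: a Gotoh affine-gap aligner
extended with an intron state whose extension is free and whose
opening costs a fixed penalty, so multi-hundred-nt genomic-only runs
are preferred over scattered short gaps.  Genomic-only runs of at
least 40 nt are called introns.  When junction repeats make a
boundary ambiguous the intron is left-justified; the simulator
records its planted coordinates in the same canonical form, so
recovery is exact in the error-free regime.  `compareStructures`
expresses intron positions as (codon index in protein-MSA
coordinates, phase) and marks which of a reference gene's introns
are present or absent in each other gene;
`detectIntronRetention` calls partial intron retention when two
isoforms differ by exactly one block located at a known intron
position — the scenario of the 21-bp retained fragment that
distinguishes the two dodder mRNA isoforms.

**Phylogeny.**  Distance trees are built by neighbor joining on
p- or Poisson-corrected protein distances with pairwise gap
deletion, and clade support comes from 100 column-resampling
pseudo-replicates (`bootstrapSupport`).  Full ML tree search and
substitution-model selection are deliberately replaced by
NJ + bootstrap: the HGT conclusion rests on clade membership plus
support, which NJ establishes on data of this scale; this is the
package's main phylogenetic fidelity divergence.  `placementTest`
walks from the query leaf to its smallest enclosing clade containing
a donor-clade member and reports `hgt_supported` when that clade
excludes the recipient lineage with support of at least 75 — the
support convention used for reporting in the original figures.

**Type-I functional divergence.**  For two duplicate clusters,
per-site substitution counts are inferred by Fitch parsimony on each
cluster's topology (`fitchCounts`).  `estimateTheta1` fits, by
bounded quasi-Newton with multi-start, the mixture in which a site
shares one gamma(α)-distributed rate between clusters with
probability 1−θ₁ or draws independent rates with probability θ₁;
both components have closed-form negative-binomial marginals, so the
likelihood is exact.  The LRT against θ₁ = 0 is referred to χ²₁ —
the convention of the original analysis — with a boundary-corrected
(50:50 χ²₀/χ²₁) p-value also reported, since θ₁ = 0 lies on the
parameter boundary.  Site posteriors of divergence follow by Bayes'
rule at the MLE, reported above the conventional 0.7 cutoff.

A caveat the tests make explicit: parsimony counts undercount
multiple hits, which attenuates θ̂₁ on deep clusters.  The
estimator's recovery study therefore runs on the simulator's true
per-site counts (θ̂₁ within ±0.1 of θ = 0.5 at 1,000 sites), while
Fitch counting is verified separately against exhaustive ancestral
enumeration.  Estimates from real alignments inherit the parsimony
bias, as does the original tool chain.

**Codon selection models.**  `fitCodonModel` implements the GY94
61-state machinery: single-nucleotide codon changes rated by target
frequency × {1, κ, ω, ωκ}, F3x4 frequencies by default, transition
probabilities via symmetric eigendecomposition of the reversible
generator, and Felsenstein pruning with column rescaling.  The
model ladder is M0, M3(k = 3), M1a/M2a, M7/M8 (the beta discretized
into K = 10 equal-probability classes by bin means) and branch-site
model A with its ω₂ = 1 null.  Mixture classes share one rate
scale — the expected substitution rate of the class mixture — so
branch lengths mean expected substitutions per codon under the
mixture, and site classes differ in rate as well as in
nonsynonymous composition.  Three simplifications are documented:
branch lengths are estimated under M0 and then held fixed for every
other model (an order-of-magnitude runtime saving; codeml
re-optimizes per model, so printed statistics from the original
study are reference points, not targets); site posteriors use naive
empirical Bayes at the MLEs rather than the Bayes empirical Bayes
prior integration, with the reporting threshold kept at 0.75; and
the M0–M3 LRT uses the standard 2k − 2 = 4 degrees of freedom for
k = 3 — the original text says 3, which does not match any common
category choice, so `codonLRT` accepts an explicit `df` for users
who want that convention.

**Expression.**  `fpkm` computes fragments per kilobase per million
mapped fragments (a read pair is one fragment).  Reference-gene
stability (`stabilityRank`) combines geNorm's M (mean SD of pairwise
log-ratios), the ΔCt method (mean SD of pairwise ΔCt — note these
two coincide on Ct-scale input, as both are pairwise-SD means) and
BestKeeper (raw Ct SD), with the composite rank the geometric mean
of the per-method ranks, following the aggregator convention; the
model-based NormFinder estimator is omitted, since the planted
most-stable-gene conclusion is reachable from the three implemented
measures.  `ddct` implements the comparative-Ct method with plain
two-sided Student's t-tests (equal variances) against the
calibrator, matching the original analysis; the fold-change SE is
delta-method propagated from the replicate variances of ΔΔCt.

## The simulators and what they do not emulate

`simulateReferenceDB` evolves one coding family per gene along a
small plant taxonomy (branch lengths in substitutions/site) by a
Poisson nucleotide process that rejects stop codons, with optional
codon-aligned deletions of geometric length; the recipient is a
Lamiales holoparasite, the sister taxon is Lamiales, the donor clade
is Brassicales and one Brassicales species doubles as the host.
`simulateRecipientTranscriptome` plants native genes (recipient
copies with 0.1 extra substitutions/site), HGT genes (host copies at
0.15 substitutions/site — comfortably below the ≥ 1.0 recipient-to-
donor divergence, the "easy regime") and contaminants (exact host
copies), with introns at recorded positions (donor-shared for HGT
genes) and an optional 21-nt partial-retention isoform pair.
`simulateReads` emits paired staged reads in which contaminants get
zero host-free coverage.  `simulateHitTable` emulates the database
search by locally aligning each query to its own family across
species (cross-family hits would fall below reporting thresholds)
and converting scores to bit scores with Karlin–Altschul constants.

The benchmark sizes are the package's study conditions: 20 native,
3 HGT and 5 contaminant transcripts at ~6× coverage with error-free
reads for the screening recovery check; 8 taxa × 500 codons for M0
recovery; 6-taxon clusters × 1,000 sites for θ₁; 6 taxa × 200 codons
× 100 replicates for the M1a–M2a null calibration; 5 replicates ×
noise SD 0.1 for qPCR.  Passing them shows the statistics and the
plumbing are correct under the generative models; it does not show
robustness to what the simulators leave out — assembly chimeras and
fragmentation, sequencing error profiles, alignment error in real
MSAs, codon usage bias beyond F3x4, or rate variation the models do
not parameterize.

Because the deposited sequence records cannot be bundled, the
package ships `syntheticSSLLocus()`: a deterministic, clearly
synthetic stand-in that reproduces the published gene architecture —
a 1597-nt cDNA whose ORF encodes 369 aa, a genomic clone with two
introns, an isoform pair differing by a 21-bp partial retention of
intron 2, and a host-clade homolog at exactly 88.0% amino-acid
identity.  The acceptance checks recover those planted values with
the package's own machinery (`predictOrf`, `mapIntrons`,
`detectIntronRetention`, `percentIdentity`); they are recoveries of
planted ground truth, not measurements of the real records.

## Numerical choices and degenerate inputs

* Alignment tie-breaks are delegated to the underlying aligner for
  pairwise alignment; percent identity canonicalizes the argument
  order so it is symmetric under co-optimal ties.
* NJ branch lengths below zero are clamped to zero with the deficit
  recorded; bootstrap replicates that fail (for instance a resample
  with an undefined Poisson distance) are dropped from the
  denominator.
* The θ₁ and codon-model optimizers run on transformed scales
  (logit for probabilities, log for rates) with multi-start;
  κ and ω are bounded to [1e-4, 99].  θ̂₁ at the boundary reports
  the null fit.
* All-gap sites are excluded (divergence) and gapped codon columns
  are dropped (selection) with their indices recorded; an alignment
  of identical rows short-circuits the bootstrap with a degeneracy
  flag.
* Every generator is bit-reproducible given its seed; the screen
  report is independent of transcript input order up to its
  documented ratio-descending sort.

## Running the workflow

```{r pipeline, eval = FALSE}
out <- runPipeline(out_dir = tempfile("hgtrun"), seed = 1)
str(out$stages)
```

`runPipeline` wires the stages together on a simulated study and
writes per-stage outputs plus a JSON manifest with MD5 checksums;
every stage can be toggled.  The package's functions are its
interface — there is no shell entry point — and
`scripts/acceptance.R` reproduces the headline numbers from a clean
session (see the README).
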