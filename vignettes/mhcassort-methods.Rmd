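---
title: "Methods: genotyping, UniFrac mate-choice testing, and counting-based selection scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotyping, UniFrac mate-choice testing, and counting-based selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mhcassort` is an analysis pipeline for hypervariable MHC class II exon 2
repertoires in songbirds with many co-amplifying duplicated loci. This
vignette explains the models and procedures each stage implements, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the design was genuinely open.

## The biological setting and the unit of analysis

In species where MHC class II has undergone extensive duplication, a single
primer pair co-amplifies on the order of a dozen loci, and an individual's
genotype is best described as a *repertoire*: the set of unique exon-2
sequences (alleles) it carries, up to twice the locus count. Three analyses
hang off this object:

1. **Genotyping** turns per-individual amplicon read counts into called
   repertoires.
2. **Mate choice** asks whether socially mated pairs are more or less
   similar at MHC than random opposite-sex pairings, using a
   phylogeny-aware repertoire distance.
3. **Selection and trans-species polymorphism** screens ask whether the
   sequence variation bears the signatures of historical balancing
   selection: an excess of nonsynonymous substitution, and allelic lineages
   older than species boundaries.

## Genotyping

Reads are assumed demultiplexed and chimera-screened upstream (a hook,
`exclude_sequences`, accepts an external exclusion list). Within each
individual, any sequence with fewer than 1% of that individual's total reads
is removed; the comparison is `count/total >= threshold`, so a sequence at
exactly 1% is kept, and the denominator is the pre-filter total. The filter
is idempotent and monotone in the threshold, and both properties are tested.

Surviving sequences are trimmed to the analyzed window (codons 8-80 of exon
2; 216 or 219 bp, the length variation reflecting a 3-bp indel) and
translated; sequences with off-frame lengths or internal stops are rejected
with logged reasons. When 216- and 219-bp sequences co-occur, the indel gap
of each 216-bp sequence is placed at the codon position maximizing identity
to the column-majority consensus of the 219-bp sequences (leftmost on ties).
This replaces a general-purpose aligner, which is justified here because the
length difference is a single in-frame codon; sequences that are already
gapped pass through unchanged, so an externally aligned catalogue is always
accepted.

Allele identifiers are assigned in lexicographic sequence order, making the
catalogue independent of input order. Identical translations collapse onto
shared *protein leaves*; the mate-choice analysis operates on these, since
peptide-binding similarity is a property of the protein.

Individuals captured in both study years keep one repertoire per year. The
genotype summary reports mean alleles per capture-year sample and per unique
individual separately, because the two denominators genuinely differ in a
two-season design and either may be wanted downstream.

## The reference tree

All downstream tree consumers take any user-supplied Newick, so an
externally computed maximum-likelihood tree can be dropped in. The built-in
tree is neighbor joining on pairwise-deletion p-distances (protein) or
Jukes-Cantor-corrected distances (DNA, `d = -(3/4) log(1 - 4p/3)`), chosen
over a likelihood search for determinism and speed at desk scale; the
conclusions consumed downstream (UniFrac, monophyly) are topology-level.
Negative NJ branch-length estimates are clamped to zero with the deficit
transferred to the adjacent branches, and the tree is midpoint rooted:
UniFrac requires a root, and midpoint rooting is deterministic and
assumption-light. Bootstrap support resamples alignment columns with
replacement and reports, per internal bipartition of the point-estimate
tree, the percentage of replicate trees containing it.

## Unweighted UniFrac and the randomized-pairing test

For two repertoires with protein-leaf sets $A$ and $B$, restrict the rooted
reference tree to branches with at least one descendant leaf in
$A \cup B$ (the *observed* branches). The unweighted UniFrac distance is

$$d(A,B) \;=\; \frac{\sum_{\text{branches unique to } A \text{ or } B} \ell_b}
{\sum_{\text{observed branches}} \ell_b},$$

where a branch is *unique* when all its observed descendants lie in
$A \setminus B$ (or all in $B \setminus A$). Identical repertoires give 0,
repertoires from completely separated clades give 1, and the unweighted
(presence/absence) form matches the binary nature of repertoire membership.
The implementation is vectorized over all pairs through a
branch-by-individual incidence matrix, and is checked in the test suite
against the independent implementation in `picante` and against a
hand-enumerated quartet case.

The mate-choice test compares the mean UniFrac distance over observed
social pairs with a Monte-Carlo null: in each of $B$ replicates (default
10,000), every observed pair's female is assigned a male drawn uniformly
*without replacement* from the males available in her year, and the
replicate's mean distance over the same number of pairs is recorded. Two
ambiguities in this design were resolved as follows, with both options kept
available:

* **Null statistic.** The null distribution holds replicate *means*, and the
  test refers the observed mean to it; this matches the very small standard
  error a mean-based null produces. The pooled distribution of single-pair
  distances (the support of the per-pair null) is also returned for
  plotting.
* **Sampling frame.** Replicate males are drawn from *all* males captured
  that year by default (`frame = "all_adults"`), since every adult male
  present was an available partner; `frame = "paired_only"` restricts the
  pool to males appearing in observed pairs. Females anchor the
  randomization so the number of pairs per year is fixed.

The p-value uses the add-one permutation convention,
$p = 2\min\!\big(\tfrac{\#\{\le\} + 1}{B+1},\, \tfrac{\#\{\ge\} + 1}{B+1}\big)$
capped at 1: standard, slightly conservative, and never exactly zero. With
$B = 199$ and a continuous statistic this test has exact size 0.05 at
$\alpha = 0.05$, which is what the calibration experiment measures (500
null cohorts; rejection rate within the binomial 95% interval around 0.05).

## Counting-based selection analyses

Codon-likelihood site models and Bayes empirical Bayes machinery are out of
scope; the package implements the counting side of the standard toolkit,
plus the bookkeeping needed to reproduce model-ranking and consensus logic
from published fits.

**Pairwise counting (NG86).** Synonymous site counts per codon sum the
fraction of synonymous single-base changes at each position, with mutations
to stop codons excluded from the per-position denominator — so synonymous
plus nonsynonymous sites equal exactly 3 per codon, and the worked
`TTT/TTC + GGG` example gives $\bar S = 4/3$, $\bar N = 14/3$. For codons
differing at 2-3 positions, all step orderings are enumerated, pathways
through stops are discarded, and the survivors are weighted equally; if
every pathway is blocked (not the case for any sense-codon pair under the
standard code, but handled defensively), all pathways are used with
stop-crossing steps counted as nonsynonymous. Proportions are
Jukes-Cantor-corrected; saturation ($p \ge 0.75$) is reported as an `Inf`
sentinel with a warning, and $\omega$ is flagged undefined when $dS = 0$.
The implementation is table-driven for speed and is tested for exact
agreement with a brute-force pathway-enumeration oracle on random codon
pairs.

**Overall Z-test.** $\bar d_N$ and $\bar d_S$ average the pairwise values
over all sequence pairs; the standard error of $\bar d_N - \bar d_S$ comes
from bootstrapping codon columns (default 500 replicates), and the test is
one-tailed for $d_N > d_S$, which is the question being asked of these
loci. Saturated pairs are dropped from the means with a warning. An
alignment of identical sequences reports $p = 0.5$ rather than failing.

**Per-site test (SLAC-style).** Ancestral codons are reconstructed by Fitch
parsimony on whole codons — the stated simplification of
likelihood-based ancestor counting — with ties resolved uniformly at random
and counts averaged over 20 seeded resolutions. Each branch's codon change
is decomposed into synonymous/nonsynonymous counts by the NG86 pathway
rules; the expected nonsynonymous fraction at a site is the NG86
nonsynonymous site fraction averaged over the codons observed at the tips;
and the observed nonsynonymous count is referred to a two-tailed binomial
test at $\alpha = 0.10$ (the conventional level for this family of site
tests). Sites with no reconstructed change are neutral with $p = 1$, and an
invariant site can never be called positive.

**AIC bookkeeping and consensus.** `aic_rank` computes $AIC = 2k - 2\ln L$
and ranks supplied fits; it never adjusts its inputs, and the documentation
of the packaged published fits notes that one published AIC value is not
internally consistent with any integer parameter count (the ranking is
unaffected). `consensus_sites` is the exact intersection of per-test
positive-site lists; `annotate_sites` flags candidate codons against the
packaged passerine consensus set (positions
7, 19, 27, 42, 46, 49, 59, 60, 62, 63, 73 of the 73-codon window) and
against a user-supplied human peptide-binding set. The human set is not
packaged because the source table's typographic marking of those positions
does not survive text extraction; supplying it is the user's choice.

## Trans-species polymorphism screen

Remote database queries are replaced by an exhaustive identity scan against
a user-supplied heterospecific panel (FASTA with `species=` header tags).
"Similarity" is ungapped-column percent identity after alignment to a
common window, with the indel block excluded pairwise; the threshold
(default 94%) is inclusive. The screen builds a bootstrapped NJ tree over
the combined set, tests whether the focal alleles form one side of a split,
reports each focal allele's nearest neighbor by patristic distance (ties
broken by raw identity), and lists minimal clades mixing focal and
heterospecific leaves with their support. A focal allele whose nearest
neighbor is heterospecific is a *TSP candidate*.

## The synthetic-data generators

The generators define the package's study conditions and return ground
truth alongside every dataset.

* **Allele pool** (`simulate_allele_pool`): a coalescent genealogy of
  allelic lineages (depth 0.08 substitutions/site within a species clade),
  stop-free in-frame 219-bp sequences evolved under Jukes-Cantor, a 3-bp
  codon deletion assigned to one basal clade, and — in two-species mode —
  focal and heterospecific clades separated by 0.15-substitutions/site stem
  branches. Trans-species lineages are engineered by grafting focal tips as
  sisters of heterospecific tips at a short attachment distance (0.01),
  with hosts spread at least four attachment-lengths apart so distinct
  engineered lineages do not collapse into one micro-clade. Sequences are
  unique by construction, as real allele catalogues are.
* **Repertoires** (`simulate_repertoires`): population allele frequencies
  drawn once from a symmetric Dirichlet(0.3) — a few common and many rare
  alleles, so "the ten most common" is meaningful — and per-individual
  allele counts Binomial(2 × 13, 14/26) truncated to [1, 26], matching a
  ~14-allele mean under a 13-locus cap. Default cohort sizes (44/49 males,
  25/38 females over two years; 18 and 22 pairs) mirror a realistic
  two-season field sample.
* **Pairings** (`simulate_pairings`): each anchor female picks, with
  probability $|a|$, the extreme-distance available male (most similar for
  $a > 0$, most dissimilar for $a < 0$) and otherwise a uniform available
  male. The mixture form is deliberate: at $a = 0$ the generator *is* the
  null mechanism of the test, which makes the calibration experiment a true
  self-test.
* **Read counts** (`simulate_read_counts`): true alleles share
  $(1-e)$ of the reads with Dirichlet(8) proportions (concentrated enough
  that a true allele in a 14-allele genotype rarely dips under 1%);
  artefact sequences — 1-2 random mutations of the individual's alleles,
  about 1.5 per true allele — share the remaining $e$ with Dirichlet(1)
  proportions, placing the overwhelming majority of artefacts below the
  filter threshold, as bacterial-cloning error-rate calibrations of such
  pipelines report.
* **Codon alignments** (`simulate_codon_alignment`): a continuous-time
  codon walk with single-base steps, transitions weighted $\kappa$ (default
  2) and nonsynonymous steps weighted by the site's $\omega$; site classes
  drawn from $(p_0, p_1, p_2)$ with ratios $(\omega_0, \omega_1, \omega_2)$
  defaulting to the published fitted mixture (0.945/0.046/0.009 and
  0.086/1/3.10). Rates are normalized by the *mixture-average* rate, the
  standard convention, so one unit of branch length is one expected
  substitution per codon across site classes — which means high-$\omega$
  sites evolve proportionally faster than the average.

What the generators do **not** emulate: read-depth variation between loci,
PCR chimeras, allele dropout, linkage between loci, recapture of the same
individual across years, demographic structure, and sequencing-quality
gradients along the read. Passing the recovery tests therefore shows the
statistical machinery is correct under its stated model, not that any
particular laboratory protocol achieves these error characteristics.

## Problem sizes and calibration scales

The test suite and the acceptance script use: 500 synthetic null cohorts
(and 100 assortative cohorts) at $B = 199$ for the permutation-test
calibration; 100 cohorts each (20 sequences, 200 codons, coalescent depth 1
substitution/codon) for the Z-test's type-I error and power; a 12-taxon
tree of total length 4 with 10% of 100 codons at $\omega = 5$ for the
per-site test, aggregated over 10 seeded replicates; 50 two-species pools
of 24 alleles for each arm of the trans-species screen; and a 100-individual
cohort at 5,000 reads for filter recovery. These are the package's chosen
desk-scale study conditions.

## Known limitations

* **Per-site counting tests need many sequences.** With 12 sequences there
  are at most 21 branches, so a site can contribute only on the order of a
  dozen observable changes; a binomial test against the neutral
  nonsynonymous fraction (~0.74) then needs nearly *all* changes to be
  nonsynonymous to reach $\alpha = 0.10$, while fast sites simultaneously
  saturate parsimony reconstruction, pulling the inferred ratio back toward
  neutrality. The per-site test's recall on the 12-taxon scenario is
  accordingly low (the acceptance script computes it); the test is
  informative at the hundreds-of-sequences scale of real exon-2 catalogues.
  The overall Z-test does not share this ceiling, because it pools
  information across sites and pairs.
* The NJ reference tree is a deterministic stand-in, not a model-based
  estimate; users wanting likelihood trees should supply their own Newick.
* Fitch parsimony underestimates change counts on long branches; the
  per-site test is therefore conservative under saturation.
* The identity screen is exhaustive and exact but assumes its inputs are
  alignable to one window; it is not a general homology search.
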