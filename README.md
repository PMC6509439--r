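# mhcassort

Analysis pipeline for hypervariable MHC class II exon 2 repertoires in
songbirds with many co-amplifying duplicated loci. It answers three
questions about such a system:

1. **Genotyping** — which unique alleles does each individual carry?
   Amplicon read counts are filtered at a per-individual read-frequency
   threshold (a sequence is kept when `count/total >= 1%`), trimmed to the
   72-73 codon analyzed window (216-219 bp; the length variation is a 3-bp
   indel), translated, and collapsed to unique DNA alleles and protein
   leaves.
2. **Mate choice** — are socially mated pairs more or less similar at MHC
   than expected under random mating? Repertoire similarity is unweighted
   UniFrac on a neighbor-joining reference tree of the translated alleles:
   for leaf sets *A*, *B* the distance is the fraction of observed branch
   length leading exclusively to one set,
   `d(A,B) = unique length / observed length` (0 for identical repertoires,
   1 for repertoires from separate clades). The observed mean pair distance
   is referred to a year-stratified Monte-Carlo null of randomized
   female-male pairings (default B = 10,000), with an add-one two-tailed
   p-value.
3. **Historical balancing selection** — does the sequence variation show
   positive selection and trans-species polymorphism? Implemented as
   counting methods: Nei-Gojobori pathway counting of synonymous and
   nonsynonymous sites/differences (`omega = dN/dS`), a bootstrap Z-test of
   `dN > dS`, a SLAC-style per-codon binomial test on Fitch-parsimony
   ancestors, AIC ranking (`AIC = 2k - 2 lnL`) of externally supplied
   codon-model fits, consensus-site intersection across tests, and a
   trans-species screen (>= 94% identity matching against a heterospecific
   panel, nearest-neighbor species, and conspecific-monophyly testing on a
   bootstrapped tree).

A synthetic-data module generates allele pools, repertoires, social
pairings with tunable assortment, noisy read counts, and codon alignments
under a mixture of omega site classes — all with ground truth — so every
stage is testable without downloads. See
`vignettes/mhcassort-methods.Rmd` for the models, parameter choices and
limitations.

## Worked example

The numbered scripts under `analysis/` run the whole pipeline on a
simulated two-season study (278-allele pool, 156 adult samples, 40 social
pairs drawn with moderate assortment `a = 0.5`, 5,000 reads/individual at a
5% artefact rate):

```sh
Rscript analysis/01_simulate_cohort.R   # writes results/*.tsv, *.fasta
Rscript analysis/02_genotype.R
Rscript analysis/03_mate_choice.R
Rscript analysis/04_selection.R
Rscript analysis/05_transspecies.R
```

`02_genotype.R` prints:

```
repertoire_set: 156 samples / 156 individuals; 209 DNA alleles, 163 protein leaves
  alleles per sample: 14.26 +/- 0.18 (SEM)
recovery vs ground truth: sensitivity 1.000, false rate 0.020
```

209 unique DNA sequences survived the 1% filter, carrying a mean of 14.26
alleles per individual; against the simulation's ground truth the filter
recovered every true allele and let through 2% artefacts.

`03_mate_choice.R` prints:

```
randomized-pairing test (B = 10000, frame = all_adults):
  observed mean = 0.3386, null mean = 0.4377 +/- 0.0001 (SEM)
  two-tailed p = 0.0002
observed pairs are more similar than random (observed 0.339 vs null 0.438, p = 0.0002)
```

The observed pairs (simulated with assortment) have a mean UniFrac distance
well below the randomized-pairing null — assortative mating is detected.

`04_selection.R` prints (abridged):

```
overall Z-test under the fitted site-class mixture: Z = -2.36, one-tailed p = 0.991
overall Z-test with all sites at omega = 5: Z = 9.78, p = 6.7e-23
AIC ranking of the published model fits (best first):
 name    lnL k   AIC delta_AIC
  M2a -11072 4 22152         0
   M8 -11105 4 22218        66
consensus positively selected codons: 2 24 42 46 62 73
of these, positively selected across passerines: 42 46 62 73
```

Under the purifying-dominated fitted mixture the Z-test correctly sees a
synonymous excess; under strong positive selection it rejects decisively.
The six consensus codons are the exact intersection of the packaged
per-test site lists, and four of them lie in the passerine consensus set of
positively selected positions.

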