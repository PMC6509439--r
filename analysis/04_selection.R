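#!/usr/bin/env Rscript
# Positive-selection screens. Counting-based analyses run on a simulated
# codon alignment with known omega site classes (the called exon-2 alleles
# are too closely related for per-site counting to say much at desk scale);
# the AIC ranking and consensus intersection run on the published model fits
# and per-test site lists, and the consensus is annotated against the
# packaged passerine reference sites.

suppressMessages(library(mhcassort))
set_log("INFO")
seed <- 4L
dir.create("results", showWarnings = FALSE)

## overall Z-test and per-site test on a known-truth codon alignment
set.seed(seed)
tr <- ape::rcoal(20)
tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
sim <- simulate_codon_alignment(tr, n_codons = 200,
                                p = c(0.945, 0.046, 0.009),
                                omega = c(0.086, 1, 3.10), kappa = 2,
                                seed = seed + 1L)
z <- overall_z_test(sim$sequences, reps = 500, seed = seed + 2L)
cat(sprintf("overall Z-test under the fitted site-class mixture: Z = %.2f, one-tailed p = %.3f\n",
            z$Z, z$p_one_tailed))

sim5 <- simulate_codon_alignment(tr, n_codons = 200, p = c(0, 0, 1),
                                 omega = c(0.086, 1, 5), seed = seed + 3L)
z5 <- overall_z_test(sim5$sequences, reps = 500, seed = seed + 4L)
cat(sprintf("overall Z-test with all sites at omega = 5: Z = %.2f, p = %.2g\n",
            z5$Z, z5$p_one_tailed))

st <- slac_site_test(sim$sequences, tr, alpha = 0.10, seed = seed + 5L)
write.table(st, "results/site_selection_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("per-site test: %d positive, %d purifying, %d neutral calls\n",
            sum(st$call == "positive"), sum(st$call == "purifying"),
            sum(st$call == "neutral")))

## AIC bookkeeping over the published codon-model fits
rk <- aic_rank(published_model_fits())
write.table(rk, "results/aic_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("AIC ranking of the published model fits (best first):\n")
print(rk, row.names = FALSE)

## consensus sites across the six published tests, with annotation
cons <- consensus_sites(published_site_tests())
ann <- annotate_sites(cons)
cat("consensus positively selected codons:", cons, "\n")
cat("of these, positively selected across passerines:",
    ann$passerine_overlap, "\n")
jsonlite::write_json(
  list(consensus_sites = cons, passerine_overlap = ann$passerine_overlap,
       z_mixture = z$Z, z_mixture_p = z$p_one_tailed,
       z_strong = z5$Z, z_strong_p = z5$p_one_tailed),
  "results/selection_report.json", auto_unbox = TRUE, digits = NA)
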