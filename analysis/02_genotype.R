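#!/usr/bin/env Rscript
# Call MHC genotypes from the simulated read counts: 1% per-individual
# read-frequency filter, trim/translate to the 72-73 codon window, collapse
# to unique DNA alleles and protein leaves. Compares the calls against the
# simulation's ground truth.

suppressMessages(library(mhcassort))
set_log("INFO")

reads <- read_table_checked("results/read_counts.tsv", "read_counts")
seqs <- read_fasta("results/read_sequences.fasta")
metadata <- read_table_checked("results/metadata.tsv", "metadata")

profiles <- profiles_from_tables(reads, seqs, metadata)
called <- call_genotypes(profiles, metadata, threshold = 0.01)
print(called)

write_fasta(setNames(called$catalogue$dna, called$catalogue$allele_id),
            "results/catalogue_dna.fasta")
write_fasta(setNames(called$catalogue$protein, called$catalogue$allele_id),
            "results/catalogue_protein.fasta")
write.table(called$genotypes, "results/called_genotypes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(called$summary, "results/genotype_summary.json",
                     auto_unbox = TRUE, digits = NA)

# recovery against the simulation truth
truth_geno <- read.delim("results/true_genotypes.tsv")
pool <- read_fasta("results/allele_pool.fasta")
truth_cat <- trim_and_translate(pool)$alleles
truth_cat <- truth_cat[order(truth_cat$dna_aligned), ]
truth_cat$allele_id <- sprintf("A%04d", seq_len(nrow(truth_cat)))
dna_of <- setNames(truth_cat$dna, truth_cat$allele_id)
truth <- lapply(split(truth_geno$allele_id, truth_geno$key),
                function(a) unname(dna_of[a]))
sc <- score_genotype_recovery(called, truth)
cat(sprintf("recovery vs ground truth: sensitivity %.3f, false rate %.3f\n",
            sc$sensitivity, sc$false_rate))
jsonlite::write_json(sc, "results/genotype_recovery.json", auto_unbox = TRUE,
                     digits = NA)
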