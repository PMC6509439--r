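#!/usr/bin/env Rscript
# Mate-choice analysis: neighbor-joining reference tree over the translated
# alleles, pairwise unweighted UniFrac between repertoires, and the
# 10,000-replicate year-stratified randomized-pairing test of nonrandom
# mating on the simulated social pairs.

suppressMessages(library(mhcassort))
set_log("INFO")
seed <- 3L

reads <- read_table_checked("results/read_counts.tsv", "read_counts")
seqs <- read_fasta("results/read_sequences.fasta")
metadata <- read_table_checked("results/metadata.tsv", "metadata")
pairs <- read_table_checked("results/pairs.tsv", "pairs")

rs <- call_genotypes(profiles_from_tables(reads, seqs, metadata), metadata)
tree <- reference_tree(rs)
write_newick(tree, "results/protein_reference_tree.nwk")

D <- pairwise_distance_table(tree, rs)
write_distance_tsv(D, "results/unifrac_distances.tsv")

res <- random_pairing_test(rs, pairs, tree, B = 10000, seed = seed,
                           dist_matrix = D)
print(res)

write.table(data.frame(replicate = seq_along(res$replicate_means),
                       mean_distance = res$replicate_means),
            "results/null_replicate_means.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(pair = names(res$per_pair),
                       distance = unname(res$per_pair)),
            "results/observed_pair_distances.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(
  list(observed_mean = res$observed_mean, null_mean = res$null_mean,
       null_sem = res$null_sem, p_two_tailed = res$p_two_tailed,
       B = res$B, seed = res$seed, frame = res$frame),
  "results/mate_choice_report.json", auto_unbox = TRUE, digits = NA)

cat(sprintf(paste0("observed pairs are %s similar than random ",
                   "(observed %.3f vs null %.3f, p = %.3g)\n"),
            if (res$observed_mean < res$null_mean) "more" else "less",
            res$observed_mean, res$null_mean, res$p_two_tailed))
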