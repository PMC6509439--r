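#!/usr/bin/env Rscript
# Generate the synthetic study: an allelic pool with the field-realistic
# structure (278 alleles, 216/219-bp with a shared 3-bp indel), two annual
# cohorts of adults genotyped at ~14 alleles each, moderately assortative
# social pairs, and noisy amplicon read counts. Writes the same file formats
# the downstream analysis stages consume, plus the ground truth.

suppressMessages(library(mhcassort))
set_log("INFO")
dir.create("results", showWarnings = FALSE)
seed <- 20140413L

pool <- simulate_allele_pool(278, seed = seed)
rs <- simulate_repertoires(pool, n_males = c(44, 49), n_females = c(25, 38),
                           years = c(2014, 2015), loci = 13,
                           mean_alleles = 14, seed = seed + 1L)
tree <- reference_tree(rs)
pairs <- simulate_pairings(rs, tree, a = 0.5, n_pairs = c(18, 22),
                           seed = seed + 2L)
reads <- simulate_read_counts(rs, total_reads = 5000, error_rate = 0.05,
                              seed = seed + 3L)

write_fasta(pool$sequences, "results/allele_pool.fasta")
write_newick(pool$tree, "results/allele_pool_true_tree.nwk")
write.table(rs$individuals[, c("individual", "sex", "year")],
            "results/metadata.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(pairs, "results/pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(rs$genotypes, "results/true_genotypes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# long-format read counts with a sequence-id FASTA companion
all_seqs <- sort(unique(unlist(lapply(reads$profiles,
                                      function(p) names(p$counts)))))
seq_ids <- setNames(sprintf("seq%05d", seq_along(all_seqs)), all_seqs)
rows <- do.call(rbind, lapply(reads$profiles, function(p)
  data.frame(individual = p$individual_id,
             sequence_id = unname(seq_ids[names(p$counts)]),
             count = unname(p$counts), year = p$year)))
write.table(rows, "results/read_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_fasta(setNames(names(seq_ids), seq_ids), "results/read_sequences.fasta")

truth <- list(seed = seed,
              n_pool_alleles = length(pool$sequences),
              n_samples = nrow(rs$individuals),
              assortment = 0.5,
              mean_alleles_per_sample = rs$summary$mean_alleles_per_sample)
jsonlite::write_json(truth, "results/ground_truth.json", auto_unbox = TRUE)

cat(sprintf(paste0("simulated %d pool alleles; %d samples over 2 cohorts; ",
                   "%d social pairs (a = 0.5); %d read-count rows\n"),
            length(pool$sequences), nrow(rs$individuals), nrow(pairs),
            nrow(rows)))
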