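test_that("every generator is byte-identical under a fixed seed", {
  p1 <- simulate_allele_pool(30, seed = 3)
  p2 <- simulate_allele_pool(30, seed = 3)
  expect_identical(p1$sequences, p2$sequences)
  expect_identical(ape::write.tree(p1$tree), ape::write.tree(p2$tree))

  r1 <- simulate_repertoires(p1, n_males = c(8), n_females = c(8),
                             years = c(2014), seed = 4)
  r2 <- simulate_repertoires(p1, n_males = c(8), n_females = c(8),
                             years = c(2014), seed = 4)
  expect_identical(r1$genotypes, r2$genotypes)

  rc1 <- simulate_read_counts(r1, 1000, 0.05, seed = 5)
  rc2 <- simulate_read_counts(r1, 1000, 0.05, seed = 5)
  expect_identical(rc1$profiles, rc2$profiles)

  tr <- p1$tree
  c1 <- simulate_codon_alignment(tr, n_codons = 20, seed = 6)
  c2 <- simulate_codon_alignment(tr, n_codons = 20, seed = 6)
  expect_identical(c1, c2)
})

test_that("allele pools satisfy their structural guarantees", {
  pool <- simulate_allele_pool(30, seed = 9)
  lens <- nchar(gsub("-", "", pool$sequences))
  expect_true(all(lens %in% c(216, 219)))
  expect_true(all(nchar(pool$sequences) == 219))
  expect_gt(length(pool$indel_tips), 0)
  prots <- vapply(pool$sequences, translate_dna, "")
  expect_false(any(grepl("\\*", prots)))
  # species-private pools keep each species monophyletic in the true tree
  p0 <- simulate_allele_pool(16, two_species = TRUE, tsp_fraction = 0,
                             seed = 10)
  foc <- names(p0$species)[p0$species == "focal"]
  expect_true(is_monophyletic_split(p0$tree, foc)$monophyletic)
  # fully trans-species pools are not monophyletic
  p1 <- simulate_allele_pool(16, two_species = TRUE, tsp_fraction = 1,
                             seed = 11)
  foc1 <- names(p1$species)[p1$species == "focal"]
  expect_false(is_monophyletic_split(p1$tree, foc1)$monophyletic)
})

test_that("repertoire sizes respect the locus cap and hit the target mean", {
  pool <- simulate_allele_pool(60, seed = 13)
  rs1 <- simulate_repertoires(pool, n_males = c(10), n_females = c(10),
                              years = 1, loci = 1, mean_alleles = 1.5,
                              seed = 14)
  sizes <- table(rs1$genotypes$key)
  expect_true(all(sizes >= 1 & sizes <= 2))
  rs <- simulate_repertoires(pool, n_males = c(40, 40), n_females = c(38, 38),
                             years = 1:2, mean_alleles = 14, seed = 15)
  m <- rs$summary$mean_alleles_per_sample
  sem <- rs$summary$sem_alleles_per_sample
  expect_lt(abs(m - 14), 3 * sem + 1e-9)
})

test_that("assortment strength moves pair distances in the right direction", {
  cohort <- toy_cohort(seed = 17)
  mean_dist <- function(a, seed) {
    prs <- simulate_pairings(cohort$rs, cohort$tree, a = a,
                             n_pairs = c(8, 8), seed = seed,
                             dist_matrix = cohort$D)
    key <- function(id, y) paste(id, y, sep = "@")
    mean(cohort$D[cbind(key(prs$female_id, prs$year),
                        key(prs$male_id, prs$year))])
  }
  m0 <- mean(vapply(1:30, function(s) mean_dist(0, s), 0))
  mp <- mean(vapply(1:30, function(s) mean_dist(1, s), 0))
  mm <- mean(vapply(1:30, function(s) mean_dist(-1, s), 0))
  expect_lt(mp, m0)
  expect_gt(mm, m0)
})

test_that("noise-free read counts reproduce the genotypes exactly", {
  pool <- simulate_allele_pool(40, seed = 19)
  rs <- simulate_repertoires(pool, n_males = c(6), n_females = c(6),
                             years = 1, seed = 20)
  rc <- simulate_read_counts(rs, total_reads = 2000, error_rate = 0,
                             seed = 21)
  called <- call_genotypes(rc$profiles,
                           rs$individuals[, c("individual", "sex", "year")])
  sc <- score_genotype_recovery(called, rc$truth)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$false_rate, 0)
})

test_that("codon alignments carry their class labels and stay stop-free", {
  set.seed(23)
  tr <- ape::rcoal(6)
  sim <- simulate_codon_alignment(tr, n_codons = 50,
                                  p = c(0.5, 0.3, 0.2),
                                  omega = c(0.1, 1, 5), seed = 24)
  expect_equal(length(sim$classes), 50)
  expect_true(all(sim$classes %in% 1:3))
  expect_true(all(nchar(sim$sequences) == 150))
  prots <- vapply(sim$sequences, translate_dna, "")
  expect_false(any(grepl("\\*", prots)))
})
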