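test_that("pairing test flags maximally similar observed pairs", {
  cohort <- toy_cohort()
  rs <- cohort$rs
  # pair each female with herself-like male: force distance-0 pairs by
  # pairing individuals with identical repertoires is not guaranteed, so
  # instead use the closest male per female and check the left tail
  prs <- simulate_pairings(rs, cohort$tree, a = 1, n_pairs = c(8, 8),
                           seed = 3, dist_matrix = cohort$D)
  res <- random_pairing_test(rs, prs, cohort$tree, B = 499, seed = 4,
                             dist_matrix = cohort$D)
  expect_lt(res$observed_mean, mean(res$replicate_means))
  expect_lte(res$p_two_tailed, 0.05)
  expect_equal(length(res$replicate_means), 499)
  expect_gt(res$p_two_tailed, 0)
})

test_that("pairing test is exactly reproducible under a fixed seed", {
  cohort <- toy_cohort()
  prs <- simulate_pairings(cohort$rs, cohort$tree, a = 0,
                           n_pairs = c(6, 6), seed = 11,
                           dist_matrix = cohort$D)
  r1 <- random_pairing_test(cohort$rs, prs, cohort$tree, B = 200, seed = 5,
                            dist_matrix = cohort$D)
  r2 <- random_pairing_test(cohort$rs, prs, cohort$tree, B = 200, seed = 5,
                            dist_matrix = cohort$D)
  expect_identical(r1$replicate_means, r2$replicate_means)
  expect_identical(r1$p_two_tailed, r2$p_two_tailed)
  r3 <- random_pairing_test(cohort$rs, prs, cohort$tree, B = 200, seed = 6,
                            dist_matrix = cohort$D)
  expect_false(identical(r1$replicate_means, r3$replicate_means))
})

# handcrafted two-year cohort over a quartet protein tree
hand_cohort <- function() {
  tree <- quartet_tree()
  ind <- data.frame(
    individual = c("m1", "m2", "f1", "f2", "m1", "f1"),
    sex = c("male", "male", "female", "female", "male", "female"),
    year = c(1, 1, 1, 1, 2, 2))
  ind$key <- paste(ind$individual, ind$year, sep = "@")
  genotypes <- data.frame(
    key = rep(ind$key, times = c(2, 2, 2, 2, 2, 2)),
    allele_id = c("A", "B", "C", "D", "A", "C", "B", "D", "A", "B", "A", "C"))
  rs <- structure(list(individuals = ind, genotypes = genotypes,
                       catalogue = data.frame(allele_id = c("A","B","C","D"),
                                              protein_id = c("A","B","C","D")),
                       summary = list()), class = "repertoire_set")
  rs
}

test_that("sampling frames differ and bad inputs are named in errors", {
  rs <- hand_cohort(); tree <- quartet_tree()
  D <- pairwise_distance_table(tree, rs)
  prs <- data.frame(male_id = c("m1", "m2"), female_id = c("f1", "f2"),
                    year = c(1, 1))
  ra <- random_pairing_test(rs, prs, tree, B = 99, seed = 1,
                            frame = "all_adults", dist_matrix = D)
  rp <- random_pairing_test(rs, prs, tree, B = 99, seed = 1,
                            frame = "paired_only", dist_matrix = D)
  expect_equal(ra$observed_mean, rp$observed_mean)
  bad <- prs; bad$male_id[1] <- "nobody"
  expect_error(random_pairing_test(rs, bad, tree, B = 9, dist_matrix = D),
               "nobody")
  toomany <- data.frame(male_id = c("m1", "m2", "m1"),
                        female_id = c("f1", "f2", "f2"), year = 1)
  expect_error(random_pairing_test(rs, toomany, tree, B = 9, dist_matrix = D),
               "available males")
})

test_that("recurring cross-year pairs trigger the pseudoreplication warning", {
  rs <- hand_cohort(); tree <- quartet_tree()
  D <- pairwise_distance_table(tree, rs)
  prs <- data.frame(male_id = c("m1", "m1"), female_id = c("f1", "f1"),
                    year = c(1, 2))
  expect_warning(random_pairing_test(rs, prs, tree, B = 9, dist_matrix = D),
                 "recur")
})
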