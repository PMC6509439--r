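test_that("NG86 reproduces hand-worked codon examples", {
  # TTT vs TTC plus invariant GGG: one synonymous third-position difference
  r <- ng86_pairwise("TTTGGG", "TTCGGG") |> suppressWarnings()
  expect_equal(r$S_sites, 4 / 3)
  expect_equal(r$N_sites, 14 / 3)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$pS, 0.75)

  # Lys -> Arg, two differences: both orderings weighted 1/2
  r2 <- suppressWarnings(ng86_pairwise("AAA", "AGG"))
  expect_equal(r2$Sd + r2$Nd, 2)
  expect_equal(r2$Sd, 1)   # AAA->AAG synonymous step appears in one pathway
  expect_equal(r2$Nd, 1)

  r3 <- ng86_pairwise("ATGAAA", "ATGAAA")
  expect_equal(r3$Sd, 0); expect_equal(r3$Nd, 0)
  expect_equal(r3$dS, 0); expect_equal(r3$dN, 0)
})

test_that("per-codon site fractions sum to exactly three", {
  tab <- mhcassort:::codon_tables()
  sense <- !tab$is_stop
  expect_equal(tab$syn_sites[sense] + tab$nonsyn_sites[sense],
               rep(3, sum(sense)))
  # spot values from the genetic code: GGG is fourfold at position 3
  g <- which(tab$codons == "GGG")
  expect_equal(tab$syn_sites[g], 1)
  f <- which(tab$codons == "TTT")
  expect_equal(tab$syn_sites[f], 1 / 3)
})

test_that("NG86 equals the brute-force pathway oracle on random pairs", {
  set.seed(41)
  for (i in 1:150) {
    n_cod <- sample(1:4, 1)
    a <- paste0(replicate(n_cod, random_sense_codon()), collapse = "")
    b <- paste0(replicate(n_cod, random_sense_codon()), collapse = "")
    want <- oracle_ng86(a, b)
    got <- suppressWarnings(ng86_pairwise(a, b))
    expect_equal(got$S_sites, want$S_sites, tolerance = 1e-12)
    expect_equal(got$N_sites, want$N_sites, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
  }
})

test_that("saturation and undefined omega are flagged", {
  r <- suppressWarnings(ng86_pairwise("TTT", "TTC"))
  expect_true("dS_saturated" %in% r$flags)    # pS = 0.75 on one codon
  expect_equal(r$dS, Inf)
  r2 <- ng86_pairwise("ATGGCA", "ATGTCA")     # one nonsynonymous change
  expect_true("omega_undefined" %in% r2$flags)
  expect_true(is.na(r2$omega))
})

test_that("overall Z-test is seed-deterministic with a sign-consistent Z", {
  set.seed(3)
  tr <- ape::rcoal(8)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  sim <- simulate_codon_alignment(tr, n_codons = 60, p = c(0, 0, 1),
                                  omega = c(0.1, 1, 5), seed = 2)
  z1 <- overall_z_test(sim$sequences, reps = 200, seed = 7)
  z2 <- overall_z_test(sim$sequences, reps = 200, seed = 7)
  expect_identical(z1, z2)
  expect_equal(sign(z1$Z), sign(z1$dN_bar - z1$dS_bar))
})

test_that("an alignment of identical sequences reports p = 0.5", {
  seqs <- setNames(rep("ATGGCAGAATTT", 4), paste0("t", 1:4))
  expect_warning(z <- overall_z_test(seqs, reps = 50, seed = 1),
                 "degenerate")
  expect_equal(z$p_one_tailed, 0.5)
  expect_equal(z$Z, 0)
})
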