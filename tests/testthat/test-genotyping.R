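mk_profile <- function(counts, id = "bird1", year = 2014)
  read_profile(id, counts, year)

dna216 <- function(seed) {
  set.seed(seed)
  repeat {
    s <- paste0(sample(c("A", "C", "G", "T"), 216, replace = TRUE),
                collapse = "")
    if (!grepl("\\*", translate_dna(s))) return(s)
  }
}

test_that("read filter keeps sequences at exactly the threshold", {
  a <- strrep("A", 216); b <- strrep("C", 216)
  p <- mk_profile(setNames(c(990, 10), c(a, b)))
  kept <- filter_low_frequency(p, 0.01)
  expect_equal(length(kept$counts), 2)          # 1.0% is not below 1%
  p2 <- mk_profile(setNames(c(995, 5), c(a, b)))
  kept2 <- filter_low_frequency(p2, 0.01)
  expect_identical(names(kept2$counts), a)      # 0.5% removed
  expect_equal(unname(kept2$counts), 995)       # retained counts unchanged
  p3 <- mk_profile(setNames(3, b))
  expect_equal(length(filter_low_frequency(p3, 0.01)$counts), 1)  # 100%
})

test_that("read filter is idempotent and monotone in the threshold", {
  set.seed(31)
  for (i in 1:10) {
    counts <- setNames(rpois(12, 80) + 1, random_dna(12, 30))
    p <- mk_profile(counts)
    thr <- runif(1, 0.005, 0.1)
    once <- filter_low_frequency(p, thr)
    twice <- filter_low_frequency(once, thr)
    expect_identical(twice$counts, once$counts)
    lo <- filter_low_frequency(p, thr / 2)
    expect_true(all(names(once$counts) %in% names(lo$counts)))
  }
})

test_that("trim/translate enforces frame, window length and stop codons", {
  s216 <- dna216(5)
  r <- trim_and_translate(c(ok = s216))
  expect_equal(nchar(r$alleles$protein), 72)
  s219 <- paste0(s216, "GCA")                   # extra in-frame codon
  r2 <- trim_and_translate(c(ok = s219))
  expect_equal(nchar(r2$alleles$protein), 73)   # 3-bp indel variant
  r3 <- trim_and_translate(c(bad = paste0(s216, "G")))
  expect_equal(nrow(r3$alleles), 0)
  expect_match(r3$rejected$reason, "217")
  withstop <- paste0("TAA", substr(s216, 4, 216))
  r4 <- trim_and_translate(c(bad = withstop))
  expect_match(r4$rejected$reason, "stop")
})

test_that("genotype calling collapses alleles and is order-invariant", {
  a <- dna216(1); b <- dna216(2)
  # c differs from a at one synonymous third position
  v <- strsplit(a, "")[[1]]
  cc <- NULL
  for (pos in seq(3, 216, 3)) {
    for (nb in setdiff(c("A", "C", "G", "T"), v[pos])) {
      w <- v; w[pos] <- nb
      cand <- paste0(w, collapse = "")
      if (translate_dna(cand) == translate_dna(a)) { cc <- cand; break }
    }
    if (!is.null(cc)) break
  }
  md <- data.frame(individual = c("i1", "i2"), sex = c("male", "female"),
                   year = 2014)
  profiles <- list(mk_profile(setNames(c(100, 100), c(a, b)), "i1"),
                   mk_profile(setNames(c(100, 100), c(a, cc)), "i2"))
  rs <- call_genotypes(profiles, md)
  expect_equal(rs$summary$n_unique_alleles, 3)  # a shared, counted once
  expect_equal(rs$summary$n_protein_leaves, 2)  # a and cc collapse
  # catalogue identical regardless of profile order
  rs2 <- call_genotypes(rev(profiles), md)
  expect_identical(rs$catalogue, rs2$catalogue)
  expect_error(call_genotypes(list(mk_profile(setNames(10, "ACGT"), "i3")),
                              md),
               "zero valid alleles|no valid alleles")
})

test_that("called allele counts recover the simulated mean", {
  pool <- simulate_allele_pool(80, seed = 21)
  rs <- simulate_repertoires(pool, n_males = c(30), n_females = c(30),
                             years = c(2014), mean_alleles = 14, seed = 22)
  rc <- simulate_read_counts(rs, total_reads = 2000, error_rate = 0.02,
                             seed = 23)
  called <- call_genotypes(rc$profiles,
                           rs$individuals[, c("individual", "sex", "year")])
  m <- called$summary$mean_alleles_per_sample
  sem <- called$summary$sem_alleles_per_sample
  expect_lt(abs(m - 14), 3 * sem + 1e-9)
})
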