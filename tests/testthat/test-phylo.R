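test_that("p-distance handles identity, mismatch and pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)   # gap column dropped
  expect_error(p_distance("--", "AA"), "ungapped")
  expect_error(p_distance("ACG", "AC"), "length")
})

test_that("p-distance matrix agrees with the ape reference on random DNA", {
  set.seed(11)
  seqs <- setNames(random_dna(8, 90), paste0("t", 1:8))
  mine <- p_distance_matrix(seqs)
  bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
})

test_that("Jukes-Cantor correction matches closed form and its properties", {
  expect_equal(jc_correct(0), 0)
  expect_lt(abs(jc_correct(0.1) - 0.107326), 1e-6)
  expect_error(jc_correct(0.75), "aturation")
  p <- seq(0.01, 0.7, by = 0.01)
  d <- jc_correct(p)
  expect_true(all(d >= p))
  expect_true(all(diff(d) > 0))                 # strictly increasing
  expect_true(all(diff(diff(d)) > 0))           # convex
})

test_that("NJ recovers generating topology from additive distances", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n)
    dm <- ape::cophenetic.phylo(tr)
    est <- nj_tree(dm[tr$tip.label, tr$tip.label])
    rf <- phangorn::RF.dist(ape::unroot(est), ape::unroot(tr))
    expect_equal(rf, 0)
  }
})

test_that("three-taxon NJ solves the three-point formulas exactly", {
  dm <- matrix(c(0, 3, 5,
                 3, 0, 6,
                 5, 6, 0), 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  est <- nj_tree(dm, root = FALSE)
  # x = (dab + dac - dbc)/2 etc.
  want <- c(a = 1, b = 2, c = 4)
  got <- setNames(est$edge.length[match(seq_along(est$tip.label),
                                        est$edge[, 2])][
    order(est$tip.label)], sort(est$tip.label))
  expect_equal(got, want[names(got)])
})

test_that("equal distances yield a tree with zero internal branches", {
  n <- 5
  dm <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(dm) <- 0
  est <- nj_tree(dm, root = FALSE)
  internal <- est$edge[, 2] > length(est$tip.label)
  expect_true(all(abs(est$edge.length[internal]) < 1e-9))
  expect_setequal(est$tip.label, letters[1:n])
})

test_that("bootstrap support is near 100 for clades with many diagnostic
           columns and is seed-deterministic", {
  base <- strrep("A", 50)
  other <- strrep("C", 50)
  noise <- function(s, k, seed) {
    set.seed(seed); v <- strsplit(s, "")[[1]]
    i <- sample(50, k); v[i] <- sample(c("G", "T"), k, replace = TRUE)
    paste0(v, collapse = "")
  }
  seqs <- c(a1 = noise(base, 2, 1), a2 = noise(base, 2, 2),
            b1 = noise(other, 2, 3), b2 = noise(other, 2, 4))
  tr <- bootstrap_support(seqs, reps = 100, seed = 9)
  expect_gte(max(attr(tr, "support")), 95)
  tr2 <- bootstrap_support(seqs, reps = 100, seed = 9)
  expect_identical(attr(tr, "support"), attr(tr2, "support"))
  expect_error(bootstrap_support(c(x = "A", y = "C"), reps = 10, seed = 1),
               "2 columns")
})

test_that("monophyly queries match hand-readable splits", {
  tr <- quartet_tree()
  r <- is_monophyletic_split(tr, c("A", "B"))
  expect_true(r$monophyletic)
  expect_setequal(r$clade_leaves, c("A", "B"))
  r2 <- is_monophyletic_split(tr, c("A", "C"))
  expect_false(r2$monophyletic)
  expect_setequal(r2$clade_leaves, c("A", "B", "C", "D"))
  expect_true(is_monophyletic_split(tr, c("A", "B", "C", "D"))$monophyletic)
  expect_error(is_monophyletic_split(tr, "Z"), "Z")
})
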