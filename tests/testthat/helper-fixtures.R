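# Shared fixtures and independent oracles. Everything here is deliberately
# written without reference to the package internals it checks.

set_log("ERROR")

quartet_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

random_dna <- function(n, len = 60) {
  vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

# --- independent Nei-Gojobori oracle -------------------------------------
# Brute-force pathway enumeration straight from the genetic code; used to
# check ng86_pairwise, never shares code with it.

.oracle_gc <- as.list(setNames(as.character(Biostrings::GENETIC_CODE),
                               names(Biostrings::GENETIC_CODE)))

oracle_syn_sites <- function(codon) {
  bases <- c("T", "C", "A", "G")
  aa <- .oracle_gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; nonstop <- 0
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (.oracle_gc[[alt]] == "*") next
      nonstop <- nonstop + 1
      if (.oracle_gc[[alt]] == aa) syn <- syn + 1
    }
    if (nonstop > 0) s <- s + syn / nonstop
  }
  s
}

oracle_path_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(S = 0, N = 0))
  perms <- if (k == 1) list(pos) else if (k == 2) list(pos, rev(pos)) else {
    idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
    lapply(idx, function(o) pos[o])
  }
  walk <- function(order, allow_stop) {
    cur <- c1; S <- 0; N <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && .oracle_gc[[nxt]] == "*") return(NULL)
      if (.oracle_gc[[cur]] == "*" || .oracle_gc[[nxt]] == "*" ||
          .oracle_gc[[cur]] != .oracle_gc[[nxt]]) N <- N + 1 else S <- S + 1
      cur <- nxt
    }
    c(S = S, N = N)
  }
  paths <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (!length(paths)) paths <- lapply(perms, walk, allow_stop = TRUE)
  Reduce(`+`, paths) / length(paths)
}

oracle_ng86 <- function(a, b) {
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- split3(a); cb <- split3(b)
  keep <- !grepl("-", ca) & !grepl("-", cb) &
    vapply(ca, function(z) .oracle_gc[[z]] != "*", TRUE) &
    vapply(cb, function(z) .oracle_gc[[z]] != "*", TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  S <- (sum(vapply(ca, oracle_syn_sites, 0)) +
          sum(vapply(cb, oracle_syn_sites, 0))) / 2
  cnt <- Reduce(`+`, Map(oracle_path_counts, ca, cb))
  list(S_sites = S, N_sites = 3 * length(ca) - S,
       Sd = unname(cnt["S"]), Nd = unname(cnt["N"]))
}

random_sense_codon <- function() {
  repeat {
    cd <- paste0(sample(c("T", "C", "A", "G"), 3, replace = TRUE),
                 collapse = "")
    if (.oracle_gc[[cd]] != "*") return(cd)
  }
}

# small two-year cohort for mate-choice tests
toy_cohort <- function(seed = 7, pool_size = 40) {
  pool <- simulate_allele_pool(pool_size, seed = seed)
  rs <- simulate_repertoires(pool, n_males = c(12, 14), n_females = c(10, 11),
                             years = c(2014, 2015), seed = seed + 1)
  tree <- reference_tree(rs)
  list(pool = pool, rs = rs, tree = tree,
       D = pairwise_distance_table(tree, rs))
}
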