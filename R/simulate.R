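# Synthetic-data generators. Every generator is deterministic under a fixed
# seed and returns ground truth alongside the data, so each pipeline stage
# has a testable no-download input surface.

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), ncol = k, byrow = TRUE)
  x / rowSums(x)
}

# random in-frame stop-free codon string of n_codons
.random_orf <- function(n_codons) {
  tab <- codon_tables()
  sense <- which(!tab$is_stop)
  paste0(tab$codons[sample(sense, n_codons, replace = TRUE)], collapse = "")
}

# evolve a DNA sequence along a branch under JC with expected `t`
# substitutions/site; mutations creating an internal stop codon are redrawn
# (up to 100 tries each, then skipped with a log line)
.evolve_jc_orf <- function(dna, t) {
  v <- strsplit(dna, "")[[1]]
  L <- length(v)
  nmut <- stats::rpois(1, L * t)
  tab <- codon_tables()
  for (k in seq_len(nmut)) {
    done <- FALSE
    for (try in seq_len(100L)) {
      pos <- sample.int(L, 1L)
      new <- sample(setdiff(.BASES, v[pos]), 1L)
      old <- v[pos]
      v[pos] <- new
      cd_start <- 3L * ((pos - 1L) %/% 3L) + 1L
      cd <- paste0(v[cd_start:(cd_start + 2L)], collapse = "")
      if (!tab$is_stop[tab$idx[[cd]]]) { done <- TRUE; break }
      v[pos] <- old
    }
    if (!done) pkg_log("DEBUG", "stop-free mutation infeasible; site skipped")
  }
  paste0(v, collapse = "")
}

# evolve sequences down a phylo from a root sequence; returns named tip seqs
.evolve_tree_orf <- function(tree, root_seq) {
  nt <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(po$edge)))   # preorder
  seqs <- vector("character", nt + tree$Nnode)
  seqs[nt + 1L] <- root_seq
  for (e in ord) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    seqs[ch] <- .evolve_jc_orf(seqs[par], po$edge.length[e])
  }
  setNames(seqs[seq_len(nt)], tree$tip.label)
}

#' Simulate an allelic lineage pool
#'
#' Simulates a genealogy of allelic lineages (coalescent within species
#' clades), evolves stop-free in-frame 219-bp sequences along it under
#' Jukes-Cantor, and assigns a 3-bp codon deletion to one basal clade so the
#' pool mixes 216- and 219-bp alleles. With `two_species = TRUE` the pool
#' holds a focal and a heterospecific clade separated by stem branches;
#' each focal lineage is independently labeled trans-species with probability
#' `tsp_fraction`, and trans-species lineages branch from within the
#' heterospecific clade (as the sister of a heterospecific tip at a short
#' distance), so their alleles cluster with heterospecifics.
#'
#' @param pool_size total number of alleles (>= 4).
#' @param two_species simulate a focal + heterospecific panel.
#' @param tsp_fraction probability a focal lineage is trans-species.
#' @param seed RNG seed.
#' @param clade_depth coalescent depth of each species clade
#'   (substitutions/site).
#' @param stem_length stem branch separating the species clades.
#' @param tsp_attach_length branch length attaching a trans-species focal tip
#'   to its heterospecific sister.
#' @param indel_codon aligned codon position carrying the 3-bp indel.
#' @return list: `sequences` (aligned, 219 columns, gaps for 216-bp alleles),
#'   `tree` (true genealogy), `species` (named vector: "focal"/"heterospecific",
#'   or all "focal" when `two_species = FALSE`), `tsp_truth` (named logical),
#'   `indel_tips`.
#' @export
simulate_allele_pool <- function(pool_size = 278L, two_species = FALSE,
                                 tsp_fraction = 0, seed = 1L,
                                 clade_depth = 0.08, stem_length = 0.15,
                                 tsp_attach_length = 0.01,
                                 indel_codon = 37L) {
  if (pool_size < 4L) stop("pool_size must be >= 4")
  if (tsp_fraction < 0 || tsp_fraction > 1) stop("tsp_fraction in [0,1]")
  set.seed(as.integer(seed))
  if (!two_species) {
    tr <- ape::rcoal(pool_size, tip.label = sprintf("AL%03d", seq_len(pool_size)))
    tr$edge.length <- tr$edge.length * clade_depth /
      max(ape::node.depth.edgelength(tr))
    species <- setNames(rep("focal", pool_size), tr$tip.label)
    tsp_truth <- setNames(rep(FALSE, pool_size), tr$tip.label)
  } else {
    n_focal <- ceiling(pool_size / 2); n_het <- pool_size - n_focal
    is_tsp <- stats::runif(n_focal) < tsp_fraction
    # at least 2 focal tips must stay in the focal clade to make it a clade
    if (sum(!is_tsp) < 2L && tsp_fraction < 1)
      is_tsp[seq_len(min(2L, n_focal))] <- FALSE
    n_in <- sum(!is_tsp)
    if (n_in < 2L) { is_tsp[] <- TRUE; n_in <- 0L }
    scale_to <- function(tr, depth) {
      tr$edge.length <- tr$edge.length * depth /
        max(ape::node.depth.edgelength(tr))
      tr
    }
    het <- scale_to(ape::rcoal(n_het,
                               tip.label = sprintf("HET%03d", seq_len(n_het))),
                    clade_depth)
    focal_names <- sprintf("SOSP%03d", seq_len(n_focal))
    tsp_names <- focal_names[is_tsp]
    # compose by Newick strings: graft each trans-species focal tip as the
    # sister of a distinct heterospecific tip at a short attachment distance
    subtree_newick <- function(tr) sub(";$", "", ape::write.tree(tr))
    het_nwk <- subtree_newick(het)
    # spread hosts out: distinct trans-species lineages should not land in
    # the same micro-clade, or the grafted focal tips become each other's
    # nearest neighbors instead of their heterospecific hosts
    hosts <- character(0)
    if (length(tsp_names)) {
      hd <- ape::cophenetic.phylo(het)
      min_sep <- 4 * tsp_attach_length
      cand <- sample(het$tip.label)
      for (i in seq_along(tsp_names)) {
        ok <- if (length(hosts)) cand[apply(hd[cand, hosts, drop = FALSE], 1,
                                            min) > min_sep] else cand
        pick <- if (length(ok)) ok[1L] else
          cand[which.max(apply(hd[cand, hosts, drop = FALSE], 1, min))]
        hosts <- c(hosts, pick)
        cand <- setdiff(cand, pick)
        if (!length(cand)) cand <- setdiff(het$tip.label, hosts)
        if (!length(cand)) cand <- het$tip.label
      }
    }
    for (i in seq_along(tsp_names)) {
      pat <- paste0(hosts[i], ":([0-9.eE+-]+)")
      m <- regmatches(het_nwk, regexpr(pat, het_nwk))[1]
      len <- as.numeric(sub(paste0(hosts[i], ":"), "", m))
      eps <- min(tsp_attach_length, len / 2)
      repl <- sprintf("(%s:%.10f,%s:%.10f):%.10f", hosts[i], eps,
                      tsp_names[i], eps, len - eps)
      het_nwk <- sub(pat, repl, het_nwk)
    }
    if (n_in >= 2L) {
      foc <- scale_to(ape::rcoal(n_in, tip.label = focal_names[!is_tsp]),
                      clade_depth)
      nwk <- sprintf("(%s:%.10f,%s:%.10f);", subtree_newick(foc), stem_length,
                     het_nwk, stem_length)
    } else {
      nwk <- sprintf("(%s:%.10f);", het_nwk, stem_length)
    }
    tr <- ape::read.tree(text = nwk)
    species <- setNames(ifelse(grepl("^SOSP", tr$tip.label),
                               "focal", "heterospecific"), tr$tip.label)
    tsp_truth <- setNames(tr$tip.label %in% tsp_names, tr$tip.label)
  }
  root_seq <- .random_orf(73L)
  seqs <- .evolve_tree_orf(tr, root_seq)
  # 3-bp deletion in the smaller basal clade (gap codon in the alignment)
  nt <- length(tr$tip.label)
  root_kids <- tr$edge[tr$edge[, 1L] == nt + 1L, 2L]
  inc <- edge_tip_incidence(tr)
  kid_edges <- which(tr$edge[, 2L] %in% root_kids)
  sizes <- rowSums(inc[kid_edges, , drop = FALSE])
  basal <- kid_edges[which.min(sizes)]
  indel_tips <- tr$tip.label[inc[basal, ]]
  cs <- 3L * (indel_codon - 1L) + 1L
  for (tp in indel_tips)
    substr(seqs[tp], cs, cs + 2L) <- "---"
  # alleles are unique sequences by definition; nudge collisions apart with
  # extra stop-free point mutations
  tab <- codon_tables()
  guard <- 0L
  while (anyDuplicated(seqs) && guard < 1000L) {
    guard <- guard + 1L
    for (i in which(duplicated(seqs))) {
      v <- strsplit(seqs[i], "")[[1]]
      repeat {
        pos <- sample.int(length(v), 1L)
        if (v[pos] == "-") next
        old <- v[pos]
        v[pos] <- sample(setdiff(.BASES, old), 1L)
        cstart <- 3L * ((pos - 1L) %/% 3L) + 1L
        cd <- paste0(v[cstart:(cstart + 2L)], collapse = "")
        if (cd != "---" && !grepl("-", cd) && tab$is_stop[tab$idx[[cd]]]) {
          v[pos] <- old; next
        }
        break
      }
      seqs[i] <- paste0(v, collapse = "")
    }
  }
  list(sequences = seqs, tree = tr, species = species,
       tsp_truth = tsp_truth, indel_tips = indel_tips)
}

#' Simulate individual repertoires from an allele pool
#'
#' Population allele frequencies are drawn once from a symmetric
#' Dirichlet(0.3), giving the realistic skew of a few common and many rare
#' alleles. Each individual carries a Binomial(2 x loci, mean/(2 x loci))
#' allele count truncated to [1, 2 x loci], sampled without replacement with
#' probability proportional to the population frequencies.
#'
#' @param pool result of [simulate_allele_pool()].
#' @param n_males,n_females per-year cohort sizes (vectors over years).
#' @param years year labels.
#' @param loci number of co-amplifying loci (allele count cap = 2 x loci).
#' @param mean_alleles mean alleles per individual.
#' @param seed RNG seed.
#' @param dirichlet_alpha skew of the population allele frequencies.
#' @return a `repertoire_set` (see [call_genotypes()]) with an extra
#'   `pool_frequencies` element.
#' @export
simulate_repertoires <- function(pool, n_males = c(44L, 49L),
                                 n_females = c(25L, 38L),
                                 years = c(2014L, 2015L), loci = 13L,
                                 mean_alleles = 14, seed = 1L,
                                 dirichlet_alpha = 0.3) {
  stopifnot(length(n_males) == length(years),
            length(n_females) == length(years))
  cap <- 2L * loci
  if (mean_alleles > cap) stop("mean_alleles exceeds 2 x loci")
  focal_ids <- names(pool$species)[pool$species == "focal"]
  seqs <- pool$sequences[focal_ids]
  if (length(seqs) < cap) stop("pool too small for sampling without replacement")
  set.seed(as.integer(seed))
  freqs <- as.vector(.rdirichlet(1, rep(dirichlet_alpha, length(seqs))))
  names(freqs) <- names(seqs)

  tt <- trim_and_translate(seqs)
  cat_df <- tt$alleles
  if (nrow(tt$rejected)) stop("pool contains invalid alleles: ",
                              paste(tt$rejected$id, collapse = ", "))
  cat_df <- cat_df[order(cat_df$dna_aligned), , drop = FALSE]
  cat_df$allele_id <- sprintf("A%04d", seq_len(nrow(cat_df)))
  prot_sorted <- sort(unique(cat_df$protein_aligned))
  cat_df$protein_id <- sprintf("P%04d", match(cat_df$protein_aligned,
                                              prot_sorted))
  rownames(cat_df) <- NULL
  pool2allele <- setNames(cat_df$allele_id, cat_df$id)

  ind_rows <- list(); geno <- list()
  for (yi in seq_along(years)) {
    y <- years[yi]
    ids <- c(sprintf("M%02d_%s", seq_len(n_males[yi]), y),
             sprintf("F%02d_%s", seq_len(n_females[yi]), y))
    sexes <- rep(c("male", "female"), c(n_males[yi], n_females[yi]))
    for (i in seq_along(ids)) {
      k <- max(1L, min(cap, rbinom(1L, cap, mean_alleles / cap)))
      picked <- sample(names(seqs), k, prob = freqs)
      key <- paste(ids[i], y, sep = "@")
      ind_rows[[length(ind_rows) + 1L]] <- data.frame(
        individual = ids[i], sex = sexes[i], year = y, key = key)
      geno[[length(geno) + 1L]] <- data.frame(
        key = key, allele_id = sort(unname(pool2allele[picked])))
    }
  }
  individuals <- do.call(rbind, ind_rows)
  genotypes <- do.call(rbind, geno)
  per_sample <- tapply(genotypes$allele_id, genotypes$key, length)[individuals$key]
  sem <- function(x) sd(x) / sqrt(length(x))
  summary <- list(
    n_unique_alleles = length(unique(genotypes$allele_id)),
    n_protein_leaves = length(prot_sorted),
    n_samples = nrow(individuals),
    n_individuals = length(unique(individuals$individual)),
    mean_alleles_per_sample = mean(per_sample),
    sem_alleles_per_sample = sem(as.numeric(per_sample)),
    mean_alleles_per_individual = mean(per_sample),
    sem_alleles_per_individual = sem(as.numeric(per_sample)))
  structure(list(individuals = individuals, genotypes = genotypes,
                 catalogue = cat_df, summary = summary,
                 pool_frequencies = freqs),
            class = "repertoire_set")
}

#' Simulate social pairings with tunable assortment
#'
#' Within each year, `n_pairs` anchor females are drawn at random; each in
#' turn picks a male from the remaining available males: with probability
#' `|a|` the extreme-distance male (the most MHC-similar if `a > 0`, the most
#' dissimilar if `a < 0`), otherwise a uniformly random available male.
#' With `a = 0` this is exactly the year-stratified random-pairing null
#' tested by [random_pairing_test()].
#'
#' @param rs a `repertoire_set`.
#' @param tree rooted reference tree (defaults to [reference_tree()]).
#' @param a assortment strength in [-1, 1].
#' @param n_pairs pairs per year (vector over the years of `rs`).
#' @param seed RNG seed.
#' @param dist_matrix optional precomputed distance matrix.
#' @return data.frame: male_id, female_id, year.
#' @export
simulate_pairings <- function(rs, tree = NULL, a = 0, n_pairs = c(18L, 22L),
                              seed = 1L, dist_matrix = NULL) {
  stopifnot(inherits(rs, "repertoire_set"), a >= -1, a <= 1)
  ind <- rs$individuals
  years <- sort(unique(ind$year))
  stopifnot(length(n_pairs) == length(years))
  if (is.null(tree) && is.null(dist_matrix)) tree <- reference_tree(rs)
  D <- if (is.null(dist_matrix)) pairwise_distance_table(tree, rs) else
    dist_matrix
  set.seed(as.integer(seed))
  out <- list()
  for (yi in seq_along(years)) {
    y <- years[yi]
    fem <- ind$key[ind$sex == "female" & ind$year == y]
    mal <- ind$key[ind$sex == "male" & ind$year == y]
    np <- n_pairs[yi]
    if (np > length(fem) || np > length(mal))
      stop("year ", y, ": n_pairs exceeds available males or females")
    anchors <- sample(fem, np)
    avail <- mal
    for (f in anchors) {
      pick_extreme <- stats::runif(1) < abs(a)
      m <- if (pick_extreme && a > 0) {
        avail[which.min(D[f, avail])]
      } else if (pick_extreme && a < 0) {
        avail[which.max(D[f, avail])]
      } else avail[sample.int(length(avail), 1L)]
      avail <- setdiff(avail, m)
      out[[length(out) + 1L]] <- data.frame(
        male_id = sub("@.*$", "", m), female_id = sub("@.*$", "", f),
        year = y)
    }
  }
  do.call(rbind, out)
}

#' Simulate amplicon read counts with low-frequency noise
#'
#' True alleles of each sample share `(1 - error_rate)` of the reads with
#' symmetric-Dirichlet proportions; artefact sequences (1-2 random mutations
#' of the sample's true alleles) share the remaining `error_rate`, split so
#' that in expectation well over 95% of artefacts fall below the 1% filter
#' threshold.
#'
#' @param rs a `repertoire_set` (the ground-truth genotypes).
#' @param total_reads reads per sample (>= 100).
#' @param error_rate fraction of reads that are artefacts.
#' @param seed RNG seed.
#' @param allele_alpha Dirichlet concentration of true-allele read shares.
#' @return list: `profiles` (list of [read_profile()]),
#'   `truth` (named list: sample key -> true DNA sequences).
#' @export
simulate_read_counts <- function(rs, total_reads = 5000L, error_rate = 0.05,
                                 seed = 1L, allele_alpha = 8) {
  stopifnot(inherits(rs, "repertoire_set"), total_reads >= 100L,
            error_rate >= 0, error_rate < 1)
  set.seed(as.integer(seed))
  dna_of <- setNames(rs$catalogue$dna, rs$catalogue$allele_id)
  profiles <- list(); truth <- list()
  for (i in seq_len(nrow(rs$individuals))) {
    key <- rs$individuals$key[i]
    alleles <- rs$genotypes$allele_id[rs$genotypes$key == key]
    seqs <- unname(dna_of[alleles])
    k <- length(seqs)
    props <- as.vector(.rdirichlet(1, rep(allele_alpha, k)))
    counts <- pmax(1L, round(props * (1 - error_rate) * total_reads))
    names(counts) <- seqs
    if (error_rate > 0) {
      n_err <- max(10L, round(1.5 * k))
      errs <- character(n_err)
      for (e in seq_len(n_err)) {
        src <- strsplit(seqs[sample.int(k, 1L)], "")[[1]]
        for (m in seq_len(sample(1:2, 1L))) {
          pos <- sample.int(length(src), 1L)
          src[pos] <- sample(setdiff(.BASES, src[pos]), 1L)
        }
        errs[e] <- paste0(src, collapse = "")
      }
      errs <- setdiff(unique(errs), seqs)
      if (length(errs)) {
        ep <- as.vector(.rdirichlet(1, rep(1, length(errs))))
        ec <- round(ep * error_rate * total_reads)
        keep <- ec > 0
        if (any(keep)) {
          add <- setNames(ec[keep], errs[keep])
          both <- intersect(names(add), names(counts))
          counts[both] <- counts[both] + add[both]
          add <- add[setdiff(names(add), both)]
          counts <- c(counts, add)
        }
      }
    }
    profiles[[length(profiles) + 1L]] <-
      read_profile(rs$individuals$individual[i], counts,
                   year = rs$individuals$year[i])
    truth[[key]] <- seqs
  }
  list(profiles = profiles, truth = truth)
}

#' Score genotype recovery of called repertoires against simulation truth
#'
#' @param called result of [call_genotypes()] on simulated profiles.
#' @param truth the `truth` element of [simulate_read_counts()].
#' @return list: sensitivity (true alleles recovered / true alleles) and
#'   false_rate (called alleles not in truth / called alleles).
#' @export
score_genotype_recovery <- function(called, truth) {
  dna_of <- setNames(called$catalogue$dna, called$catalogue$allele_id)
  tp <- 0L; fn <- 0L; fp <- 0L
  for (key in names(truth)) {
    got <- unname(dna_of[called$genotypes$allele_id[called$genotypes$key == key]])
    want <- truth[[key]]
    tp <- tp + length(intersect(got, want))
    fn <- fn + length(setdiff(want, got))
    fp <- fp + length(setdiff(got, want))
  }
  list(sensitivity = tp / (tp + fn), false_rate = fp / (tp + fp))
}

#' Simulate a codon alignment under a mixture of omega site classes
#'
#' Each codon site is assigned to a class with proportions `p` and
#' nonsynonymous/synonymous rate ratios `omega`; evolution along the tree is
#' a continuous-time codon walk with single-base steps, transitions weighted
#' `kappa`, nonsynonymous steps weighted by the site's omega, and stop codons
#' excluded. Rates are normalized so one unit of branch length equals one
#' expected substitution per codon under the class mixture.
#'
#' @param tree `phylo` with branch lengths (expected substitutions/codon).
#' @param n_codons sites to simulate.
#' @param p class proportions, summing to 1.
#' @param omega class dN/dS ratios (>= 0), same length as `p`.
#' @param kappa transition/transversion rate ratio.
#' @param seed RNG seed.
#' @return list: `sequences` (named codon strings, one per tip),
#'   `classes` (integer class index per site, 1-based).
#' @export
simulate_codon_alignment <- function(tree, n_codons = 200L,
                                     p = c(0.945, 0.046, 0.009),
                                     omega = c(0.086, 1, 3.10),
                                     kappa = 2, seed = 1L) {
  stopifnot(abs(sum(p) - 1) < 1e-8, all(omega >= 0),
            length(p) == length(omega))
  tab <- codon_tables()
  sense <- which(!tab$is_stop)
  nsense <- length(sense)
  pos_of <- setNames(seq_len(nsense), sense)

  is_ti <- function(x, y) (x %in% c("A", "G") && y %in% c("A", "G")) ||
    (x %in% c("C", "T") && y %in% c("C", "T"))
  # neighbor structure shared by all classes
  nb <- vector("list", nsense)
  for (ii in seq_len(nsense)) {
    i <- sense[ii]
    ci <- strsplit(tab$codons[i], "")[[1]]
    tgt <- integer(0); ti <- logical(0); nsy <- logical(0)
    for (posn in 1:3) for (b in setdiff(.BASES, ci[posn])) {
      cj <- ci; cj[posn] <- b
      j <- tab$idx[[paste0(cj, collapse = "")]]
      if (tab$is_stop[j]) next
      tgt <- c(tgt, pos_of[[as.character(j)]])
      ti <- c(ti, is_ti(ci[posn], b))
      nsy <- c(nsy, tab$aa[i] != tab$aa[j])
    }
    nb[[ii]] <- list(tgt = tgt, ti = ti, nsy = nsy)
  }
  classes_rates <- lapply(omega, function(w) {
    lapply(nb, function(x) {
      r <- ifelse(x$ti, kappa, 1) * ifelse(x$nsy, w, 1)
      list(tgt = x$tgt, rate = r, tot = sum(r))
    })
  })
  tot_mat <- vapply(classes_rates,
                    function(cl) vapply(cl, `[[`, 0, "tot"),
                    numeric(nsense))          # state x class total rates
  scale <- sum(p * colMeans(tot_mat))  # mixture mean rate -> unit branch length

  set.seed(as.integer(seed))
  cls <- sample.int(length(p), n_codons, replace = TRUE, prob = p)
  states <- sample.int(nsense, n_codons, replace = TRUE)  # root, uniform

  nt <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(po$edge)))
  node_states <- matrix(NA_integer_, nt + tree$Nnode, n_codons)
  node_states[nt + 1L, ] <- states
  for (e in ord) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    st <- node_states[par, ]
    # Gillespie walk, vectorized over sites still within the branch
    trem <- rep(po$edge.length[e], n_codons)
    active <- seq_len(n_codons)
    while (length(active)) {
      waits <- rexp(length(active),
                    tot_mat[cbind(st[active], cls[active])] / scale)
      trem[active] <- trem[active] - waits
      active <- active[trem[active] > 0]
      for (s in active) {
        cur <- classes_rates[[cls[s]]][[st[s]]]
        st[s] <- cur$tgt[sample.int(length(cur$tgt), 1L, prob = cur$rate)]
      }
    }
    node_states[ch, ] <- st
  }
  seqs <- apply(node_states[seq_len(nt), , drop = FALSE], 1L, function(r)
    paste0(tab$codons[sense[r]], collapse = ""))
  names(seqs) <- tree$tip.label
  list(sequences = seqs, classes = cls)
}
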