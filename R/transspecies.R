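# Trans-species polymorphism screen: identity matching against a
# heterospecific reference panel, nearest-neighbor species on a bootstrapped
# tree, and conspecific-monophyly testing.

#' Percent DNA identity between two sequences
#'
#' Computed over ungapped shared columns (the indel block is excluded
#' pairwise). Equal-length inputs are compared column-wise; unequal-length
#' inputs are first globally aligned with [Biostrings::pairwiseAlignment()].
#'
#' @param a,b DNA sequences, gaps allowed.
#' @return identity percentage in `[0, 100]`; symmetric.
#' @export
percent_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    al <- Biostrings::pairwiseAlignment(
      gsub("-", "", a), gsub("-", "", b), type = "global")
    a <- as.character(Biostrings::alignedPattern(al))
    b <- as.character(Biostrings::alignedSubject(al))
  }
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  use <- va != "-" & vb != "-"
  if (!any(use)) stop("no shared ungapped columns")
  100 * sum(va[use] == vb[use]) / sum(use)
}

#' Most common alleles of a repertoire set
#'
#' Population allele frequency is the count of carrier samples divided by the
#' number of samples; ties are broken by allele id.
#'
#' @param rs a `repertoire_set`.
#' @param n how many alleles to return.
#' @return data.frame: allele_id, carriers, frequency (sorted).
#' @export
most_common_alleles <- function(rs, n = 10L) {
  stopifnot(inherits(rs, "repertoire_set"))
  carriers <- table(rs$genotypes$allele_id)
  df <- data.frame(allele_id = names(carriers),
                   carriers = as.integer(carriers))
  df$frequency <- df$carriers / nrow(rs$individuals)
  df <- df[order(-df$frequency, df$allele_id), , drop = FALSE]
  rownames(df) <- NULL
  head(df, n)
}

#' Identity screen of focal alleles against a heterospecific panel
#'
#' All (focal, reference) pairs at or above the identity threshold, sorted by
#' identity descending. An empty result is allowed.
#'
#' @param focal named character vector of focal allele DNA sequences.
#' @param reference data.frame with columns seq_id, species, dna (optional
#'   family).
#' @param threshold minimum identity as a fraction (default 0.94).
#' @return data.frame: focal_id, ref_id, species, identity (percent).
#' @export
find_heterospecific_matches <- function(focal, reference, threshold = 0.94) {
  stopifnot(!is.null(names(focal)), nrow(reference) >= 1,
            all(c("seq_id", "species", "dna") %in% names(reference)))
  rows <- list()
  for (i in seq_along(focal)) {
    for (j in seq_len(nrow(reference))) {
      idt <- percent_identity(focal[[i]], reference$dna[j])
      if (idt >= 100 * threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          focal_id = names(focal)[i], ref_id = reference$seq_id[j],
          species = reference$species[j], identity = idt)
    }
  }
  if (!length(rows))
    return(data.frame(focal_id = character(), ref_id = character(),
                      species = character(), identity = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$identity, out$focal_id, out$ref_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse `species=` / `family=` tags from FASTA headers
#'
#' @param seqs result of [read_fasta()] on a reference panel whose headers
#'   carry `species=<label>` and optionally `family=<label>` tags.
#' @return data.frame: seq_id, species, family, dna.
#' @export
species_tagged_panel <- function(seqs) {
  headers <- attr(seqs, "header")
  if (is.null(headers)) headers <- names(seqs)
  grab <- function(h, tag) {
    m <- regmatches(h, regexpr(paste0(tag, "=[^ \t]+"), h))
    if (length(m)) sub(paste0(tag, "="), "", m) else NA_character_
  }
  species <- vapply(headers, grab, "", tag = "species")
  family <- vapply(headers, grab, "", tag = "family")
  if (anyNA(species) || any(!nzchar(species)))
    stop("every reference header needs a species= tag")
  data.frame(seq_id = names(seqs), species = unname(species),
             family = unname(family), dna = unname(seqs))
}

#' Trans-species polymorphism screen
#'
#' Builds a bootstrapped neighbor-joining tree (JC-corrected distances) over
#' the combined focal + heterospecific set, tests whether the focal alleles
#' form one side of a split, reports each focal allele's nearest neighbor by
#' patristic distance (ties broken by raw identity), and lists every minimal
#' clade mixing focal and heterospecific leaves with its bootstrap support.
#' A focal allele whose nearest neighbor is heterospecific is flagged a
#' TSP candidate.
#'
#' @param focal named character vector of focal DNA sequences (aligned to the
#'   same window as the reference panel).
#' @param reference data.frame as in [find_heterospecific_matches()].
#' @param reps bootstrap replicates.
#' @param seed RNG seed.
#' @param identity_threshold match threshold passed through to the identity
#'   screen.
#' @return object of class `tsp_report`: list with `per_allele` (data.frame
#'   allele, nn_id, nn_species, nn_patristic, nn_identity, tsp_candidate),
#'   `is_focal_monophyletic`, `mixed_clades` (data.frame support, n_focal,
#'   n_heterospecific, tips), `matches`, `tree`.
#' @export
tsp_screen <- function(focal, reference, reps = 500L, seed = 1L,
                       identity_threshold = 0.94) {
  stopifnot(!is.null(names(focal)))
  all_ids <- c(names(focal), reference$seq_id)
  if (anyDuplicated(all_ids)) stop("focal and reference ids must be distinct")
  if (length(all_ids) < 4L) stop("combined sequence set must have >= 4 members")
  seqs <- c(focal, setNames(reference$dna, reference$seq_id))
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must share one aligned length; align them first")
  species <- c(setNames(rep("focal", length(focal)), names(focal)),
               setNames(reference$species, reference$seq_id))

  matches <- find_heterospecific_matches(focal, reference, identity_threshold)
  tr <- bootstrap_support(seqs, reps = reps, seed = seed)
  support <- attr(tr, "support")

  pat <- ape::cophenetic.phylo(tr)
  per <- list()
  for (f in names(focal)) {
    d <- pat[f, setdiff(colnames(pat), f)]
    nn_all <- names(d)[d == min(d)]
    if (length(nn_all) > 1L) {  # tie-break by raw identity, highest wins
      idt <- vapply(nn_all, function(id) percent_identity(seqs[[f]],
                                                          seqs[[id]]), 0)
      nn_all <- nn_all[order(-idt, nn_all)]
    }
    nn <- nn_all[1L]
    per[[f]] <- data.frame(
      allele = f, nn_id = nn, nn_species = species[[nn]],
      nn_patristic = unname(d[nn]),
      nn_identity = percent_identity(seqs[[f]], seqs[[nn]]),
      tsp_candidate = species[[nn]] != "focal")
  }
  per_allele <- do.call(rbind, per)
  rownames(per_allele) <- NULL

  mono <- is_monophyletic_split(tr, names(focal))$monophyletic

  # minimal mixed clades: internal nodes whose subtree holds both focal and
  # heterospecific leaves but none of whose child subtrees does
  nt <- length(tr$tip.label)
  inc <- edge_tip_incidence(tr)
  is_focal_tip <- tr$tip.label %in% names(focal)
  node_of_edge <- tr$edge[, 2L]
  internal <- which(node_of_edge > nt)
  mixed <- vapply(internal, function(e)
    any(inc[e, is_focal_tip]) && any(inc[e, !is_focal_tip]), TRUE)
  clades <- list()
  for (k in seq_along(internal)) {
    if (!mixed[k]) next
    e <- internal[k]; node <- node_of_edge[e]
    child_edges <- which(tr$edge[, 1L] == node & tr$edge[, 2L] > nt)
    child_mixed <- vapply(child_edges, function(ce)
      any(inc[ce, is_focal_tip]) && any(inc[ce, !is_focal_tip]), TRUE)
    if (any(child_mixed)) next
    tips <- tr$tip.label[inc[e, ]]
    sup <- if (!is.null(support)) support[node - nt] else NA_real_
    clades[[length(clades) + 1L]] <- data.frame(
      support = sup, n_focal = sum(tips %in% names(focal)),
      n_heterospecific = sum(!tips %in% names(focal)),
      tips = paste(tips, collapse = ","))
  }
  mixed_clades <- if (length(clades)) do.call(rbind, clades) else
    data.frame(support = numeric(), n_focal = integer(),
               n_heterospecific = integer(), tips = character())
  structure(list(per_allele = per_allele,
                 is_focal_monophyletic = mono,
                 mixed_clades = mixed_clades,
                 matches = matches, tree = tr),
            class = "tsp_report")
}

#' @export
print.tsp_report <- function(x, ...) {
  cat("trans-species polymorphism screen:\n")
  cat("  focal alleles monophyletic:", x$is_focal_monophyletic, "\n")
  cat("  TSP candidates:", sum(x$per_allele$tsp_candidate), "of",
      nrow(x$per_allele), "\n")
  cat("  heterospecific matches at threshold:", nrow(x$matches), "\n")
  invisible(x)
}
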