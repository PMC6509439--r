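# Unweighted UniFrac over allele repertoires, computed from the
# branch-partition definition on a rooted reference tree.

# edges x tips incidence: TRUE when the tip is a descendant of the edge's
# child node
edge_tip_incidence <- function(tree) {
  nt <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- nt + tree$Nnode
  desc <- matrix(FALSE, nnode, nt)
  desc[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    desc[par, ] <- desc[par, ] | desc[ch, ]
  }
  inc <- desc[tree$edge[, 2L], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  inc
}

#' Unweighted UniFrac distance between two leaf sets
#'
#' Over the branches of the rooted reference tree that have at least one
#' descendant in the union of the two sets ("observed" branches), the
#' distance is the fraction of observed branch length leading exclusively to
#' leaves of one set: identical sets give 0, sets drawn from completely
#' separated clades give 1.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param leaves_a,leaves_b nonempty character vectors of tip labels.
#' @return distance in `[0, 1]`.
#' @export
unweighted_unifrac <- function(tree, leaves_a, leaves_b) {
  d <- unifrac_matrix(tree, list(A = leaves_a, B = leaves_b))
  d["A", "B"]
}

#' Pairwise unweighted UniFrac matrix
#'
#' Vectorized over all pairs: with `P` the branches-by-samples incidence of
#' "has a descendant leaf in the sample" and `l` the branch lengths,
#' `d(i,j) = l(P_i xor P_j) / l(P_i or P_j)`.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param sets named list of nonempty tip-label vectors.
#' @return symmetric matrix of distances with zero diagonal.
#' @export
unifrac_matrix <- function(tree, sets) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tips <- tree$tip.label
  for (nm in names(sets)) {
    if (!length(sets[[nm]])) stop("empty leaf set: ", nm)
    bad <- setdiff(sets[[nm]], tips)
    if (length(bad))
      stop("leaf(s) not in tree for ", nm, ": ", paste(bad, collapse = ", "))
  }
  inc <- edge_tip_incidence(tree)
  m <- length(sets)
  S <- matrix(0, length(tips), m, dimnames = list(tips, names(sets)))
  for (j in seq_len(m)) S[unique(sets[[j]]), j] <- 1
  P <- (inc %*% S) > 0
  len <- tree$edge.length
  Lp <- colSums(len * P)                    # observed length per sample
  cross <- crossprod(P, len * P)            # shared observed length
  tot <- outer(Lp, Lp, "+")
  den <- tot - cross                        # union
  num <- tot - 2 * cross                    # symmetric difference
  if (any(den <= 0 & upper.tri(den)))
    stop("degenerate tree: all observed branch lengths are 0 for some pair")
  d <- num / den
  d[den <= 0] <- 0
  diag(d) <- 0
  # clip tiny negatives from floating error
  d[d < 0] <- 0
  d
}

#' Reference tree over the protein leaves of a repertoire set
#'
#' Neighbor joining on pairwise-deletion p-distances between the unique
#' translated alleles, midpoint rooted.
#'
#' @param rs a `repertoire_set`.
#' @return rooted `phylo` with protein ids as tips.
#' @export
reference_tree <- function(rs) {
  stopifnot(inherits(rs, "repertoire_set"))
  cat_df <- rs$catalogue
  prot <- cat_df$protein_aligned[!duplicated(cat_df$protein_id)]
  names(prot) <- cat_df$protein_id[!duplicated(cat_df$protein_id)]
  nj_tree(p_distance_matrix(prot))
}

#' Pairwise UniFrac distances between individuals of a repertoire set
#'
#' @param tree rooted reference tree over protein leaves.
#' @param rs a `repertoire_set`.
#' @return symmetric matrix over sample keys.
#' @export
pairwise_distance_table <- function(tree, rs) {
  unifrac_matrix(tree, protein_leaves(rs))
}
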