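# Distances, neighbor-joining reference trees, bootstrap support, and
# monophyly queries. Trees are ape "phylo" objects throughout.

#' Proportion of differing sites between two aligned sequences
#'
#' Pairwise deletion: columns where either sequence has a gap (`-`) are
#' excluded; the proportion is over the remaining shared columns.
#'
#' @param a,b equal-length aligned sequences (DNA or protein).
#' @return fraction in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences differ in aligned length (", nchar(a), " vs ", nchar(b), ")")
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  use <- va != "-" & vb != "-"
  if (!any(use)) stop("no ungapped shared columns")
  sum(va[use] != vb[use]) / sum(use)
}

#' Pairwise p-distance matrix for a set of aligned sequences
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return symmetric matrix of pairwise-deletion p-distances.
#' @export
p_distance_matrix <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  L <- nchar(seqs[[1]])
  if (any(nchar(seqs) != L)) stop("sequences differ in aligned length")
  m <- matrix(unlist(strsplit(unname(seqs), "")), nrow = n, byrow = TRUE)
  gap <- m == "-"
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      use <- !gap[i, ] & !gap[j, ]
      if (!any(use))
        stop("no ungapped shared columns between ", names(seqs)[i], " and ",
             names(seqs)[j])
      d[i, j] <- d[j, i] <- sum(m[i, use] != m[j, use]) / sum(use)
    }
  }
  d
}

#' Jukes-Cantor correction of a p-distance
#'
#' `d = -(3/4) log(1 - 4p/3)`; strictly increasing and convex on
#' `[0, 0.75)`, with `d >= p` and `d(0) = 0`.
#'
#' @param p proportion of differing sites, `0 <= p < 0.75`.
#' @return corrected distance in substitutions/site.
#' @export
jc_correct <- function(p) {
  if (any(p < 0)) stop("p must be nonnegative")
  if (any(p >= 0.75))
    stop("Jukes-Cantor saturation: p = ", max(p), " >= 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' Neighbor-joining reference tree
#'
#' NJ on a distance matrix (Saitou-Nei Q-criterion via [ape::nj()]), followed
#' by two normalizations: negative estimated branch lengths are clamped to
#' zero with the deficit transferred to the adjacent branch (so path lengths
#' through the node are approximately preserved), and the tree is midpoint
#' rooted, which downstream UniFrac requires.
#'
#' @param dm symmetric distance matrix with >= 3 labels, zero diagonal,
#'   finite entries.
#' @param root midpoint-root the result (default TRUE).
#' @return a rooted (unless `root = FALSE`) `phylo` object.
#' @export
nj_tree <- function(dm, root = TRUE) {
  stopifnot(is.matrix(dm))
  if (nrow(dm) < 3L) stop("need >= 3 labels for neighbor joining")
  if (any(!is.finite(dm))) stop("non-finite entries in distance matrix")
  if (max(abs(dm - t(dm))) > 1e-9) stop("distance matrix not symmetric")
  tr <- ape::nj(as.dist(dm))
  neg <- which(tr$edge.length < 0)
  if (length(neg)) {
    pkg_log("DEBUG", "clamping ", length(neg), " negative NJ branch length(s)")
    for (e in neg) {
      deficit <- tr$edge.length[e]   # negative
      tr$edge.length[e] <- 0
      node <- tr$edge[e, 2L]
      kids <- which(tr$edge[, 1L] == node)
      if (length(kids)) {
        tr$edge.length[kids] <- pmax(0, tr$edge.length[kids] + deficit)
      } else {
        up <- which(tr$edge[, 2L] == tr$edge[e, 1L])
        if (length(up)) tr$edge.length[up] <- pmax(0, tr$edge.length[up] + deficit)
      }
    }
  }
  if (root) tr <- phangorn::midpoint(tr)
  tr
}

#' Column-bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the tree with
#' `tree_fun`, and reports for each internal bipartition of the point-estimate
#' tree the percentage of replicate trees containing it
#' (via [ape::prop.clades()], unrooted bipartitions).
#'
#' @param seqs named aligned sequences (the tree leaves).
#' @param reps bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param tree_fun function(seqs) -> phylo; default: NJ on JC-corrected
#'   p-distances (saturated entries fall back to the p-distance cap, logged).
#' @return the point-estimate tree with `node.label` support percentages
#'   (root label empty).
#' @export
bootstrap_support <- function(seqs, reps = 500L, seed = 1L,
                              tree_fun = NULL) {
  if (reps < 1L) stop("reps must be >= 1")
  L <- nchar(seqs[[1]])
  if (L < 2L) stop("alignment must have >= 2 columns")
  if (is.null(tree_fun)) tree_fun <- function(s) nj_tree(jc_distance_matrix(s))
  point <- tree_fun(seqs)
  chars <- strsplit(unname(seqs), "")
  set.seed(as.integer(seed))
  boots <- vector("list", reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    res <- vapply(chars, function(v) paste0(v[idx], collapse = ""), "")
    names(res) <- names(seqs)
    boots[[r]] <- tree_fun(res)
  }
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / reps
  point$node.label <- as.character(round(support, 1))
  # the root "bipartition" is the trivial split; report it blank
  point$node.label[1L] <- ""
  attr(point, "support") <- support
  point
}

#' JC-corrected distance matrix with saturation fallback
#'
#' p-distances (pairwise deletion) corrected by [jc_correct()]; entries at or
#' beyond the 0.75 saturation bound fall back to the uncorrected p-distance
#' and are logged.
#'
#' @param seqs named aligned DNA sequences.
#' @return symmetric distance matrix.
#' @export
jc_distance_matrix <- function(seqs) {
  p <- p_distance_matrix(seqs)
  sat <- p >= 0.75
  if (any(sat)) {
    pkg_log("WARN", sum(sat & upper.tri(sat)),
            " saturated pairwise distance(s); using uncorrected p")
  }
  d <- p
  d[!sat] <- jc_correct(p[!sat])
  d
}

#' Test whether a leaf subset forms one side of a split
#'
#' True iff some edge of the unrooted topology separates exactly the subset
#' from the remaining leaves (the full leaf set is trivially monophyletic).
#' Also returns the smallest clade of the rooted tree containing the subset.
#'
#' @param tree a `phylo` object.
#' @param leaves nonempty character vector of tip labels.
#' @return list(monophyletic = logical, clade_leaves = tips of the smallest
#'   containing rooted clade).
#' @export
is_monophyletic_split <- function(tree, leaves) {
  if (!length(leaves)) stop("leaf subset is empty")
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown))
    stop("unknown leaf(s): ", paste(unknown, collapse = ", "))
  leaves <- unique(leaves)
  if (length(leaves) == length(tree$tip.label))
    return(list(monophyletic = TRUE, clade_leaves = tree$tip.label))
  comp <- setdiff(tree$tip.label, leaves)
  mono <- ape::is.monophyletic(tree, leaves) ||
    ape::is.monophyletic(tree, comp)
  if (length(leaves) == 1L) {
    clade <- leaves
  } else {
    mrca <- ape::getMRCA(tree, leaves)
    clade <- ape::extract.clade(tree, mrca)$tip.label
  }
  list(monophyletic = mono, clade_leaves = clade)
}
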