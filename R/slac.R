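# SLAC-style per-codon selection test: Fitch parsimony ancestors on whole
# codons, NG86 decomposition of each branch change, binomial test of the
# nonsynonymous excess per site.

# one Fitch pass over a rooted phylo for a single site.
# states: integer codon indices per tip (NA = missing).
# Returns per-branch (edge order of `tree`) parent and child codon states for
# one uniformly drawn tie resolution.
.fitch_resolve <- function(tree, states, tab) {
  nt <- length(tree$tip.label)
  nnode <- nt + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", nnode)   # NULL = not yet visited
  for (i in seq_len(nt))
    sets[[i]] <- if (is.na(states[i])) integer(0) else states[i]  # 0-len = any
  edge <- po$edge
  # bottom-up: fold each child into its parent's running state set; an edge is
  # visited only after the child's whole subtree (postorder), and a
  # zero-length set is a missing-data wildcard
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    s2 <- sets[[ch]]
    cur <- sets[[par]]
    sets[[par]] <- if (is.null(cur)) s2
    else if (length(s2) == 0L) cur
    else if (length(cur) == 0L) s2
    else {
      inter <- intersect(cur, s2)
      if (length(inter)) inter else union(cur, s2)
    }
  }
  root <- nt + 1L
  assign_state <- integer(nnode); assign_state[] <- NA_integer_
  pick <- function(s) if (length(s) == 1L) s else s[sample.int(length(s), 1L)]
  rs <- sets[[root]]
  if (length(rs) == 0L) return(NULL)  # entirely missing site
  assign_state[root] <- pick(rs)
  # top-down in preorder (reverse postorder edge order)
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    s <- sets[[ch]]
    ps <- assign_state[par]
    assign_state[ch] <- if (length(s) == 0L || ps %in% s) ps else pick(s)
  }
  # report in the original tree's edge order
  cbind(parent = assign_state[tree$edge[, 1L]],
        child = assign_state[tree$edge[, 2L]])
}

#' SLAC-style per-codon selection test
#'
#' Ancestral codons are reconstructed by Fitch parsimony on whole codons
#' (ties resolved uniformly at random and averaged over `n_resolutions`
#' seeded resolutions); each branch's codon change is decomposed into
#' nonsynonymous and synonymous counts by the NG86 pathway rules; the
#' expected nonsynonymous fraction at a site is the NG86 nonsynonymous site
#' fraction averaged over the codons observed at the tips; and the observed
#' nonsynonymous count is referred to a two-tailed binomial test against that
#' expectation. A site is called `positive` (`purifying`) when it shows a
#' nonsynonymous (synonymous) excess at `p <= alpha`, `neutral` otherwise;
#' a site with no reconstructed change is neutral with p = 1.
#'
#' @param seqs named aligned in-frame DNA sequences; names must match the
#'   tree's tip labels.
#' @param tree `phylo` over the sequences (rooting only affects tie
#'   resolution at the root).
#' @param alpha per-site significance level.
#' @param n_resolutions tie resolutions averaged per site.
#' @param seed RNG seed.
#' @return data.frame, one row per codon: codon, n_changes, N_changes,
#'   S_changes, expected_N_fraction, dn_minus_ds, p_value, call.
#' @export
slac_site_test <- function(seqs, tree, alpha = 0.10, n_resolutions = 20L,
                           seed = 1L) {
  if (length(seqs) < 3L) stop("need >= 3 sequences")
  if (!setequal(names(seqs), tree$tip.label))
    stop("tree leaves must match alignment row ids")
  tab <- codon_tables()
  cod <- t(vapply(unname(seqs[tree$tip.label]), .codon_index,
                  integer(nchar(seqs[[1]]) / 3L), tab = tab))
  C <- ncol(cod)
  set.seed(as.integer(seed))
  out <- vector("list", C)
  for (s in seq_len(C)) {
    tipstates <- cod[, s]
    tipstates[!is.na(tipstates) & tab$is_stop[tipstates]] <- NA_integer_
    obs <- tipstates[!is.na(tipstates)]
    if (length(obs) == 0L) {
      out[[s]] <- data.frame(codon = s, n_changes = 0, N_changes = 0,
                             S_changes = 0, expected_N_fraction = NA_real_,
                             dn_minus_ds = NA_real_, p_value = 1,
                             call = "neutral")
      next
    }
    EN <- mean(tab$nonsyn_sites[obs] / 3)
    Ns <- 0; Ss <- 0
    for (r in seq_len(n_resolutions)) {
      res <- .fitch_resolve(tree, tipstates, tab)
      if (is.null(res)) break
      chg <- res[, 1L] != res[, 2L]
      if (any(chg)) {
        Ns <- Ns + sum(tab$ND[res[chg, , drop = FALSE]])
        Ss <- Ss + sum(tab$SD[res[chg, , drop = FALSE]])
      }
    }
    Ns <- Ns / n_resolutions; Ss <- Ss / n_resolutions
    n <- round(Ns + Ss); x <- round(Ns)
    x <- min(x, n)
    if (n == 0L) {
      pv <- 1; call <- "neutral"
    } else {
      pv <- binom.test(x, n, p = EN)$p.value
      frac <- Ns / (Ns + Ss)
      call <- if (pv <= alpha && frac > EN) "positive"
      else if (pv <= alpha && frac < EN) "purifying"
      else "neutral"
    }
    en_sites <- mean(tab$nonsyn_sites[obs])
    es_sites <- mean(tab$syn_sites[obs])
    dnds <- Ns / en_sites - if (es_sites > 0) Ss / es_sites else 0
    out[[s]] <- data.frame(codon = s, n_changes = Ns + Ss, N_changes = Ns,
                           S_changes = Ss, expected_N_fraction = EN,
                           dn_minus_ds = dnds, p_value = pv, call = call)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
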