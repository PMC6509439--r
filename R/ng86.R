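# Nei-Gojobori (1986) pathway counting of synonymous and nonsynonymous sites
# and differences, with Jukes-Cantor correction, and the bootstrap Z-test of
# positive selection. All per-codon quantities are precomputed into lookup
# tables once per session.

.BASES <- c("T", "C", "A", "G")

codon_tables <- function() {
  if (!is.null(.pkg_env$ng)) return(.pkg_env$ng)
  codons <- apply(expand.grid(.BASES, .BASES, .BASES)[, 3:1], 1, paste0,
                  collapse = "")
  gc <- .genetic_code()
  aa <- vapply(codons, function(cd) gc[[cd]], "")
  is_stop <- aa == "*"
  n <- length(codons)
  idx <- setNames(seq_len(n), codons)

  # per-codon synonymous site count: at each position, the fraction of
  # synonymous single-base changes among the non-stop changes (stop mutations
  # excluded from the denominator), so S + N = 3 for every sense codon
  syn_sites <- rep(NA_real_, n)
  for (i in which(!is_stop)) {
    s <- 0
    for (pos in 1:3) {
      b <- substr(codons[i], pos, pos)
      alts <- setdiff(.BASES, b)
      targets <- vapply(alts, function(nb) {
        cd <- codons[i]; substr(cd, pos, pos) <- nb; cd
      }, "")
      sense <- !is_stop[idx[targets]]
      if (any(sense))
        s <- s + sum(aa[idx[targets[sense]]] == aa[i]) / sum(sense)
    }
    syn_sites[i] <- s
  }
  nonsyn_sites <- unname(ifelse(is_stop, NA_real_, 3 - syn_sites))

  # pathway-averaged synonymous/nonsynonymous differences between codon pairs
  SD <- matrix(0, n, n); ND <- matrix(0, n, n)
  step_type <- function(c1, c2) if (aa[idx[c1]] == aa[idx[c2]]) "S" else "N"
  for (i in which(!is_stop)) {
    for (j in which(!is_stop)) {
      if (j <= i) next
      pos <- which(strsplit(codons[i], "")[[1]] != strsplit(codons[j], "")[[1]])
      k <- length(pos)
      if (k == 0L) next
      perms <- if (k == 1L) list(pos) else
        if (k == 2L) list(pos, rev(pos)) else
          lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                      c(3,2,1)), function(o) pos[o])
      tally <- function(skip_stops) {
        sd_ <- 0; nd_ <- 0; used <- 0L
        for (perm in perms) {
          cur <- codons[i]; ok <- TRUE; s <- 0; d <- 0
          for (p in perm) {
            nxt <- cur
            substr(nxt, p, p) <- substr(codons[j], p, p)
            if (skip_stops && is_stop[idx[nxt]]) { ok <- FALSE; break }
            if (is_stop[idx[cur]] || is_stop[idx[nxt]]) d <- d + 1
            else if (aa[idx[cur]] == aa[idx[nxt]]) s <- s + 1
            else d <- d + 1
            cur <- nxt
          }
          if (ok) { sd_ <- sd_ + s; nd_ <- nd_ + d; used <- used + 1L }
        }
        if (used == 0L) return(NULL)
        c(sd_ / used, nd_ / used)
      }
      res <- tally(TRUE)
      if (is.null(res)) res <- tally(FALSE)  # all pathways blocked by stops
      SD[i, j] <- SD[j, i] <- res[1]
      ND[i, j] <- ND[j, i] <- res[2]
    }
  }
  .pkg_env$ng <- list(codons = codons, idx = idx, aa = aa, is_stop = is_stop,
                      syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
                      SD = SD, ND = ND)
  .pkg_env$ng
}

# split an aligned in-frame DNA string into codons; fully-gapped or partially
# gapped codons return NA
.codon_index <- function(dna, tab) {
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("aligned length ", n, " not divisible by 3")
  cds <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  out <- unname(tab$idx[cds])
  out[is.na(out)] <- NA_integer_  # codons containing gaps/ambiguity
  out
}

#' Nei-Gojobori pairwise dN/dS
#'
#' Counts synonymous and nonsynonymous sites (stop mutations excluded from
#' the per-position denominator) and pathway-averaged synonymous and
#' nonsynonymous differences (all orderings of single-base steps enumerated,
#' pathways through stop codons discarded, survivors weighted equally) over
#' the codons shared ungapped by the two sequences; proportions are corrected
#' with [jc_correct()]. Saturation (`pS` or `pN >= 0.75`) is reported as an
#' `Inf` distance with a warning and flagged; `omega` is `NA` (flagged) when
#' `dS = 0`.
#'
#' @param a,b aligned in-frame DNA sequences (equal length, gaps allowed).
#' @return list: S_sites, N_sites, Sd, Nd, pS, pN, dS, dN, omega,
#'   n_codons (shared ungapped), flags (character vector).
#' @export
ng86_pairwise <- function(a, b) {
  tab <- codon_tables()
  ca <- .codon_index(a, tab); cb <- .codon_index(b, tab)
  if (length(ca) != length(cb)) stop("sequences differ in codon count")
  use <- !is.na(ca) & !is.na(cb) & !tab$is_stop[ca] & !tab$is_stop[cb]
  if (!any(use)) stop("no shared ungapped sense codons")
  ca <- ca[use]; cb <- cb[use]
  S <- (sum(tab$syn_sites[ca]) + sum(tab$syn_sites[cb])) / 2
  N <- (sum(tab$nonsyn_sites[ca]) + sum(tab$nonsyn_sites[cb])) / 2
  Sd <- sum(tab$SD[cbind(ca, cb)])
  Nd <- sum(tab$ND[cbind(ca, cb)])
  pS <- Sd / S; pN <- Nd / N
  flags <- character()
  corr <- function(p, what) {
    if (p >= 0.75) {
      warning("NG86 ", what, " saturated (p = ", signif(p, 4), ")")
      flags <<- c(flags, paste0(what, "_saturated"))
      return(Inf)
    }
    jc_correct(p)
  }
  dS <- corr(pS, "dS"); dN <- corr(pN, "dN")
  omega <- if (is.finite(dS) && dS > 0) dN / dS else {
    flags <- c(flags, "omega_undefined")
    NA_real_
  }
  list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = dS, dN = dN, omega = omega, n_codons = length(ca), flags = flags)
}

# per-pair, per-codon-column contribution matrices for an alignment:
# Sd, Nd, and the pairwise site counts (0 where either member is gapped)
.ng_pair_columns <- function(seqs) {
  tab <- codon_tables()
  n <- length(seqs)
  cod <- t(vapply(unname(seqs), .codon_index, integer(nchar(seqs[[1]]) / 3L),
                  tab = tab))
  C <- ncol(cod)
  prs <- combn(n, 2L)
  P <- ncol(prs)
  Sdm <- matrix(0, P, C); Ndm <- matrix(0, P, C)
  Ssm <- matrix(0, P, C); Nsm <- matrix(0, P, C)
  for (p in seq_len(P)) {
    ci <- cod[prs[1L, p], ]; cj <- cod[prs[2L, p], ]
    ok <- !is.na(ci) & !is.na(cj) & !tab$is_stop[ci] & !tab$is_stop[cj]
    ok[is.na(ok)] <- FALSE
    Sdm[p, ok] <- tab$SD[cbind(ci[ok], cj[ok])]
    Ndm[p, ok] <- tab$ND[cbind(ci[ok], cj[ok])]
    Ssm[p, ok] <- (tab$syn_sites[ci[ok]] + tab$syn_sites[cj[ok]]) / 2
    Nsm[p, ok] <- (tab$nonsyn_sites[ci[ok]] + tab$nonsyn_sites[cj[ok]]) / 2
  }
  list(Sd = Sdm, Nd = Ndm, Ss = Ssm, Ns = Nsm, pairs = prs)
}

# mean pairwise dN and dS given per-pair totals; saturated pairs dropped
.mean_dn_ds <- function(Sd, Nd, Ss, Ns) {
  pS <- Sd / Ss; pN <- Nd / Ns
  okS <- pS < 0.75 & Ss > 0; okN <- pN < 0.75 & Ns > 0
  ok <- okS & okN
  if (!any(ok)) return(c(NA_real_, NA_real_))
  c(mean(-0.75 * log(1 - 4 * pN[ok] / 3)),
    mean(-0.75 * log(1 - 4 * pS[ok] / 3)))
}

#' Overall Z-test of positive selection (dN > dS)
#'
#' `dN_bar` and `dS_bar` are the means of NG86 pairwise dN and dS over all
#' sequence pairs; the standard error of `dN_bar - dS_bar` is estimated by
#' bootstrapping codon columns, and `Z = (dN_bar - dS_bar)/SE` is referred to
#' the one-tailed standard normal (alternative: positive selection).
#'
#' @param seqs named aligned in-frame DNA sequences (>= 2).
#' @param reps bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @return list: dN_bar, dS_bar, Z, p_one_tailed, se, reps, seed,
#'   n_dropped_pairs (saturated pairs excluded from the means).
#' @export
overall_z_test <- function(seqs, reps = 500L, seed = 1L) {
  if (length(seqs) < 2L) stop("need >= 2 sequences")
  if (reps < 2L) stop("reps must be >= 2")
  mats <- .ng_pair_columns(seqs)
  Sd <- rowSums(mats$Sd); Nd <- rowSums(mats$Nd)
  Ss <- rowSums(mats$Ss); Ns <- rowSums(mats$Ns)
  pS <- Sd / Ss; pN <- Nd / Ns
  dropped <- sum(pS >= 0.75 | pN >= 0.75)
  if (dropped > 0)
    pkg_log("WARN", dropped, " saturated pair(s) dropped from Z-test means")
  est <- .mean_dn_ds(Sd, Nd, Ss, Ns)
  dN_bar <- est[1]; dS_bar <- est[2]
  C <- ncol(mats$Sd)
  set.seed(as.integer(seed))
  W <- rmultinom(reps, C, rep(1 / C, C))
  SdB <- mats$Sd %*% W; NdB <- mats$Nd %*% W
  SsB <- mats$Ss %*% W; NsB <- mats$Ns %*% W
  deltas <- vapply(seq_len(reps), function(r) {
    e <- .mean_dn_ds(SdB[, r], NdB[, r], SsB[, r], NsB[, r])
    e[1] - e[2]
  }, numeric(1))
  se <- sd(deltas, na.rm = TRUE)
  num <- dN_bar - dS_bar
  if (!is.finite(se) || se == 0) {
    if (is.na(num) || num == 0) {
      warning("degenerate bootstrap with zero numerator; p = 0.5")
      return(list(dN_bar = dN_bar, dS_bar = dS_bar, Z = 0,
                  p_one_tailed = 0.5, se = 0, reps = reps, seed = seed,
                  n_dropped_pairs = dropped))
    }
    stop("degenerate bootstrap: zero SE with nonzero dN - dS")
  }
  Z <- num / se
  list(dN_bar = dN_bar, dS_bar = dS_bar, Z = Z,
       p_one_tailed = pnorm(Z, lower.tail = FALSE), se = se,
       reps = as.integer(reps), seed = as.integer(seed),
       n_dropped_pairs = dropped)
}
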