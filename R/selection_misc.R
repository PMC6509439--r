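# Consensus-site bookkeeping: AIC ranking of externally supplied codon-model
# fits, intersection of per-test positive-site lists, and annotation against
# reference site sets.

#' Codon positions reported as positively selected across passerines
#'
#' Consensus positive-selection positions in passerine MHC class II exon 2
#' (1-based within the 73-codon analyzed window), packaged as the default
#' annotation set. The human peptide-binding positions are not packaged and
#' must be supplied by the user.
#'
#' @return integer vector of codon positions.
#' @export
passerine_positive_sites <- function() {
  c(7L, 19L, 27L, 42L, 46L, 49L, 59L, 60L, 62L, 63L, 73L)
}

#' Published per-test positive-site lists for song sparrow MHC class II
#'
#' Positively selected codons reported by six site-level analyses of the song
#' sparrow exon 2 data (two codon-ML site models and four site tests), as
#' printed inputs for consensus intersection. Positions are 1-based within
#' the analyzed 73-codon window.
#'
#' @return named list of integer vectors.
#' @export
published_site_tests <- function() {
  list(
    M2a   = c(1L, 2L, 24L, 26L, 42L, 46L, 56L, 60L, 62L, 73L),
    M8    = c(1L, 2L, 19L, 24L, 26L, 27L, 42L, 46L, 56L, 60L, 62L, 63L, 67L,
              73L),
    MEME  = c(2L, 7L, 17L, 19L, 24L, 25L, 27L, 41L, 42L, 46L, 49L, 50L, 56L,
              60L, 62L, 66L, 67L, 71L, 73L),
    FEL   = c(2L, 7L, 19L, 24L, 42L, 46L, 56L, 60L, 62L, 67L, 73L),
    SLAC  = c(2L, 7L, 17L, 19L, 24L, 25L, 27L, 41L, 42L, 46L, 49L, 59L, 62L,
              67L, 73L),
    FUBAR = c(2L, 7L, 19L, 24L, 27L, 42L, 46L, 62L, 67L, 73L))
}

#' Published codon-model fits for the song sparrow exon 2 data
#'
#' Log-likelihoods of the four standard codon site models (M1a, M2a, M7, M8)
#' as published for this dataset, with the nominal free-parameter counts of
#' each model family (M1a: p1, w0; M2a: p1, p2, w0, w2; M7: p, q;
#' M8: p0, p, q, w). Note the published AIC column is not internally
#' consistent with these lnL/k values for every row (the published M2a AIC is
#' smaller than any 2k - 2 lnL with k >= 1 allows); [aic_rank()] always
#' recomputes AIC from lnL and k and never adjusts the inputs.
#'
#' @return data.frame with columns name, lnL, k.
#' @export
published_model_fits <- function() {
  data.frame(name = c("M2a", "M8", "M1a", "M7"),
             lnL = c(-11072, -11105, -11290, -11359),
             k = c(4, 4, 2, 2))
}

#' Intersection of per-test positive-site lists
#'
#' @param site_sets nonempty list of integer vectors.
#' @return sorted integer vector of sites present in every set.
#' @export
consensus_sites <- function(site_sets) {
  if (!length(site_sets)) stop("need at least one site set")
  out <- Reduce(intersect, site_sets)
  sort(unique(as.integer(out)))
}

#' AIC ranking of model fits
#'
#' `AIC = 2k - 2 lnL`; fits are returned in ascending AIC with
#' `delta_AIC` relative to the best; exact ties are ordered by name.
#'
#' @param fits data.frame with columns name, lnL, k (k > 0).
#' @return data.frame: name, lnL, k, AIC, delta_AIC.
#' @export
aic_rank <- function(fits) {
  stopifnot(is.data.frame(fits), nrow(fits) >= 1,
            all(c("name", "lnL", "k") %in% names(fits)))
  if (any(fits$k <= 0)) stop("free-parameter count k must be positive")
  out <- data.frame(name = fits$name, lnL = fits$lnL, k = fits$k,
                    AIC = 2 * fits$k - 2 * fits$lnL)
  out <- out[order(out$AIC, out$name), , drop = FALSE]
  out$delta_AIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  out
}

#' Annotate candidate sites against reference site sets
#'
#' Flags each input site as belonging to the human peptide-binding-region
#' homologues (`pbr`, user-supplied) and/or the passerine consensus
#' positive-selection set, and reports overlap counts.
#'
#' @param sites integer vector of codon positions.
#' @param pbr_sites optional integer vector of human antigen-binding
#'   positions; when `NULL` the pbr column is reported as not supplied.
#' @param passerine_sites reference set; defaults to
#'   [passerine_positive_sites()].
#' @return list: `table` (data.frame site, pbr, passerine),
#'   `pbr_overlap`, `passerine_overlap` (sorted vectors or a
#'   "pbr not supplied" note), `n_pbr`, `n_passerine`.
#' @export
annotate_sites <- function(sites, pbr_sites = NULL,
                           passerine_sites = passerine_positive_sites()) {
  sites <- sort(unique(as.integer(sites)))
  pass_flag <- sites %in% passerine_sites
  if (is.null(pbr_sites)) {
    pbr_flag <- rep(NA, length(sites))
    pbr_overlap <- "pbr not supplied"
    n_pbr <- NA_integer_
  } else {
    pbr_flag <- sites %in% pbr_sites
    pbr_overlap <- sites[pbr_flag]
    n_pbr <- sum(pbr_flag)
  }
  list(table = data.frame(site = sites, pbr = pbr_flag,
                          passerine = pass_flag),
       pbr_overlap = pbr_overlap,
       passerine_overlap = sites[pass_flag],
       n_pbr = n_pbr,
       n_passerine = sum(pass_flag))
}
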