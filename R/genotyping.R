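# Genotype calling for multilocus MHC amplicons: per-individual read-frequency
# filter, trim/translate to the analyzed codon window, collapse to unique
# protein alleles.

#' Standard-code translation of an in-frame DNA sequence
#'
#' Gap codons (`---`) translate to `-`; stop codons to `*`. Mixed gap/base
#' codons are an error.
#'
#' @param dna character scalar, length divisible by 3, alphabet ACGT-.
#' @return amino-acid string.
#' @export
translate_dna <- function(dna) {
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("sequence length ", n, " not divisible by 3")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- character(length(codons))
  gc <- .genetic_code()
  for (i in seq_along(codons)) {
    cd <- codons[i]
    if (cd == "---") { aa[i] <- "-"; next }
    if (grepl("-", cd, fixed = TRUE))
      stop("codon ", i, " ('", cd, "') mixes gaps and bases")
    a <- gc[[cd]]
    if (is.null(a)) stop("codon ", i, " ('", cd, "') is not ACGT")
    aa[i] <- a
  }
  paste0(aa, collapse = "")
}

.genetic_code <- function() {
  if (is.null(.pkg_env$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_env$gc <- as.list(setNames(as.character(gc), names(gc)))
  }
  .pkg_env$gc
}

#' A per-individual amplicon read profile
#'
#' @param individual_id identifier.
#' @param counts named numeric vector: names are DNA sequences (ACGT), values
#'   nonnegative read counts with positive total.
#' @param year season label.
#' @return a `read_profile` list.
#' @export
read_profile <- function(individual_id, counts, year = NA) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("read_profile: counts must be named by sequence")
  if (any(counts < 0)) stop("read_profile: negative count")
  if (sum(counts) <= 0) stop("read_profile: total count must be > 0 for ",
                             individual_id)
  if (any(grepl("[^ACGT]", names(counts))))
    stop("read_profile: sequence alphabet must be ACGT")
  structure(list(individual_id = as.character(individual_id),
                 counts = counts, year = year),
            class = "read_profile")
}

#' Remove low-frequency sequences from a read profile
#'
#' A sequence is retained iff `count / total >= threshold`, where `total` is
#' the pre-filter sum of the individual's reads. A sequence at exactly the
#' threshold is kept: the filter removes only sequences below it. Retained
#' counts are unchanged.
#'
#' @param profile a [read_profile()].
#' @param threshold fraction in (0, 1); default the conventional 1%.
#' @return the filtered `read_profile`.
#' @export
filter_low_frequency <- function(profile, threshold = 0.01) {
  stopifnot(inherits(profile, "read_profile"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  total <- sum(profile$counts)
  keep <- profile$counts / total >= threshold
  if (!any(keep))
    stop("no alleles survive filter for individual ", profile$individual_id)
  removed <- sum(!keep)
  if (removed > 0)
    pkg_log("DEBUG", profile$individual_id, ": filter removed ", removed, "/",
            length(keep), " sequences (",
            sprintf("%.2f%%", 100 * sum(profile$counts[!keep]) / total),
            " of reads)")
  profile$counts <- profile$counts[keep]
  profile
}

#' Trim and translate candidate allele sequences
#'
#' Sequences are expected already aligned/trimmed to the analyzed window
#' (codons 8-80 of exon 2, 216-219 bp; the 3-bp length variation is a single
#' codon indel, represented as a `---` codon in aligned input). A sequence is
#' rejected, with a logged reason, when its ungapped length is not 216 or 219,
#' when its length is out of frame, or when its translation contains an
#' internal stop.
#'
#' @param seqs named character vector of DNA sequences, possibly containing
#'   `-` gap columns.
#' @param codon_offset exon codon number of the first trimmed codon (kept as
#'   annotation; codon numbering downstream is 1-based within the window).
#' @return list with `alleles` (data.frame: id, dna, dna_aligned, protein,
#'   protein_aligned) and `rejected` (data.frame: id, reason).
#' @export
trim_and_translate <- function(seqs, codon_offset = 8L) {
  stopifnot(!is.null(names(seqs)))
  ok <- list(); bad <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    aligned <- toupper(seqs[[i]])
    dna <- gsub("-", "", aligned, fixed = TRUE)
    if (!nchar(dna) %in% c(216L, 219L)) {
      bad[[length(bad) + 1L]] <- data.frame(
        id = id, reason = paste0("ungapped length ", nchar(dna),
                                 " not in {216, 219}"))
      next
    }
    prot_aln <- tryCatch(translate_dna(aligned), error = function(e) NULL)
    if (is.null(prot_aln)) {
      bad[[length(bad) + 1L]] <- data.frame(id = id, reason = "out of frame")
      next
    }
    prot <- gsub("-", "", prot_aln, fixed = TRUE)
    if (grepl("*", prot, fixed = TRUE)) {
      bad[[length(bad) + 1L]] <- data.frame(id = id,
                                            reason = "internal stop codon")
      next
    }
    ok[[length(ok) + 1L]] <- data.frame(
      id = id, dna = dna, dna_aligned = aligned,
      protein = prot, protein_aligned = prot_aln)
  }
  rejected <- if (length(bad)) do.call(rbind, bad) else
    data.frame(id = character(), reason = character())
  for (j in seq_len(nrow(rejected)))
    pkg_log("WARN", "rejected sequence ", rejected$id[j], ": ",
            rejected$reason[j])
  alleles <- if (length(ok)) do.call(rbind, ok) else
    data.frame(id = character(), dna = character(), dna_aligned = character(),
               protein = character(), protein_aligned = character())
  alleles$codon_offset <- rep(as.integer(codon_offset), nrow(alleles))
  rownames(alleles) <- NULL
  list(alleles = alleles, rejected = rejected)
}

# Place the single-codon indel gap of 216-bp sequences within the 219-column
# window. Already-gapped and 219-bp inputs pass through; each ungapped 216-bp
# sequence gets a "---" codon at the position maximizing identity to the
# column-majority consensus of the 219-column sequences (ties: leftmost).
# With no 219-bp sequence present all sequences share the 216 frame already.
.place_indel_gap <- function(seqs) {
  ung <- !grepl("-", seqs, fixed = TRUE)
  short <- ung & nchar(seqs) == 216L
  full <- nchar(seqs) == 219L
  if (!any(short) || !any(full)) return(seqs)
  refm <- do.call(rbind, strsplit(seqs[full], ""))
  consensus <- apply(refm, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("-")
    names(sort(table(col), decreasing = TRUE))[1L]
  })
  out <- seqs
  for (i in which(short)) {
    v <- strsplit(seqs[i], "")[[1]]
    best_g <- 1L; best_m <- -1L
    for (g in seq_len(73L)) {
      cut <- 3L * (g - 1L)
      cand <- c(v[seq_len(cut)], "-", "-", "-",
                if (cut < 216L) v[(cut + 1L):216L])
      m <- sum(cand == consensus & cand != "-")
      if (m > best_m) { best_m <- m; best_g <- g }
    }
    cut <- 3L * (best_g - 1L)
    out[i] <- paste0(c(v[seq_len(cut)], "-", "-", "-",
                       if (cut < 216L) v[(cut + 1L):216L]), collapse = "")
  }
  pkg_log("INFO", "placed the 3-bp indel gap in ", sum(short),
          " 216-bp sequence(s) against the 219-column consensus")
  out
}

#' Call multilocus genotypes from read profiles
#'
#' Applies the read-frequency filter to each profile, trims/translates
#' surviving sequences, assigns stable allele identifiers (lexicographic in
#' the aligned DNA sequence, so identical inputs yield identical catalogues
#' regardless of profile order), collapses identical translations onto shared
#' protein leaves, and summarizes allele counts per individual.
#'
#' Because the mate-choice null is stratified by year, an individual sampled
#' in two seasons keeps one repertoire per season; the summary reports the
#' mean both per capture-year sample and per unique individual.
#'
#' @param profiles list of [read_profile()]s (one per individual per year).
#' @param metadata data.frame with columns individual, sex, year.
#' @param threshold read-frequency filter threshold.
#' @param exclude_sequences optional character vector of raw sequences to drop
#'   before filtering (hook for an external chimera screen).
#' @return an object of class `repertoire_set`: list with
#'   `individuals` (data.frame individual, sex, year, key),
#'   `genotypes` (data.frame key, allele_id),
#'   `catalogue` (allele data.frame with allele_id, protein_id),
#'   `summary` (list of cohort statistics).
#' @export
call_genotypes <- function(profiles, metadata, threshold = 0.01,
                           exclude_sequences = NULL) {
  stopifnot(length(profiles) > 0)
  filtered <- lapply(profiles, function(p) {
    if (!is.null(exclude_sequences)) {
      drop <- names(p$counts) %in% exclude_sequences
      if (any(drop)) {
        pkg_log("INFO", p$individual_id, ": excluding ", sum(drop),
                " sequence(s) from external exclusion list")
        p$counts <- p$counts[!drop]
        if (!length(p$counts))
          stop("all sequences excluded for individual ", p$individual_id)
      }
    }
    filter_low_frequency(p, threshold)
  })

  all_seqs <- sort(unique(unlist(lapply(filtered, function(p) names(p$counts)))))
  aligned <- .place_indel_gap(all_seqs)
  tt <- trim_and_translate(setNames(aligned, paste0("s", seq_along(aligned))))
  cat_df <- tt$alleles
  if (!nrow(cat_df)) stop("no valid alleles in any profile")
  cat_df <- cat_df[order(cat_df$dna_aligned), , drop = FALSE]
  cat_df$allele_id <- sprintf("A%04d", seq_len(nrow(cat_df)))
  prot_sorted <- sort(unique(cat_df$protein_aligned))
  cat_df$protein_id <- sprintf("P%04d", match(cat_df$protein_aligned, prot_sorted))
  rownames(cat_df) <- NULL
  seq2allele <- setNames(cat_df$allele_id, cat_df$dna)
  rejected_seqs <- setdiff(gsub("-", "", all_seqs), cat_df$dna)

  md_key <- paste(metadata$individual, metadata$year, sep = "@")
  geno <- list(); ind_rows <- list()
  for (p in filtered) {
    key <- paste(p$individual_id, p$year, sep = "@")
    seqs <- setdiff(names(p$counts), rejected_seqs)
    ids <- unname(seq2allele[seqs])
    ids <- ids[!is.na(ids)]
    if (!length(ids))
      stop("individual ", p$individual_id, " has zero valid alleles")
    i <- match(key, md_key)
    sex <- if (is.na(i)) NA_character_ else as.character(metadata$sex[i])
    ind_rows[[length(ind_rows) + 1L]] <- data.frame(
      individual = p$individual_id, sex = sex, year = p$year, key = key)
    geno[[length(geno) + 1L]] <- data.frame(key = key, allele_id = sort(ids))
  }
  individuals <- do.call(rbind, ind_rows)
  genotypes <- do.call(rbind, geno)

  per_sample <- tapply(genotypes$allele_id, genotypes$key, length)
  per_sample <- per_sample[individuals$key]
  n_by_ind <- tapply(per_sample, individuals$individual, mean)
  sem <- function(x) sd(x) / sqrt(length(x))
  summary <- list(
    n_unique_alleles = nrow(cat_df),
    n_protein_leaves = length(prot_sorted),
    n_samples = nrow(individuals),
    n_individuals = length(unique(individuals$individual)),
    mean_alleles_per_sample = mean(per_sample),
    sem_alleles_per_sample = sem(as.numeric(per_sample)),
    mean_alleles_per_individual = mean(n_by_ind),
    sem_alleles_per_individual = sem(as.numeric(n_by_ind)))
  pkg_log("INFO", "called ", summary$n_unique_alleles, " unique alleles (",
          summary$n_protein_leaves, " protein leaves) across ",
          summary$n_samples, " samples; mean ",
          sprintf("%.2f", summary$mean_alleles_per_sample),
          " alleles/sample")
  structure(list(individuals = individuals, genotypes = genotypes,
                 catalogue = cat_df, summary = summary),
            class = "repertoire_set")
}

#' Protein-leaf membership of each sample
#'
#' @param rs a `repertoire_set`.
#' @return named list: sample key -> character vector of protein leaf ids.
#' @export
protein_leaves <- function(rs) {
  stopifnot(inherits(rs, "repertoire_set"))
  a2p <- setNames(rs$catalogue$protein_id, rs$catalogue$allele_id)
  sp <- split(unname(a2p[rs$genotypes$allele_id]), rs$genotypes$key)
  lapply(sp, unique)[rs$individuals$key]
}

#' @export
print.repertoire_set <- function(x, ...) {
  s <- x$summary
  cat("repertoire_set:", s$n_samples, "samples /", s$n_individuals,
      "individuals;", s$n_unique_alleles, "DNA alleles,",
      s$n_protein_leaves, "protein leaves\n")
  cat(sprintf("  alleles per sample: %.2f +/- %.2f (SEM)\n",
              s$mean_alleles_per_sample, s$sem_alleles_per_sample))
  invisible(x)
}

#' Assemble read profiles from a read-count table and a sequence FASTA
#'
#' Joins the long-format read-count table (individual, sequence_id, count,
#' optional year) with the sequences named by `sequence_id`, yielding one
#' [read_profile()] per individual (per year when a year column is present).
#'
#' @param reads data.frame from [read_table_checked()] with schema
#'   `"read_counts"`.
#' @param sequences named character vector mapping sequence_id to DNA.
#' @param metadata data.frame with columns individual, sex, year (used to
#'   fill the year when the reads table lacks one).
#' @return list of `read_profile` objects.
#' @export
profiles_from_tables <- function(reads, sequences, metadata = NULL) {
  stopifnot(all(c("individual", "sequence_id", "count") %in% names(reads)))
  missing <- setdiff(unique(reads$sequence_id), names(sequences))
  if (length(missing))
    stop("sequence_id(s) missing from FASTA: ",
         paste(head(missing, 5), collapse = ", "))
  if (!"year" %in% names(reads)) {
    if (is.null(metadata))
      stop("reads table has no year column and no metadata was supplied")
    reads$year <- metadata$year[match(reads$individual, metadata$individual)]
  }
  out <- list()
  for (key in unique(paste(reads$individual, reads$year, sep = "@"))) {
    sel <- paste(reads$individual, reads$year, sep = "@") == key
    counts <- tapply(reads$count[sel],
                     unname(sequences[reads$sequence_id[sel]]), sum)
    out[[length(out) + 1L]] <- read_profile(
      sub("@.*$", "", key), setNames(as.numeric(counts), names(counts)),
      year = reads$year[sel][1])
  }
  out
}
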