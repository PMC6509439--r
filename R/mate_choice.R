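# Monte-Carlo randomized-pairing test of nonrandom mating at MHC.

#' Randomized-pairing test of nonrandom mating
#'
#' Compares the mean UniFrac distance of observed social pairs against the
#' distribution of replicate means under year-stratified random pairing: in
#' each replicate, every observed pair's female is assigned a male drawn
#' uniformly without replacement from the males available in her year
#' (`frame = "all_adults"`: every male captured that year;
#' `frame = "paired_only"`: only males that appear in observed pairs).
#' The two-tailed p-value uses the add-one permutation convention,
#' `p = 2 min((#{<= obs}+1)/(B+1), (#{>= obs}+1)/(B+1))`, capped at 1.
#'
#' @param rs a `repertoire_set`.
#' @param pairs data.frame with columns male_id, female_id, year.
#' @param tree rooted reference tree over protein leaves; built with
#'   [reference_tree()] when `NULL`.
#' @param B number of Monte-Carlo replicates.
#' @param seed RNG seed.
#' @param frame sampling frame for replicate males.
#' @param dist_matrix optional precomputed [pairwise_distance_table()] result
#'   (reused across repeated tests on one cohort).
#' @return object of class `pairing_null`: observed_mean, replicate_means,
#'   p_two_tailed, B, seed, null_mean, null_sem, per_pair (observed pair
#'   distances), pair_distance_pool (all anchor-female x candidate-male
#'   distances, the support of the single-pair null, for plotting).
#' @export
random_pairing_test <- function(rs, pairs, tree = NULL, B = 10000L,
                                seed = 1L,
                                frame = c("all_adults", "paired_only"),
                                dist_matrix = NULL) {
  stopifnot(inherits(rs, "repertoire_set"), B >= 1L)
  frame <- match.arg(frame)
  req <- c("male_id", "female_id", "year")
  if (!all(req %in% names(pairs)))
    stop("pairs table must have columns: ", paste(req, collapse = ", "))

  dup <- duplicated(pairs[, c("male_id", "female_id")])
  if (any(dup))
    warning(sum(dup), " male-female pair(s) recur across years; ",
            "keep one year only to avoid pseudoreplication")

  ind <- rs$individuals
  if (is.null(tree)) tree <- reference_tree(rs)
  D <- if (is.null(dist_matrix)) pairwise_distance_table(tree, rs) else
    dist_matrix

  key_of <- function(id, year) {
    k <- paste(id, year, sep = "@")
    miss <- !(k %in% ind$key)
    if (any(miss))
      stop("pair references unknown individual(s): ",
           paste(unique(id[miss]), collapse = ", "))
    k
  }
  fkey <- key_of(pairs$female_id, pairs$year)
  mkey <- key_of(pairs$male_id, pairs$year)
  sex_of <- setNames(ind$sex, ind$key)
  if (any(!is.na(sex_of[mkey]) & sex_of[mkey] != "male"))
    stop("male_id column contains non-male individual(s)")
  if (any(!is.na(sex_of[fkey]) & sex_of[fkey] != "female"))
    stop("female_id column contains non-female individual(s)")

  per_pair <- D[cbind(fkey, mkey)]
  observed_mean <- mean(per_pair)
  n_total <- length(per_pair)

  years <- sort(unique(pairs$year))
  set.seed(as.integer(seed))
  rep_sums <- numeric(B)
  pool_distances <- list()
  for (y in years) {
    sel <- pairs$year == y
    anchors <- fkey[sel]
    males_pool <- if (frame == "all_adults")
      ind$key[ind$sex == "male" & ind$year == y & !is.na(ind$sex)]
    else unique(mkey[sel])
    np <- length(anchors)
    if (np > length(males_pool))
      stop("year ", y, ": ", np, " observed pairs but only ",
           length(males_pool), " available males")
    Dy <- D[anchors, males_pool, drop = FALSE]
    pool_distances[[as.character(y)]] <- as.vector(Dy)
    idx <- vapply(seq_len(B),
                  function(b) sample.int(length(males_pool), np),
                  integer(np))
    if (np == 1L) idx <- matrix(idx, nrow = 1L)
    vals <- Dy[cbind(rep(seq_len(np), B), as.vector(idx))]
    rep_sums <- rep_sums + colSums(matrix(vals, nrow = np))
  }
  replicate_means <- rep_sums / n_total
  lo <- (sum(replicate_means <= observed_mean) + 1) / (B + 1)
  hi <- (sum(replicate_means >= observed_mean) + 1) / (B + 1)
  p <- min(1, 2 * min(lo, hi))
  structure(list(observed_mean = observed_mean,
                 replicate_means = replicate_means,
                 p_two_tailed = p,
                 B = as.integer(B), seed = as.integer(seed),
                 frame = frame,
                 null_mean = mean(replicate_means),
                 null_sem = sd(replicate_means) / sqrt(B),
                 per_pair = setNames(per_pair, paste(fkey, mkey, sep = "x")),
                 pair_distance_pool = unlist(pool_distances, use.names = FALSE)),
            class = "pairing_null")
}

#' @export
print.pairing_null <- function(x, ...) {
  cat(sprintf(paste0("randomized-pairing test (B = %d, frame = %s):\n",
                     "  observed mean = %.4f, null mean = %.4f +/- %.4f (SEM)\n",
                     "  two-tailed p = %.4g\n"),
              x$B, x$frame, x$observed_mean, x$null_mean, x$null_sem,
              x$p_two_tailed))
  invisible(x)
}
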