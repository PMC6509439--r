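#' @importFrom stats sd setNames rbinom rexp runif rnorm pnorm pbinom binom.test
#'   quantile rmultinom as.dist
#' @importFrom utils read.delim write.table combn head
NULL

# package-wide log level ordering
.LOG_LEVELS <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)

.pkg_env <- new.env(parent = emptyenv())
.pkg_env$log_level <- "INFO"
.pkg_env$log_file <- NULL

#' Configure pipeline logging
#'
#' Messages are timestamped, level-tagged and written to `stderr()` and,
#' optionally, appended to a file. Filtering steps throughout the package log
#' counts in and out at level `"INFO"`.
#'
#' @param level minimum level to emit: `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @param file optional path; log lines are appended there as well.
#' @return invisibly, the previous settings.
#' @export
set_log <- function(level = "INFO", file = NULL) {
  level <- match.arg(level, names(.LOG_LEVELS))
  old <- list(level = .pkg_env$log_level, file = .pkg_env$log_file)
  .pkg_env$log_level <- level
  .pkg_env$log_file <- file
  invisible(old)
}

#' Emit a log line
#'
#' @param level one of `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @param ... pieces pasted into the message.
#' @return invisibly, the formatted line (or `NULL` if below the level).
#' @export
pkg_log <- function(level, ...) {
  level <- match.arg(level, names(.LOG_LEVELS))
  if (.LOG_LEVELS[level] < .LOG_LEVELS[.pkg_env$log_level]) return(invisible(NULL))
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(..., collapse = ""))
  cat(line, "\n", file = stderr())
  if (!is.null(.pkg_env$log_file))
    cat(line, "\n", file = .pkg_env$log_file, append = TRUE)
  invisible(line)
}

#' Run configuration
#'
#' Bundles the tunable constants of the pipeline: the RNG seed, the number of
#' Monte-Carlo pairings, the per-individual read-frequency filter, the
#' trans-species identity threshold, bootstrap replicate counts and the
#' per-site test level. All fractions must lie in (0, 1) and all counts be at
#' least 1.
#'
#' @param seed integer RNG seed.
#' @param n_permutations randomized pairings for the mate-choice null.
#' @param read_filter_threshold per-individual read-frequency cutoff; a
#'   sequence is kept when `count/total >= threshold`.
#' @param identity_threshold minimum DNA identity for a heterospecific match.
#' @param bootstrap_reps_tree column-bootstrap replicates for tree support.
#' @param bootstrap_reps_ztest bootstrap replicates for the overall Z-test.
#' @param site_test_alpha significance level of the per-codon test.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1L,
                       n_permutations = 10000L,
                       read_filter_threshold = 0.01,
                       identity_threshold = 0.94,
                       bootstrap_reps_tree = 500L,
                       bootstrap_reps_ztest = 500L,
                       site_test_alpha = 0.10) {
  cfg <- list(seed = as.integer(seed),
              n_permutations = as.integer(n_permutations),
              read_filter_threshold = as.numeric(read_filter_threshold),
              identity_threshold = as.numeric(identity_threshold),
              bootstrap_reps_tree = as.integer(bootstrap_reps_tree),
              bootstrap_reps_ztest = as.integer(bootstrap_reps_ztest),
              site_test_alpha = as.numeric(site_test_alpha))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  fr <- c("read_filter_threshold", "identity_threshold", "site_test_alpha")
  for (f in fr)
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("run_config: '", f, "' must lie in (0, 1), got ", cfg[[f]])
  ct <- c("n_permutations", "bootstrap_reps_tree", "bootstrap_reps_ztest")
  for (f in ct)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("run_config: '", f, "' must be a count >= 1, got ", cfg[[f]])
  if (is.na(cfg$seed)) stop("run_config: 'seed' must be an integer")
  invisible(cfg)
}

#' Read / write a run configuration
#'
#' The on-disk form is a flat YAML key-value file; the round trip is lossless.
#'
#' @param path file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that enforces the pipeline
#' contracts: ids unique, sequences uppercased, record order preserved. The id
#' is the first whitespace-delimited token of the header; the full header is
#' kept in the `"header"` attribute.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences, names = ids.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  attr(seqs, "header") <- headers
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (names become headers).
#' @param path output path.
#' @param width line width for wrapping.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    cat(paste0(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               collapse = "\n"), "\n", sep = "", file = con)
  }
  invisible(path)
}

#' Read a single Newick tree
#'
#' Wraps [ape::read.tree()] with stricter diagnostics: unbalanced parentheses
#' are reported with the offending position, leaf labels must be unique, and
#' missing branch lengths are set to zero with a logged warning.
#'
#' @param path Newick file containing one tree.
#' @return an [ape::phylo] object with `edge.length` always present.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i, " in ", path)
    }
  }
  if (depth != 0L)
    stop("unbalanced '(' in ", path, ": ", depth, " unclosed at end of input")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree in ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    pkg_log("WARN", "tree in ", path, " has no branch lengths; using 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    pkg_log("WARN", "missing branch lengths in ", path, " set to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

# column schemas of the delimited tables the pipeline consumes
.TABLE_SCHEMAS <- list(
  read_counts = list(required = c("individual", "sequence_id", "count"),
                     numeric = "count"),
  pairs = list(required = c("male_id", "female_id", "year"), numeric = NULL),
  metadata = list(required = c("individual", "sex", "year"), numeric = NULL),
  genotypes = list(required = c("individual", "allele_id"), numeric = NULL),
  model_fits = list(required = c("name", "lnL", "k"), numeric = c("lnL", "k"))
)

#' Read a typed TSV table
#'
#' @param path tab-delimited file with a header row.
#' @param schema one of `"read_counts"` (individual, sequence_id, count),
#'   `"pairs"` (male_id, female_id, year), `"metadata"` (individual, sex,
#'   year), `"genotypes"` (individual, allele_id), `"model_fits"`
#'   (name, lnL, k). Unknown extra columns are kept with a logged warning;
#'   a missing required column is an error naming it.
#' @return a data.frame.
#' @export
read_table_checked <- function(path, schema) {
  schema <- match.arg(schema, names(.TABLE_SCHEMAS))
  sc <- .TABLE_SCHEMAS[[schema]]
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(sc$required, names(df))
  if (length(missing))
    stop("table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), sc$required)
  if (length(extra))
    pkg_log("WARN", "table ", path, ": ignoring extra column(s) ",
            paste(extra, collapse = ", "))
  for (cl in sc$numeric) {
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(df[[cl]])) stop("column '", cl, "' in ", path, " is not numeric")
  }
  if (schema == "read_counts" && any(df$count < 0))
    stop("column 'count' in ", path, " contains negative values")
  if (schema == "model_fits" && any(df$k <= 0))
    stop("column 'k' in ", path, " must be positive")
  df
}

#' Write a symmetric distance matrix as square TSV
#'
#' @param dm square numeric matrix with row/col names.
#' @param path output path.
#' @export
write_distance_tsv <- function(dm, path) {
  stopifnot(is.matrix(dm), !is.null(rownames(dm)))
  df <- data.frame(id = rownames(dm), dm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
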