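# Readers and writers for the plain-text formats the pipeline touches:
# FASTA, the 12-column tabular hit dialect, newick trees, TSV report tables
# and a YAML run configuration.

#' Read a FASTA file into a sequence table
#'
#' Record ids are the first whitespace-delimited token of each header; the
#' remainder of the header is kept as the description. Duplicate ids are a
#' hard error.
#'
#' @param path Path to an existing FASTA file.
#' @param alphabet Forced alphabet, or `NULL` to guess per record.
#' @return A sequence table (see [seq_tbl()]), in file order.
#' @export
read_fasta <- function(path, alphabet = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)))
  )
  if (length(set) == 0L) abort(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), str_trim(sub("^\\S+\\s+", "", headers)), "")
  seq_tbl(id, as.character(set), description = desc, alphabet = alphabet)
}

#' Write a sequence table to FASTA
#'
#' @param seqs A sequence table.
#' @param path Output path.
#' @param width Line width for wrapped sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  .assert_seq_tbl(seqs)
  set <- Biostrings::BStringSet(seqs$seq)
  names(set) <- ifelse(nzchar(seqs$description),
                       paste(seqs$id, seqs$description), seqs$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

.hit_cols <- c("query_id", "subject_id", "identity", "length", "mismatches",
               "gap_opens", "qstart", "qend", "sstart", "send",
               "evalue", "bitscore")

#' Read similarity-search hits in the standard 12-column tabular dialect
#'
#' Columns: query, subject, percent identity, alignment length, mismatches,
#' gap opens, query start/end, subject start/end, e-value, bit score. Lines
#' with extra columns raise a warning and the extras are ignored; lines with
#' fewer than 12 columns, unparseable numeric fields, or identities outside
#' \[0, 100\] are errors that name the offending line.
#'
#' @param path Path to a tab-separated hit file.
#' @return A tibble of hits, one row per line.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort(sprintf("empty hit file: %s", path))
  fields <- str_split(lines, "\t")
  n_col <- lengths(fields)
  if (any(n_col < 12L)) {
    bad <- which(n_col < 12L)[1]
    abort(sprintf("line %d of %s has %d columns; 12 required", bad, path, n_col[bad]))
  }
  if (any(n_col > 12L)) {
    warn(sprintf("%s: %d line(s) carry more than 12 columns; extras ignored",
                 path, sum(n_col > 12L)))
    fields <- map(fields, ~ .x[1:12])
  }
  m <- do.call(rbind, fields)
  hits <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    identity = suppressWarnings(as.numeric(m[, 3])),
    length = suppressWarnings(as.integer(m[, 4])),
    mismatches = suppressWarnings(as.integer(m[, 5])),
    gap_opens = suppressWarnings(as.integer(m[, 6])),
    qstart = suppressWarnings(as.integer(m[, 7])),
    qend = suppressWarnings(as.integer(m[, 8])),
    sstart = suppressWarnings(as.integer(m[, 9])),
    send = suppressWarnings(as.integer(m[, 10])),
    evalue = suppressWarnings(as.numeric(m[, 11])),
    bitscore = suppressWarnings(as.numeric(m[, 12]))
  )
  num_na <- which(!stats::complete.cases(hits[, 3:12]))
  if (length(num_na)) {
    abort(sprintf("line %d of %s has an unparseable numeric field", num_na[1], path))
  }
  bad_ident <- which(hits$identity < 0 | hits$identity > 100)
  if (length(bad_ident)) {
    abort(sprintf("line %d of %s: identity %.2f outside [0, 100]",
                  bad_ident[1], path, hits$identity[bad_ident[1]]))
  }
  hits
}

#' Write hits in the 12-column tabular dialect
#'
#' @param hits A hit tibble with the columns produced by [read_tabular_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  missing <- setdiff(.hit_cols, names(hits))
  if (length(missing)) abort(sprintf("hits lack column(s): %s", .oxford(missing)))
  out <- hits[, .hit_cols]
  out$identity <- sprintf("%.2f", out$identity)
  out$evalue <- format(out$evalue, scientific = TRUE, digits = 3)
  out$bitscore <- sprintf("%.1f", out$bitscore)
  lines <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a cluster tree to newick
#'
#' @param tree A rooted tree of class `phylo` (e.g. from [upgma()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo object")
  if (ape::Ntip(tree) < 2L) abort("tree must have at least 2 leaves")
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label) | !nzchar(tree$tip.label))) {
    abort("all leaves must be labelled")
  }
  if (is.null(tree$edge.length)) abort("tree must carry branch lengths")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#'
#' @param path Path to a newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(sprintf("malformed newick in %s", path))
  tree
}

#' Write a tab-separated report table
#'
#' All report tables the pipeline emits are UTF-8 TSV with a single header
#' row, so outputs diff cleanly across runs.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path Path to a TSV file with one header row.
#' @return A tibble.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                              check.names = FALSE))
}

#' Run configuration
#'
#' Bundles the thresholds and knobs shared across the pipeline. Defaults
#' follow the analysis this package reproduces: e-value cutoff 1e-05 for all
#' similarity searches, five 5-point identity bands from 75 to 100 percent,
#' a strict >98 percent strain-identity cutoff, and Spearman correlation for
#' profile comparison.
#'
#' @param evalue_max Maximum e-value for any accepted hit (> 0).
#' @param correlation_method `"spearman"` or `"pearson"`.
#' @param contig_order `"ascending"` or `"descending"` contig length order
#'   when concatenating pseudogenomes.
#' @param identity_bands List of `c(lo, hi)` percent intervals; must be
#'   ordered, non-overlapping and within \[0, 100\].
#' @param strain_identity_cutoff Percent identity above which a recruited
#'   read counts as strain-level (strict inequality).
#' @param min_orf_codons Minimum open reading frame length, in codons.
#' @param gc_window_bp,gc_step_bp Window and step for GC tracks (window >=
#'   step > 0).
#' @param seed Integer seed for every stochastic operation.
#' @return A `run_config` list.
#' @export
run_config <- function(evalue_max = 1e-05,
                       correlation_method = c("spearman", "pearson"),
                       contig_order = c("ascending", "descending"),
                       identity_bands = list(c(95, 100), c(90, 95), c(85, 90),
                                             c(80, 85), c(75, 80)),
                       strain_identity_cutoff = 98,
                       min_orf_codons = 60L,
                       gc_window_bp = 10000L,
                       gc_step_bp = 1000L,
                       seed = 1L) {
  assert_scalar_number(evalue_max, "evalue_max")
  if (evalue_max <= 0) abort("`evalue_max` must be > 0")
  correlation_method <- match.arg(correlation_method)
  contig_order <- match.arg(contig_order)
  .validate_bands(identity_bands)
  assert_scalar_number(strain_identity_cutoff, "strain_identity_cutoff", 0, 100)
  assert_scalar_number(min_orf_codons, "min_orf_codons", 1)
  assert_scalar_number(gc_window_bp, "gc_window_bp", 1)
  assert_scalar_number(gc_step_bp, "gc_step_bp", 1)
  if (gc_window_bp < gc_step_bp) abort("`gc_window_bp` must be >= `gc_step_bp`")
  assert_scalar_number(seed, "seed")
  structure(
    list(evalue_max = evalue_max, correlation_method = correlation_method,
         contig_order = contig_order, identity_bands = identity_bands,
         strain_identity_cutoff = strain_identity_cutoff,
         min_orf_codons = as.integer(min_orf_codons),
         gc_window_bp = as.integer(gc_window_bp),
         gc_step_bp = as.integer(gc_step_bp), seed = as.integer(seed)),
    class = "run_config"
  )
}

.validate_bands <- function(bands) {
  if (!is.list(bands) || !length(bands)) abort("`identity_bands` must be a non-empty list")
  m <- do.call(rbind, bands)
  if (ncol(m) != 2 || any(m < 0 | m > 100) || any(m[, 1] >= m[, 2])) {
    abort("each identity band must be c(lo, hi) with 0 <= lo < hi <= 100")
  }
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  if (any(m[-1, 1] < m[-nrow(m), 2])) abort("identity bands must not overlap")
  invisible(bands)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  bands <- paste(map_chr(x$identity_bands, ~ sprintf("%g-%g", .x[1], .x[2])),
                 collapse = ", ")
  cat(sprintf("  evalue_max: %g | correlation: %s | contig order: %s\n",
              x$evalue_max, x$correlation_method, x$contig_order))
  cat(sprintf("  identity bands: %s | strain cutoff: >%g%%\n", bands,
              x$strain_identity_cutoff))
  cat(sprintf("  min ORF codons: %d | GC window/step: %d/%d | seed: %d\n",
              x$min_orf_codons, x$gc_window_bp, x$gc_step_bp, x$seed))
  invisible(x)
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()] object.
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   returns a validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- yaml::read_yaml(path)
  raw$identity_bands <- map(raw$identity_bands, unlist)
  do.call(run_config, raw)
}
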