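# Sequence tables: the package represents sequence sets as tibbles with one
# row per record (columns id, description, seq, alphabet) so they compose with
# dplyr verbs; Biostrings does the heavy lifting underneath.

.nt_chars <- c("A", "C", "G", "T", "U", "N")
.aa_chars <- strsplit("ACDEFGHIKLMNPQRSTVWYBXZJUO*", "")[[1]]

guess_alphabet <- function(seq) {
  chars <- unique(strsplit(str_to_upper(seq), "")[[1]])
  if (all(chars %in% .nt_chars)) "nucleotide" else "protein"
}

#' Build a sequence table
#'
#' @param id Character vector of unique, non-empty record identifiers.
#' @param seq Character vector of sequences (upper-cased on input).
#' @param description Optional free-text descriptions (default `""`).
#' @param alphabet `"nucleotide"`, `"protein"`, or `NULL` to guess per record.
#'   A sequence over `{A,C,G,T,U,N}` only is called nucleotide.
#'
#' @return A tibble with columns `id`, `description`, `seq`, `alphabet`.
#' @export
#'
#' @examples
#' seq_tbl(c("a", "b"), c("ACGT", "MKV"))
seq_tbl <- function(id, seq, description = "", alphabet = NULL) {
  id <- as.character(id)
  seq <- str_to_upper(as.character(seq))
  if (length(id) != length(seq)) abort("`id` and `seq` must have equal length")
  if (any(!nzchar(id))) abort("sequence ids must be non-empty")
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    abort(sprintf("duplicate sequence id(s): %s", .oxford(dup)))
  }
  if (any(!nzchar(seq))) {
    abort(sprintf("empty sequence(s): %s", .oxford(id[!nzchar(seq)])))
  }
  if (is.null(alphabet)) {
    alphabet <- map_chr(seq, guess_alphabet)
  } else {
    alphabet <- match.arg(alphabet, c("nucleotide", "protein"))
    alphabet <- rep(alphabet, length(seq))
  }
  tibble(
    id = id,
    description = rep_len(as.character(description), length(id)),
    seq = seq,
    alphabet = alphabet
  )
}

.assert_seq_tbl <- function(x, alphabet = NULL, arg = "sequences") {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort(sprintf("`%s` must be a sequence table with columns id and seq", arg))
  }
  if (!is.null(alphabet) && "alphabet" %in% names(x)) {
    bad <- x$id[x$alphabet != alphabet]
    if (length(bad)) {
      abort(sprintf("`%s` must be %s; offending id(s): %s",
                    arg, alphabet, .oxford(bad)))
    }
  }
  invisible(x)
}

#' Reverse-complement nucleotide sequences
#'
#' @param seqs A sequence table ([seq_tbl()]) of nucleotide records.
#' @return The table with each `seq` reverse-complemented.
#' @export
revcomp <- function(seqs) {
  .assert_seq_tbl(seqs, "nucleotide")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs$seq)
  ))
  mutate(seqs, seq = unname(rc))
}

#' GC content of sequences
#'
#' GC is computed as (G + C) / (A + C + G + T); ambiguous bases are excluded
#' from the denominator. A sequence with no unambiguous base is an error.
#'
#' @param seqs A nucleotide sequence table.
#' @return The input with a `gc_percent` column appended (0-100 scale).
#' @export
#'
#' @examples
#' gc_content(seq_tbl("x", "ATGC"))$gc_percent # 50
gc_content <- function(seqs) {
  .assert_seq_tbl(seqs, "nucleotide")
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs$seq))
  gc <- counts[, "G", drop = TRUE] + counts[, "C", drop = TRUE]
  acgt <- gc + counts[, "A", drop = TRUE] + counts[, "T", drop = TRUE]
  if (any(acgt == 0)) {
    abort(sprintf("sequence(s) with no unambiguous base: %s",
                  .oxford(seqs$id[acgt == 0])))
  }
  mutate(seqs, gc_percent = unname(100 * gc / acgt))
}
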