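# Desk-scale top-hit similarity search: k-mer seeding to locate candidate
# subjects and diagonals, then Smith-Waterman local alignment (Biostrings)
# restricted to the seeded window. The e-value follows the standard
# extreme-value form E = m * n * 2^-bit with nominal Karlin-Altschul style
# parameters, computed for the database size actually indexed, so the 1e-05
# acceptance threshold keeps its meaning at fixture scale. Externally
# computed hits in the 12-column tabular dialect can replace this engine
# wholesale via read_tabular_hits().

.ka_params <- list(
  nucleotide = list(lambda = log(3), K = 1 / 3),   # match +1 / mismatch -1
  protein    = list(lambda = 0.267, K = 0.041)     # BLOSUM62, affine 11/1
)

.kmers <- function(seq, k) {
  l <- nchar(seq)
  if (l < k) return(character(0))
  str_sub(seq, 1:(l - k + 1L), k:l)
}

#' Build a k-mer search index
#'
#' @param references A sequence table of uniform alphabet.
#' @param taxonomy Optional tibble (`genome_id`, `genus`, `superkingdom`)
#'   used to decorate hits; reference ids absent from it resolve to
#'   `"Unknown"`.
#' @param k Seed length: 4-16 for nucleotide, 3-6 for protein references.
#' @return A `search_index` object. The index is identical whatever the
#'   input order of the references.
#' @export
build_index <- function(references, taxonomy = NULL, k = NULL) {
  .assert_seq_tbl(references, NULL, "references")
  if (!nrow(references)) abort("reference set is empty")
  alph <- unique(references$alphabet %||% map_chr(references$seq, guess_alphabet))
  if (length(alph) != 1L) abort("references mix nucleotide and protein records")
  k <- k %||% if (alph == "nucleotide") 11L else 4L
  if (alph == "nucleotide" && (k < 4 || k > 16)) abort("nucleotide k must be in [4, 16]")
  if (alph == "protein" && (k < 3 || k > 6)) abort("protein k must be in [3, 6]")
  refs <- arrange(references, .data$id)
  seed_tbl <- list_rbind(map(seq_len(nrow(refs)), function(i) {
    km <- .kmers(refs$seq[i], k)
    if (!length(km)) return(NULL)
    tibble(kmer = km, ref = i, pos = seq_along(km))
  }))
  kmap <- split(seed_tbl[, c("ref", "pos")], seed_tbl$kmer)
  structure(
    list(refs = refs, taxonomy = taxonomy, k = as.integer(k),
         alphabet = alph, kmap = kmap,
         db_size = sum(nchar(refs$seq))),
    class = "search_index"
  )
}

#' @export
print.search_index <- function(x, ...) {
  cat(sprintf("<search_index> %d %s reference(s), %s residues, k = %d\n",
              nrow(x$refs), x$alphabet, format(x$db_size, big.mark = ","), x$k))
  invisible(x)
}

.subst_matrix <- function(alphabet) {
  if (alphabet == "nucleotide") {
    Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                             baseOnly = FALSE, type = "DNA")
  } else {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  }
}

.gap_params <- function(alphabet) {
  if (alphabet == "nucleotide") list(open = 1, ext = 1) else list(open = 10, ext = 1)
}

# Seed the query against the index; returns per (ref, diagonal-cluster)
# candidates ordered by seed support.
.seed_candidates <- function(qseq, index, band = 16L) {
  km <- .kmers(qseq, index$k)
  if (!length(km)) return(NULL)
  found <- index$kmap[unique(km)]
  found <- found[!map_lgl_(found, is.null)]
  if (!length(found)) return(NULL)
  qpos <- split(seq_along(km), km)
  rows <- list_rbind(imap(found, function(tbl, kmer) {
    qp <- qpos[[kmer]]
    tibble(ref = rep(tbl$ref, each = length(qp)),
           diag = rep(tbl$pos, each = length(qp)) - rep(qp, times = nrow(tbl)))
  }))
  rows |>
    group_by(.data$ref) |>
    summarise(diag = .mode_diag(.data$diag, band), n_seeds = n()) |>
    arrange(desc(.data$n_seeds))
}

map_lgl_ <- function(x, f) vapply(x, f, logical(1))

# densest diagonal (centre of the band with most seeds)
.mode_diag <- function(diags, band) {
  tab <- table(diags)
  vals <- as.integer(names(tab))
  support <- map_dbl(vals, function(v) sum(tab[abs(vals - v) <= band]))
  vals[which.max(support)]
}

.align_window <- function(qseq, sseq, diag, alphabet, pad) {
  lq <- nchar(qseq)
  ls <- nchar(sseq)
  s_from <- max(1L, diag + 1L - pad)
  s_to <- min(ls, diag + lq + pad)
  window <- str_sub(sseq, s_from, s_to)
  gaps <- .gap_params(alphabet)
  str_cls <- if (alphabet == "nucleotide") Biostrings::DNAString else Biostrings::AAString
  pa <- Biostrings::pairwiseAlignment(
    str_cls(qseq), str_cls(window), type = "local",
    substitutionMatrix = .subst_matrix(alphabet),
    gapOpening = gaps$open, gapExtension = gaps$ext
  )
  aln_p <- as.character(Biostrings::pattern(pa))
  aln_s <- as.character(Biostrings::subject(pa))
  columns <- nchar(aln_p)
  matches <- Biostrings::nmatch(pa)
  mismatches <- Biostrings::nmismatch(pa)
  list(
    score = Biostrings::score(pa),
    matches = matches,
    mismatches = mismatches,
    columns = columns,
    gap_opens = str_count(aln_p, "-+") + str_count(aln_s, "-+"),
    qstart = Biostrings::start(Biostrings::pattern(pa)),
    qend = Biostrings::end(Biostrings::pattern(pa)),
    sstart = s_from - 1L + Biostrings::start(Biostrings::subject(pa)),
    send = s_from - 1L + Biostrings::end(Biostrings::subject(pa))
  )
}

.bit_score <- function(score, alphabet) {
  p <- .ka_params[[alphabet]]
  (p$lambda * score - log(p$K)) / log(2)
}

# Align one query (one orientation) against its seeded candidates.
.query_hits <- function(qid, qseq, index, evalue_max, max_targets, minus = FALSE) {
  cands <- .seed_candidates(qseq, index)
  if (is.null(cands) || !nrow(cands)) return(NULL)
  cands <- head(cands, max_targets)
  lq <- nchar(qseq)
  pad <- 30L + as.integer(0.1 * lq)
  rows <- map(seq_len(nrow(cands)), function(i) {
    ref_i <- cands$ref[i]
    aln <- .align_window(qseq, index$refs$seq[ref_i], cands$diag[i],
                         index$alphabet, pad)
    if (aln$columns == 0L) return(NULL)
    bit <- .bit_score(aln$score, index$alphabet)
    ev <- lq * index$db_size * 2^(-bit)
    if (ev > evalue_max) return(NULL)
    sstart <- aln$sstart
    send <- aln$send
    qstart <- aln$qstart
    qend <- aln$qend
    if (minus) {                      # report on the original query strand
      tmp <- qstart
      qstart <- lq - qend + 1L
      qend <- lq - tmp + 1L
      tmp <- sstart
      sstart <- send
      send <- tmp
    }
    tibble(
      query_id = qid, subject_id = index$refs$id[ref_i],
      identity = 100 * aln$matches / aln$columns,
      length = aln$columns, mismatches = aln$mismatches,
      gap_opens = aln$gap_opens,
      qstart = qstart, qend = qend, sstart = sstart, send = send,
      evalue = ev, bitscore = bit, score = aln$score
    )
  })
  list_rbind(rows)
}

#' Search queries against an index
#'
#' @param queries A sequence table whose alphabet matches the index.
#' @param index A [build_index()] result.
#' @param evalue_max Accept hits with e-value at or below this threshold.
#' @param mode `"top"` keeps the single best hit per query (ties broken by
#'   lower e-value then lexicographically smallest subject id);
#'   `"per_subject"` keeps the best hit per (query, subject) pair.
#' @param max_targets Cap on seeded candidate subjects examined per query.
#' @return A hit tibble in the 12-column layout plus `score` and (when a
#'   taxonomy is attached to the index) `subject_genus` and
#'   `subject_superkingdom`. Queries without an accepted hit are absent.
#' @export
search_hits <- function(queries, index, evalue_max = 1e-05,
                        mode = c("top", "per_subject"), max_targets = 25L) {
  .assert_seq_tbl(queries, NULL, "queries")
  stopifnot(inherits(index, "search_index"))
  mode <- match.arg(mode)
  qalph <- unique(queries$alphabet %||% map_chr(queries$seq, guess_alphabet))
  if (!all(qalph == index$alphabet)) {
    abort(sprintf("query alphabet (%s) does not match index (%s)",
                  paste(qalph, collapse = "/"), index$alphabet))
  }
  hits <- list_rbind(map(seq_len(nrow(queries)), function(i) {
    fwd <- .query_hits(queries$id[i], queries$seq[i], index, evalue_max,
                       max_targets)
    if (index$alphabet == "nucleotide") {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(queries$seq[i])
      ))
      rev <- .query_hits(queries$id[i], rc, index, evalue_max, max_targets,
                         minus = TRUE)
      fwd <- bind_rows(fwd, rev)
    }
    fwd
  }))
  if (is.null(hits) || !nrow(hits)) return(.empty_hits(index))
  hits <- hits |>
    arrange(.data$query_id, desc(.data$score), .data$evalue, .data$subject_id)
  hits <- if (mode == "top") {
    distinct(hits, .data$query_id, .keep_all = TRUE)
  } else {
    distinct(hits, .data$query_id, .data$subject_id, .keep_all = TRUE)
  }
  .attach_taxonomy(hits, index$taxonomy)
}

.empty_hits <- function(index = NULL) {
  out <- tibble(
    query_id = character(), subject_id = character(), identity = numeric(),
    length = integer(), mismatches = integer(), gap_opens = integer(),
    qstart = integer(), qend = integer(), sstart = integer(), send = integer(),
    evalue = numeric(), bitscore = numeric(), score = numeric()
  )
  if (!is.null(index) && !is.null(index$taxonomy)) {
    out$subject_genus <- character()
    out$subject_superkingdom <- character()
  }
  out
}

.attach_taxonomy <- function(hits, taxonomy) {
  if (is.null(taxonomy)) return(hits)
  tax <- taxonomy |>
    select(subject_id = "genome_id", subject_genus = "genus",
           subject_superkingdom = "superkingdom")
  hits |>
    left_join(tax, by = "subject_id") |>
    mutate(
      subject_genus = dplyr::coalesce(.data$subject_genus, "Unknown"),
      subject_superkingdom = dplyr::coalesce(.data$subject_superkingdom, "Unknown")
    )
}

#' Best hit for a single query
#'
#' @param query A single-row sequence table.
#' @inheritParams search_hits
#' @return A one-row hit tibble, or a zero-row tibble when no alignment
#'   attains the e-value threshold (absence of a hit is a value, not an
#'   error).
#' @export
top_hit <- function(query, index, evalue_max = 1e-05) {
  if (nrow(query) != 1L) abort("`query` must be a single record")
  search_hits(query, index, evalue_max, mode = "top")
}

#' Six-frame translation
#'
#' Translates frames +1..+3 and -1..-3 with the standard genetic code; stop
#' codons become `*`, ambiguous codons `X`. Sequences shorter than three
#' bases yield no frames.
#'
#' @param seqs A nucleotide sequence table.
#' @return A tibble with columns `id`, `frame` (+1..+3, -1..-3) and `seq`
#'   (protein).
#' @export
#'
#' @examples
#' six_frame_translate(seq_tbl("x", "ATGAAATAA"))
six_frame_translate <- function(seqs) {
  .assert_seq_tbl(seqs, "nucleotide")
  out <- list_rbind(map(seq_len(nrow(seqs)), function(i) {
    s <- seqs$seq[i]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    list_rbind(map(1:3, function(f) {
      frames <- list(`+` = str_sub(s, f), `-` = str_sub(rc, f))
      list_rbind(imap(frames, function(sub, strand) {
        n_cod <- nchar(sub) %/% 3L
        if (n_cod == 0L) return(NULL)
        prot <- .translate_str(str_sub(sub, 1L, n_cod * 3L))
        tibble(id = seqs$id[i],
               frame = if (strand == "+") f else -f,
               seq = prot)
      }))
    }))
  }))
  if (is.null(out) || !nrow(out)) {
    return(tibble(id = character(), frame = integer(), seq = character()))
  }
  arrange(out, .data$id, .data$frame)
}

.translate_str <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}
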