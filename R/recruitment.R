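# Fragment recruitment: concatenate draft-genome contigs into pseudogenomes
# with a single coordinate system, recruit each read to its best genome,
# band recruited reads by percent identity, summarise strain-level identity
# fractions and per-genome identity means, and emit windowed GC deviation
# tracks.

#' Concatenate contigs into a pseudogenome
#'
#' Contigs are sorted by length (ties by id) in the requested order and
#' concatenated; per-contig global offsets give a coordinate map in both
#' directions.
#'
#' @param contigs A nucleotide sequence table of the draft genome's contigs.
#' @param genome_id Identifier for the pseudogenome.
#' @param order `"ascending"` (default) or `"descending"` contig length
#'   order.
#' @return A `pseudogenome` list: `genome_id`, `contigs` (tibble
#'   `contig_id`, `length`, `offset`), `seq`, `total`, `order`.
#' @export
build_pseudogenome <- function(contigs, genome_id = "pseudogenome",
                               order = c("ascending", "descending")) {
  .assert_seq_tbl(contigs, "nucleotide", "contigs")
  if (!nrow(contigs)) abort("empty contig set")
  order <- match.arg(order)
  len <- nchar(contigs$seq)
  ord <- if (order == "ascending") base::order(len, contigs$id) else base::order(-len, contigs$id)
  contigs <- contigs[ord, ]
  len <- len[ord]
  offsets <- cumsum(c(0L, head(len, -1L)))
  structure(
    list(
      genome_id = genome_id,
      contigs = tibble(contig_id = contigs$id, length = len, offset = offsets),
      seq = paste(contigs$seq, collapse = ""),
      total = sum(len),
      order = order
    ),
    class = "pseudogenome"
  )
}

#' @export
print.pseudogenome <- function(x, ...) {
  cat(sprintf("<pseudogenome> %s: %d contig(s), %s bp, %s length order\n",
              x$genome_id, nrow(x$contigs), format(x$total, big.mark = ","),
              x$order))
  invisible(x)
}

#' Map pseudogenome coordinates to contigs and back
#'
#' Positions are 0-based; `pseudo_to_contig()` returns the contig owning
#' each global position and the local offset within it, and
#' `contig_to_pseudo()` inverts the map.
#'
#' @param pg A [build_pseudogenome()] result.
#' @param pos Integer vector of 0-based global positions.
#' @param contig_id,local Contig ids and 0-based local positions.
#' @return A tibble (`contig_id`, `local`) or an integer vector of global
#'   positions.
#' @export
pseudo_to_contig <- function(pg, pos) {
  stopifnot(inherits(pg, "pseudogenome"))
  if (any(pos < 0 | pos >= pg$total)) abort("position outside the pseudogenome")
  idx <- findInterval(pos, pg$contigs$offset)
  tibble(contig_id = pg$contigs$contig_id[idx],
         local = as.integer(pos - pg$contigs$offset[idx]))
}

#' @rdname pseudo_to_contig
#' @export
contig_to_pseudo <- function(pg, contig_id, local) {
  stopifnot(inherits(pg, "pseudogenome"))
  m <- match(contig_id, pg$contigs$contig_id)
  if (anyNA(m)) abort(sprintf("unknown contig id(s): %s", .oxford(contig_id[is.na(m)])))
  if (any(local < 0 | local >= pg$contigs$length[m])) abort("local position outside its contig")
  as.integer(pg$contigs$offset[m] + local)
}

.band_label <- function(lo, hi) sprintf("%g-%g", lo, hi)

# Band identities into half-open [lo, hi) intervals, topmost closed at its
# upper edge; identities below the lowest band go to "below-range".
.assign_bands <- function(identity, bands) {
  m <- do.call(rbind, bands)
  m <- m[base::order(m[, 1]), , drop = FALSE]
  labels <- .band_label(m[, 1], m[, 2])
  top <- nrow(m)
  out <- rep("below-range", length(identity))
  for (b in seq_len(top)) {
    sel <- identity >= m[b, 1] & (identity < m[b, 2] | (b == top & identity <= m[b, 2]))
    out[sel] <- labels[b]
  }
  factor(out, levels = c(rev(labels), "below-range"))
}

#' Recruit reads against a genome database
#'
#' Each read takes its single best accepted hit across the whole database
#' (pseudogenomes and/or plain genome records); reads with no hit are
#' excluded. The recruited global position (0-based, minimum of the aligned
#' subject range), percent identity and identity band are recorded, and
#' alignments spanning a contig junction inside a pseudogenome are flagged
#' rather than discarded.
#'
#' @param reads A nucleotide sequence table.
#' @param genomes A list of [build_pseudogenome()] objects and/or
#'   single-row sequence tables (treated as one-contig genomes).
#' @param config A [run_config()]; supplies `evalue_max`, `identity_bands`
#'   and the strain identity cutoff used by [band_summary()].
#' @return A `recruitment_result` list: `reads` (tibble `read_id`,
#'   `genome_id`, `position`, `identity`, `band`, `junction`), `genomes`
#'   (per-genome contig maps), `bands`, `cutoff`, `n_input_reads`.
#' @export
recruit_reads <- function(reads, genomes, config = run_config()) {
  .assert_seq_tbl(reads, "nucleotide", "reads")
  stopifnot(inherits(config, "run_config"))
  if (inherits(genomes, "pseudogenome") || is.data.frame(genomes)) {
    genomes <- list(genomes)
  }
  pgs <- map(genomes, function(g) {
    if (inherits(g, "pseudogenome")) return(g)
    .assert_seq_tbl(g, "nucleotide", "genomes")
    build_pseudogenome(g, genome_id = g$id[1], order = config$contig_order)
  })
  ids <- map_chr(pgs, "genome_id")
  if (anyDuplicated(ids)) abort("duplicate genome ids in the database")
  db <- seq_tbl(ids, map_chr(pgs, "seq"), alphabet = "nucleotide")
  idx <- build_index(db, k = 11L)
  hits <- search_hits(reads, idx, config$evalue_max, mode = "top")
  names(pgs) <- ids
  recruited <- if (nrow(hits)) {
    tmp <- hits |>
      mutate(
        position = pmin(.data$sstart, .data$send) - 1L,
        s_hi = pmax(.data$sstart, .data$send) - 1L,
        band = .assign_bands(.data$identity, config$identity_bands)
      )
    tmp$junction <- map_lgl_(seq_len(nrow(tmp)), function(r) {
      pg <- pgs[[tmp$subject_id[r]]]
      lo <- pseudo_to_contig(pg, tmp$position[r])$contig_id
      hi <- pseudo_to_contig(pg, tmp$s_hi[r])$contig_id
      lo != hi
    })
    select(tmp, read_id = "query_id", genome_id = "subject_id", "position",
           "identity", "band", "junction")
  } else {
    tibble(read_id = character(), genome_id = character(),
           position = integer(), identity = numeric(),
           band = factor(levels = levels(.assign_bands(numeric(0), config$identity_bands))),
           junction = logical())
  }
  structure(
    list(reads = recruited, genomes = pgs, bands = config$identity_bands,
         cutoff = config$strain_identity_cutoff, n_input_reads = nrow(reads)),
    class = "recruitment_result"
  )
}

#' @export
print.recruitment_result <- function(x, ...) {
  cat(sprintf("<recruitment_result> %d/%d reads recruited to %d genome(s)\n",
              nrow(x$reads), x$n_input_reads, length(x$genomes)))
  invisible(x)
}

#' @export
tidy.recruitment_result <- function(x, ...) x$reads

#' @export
glance.recruitment_result <- function(x, ...) {
  tibble(
    n_input_reads = x$n_input_reads,
    n_recruited = nrow(x$reads),
    n_genomes = length(x$genomes),
    mean_identity = if (nrow(x$reads)) mean(x$reads$identity) else NA_real_
  )
}

#' Per-genome identity band summary
#'
#' Counts recruited reads per identity band and per genome, with the total,
#' the count above the strain identity cutoff (strict `>`), and the
#' corresponding fraction. Identities below the lowest band fall into an
#' explicit below-range bucket, so band counts always sum to the total.
#'
#' @param result A [recruit_reads()] result.
#' @param cutoff Strain identity cutoff in percent (default: the cutoff in
#'   the result's configuration).
#' @return A tibble: `genome_id`, one count column per band (high to low),
#'   `below_range`, `total`, `n_above_cutoff`, `fraction_above_cutoff`.
#' @export
band_summary <- function(result, cutoff = NULL) {
  stopifnot(inherits(result, "recruitment_result"))
  cutoff <- cutoff %||% result$cutoff
  if (!nrow(result$reads)) abort("no recruited reads to summarise")
  counts <- result$reads |>
    group_by(.data$genome_id, .data$band, .drop = FALSE) |>
    summarise(n = n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "band", values_from = "n",
                       values_fill = 0L) |>
    rename(below_range = "below-range")
  extras <- result$reads |>
    group_by(.data$genome_id) |>
    summarise(total = n(),
              n_above_cutoff = sum(.data$identity > cutoff),
              fraction_above_cutoff = .data$n_above_cutoff / .data$total,
              .groups = "drop")
  counts |>
    inner_join(extras, by = "genome_id") |>
    filter(.data$total > 0) |>
    arrange(desc(.data$total))
}

#' Per-genome recruited identity summary
#'
#' Sample mean and standard deviation of recruited identities per genome,
#' restricted to genomes with more than `min_reads` recruited reads (strict
#' inequality: a genome with exactly `min_reads` reads is omitted).
#'
#' @param result A [recruit_reads()] result.
#' @param min_reads Minimum recruited read count (exclusive); default 100.
#' @return A tibble `genome_id`, `n_reads`, `mean_identity`, `sd_identity`.
#' @export
identity_summary <- function(result, min_reads = 100L) {
  stopifnot(inherits(result, "recruitment_result"))
  result$reads |>
    group_by(.data$genome_id) |>
    summarise(n_reads = n(),
              mean_identity = mean(.data$identity),
              sd_identity = sd(.data$identity),
              .groups = "drop") |>
    filter(.data$n_reads > min_reads) |>
    arrange(desc(.data$n_reads))
}

#' Windowed GC deviation track
#'
#' GC content in sliding windows minus the genome-wide mean GC. Windows
#' start every `step` bp and tile the pseudogenome; the final window may be
#' short so that the last window's end equals the total length.
#'
#' @param pg A [build_pseudogenome()] result.
#' @param window,step Window and step sizes in bp (`window >= step`).
#' @return A `gc_track` tibble: `genome_id`, `start`, `end` (0-based
#'   half-open), `gc_percent`, `deviation`.
#' @export
gc_track <- function(pg, window = 10000L, step = 1000L) {
  stopifnot(inherits(pg, "pseudogenome"))
  if (window < step) abort("`window` must be >= `step`")
  if (window > pg$total) abort("`window` exceeds the genome length")
  chars <- strsplit(pg$seq, "")[[1]]
  is_gc <- cumsum(chars %in% c("G", "C"))
  is_acgt <- cumsum(chars %in% c("A", "C", "G", "T"))
  starts <- seq(0L, pg$total - 1L, by = step)
  ends <- pmin(starts + window, pg$total)
  last <- which(ends == pg$total)[1]      # stop once the end is covered
  starts <- starts[seq_len(last)]; ends <- ends[seq_len(last)]
  gc_n <- is_gc[ends] - ifelse(starts == 0L, 0L, is_gc[starts])
  base_n <- is_acgt[ends] - ifelse(starts == 0L, 0L, is_acgt[starts])
  if (any(base_n == 0)) abort("window containing no unambiguous base")
  gc_pct <- 100 * gc_n / base_n
  mean_gc <- 100 * tail(is_gc, 1) / tail(is_acgt, 1)
  out <- tibble(genome_id = pg$genome_id, start = starts, end = ends,
                gc_percent = gc_pct, deviation = gc_pct - mean_gc)
  structure(out, class = c("gc_track", class(out)))
}
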