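# Top-hit taxonomic binning: superkingdom partition, genus-level rank tables
# under sequence-count / nucleotide / coding-nucleotide weighting, rank
# concordance across binning methods, and per-group GC histograms.

.superkingdoms <- c("Bacterial", "Eukaryotic", "Viral", "Unknown")

#' Assign each query to a superkingdom from its best hit
#'
#' Queries with no accepted hit -- and hits whose subject taxonomy cannot be
#' resolved -- fall into `"Unknown"`, mirroring a binning scheme whose
#' unclassified set is defined purely by the absence of a classified top
#' hit. The partition over `query_ids` is exhaustive and exclusive.
#'
#' @param hits A hit tibble with at most one row per query and a
#'   `subject_superkingdom` column (e.g. `search_hits(..., mode = "top")`).
#' @param query_ids Character vector of every query searched (hit or not).
#' @return A tibble `query_id`, `superkingdom` covering all of `query_ids`.
#' @export
assign_superkingdom <- function(hits, query_ids) {
  if (anyDuplicated(hits$query_id)) {
    abort(sprintf("query appears more than once in `hits`: %s",
                  .oxford(unique(hits$query_id[duplicated(hits$query_id)]))))
  }
  if (!"subject_superkingdom" %in% names(hits)) {
    abort("`hits` lacks subject_superkingdom; search with a taxonomy attached")
  }
  sk <- hits$subject_superkingdom
  sk[!sk %in% .superkingdoms] <- "Unknown"
  tibble(query_id = as.character(query_ids)) |>
    left_join(tibble(query_id = hits$query_id, superkingdom = sk),
              by = "query_id") |>
    mutate(superkingdom = dplyr::coalesce(.data$superkingdom, "Unknown"))
}

.rank_by_weight <- function(tbl, weight_col) {
  tbl <- arrange(tbl, desc(.data[[weight_col]]), .data$genus)
  tbl$rank <- seq_len(nrow(tbl))
  tbl$tied <- duplicated(tbl[[weight_col]]) |
    duplicated(tbl[[weight_col]], fromLast = TRUE)
  tbl
}

#' Tabulate genus-level bins from top hits
#'
#' One row per genus with the number of member sequences and their total
#' nucleotides; ranks are assigned by the chosen weight in descending order.
#' Ties share consecutive ranks in lexicographic genus order and are flagged
#' in the `tied` column.
#'
#' @param hits A top-hit tibble carrying `subject_genus` (and optionally
#'   `subject_group`, a finer taxonomic group label used for reporting).
#' @param lengths A tibble `query_id`, `length_bp` giving each binned
#'   sequence's nucleotide length.
#' @param weight `"nucleotide"` (total bp, the default) or
#'   `"sequence_count"`.
#' @return A `taxon_bins` tibble: `genus`, `group`, `n_seqs`, `total_nt`,
#'   `rank`, `tied`.
#' @export
tabulate_genus_bins <- function(hits, lengths,
                                weight = c("nucleotide", "sequence_count")) {
  weight <- match.arg(weight)
  if (!nrow(hits)) abort("empty hit set")
  if (!"subject_genus" %in% names(hits)) abort("`hits` lacks subject_genus")
  joined <- hits |>
    inner_join(as_tibble(lengths), by = "query_id")
  if (nrow(joined) < nrow(hits)) {
    abort("some hit queries have no length entry")
  }
  grp_col <- if ("subject_group" %in% names(joined)) "subject_group" else "subject_superkingdom"
  if (!grp_col %in% names(joined)) joined[[grp_col]] <- NA_character_
  tbl <- joined |>
    group_by(genus = .data$subject_genus) |>
    summarise(group = .data[[grp_col]][1],
              n_seqs = n(),
              total_nt = sum(.data$length_bp)) |>
    ungroup()
  weight_col <- if (weight == "nucleotide") "total_nt" else "n_seqs"
  out <- .rank_by_weight(tbl, weight_col)
  structure(out, class = c("taxon_bins", class(out)),
            weight = weight)
}

#' Tabulate genus bins for protein hits weighted by coding nucleotides
#'
#' As [tabulate_genus_bins()], but each protein contributes its coding-region
#' nucleotide length (3 residues + stop codon, i.e. `3 * aa + 3`).
#'
#' @param hits A top-hit tibble for proteins carrying `subject_genus`.
#' @param protein_lengths A tibble `query_id`, `length_aa` of predicted
#'   protein lengths in residues.
#' @return A `taxon_bins` tibble ranked by coding nucleotides.
#' @export
tabulate_protein_bins <- function(hits, protein_lengths) {
  pl <- as_tibble(protein_lengths)
  if (!all(c("query_id", "length_aa") %in% names(pl))) {
    abort("`protein_lengths` needs columns query_id and length_aa")
  }
  missing <- setdiff(hits$query_id, pl$query_id)
  if (length(missing)) {
    abort(sprintf("protein(s) lacking a coding length: %s", .oxford(missing)))
  }
  lengths <- mutate(pl, length_bp = 3L * .data$length_aa + 3L)
  tabulate_genus_bins(hits, lengths[, c("query_id", "length_bp")],
                      weight = "nucleotide")
}

#' Compare genus rankings across binning methods
#'
#' Joins two or more rank tables over the union of their genera (absent
#' genera are reported as missing, not as rank 0) and computes Spearman rank
#' correlations over the genera shared by each pair.
#'
#' @param tables A named list of >= 2 `taxon_bins` tables (or any tibbles
#'   with `genus` and `rank`).
#' @return A list: `ranks` (side-by-side tibble, one rank column per method)
#'   and `concordance` (tibble `method_a`, `method_b`, `n_shared`, `rho`).
#' @export
compare_rankings <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L) abort("supply at least two rank tables")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("method_", seq_along(tables))
  }
  ranks <- purrr::reduce(imap(tables, function(t, nm) {
    tibble(genus = t$genus, !!paste0("rank_", nm) := t$rank)
  }), full_join, by = "genus") |> arrange(.data$genus)
  pairs <- utils::combn(names(tables), 2L, simplify = FALSE)
  concordance <- list_rbind(map(pairs, function(p) {
    a <- ranks[[paste0("rank_", p[1])]]
    b <- ranks[[paste0("rank_", p[2])]]
    shared <- !is.na(a) & !is.na(b)
    if (sum(shared) < 3L) {
      abort(sprintf("methods %s and %s share fewer than 3 genera", p[1], p[2]))
    }
    tibble(method_a = p[1], method_b = p[2], n_shared = sum(shared),
           rho = cor(a[shared], b[shared], method = "spearman"))
  }))
  list(ranks = ranks, concordance = concordance)
}

#' Per-group GC histograms
#'
#' @param seqs A nucleotide sequence table.
#' @param groups A tibble `id`, `group` assigning each sequence to a group
#'   (e.g. taxonomic group from binning).
#' @param bin_width Bin width in percent GC (default 1, i.e. per-percentage
#'   tabulation).
#' @return A `gc_histogram` tibble: `group`, `bin_low`, `bin_high`, `count`;
#'   within each group the counts sum to the group's sequence count.
#' @export
gc_histogram <- function(seqs, groups, bin_width = 1) {
  gc <- gc_content(seqs) |>
    inner_join(as_tibble(groups), by = "id")
  if (!nrow(gc)) abort("no sequence is assigned to a group")
  edges <- seq(0, 100, by = bin_width)
  if (tail(edges, 1) < 100) edges <- c(edges, 100)
  out <- gc |>
    mutate(bin = cut(.data$gc_percent, breaks = edges, include.lowest = TRUE,
                     right = FALSE, labels = FALSE)) |>
    mutate(bin = pmin(.data$bin, length(edges) - 1L)) |>
    group_by(.data$group, .data$bin) |>
    summarise(count = n(), .groups = "drop") |>
    mutate(bin_low = edges[.data$bin], bin_high = edges[.data$bin + 1L]) |>
    select("group", "bin_low", "bin_high", "count") |>
    arrange(.data$group, .data$bin_low)
  structure(out, class = c("gc_histogram", class(out)))
}
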