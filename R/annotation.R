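# Functional annotation: naive ORF calling, dual-evidence CAZy-style family
# annotation (a protein is accepted for a family only with BOTH a hit to the
# family's member proteins AND a hit to its correlated domain model), the
# translated-search variant for nucleotide input, the family-by-source
# summary, and COG-style best-hit annotation with category proportions.

.stop_codons <- c("TAA", "TAG", "TGA")

#' Call open reading frames naively
#'
#' Reports every ATG-to-nearest-in-frame-stop open reading frame on all six
#' frames with at least `min_orf_codons` codons (start codon included, stop
#' excluded). Nested ORFs sharing a stop are all reported, so a planted gene
#' is always recovered at its exact coordinates regardless of upstream
#' context. Coordinates are 0-based half-open on the forward strand and
#' include the stop codon; a strand flag records orientation.
#'
#' @param contigs A nucleotide sequence table.
#' @param min_orf_codons Minimum ORF length in codons (default 60, a typical
#'   bacterial floor).
#' @return A tibble: `contig_id`, `orf_id`, `start`, `end`, `strand`,
#'   `n_codons`, `protein`. Contigs without ORFs contribute no rows.
#' @export
#'
#' @examples
#' call_orfs(seq_tbl("c", "ATGAAATAA"), min_orf_codons = 2)
call_orfs <- function(contigs, min_orf_codons = 60L) {
  .assert_seq_tbl(contigs, "nucleotide", "contigs")
  assert_scalar_number(min_orf_codons, "min_orf_codons", 1)
  list_rbind(map(seq_len(nrow(contigs)), function(i) {
    s <- contigs$seq[i]
    l <- nchar(s)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    rows <- list_rbind(map(c("+", "-"), function(strand) {
      src <- if (strand == "+") s else rc
      list_rbind(map(0:2, function(f) {
        n_cod <- (nchar(src) - f) %/% 3L
        if (n_cod < 2L) return(NULL)
        codons <- str_sub(src, f + 1L + 3L * (seq_len(n_cod) - 1L),
                          f + 3L * seq_len(n_cod))
        starts <- which(codons == "ATG")
        stops <- which(codons %in% .stop_codons)
        if (!length(starts) || !length(stops)) return(NULL)
        stop_after <- stops[findInterval(starts, stops) + 1L]
        # findInterval gives the last stop <= start; the next one ends the ORF
        keep <- !is.na(stop_after)
        starts <- starts[keep]
        stop_after <- stop_after[keep]
        len <- stop_after - starts
        keep <- len >= min_orf_codons
        if (!any(keep)) return(NULL)
        starts <- starts[keep]
        stop_after <- stop_after[keep]
        len <- len[keep]
        # coordinates on the source strand, 0-based half-open incl. stop codon
        from <- f + 3L * (starts - 1L)
        to <- f + 3L * stop_after
        if (strand == "-") {
          tmp <- from
          from <- l - to
          to <- l - tmp
        }
        prot <- map_chr(seq_along(starts), function(j) {
          .translate_str(str_sub(src,
                                 f + 1L + 3L * (starts[j] - 1L),
                                 f + 3L * (stop_after[j] - 1L)))
        })
        tibble(contig_id = contigs$id[i], start = from, end = to,
               strand = strand, n_codons = len, protein = prot)
      }))
    }))
    if (is.null(rows) || !nrow(rows)) return(NULL)
    rows <- arrange(rows, .data$start, .data$end, .data$strand)
    mutate(rows,
           orf_id = sprintf("%s_orf%03d", .data$contig_id, row_number()),
           .after = "contig_id")
  }))
}

# Evidence gathering shared by the protein-level and translated annotators:
# per query, the best accepted e-value against each family's members and
# against each correlated domain.
.family_evidence <- function(queries, db, evalue_max) {
  member_idx <- build_index(db$members, k = 4L)
  domain_idx <- build_index(db$domains, k = 4L)
  member_hits <- search_hits(queries, member_idx, evalue_max,
                             mode = "per_subject")
  domain_hits <- search_hits(queries, domain_idx, evalue_max,
                             mode = "per_subject")
  fam_of_member <- db$member_families
  member_ev <- if (nrow(member_hits)) {
    member_hits |>
      mutate(family_id = unname(fam_of_member[.data$subject_id])) |>
      group_by(.data$query_id, .data$family_id) |>
      summarise(member_evalue = min(.data$evalue), .groups = "drop")
  } else {
    tibble(query_id = character(), family_id = character(),
           member_evalue = numeric())
  }
  fam_of_domain <- setNames(db$family_map$family_id, db$family_map$domain_id)
  domain_ev <- if (nrow(domain_hits)) {
    domain_hits |>
      mutate(family_id = unname(fam_of_domain[.data$subject_id])) |>
      group_by(.data$query_id, .data$family_id) |>
      summarise(domain_evalue = min(.data$evalue), .groups = "drop")
  } else {
    tibble(query_id = character(), family_id = character(),
           domain_evalue = numeric())
  }
  list(member = member_ev, domain = domain_ev)
}

.combine_evidence <- function(ev, evidence) {
  switch(evidence,
    both = inner_join(ev$member, ev$domain, by = c("query_id", "family_id")),
    member = mutate(ev$member, domain_evalue = NA_real_),
    domain = mutate(ev$domain, member_evalue = NA_real_)
  )
}

#' Dual-evidence CAZy-style annotation of proteins
#'
#' A protein is annotated to a family only when it has an accepted hit to
#' one of the family's member proteins AND an accepted hit to that family's
#' correlated domain model, both at e-value <= `evalue_max`. Member evidence
#' for one family combined with domain evidence for a different,
#' uncorrelated family is rejected for both. A protein may carry several
#' family annotations; each (protein, family) pair counts as one module.
#'
#' @param proteins A protein sequence table.
#' @param db A [family_db()].
#' @param evalue_max Acceptance threshold for each evidence channel.
#' @param evidence `"both"` (the dual-evidence rule, default) or the
#'   relaxations `"member"` / `"domain"` used for evidence-channel audits.
#' @param source_groups Optional tibble `protein_id`, `source_group` (e.g.
#'   taxonomic groups from binning) carried through to the annotations.
#' @return A `cazyme_annotation` tibble: `protein_id`, `family_id`,
#'   `member_evalue`, `domain_evalue` (and `source_group` if supplied).
#' @export
annotate_cazy <- function(proteins, db, evalue_max = 1e-05,
                          evidence = c("both", "member", "domain"),
                          source_groups = NULL) {
  .assert_seq_tbl(proteins, "protein", "proteins")
  stopifnot(inherits(db, "family_db"))
  evidence <- match.arg(evidence)
  ev <- .family_evidence(proteins, db, evalue_max)
  out <- .combine_evidence(ev, evidence) |>
    rename(protein_id = "query_id") |>
    distinct(.data$protein_id, .data$family_id, .keep_all = TRUE) |>
    arrange(.data$protein_id, .data$family_id)
  if (!is.null(source_groups)) {
    out <- left_join(out, as_tibble(source_groups), by = "protein_id")
  }
  structure(out, class = c("cazyme_annotation", class(out)))
}

#' Dual-evidence CAZy-style annotation of nucleotide contigs
#'
#' For input where protein prediction is unreliable, evidence is gathered
#' over all six translated reading frames and the annotation is attributed
#' to the contig id. The dual-evidence rule is identical to
#' [annotate_cazy()]; a frame hit in any frame counts for its channel.
#'
#' @param contigs A nucleotide sequence table.
#' @inheritParams annotate_cazy
#' @return A `cazyme_annotation` tibble keyed by `contig_id`.
#' @export
annotate_cazy_translated <- function(contigs, db, evalue_max = 1e-05,
                                     evidence = c("both", "member", "domain")) {
  .assert_seq_tbl(contigs, "nucleotide", "contigs")
  if (!nrow(contigs)) abort("empty contig set")
  stopifnot(inherits(db, "family_db"))
  evidence <- match.arg(evidence)
  frames <- six_frame_translate(contigs)
  frames_tbl <- seq_tbl(sprintf("%s|frame%+d", frames$id, frames$frame),
                        frames$seq, alphabet = "protein")
  ev <- .family_evidence(frames_tbl, db, evalue_max)
  collapse <- function(tbl, col) {
    if (!nrow(tbl)) {
      return(tibble(contig_id = character(), family_id = character(),
                    !!col := numeric()))
    }
    tbl |>
      mutate(contig_id = sub("\\|frame[+-]\\d$", "", .data$query_id)) |>
      group_by(.data$contig_id, .data$family_id) |>
      summarise(!!col := min(.data[[col]]), .groups = "drop")
  }
  member_ev <- collapse(ev$member, "member_evalue")
  domain_ev <- collapse(ev$domain, "domain_evalue")
  out <- switch(evidence,
    both = inner_join(member_ev, domain_ev, by = c("contig_id", "family_id")),
    member = mutate(member_ev, domain_evalue = NA_real_),
    domain = mutate(domain_ev, member_evalue = NA_real_)
  ) |>
    arrange(.data$contig_id, .data$family_id)
  structure(out, class = c("cazyme_annotation", class(out)))
}

#' Summarise family annotations
#'
#' A module is one (protein, family) pair. The summary gives per-family
#' module counts with a source-organism breakdown, plus grand totals of
#' modules and of distinct families. Accepts either annotation rows (one
#' per module) or pre-tabulated counts (a `count` column), so printed
#' summary tables can be ingested directly.
#'
#' @param annotations A `cazyme_annotation` tibble (optionally carrying
#'   `source_group`), or a tibble `family_id`, `count`.
#' @return A `family_summary` tibble: `family_id`, `modules` and, when
#'   source groups are present, a `sources` breakdown string. Totals are
#'   available via [glance()].
#' @export
summarize_families <- function(annotations) {
  annotations <- as_tibble(annotations)
  if ("count" %in% names(annotations)) {
    out <- annotations |>
      group_by(.data$family_id) |>
      summarise(modules = sum(.data$count), .groups = "drop")
  } else {
    key <- if ("protein_id" %in% names(annotations)) "protein_id" else "contig_id"
    has_src <- "source_group" %in% names(annotations)
    out <- annotations |>
      distinct(.data[[key]], .data$family_id, .keep_all = TRUE) |>
      group_by(.data$family_id) |>
      summarise(
        modules = n(),
        sources = if (has_src) {
          paste(sprintf("%d %s", as.integer(table(.data$source_group)),
                        names(table(.data$source_group))), collapse = ", ")
        } else NA_character_,
        .groups = "drop"
      )
  }
  out <- arrange(out, .data$family_id)
  structure(out, class = c("family_summary", class(out)))
}

#' @export
glance.family_summary <- function(x, ...) {
  tibble(total_modules = sum(x$modules), total_families = nrow(x))
}

#' COG-style best-hit annotation
#'
#' Each protein receives the COG of its best accepted hit and that COG's
#' one-letter functional category; category proportions are computed over
#' the annotated proteins and sum to 1.
#'
#' @param proteins A protein sequence table.
#' @param cog_db A list with `profiles` (protein sequence table of COG
#'   models) and `categories` (tibble `cog_id`, `category`), e.g. from
#'   [simulate_cog_db()].
#' @param evalue_max Acceptance threshold.
#' @return A list: `annotations` (tibble `protein_id`, `cog_id`,
#'   `category`, `evalue`), `category_proportions` (tibble `category`, `n`,
#'   `proportion`) and `annotation_rate` (annotated / searched).
#' @export
annotate_cog <- function(proteins, cog_db, evalue_max = 1e-05) {
  .assert_seq_tbl(proteins, "protein", "proteins")
  if (!all(c("profiles", "categories") %in% names(cog_db))) {
    abort("`cog_db` needs elements profiles and categories")
  }
  idx <- build_index(cog_db$profiles, k = 4L)
  hits <- search_hits(proteins, idx, evalue_max, mode = "top")
  ann <- hits |>
    select(protein_id = "query_id", cog_id = "subject_id", "evalue") |>
    left_join(as_tibble(cog_db$categories), by = "cog_id")
  if (any(is.na(ann$category))) {
    abort(sprintf("COG id(s) lacking a category: %s",
                  .oxford(unique(ann$cog_id[is.na(ann$category)]))))
  }
  props <- ann |>
    group_by(.data$category) |>
    summarise(n = n(), .groups = "drop") |>
    mutate(proportion = .data$n / sum(.data$n))
  list(
    annotations = ann,
    category_proportions = props,
    annotation_rate = nrow(ann) / nrow(proteins)
  )
}

#' Published-scale CAZy family count table
#'
#' The per-family module counts of a dual-evidence CAZy characterization of
#' a fungus-garden community metagenome (28 families, 69 modules), shipped
#' as a plain-text fixture. Useful as a worked input for
#' [summarize_families()] and [build_profile_matrix()].
#'
#' @return A tibble: `family_id`, `correlated_domain`, `count`.
#' @export
cazy_metagenome_counts <- function() {
  path <- system.file("extdata", "cazy_metagenome_counts.tsv",
                      package = "hortus", mustWork = TRUE)
  read_report(path)
}
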