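# Synthetic communities: reference genomes at controlled GC, diverged strains,
# planted enzyme-family genes, and error-bearing reads -- all with truth
# tables, so every downstream statistic can be checked against known answers.

#' Specify a synthetic community
#'
#' @param genera A data frame with columns `genus`, `superkingdom`,
#'   `abundance` (relative, summing to 1), `genome_bp` and `gc` (fraction).
#' @param strain_divergence Per-site substitution probability applied when
#'   deriving community strains from the reference genomes; either a single
#'   value or one per genus. Must lie in \[0, 0.25\].
#' @param read_length_bp Simulated read length.
#' @param read_error_rate Per-base substitution error probability of the
#'   simulated sequencer, in \[0, 0.25\].
#' @param n_reads Number of reads to simulate.
#' @param seed Integer seed; all generator operations derive their own RNG
#'   stream from it.
#' @return A `community_spec` list.
#' @export
#'
#' @examples
#' community_spec(
#'   tibble::tibble(
#'     genus = c("Klebsiella", "Pantoea"), superkingdom = "Bacterial",
#'     abundance = c(0.6, 0.4), genome_bp = 50000, gc = c(0.57, 0.55)
#'   ),
#'   strain_divergence = c(0.001, 0.03), n_reads = 1000
#' )
community_spec <- function(genera, strain_divergence = 0,
                           read_length_bp = 250L, read_error_rate = 0,
                           n_reads = 1000L, seed = 1L) {
  need <- c("genus", "superkingdom", "abundance", "genome_bp", "gc")
  missing <- setdiff(need, names(genera))
  if (length(missing)) abort(sprintf("`genera` lacks column(s): %s", .oxford(missing)))
  if (!nrow(genera)) abort("`genera` must contain at least one genus")
  if (anyDuplicated(genera$genus)) abort("genus names must be unique")
  if (abs(sum(genera$abundance) - 1) > 1e-9) abort("abundances must sum to 1")
  if (any(genera$abundance < 0)) abort("abundances must be non-negative")
  if (any(genera$genome_bp <= 0)) abort("genome lengths must be positive")
  if (any(genera$gc < 0 | genera$gc > 1)) abort("gc must be a fraction in [0, 1]")
  if (any(strain_divergence < 0 | strain_divergence > 0.25)) {
    abort("`strain_divergence` must lie in [0, 0.25]")
  }
  if (!length(strain_divergence) %in% c(1L, nrow(genera))) {
    abort("`strain_divergence` must be length 1 or one per genus")
  }
  assert_scalar_number(read_error_rate, "read_error_rate", 0, 0.25)
  assert_scalar_number(read_length_bp, "read_length_bp", 1)
  assert_scalar_number(n_reads, "n_reads", 1)
  structure(
    list(
      genera = as_tibble(genera[, need]),
      strain_divergence = rep_len(strain_divergence, nrow(genera)),
      read_length_bp = as.integer(read_length_bp),
      read_error_rate = read_error_rate,
      n_reads = as.integer(n_reads),
      seed = as.integer(seed)
    ),
    class = "community_spec"
  )
}

.sample_bases <- function(n, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Generate a reference genome collection
#'
#' One genome per genus with i.i.d. bases at the requested GC fraction, plus
#' the taxonomy table mapping genome ids to genus and superkingdom.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [community_spec()].
#' @return A list with elements `genomes` (sequence table, ids
#'   `<genus>_ref`) and `taxonomy` (tibble: `genome_id`, `genus`,
#'   `superkingdom`).
#' @export
generate_reference_collection <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  g <- spec$genera
  seqs <- with_op_seed(spec$seed, "reference", {
    map_chr(seq_len(nrow(g)), function(i) .sample_bases(g$genome_bp[i], g$gc[i]))
  })
  genomes <- seq_tbl(paste0(g$genus, "_ref"), seqs,
                     description = paste("synthetic reference for", g$genus),
                     alphabet = "nucleotide")
  taxonomy <- tibble(genome_id = genomes$id, genus = g$genus,
                     superkingdom = g$superkingdom)
  list(genomes = genomes, taxonomy = taxonomy)
}

.mutate_seq <- function(seq, divergence) {
  if (divergence == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < divergence)
  if (length(hit)) {
    alts <- c("A", "C", "G", "T")
    repl <- map_chr(chars[hit], function(b) sample(setdiff(alts, b), 1L))
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

#' Derive diverged strains from reference genomes
#'
#' Each site is substituted independently with probability equal to the
#' divergence, uniformly over the three alternative bases; lengths are
#' preserved (no indels), so strain and reference stay colinear.
#'
#' @param genomes A nucleotide sequence table.
#' @param divergence Per-site substitution probability in \[0, 0.25\]; scalar
#'   or one per genome.
#' @param seed Integer seed.
#' @param suffix Appended to each id to form the strain id.
#' @return A sequence table of strains, same order and lengths as the input.
#' @export
mutate_strain <- function(genomes, divergence, seed = 1L, suffix = "_strain") {
  .assert_seq_tbl(genomes, "nucleotide", "genomes")
  if (any(divergence < 0 | divergence > 0.25)) abort("`divergence` must lie in [0, 0.25]")
  divergence <- rep_len(divergence, nrow(genomes))
  seqs <- with_op_seed(seed, "strain", {
    map_chr(seq_len(nrow(genomes)),
            function(i) .mutate_seq(genomes$seq[i], divergence[i]))
  })
  seq_tbl(paste0(genomes$id, suffix), seqs,
          description = sprintf("strain of %s at divergence %g",
                                genomes$id, divergence),
          alphabet = "nucleotide")
}

# Codon table used to reverse-translate planted proteins; one codon per
# residue, none of which is a stop.
.codon_of <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT", H = "CAT",
  I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT", P = "CCT", Q = "CAA",
  R = "CGT", S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT"
)

.reverse_translate <- function(protein) {
  paste(.codon_of[strsplit(protein, "")[[1]]], collapse = "")
}

#' Simulate a CAZy-like enzyme family database
#'
#' Families mimic the structure the dual-evidence annotation relies on: each
#' family has member proteins sharing a conserved motif flanked by
#' family-specific random sequence, and a correlated domain model that is the
#' motif consensus itself. The family-to-domain correlation table links the
#' two evidence channels.
#'
#' @param n_families Number of families.
#' @param members_per_family Member proteins per family.
#' @param motif_aa Conserved motif length in residues (>= 10).
#' @param flank_aa Random flank length on each side of the motif in members.
#' @param seed Integer seed.
#' @return A `family_db` list: `members` (protein sequence table with a
#'   `family_id` attribute column mapping), `domains`, `family_map`
#'   (tibble `family_id`, `domain_id`) and `motifs` (named character).
#' @export
simulate_family_db <- function(n_families = 4L, members_per_family = 3L,
                               motif_aa = 60L, flank_aa = 40L, seed = 1L) {
  assert_scalar_number(n_families, "n_families", 1)
  assert_scalar_number(members_per_family, "members_per_family", 1)
  assert_scalar_number(motif_aa, "motif_aa", 10)
  aa <- names(.codon_of)
  with_op_seed(seed, "family_db", {
    fam_ids <- sprintf("GH%d-like", seq_len(n_families) + 7L)
    motifs <- setNames(
      map_chr(fam_ids, ~ paste(sample(aa, motif_aa, replace = TRUE), collapse = "")),
      fam_ids
    )
    members <- list_rbind(map(fam_ids, function(f) {
      tibble(
        id = sprintf("%s_member%d", f, seq_len(members_per_family)),
        family_id = f,
        seq = map_chr(seq_len(members_per_family), function(i) {
          left <- paste(sample(aa, flank_aa, replace = TRUE), collapse = "")
          right <- paste(sample(aa, flank_aa, replace = TRUE), collapse = "")
          paste0(left, motifs[[f]], right)
        })
      )
    }))
    domains <- tibble(
      id = sprintf("dom_%s", fam_ids),
      seq = unname(motifs)
    )
    family_db(
      members = seq_tbl(members$id, members$seq, alphabet = "protein"),
      domains = seq_tbl(domains$id, domains$seq, alphabet = "protein"),
      family_map = tibble(family_id = fam_ids, domain_id = domains$id),
      member_families = setNames(members$family_id, members$id),
      motifs = motifs
    )
  })
}

#' Construct an enzyme family database
#'
#' @param members Protein sequence table of family member proteins.
#' @param domains Protein sequence table of correlated domain consensus
#'   sequences.
#' @param family_map Tibble with columns `family_id`, `domain_id`.
#' @param member_families Named character vector mapping member id to
#'   family id.
#' @param motifs Optional named motif strings (used by simulators/tests).
#' @return A `family_db` list.
#' @export
family_db <- function(members, domains, family_map, member_families,
                      motifs = NULL) {
  .assert_seq_tbl(members, "protein", "members")
  .assert_seq_tbl(domains, "protein", "domains")
  if (!all(c("family_id", "domain_id") %in% names(family_map))) {
    abort("`family_map` needs columns family_id and domain_id")
  }
  if (!nrow(members)) abort("family database has no member proteins")
  if (!all(family_map$domain_id %in% domains$id)) {
    abort("family_map references unknown domain id(s)")
  }
  if (!all(member_families %in% family_map$family_id)) {
    abort("member mapped to a family with no correlated domain")
  }
  if (!all(members$id %in% names(member_families))) {
    abort("every member protein needs a family assignment")
  }
  structure(
    list(members = members, domains = domains, family_map = as_tibble(family_map),
         member_families = member_families, motifs = motifs),
    class = "family_db"
  )
}

#' Plant enzyme-family genes into a genome
#'
#' Each planted gene is a start codon, a coding sequence reverse-translated
#' from the family motif, and a stop codon, inserted at uniformly random
#' non-overlapping positions (optionally on either strand). The truth table
#' records every planted gene's family, coordinates (0-based half-open on the
#' forward strand of the *returned* genome) and strand.
#'
#' @param genome A single-row nucleotide sequence table.
#' @param db A [family_db()] whose `motifs` are available (e.g. from
#'   [simulate_family_db()]).
#' @param copies_per_family Number of gene copies planted per family.
#' @param strands `"both"`, `"forward"` or `"reverse"`.
#' @param seed Integer seed.
#' @return A list: `genome` (the lengthened sequence table row) and `truth`
#'   (tibble `gene_id`, `family_id`, `start`, `end`, `strand`, `protein`).
#' @export
plant_family_genes <- function(genome, db, copies_per_family = 1L,
                               strands = c("both", "forward", "reverse"),
                               seed = 1L) {
  .assert_seq_tbl(genome, "nucleotide", "genome")
  if (nrow(genome) != 1L) abort("`genome` must be a single record")
  stopifnot(inherits(db, "family_db"))
  if (is.null(db$motifs)) abort("`db` carries no motif sequences to plant")
  strands <- match.arg(strands)
  fam_ids <- names(db$motifs)
  n_genes <- length(fam_ids) * copies_per_family
  base_len <- nchar(genome$seq)
  if (base_len < n_genes + 1L) abort("genome too short to host the requested gene copies")

  genes <- tibble(
    gene_id = sprintf("planted_%02d", seq_len(n_genes)),
    family_id = rep(fam_ids, each = copies_per_family),
    protein = paste0("M", db$motifs[rep(fam_ids, each = copies_per_family)])
  )
  genes$cds <- map_chr(genes$protein, function(p) paste0(.reverse_translate(p), "TAA"))
  if (base_len < sum(nchar(genes$cds))) {
    abort("genome too short to host the requested gene copies")
  }

  with_op_seed(seed, "plant", {
    genes$strand <- switch(strands,
      both = sample(c("+", "-"), n_genes, replace = TRUE),
      forward = rep("+", n_genes),
      reverse = rep("-", n_genes)
    )
    # insertion points in the original genome, strictly increasing
    points <- sort(sample.int(base_len - 1L, n_genes))
    seq <- genome$seq
    offset <- 0L
    rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      insert <- genes$cds[i]
      if (genes$strand[i] == "-") {
        insert <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(insert)))
      }
      at <- points[i] + offset          # insert after position `at` (1-based)
      seq <- paste0(str_sub(seq, 1L, at), insert, str_sub(seq, at + 1L))
      rows[[i]] <- tibble(start = at, end = at + nchar(insert))  # 0-based half-open
      offset <- offset + nchar(insert)
    }
    truth <- bind_rows(rows)
    genes$start <- truth$start
    genes$end <- truth$end
  })
  list(
    genome = seq_tbl(genome$id, seq, description = genome$description,
                     alphabet = "nucleotide"),
    truth = genes[, c("gene_id", "family_id", "start", "end", "strand", "protein")]
  )
}

.apply_read_errors <- function(seq, rate) {
  if (rate == 0) return(list(seq = seq, n_errors = 0L))
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    alts <- c("A", "C", "G", "T")
    chars[hit] <- map_chr(chars[hit], function(b) sample(setdiff(alts, b), 1L))
  }
  list(seq = paste(chars, collapse = ""), n_errors = length(hit))
}

#' Simulate shotgun reads from a set of genomes
#'
#' Each read is drawn from a genome with probability equal to its abundance,
#' starts uniformly at random, has fixed length, and accumulates i.i.d.
#' substitution errors at the spec's `read_error_rate`. The truth table
#' records provenance: source genome, 0-based half-open coordinates on that
#' genome, strand, error count and the read's true identity to its source.
#'
#' @param genomes A nucleotide sequence table (e.g. community strains).
#' @param spec A [community_spec()]; its `genera$abundance` entries are
#'   matched to `genomes` rows in order.
#' @param strands `"both"` or `"forward"`.
#' @return A list with `reads` (sequence table) and `truth` (tibble).
#' @export
simulate_reads <- function(genomes, spec, strands = c("both", "forward")) {
  .assert_seq_tbl(genomes, "nucleotide", "genomes")
  stopifnot(inherits(spec, "community_spec"))
  strands <- match.arg(strands)
  if (nrow(genomes) != nrow(spec$genera)) {
    abort("`genomes` must have one row per genus in the spec")
  }
  len <- spec$read_length_bp
  if (any(nchar(genomes$seq) < len)) abort("read length exceeds a genome length")
  n <- spec$n_reads
  with_op_seed(spec$seed, "reads", {
    src <- sample.int(nrow(genomes), n, replace = TRUE, prob = spec$genera$abundance)
    starts <- map_int(src, function(i) sample.int(nchar(genomes$seq[i]) - len + 1L, 1L))
    strand <- if (strands == "both") sample(c("+", "-"), n, replace = TRUE) else rep("+", n)
    raw <- str_sub(genomes$seq[src], starts, starts + len - 1L)
    flip <- strand == "-"
    if (any(flip)) {
      raw[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(raw[flip])
      ))
    }
    errored <- map(raw, .apply_read_errors, rate = spec$read_error_rate)
    reads <- seq_tbl(sprintf("read_%06d", seq_len(n)),
                     map_chr(errored, "seq"), alphabet = "nucleotide")
    n_err <- map_int(errored, "n_errors")
    truth <- tibble(
      read_id = reads$id,
      genome_id = genomes$id[src],
      genus = spec$genera$genus[src],
      start = starts - 1L,          # 0-based half-open
      end = starts - 1L + len,
      strand = strand,
      n_errors = n_err,
      true_identity = 100 * (len - n_err) / len
    )
    list(reads = reads, truth = truth)
  })
}

#' Simulate a COG-like profile database
#'
#' @param n_cogs Number of COG models.
#' @param protein_aa Model length in residues.
#' @param categories Pool of one-letter functional categories to assign.
#' @param seed Integer seed.
#' @return A list: `profiles` (protein sequence table) and `categories`
#'   (tibble `cog_id`, `category`).
#' @export
simulate_cog_db <- function(n_cogs = 10L, protein_aa = 80L,
                            categories = c("C", "E", "G", "J", "K", "L", "M",
                                           "P", "R", "T"),
                            seed = 1L) {
  aa <- names(.codon_of)
  with_op_seed(seed, "cog_db", {
    ids <- sprintf("COG%04d", seq_len(n_cogs))
    profiles <- seq_tbl(
      ids,
      map_chr(seq_len(n_cogs), ~ paste(sample(aa, protein_aa, replace = TRUE),
                                       collapse = "")),
      alphabet = "protein"
    )
    list(
      profiles = profiles,
      categories = tibble(cog_id = ids,
                          category = sample(categories, n_cogs, replace = TRUE))
    )
  })
}

#' Simulate per-metagenome feature counts
#'
#' Draws multinomial feature counts (e.g. CAZy family or genus annotations)
#' for a set of metagenomes from given expected proportion vectors -- the
#' sampling model behind proportion-profile clustering.
#'
#' @param proportions A matrix or data frame: rows = metagenomes (named),
#'   columns = features (named); each row sums to 1.
#' @param n_annotations Annotated features drawn per metagenome (scalar or
#'   one per row).
#' @param seed Integer seed.
#' @return A long tibble: `metagenome`, `feature`, `count` (zero counts
#'   dropped).
#' @export
simulate_feature_counts <- function(proportions, n_annotations = 500L, seed = 1L) {
  m <- as.matrix(proportions)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("`proportions` must have row (metagenome) and column (feature) names")
  }
  if (any(abs(rowSums(m) - 1) > 1e-9)) abort("each proportion row must sum to 1")
  n_annotations <- rep_len(as.integer(n_annotations), nrow(m))
  with_op_seed(seed, "counts", {
    list_rbind(map(seq_len(nrow(m)), function(i) {
      counts <- as.integer(rmultinom(1, n_annotations[i], m[i, ]))
      tibble(metagenome = rownames(m)[i], feature = colnames(m),
             count = counts)
    })) |> filter(.data$count > 0)
  })
}
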