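test_that("community specs enforce their invariants", {
  g <- tibble::tibble(genus = "X", superkingdom = "Bacterial", abundance = 1,
                      genome_bp = 1000, gc = 0.5)
  expect_s3_class(community_spec(g), "community_spec")
  expect_error(community_spec(dplyr::mutate(g, abundance = 0.9)), "sum to 1")
  expect_error(community_spec(g, strain_divergence = 0.3), "0.25")
  expect_error(community_spec(g, read_error_rate = 0.5), "read_error_rate")
  expect_error(community_spec(g[0, ]), "at least one genus")
})

test_that("reference genomes hit the requested GC and are reproducible", {
  g <- tibble::tibble(genus = "X", superkingdom = "Bacterial", abundance = 1,
                      genome_bp = 10000, gc = 0.5)
  ref <- generate_reference_collection(community_spec(g, seed = 3))
  gc <- gc_content(ref$genomes)$gc_percent / 100
  # central 99% binomial interval for n = 10,000, p = 0.5
  expect_gt(gc, 0.47)
  expect_lt(gc, 0.53)

  again <- generate_reference_collection(community_spec(g, seed = 3))
  expect_identical(ref, again)

  at_only <- generate_reference_collection(
    community_spec(dplyr::mutate(g, gc = 0), seed = 1)
  )
  expect_false(grepl("[GC]", at_only$genomes$seq))
})

test_that("taxonomy table maps each genome to its genus and superkingdom", {
  spec <- demo_spec()
  ref <- generate_reference_collection(spec)
  expect_equal(nrow(ref$taxonomy), 3)
  expect_equal(ref$taxonomy$genome_id, ref$genomes$id)
  expect_setequal(ref$taxonomy$genus, spec$genera$genus)
})

test_that("strain mutation follows the per-site substitution model", {
  ref <- seq_tbl("g", random_dna(100000, seed = 8))
  expect_identical(mutate_strain(ref, 0, seed = 1)$seq, ref$seq)

  strain <- mutate_strain(ref, 0.02, seed = 2)
  expect_equal(nchar(strain$seq), nchar(ref$seq))
  h <- hamming(ref$seq, strain$seq)
  # central 99% binomial interval around 2,000 for n = 100,000, p = 0.02
  expect_gt(h, stats::qbinom(0.005, 100000, 0.02))
  expect_lt(h, stats::qbinom(0.995, 100000, 0.02))

  expect_error(mutate_strain(seq_tbl("p", "MKVL"), 0.01), "nucleotide")
  expect_error(mutate_strain(ref, 0.5), "0.25")
})

test_that("strain-vs-reference alignment identity tracks 1 - divergence", {
  ref <- seq_tbl("g", random_dna(10000, seed = 21))
  strain <- mutate_strain(ref, 0.03, seed = 22)
  idx <- build_index(ref, k = 11)
  slice <- seq_tbl("q", substr(strain$seq, 2001, 3000))
  hit <- top_hit(slice, idx)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$identity / 100, 1 - 0.03, tolerance = 0.2)
  # and exactly matches the Hamming-derived identity of the colinear pair
  m <- hamming(substr(ref$seq, 2001, 3000), slice$seq)
  expect_equal(hit$identity, 100 * (1000 - m) / 1000, tolerance = 1e-6)
})

test_that("planted genes are recorded and translate back to their motif", {
  db <- simulate_family_db(n_families = 3, seed = 13)
  genome <- seq_tbl("g", random_dna(20000, seed = 13))
  pl <- plant_family_genes(genome, db, copies_per_family = 2, seed = 13)
  expect_equal(nrow(pl$truth), 6)
  per_family <- dplyr::count(pl$truth, family_id)
  expect_setequal(per_family$family_id, names(db$motifs))
  expect_true(all(per_family$n == 2))
  for (i in seq_len(nrow(pl$truth))) {
    gene <- substr(pl$genome$seq, pl$truth$start[i] + 1, pl$truth$end[i])
    if (pl$truth$strand[i] == "-") {
      gene <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene)))
    }
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(gene)))
    expect_equal(sub("\\*$", "", prot), pl$truth$protein[i])
    expect_true(grepl(db$motifs[[pl$truth$family_id[i]]], prot, fixed = TRUE))
  }
  expect_error(plant_family_genes(seq_tbl("tiny", "ACGT"), db), "too short")
})

test_that("the naive ORF caller recovers every planted gene exactly", {
  db <- simulate_family_db(n_families = 4, seed = 17)
  genome <- seq_tbl("g", random_dna(30000, seed = 17))
  pl <- plant_family_genes(genome, db, copies_per_family = 1, seed = 17)
  orfs <- call_orfs(pl$genome, min_orf_codons = 60)
  found <- dplyr::inner_join(pl$truth, orfs, by = c("start", "end", "strand"))
  expect_equal(nrow(found), nrow(pl$truth))
})

test_that("error-free reads are exact substrings of their source", {
  spec <- demo_spec(n_reads = 40, seed = 31)
  ref <- generate_reference_collection(spec)
  sim <- simulate_reads(ref$genomes, spec)
  for (i in seq_len(nrow(sim$reads))) {
    t <- sim$truth[i, ]
    frag <- substr(ref$genomes$seq[ref$genomes$id == t$genome_id],
                   t$start + 1, t$end)
    if (t$strand == "-") {
      frag <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
    }
    expect_identical(sim$reads$seq[i], frag)
  }
  expect_true(all(sim$truth$true_identity == 100))
})

test_that("read provenance follows the abundance model", {
  g <- tibble::tibble(genus = c("A", "B"), superkingdom = "Bacterial",
                      abundance = c(0.7, 0.3), genome_bp = 5000, gc = 0.5)
  spec <- community_spec(g, n_reads = 10000, read_length_bp = 60, seed = 5)
  ref <- generate_reference_collection(spec)
  sim <- simulate_reads(ref$genomes, spec)
  n_a <- sum(sim$truth$genus == "A")
  expect_gt(n_a, stats::qbinom(0.005, 10000, 0.7))
  expect_lt(n_a, stats::qbinom(0.995, 10000, 0.7))
})

test_that("read errors accumulate at the configured per-base rate", {
  g <- tibble::tibble(genus = "A", superkingdom = "Bacterial", abundance = 1,
                      genome_bp = 5000, gc = 0.5)
  spec <- community_spec(g, n_reads = 2000, read_length_bp = 100,
                         read_error_rate = 0.01, seed = 6)
  ref <- generate_reference_collection(spec)
  sim <- simulate_reads(ref$genomes, spec)
  # mean of Binomial(100, 0.01) is 1 error per read
  expect_equal(mean(sim$truth$n_errors), 1.0, tolerance = 0.15)
  expect_equal(mean(sim$truth$true_identity), 99, tolerance = 0.15)
})

test_that("simulation is byte-identical under a fixed seed", {
  spec <- demo_spec(n_reads = 25, read_error_rate = 0.01,
                    strain_divergence = 0.02, seed = 77)
  run <- function() {
    ref <- generate_reference_collection(spec)
    strains <- mutate_strain(ref$genomes, spec$strain_divergence, seed = spec$seed)
    simulate_reads(strains, spec)
  }
  expect_identical(run(), run())
})

test_that("feature-count simulation respects proportions and drops zeros", {
  p <- matrix(c(0.5, 0.3, 0.2, 0.1, 0.2, 0.7), 2, byrow = TRUE,
              dimnames = list(c("m1", "m2"), c("f1", "f2", "f3")))
  counts <- simulate_feature_counts(p, n_annotations = 400, seed = 9)
  expect_true(all(counts$count > 0))
  tot <- dplyr::count(counts, metagenome, wt = count)
  expect_true(all(tot$n == 400))
  expect_error(simulate_feature_counts(p * 2), "sum to 1")
})
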