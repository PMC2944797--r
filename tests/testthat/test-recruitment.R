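test_that("pseudogenome concatenation orders contigs and maps coordinates", {
  contigs <- seq_tbl(c("big", "small"),
                     c(random_dna(100, seed = 60), random_dna(50, seed = 61)))
  pg <- build_pseudogenome(contigs, "draft", order = "ascending")
  expect_equal(pg$contigs$contig_id, c("small", "big"))
  expect_equal(pg$contigs$offset, c(0, 50))
  expect_equal(pg$total, 150)

  # global position 120 lives in the big contig at local 70, and back
  hit <- pseudo_to_contig(pg, 120)
  expect_equal(hit$contig_id, "big")
  expect_equal(hit$local, 70)
  expect_equal(contig_to_pseudo(pg, "big", 70), 120)

  desc <- build_pseudogenome(contigs, "draft", order = "descending")
  expect_equal(desc$contigs$contig_id, c("big", "small"))
  expect_equal(desc$contigs$offset, c(0, 100))

  expect_error(build_pseudogenome(contigs[0, ]), "empty")
  expect_error(pseudo_to_contig(pg, 150), "outside")
})

test_that("coordinate round-trips are the identity for every position", {
  contigs <- seq_tbl(c("a", "b", "c"),
                     c(random_dna(30, seed = 62), random_dna(20, seed = 63),
                       random_dna(25, seed = 64)))
  pg <- build_pseudogenome(contigs, "draft")
  pos <- 0:(pg$total - 1)
  mapped <- pseudo_to_contig(pg, pos)
  expect_equal(contig_to_pseudo(pg, mapped$contig_id, mapped$local), pos)
})

test_that("error-free reads recruit at full identity to their true position", {
  genome <- seq_tbl("gA", random_dna(8000, seed = 65))
  other <- seq_tbl("gB", random_dna(8000, seed = 66))
  pgA <- build_pseudogenome(genome, "gA")
  pgB <- build_pseudogenome(other, "gB")
  read <- seq_tbl("r1", substr(genome$seq, 3001, 3250))
  rr <- recruit_reads(read, list(pgA, pgB))
  expect_equal(rr$reads$genome_id, "gA")
  expect_equal(rr$reads$identity, 100)
  expect_equal(rr$reads$position, 3000)
  expect_equal(as.character(rr$reads$band), "95-100")
})

test_that("reads recruit to the closer of two related genomes", {
  ref <- seq_tbl("base", random_dna(8000, seed = 67))
  far <- mutate_strain(ref, 0.10, seed = 68, suffix = "_far")
  near <- mutate_strain(ref, 0.01, seed = 69, suffix = "_near")
  read <- seq_tbl("r1", substr(ref$seq, 2001, 2250))
  rr <- recruit_reads(read, list(build_pseudogenome(far, "far"),
                                 build_pseudogenome(near, "near")))
  expect_equal(rr$reads$genome_id, "near")
})

test_that("unrelated reads are excluded rather than force-recruited", {
  genome <- seq_tbl("gA", random_dna(5000, seed = 70))
  rr <- recruit_reads(seq_tbl("noise", random_dna(250, seed = 71)),
                      list(build_pseudogenome(genome, "gA")))
  expect_equal(nrow(rr$reads), 0)
  expect_equal(glance(rr)$n_recruited, 0)
})

test_that("identity banding follows half-open intervals with a closed top", {
  cfg <- run_config()
  reads <- tibble::tibble(
    read_id = paste0("r", 1:5), genome_id = "g", position = 0L,
    identity = c(99, 99, 97, 95, 74),
    junction = FALSE
  )
  reads$band <- hortus:::.assign_bands(reads$identity, cfg$identity_bands)
  rr <- structure(list(reads = reads, genomes = list(), bands = cfg$identity_bands,
                       cutoff = 98, n_input_reads = 5),
                  class = "recruitment_result")
  bs <- band_summary(rr)
  expect_equal(bs$`95-100`, 4)     # 95.0 sits in the top band
  expect_equal(bs$below_range, 1)  # 74 falls under the lowest band
  expect_equal(bs$n_above_cutoff, 2)  # >98 is strict
  expect_equal(bs$fraction_above_cutoff, 2 / 5)
  # conservation: bands + below-range = total
  band_cols <- setdiff(names(bs), c("genome_id", "total", "n_above_cutoff",
                                    "fraction_above_cutoff"))
  expect_equal(sum(bs[, band_cols]), bs$total)
})

test_that("band counts conserve the recruited total on simulated data", {
  ref <- seq_tbl("g", random_dna(20000, seed = 72))
  strain <- mutate_strain(ref, 0.05, seed = 73)
  spec <- community_spec(
    tibble::tibble(genus = "g", superkingdom = "Bacterial", abundance = 1,
                   genome_bp = 20000, gc = 0.5),
    n_reads = 80, read_length_bp = 200, seed = 74
  )
  sim <- simulate_reads(strain, spec)
  rr <- recruit_reads(sim$reads, list(build_pseudogenome(ref, "g")))
  bs <- band_summary(rr)
  band_cols <- setdiff(names(bs), c("genome_id", "total", "n_above_cutoff",
                                    "fraction_above_cutoff"))
  expect_equal(sum(bs[, band_cols]), bs$total)
  expect_equal(sum(bs$total), nrow(rr$reads))
})

test_that("identity summaries use sample statistics and a strict floor", {
  reads <- tibble::tibble(
    read_id = paste0("r", 1:102),
    genome_id = c(rep("gA", 2), rep("gB", 100)),
    position = 0L,
    identity = c(98, 100, rep(99, 100)),
    band = factor("95-100"),
    junction = FALSE
  )
  rr <- structure(list(reads = reads, genomes = list(), bands = list(c(95, 100)),
                       cutoff = 98, n_input_reads = 102),
                  class = "recruitment_result")
  s_all <- identity_summary(rr, min_reads = 1)
  expect_equal(s_all$mean_identity[s_all$genome_id == "gA"], 99)
  expect_equal(s_all$sd_identity[s_all$genome_id == "gA"], sqrt(2))
  # "more than min_reads" is strict: gB has exactly 100 reads
  s100 <- identity_summary(rr, min_reads = 100)
  expect_false("gB" %in% s100$genome_id)
})

test_that("mean recruited identity tracks strain divergence", {
  delta <- 0.02
  ref <- seq_tbl("g", random_dna(15000, seed = 75))
  strain <- mutate_strain(ref, delta, seed = 76)
  spec <- community_spec(
    tibble::tibble(genus = "g", superkingdom = "Bacterial", abundance = 1,
                   genome_bp = 15000, gc = 0.5),
    n_reads = 60, read_length_bp = 250, seed = 77
  )
  sim <- simulate_reads(strain, spec)
  rr <- recruit_reads(sim$reads, list(build_pseudogenome(ref, "g")))
  s <- identity_summary(rr, min_reads = 10)
  expect_equal(s$mean_identity, 100 * (1 - delta), tolerance = 0.01)
})

test_that("junction-spanning alignments are flagged, not dropped", {
  left <- random_dna(400, seed = 78)
  right <- random_dna(500, seed = 79)
  contigs <- seq_tbl(c("c1", "c2"), c(left, right))
  pg <- build_pseudogenome(contigs, "draft", order = "ascending")
  spanning <- seq_tbl("r_span", substr(pg$seq, 351, 500))  # crosses offset 400
  rr <- recruit_reads(spanning, list(pg))
  expect_equal(nrow(rr$reads), 1)
  expect_true(rr$reads$junction)
  inside <- seq_tbl("r_in", substr(pg$seq, 1, 150))
  expect_false(recruit_reads(inside, list(pg))$reads$junction)
})

test_that("GC tracks are centred, tile the genome, and expose islands", {
  # homogeneous genome: deviations hover near zero
  pg <- build_pseudogenome(seq_tbl("g", random_dna(30000, gc = 0.5, seed = 80)), "g")
  tr <- gc_track(pg, window = 5000, step = 1000)
  # 99% binomial band for a 5,000 bp window at p = 0.5 is about +/- 1.8 points
  expect_true(all(abs(tr$deviation) < 2.5))
  expect_equal(tr$start, seq(0, by = 1000, length.out = nrow(tr)))
  expect_equal(dplyr::last(tr$end), pg$total)

  # a planted GC-rich island shows contiguous positive deviations
  island_seq <- paste0(random_dna(10000, gc = 0.45, seed = 81),
                       random_dna(10000, gc = 0.70, seed = 82),
                       random_dna(10000, gc = 0.45, seed = 83))
  pg2 <- build_pseudogenome(seq_tbl("isl", island_seq), "isl")
  tr2 <- gc_track(pg2, window = 5000, step = 2500)
  inside <- tr2$start >= 10000 & tr2$end <= 20000
  expect_true(all(tr2$deviation[inside] > 5))
  expect_true(all(tr2$deviation[tr2$end <= 10000] < 0))
  expect_error(gc_track(pg2, window = 40000), "exceeds")
})
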