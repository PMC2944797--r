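# Shared fixture builders. Everything is generated in code at test time.

random_dna <- function(n, gc = 0.5, seed = NULL) {
  draw <- function() {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

random_protein <- function(n, seed = NULL) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  draw <- function() paste(sample(aa, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# A small three-genus bacterial community with distinct genomes.
demo_spec <- function(n_reads = 60L, read_error_rate = 0,
                      strain_divergence = 0, seed = 42L,
                      genome_bp = 12000L) {
  community_spec(
    tibble::tibble(
      genus = c("Klebsiella", "Pantoea", "Burkholderia"),
      superkingdom = "Bacterial",
      abundance = c(0.5, 0.3, 0.2),
      genome_bp = genome_bp,
      gc = c(0.57, 0.55, 0.62)
    ),
    strain_divergence = strain_divergence,
    read_length_bp = 150L,
    read_error_rate = read_error_rate,
    n_reads = n_reads,
    seed = seed
  )
}

# Substitute exactly `k` positions of a sequence (chosen reproducibly).
substitute_at <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  alts <- c(A = "C", C = "G", G = "T", T = "A")
  chars[positions] <- alts[chars[positions]]
  paste(chars, collapse = "")
}

expect_sisters <- function(tree, a, b) {
  nb <- nearest_neighbors(tree)
  expect_equal(nb$nearest[nb$metagenome == a], b)
}

are_sisters <- function(tree, a, b) {
  nb <- nearest_neighbors(tree)
  identical(nb$nearest[nb$metagenome == a], b)
}
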