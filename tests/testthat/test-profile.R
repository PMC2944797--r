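test_that("profile matrices are row-normalized over the feature union", {
  counts <- tibble::tibble(
    metagenome = c("m1", "m1", "m2"),
    feature = c("GH1", "GH8", "CE4"),
    count = c(3, 1, 5)
  )
  p <- build_profile_matrix(counts)
  m <- as.matrix(p[, -1])
  expect_equal(unname(rowSums(m)), c(1, 1))
  expect_equal(p$GH1[p$metagenome == "m1"], 0.75)
  # disjoint features: orthogonal non-zero supports
  expect_equal(p$CE4, c(0, 1))
  expect_equal(p$GH1[p$metagenome == "m2"], 0)
  # degenerate single-feature metagenome normalizes to 1
  single <- build_profile_matrix(tibble::tibble(metagenome = "m", feature = "GH1",
                                                count = 7))
  expect_equal(single$GH1, 1)
  expect_error(build_profile_matrix(dplyr::mutate(counts, count = 0)),
               "zero annotations")
  expect_error(build_profile_matrix(counts[c(1, 1, 2), ]), "duplicate")
})

test_that("one row of published-scale family counts normalizes correctly", {
  counts <- cazy_metagenome_counts()
  p <- build_profile_matrix(
    tibble::tibble(metagenome = "fungus_garden", feature = counts$family_id,
                   count = counts$count)
  )
  expect_equal(sum(p[, -1]), 1, tolerance = 1e-9)
  expect_equal(p$GH1[[1]], 14 / 69)
})

test_that("correlation similarity matches direct rank computation", {
  m <- tibble::tibble(
    metagenome = c("a", "b"),
    f1 = c(0.5, 0.1), f2 = c(0.2, 0.2), f3 = c(0.1, 0.3),
    f4 = c(0.1, 0.3), f5 = c(0.1, 0.1)
  )
  class(m) <- c("profile_matrix", class(m))
  sim <- correlation_similarity(m, "spearman")
  expect_equal(sim["a", "b"],
               spearman_oracle(c(0.5, 0.2, 0.1, 0.1, 0.1),
                               c(0.1, 0.2, 0.3, 0.3, 0.1)),
               tolerance = 1e-12)
  expect_equal(diag(sim), c(a = 1, b = 1))
  expect_equal(sim, t(sim))

  # identical rows correlate at 1; reversed ranks at -1
  m2 <- tibble::tibble(metagenome = c("a", "b", "c"),
                       f1 = c(0.5, 0.5, 0.1), f2 = c(0.3, 0.3, 0.3),
                       f3 = c(0.2, 0.2, 0.6))
  sim2 <- correlation_similarity(m2, "spearman")
  expect_equal(sim2["a", "b"], 1)
  expect_equal(sim2["a", "c"], -1)

  flat <- tibble::tibble(metagenome = c("a", "flatliner"),
                         f1 = c(0.5, 1 / 3), f2 = c(0.3, 1 / 3),
                         f3 = c(0.2, 1 / 3))
  expect_error(correlation_similarity(flat), "flatliner")
})

test_that("similarity converts to 1 - r distance with exact bounds", {
  sim <- matrix(c(1, 1, -1, 1, 1, -1, -1, -1, 1), 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d <- similarity_to_distance(sim)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(attr(d, "transform"), "1 - r")
})

test_that("UPGMA reproduces hand-computed agglomerations", {
  # two leaves: forced result
  d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(ape::write.tree(t2), "(A:2,B:2);")

  # three leaves: merge A,B at 2, then C at 6
  d3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_equal(ape::write.tree(t3), "((A:1,B:1):2,C:3);")
  coph <- ape::cophenetic.phylo(t3)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 6)
})

test_that("UPGMA equals the brute-force oracle on random matrices", {
  withr::with_seed(50, {
    for (rep in 1:50) {
      n <- sample(3:6, 1)
      labs <- paste0("m", seq_len(n))
      d <- as.matrix(stats::dist(matrix(stats::runif(n * 4), n)))
      dimnames(d) <- list(labs, labs)
      tree <- upgma(d)
      coph <- ape::cophenetic.phylo(tree)[labs, labs]
      expect_equal(coph, upgma_cophenetic_oracle(d), tolerance = 1e-9)
    }
  })
})

test_that("UPGMA agrees with average-linkage hclust heights", {
  withr::with_seed(51, {
    n <- 8
    labs <- paste0("m", 1:n)
    d <- as.matrix(stats::dist(matrix(stats::runif(n * 4), n)))
    dimnames(d) <- list(labs, labs)
  })
  tree <- upgma(d)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  expect_equal(sort(attr(tree, "heights")), sort(hc$height), tolerance = 1e-9)
})

test_that("ultrametric inputs round-trip exactly through UPGMA", {
  withr::with_seed(52, {
    for (rep in 1:10) {
      phy <- ape::rcoal(6)
      phy$tip.label <- paste0("t", 1:6)
      coph <- ape::cophenetic.phylo(phy)[phy$tip.label, phy$tip.label]
      tree <- upgma(coph)
      back <- ape::cophenetic.phylo(tree)[phy$tip.label, phy$tip.label]
      expect_equal(back, coph, tolerance = 1e-9)
    }
  })
})

test_that("trees are ultrametric with n - 1 merges and order-stable", {
  withr::with_seed(53, {
    n <- 7
    labs <- paste0("m", 1:n)
    d <- as.matrix(stats::dist(matrix(stats::runif(n * 4), n)))
    dimnames(d) <- list(labs, labs)
  })
  tree <- upgma(d)
  g <- glance(tree)
  expect_true(g$ultrametric)
  expect_equal(g$n_merges, n - 1)
  # permuting the input leaves the tree invariant
  perm <- sample(n)
  tree_p <- upgma(d[perm, perm])
  expect_equal(ape::cophenetic.phylo(tree_p)[labs, labs],
               ape::cophenetic.phylo(tree)[labs, labs], tolerance = 1e-12)
  expect_equal(ape::write.tree(tree_p), ape::write.tree(tree))
})

test_that("profile clustering pairs metagenomes sharing a family mixture", {
  counts <- dplyr::bind_rows(
    tibble::tibble(metagenome = "garden", feature = c("GH1", "GH8", "CE4"),
                   count = c(30, 20, 10)),
    tibble::tibble(metagenome = "rumen", feature = c("GH1", "GH8", "CE4"),
                   count = c(28, 22, 11)),
    tibble::tibble(metagenome = "soil", feature = c("GH19", "PL1", "CE8"),
                   count = c(40, 5, 3))
  )
  cl <- cluster_metagenomes(counts, method = "spearman")
  expect_sisters(cl$tree, "garden", "rumen")
  expect_equal(glance(cl)$n_metagenomes, 3)
})

test_that("CAZy- and COG-based trees can disagree on engineered profiles", {
  # CAZy profiles: A~B convergent, C~D convergent
  cazy <- dplyr::bind_rows(
    tibble::tibble(metagenome = "A", feature = c("GH1", "GH8", "CE4"), count = c(30, 5, 5)),
    tibble::tibble(metagenome = "B", feature = c("GH1", "GH8", "CE4"), count = c(29, 6, 5)),
    tibble::tibble(metagenome = "C", feature = c("GH1", "GH8", "CE4"), count = c(5, 30, 5)),
    tibble::tibble(metagenome = "D", feature = c("GH1", "GH8", "CE4"), count = c(6, 29, 5))
  )
  # COG profiles: A~C convergent, B~D convergent
  cog <- dplyr::bind_rows(
    tibble::tibble(metagenome = "A", feature = c("COG1", "COG2", "COG3"), count = c(40, 5, 5)),
    tibble::tibble(metagenome = "C", feature = c("COG1", "COG2", "COG3"), count = c(38, 6, 5)),
    tibble::tibble(metagenome = "B", feature = c("COG1", "COG2", "COG3"), count = c(5, 40, 5)),
    tibble::tibble(metagenome = "D", feature = c("COG1", "COG2", "COG3"), count = c(6, 38, 5))
  )
  t_cazy <- cluster_metagenomes(cazy, "pearson")$tree
  t_cog <- cluster_metagenomes(cog, "pearson")$tree
  expect_true(are_sisters(t_cazy, "A", "B"))
  expect_true(are_sisters(t_cog, "A", "C"))
  expect_false(are_sisters(t_cog, "A", "B"))
})
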