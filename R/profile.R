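# Proportion-profile comparison across metagenomes: feature counts ->
# row-normalized profile matrix -> correlation similarity -> 1 - r distance
# -> UPGMA tree, plus the composed clustering driver with nearest-neighbour
# reporting.

#' Build a metagenome-by-feature proportion matrix
#'
#' Each cell is the proportion of that feature among all annotated features
#' of the metagenome; columns are the union of observed features, with
#' absent features at 0, so every row sums to 1.
#'
#' @param counts A long tibble `metagenome`, `feature`, `count` (counts >
#'   0; a metagenome with zero annotations is an error).
#' @return A `profile_matrix` tibble: first column `metagenome`, one column
#'   per feature.
#' @export
build_profile_matrix <- function(counts) {
  counts <- as_tibble(counts)
  need <- c("metagenome", "feature", "count")
  if (!all(need %in% names(counts))) {
    abort("`counts` needs columns metagenome, feature, count")
  }
  if (any(counts$count < 0)) abort("counts must be non-negative")
  totals <- counts |>
    group_by(.data$metagenome) |>
    summarise(total = sum(.data$count), .groups = "drop")
  empty <- totals$metagenome[totals$total == 0]
  if (length(empty)) {
    abort(sprintf("metagenome(s) with zero annotations: %s", .oxford(empty)))
  }
  if (anyDuplicated(counts[, c("metagenome", "feature")])) {
    abort("duplicate (metagenome, feature) rows in `counts`")
  }
  wide <- counts |>
    left_join(totals, by = "metagenome") |>
    mutate(proportion = .data$count / .data$total) |>
    select("metagenome", "feature", "proportion") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "proportion",
                       values_fill = 0, names_sort = TRUE) |>
    arrange(.data$metagenome)
  structure(wide, class = c("profile_matrix", class(wide)))
}

.profile_as_matrix <- function(profile) {
  if (!"metagenome" %in% names(profile)) {
    abort("`profile` must carry a metagenome column (see build_profile_matrix)")
  }
  m <- as.matrix(profile[, setdiff(names(profile), "metagenome")])
  rownames(m) <- profile$metagenome
  storage.mode(m) <- "double"
  m
}

#' Correlation similarity between metagenome profiles
#'
#' Pairwise row correlations of the proportion matrix. Spearman (the
#' default) uses mid-ranks, which carries the usual tie correction.
#'
#' @param profile A `profile_matrix` (>= 2 rows, >= 3 feature columns).
#' @param method `"spearman"` or `"pearson"`.
#' @return A symmetric similarity matrix with unit diagonal, entries in
#'   \[-1, 1\], dimnames = metagenome ids.
#' @export
correlation_similarity <- function(profile, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- .profile_as_matrix(profile)
  if (nrow(m) < 2L) abort("need at least 2 metagenomes")
  if (ncol(m) < 3L) abort("need at least 3 features")
  flat <- apply(m, 1, stats::var) == 0
  if (any(flat)) {
    abort(sprintf("zero-variance profile row(s): %s",
                  .oxford(rownames(m)[flat])))
  }
  sim <- cor(t(m), method = method)
  diag(sim) <- 1
  sim
}

#' Convert a similarity matrix to a distance matrix
#'
#' Uses d = 1 - r, the simplest monotone transform; it is recorded as the
#' `transform` attribute of the result. 1 - r need not satisfy the triangle
#' inequality; violations are reported with a message, never rejected.
#'
#' @param sim A symmetric similarity matrix with unit diagonal.
#' @return A distance matrix (zero diagonal) with attribute
#'   `transform = "1 - r"`.
#' @export
similarity_to_distance <- function(sim) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim)) abort("`sim` must be square")
  if (max(abs(sim - t(sim))) > 1e-12) abort("`sim` must be symmetric")
  d <- 1 - sim
  diag(d) <- 0
  n <- nrow(d)
  if (n >= 3) {
    viol <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      if (d[i, j] > d[i, k] + d[k, j] + 1e-12) viol <- TRUE
    }
    if (viol) inform("1 - r distances violate the triangle inequality (logged, not rejected)")
  }
  attr(d, "transform") <- "1 - r"
  d
}

#' UPGMA hierarchical clustering
#'
#' Classic unweighted pair-group agglomeration: repeatedly merge the closest
#' pair of clusters; the distance from a merged cluster to any other is the
#' size-weighted average of its parts, which equals the mean of the original
#' pairwise distances between member sets. Equal-distance ties merge the
#' lexicographically smallest eligible pair (clusters ordered by their
#' smallest leaf label), making the output deterministic. Branch lengths are
#' half the merge distance minus the child's height, so the tree is
#' ultrametric and cophenetic distances reproduce the merge heights.
#'
#' The tree is rooted (UPGMA is inherently rooted); consumers that want an
#' unrooted view may unroot it downstream.
#'
#' @param dist A symmetric distance matrix with labelled rows/columns, or a
#'   [stats::dist] object; n >= 2.
#' @return A rooted, ultrametric `phylo` object (class
#'   `c("hortus_tree", "phylo")`) with a `heights` attribute naming each
#'   merge height.
#' @export
#'
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(upgma(d))
upgma <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (!is.matrix(dist) || nrow(dist) != ncol(dist)) abort("`dist` must be square")
  if (max(abs(dist - t(dist))) > 1e-12) abort("`dist` must be symmetric")
  n <- nrow(dist)
  if (n < 2L) abort("need at least 2 leaves")
  labels <- rownames(dist) %||% paste0("L", seq_len(n))
  if (anyDuplicated(labels)) abort("leaf labels must be unique")

  d <- dist
  dimnames(d) <- NULL
  active <- seq_len(n)
  size <- rep(1L, n)
  height <- rep(0, n)
  newick <- labels
  minlab <- labels                       # smallest leaf label per cluster
  merge_heights <- numeric(0)

  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        dij <- d[i, j]
        lab <- sort(c(minlab[i], minlab[j]))
        if (is.null(best) || dij < best$d - 1e-15 ||
            (abs(dij - best$d) <= 1e-15 &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- list(i = i, j = j, d = dij, lab = lab)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    bl_i <- h - height[i]
    bl_j <- h - height[j]
    # order children by smallest leaf label for a canonical newick
    kids <- if (minlab[i] <= minlab[j]) {
      c(sprintf("%s:%.12g", newick[i], bl_i), sprintf("%s:%.12g", newick[j], bl_j))
    } else {
      c(sprintf("%s:%.12g", newick[j], bl_j), sprintf("%s:%.12g", newick[i], bl_i))
    }
    new <- length(size) + 1L
    size <- c(size, size[i] + size[j])
    height <- c(height, h)
    newick <- c(newick, sprintf("(%s,%s)", kids[1], kids[2]))
    minlab <- c(minlab, min(minlab[i], minlab[j]))
    merge_heights <- c(merge_heights, best$d)

    # weighted-average update against every other active cluster
    d <- rbind(cbind(d, 0), 0)
    others <- setdiff(active, c(i, j))
    for (o in others) {
      d[new, o] <- d[o, new] <-
        (size[i] * d[i, o] + size[j] * d[j, o]) / (size[i] + size[j])
    }
    active <- c(others, new)
  }
  tree <- ape::read.tree(text = paste0(newick[length(newick)], ";"))
  class(tree) <- c("hortus_tree", "phylo")
  attr(tree, "heights") <- merge_heights
  tree
}

#' Sister (nearest-neighbour) report for a tree
#'
#' For each leaf, the set of leaves in its sister clade at its first merge.
#'
#' @param tree A rooted `phylo` tree.
#' @return A tibble `metagenome`, `nearest` (comma-joined sister leaves).
#' @export
nearest_neighbors <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  list_rbind(map(seq_along(tips), function(i) {
    parent <- tree$edge[tree$edge[, 2] == i, 1]
    kids <- tree$edge[tree$edge[, 1] == parent, 2]
    sisters <- setdiff(kids, i)
    sis_tips <- sort(unlist(map(sisters, function(s) {
      if (s <= length(tips)) tips[s] else ape::extract.clade(tree, s)$tip.label
    })))
    tibble(metagenome = tips[i], nearest = paste(sis_tips, collapse = ","))
  }))
}

#' Cluster metagenomes by proportion profiles
#'
#' The composed procedure: feature counts -> proportion profile ->
#' correlation similarity -> 1 - r distance -> UPGMA tree, plus each
#' metagenome's nearest neighbour (its sister at its first merge).
#'
#' @param counts A long tibble `metagenome`, `feature`, `count` covering >=
#'   3 metagenomes.
#' @param method Correlation method, `"spearman"` or `"pearson"`.
#' @return A `metagenome_clustering` list: `profile`, `similarity`,
#'   `distance`, `tree`, `neighbors`, `method`.
#' @export
cluster_metagenomes <- function(counts, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  profile <- build_profile_matrix(counts)
  if (nrow(profile) < 3L) abort("need at least 3 metagenomes to cluster")
  sim <- correlation_similarity(profile, method)
  dist <- similarity_to_distance(sim)
  tree <- upgma(dist)
  structure(
    list(profile = profile, similarity = sim, distance = dist, tree = tree,
         neighbors = nearest_neighbors(tree), method = method),
    class = "metagenome_clustering"
  )
}

#' @export
print.metagenome_clustering <- function(x, ...) {
  cat(sprintf("<metagenome_clustering> %d metagenomes, %d features, %s correlation\n",
              nrow(x$profile), ncol(x$profile) - 1L, x$method))
  cat(ape::write.tree(x$tree), "\n")
  invisible(x)
}

#' @export
glance.metagenome_clustering <- function(x, ...) {
  tibble(
    n_metagenomes = nrow(x$profile),
    n_features = ncol(x$profile) - 1L,
    method = x$method,
    tree_height = max(attr(x$tree, "heights")) / 2
  )
}

#' @export
tidy.metagenome_clustering <- function(x, ...) {
  x$neighbors
}
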