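# ggplot2 views of the pipeline's result types. Trees render through ape's
# plot.phylo (the natural device for dendrograms); the tabular results get
# autoplot methods.

#' @export
autoplot.gc_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = (.data$bin_low + .data$bin_high) / 2, y = .data$count
  )) +
    ggplot2::geom_col(width = object$bin_high[1] - object$bin_low[1],
                      fill = "grey35") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group), scales = "free_y") +
    ggplot2::labs(x = "GC content (%)", y = "Sequences") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.recruitment_result <- function(object, ...) {
  ggplot2::ggplot(object$reads, ggplot2::aes(
    x = .data$position, y = .data$identity, colour = .data$band
  )) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$genome_id), ncol = 1) +
    ggplot2::labs(x = "Pseudogenome position (bp)",
                  y = "Percent identity", colour = "Identity band") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gc_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = (.data$start + .data$end) / 2, y = .data$deviation,
    fill = .data$deviation > 0
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "darkgreen",
                                          `FALSE` = "darkolivegreen4")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$genome_id), ncol = 1) +
    ggplot2::labs(x = "Pseudogenome position (bp)",
                  y = "GC deviation from genome mean (%)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.profile_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"metagenome",
                              names_to = "feature", values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$feature, y = .data$metagenome, fill = .data$proportion
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Feature", y = "Metagenome", fill = "Proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Tidy a cluster tree
#'
#' @param x A tree from [upgma()].
#' @param ... Unused.
#' @return A tibble of edges: `parent`, `node`, `branch_length`, `label`
#'   (leaf label or `NA` for internal nodes).
#' @export
tidy.hortus_tree <- function(x, ...) {
  tibble(
    parent = x$edge[, 1],
    node = x$edge[, 2],
    branch_length = x$edge.length,
    label = ifelse(x$edge[, 2] <= length(x$tip.label),
                   x$tip.label[x$edge[, 2]], NA_character_)
  )
}

#' @export
glance.hortus_tree <- function(x, ...) {
  depths <- ape::node.depth.edgelength(x)
  tip_depths <- depths[seq_along(x$tip.label)]
  tibble(
    n_leaves = length(x$tip.label),
    n_merges = x$Nnode,
    tree_height = max(tip_depths),
    ultrametric = diff(range(tip_depths)) < 1e-8
  )
}
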