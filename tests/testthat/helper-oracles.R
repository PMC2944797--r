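# Independent oracles used to cross-check the package's implementations.
# These deliberately use different algorithms from the package code paths.

# Brute-force UPGMA oracle: cluster distances are recomputed each round as
# the plain mean of ORIGINAL pairwise distances between member sets (the
# defining property of unweighted average linkage), rather than by the
# incremental weighted update the package uses. Returns the cophenetic
# matrix, which determines the ultrametric tree uniquely.
upgma_cophenetic_oracle <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- c(NA, NA)
    best_d <- Inf
    best_lab <- c("￿", "￿")
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        dm <- mean(d[clusters[[i]], clusters[[j]]])
        lab <- sort(c(min(labels[clusters[[i]]]), min(labels[clusters[[j]]])))
        better <- dm < best_d - 1e-15 ||
          (abs(dm - best_d) <= 1e-15 &&
           (lab[1] < best_lab[1] || (lab[1] == best_lab[1] && lab[2] < best_lab[2])))
        if (better) {
          best <- c(i, j); best_d <- dm; best_lab <- lab
        }
      }
    }
    for (a in clusters[[best[1]]]) for (b in clusters[[best[2]]]) {
      coph[a, b] <- coph[b, a] <- best_d
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Full Gotoh (affine-gap) Smith-Waterman best local score, pure R.
# Scoring mirrors the nucleotide engine: match +1, mismatch -1, gap of
# length L costs open + L * ext (open 1, ext 1 => -2 first, -1 after).
sw_score_oracle <- function(a, b, match = 1, mismatch = -1, open = 1, ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in a (horizontal)
  F <- matrix(-Inf, n + 1L, m + 1L)  # gap in b (vertical)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
      F[i, j] <- max(H[i - 1L, j] - open - ext, F[i - 1L, j] - ext)
      s <- if (a[i - 1L] == b[j - 1L]) match else mismatch
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Tie-corrected Spearman rank correlation computed from first principles
# (mid-ranks + Pearson on the ranks), independent of stats::cor's shortcut.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
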