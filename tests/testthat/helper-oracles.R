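# Independent oracles used to cross-check the package's own implementations.
# Each is written as a direct, naive computation that shares no code with
# the implementation path it checks.

# Naive substring k-mer counter: O(N * k) scan.
naive_count_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(integer(0))
  words <- substring(seq, 1:(n - k + 1), k:n)
  table(words)
}

# IUPAC motif occurrence starts (0-based) via regex with lookahead so
# overlapping matches are all found.
regex_iupac_starts <- function(seq, consensus) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
               S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
               D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  pat <- paste(vapply(strsplit(consensus, "")[[1]],
                      function(ch) paste0("[", sets[[ch]], "]"), character(1)),
               collapse = "")
  m <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# Exact PWM score tail by exhaustive enumeration of all 4^w words on the
# same integer score grid as the DP (grid rounding is part of the contract).
enumerate_pwm_tail <- function(pwm, background, pseudocount = 1e-4, step = 1e-3) {
  p <- sweep(pwm + pseudocount, 2, colSums(pwm + pseudocount), "/")
  ints <- round(log2(p / background) / step)
  w <- ncol(pwm)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(words))
  probs <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    scores[i] <- sum(ints[cbind(words[i, ], seq_len(w))])
    probs[i] <- prod(background[words[i, ]])
  }
  function(int_threshold) sum(probs[scores >= int_threshold])
}

# Hypergeometric upper-tail enumeration for a 2x2 enrichment table.
enumerate_fisher_tail <- function(a_with, a_without, b_with, b_without) {
  k_white <- a_with + b_with
  k_black <- a_without + b_without
  n_draw <- a_with + a_without
  xs <- a_with:min(n_draw, k_white)
  sum(stats::dhyper(xs, k_white, k_black, n_draw))
}

# Textbook UPGMA recomputation: matrix-indexed, no label tie-breaking
# cleverness (callers use continuous random distances so ties do not occur).
# Returns merge heights (sorted) and the leaf partition after each merge.
naive_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  D <- d
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (D[i, j] < best[1]) best <- c(D[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights[s] <- best[1] / 2
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    newd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]), c(newd[keep], 0))
    clusters <- c(clusters[keep], list(sort(c(clusters[[i]], clusters[[j]]))))
    partitions[[s]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# Leaf sets of every internal node of an hclust-style tree, as leaf indices.
tree_leaf_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  for (s in seq_len(nrow(tree$merge))) {
    get <- function(x) if (x < 0) -x else sets[[x]]
    sets[[s]] <- sort(c(get(tree$merge[s, 1]), get(tree$merge[s, 2])))
  }
  sets
}

random_acgt <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Small wide-format count fixture: 2 genes x 5 segments x n replicates.
wide_counts_fixture <- function(n_rep = 1) {
  cols <- as.vector(outer(c("A", "B", "C", "D", "E"), seq_len(n_rep),
                          function(s, r) paste0(s, "_r", r)))
  vals <- matrix(seq_len(2 * length(cols)) * 1.5, nrow = 2)
  out <- tibble::as_tibble(as.data.frame(vals))
  names(out) <- cols
  dplyr::bind_cols(tibble::tibble(gene_id = c("g1", "g2")), out)
}

classification_accuracy <- function(labels, truth) {
  m <- dplyr::inner_join(dplyr::rename(labels, called = category),
                         truth[, c("gene_id", "category")], by = "gene_id")
  mean(as.character(m$called) == m$category)
}
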