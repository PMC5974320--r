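# Motif family construction.
#
# Motifs (as PWMs; IUPAC consensi are 0/1-normalized first) are compared by
# ungapped alignment: slide one over the other and score each offset by the
# mean per-column Pearson correlation of the aligned probability columns,
# keeping the best offset with at least `min_overlap` aligned columns.
# 1 - best correlation is an alignment distance in [0, 2]; a UPGMA
# dendrogram over that distance is cut at a user height into families, and
# each family gets a consensus profile by aligning members to the family's
# widest member and averaging columns.

col_correlation <- function(x, y, pseudocount = 1e-3, eps = 1e-12) {
  x <- (x + pseudocount) / (1 + 4 * pseudocount)
  y <- (y + pseudocount) / (1 + 4 * pseudocount)
  vx <- sum((x - mean(x))^2)
  vy <- sum((y - mean(y))^2)
  sum((x - mean(x)) * (y - mean(y))) / sqrt((vx + eps) * (vy + eps))
}

#' Best ungapped alignment similarity of two motifs
#'
#' Maximizes, over all offsets with at least `min_overlap` aligned columns,
#' the mean per-column Pearson correlation between the PWM columns. Columns
#' of a constant (zero-variance) profile contribute a correlation of 0.
#'
#' @param m1,m2 one-row motif tibbles (or IUPAC strings).
#' @param min_overlap minimum aligned columns (default 4).
#' @return list with `score` (in [-1, 1]) and `offset` (start of `m2`
#'   relative to `m1`, in columns; may be negative).
#' @export
motif_similarity <- function(m1, m2, min_overlap = 4) {
  m1 <- coerce_motif(m1); m2 <- coerce_motif(m2)
  p1 <- motif_pwm(m1, 1); p2 <- motif_pwm(m2, 1)
  w1 <- ncol(p1); w2 <- ncol(p2)
  if (min_overlap > min(w1, w2)) {
    abort(sprintf("min_overlap (%d) exceeds a motif width (%d)",
                  min_overlap, min(w1, w2)))
  }
  best <- list(score = -Inf, offset = NA_integer_)
  for (o in seq(-(w2 - min_overlap), w1 - min_overlap)) {
    j1 <- seq(max(1L, 1L + o), min(w1, w2 + o))
    j2 <- j1 - o
    r <- mean(vapply(seq_along(j1), function(i) {
      col_correlation(p1[, j1[i]], p2[, j2[i]])
    }, numeric(1)))
    if (r > best$score) best <- list(score = r, offset = as.integer(o))
  }
  best
}

#' Pairwise motif distance matrix (1 - best alignment correlation)
#'
#' @param motifs motif set tibble.
#' @param min_overlap passed to [motif_similarity()].
#' @return symmetric matrix with zero diagonal, entries in [0, 2];
#'   best-alignment offsets attached as attribute `"offsets"`.
#' @export
motif_distance_matrix <- function(motifs, min_overlap = 4) {
  n <- nrow(motifs)
  ids <- motifs$motif_id
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  off <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- motif_similarity(motifs[i, ], motifs[j, ], min_overlap)
        d[i, j] <- d[j, i] <- 1 - s$score
        off[i, j] <- s$offset
        off[j, i] <- -s$offset
      }
    }
  }
  structure(d, offsets = off)
}

#' UPGMA clustering of a motif distance matrix
#'
#' Standard unweighted pair-group average linkage: repeatedly merge the
#' closest pair; distances to the merged cluster are the size-weighted
#' arithmetic mean; node heights are half the merge distance (ultrametric).
#' Ties are broken deterministically by the lexicographically smallest pair
#' of cluster labels (a cluster is labelled by its smallest member id).
#'
#' @param d symmetric distance matrix with dimnames (e.g. from
#'   [motif_distance_matrix()]), n >= 2.
#' @return an `hclust`-compatible object (usable with [stats::cutree()] and
#'   `ape::as.phylo()`), heights on the half-distance scale.
#' @export
upgma <- function(d) {
  d <- unclass(d)
  n <- nrow(d)
  stopifnot(n >= 2, isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
  if (any(is.na(d))) abort("distance matrix contains NA")
  labels <- rownames(d) %||% as.character(seq_len(n))
  active <- seq_len(n)
  size <- rep(1L, n)
  node <- -seq_len(n)           # hclust convention: negative = leaf
  rep_label <- labels
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- NULL
    for (ii in seq_len(k - 1)) {
      for (jj in (ii + 1):k) {
        dij <- D[ii, jj]
        key <- sort(c(rep_label[ii], rep_label[jj]))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = ii, j = jj, d = dij, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- best$d / 2
    newD <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
               c(newD[keep], 0))
    size <- c(size[keep], size[i] + size[j])
    node <- c(node[keep], step)
    rep_label <- c(rep_label[keep], min(c(rep_label[i], rep_label[j])))
    active <- seq_len(k - 1)
  }
  structure(list(merge = merge, height = height,
                 order = hclust_order(merge, n), labels = labels,
                 method = "upgma", call = match.call(),
                 dist.method = "motif_alignment"),
            class = "hclust")
}

hclust_order <- function(merge, n) {
  unfold <- function(node) {
    if (node < 0) return(-node)
    c(unfold(merge[node, 1]), unfold(merge[node, 2]))
  }
  unfold(nrow(merge))
}

#' Cut a motif dendrogram into families and build familial consensus PWMs
#'
#' Subtrees entirely below `height` become families (the grouping the
#' original heatmaps drew by hand from the dendrogram). Each family's
#' consensus aligns every member to the family's widest member at their
#' pairwise best offset and averages the overlapping columns, renormalized.
#'
#' @param tree `hclust`-style tree from [upgma()].
#' @param motifs the motif set that was clustered (ids must match the tree
#'   labels).
#' @param height cut height (on the tree's half-distance scale); 0 makes
#'   every motif its own family.
#' @param min_overlap passed to [motif_similarity()] for consensus alignment.
#' @return tibble with one row per family: `family`, `n_members`, `members`
#'   (list of motif ids), `height` (highest merge inside the family),
#'   `consensus` (IUPAC), `pwm` (list).
#' @export
cut_families <- function(tree, motifs, height, min_overlap = 4) {
  stopifnot(height >= 0)
  membership <- stats::cutree(tree, h = height)
  ids <- names(membership)
  fams <- sort(unique(membership))
  rows <- map(fams, function(f) {
    members <- ids[membership == f]
    sub <- motifs[match(members, motifs$motif_id), ]
    heights <- tree$height[apply_family_heights(tree, members)]
    widest <- which.max(sub$width)
    ref_pwm <- motif_pwm(sub, widest)
    acc <- matrix(0, 4, ncol(ref_pwm))
    cover <- matrix(0, 4, ncol(ref_pwm))
    for (i in seq_len(nrow(sub))) {
      p <- motif_pwm(sub, i)
      o <- if (i == widest) 0L
           else motif_similarity(sub[widest, ], sub[i, ],
                                 min(min_overlap, min(sub$width)))$offset
      cols <- seq_len(ncol(p)) + o        # member column j sits at ref column j + o
      inside <- cols >= 1 & cols <= ncol(ref_pwm)
      acc[, cols[inside]] <- acc[, cols[inside]] + p[, inside, drop = FALSE]
      cover[, cols[inside]] <- cover[, cols[inside]] + 1
    }
    consensus_pwm <- acc / pmax(cover, 1)
    consensus_pwm <- sweep(consensus_pwm, 2, colSums(consensus_pwm), "/")
    rownames(consensus_pwm) <- DNA_BASES
    tibble(family = f, n_members = length(members), members = list(members),
           height = if (length(heights)) max(heights) else 0,
           consensus = pwm_consensus(consensus_pwm), pwm = list(consensus_pwm))
  })
  bind_rows(rows)
}

# Indices of merges whose leaves all belong to `members`.
apply_family_heights <- function(tree, members) {
  n <- length(tree$labels)
  leaf_sets <- vector("list", nrow(tree$merge))
  inside <- logical(nrow(tree$merge))
  for (s in seq_len(nrow(tree$merge))) {
    get <- function(x) if (x < 0) tree$labels[-x] else leaf_sets[[x]]
    leaf_sets[[s]] <- c(get(tree$merge[s, 1]), get(tree$merge[s, 2]))
    inside[s] <- all(leaf_sets[[s]] %in% members)
  }
  which(inside)
}

#' Write a motif dendrogram as newick
#'
#' @param tree tree from [upgma()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required to write newick trees")
  }
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
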