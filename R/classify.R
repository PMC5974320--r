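# Rule-based localization classification.
#
# RNA profiles over segments A..E (animal -> vegetal) are assigned one of
# five categories by published threshold rules on the gene's transcript
# fractions; proteins over A..D get one of four. All "maximum in X"
# comparisons are strict, so ties (degenerate flat profiles) fall through to
# "other". The extreme categories are checked before the broad ones because
# an extremely vegetal profile necessarily also satisfies the vegetal rules.

# Coerce long tibble / wide data frame / numeric vector to an n x k fraction
# matrix with gene ids (and replicate ids when present) as attributes.
profile_matrix <- function(x, segs) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != length(segs)) {
      abort(sprintf("expected %d fractions (segments %s)", length(segs),
                    paste(segs, collapse = "..")))
    }
    m <- matrix(x, nrow = 1, dimnames = list(NULL, segs))
    return(list(m = m, ids = NULL, reps = NULL, scalar = TRUE))
  }
  x <- as_tibble(x)
  if (all(c("gene_id", "segment") %in% names(x))) {
    valcol <- if ("fraction" %in% names(x)) "fraction" else "value"
    keys <- if ("replicate" %in% names(x)) c("gene_id", "replicate") else "gene_id"
    wide <- x |>
      select(dplyr::all_of(c(keys, "segment", valcol))) |>
      pivot_wider(names_from = "segment", values_from = dplyr::all_of(valcol))
    missing <- setdiff(segs, names(wide))
    if (length(missing)) {
      abort(sprintf("profile lacks segment(s): %s", paste(missing, collapse = ", ")))
    }
    m <- as.matrix(wide[, segs])
    return(list(m = m, ids = wide$gene_id,
                reps = if ("replicate" %in% names(wide)) wide$replicate else NULL))
  }
  missing <- setdiff(segs, names(x))
  if (length(missing)) {
    abort(sprintf("profile lacks segment column(s): %s", paste(missing, collapse = ", ")))
  }
  list(m = as.matrix(x[, segs]),
       ids = if ("gene_id" %in% names(x)) x$gene_id else NULL, reps = NULL)
}

validate_fractions <- function(m, normalize, tol = 1e-6) {
  if (any(m < 0, na.rm = TRUE)) abort("negative fraction")
  if (any(is.na(m))) abort("missing fraction")
  rs <- rowSums(m)
  if (normalize) {
    if (any(rs <= 0)) abort("profile with non-positive total")
    m <- m / rs
  } else if (any(abs(rs - 1) > tol)) {
    abort(sprintf("fractions must sum to 1 within %g (worst deviation %.3g)",
                  tol, max(abs(rs - 1))))
  }
  m
}

strict_max <- function(m, j) {
  others <- setdiff(seq_len(ncol(m)), j)
  Reduce(`&`, lapply(others, function(o) m[, j] > m[, o]))
}

rna_rule_matrix <- function(m) {
  A <- m[, "A"]; B <- m[, "B"]; C <- m[, "C"]; D <- m[, "D"]; E <- m[, "E"]
  cbind(
    extremely_animal = strict_max(m, 1) & (A + B) > (D + E) & (C > D | C > E),
    animal = strict_max(m, 2) & (D + E) < 0.40,
    vegetal = (D + E) > (A + B + C) & (D > A | D > B | D > C),
    extremely_vegetal = E > 0.50 & E > 2 * D
  )
}

#' Classify RNA fraction profiles into localization categories
#'
#' Applies the five-segment rules with strict inequalities and precedence
#' extremely_vegetal, extremely_animal, vegetal, animal, other:
#' * extremely animal: strict maximum in A; (A+B) > (D+E); C > D or C > E
#' * animal: strict maximum in B; D+E below 40% of the gene's transcripts
#' * vegetal: (D+E) > (A+B+C); D > A or D > B or D > C
#' * extremely vegetal: E above 50% of the gene's transcripts and E > 2D
#' * other: none of the above
#'
#' @param fractions a long tibble (`gene_id`, `segment`, `fraction`, optional
#'   `replicate`), a wide data frame with columns `A`..`E`, or a single
#'   numeric vector of five fractions.
#' @param normalize divide each profile by its total instead of requiring it
#'   to sum to 1 (classification is scale-invariant under this option).
#' @return tibble with `gene_id` (and `replicate` if supplied) and
#'   `category`; a bare character label for a single numeric profile.
#' @export
classify_rna <- function(fractions, normalize = FALSE) {
  pm <- profile_matrix(fractions, RNA_SEGMENTS)
  m <- validate_fractions(pm$m, normalize)
  fired <- rna_rule_matrix(m)
  precedence <- c("extremely_vegetal", "extremely_animal", "vegetal", "animal")
  label <- rep("other", nrow(m))
  for (cat in rev(precedence)) label[fired[, cat]] <- cat
  finish_classification(label, pm, RNA_CATEGORIES)
}

protein_rule_matrix <- function(m) {
  A <- m[, "A"]; B <- m[, "B"]; C <- m[, "C"]; D <- m[, "D"]
  rsd <- apply(m, 1, sd) / rowMeans(m) * 100
  maxCD <- pmax(C, D)
  cbind(
    animal = strict_max(m, 1) & (A - D) > 0.05,
    even = (m[, 1] >= 0.20 & m[, 1] <= 0.30 & B >= 0.20 & B <= 0.30 &
              C >= 0.20 & C <= 0.30 & D >= 0.20 & D <= 0.30 & rsd < 5) |
           (strict_max(m, 2) & C > D),
    vegetal = maxCD > A & maxCD > B & (maxCD - A) > 0.05
  )
}

#' Classify protein fraction profiles into localization categories
#'
#' Four-segment (A..D) rules with precedence animal, even, vegetal, other:
#' * animal: strict maximum in A and A - D > 0.05 (fraction scale)
#' * even: every segment between 20 and 30% with relative standard deviation
#'   below 5%, or strict maximum in B with C > D
#' * vegetal: the larger of C and D exceeds both A and B, with a margin over
#'   A above 0.05
#'
#' @inheritParams classify_rna
#' @return as [classify_rna()], with protein categories.
#' @export
classify_protein <- function(fractions, normalize = FALSE) {
  pm <- profile_matrix(fractions, PROTEIN_SEGMENTS)
  m <- validate_fractions(pm$m, normalize)
  fired <- protein_rule_matrix(m)
  label <- rep("other", nrow(m))
  for (cat in c("vegetal", "even", "animal")) label[fired[, cat]] <- cat
  finish_classification(label, pm, PROTEIN_CATEGORIES)
}

finish_classification <- function(label, pm, levels) {
  if (isTRUE(pm$scalar)) return(label)
  out <- tibble(gene_id = pm$ids %||% as.character(seq_along(label)))
  if (!is.null(pm$reps)) out$replicate <- pm$reps
  out$category <- factor(label, levels = levels)
  out
}

#' Replicate consensus category
#'
#' Returns the label shared by at least `min_agree` replicates; when no
#' label reaches the quorum (or two tie at it), returns `"other"`.
#'
#' @param labels character/factor vector of per-replicate categories.
#' @param min_agree quorum (default 2, i.e. two of three replicates).
#' @return single category label (character).
#' @export
consensus_category <- function(labels, min_agree = 2) {
  labels <- as.character(labels)
  if (!length(labels)) abort("no labels supplied")
  mixed_rna <- any(labels %in% setdiff(RNA_CATEGORIES, PROTEIN_CATEGORIES))
  mixed_prot <- any(labels %in% setdiff(PROTEIN_CATEGORIES, RNA_CATEGORIES))
  if (mixed_rna && mixed_prot) abort("RNA and protein labels mixed")
  tab <- sort(table(labels), decreasing = TRUE)
  if (tab[1] >= min_agree && (length(tab) == 1L || tab[1] > tab[2])) {
    names(tab)[1]
  } else {
    "other"
  }
}

#' Per-replicate classification with quorum consensus
#'
#' Classifies each replicate's fraction profile and collapses them per gene
#' with [consensus_category()]. This is the default route for proteins.
#'
#' @param fractions long tibble with `gene_id`, `segment`, `replicate`,
#'   `fraction`.
#' @param molecule_kind `"rna"` or `"protein"`.
#' @param min_agree replicate quorum.
#' @param normalize see [classify_rna()].
#' @return tibble with `gene_id`, `category`.
#' @export
classify_replicates <- function(fractions, molecule_kind = c("rna", "protein"),
                                min_agree = 2, normalize = FALSE) {
  molecule_kind <- match.arg(molecule_kind)
  per_rep <- if (molecule_kind == "rna") classify_rna(fractions, normalize)
             else classify_protein(fractions, normalize)
  per_rep |>
    group_by(.data$gene_id) |>
    summarise(category = consensus_category(.data$category, min_agree),
              .groups = "drop") |>
    mutate(category = factor(.data$category, levels = categories_for(molecule_kind)))
}

#' Category counts and proportions
#'
#' @param labels tibble with a `category` column (e.g. from [classify_rna()])
#'   or a character/factor vector.
#' @param molecule_kind `"rna"` or `"protein"`; sets the category ordering.
#' @return tibble with `category`, `n`, `proportion` over all categories in
#'   canonical order (zero rows included).
#' @export
summarize_categories <- function(labels, molecule_kind = c("rna", "protein")) {
  molecule_kind <- match.arg(molecule_kind)
  lev <- categories_for(molecule_kind)
  cats <- if (is.data.frame(labels)) labels$category else labels
  cats <- as.character(cats)
  if (!length(cats)) {
    warn("no classified genes to summarize")
    return(tibble(category = factor(lev, levels = lev), n = 0L, proportion = NA_real_))
  }
  unknown <- setdiff(unique(cats), lev)
  if (length(unknown)) {
    abort(sprintf("unknown category label(s): %s", paste(unknown, collapse = ", ")))
  }
  tab <- table(factor(cats, levels = lev))
  tibble(category = factor(lev, levels = lev), n = as.integer(tab),
         proportion = as.integer(tab) / sum(tab))
}
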