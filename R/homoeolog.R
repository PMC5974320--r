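# Homoeologue (.L/.S) analysis. Allotetraploid genomes carry duplicated
# gene copies from the two ancestral subgenomes, annotated with .L (long
# chromosome) and .S (short chromosome) suffixes; high-depth tomographic
# profiles can resolve the two, so their localization categories and 3'UTR
# motif content can be compared pair by pair.

#' Pair .L/.S homoeologues by base symbol
#'
#' @param gene_ids character vector of gene ids; homoeologues carry `.L` /
#'   `.S` suffixes (configurable).
#' @param suffix_l,suffix_s suffix regular expressions (anchored at the end).
#' @return list with `pairs` (tibble `base_symbol`, `gene_l`, `gene_s`) and
#'   `unpaired` (character vector: suffixed genes without a partner and
#'   unsuffixed genes).
#' @export
pair_homoeologs <- function(gene_ids, suffix_l = "\\.L$", suffix_s = "\\.S$") {
  is_l <- grepl(suffix_l, gene_ids)
  is_s <- grepl(suffix_s, gene_ids)
  l_base <- sub(suffix_l, "", gene_ids[is_l])
  s_base <- sub(suffix_s, "", gene_ids[is_s])
  if (anyDuplicated(l_base)) {
    abort(sprintf("base symbol(s) with two .L entries: %s",
                  paste(unique(l_base[duplicated(l_base)]), collapse = ", ")))
  }
  if (anyDuplicated(s_base)) {
    abort(sprintf("base symbol(s) with two .S entries: %s",
                  paste(unique(s_base[duplicated(s_base)]), collapse = ", ")))
  }
  common <- intersect(l_base, s_base)
  pairs <- tibble(
    base_symbol = common,
    gene_l = gene_ids[is_l][match(common, l_base)],
    gene_s = gene_ids[is_s][match(common, s_base)]
  ) |> arrange(.data$base_symbol)
  unpaired <- c(gene_ids[is_l][!l_base %in% common],
                gene_ids[is_s][!s_base %in% common],
                gene_ids[!is_l & !is_s])
  list(pairs = pairs, unpaired = unpaired)
}

vegetal_side <- c("vegetal", "extremely_vegetal")
animal_side <- c("animal", "extremely_animal")

#' Localization concordance of homoeologue pairs
#'
#' Joins each pair member's category, flags concordant pairs (identical
#' categories) and diametrically opposite pairs (one member
#' vegetal/extremely vegetal, the other animal/extremely animal), and
#' tabulates the L-by-S category contingency. Pairs with an unclassified
#' member are excluded with a warning.
#'
#' @param pairs tibble with `base_symbol`, `gene_l`, `gene_s` (from
#'   [pair_homoeologs()]).
#' @param categories tibble with `gene_id`, `category`.
#' @return object of class `homoeolog_concordance`: list with `pairs`
#'   (per-pair tibble with `category_l`, `category_s`, `concordant`,
#'   `opposite`), `fraction_concordant`, `n_pairs`, `n_total`, and
#'   `contingency` (L x S category table).
#' @export
concordance <- function(pairs, categories) {
  cats <- select(categories, "gene_id", "category") |>
    mutate(category = as.character(.data$category))
  out <- pairs |>
    left_join(rename(cats, gene_l = "gene_id", category_l = "category"), by = "gene_l") |>
    left_join(rename(cats, gene_s = "gene_id", category_s = "category"), by = "gene_s")
  unclassified <- is.na(out$category_l) | is.na(out$category_s)
  if (any(unclassified)) {
    warn(sprintf("%d pair(s) with an unclassified member excluded", sum(unclassified)))
  }
  kept <- out[!unclassified, ] |>
    mutate(
      concordant = .data$category_l == .data$category_s,
      opposite = (.data$category_l %in% vegetal_side & .data$category_s %in% animal_side) |
                 (.data$category_l %in% animal_side & .data$category_s %in% vegetal_side)
    )
  lev <- RNA_CATEGORIES
  structure(list(
    pairs = kept,
    fraction_concordant = mean(kept$concordant),
    n_pairs = nrow(kept),
    n_total = nrow(pairs),
    contingency = table(L = factor(kept$category_l, levels = lev),
                        S = factor(kept$category_s, levels = lev))
  ), class = "homoeolog_concordance")
}

#' @export
print.homoeolog_concordance <- function(x, ...) {
  cat(sprintf("homoeologue concordance: %.1f%% of %d classified pairs (%d total)\n",
              100 * x$fraction_concordant, x$n_pairs, x$n_total))
  cat(sprintf("  discordant: %d, diametrically opposite: %d\n",
              sum(!x$pairs$concordant), sum(x$pairs$opposite)))
  invisible(x)
}

#' Motif occurrence counts in the two 3'UTRs of each pair
#'
#' Counts IUPAC occurrences of each motif in the L and S UTRs. When the two
#' members' categories differ, the count ratio is reported vegetal copy
#' first (`"3:0"` style).
#'
#' @param pairs per-pair tibble (with `category_l`/`category_s` columns when
#'   available, e.g. `concordance(...)$pairs`).
#' @param utrs UTR set tibble covering the pair members.
#' @param motifs motif set tibble (or character vector of IUPAC strings).
#' @return long tibble: `base_symbol`, `motif_id`, `count_l`, `count_s`,
#'   `ratio` (`NA` when a UTR is missing; counts `NA` flagged missing).
#' @export
pair_motif_counts <- function(pairs, utrs, motifs) {
  if (is.character(motifs)) {
    motifs <- motif_set(!!!map(motifs, function(m) motif_from_iupac(as_dna(m), m)))
  }
  count_in <- function(gene, motif_row) {
    i <- match(gene, utrs$gene_id)
    if (is.na(i)) return(NA_integer_)
    nrow(scan_iupac(utrs[i, ], motif_row))
  }
  rows <- list()
  for (m in seq_len(nrow(motifs))) {
    cl <- map_int(pairs$gene_l, count_in, motif_row = motifs[m, ])
    cs <- map_int(pairs$gene_s, count_in, motif_row = motifs[m, ])
    ratio <- map_chr(seq_len(nrow(pairs)), function(i) {
      if (is.na(cl[i]) || is.na(cs[i])) return(NA_character_)
      veg_first <- !is.null(pairs$category_l) &&
        !identical(pairs$category_l[i], pairs$category_s[i]) &&
        isTRUE(pairs$category_s[i] %in% vegetal_side)
      if (veg_first) paste0(cs[i], ":", cl[i]) else paste0(cl[i], ":", cs[i])
    })
    rows[[m]] <- tibble(base_symbol = pairs$base_symbol,
                        motif_id = motifs$motif_id[m],
                        count_l = cl, count_s = cs, ratio = ratio)
  }
  bind_rows(rows)
}
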