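# qPCR-anchored normalization of tomographic section counts.
#
# Standard count normalization (median-of-ratios and friends) assumes most
# genes are equally distributed across samples; along an intracellular axis
# that assumption fails by construction. Instead a handful of anchor genes
# are quantified by qPCR tomography on whole eggs; their qPCR fraction
# profiles define how sequencing counts must be rescaled per segment so that
# profiles reflect whole-egg content.

#' Read an anchor Cq table
#'
#' Long TSV with columns `anchor_id`, `segment`, `replicate`, `cq` and
#' optionally `efficiency` (amplification efficiency per anchor; defaults to
#' 2, i.e. perfect doubling).
#'
#' @param path TSV file.
#' @return tibble with those columns (efficiency filled in).
#' @export
read_cq_table <- function(path) {
  cq <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("anchor_id", "segment", "replicate", "cq")
  missing <- setdiff(needed, names(cq))
  if (length(missing)) {
    abort(sprintf("Cq table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!"efficiency" %in% names(cq)) cq$efficiency <- 2
  validate_cq(cq)
}

validate_cq <- function(cq) {
  if (!"efficiency" %in% names(cq)) cq$efficiency <- 2
  if (any(cq$efficiency <= 1 | cq$efficiency > 2)) {
    abort("amplification efficiency must lie in (1, 2]")
  }
  if (any(!is.finite(cq$cq))) abort("non-finite Cq value")
  as_tibble(cq) |> mutate(replicate = as.integer(.data$replicate))
}

#' Convert an anchor's Cq profile to segment fractions
#'
#' Relative quantity per segment is `efficiency^(-Cq)`. Each qPCR replicate
#' is normalized to sum 1 before averaging, so constant per-replicate offsets
#' (plate effects, input amounts) cancel; the averaged vector is renormalized.
#'
#' @param cq Cq tibble (see [read_cq_table()]).
#' @param anchor anchor gene id to extract.
#' @return tibble with `segment` and `fraction` (sums to 1).
#' @export
cq_to_fractions <- function(cq, anchor) {
  cq <- validate_cq(cq)
  x <- filter(cq, .data$anchor_id == anchor)
  if (!nrow(x)) abort(sprintf("anchor '%s' not present in Cq table", anchor))
  segs <- segment_levels(x)
  per_rep <- x |>
    group_by(.data$replicate) |>
    group_modify_quiet(function(d) {
      if (!setequal(d$segment, segs)) {
        abort(sprintf("anchor '%s': Cq missing for segment(s) %s", anchor,
                      paste(setdiff(segs, d$segment), collapse = ", ")))
      }
      q <- d$efficiency^(-d$cq)
      tibble(segment = d$segment, q = q / sum(q))
    }) |>
    ungroup()
  per_rep |>
    group_by(.data$segment) |>
    summarise(fraction = mean(.data$q), .groups = "drop") |>
    mutate(fraction = .data$fraction / sum(.data$fraction)) |>
    arrange(factor(.data$segment, levels = segs))
}

# dplyr::group_modify without carrying the grouping key into `d`
group_modify_quiet <- function(.data, .f) {
  dplyr::group_modify(.data, function(d, key) .f(d))
}

#' Compute per-segment size factors from qPCR anchors
#'
#' For each anchor the qPCR fraction profile (truth, via
#' [cq_to_fractions()]) is divided by the anchor's RNA-seq fraction profile
#' in each sequencing replicate; the per-segment median over anchors is the
#' raw factor, rescaled to geometric mean 1 per replicate. The median makes
#' the factors robust to a single misbehaving anchor.
#'
#' @param counts raw long segment tibble.
#' @param cq anchor Cq tibble.
#' @param anchors anchor ids to use (default: all in `cq`).
#' @return tibble with `segment`, `replicate`, `size_factor`.
#' @export
compute_size_factors <- function(counts, cq, anchors = NULL) {
  cq <- validate_cq(cq)
  anchors <- anchors %||% unique(cq$anchor_id)
  segs <- segment_levels(counts)
  usable <- character(0)
  ratio_rows <- list()
  for (g in anchors) {
    sub <- filter(counts, .data$gene_id == g)
    if (!nrow(sub)) {
      warn(sprintf("anchor '%s' absent from the count table; excluded", g))
      next
    }
    if (any(is.na(sub$value)) || any(sub$value <= 0)) {
      warn(sprintf("anchor '%s' has zero/missing counts in some segment; excluded", g))
      next
    }
    qf <- cq_to_fractions(cq, g)
    r <- sub |>
      group_by(.data$replicate) |>
      mutate(r = .data$value / sum(.data$value)) |>
      ungroup() |>
      left_join(qf, by = "segment") |>
      mutate(anchor_id = g, ratio = .data$fraction / .data$r) |>
      select("anchor_id", "segment", "replicate", "ratio")
    ratio_rows[[g]] <- r
    usable <- c(usable, g)
  }
  if (!length(usable)) abort("no usable anchor for size-factor estimation")
  bind_rows(ratio_rows) |>
    group_by(.data$segment, .data$replicate) |>
    summarise(size_factor = median(.data$ratio), .groups = "drop") |>
    group_by(.data$replicate) |>
    mutate(size_factor = .data$size_factor / exp(mean(log(.data$size_factor)))) |>
    ungroup() |>
    arrange(factor(.data$segment, levels = segs), .data$replicate)
}

#' Apply size factors to a segment table
#'
#' @param counts long segment tibble.
#' @param size_factors tibble with `segment`, `size_factor` and optionally
#'   `replicate` (factors applied per replicate when present).
#' @return normalized long segment tibble.
#' @export
apply_size_factors <- function(counts, size_factors) {
  if (!setequal(unique(counts$segment), unique(size_factors$segment))) {
    abort("segment labels of counts and size factors do not match")
  }
  by <- if ("replicate" %in% names(size_factors)) c("segment", "replicate") else "segment"
  out <- left_join(counts, select(size_factors, dplyr::all_of(c(by, "size_factor"))),
                   by = by)
  if (any(is.na(out$size_factor))) {
    abort("no size factor for some (segment, replicate) combination")
  }
  out |>
    mutate(value = .data$value * .data$size_factor) |>
    select(-"size_factor")
}

#' Remove genes with low average normalized signal
#'
#' A gene is kept when its mean normalized value over all segment x replicate
#' cells is at least `threshold`; removal is strictly below the threshold.
#'
#' @param norm normalized long segment tibble.
#' @param threshold minimum mean normalized read (default 15).
#' @return filtered tibble; warns when nothing survives.
#' @export
filter_low_expression <- function(norm, threshold = 15) {
  keep <- norm |>
    group_by(.data$gene_id) |>
    summarise(m = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    filter(.data$m >= threshold) |>
    pull("gene_id")
  if (!length(keep)) warn("no gene passes the expression filter")
  filter(norm, .data$gene_id %in% keep)
}

#' Per-replicate fraction profiles
#'
#' Each replicate's values are divided by the gene's replicate total, so
#' fractions sum to 1 per (gene, replicate). Replicates with zero total are
#' dropped for that gene with a warning.
#'
#' @param norm normalized long segment tibble.
#' @return tibble with `gene_id`, `segment`, `replicate`, `fraction`.
#' @export
to_fractions <- function(norm) {
  totals <- norm |>
    group_by(.data$gene_id, .data$replicate) |>
    summarise(total = sum(.data$value, na.rm = TRUE), .groups = "drop")
  zero <- filter(totals, .data$total <= 0)
  if (nrow(zero)) {
    warn(sprintf("%d (gene, replicate) profile(s) with zero total dropped", nrow(zero)))
  }
  norm |>
    inner_join(filter(totals, .data$total > 0), by = c("gene_id", "replicate")) |>
    mutate(fraction = .data$value / .data$total) |>
    select("gene_id", "segment", "replicate", "fraction")
}

#' Consensus fraction profile per gene
#'
#' Arithmetic mean of the replicate fraction vectors, renormalized, so each
#' replicate weighs equally regardless of depth.
#'
#' @param fractions tibble from [to_fractions()].
#' @return tibble with `gene_id`, `segment`, `fraction`.
#' @export
consensus_fractions <- function(fractions) {
  fractions |>
    group_by(.data$gene_id, .data$segment) |>
    summarise(fraction = mean(.data$fraction), .groups = "drop_last") |>
    mutate(fraction = .data$fraction / sum(.data$fraction)) |>
    ungroup()
}

#' Global-mean normalization of a protein intensity table
#'
#' Each sample (segment x replicate column) is divided by its mean intensity
#' over proteins, removing inter-sample variation so all column means equal 1.
#'
#' @param protein long segment tibble of protein intensities.
#' @return normalized tibble.
#' @export
global_mean_normalize <- function(protein) {
  out <- protein |>
    group_by(.data$segment, .data$replicate) |>
    mutate(.colmean = mean(.data$value, na.rm = TRUE)) |>
    ungroup()
  if (any(out$.colmean <= 0 | !is.finite(out$.colmean))) {
    abort("sample with zero mean intensity cannot be normalized")
  }
  out |>
    mutate(value = .data$value / .data$.colmean) |>
    select(-".colmean")
}
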