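# Segment count/intensity tables.
#
# On disk: wide TSV, first column `gene_id`, then one column per
# (segment, replicate) cell named `<segment>_r<replicate>` (A_r1 ... E_r3).
# In memory: a long tibble with columns gene_id, segment, replicate, value —
# the shape every downstream verb (normalization, fractions, classification)
# operates on. Segment order is animal-pole-first (A..E for RNA, A..D for
# protein) and is preserved by keeping `segment` a character validated against
# that order; helpers always arrange by factor(segment, segments).

#' Read a segment table (wide TSV) into long form
#'
#' @param path TSV file; header `gene_id` then `<segment>_r<replicate>`
#'   columns, e.g. `A_r1`.
#' @param molecule_kind `"rna"` (segments A..E) or `"protein"` (A..D).
#' @return tibble with columns `gene_id`, `segment`, `replicate` (integer),
#'   `value`; missing cells appear as `NA`.
#' @export
read_segment_table <- function(path, molecule_kind = c("rna", "protein")) {
  molecule_kind <- match.arg(molecule_kind)
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(wide)) {
    abort("segment table must have a 'gene_id' column")
  }
  as_segment_table(wide, molecule_kind)
}

#' Validate a wide gene-by-sample data frame as a segment table
#'
#' @param wide data frame with `gene_id` and `<segment>_r<replicate>` columns.
#' @inheritParams read_segment_table
#' @return long tibble as in [read_segment_table()].
#' @export
as_segment_table <- function(wide, molecule_kind = c("rna", "protein")) {
  molecule_kind <- match.arg(molecule_kind)
  segs <- segments_for(molecule_kind)
  wide <- as_tibble(wide)
  if (anyDuplicated(wide$gene_id)) {
    abort(sprintf("duplicate gene ids: %s",
                  paste(unique(wide$gene_id[duplicated(wide$gene_id)]), collapse = ", ")))
  }
  value_cols <- setdiff(names(wide), "gene_id")
  m <- regmatches(value_cols, regexec("^([A-Za-z]+)_r([0-9]+)$", value_cols))
  bad <- value_cols[vapply(m, length, integer(1)) != 3L]
  if (length(bad)) {
    abort(sprintf("column names must follow '<segment>_r<replicate>': %s",
                  paste(bad, collapse = ", ")))
  }
  col_seg <- vapply(m, `[`, character(1), 2L)
  unknown <- setdiff(unique(col_seg), segs)
  if (length(unknown)) {
    abort(sprintf("unknown segment label(s) for %s data: %s (expected %s)",
                  molecule_kind, paste(unknown, collapse = ", "),
                  paste(segs, collapse = "..")))
  }
  long <- wide |>
    pivot_longer(-"gene_id", names_to = c("segment", "replicate"),
                 names_pattern = "^([A-Za-z]+)_r([0-9]+)$",
                 values_to = "value") |>
    mutate(replicate = as.integer(.data$replicate))
  if (any(long$value < 0, na.rm = TRUE)) {
    abort("segment table contains negative values")
  }
  arrange(long, .data$gene_id,
          factor(.data$segment, levels = segs), .data$replicate)
}

#' Write a long segment table as wide TSV
#'
#' Inverse of [read_segment_table()]; round-trips values exactly (full
#' precision decimal rendering).
#'
#' @param x long segment tibble (`gene_id`, `segment`, `replicate`, `value`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(x, path) {
  segs <- segment_levels(x)
  wide <- x |>
    mutate(segment = factor(.data$segment, levels = segs)) |>
    arrange(.data$segment, .data$replicate) |>
    mutate(col = paste0(.data$segment, "_r", .data$replicate)) |>
    select("gene_id", "col", "value") |>
    pivot_wider(names_from = "col", values_from = "value")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

# Segment labels present, in canonical animal-first order.
segment_levels <- function(x) {
  present <- unique(x$segment)
  segs <- RNA_SEGMENTS[RNA_SEGMENTS %in% present]
  if (!setequal(segs, present)) {
    abort(sprintf("unexpected segment labels: %s",
                  paste(setdiff(present, segs), collapse = ", ")))
  }
  segs
}

molecule_kind_of <- function(x) {
  if ("E" %in% x$segment) "rna" else "protein"
}
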