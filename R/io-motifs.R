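# Motif definitions. A motif set is a tibble with one row per motif:
#   motif_id, width, consensus (IUPAC string), pwm (list column of 4 x width
#   probability matrices; NULL when the motif was given only as a consensus),
#   source_tag. Two interchange dialects are read: MEME minimal format
# (MOTIF blocks with letter-probability matrices) and a plain list of IUPAC
# strings, one motif per line ("UUCAC" or "id<TAB>UUCAC"). RNA alphabets are
# normalized to DNA on ingest.

#' Construct a motif from an IUPAC consensus
#'
#' @param id motif identifier.
#' @param consensus IUPAC string (RNA or DNA; brackets like `[UC]` allowed).
#' @param source_tag free-text provenance tag.
#' @return one-row motif tibble.
#' @export
motif_from_iupac <- function(id, consensus, source_tag = "iupac") {
  consensus <- iupac_collapse_brackets(as_dna(consensus))
  assert_iupac(consensus)
  tibble(motif_id = id, width = nchar(consensus), consensus = consensus,
         pwm = list(iupac_to_pwm(consensus)), source_tag = source_tag)
}

#' Construct a motif from a position probability matrix
#'
#' @param id motif identifier.
#' @param pwm 4 x width matrix (rows A,C,G,T), columns summing to 1 within
#'   1e-6.
#' @param source_tag free-text provenance tag.
#' @param consensus_threshold per-base probability for the degenerate
#'   consensus rendering (see [pwm_consensus()]).
#' @return one-row motif tibble.
#' @export
motif_from_pwm <- function(id, pwm, source_tag = "pwm",
                           consensus_threshold = 0.25) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4)
  if (is.null(rownames(pwm))) rownames(pwm) <- DNA_BASES
  sums <- colSums(pwm)
  if (any(abs(sums - 1) > 1e-6)) {
    abort(sprintf("PWM column(s) %s do not sum to 1 within 1e-6",
                  paste(which(abs(sums - 1) > 1e-6), collapse = ", ")))
  }
  if (any(pwm < 0)) abort("PWM probabilities must be non-negative")
  tibble(motif_id = id, width = ncol(pwm),
         consensus = pwm_consensus(pwm, consensus_threshold),
         pwm = list(pwm), source_tag = source_tag)
}

#' Bind motifs into one motif set
#' @param ... one-row motif tibbles or motif sets.
#' @return motif set tibble; ids must be unique.
#' @export
motif_set <- function(...) {
  out <- bind_rows(...)
  if (anyDuplicated(out$motif_id)) {
    abort(sprintf("duplicate motif ids: %s",
                  paste(unique(out$motif_id[duplicated(out$motif_id)]), collapse = ", ")))
  }
  out
}

#' Read motifs from a file, auto-detecting the dialect
#'
#' Files containing a `MOTIF` line are parsed as MEME minimal format,
#' anything else as one-IUPAC-motif-per-line.
#'
#' @param path motif file.
#' @return motif set tibble.
#' @export
read_motifs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^MOTIF\\b", lines))) read_meme_minimal(path)
  else read_iupac_motifs(path)
}

#' Read a MEME-minimal-format motif file
#'
#' Parses `MOTIF` blocks with `letter-probability matrix:` sections. Every
#' matrix row must sum to 1 within 1e-6.
#'
#' @param path MEME minimal text file.
#' @return motif set tibble (PWM representation, with degenerate consensus).
#' @export
read_meme_minimal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) abort("no MOTIF blocks found")
  motifs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    header <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]]
    id <- if (length(header) >= 2) header[2] else abort("MOTIF line without an id")
    block_end <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
    block <- lines[starts[i]:block_end]
    lp <- grep("^\\s*letter-probability matrix", block)
    if (!length(lp)) abort(sprintf("motif %s has no letter-probability matrix", id))
    w <- as.integer(sub(".*\\bw=\\s*([0-9]+).*", "\\1", block[lp[1]]))
    if (is.na(w)) {
      # width not declared; take all numeric rows that follow
      rows <- grep("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", block[-seq_len(lp[1])])
      w <- length(rows)
    }
    row_lines <- block[(lp[1] + 1):(lp[1] + w)]
    vals <- lapply(row_lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (any(vapply(vals, length, integer(1)) != 4L)) {
      abort(sprintf("motif %s: probability rows must have 4 entries (A C G T)", id))
    }
    m <- t(do.call(rbind, vals))  # rows A,C,G,T; columns are positions
    rownames(m) <- DNA_BASES
    bad <- which(abs(colSums(m) - 1) > 1e-6)
    if (length(bad)) {
      abort(sprintf("motif %s: probability row(s) %s do not sum to 1 within 1e-6",
                    id, paste(bad, collapse = ", ")))
    }
    motifs[[i]] <- motif_from_pwm(id, m, source_tag = "meme_minimal")
  }
  motif_set(!!!motifs)
}

#' Read a plain list of IUPAC motifs
#'
#' One motif per line, either `CONSENSUS` or `id<TAB>CONSENSUS`; `#` lines
#' and blank lines are skipped. Unnamed motifs are given ids `m1`, `m2`, ...
#'
#' @param path text file.
#' @return motif set tibble.
#' @export
read_iupac_motifs <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort("no motifs found")
  parts <- strsplit(lines, "\t")
  motifs <- imap(parts, function(p, i) {
    if (length(p) >= 2) motif_from_iupac(p[1], p[2])
    else motif_from_iupac(paste0("m", i), p[1])
  })
  motif_set(!!!motifs)
}

#' Write a motif set in MEME minimal format
#'
#' @param motifs motif set tibble; motifs without a PWM are written from
#'   their IUPAC consensus (0/1-normalized columns).
#' @param path output path.
#' @param background background base frequencies recorded in the header.
#' @return `path`, invisibly.
#' @export
write_meme_minimal <- function(motifs, path,
                               background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies", sprintf(
                 "A %.5f C %.5f G %.5f T %.5f",
                 background["A"], background["C"], background["G"], background["T"]),
               ""), con)
  for (i in seq_len(nrow(motifs))) {
    pwm <- motifs$pwm[[i]] %||% iupac_to_pwm(motifs$consensus[i])
    writeLines(sprintf("MOTIF %s", motifs$motif_id[i]), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(pwm)), con)
    writeLines(apply(pwm, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

motif_pwm <- function(motifs, i) {
  motifs$pwm[[i]] %||% iupac_to_pwm(motifs$consensus[i])
}
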