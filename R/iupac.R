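# IUPAC degenerate nucleotide code, DNA alphabet. Motif consensus strings may
# use any of the 15 letters; UTR sequences themselves must be plain ACGT.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

DNA_BASES <- c("A", "C", "G", "T")

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases and converts U to T. Used on every ingested sequence and motif
#' consensus so all downstream matching happens in one alphabet; results can be
#' rendered back as RNA with [as_rna()].
#'
#' @param x character vector of sequences.
#' @return character vector, uppercase DNA.
#' @export
as_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Render a DNA string as RNA (T to U)
#' @param x character vector of DNA sequences.
#' @return character vector with T replaced by U.
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

iupac_chars <- function() names(IUPAC_SETS)

assert_acgt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    offending <- unique(unlist(strsplit(gsub("[ACGT]", "", x[bad]), "")))
    abort(sprintf("%s contains non-ACGT characters after U->T normalization: %s",
                  what, paste(offending, collapse = ", ")))
  }
  invisible(x)
}

assert_iupac <- function(x, what = "motif consensus") {
  bad <- grepl(sprintf("[^%s]", paste(iupac_chars(), collapse = "")), x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside the IUPAC nucleotide code", what))
  }
  invisible(x)
}

# Bracket-expanded consensus like "[TA][TC]CAC" -> one IUPAC letter per column
iupac_collapse_brackets <- function(x) {
  vapply(x, function(s) {
    out <- character(0)
    i <- 1L
    chars <- strsplit(s, "")[[1]]
    while (i <= length(chars)) {
      if (chars[i] == "[") {
        j <- i + 1L
        set <- character(0)
        while (j <= length(chars) && chars[j] != "]") {
          set <- c(set, chars[j])
          j <- j + 1L
        }
        if (j > length(chars)) abort("unbalanced '[' in consensus string")
        out <- c(out, iupac_letter_for(sort(unique(set))))
        i <- j + 1L
      } else {
        out <- c(out, chars[i])
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

iupac_letter_for <- function(bases) {
  bases <- sort(unique(bases))
  for (nm in names(IUPAC_SETS)) {
    if (identical(sort(IUPAC_SETS[[nm]]), bases)) return(nm)
  }
  abort(sprintf("no IUPAC letter for base set {%s}", paste(bases, collapse = ",")))
}

#' Convert an IUPAC consensus to a position probability matrix
#'
#' Each column gives equal probability to the bases admitted by its IUPAC
#' letter and zero to the rest (0/1-normalized PWM).
#'
#' @param consensus single IUPAC string (DNA; use [as_dna()] first for RNA).
#' @return 4 x width numeric matrix, rows A,C,G,T, columns summing to 1.
#' @export
iupac_to_pwm <- function(consensus) {
  stopifnot(length(consensus) == 1L)
  consensus <- iupac_collapse_brackets(as_dna(consensus))
  assert_iupac(consensus)
  cols <- strsplit(consensus, "")[[1]]
  m <- vapply(cols, function(ch) {
    p <- setNames(numeric(4), DNA_BASES)
    p[IUPAC_SETS[[ch]]] <- 1 / length(IUPAC_SETS[[ch]])
    p
  }, numeric(4))
  dimnames(m) <- list(DNA_BASES, NULL)
  m
}

#' Degenerate IUPAC consensus of a PWM
#'
#' A base enters a column's IUPAC set when its probability is at least
#' `threshold` (default 0.25, i.e. at least the uniform share). Columns where
#' no base reaches the threshold fall back to the most probable base.
#'
#' @param pwm 4 x width matrix, rows A,C,G,T.
#' @param threshold minimum per-base probability for inclusion.
#' @return single IUPAC string.
#' @export
pwm_consensus <- function(pwm, threshold = 0.25) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4)
  rn <- rownames(pwm) %||% DNA_BASES
  paste(vapply(seq_len(ncol(pwm)), function(j) {
    bases <- rn[pwm[, j] >= threshold]
    if (length(bases) == 0) bases <- rn[which.max(pwm[, j])]
    iupac_letter_for(bases)
  }, character(1)), collapse = "")
}
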