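# 3'UTR sequence sets. UTRs arrive pre-extracted as FASTA (DNA or RNA
# alphabet); on ingest everything is uppercased and U -> T so the whole
# package works in one alphabet. Ambiguity codes are rejected in UTRs
# (motifs may use them; see io-motifs.R).

#' Read a 3'UTR FASTA into a UTR set
#'
#' The first whitespace-delimited token of each header is taken as the gene
#' id. Sequences are uppercased and U is converted to T; any remaining
#' non-ACGT character is an error, as is a duplicate id or an empty sequence.
#'
#' @param path FASTA file.
#' @return tibble with columns `gene_id`, `seq`, `width`.
#' @export
read_fasta_utrs <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  utr_set(setNames(as.character(set), ids))
}

#' Build a UTR set from a named character vector
#'
#' @param seqs named character vector, names are gene ids.
#' @return tibble with columns `gene_id`, `seq`, `width`.
#' @export
utr_set <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) abort("all UTR sequences must be named")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate gene ids in UTR set: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- as_dna(seqs)
  if (any(!nzchar(seqs))) abort("empty UTR sequence")
  assert_acgt(seqs, "UTR sequence")
  tibble(gene_id = ids, seq = unname(seqs), width = nchar(unname(seqs)))
}

#' Write a UTR set as FASTA
#'
#' @param utrs tibble from [read_fasta_utrs()] / [utr_set()].
#' @param path output path.
#' @param alphabet `"dna"` (default) or `"rna"` (T rendered as U).
#' @return `path`, invisibly.
#' @export
write_fasta_utrs <- function(utrs, path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  seqs <- utrs$seq
  if (alphabet == "rna") seqs <- as_rna(seqs)
  set <- Biostrings::BStringSet(setNames(seqs, utrs$gene_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# DNAStringSet view, used by the k-mer counting and scanning internals.
utr_stringset <- function(utrs) {
  Biostrings::DNAStringSet(setNames(utrs$seq, utrs$gene_id))
}
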