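# k-mer over-representation in 3'UTR sets.
#
# Observed counts are overlapping forward-strand window counts; the expected
# count per gene under a uniform-composition random-sequence model is
# E = choose(N - t*(k-1), t) / A^(t*k), which for the default single
# occurrence (t = 1) reduces to (N - k + 1) / 4^k. Over-representation is
# judged by an upper-tailed goodness-of-fit statistic
# x2 = sum_g (O_g - E_g)^2 / E_g with df = n - 1 (genes as cells), declared
# significant at raw p < alpha (no multiple-testing correction) and only in
# the direction of excess (sum O > sum E).

#' Count overlapping k-mers in a sequence
#'
#' @param seq single ACGT string.
#' @param k k-mer length.
#' @return tibble with `kmer`, `count` for every observed k-mer; counts sum
#'   to `nchar(seq) - k + 1` (empty when the sequence is shorter than k).
#' @export
count_kmers <- function(seq, k) {
  stopifnot(length(seq) == 1L, k >= 1)
  seq <- as_dna(seq)
  assert_acgt(seq)
  if (nchar(seq) < k) return(tibble(kmer = character(0), count = integer(0)))
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), width = k)
  counts <- counts[counts > 0]
  tibble(kmer = names(counts), count = as.integer(counts)) |> arrange(.data$kmer)
}

#' Expected k-mer count under the uniform random-sequence model
#'
#' `E = choose(N - t*(k-1), t) / A^(t*k)`; with `t = 1` this is
#' `(N - k + 1) / 4^k`. Returns 0 with a warning when the sequence is too
#' short to host `t` copies.
#'
#' @param N sequence length (nt); vectorized.
#' @param k k-mer length.
#' @param t number of (non-overlapping) repeats considered (default 1).
#' @param A alphabet size (default 4).
#' @return numeric vector of expected counts.
#' @export
expected_kmer_count <- function(N, k, t = 1, A = 4) {
  short <- N < t * (k - 1) + t
  if (any(short)) {
    warn(sprintf("%d sequence(s) shorter than k; expected count set to 0", sum(short)))
  }
  E <- choose(N - t * (k - 1), t) / A^(t * k)
  E[short] <- 0
  E
}

# Overlapping occurrence counts of one k-mer in each UTR.
observed_kmer_counts <- function(utrs, kmer) {
  as.integer(Biostrings::vcountPattern(as_dna(kmer), utr_stringset(utrs)))
}

#' Over-representation test for one k-mer in a UTR category
#'
#' @param utrs UTR set tibble (a localization category's 3'UTRs).
#' @param kmer k-mer string.
#' @param alpha raw significance level (default 0.001).
#' @param t repeat parameter of the expectation model.
#' @return one-row tibble: `kmer`, `k`, `n_genes`, `obs_total`, `exp_total`,
#'   `statistic`, `df`, `p_value`, `significant`. Genes shorter than k are
#'   excluded from the statistic.
#' @export
kmer_chi2 <- function(utrs, kmer, alpha = 0.001, t = 1) {
  kmer <- as_dna(kmer)
  assert_acgt(kmer, "k-mer")
  k <- nchar(kmer)
  keep <- utrs$width >= k
  if (sum(keep) < 2) abort("need at least 2 genes with UTR length >= k")
  utrs <- utrs[keep, ]
  O <- observed_kmer_counts(utrs, kmer)
  E <- expected_kmer_count(utrs$width, k, t = t)
  if (all(E == 0)) abort("all expected counts are zero")
  x2 <- sum((O - E)^2 / E)
  df <- nrow(utrs) - 1L
  p <- pchisq(x2, df = df, lower.tail = FALSE)
  tibble(kmer = kmer, k = k, n_genes = nrow(utrs),
         obs_total = sum(O), exp_total = sum(E),
         statistic = x2, df = df, p_value = p,
         significant = p < alpha & sum(O) > sum(E))
}

# Observed counts for all 4^k k-mers at once: genes x 4^k matrix.
kmer_count_matrix <- function(utrs, k) {
  Biostrings::oligonucleotideFrequency(utr_stringset(utrs), width = k)
}

#' Screen all k-mers of one length for over-representation
#'
#' Runs the [kmer_chi2()] statistic for every one of the `4^k` k-mers over a
#' category's UTR set, at raw `alpha` (the tests are deliberately not
#' corrected for multiplicity).
#'
#' @param utrs UTR set tibble.
#' @param k k-mer length (3..7 in the intended range, any k >= 1 accepted).
#' @param alpha raw significance level.
#' @param all return all k-mers (default) or only the significant ones.
#' @return tibble as [kmer_chi2()], one row per k-mer, sorted by p-value.
#' @export
overrepresented_kmers <- function(utrs, k, alpha = 0.001, all = TRUE) {
  keep <- utrs$width >= k
  if (sum(keep) < 2) abort("need at least 2 genes with UTR length >= k")
  if (any(!keep)) {
    warn(sprintf("%d UTR(s) shorter than k excluded", sum(!keep)))
    utrs <- utrs[keep, ]
  }
  O <- kmer_count_matrix(utrs, k)
  E <- expected_kmer_count(utrs$width, k)
  x2 <- colSums((O - E)^2 / E)
  df <- nrow(utrs) - 1L
  p <- pchisq(x2, df = df, lower.tail = FALSE)
  obs_tot <- colSums(O)
  exp_tot <- sum(E)
  out <- tibble(kmer = colnames(O), k = k, n_genes = nrow(utrs),
                obs_total = as.integer(obs_tot), exp_total = exp_tot,
                statistic = x2, df = df, p_value = p,
                significant = p < alpha & obs_tot > exp_tot) |>
    arrange(.data$p_value, .data$kmer)
  if (all) out else filter(out, .data$significant)
}

#' Null calibration of the k-mer over-representation test
#'
#' Simulates categories of iid uniform-composition sequences, applies the
#' [kmer_chi2()] decision rule to a fixed k-mer in each, and returns the
#' empirical rejection rate at `alpha`. The statistic treats genes as cells
#' of a goodness-of-fit test with df = n - 1 even though expected counts are
#' small and overlapping windows are dependent, so the empirical rate is not
#' expected to match the nominal level exactly; this function measures the
#' deviation.
#'
#' @param kmer fixed k-mer under test.
#' @param n_genes sequences per simulated category.
#' @param utr_length length of every simulated sequence (nt).
#' @param n_sim number of simulated categories.
#' @param alpha nominal level.
#' @param chunk simulations per block (memory control).
#' @return one-row tibble: `kmer`, `n_sim`, `alpha`, `rejection_rate`,
#'   `ratio_to_nominal`.
#' @export
kmer_null_calibration <- function(kmer, n_genes = 10, utr_length = 300,
                                  n_sim = 10000, alpha = 0.001, chunk = 1000) {
  kmer <- as_dna(kmer)
  assert_acgt(kmer, "k-mer")
  k <- nchar(kmer)
  pat <- match(strsplit(kmer, "")[[1]], DNA_BASES)
  E <- expected_kmer_count(utr_length, k)
  df <- n_genes - 1L
  rejections <- 0L
  done <- 0L
  while (done < n_sim) {
    b <- min(chunk, n_sim - done)
    n_seq <- b * n_genes
    m <- matrix(sample.int(4L, n_seq * utr_length, replace = TRUE),
                nrow = utr_length)
    ok <- m[seq_len(utr_length - k + 1L), , drop = FALSE] == pat[1]
    for (j in 2:k) {
      ok <- ok & m[seq_len(utr_length - k + 1L) + j - 1L, , drop = FALSE] == pat[j]
    }
    O <- matrix(colSums(ok), nrow = b, byrow = TRUE)  # simulations x genes
    x2 <- rowSums((O - E)^2 / E)
    p <- pchisq(x2, df = df, lower.tail = FALSE)
    rejections <- rejections + sum(p < alpha & rowSums(O) > n_genes * E)
    done <- done + b
  }
  rate <- rejections / n_sim
  tibble(kmer = kmer, n_sim = n_sim, alpha = alpha,
         rejection_rate = rate, ratio_to_nominal = rate / alpha)
}

#' k-mers exclusive to one of two category screens
#'
#' @param animal,vegetal significant k-mer sets: character vectors or screen
#'   tibbles from [overrepresented_kmers()] (their `significant` rows are
#'   used). Both must be at the same k.
#' @return tibble with `kmer`, `unique_to` (`"animal"`/`"vegetal"`).
#' @export
unique_kmers <- function(animal, vegetal) {
  a <- significant_set(animal)
  v <- significant_set(vegetal)
  if (length(a) && length(v) &&
      length(unique(nchar(c(a, v)))) > 1L) {
    abort("animal and vegetal k-mer sets have different k")
  }
  bind_rows(
    tibble(kmer = sort(setdiff(a, v)), unique_to = "animal"),
    tibble(kmer = sort(setdiff(v, a)), unique_to = "vegetal")
  )
}

significant_set <- function(x) {
  if (is.data.frame(x)) x$kmer[x$significant] else as.character(x)
}

#' Cross-reference k-mers against motif consensus sequences
#'
#' A k-mer is "found within" a motif when some length-k window of the
#' motif's IUPAC consensus accepts it position-wise (PWM motifs are rendered
#' as degenerate consensus at the 0.25-per-base threshold first).
#'
#' @param kmers character vector of k-mers.
#' @param motifs motif set tibble.
#' @return tibble with `kmer`, `motif_id`, one row per (k-mer, motif) match;
#'   k-mers matching no motif are absent.
#' @export
crossref_motifs <- function(kmers, motifs) {
  kmers <- as_dna(kmers)
  consensi <- vapply(seq_len(nrow(motifs)), function(i) {
    if (is.null(motifs$pwm[[i]])) motifs$consensus[i]
    else pwm_consensus(motifs$pwm[[i]])
  }, character(1))
  rows <- list()
  for (i in seq_along(kmers)) {
    km <- kmers[i]
    hit <- vapply(consensi, function(cons) {
      length(iupac_match_starts(km, cons)) > 0
    }, logical(1))
    if (any(hit)) {
      rows[[i]] <- tibble(kmer = km, motif_id = motifs$motif_id[hit])
    }
  }
  bind_rows_or(rows, tibble(kmer = character(0), motif_id = character(0)))
}

# Start positions (0-based) where `word` (plain ACGT) fits inside the IUPAC
# string `consensus` position-wise.
iupac_match_starts <- function(word, consensus) {
  k <- nchar(word)
  w <- nchar(consensus)
  if (k > w) return(integer(0))
  wc <- strsplit(word, "")[[1]]
  cc <- strsplit(consensus, "")[[1]]
  ok <- integer(0)
  for (s in 0:(w - k)) {
    if (all(mapply(function(b, iu) b %in% IUPAC_SETS[[iu]], wc, cc[s + seq_len(k)]))) {
      ok <- c(ok, s)
    }
  }
  ok
}
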