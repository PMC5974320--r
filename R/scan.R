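# Motif occurrence scanning.
#
# Two modes: exact degenerate-consensus (IUPAC) matching, and PWM log-odds
# scanning with an exact score p-value obtained by dynamic programming over
# the null distribution of window scores (the convolution of per-column
# score masses under the background, discretized on a fixed grid). Scanning
# is forward-strand only — these are single-stranded mRNA elements — and
# overlapping occurrences are all reported.

empty_occurrences <- function() {
  tibble(gene_id = character(0), motif_id = character(0), start = integer(0),
         matched = character(0), score = numeric(0), p_value = numeric(0))
}

# bind_rows over a list that may be all-NULL, with a guaranteed shape
bind_rows_or <- function(rows, template) {
  out <- bind_rows(rows)
  if (!nrow(out) || !ncol(out)) template else out
}

coerce_motif <- function(motif) {
  if (is.character(motif) && length(motif) == 1L) {
    return(motif_from_iupac(motif, motif))
  }
  stopifnot(is.data.frame(motif), nrow(motif) == 1L)
  motif
}

coerce_utrs <- function(utr) {
  if (is.character(utr)) {
    ids <- names(utr) %||% paste0("seq", seq_along(utr))
    return(utr_set(setNames(as_dna(utr), ids)))
  }
  utr
}

#' Scan sequences for exact IUPAC consensus matches
#'
#' Reports every window position-wise compatible with the motif's IUPAC
#' sets; overlapping hits are all reported; positions are 0-based.
#'
#' @param utr UTR set tibble, or a (named) character vector of sequences.
#' @param motif one-row motif tibble or a bare IUPAC string.
#' @return tibble with `gene_id`, `motif_id`, `start` (0-based), `matched`,
#'   `score` (the motif width), `p_value` (`NA` in IUPAC mode).
#' @export
scan_iupac <- function(utr, motif) {
  utrs <- coerce_utrs(utr)
  motif <- coerce_motif(motif)
  cons <- motif$consensus[1]
  w <- nchar(cons)
  allowed <- lapply(strsplit(cons, "")[[1]], function(ch) IUPAC_SETS[[ch]])
  rows <- pmap(list(utrs$gene_id, utrs$seq), function(id, s) {
    n <- nchar(s)
    if (w > n) return(NULL)
    chars <- strsplit(s, "")[[1]]
    starts <- seq_len(n - w + 1L)
    ok <- rep(TRUE, length(starts))
    for (j in seq_len(w)) {
      ok <- ok & chars[starts + j - 1L] %in% allowed[[j]]
      if (!any(ok)) break
    }
    if (!any(ok)) return(NULL)
    hit <- starts[ok]
    tibble(gene_id = id, motif_id = motif$motif_id[1], start = hit - 1L,
           matched = substring(s, hit, hit + w - 1L),
           score = w, p_value = NA_real_)
  })
  bind_rows_or(rows, empty_occurrences())
}

# Integer-grid log-odds score matrix and null score distribution of a PWM.
pwm_score_model <- function(pwm, background, pseudocount = 1e-4, step = 1e-3) {
  stopifnot(abs(sum(background) - 1) < 1e-6)
  bg <- background
  if (any(bg <= 0)) {
    bg <- bg + pseudocount
    bg <- bg / sum(bg)
  }
  p <- sweep(pwm + pseudocount, 2, colSums(pwm + pseudocount), "/")
  score <- log2(p / bg)
  int_score <- round(score / step)
  w <- ncol(pwm)
  lo <- sum(apply(int_score, 2, min))
  hi <- sum(apply(int_score, 2, max))
  dist <- numeric(hi - lo + 1L)  # indexed by int score - lo + 1
  # convolution, column by column, under the background
  cur_lo <- 0L
  cur <- 1
  for (j in seq_len(w)) {
    smin <- min(int_score[, j])
    new_lo <- cur_lo + smin
    new_hi <- cur_lo + length(cur) - 1L + max(int_score[, j])
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- int_score[b, j] - smin
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * bg[b]
    }
    cur <- new
    cur_lo <- new_lo
  }
  tail <- rev(cumsum(rev(cur)))  # P(S >= s) for s = cur_lo .. cur_lo+len-1
  list(score = score, int_score = int_score, step = step,
       dist = cur, dist_lo = cur_lo, tail = tail)
}

#' Exact PWM score threshold for a match p-value level
#'
#' Computes the full null distribution of window log-odds scores under the
#' background by dynamic programming (scores discretized at `step` log2
#' units) and returns the smallest score whose upper-tail probability is at
#' most `alpha`.
#'
#' @param motif one-row motif tibble with a PWM.
#' @param background base frequencies (A,C,G,T), summing to 1.
#' @param alpha match p-value level (default 0.001).
#' @param pseudocount added to PWM entries (and to zero background entries)
#'   before taking log-odds.
#' @param step score discretization step in log2 units.
#' @return object of class `pwm_threshold`: list with `threshold` (score),
#'   `alpha`, and the score model used by [scan_pwm()].
#' @export
pwm_pvalue_threshold <- function(motif, background = c(A = 0.25, C = 0.25,
                                                       G = 0.25, T = 0.25),
                                 alpha = 0.001, pseudocount = 1e-4, step = 1e-3) {
  motif <- coerce_motif(motif)
  pwm <- motif_pwm(motif, 1)
  model <- pwm_score_model(pwm, background, pseudocount, step)
  ok <- which(model$tail <= alpha + 1e-15)
  thr_int <- if (length(ok)) model$dist_lo + ok[1] - 1L
             else model$dist_lo + length(model$tail)  # above max score: nothing matches
  list(threshold = thr_int * model$step, threshold_int = thr_int,
       alpha = alpha, motif_id = motif$motif_id[1], model = model) |>
    structure(class = "pwm_threshold")
}

#' @export
print.pwm_threshold <- function(x, ...) {
  cat(sprintf("PWM score threshold for motif '%s': %.4f (match p <= %g)\n",
              x$motif_id, x$threshold, x$alpha))
  invisible(x)
}

# Upper-tail p of an integer grid score.
pwm_tail_p <- function(model, int_s) {
  i <- int_s - model$dist_lo + 1L
  i <- pmin(pmax(i, 1L), length(model$tail) + 1L)
  ifelse(i > length(model$tail), 0, model$tail[i])
}

#' Scan sequences with a PWM at an exact p-value threshold
#'
#' @param utr UTR set tibble or (named) character vector.
#' @param motif one-row motif tibble with a PWM.
#' @param threshold a `pwm_threshold` from [pwm_pvalue_threshold()]; when
#'   omitted it is computed at `alpha` under `background`.
#' @param alpha,background used only when `threshold` is not supplied.
#' @return tibble as [scan_iupac()] with log-odds `score` and exact match
#'   `p_value` per hit.
#' @export
scan_pwm <- function(utr, motif, threshold = NULL, alpha = 0.001,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  utrs <- coerce_utrs(utr)
  motif <- coerce_motif(motif)
  if (is.null(threshold)) {
    threshold <- pwm_pvalue_threshold(motif, background, alpha)
  }
  model <- threshold$model
  ints <- model$int_score
  w <- ncol(ints)
  rows <- pmap(list(utrs$gene_id, utrs$seq), function(id, s) {
    n <- nchar(s)
    if (w > n) return(NULL)
    base_idx <- match(strsplit(s, "")[[1]], DNA_BASES)
    n_win <- n - w + 1L
    win_int <- integer(n_win)
    for (j in seq_len(w)) {
      win_int <- win_int + ints[cbind(base_idx[seq_len(n_win) + j - 1L], j)]
    }
    hit <- which(win_int >= threshold$threshold_int)
    if (!length(hit)) return(NULL)
    tibble(gene_id = id, motif_id = motif$motif_id[1], start = hit - 1L,
           matched = substring(s, hit, hit + w - 1L),
           score = win_int[hit] * model$step,
           p_value = pwm_tail_p(model, win_int[hit]))
  })
  bind_rows_or(rows, empty_occurrences())
}

scan_motif <- function(utrs, motif, mode = c("iupac", "pwm"), alpha = 0.001,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  mode <- match.arg(mode)
  if (mode == "iupac") scan_iupac(utrs, motif)
  else scan_pwm(utrs, motif, alpha = alpha, background = background)
}

#' Per-category motif presence summary
#'
#' For every (motif, category): the number of genes, the number with at
#' least one occurrence, the proportion with a hit (the heatmap quantity)
#' and occurrences per kbp of category UTR sequence.
#'
#' @param utrs UTR set tibble.
#' @param categories tibble with `gene_id`, `category`.
#' @param motifs motif set tibble.
#' @param mode `"iupac"` or `"pwm"`.
#' @param alpha match p-value level (PWM mode).
#' @return long tibble with `motif_id`, `category`, `n_genes`, `n_with_hit`,
#'   `proportion`, `occ_per_kbp`.
#' @export
presence_summary <- function(utrs, categories, motifs, mode = c("iupac", "pwm"),
                             alpha = 0.001) {
  mode <- match.arg(mode)
  utrs <- inner_join(utrs, select(categories, "gene_id", "category"), by = "gene_id")
  if (!nrow(utrs)) abort("no UTR has a category assignment")
  cats <- unique(as.character(utrs$category))
  rows <- list()
  for (i in seq_len(nrow(motifs))) {
    hits <- scan_motif(select(utrs, -"category"), motifs[i, ], mode, alpha)
    hit_counts <- count(hits, .data$gene_id, name = "n_occ")
    per_gene <- utrs |>
      left_join(hit_counts, by = "gene_id") |>
      mutate(n_occ = dplyr::coalesce(.data$n_occ, 0L))
    rows[[i]] <- per_gene |>
      group_by(.data$category) |>
      summarise(n_genes = dplyr::n(), n_with_hit = sum(.data$n_occ > 0),
                proportion = .data$n_with_hit / .data$n_genes,
                occ_per_kbp = sum(.data$n_occ) / sum(.data$width) * 1000,
                .groups = "drop") |>
      mutate(motif_id = motifs$motif_id[i]) |>
      relocate("motif_id")
  }
  bind_rows(rows)
}

#' One-sided Fisher enrichment of motif presence
#'
#' Upper-tail (enrichment) hypergeometric p for a 2x2 table of genes with /
#' without a motif in a category versus a control set; the odds ratio uses
#' the Haldane 0.5 correction when any cell is zero.
#'
#' @param a_with,a_without genes with/without the motif in the category.
#' @param b_with,b_without genes with/without the motif in the control.
#'   All four arguments are vectorized over tables.
#' @return tibble with one row per table: the four cells, `odds_ratio`
#'   (Haldane-corrected when a cell is zero) and one-sided `p_value`.
#' @export
fisher_enrichment <- function(a_with, a_without, b_with, b_without) {
  cells <- cbind(a_with, a_without, b_with, b_without)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  if (any(rowSums(cells) == 0)) abort("all-zero contingency table")
  p <- phyper(a_with - 1, a_with + b_with, a_without + b_without,
              a_with + a_without, lower.tail = FALSE)
  h <- ifelse(rowSums(cells == 0) > 0, 0.5, 0)
  or <- ((a_with + h) * (b_without + h)) / ((a_without + h) * (b_with + h))
  tibble(a_with = a_with, a_without = a_without, b_with = b_with,
         b_without = b_without, odds_ratio = or, p_value = p)
}

#' Positional occurrence map of motifs along UTRs
#'
#' @param utr UTR set tibble or (named) character vector.
#' @param motifs motif set tibble.
#' @param mode,alpha as [presence_summary()].
#' @return tibble with `gene_id`, `motif_id`, `start`, sorted by position —
#'   ready for plotting occurrence tracks along a 3'UTR.
#' @export
position_map <- function(utr, motifs, mode = c("iupac", "pwm"), alpha = 0.001) {
  mode <- match.arg(mode)
  utrs <- coerce_utrs(utr)
  rows <- map(seq_len(nrow(motifs)), function(i) {
    scan_motif(utrs, motifs[i, ], mode, alpha) |>
      select("gene_id", "motif_id", "start")
  })
  bind_rows_or(rows, select(empty_occurrences(), "gene_id", "motif_id", "start")) |>
    arrange(.data$gene_id, .data$motif_id, .data$start)
}
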