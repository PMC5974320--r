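# Seeded synthetic data with the statistical structure the analysis assumes:
# segment count matrices built from localization archetypes, anchor Cq
# tables, 3'UTR sets with category-dependent planted motifs, and .L/.S
# homoeologue pairs with a designed discordant fraction. Every gene's true
# fraction profile is drawn from a Dirichlet around its category archetype
# and rejection-sampled until it satisfies its own category's rules, so the
# generated truth is classified-back by construction; measurement noise
# (negative-binomial counting, Cq noise, segment library distortions) is
# layered on top and can be switched off for exact-recovery experiments.

#' Synthetic-study configuration
#'
#' Defaults emulate the structure of a tomographic egg study at desk scale:
#' 2000 genes over five segments with three replicates, category proportions
#' 2.8 / 94.4 / 1.3 / 0.2 / 1.3 percent (extremely animal, animal, vegetal,
#' extremely vegetal, other), archetype profiles sitting safely inside each
#' rule region, deep-sequencing counting noise, ten qPCR anchor genes, ~0.9
#' kb 3'UTRs with a vegetally planted TTCAC element, and half the genes in
#' .L/.S pairs of which 3 percent are discordant.
#'
#' @param seed integer seed; every random draw flows from it.
#' @param n_genes number of base genes.
#' @param category_proportions named proportions over the five RNA
#'   categories (must sum to 1).
#' @param archetypes named list of five-segment fraction vectors; each must
#'   satisfy its own category's classification rules.
#' @param dirichlet_concentration total Dirichlet concentration of per-gene
#'   profile draws around the archetype (larger = tighter).
#' @param abundance_meanlog,abundance_sdlog log-normal expected total counts
#'   per gene and replicate.
#' @param nb_size negative-binomial size (inverse dispersion) of counting
#'   noise.
#' @param count_model `"nb"`, `"poisson"`, or `"none"` (observed = expected,
#'   for noise-free validation runs).
#' @param segment_distortion per-segment multiplicative library biases
#'   (length 5).
#' @param n_replicates sequencing replicates.
#' @param n_anchors,anchor_abundance qPCR anchor genes appended to the count
#'   table (abundant, spanning the categories).
#' @param cq_sigma Cq technical noise, cycles.
#' @param n_proteins,protein_proportions,protein_archetypes,protein_sdlog
#'   four-segment proteome settings (log-normal intensity noise).
#' @param utr_meanlog,utr_sdlog,utr_min_length 3'UTR length distribution.
#' @param base_composition background base frequencies (A,C,G,T).
#' @param plant_motif,plant_rates planted localization element (IUPAC
#'   string) and per-category Poisson copies per UTR.
#' @param pair_fraction fraction of base genes expanded into .L/.S pairs.
#' @param discordant_q probability a pair's S copy is re-assigned to a
#'   different category.
#' @param s_mutation_rate per-base substitution rate of the S-copy UTR
#'   background.
#' @return list of class `synth_config` (validated).
#' @export
synth_config <- function(
    seed = 1L,
    n_genes = 2000L,
    category_proportions = c(extremely_animal = 0.028, animal = 0.944,
                             vegetal = 0.013, extremely_vegetal = 0.002,
                             other = 0.013),
    archetypes = list(
      extremely_animal = c(0.40, 0.30, 0.15, 0.10, 0.05),
      animal = c(0.25, 0.35, 0.20, 0.12, 0.08),
      vegetal = c(0.10, 0.10, 0.15, 0.35, 0.30),
      extremely_vegetal = c(0.05, 0.05, 0.10, 0.15, 0.65),
      other = rep(0.2, 5)
    ),
    dirichlet_concentration = 200,
    abundance_meanlog = log(4000), abundance_sdlog = 1.2,
    nb_size = 2000, count_model = c("nb", "poisson", "none"),
    segment_distortion = rep(1, 5),
    n_replicates = 3L,
    n_anchors = 10L, anchor_abundance = 5e4, cq_sigma = 0.2,
    n_proteins = 400L,
    protein_proportions = c(animal = 0.15, even = 0.70, vegetal = 0.15),
    protein_archetypes = list(
      animal = c(0.40, 0.25, 0.20, 0.15),
      even = c(0.20, 0.32, 0.28, 0.20),
      vegetal = c(0.15, 0.20, 0.25, 0.40)
    ),
    protein_sdlog = 0.05,
    utr_meanlog = log(900), utr_sdlog = 0.5, utr_min_length = 100L,
    base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    plant_motif = "TTCAC",
    plant_rates = c(extremely_animal = 0, animal = 0, vegetal = 2,
                    extremely_vegetal = 2, other = 0),
    pair_fraction = 0.5, discordant_q = 0.03, s_mutation_rate = 0.01) {
  count_model <- match.arg(count_model)
  stopifnot(abs(sum(category_proportions) - 1) < 1e-9,
            setequal(names(category_proportions), RNA_CATEGORIES),
            abs(sum(protein_proportions) - 1) < 1e-9,
            length(segment_distortion) == 5, all(segment_distortion > 0),
            all(unlist(plant_rates) >= 0), pair_fraction >= 0, pair_fraction <= 1,
            discordant_q >= 0, discordant_q <= 1)
  cfg <- mget(names(formals()))
  cfg$count_model <- count_model
  for (cat in names(archetypes)) {
    got <- classify_rna(archetypes[[cat]], normalize = TRUE)
    if (got != cat) {
      abort(sprintf("RNA archetype for '%s' classifies as '%s'", cat, got))
    }
  }
  for (cat in names(protein_archetypes)) {
    got <- classify_protein(protein_archetypes[[cat]], normalize = TRUE)
    if (got != cat) {
      abort(sprintf("protein archetype for '%s' classifies as '%s'", cat, got))
    }
  }
  structure(cfg, class = "synth_config")
}

# n draws from Dirichlet(alpha); rows sum to 1.
rdirichlet_mat <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# Fraction profiles for one category: Dirichlet around the archetype,
# rejection-sampled until each profile satisfies its category's rules.
draw_category_profiles <- function(n, category, config) {
  if (n == 0) return(matrix(numeric(0), 0, 5, dimnames = list(NULL, RNA_SEGMENTS)))
  alpha <- config$dirichlet_concentration * config$archetypes[[category]]
  out <- matrix(NA_real_, n, 5, dimnames = list(NULL, RNA_SEGMENTS))
  need <- seq_len(n)
  for (round in 1:100) {
    draw <- rdirichlet_mat(length(need), alpha)
    colnames(draw) <- RNA_SEGMENTS
    lab <- classify_rna(as_tibble(draw))$category
    ok <- lab == category
    out[need[ok], ] <- draw[ok, , drop = FALSE]
    need <- need[!ok]
    if (!length(need)) break
  }
  if (length(need)) {
    abort(sprintf("could not draw rule-consistent profiles for '%s'", category))
  }
  out
}

simulate_truth <- function(config) {
  n_cat <- as.vector(stats::rmultinom(1, config$n_genes,
                                      config$category_proportions[RNA_CATEGORIES]))
  names(n_cat) <- RNA_CATEGORIES
  rows <- list()
  for (cat in RNA_CATEGORIES) {
    prof <- draw_category_profiles(n_cat[[cat]], cat, config)
    if (!nrow(prof)) next
    rows[[cat]] <- tibble(category = cat, as_tibble(prof))
  }
  truth <- bind_rows(rows)
  truth <- truth[sample.int(nrow(truth)), ]
  truth$gene_id <- sprintf("g%05d", seq_len(nrow(truth)))
  truth$abundance <- rlnorm(nrow(truth), config$abundance_meanlog,
                            config$abundance_sdlog)
  truth$is_anchor <- FALSE
  # anchors: abundant genes cycling through the categories
  anchor_cats <- rep(RNA_CATEGORIES, length.out = config$n_anchors)
  arows <- map(seq_len(config$n_anchors), function(i) {
    prof <- draw_category_profiles(1, anchor_cats[i], config)
    tibble(category = anchor_cats[i], as_tibble(prof),
           gene_id = sprintf("anchor%02d", i),
           abundance = config$anchor_abundance, is_anchor = TRUE)
  })
  bind_rows(truth, bind_rows(arows)) |> relocate("gene_id")
}

counts_from_truth <- function(config, truth) {
  segs <- RNA_SEGMENTS
  frac <- as.matrix(truth[, segs])
  rows <- list()
  for (r in seq_len(config$n_replicates)) {
    mu <- frac * truth$abundance  # genes x segments
    mu <- sweep(mu, 2, config$segment_distortion, "*")
    obs <- switch(config$count_model,
      nb = matrix(rnbinom(length(mu), mu = mu, size = config$nb_size), nrow(mu)),
      poisson = matrix(rpois(length(mu), mu), nrow(mu)),
      none = mu)
    colnames(obs) <- segs
    rows[[r]] <- tibble(gene_id = rep(truth$gene_id, times = 5),
                        segment = rep(segs, each = nrow(truth)),
                        replicate = r, value = as.vector(obs))
  }
  bind_rows(rows) |>
    arrange(.data$gene_id, factor(.data$segment, levels = segs), .data$replicate)
}

simulate_cq <- function(config, truth, n_cq_replicates = 3L) {
  anchors <- filter(truth, .data$is_anchor)
  rows <- list()
  for (r in seq_len(n_cq_replicates)) {
    offset <- 15 + rnorm(1)  # per-replicate plate/input offset; cancels
    for (i in seq_len(nrow(anchors))) {
      fr <- as.numeric(anchors[i, RNA_SEGMENTS])
      cqv <- -log2(fr) + offset + rnorm(5, 0, config$cq_sigma)
      rows[[length(rows) + 1L]] <- tibble(
        anchor_id = anchors$gene_id[i], segment = RNA_SEGMENTS,
        replicate = r, cq = cqv, efficiency = 2)
    }
  }
  bind_rows(rows)
}

#' Simulate a tomographic RNA-seq experiment
#'
#' @param config `synth_config`.
#' @param truth optionally a pre-built truth table (e.g. after
#'   [simulate_homoeologs()]); by default one is drawn from the config.
#' @return list with `counts` (long segment tibble, anchors included), `cq`
#'   (anchor Cq tibble) and `truth` (per-gene category, true fractions
#'   `A`..`E`, abundance, `is_anchor`).
#' @export
simulate_rna <- function(config, truth = NULL) {
  if (is.null(truth)) {
    set.seed(config$seed)
    truth <- simulate_truth(config)
  }
  set.seed(config$seed + 2L)
  counts <- counts_from_truth(config, truth)
  cq <- simulate_cq(config, truth)
  list(counts = counts, cq = cq, truth = truth)
}

#' Expand a truth table with .L/.S homoeologue pairs
#'
#' A `pair_fraction` share of base genes is duplicated into `.L` and `.S`
#' copies. The S copy keeps the L category with probability `1 -
#' discordant_q`, otherwise it is re-assigned to a different category
#' (sampled by the remaining categories' proportions); either way its
#' fraction profile is re-drawn from its own category. Unpaired genes keep
#' their plain ids.
#'
#' @param config `synth_config`.
#' @param truth truth tibble (default: drawn from the config).
#' @return list with `truth` (updated) and `pairs` (tibble `base_symbol`,
#'   `gene_l`, `gene_s`, `designed_concordant`).
#' @export
simulate_homoeologs <- function(config, truth = NULL) {
  if (is.null(truth)) {
    set.seed(config$seed)
    truth <- simulate_truth(config)
  }
  set.seed(config$seed + 1L)
  base <- filter(truth, !.data$is_anchor)
  anchors <- filter(truth, .data$is_anchor)
  n_pairs <- round(config$pair_fraction * nrow(base))
  sel <- sort(sample.int(nrow(base), n_pairs))
  paired <- base[sel, ]
  rest <- base[-sel, ]
  discord <- runif(n_pairs) < config$discordant_q
  s_cat <- paired$category
  for (i in which(discord)) {
    others <- setdiff(RNA_CATEGORIES, paired$category[i])
    w <- config$category_proportions[others]
    s_cat[i] <- sample(others, 1, prob = w / sum(w))
  }
  s_rows <- paired
  s_rows$category <- s_cat
  for (cat in unique(s_cat)) {
    idx <- which(s_cat == cat)
    s_rows[idx, RNA_SEGMENTS] <-
      as_tibble(draw_category_profiles(length(idx), cat, config))
  }
  s_rows$abundance <- rlnorm(n_pairs, config$abundance_meanlog, config$abundance_sdlog)
  l_rows <- paired
  base_symbol <- paired$gene_id
  l_rows$gene_id <- paste0(base_symbol, ".L")
  s_rows$gene_id <- paste0(base_symbol, ".S")
  pairs <- tibble(base_symbol = base_symbol, gene_l = l_rows$gene_id,
                  gene_s = s_rows$gene_id, designed_concordant = !discord)
  list(truth = bind_rows(rest, l_rows, s_rows, anchors), pairs = pairs)
}

random_sequence <- function(n, composition) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = composition), collapse = "")
}

plant_motif_copies <- function(seq, motif, n_copies) {
  w <- nchar(motif)
  n <- nchar(seq)
  if (n_copies == 0) return(list(seq = seq, starts = integer(0)))
  if (w > n) {
    message("motif longer than UTR; insertion skipped")
    return(list(seq = seq, starts = integer(0)))
  }
  occupied <- integer(0)
  starts <- integer(0)
  for (i in seq_len(n_copies)) {
    placed <- FALSE
    for (try in 1:50) {
      s <- sample.int(n - w + 1L, 1)
      if (!any(abs(s - occupied) < w)) {
        occupied <- c(occupied, s)
        starts <- c(starts, s)
        placed <- TRUE
        break
      }
    }
    if (!placed) message("no room for motif copy; insertion skipped")
  }
  for (s in starts) substr(seq, s, s + w - 1L) <- motif
  list(seq = seq, starts = sort(starts) - 1L)  # 0-based
}

#' Simulate 3'UTR sequences with category-dependent planted motifs
#'
#' Backgrounds are iid sequences from the configured base composition with
#' log-normal lengths; each UTR receives a Poisson number (the category's
#' planting rate) of copies of the planted motif at uniform non-overlapping
#' positions. For homoeologue pairs the S-copy background is the mutated
#' L background (per-base substitution rate `s_mutation_rate`) and planting
#' follows each copy's own category.
#'
#' @param config `synth_config`.
#' @param truth truth tibble (with `.L`/`.S` ids when `pairs` is given).
#' @param pairs optional pair map from [simulate_homoeologs()].
#' @return list with `utrs` (UTR set tibble) and `plants` (tibble
#'   `gene_id`, `motif`, `start`, 0-based planted positions).
#' @export
simulate_utrs <- function(config, truth, pairs = NULL) {
  set.seed(config$seed + 3L)
  motif <- as_dna(config$plant_motif)
  genes <- filter(truth, !.data$is_anchor)
  lens <- pmax(config$utr_min_length,
               round(rlnorm(nrow(genes), config$utr_meanlog, config$utr_sdlog)))
  backgrounds <- setNames(vapply(lens, random_sequence, character(1),
                                 composition = config$base_composition),
                          genes$gene_id)
  if (!is.null(pairs)) {
    # S background = mutated copy of the L background
    for (i in seq_len(nrow(pairs))) {
      lseq <- backgrounds[[pairs$gene_l[i]]]
      chars <- strsplit(lseq, "")[[1]]
      mut <- runif(length(chars)) < config$s_mutation_rate
      if (any(mut)) {
        chars[mut] <- vapply(chars[mut], function(b) {
          sample(setdiff(DNA_BASES, b), 1)
        }, character(1))
      }
      backgrounds[[pairs$gene_s[i]]] <- paste(chars, collapse = "")
    }
  }
  seqs <- character(nrow(genes))
  plant_rows <- list()
  for (i in seq_len(nrow(genes))) {
    rate <- config$plant_rates[[genes$category[i]]]
    n_copies <- if (rate > 0) rpois(1, rate) else 0L
    planted <- plant_motif_copies(backgrounds[[genes$gene_id[i]]], motif, n_copies)
    seqs[i] <- planted$seq
    if (length(planted$starts)) {
      plant_rows[[length(plant_rows) + 1L]] <-
        tibble(gene_id = genes$gene_id[i], motif = motif, start = planted$starts)
    }
  }
  list(utrs = utr_set(setNames(seqs, genes$gene_id)),
       plants = bind_rows_or(plant_rows, tibble(gene_id = character(0),
                                                motif = character(0),
                                                start = integer(0))))
}

#' Simulate a four-segment proteome intensity table
#'
#' Intensities are archetype fractions scaled by a log-normal protein
#' abundance with multiplicative log-normal noise per cell; three replicates.
#'
#' @param config `synth_config`.
#' @return list with `intensities` (long segment tibble over A..D) and
#'   `truth` (`protein_id`, `category`).
#' @export
simulate_protein <- function(config) {
  set.seed(config$seed + 4L)
  n <- config$n_proteins
  cats <- sample(names(config$protein_proportions), n, replace = TRUE,
                 prob = config$protein_proportions)
  abundance <- rlnorm(n, 0, 1)
  rows <- list()
  for (r in seq_len(config$n_replicates)) {
    mu <- t(vapply(cats, function(cat) config$protein_archetypes[[cat]],
                   numeric(4))) * abundance
    obs <- mu * matrix(rlnorm(length(mu), 0, config$protein_sdlog), nrow(mu))
    colnames(obs) <- PROTEIN_SEGMENTS
    rows[[r]] <- tibble(gene_id = rep(sprintf("p%04d", seq_len(n)), times = 4),
                        segment = rep(PROTEIN_SEGMENTS, each = n),
                        replicate = r, value = as.vector(obs))
  }
  list(intensities = bind_rows(rows) |>
         arrange(.data$gene_id, .data$segment, .data$replicate),
       truth = tibble(protein_id = sprintf("p%04d", seq_len(n)), category = cats))
}

#' Simulate the full study: RNA, anchors, UTRs, homoeologues, proteome
#'
#' @param config `synth_config`.
#' @param homoeologs expand genes into .L/.S pairs (default TRUE).
#' @return list with `counts`, `cq`, `utrs`, `plants`, `truth`, `pairs`
#'   (NULL when `homoeologs = FALSE`), `protein` (list of `intensities`,
#'   `truth`).
#' @export
simulate_dataset <- function(config, homoeologs = TRUE) {
  set.seed(config$seed)
  truth <- simulate_truth(config)
  pairs <- NULL
  if (homoeologs) {
    hom <- simulate_homoeologs(config, truth)
    truth <- hom$truth
    pairs <- hom$pairs
  }
  rna <- simulate_rna(config, truth)
  utr <- simulate_utrs(config, truth, pairs)
  prot <- simulate_protein(config)
  list(counts = rna$counts, cq = rna$cq, utrs = utr$utrs, plants = utr$plants,
       truth = truth, pairs = pairs, protein = prot)
}
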