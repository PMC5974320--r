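small_cfg <- function(seed = 11, ...) {
  synth_config(seed = seed, n_genes = 120, n_anchors = 5, n_proteins = 60, ...)
}

test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_cfg()
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$cq, b$cq)
  expect_identical(a$utrs, b$utrs)
  expect_identical(a$truth, b$truth)
  expect_identical(a$protein$intensities, b$protein$intensities)
  # and different under another seed
  c_ <- simulate_dataset(small_cfg(seed = 12))
  expect_false(identical(a$counts$value, c_$counts$value))
})

test_that("archetypes violating their own rules are rejected at config time", {
  bad <- list(extremely_animal = c(0.2, 0.2, 0.2, 0.2, 0.2),
              animal = c(0.25, 0.35, 0.20, 0.12, 0.08),
              vegetal = c(0.10, 0.10, 0.15, 0.35, 0.30),
              extremely_vegetal = c(0.05, 0.05, 0.10, 0.15, 0.65),
              other = rep(0.2, 5))
  expect_error(small_cfg(archetypes = bad), "classifies as")
  bad_prot <- list(animal = c(0.15, 0.20, 0.25, 0.40),
                   even = c(0.20, 0.32, 0.28, 0.20),
                   vegetal = c(0.40, 0.25, 0.20, 0.15))
  expect_error(small_cfg(protein_archetypes = bad_prot), "classifies as")
})

test_that("generated truth is classified-back by construction", {
  sim <- simulate_rna(small_cfg())
  truth_labels <- classify_rna(sim$truth[, c("gene_id", "A", "B", "C", "D", "E")],
                               normalize = TRUE)
  expect_identical(as.character(truth_labels$category), sim$truth$category)
})

test_that("noise-free counts reproduce the truth exactly", {
  cfg <- small_cfg(count_model = "none", cq_sigma = 0)
  sim <- simulate_rna(cfg)
  labels <- classify_rna(consensus_fractions(to_fractions(sim$counts)))
  expect_equal(classification_accuracy(labels, sim$truth), 1)
})

test_that("protein simulation recovers designed categories under the quorum rule", {
  cfg <- small_cfg(protein_sdlog = 0.01)
  prot <- simulate_protein(cfg)
  fr <- to_fractions(global_mean_normalize(prot$intensities))
  labels <- classify_replicates(fr, "protein")
  m <- dplyr::inner_join(labels, dplyr::rename(prot$truth, gene_id = protein_id),
                         by = "gene_id")
  expect_equal(mean(as.character(m$category.x) == m$category.y), 1)

  # quorum absorbs one corrupted replicate
  corrupted <- dplyr::mutate(fr, fraction = ifelse(replicate == 3, 0.25, fraction))
  labels2 <- classify_replicates(corrupted, "protein")
  m2 <- dplyr::inner_join(labels2, dplyr::rename(prot$truth, gene_id = protein_id),
                          by = "gene_id")
  expect_equal(mean(as.character(m2$category.x) == m2$category.y), 1)
})

test_that("UTR simulation plants motifs where it says it does", {
  cfg <- small_cfg()
  sim <- simulate_rna(cfg)
  utr <- simulate_utrs(cfg, sim$truth)
  expect_equal(nrow(utr$utrs), sum(!sim$truth$is_anchor))
  # every recorded plant is an actual occurrence at that position
  hits <- scan_iupac(utr$utrs, cfg$plant_motif)
  keyed <- paste(hits$gene_id, hits$start)
  expect_true(all(paste(utr$plants$gene_id, utr$plants$start) %in% keyed))
  # planting is confined to the vegetal-side categories by default
  veg_genes <- sim$truth$gene_id[sim$truth$category %in%
                                   c("vegetal", "extremely_vegetal")]
  expect_true(all(utr$plants$gene_id %in% veg_genes))

  # with no planting anywhere, presence matches the uniform background rate
  cfg0 <- synth_config(seed = 21, n_genes = 400,
                       plant_rates = c(extremely_animal = 0, animal = 0,
                                       vegetal = 0, extremely_vegetal = 0,
                                       other = 0),
                       utr_meanlog = log(1000), utr_sdlog = 0)
  sim0 <- simulate_rna(cfg0)
  utr0 <- simulate_utrs(cfg0, sim0$truth)
  expect_equal(nrow(utr0$plants), 0)
  hit_rate <- dplyr::n_distinct(scan_iupac(utr0$utrs, "TTCAC")$gene_id) /
    nrow(utr0$utrs)
  p_bg <- 1 - (1 - 4^-5)^(1000 - 5 + 1)  # approx. per-UTR background hit prob.
  expect_lt(abs(hit_rate - p_bg), 0.07)
})

test_that("homoeologue expansion respects the designed discordance", {
  cfg <- small_cfg(pair_fraction = 1, discordant_q = 0)
  hom <- simulate_homoeologs(cfg)
  expect_equal(nrow(hom$pairs), 120)
  cats <- tibble::tibble(gene_id = hom$truth$gene_id, category = hom$truth$category)
  conc <- concordance(hom$pairs, cats)
  expect_equal(conc$fraction_concordant, 1)

  cfg2 <- small_cfg(pair_fraction = 0.5, discordant_q = 1)
  hom2 <- simulate_homoeologs(cfg2)
  expect_equal(nrow(hom2$pairs), 60)
  cats2 <- tibble::tibble(gene_id = hom2$truth$gene_id, category = hom2$truth$category)
  expect_equal(concordance(hom2$pairs, cats2)$fraction_concordant, 0)
  # designed flags agree with realized categories
  expect_true(all(!hom2$pairs$designed_concordant))

  # S-copy UTRs exist and follow their own category's planting
  utr2 <- simulate_utrs(cfg2, hom2$truth, hom2$pairs)
  expect_true(all(c(hom2$pairs$gene_l, hom2$pairs$gene_s) %in% utr2$utrs$gene_id))
})
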