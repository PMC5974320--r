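cq_tbl <- function(cq_by_rep, anchor = "a", segs = NULL, efficiency = 2) {
  segs <- segs %||% c("A", "B", "C", "D", "E")[seq_along(cq_by_rep[[1]])]
  dplyr::bind_rows(lapply(seq_along(cq_by_rep), function(r) {
    tibble::tibble(anchor_id = anchor, segment = segs, replicate = r,
                   cq = cq_by_rep[[r]], efficiency = efficiency)
  }))
}

long_counts <- function(values, segs, gene = "g", rep = 1L) {
  tibble::tibble(gene_id = gene, segment = segs, replicate = rep, value = values)
}

test_that("Cq profiles convert to fractions by efficiency^(-Cq)", {
  expect_equal(cq_to_fractions(cq_tbl(list(rep(10, 5))), "a")$fraction, rep(0.2, 5))
  expect_equal(cq_to_fractions(cq_tbl(list(c(10, 11)), segs = c("A", "B")), "a")$fraction,
               c(2 / 3, 1 / 3))
  expect_equal(cq_to_fractions(cq_tbl(list(c(10, 12)), segs = c("A", "B")), "a")$fraction,
               c(0.8, 0.2))
  # per-replicate plate offsets cancel
  with_offset <- cq_tbl(list(c(10, 12), c(20, 22)), segs = c("A", "B"))
  expect_equal(cq_to_fractions(with_offset, "a")$fraction, c(0.8, 0.2))
})

test_that("Cq validation rejects bad efficiency and missing segments", {
  expect_error(cq_to_fractions(cq_tbl(list(c(10, 11)), segs = c("A", "B"),
                                      efficiency = 1), "a"), "efficiency")
  expect_error(cq_to_fractions(cq_tbl(list(c(10, 11)), segs = c("A", "B"),
                                      efficiency = 2.5), "a"), "efficiency")
  partial <- cq_tbl(list(c(10, 11, 12)), segs = c("A", "B", "C"))
  rep2_short <- tibble::tibble(anchor_id = "a", segment = c("A", "B"),
                               replicate = 2L, cq = c(9, 9), efficiency = 2)
  # second replicate lacks segment C
  expect_error(cq_to_fractions(dplyr::bind_rows(partial, rep2_short), "a"),
               "missing for segment")
  expect_error(cq_to_fractions(partial, "nope"), "not present")
})

test_that("size factors recover the qPCR/RNA-seq fraction ratio", {
  # anchors whose RNA-seq fractions equal their qPCR fractions -> factors 1
  counts <- long_counts(c(80, 20), c("A", "B"), gene = "a")
  cq_match <- cq_tbl(list(-log2(c(0.8, 0.2))), segs = c("A", "B"))
  sf <- compute_size_factors(counts, cq_match)
  expect_equal(sf$size_factor, c(1, 1))

  # worked example: q = (.5,.5), r = (.8,.2) -> factors (0.5, 2.0)
  cq_flat <- cq_tbl(list(c(10, 10)), segs = c("A", "B"))
  sf2 <- compute_size_factors(counts, cq_flat)
  expect_equal(sf2$size_factor[sf2$segment == "A"], 0.5)
  expect_equal(sf2$size_factor[sf2$segment == "B"], 2.0)
  expect_equal(exp(mean(log(sf2$size_factor))), 1)  # geometric mean 1
})

test_that("the per-segment median over anchors is used", {
  # three anchors; at segment A their ratios are {1, 1, 4} before rescaling
  segs <- c("A", "B")
  counts <- dplyr::bind_rows(
    long_counts(c(50, 50), segs, gene = "a1"),
    long_counts(c(50, 50), segs, gene = "a2"),
    long_counts(c(20, 80), segs, gene = "a3"))
  cq <- dplyr::bind_rows(
    cq_tbl(list(c(10, 10)), anchor = "a1", segs = segs),
    cq_tbl(list(c(10, 10)), anchor = "a2", segs = segs),
    cq_tbl(list(c(10, 10)), anchor = "a3", segs = segs))
  sf <- compute_size_factors(counts, cq)
  # raw medians are (1, 1); rescaling keeps them equal
  expect_equal(sf$size_factor, c(1, 1))
})

test_that("unusable anchors are excluded with a warning, none is an error", {
  segs <- c("A", "B")
  counts <- dplyr::bind_rows(long_counts(c(50, 50), segs, gene = "a1"),
                             long_counts(c(0, 100), segs, gene = "a2"))
  cq <- dplyr::bind_rows(cq_tbl(list(c(10, 10)), anchor = "a1", segs = segs),
                         cq_tbl(list(c(10, 10)), anchor = "a2", segs = segs))
  expect_warning(sf <- compute_size_factors(counts, cq), "excluded")
  expect_equal(sf$size_factor, c(1, 1))
  only_bad <- dplyr::filter(counts, gene_id == "a2")
  expect_error(suppressWarnings(compute_size_factors(only_bad, cq)), "no usable anchor")
})

test_that("applying size factors scales per segment and checks labels", {
  tab <- long_counts(c(10, 20, 30, 40, 50), c("A", "B", "C", "D", "E"))
  unit <- tibble::tibble(segment = c("A", "B", "C", "D", "E"), size_factor = 1)
  expect_equal(apply_size_factors(tab, unit), tab)
  double_a <- dplyr::mutate(unit, size_factor = ifelse(segment == "A", 2, 1))
  scaled <- apply_size_factors(tab, double_a)
  expect_equal(scaled$value, c(20, 20, 30, 40, 50))
  expect_error(apply_size_factors(tab, unit[1:3, ]), "do not match")
})

test_that("expression filter removes strictly below threshold", {
  tab <- dplyr::bind_rows(
    long_counts(rep(14.9, 5), c("A", "B", "C", "D", "E"), gene = "low"),
    long_counts(rep(15.0, 5), c("A", "B", "C", "D", "E"), gene = "edge"),
    long_counts(rep(0, 5), c("A", "B", "C", "D", "E"), gene = "zero"))
  kept <- filter_low_expression(tab)
  expect_setequal(unique(kept$gene_id), "edge")
  expect_equal(dplyr::n_distinct(filter_low_expression(tab, threshold = 0)$gene_id), 3)
  expect_warning(filter_low_expression(dplyr::filter(tab, gene_id == "zero")),
                 "no gene")
})

test_that("fraction profiles sum to one and average across replicates", {
  tab <- long_counts(c(60, 20, 10, 5, 5), c("A", "B", "C", "D", "E"))
  fr <- to_fractions(tab)
  expect_equal(fr$fraction, c(0.6, 0.2, 0.1, 0.05, 0.05))

  two_rep <- dplyr::bind_rows(tab, dplyr::mutate(tab, replicate = 2L, value = value * 7))
  cons <- consensus_fractions(to_fractions(two_rep))
  expect_equal(cons$fraction, c(0.6, 0.2, 0.1, 0.05, 0.05))

  with_zero <- dplyr::bind_rows(tab, dplyr::mutate(tab, replicate = 2L, value = 0))
  expect_warning(fr2 <- to_fractions(with_zero), "zero total")
  expect_equal(unique(fr2$replicate), 1L)

  # per-replicate sums are exactly 1
  set.seed(5)
  big <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:20), each = 15),
    segment = rep(rep(c("A", "B", "C", "D", "E"), each = 3), 20),
    replicate = rep(1:3, 100), value = runif(300, 1, 100))
  sums <- to_fractions(big) |>
    dplyr::summarise(s = sum(fraction), .by = c(gene_id, replicate))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("global-mean normalization equalizes sample means", {
  set.seed(9)
  tab <- tibble::tibble(
    gene_id = rep(sprintf("p%d", 1:10), each = 8),
    segment = rep(rep(c("A", "B", "C", "D"), each = 2), 10),
    replicate = rep(1:2, 40), value = rlnorm(80))
  scale <- c(A = 1, B = 2, C = 4, D = 8)
  skewed <- dplyr::mutate(tab, value = value * scale[segment])
  norm <- global_mean_normalize(skewed)
  colmeans <- norm |> dplyr::summarise(m = mean(value), .by = c(segment, replicate))
  expect_true(all(abs(colmeans$m - 1) < 1e-12))
  # already balanced table only gets rescaled to mean 1
  expect_equal(global_mean_normalize(norm), norm)
  # single protein -> all values 1
  single <- dplyr::filter(tab, gene_id == "p1")
  expect_true(all(global_mean_normalize(single)$value == 1))
  zero <- dplyr::mutate(single, value = 0)
  expect_error(global_mean_normalize(zero), "zero mean")
})

test_that("size factors compensate a synthetic segment-wise distortion", {
  cfg <- synth_config(seed = 3, n_genes = 50, count_model = "none", cq_sigma = 0,
                      segment_distortion = c(2, 1, 1, 1, 0.5))
  sim <- simulate_rna(cfg)
  sf <- compute_size_factors(sim$counts, sim$cq)
  d <- c(A = 2, B = 1, C = 1, D = 1, E = 0.5)
  expected <- (1 / d) / exp(mean(log(1 / d)))
  expect_equal(sf$size_factor, unname(expected[sf$segment]), tolerance = 1e-9)
  # anchor fraction profiles equal their qPCR profiles after normalization
  normed <- apply_size_factors(sim$counts, sf)
  anchor <- sim$truth$gene_id[sim$truth$is_anchor][1]
  got <- to_fractions(dplyr::filter(normed, gene_id == anchor)) |>
    dplyr::filter(replicate == 1)
  expect_equal(got$fraction, cq_to_fractions(sim$cq, anchor)$fraction,
               tolerance = 1e-9)
})
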