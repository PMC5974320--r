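test_that("overlapping k-mer counting matches the examples and a naive scan", {
  c1 <- count_kmers("ACACA", 3)
  expect_equal(c1$count[c1$kmer == "ACA"], 2)
  expect_equal(c1$count[c1$kmer == "CAC"], 1)
  expect_equal(sum(c1$count), 3)

  c2 <- count_kmers("AAAA", 2)
  expect_equal(c2, tibble::tibble(kmer = "AA", count = 3L))

  expect_equal(nrow(count_kmers("ACGT", 5)), 0)
  expect_error(count_kmers("ACGX", 2), "non-ACGT")

  set.seed(31)
  for (i in 1:20) {
    s <- random_acgt(sample(30:120, 1))
    k <- sample(2:6, 1)
    mine <- count_kmers(s, k)
    oracle <- naive_count_kmers(s, k)
    expect_equal(setNames(mine$count, mine$kmer),
                 setNames(as.integer(oracle), names(oracle))[mine$kmer])
    expect_equal(sum(mine$count), nchar(s) - k + 1)
  }
})

test_that("expected counts follow the closed form and its identities", {
  expect_identical(expected_kmer_count(100, 5), 96 / 1024)
  expect_equal(expected_kmer_count(7, 7), 4^-7)
  # sum over all 4^k k-mers equals N - k + 1 for t = 1
  expect_equal(4^3 * expected_kmer_count(50, 3), 50 - 3 + 1)
  # binomial-coefficient form for t = 2
  expect_equal(expected_kmer_count(20, 3, t = 2), choose(16, 2) / 4^6)
  expect_warning(e <- expected_kmer_count(3, 5), "shorter")
  expect_equal(e, 0)
})

test_that("per-gene observed and expected totals are conserved", {
  set.seed(12)
  utrs <- utr_set(setNames(vapply(1:5, function(i) random_acgt(200), character(1)),
                           paste0("g", 1:5)))
  for (k in c(3, 5)) {
    screen <- overrepresented_kmers(utrs, k)
    expect_equal(sum(screen$obs_total), sum(utrs$width - k + 1))
    expect_equal(4^k * screen$exp_total[1], sum(utrs$width - k + 1), tolerance = 1e-9)
  }
})

test_that("the chi-squared statistic reproduces the worked two-gene example", {
  # two 20-nt genes with 2 and 0 copies of CAT: E = 18/64 each
  u <- utr_set(c(g1 = "CATCATAAGGAAGGAAGGAA", g2 = "GGGGGGGGGGGGGGGGGGGG"))
  res <- kmer_chi2(u, "CAT")
  E <- 18 / 64
  x2_hand <- (2 - E)^2 / E + (0 - E)^2 / E
  expect_equal(res$statistic, x2_hand, tolerance = 1e-9)
  expect_equal(res$statistic, 10.785, tolerance = 1e-3)
  expect_equal(res$df, 1)
  # independent survival-function oracle for df = 1: 2 * pnorm(-sqrt(x2))
  expect_equal(res$p_value, 2 * pnorm(-sqrt(x2_hand)), tolerance = 1e-6)
  expect_false(res$significant)  # p just above 0.001

  # O exactly equal to E in every gene -> x2 = 0, p = 1
  # k = 2, N = 17: E = 16/16 = 1; each sequence carries exactly one AA
  exact <- utr_set(c(g1 = "AACGCGCGCGCGCGCGC", g2 = "CGCGCGCGCGCGCAACG"))
  res0 <- kmer_chi2(exact, "AA")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  expect_error(kmer_chi2(utr_set(c(g1 = "ACGTACGT")), "ACG"), "at least 2")
})

test_that("planted k-mers are flagged and the null mostly is not", {
  set.seed(21)
  seqs <- vapply(1:30, function(i) {
    s <- random_acgt(300)
    paste0(substr(s, 1, 100), "TTCAC", substr(s, 106, 200), "TTCAC",
           substr(s, 206, 300))
  }, character(1))
  planted <- utr_set(setNames(seqs, paste0("v", 1:30)))
  screen <- overrepresented_kmers(planted, 5, all = FALSE)
  expect_true("TTCAC" %in% screen$kmer)

  nulls <- utr_set(setNames(vapply(1:30, function(i) random_acgt(300),
                                   character(1)), paste0("n", 1:30)))
  null_screen <- overrepresented_kmers(nulls, 3)
  expect_lt(sum(null_screen$significant), 15)  # far from flagging most of 64
  expect_error(overrepresented_kmers(planted[0, ], 3), "at least 2")
})

test_that("chi-squared grows with the planting rate", {
  set.seed(77)
  stat_at_rate <- function(n_copies) {
    seqs <- vapply(1:25, function(i) {
      s <- random_acgt(400)
      for (j in seq_len(n_copies)) {
        pos <- 30 * j
        substr(s, pos, pos + 4) <- "TTCAC"
      }
      s
    }, character(1))
    kmer_chi2(utr_set(setNames(seqs, paste0("g", 1:25))), "TTCAC")$statistic
  }
  lo <- vapply(1:8, function(i) stat_at_rate(1), numeric(1))
  hi <- vapply(1:8, function(i) stat_at_rate(3), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("unique k-mers are plain set differences at matched k", {
  uq <- unique_kmers(c("ACCA", "AAAA"), c("AAAA", "CTTA"))
  expect_equal(uq$kmer[uq$unique_to == "animal"], "ACCA")
  expect_equal(uq$kmer[uq$unique_to == "vegetal"], "CTTA")
  uq2 <- unique_kmers(c("AC", "GT"), c("CA", "TG"))
  expect_equal(nrow(uq2), 4)
  uq3 <- unique_kmers(c("ACG"), c("ACG"))
  expect_equal(nrow(uq3), 0)
  expect_error(unique_kmers("ACGT", "ACG"), "different k")
})

test_that("k-mers cross-reference against motif consensus windows", {
  motifs <- motif_set(motif_from_iupac("E2", "[TA][TC]CAC"),
                      motif_from_iupac("polyC", "CCCCCC"),
                      motif_from_iupac("lit", "GGTTCACGG"))
  xr <- crossref_motifs(c("TCCAC", "GATAA", "TTCAC"), motifs)
  expect_setequal(xr$motif_id[xr$kmer == "TCCAC"], "E2")
  expect_false("GATAA" %in% xr$kmer)
  # literal substring of a motif matches
  expect_true("lit" %in% xr$motif_id[xr$kmer == "TTCAC"])
})
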