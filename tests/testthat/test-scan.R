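test_that("IUPAC scanning finds exactly the compatible windows", {
  hits <- scan_iupac(c(s1 = "ATTCACG"), "TTCAC")
  expect_equal(hits$start, 1L)
  expect_equal(hits$matched, "TTCAC")

  hits2 <- scan_iupac(c(s1 = "CTTCTA"), "[TC][TC]TCT")
  expect_equal(hits2$start, 0L)

  expect_equal(nrow(scan_iupac(c(s1 = "GGGGG"), "TTCAC")), 0)
  expect_equal(nrow(scan_iupac(c(s1 = "ACG"), "TTCAC")), 0)  # motif wider than UTR

  # overlapping occurrences are all reported
  hits3 <- scan_iupac(c(s1 = "AAAA"), "AA")
  expect_equal(hits3$start, 0:2)
})

test_that("IUPAC scanning agrees with a regex oracle on random inputs", {
  set.seed(19)
  motifs <- c("TTCAC", "WYCAC", "RNYG", "TGCAC", "HVDA")
  for (i in 1:200) {
    s <- random_acgt(sample(20:150, 1))
    m <- sample(motifs, 1)
    mine <- scan_iupac(c(x = s), m)$start
    expect_identical(mine, regex_iupac_starts(s, m))
  }
})

test_that("the exact PWM score threshold matches its definition", {
  pwm <- matrix(c(0.7, 0.1, 0.1, 0.1, 0.7, 0.1, 0.1, 0.1), 4, 2,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- motif_from_pwm("x", pwm)
  th <- pwm_pvalue_threshold(m, alpha = 1 / 16)
  # only the best word AA reaches the threshold; its null mass is exactly 1/16
  expect_equal(tomoloc:::pwm_tail_p(th$model, th$threshold_int), 1 / 16)
  hits <- scan_pwm(c(s = "CAAGAC"), m, th)
  expect_equal(hits$matched, "AA")
  expect_equal(hits$p_value, 1 / 16)

  # alpha = 1: every window matches
  th1 <- pwm_pvalue_threshold(m, alpha = 1)
  expect_equal(nrow(scan_pwm(c(s = "CGTGC"), m, th1)), 4)

  # threshold above the maximum score matches nothing
  tiny <- pwm_pvalue_threshold(m, alpha = 1e-9)
  expect_equal(nrow(scan_pwm(c(s = "AAAA"), m, tiny)), 0)
})

test_that("the DP tail equals exhaustive enumeration for small widths", {
  set.seed(8)
  for (w in 2:5) {
    raw <- matrix(rgamma(4 * w, 1), 4, w)
    pwm <- sweep(raw, 2, colSums(raw), "/")
    rownames(pwm) <- c("A", "C", "G", "T")
    bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    th <- pwm_pvalue_threshold(motif_from_pwm("w", pwm), background = bg,
                               alpha = 0.01)
    oracle <- enumerate_pwm_tail(pwm, bg)
    for (q in c(th$threshold_int, th$threshold_int - 500, th$threshold_int + 500)) {
      expect_equal(tomoloc:::pwm_tail_p(th$model, q), oracle(q), tolerance = 1e-9)
    }
  }
})

test_that("PWM scanning reduces to IUPAC scanning for 0/1 matrices", {
  set.seed(23)
  cons <- "WYCAC"
  m_iupac <- motif_from_iupac("e", cons)
  # alpha exactly the null mass of the accepted word set: 2*2*1*1*1 / 4^5
  th <- pwm_pvalue_threshold(m_iupac, alpha = 4 / 1024)
  for (i in 1:25) {
    s <- random_acgt(120)
    expect_identical(scan_pwm(c(x = s), m_iupac, th)$start,
                     scan_iupac(c(x = s), m_iupac)$start)
  }
})

test_that("presence summaries report hit proportions per category", {
  utrs <- utr_set(c(g1 = "TTCACGG", g2 = "GGTTCAC", g3 = "GGGGGGG",
                    g4 = "AAAAAAA"))
  cats <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                         category = c("vegetal", "vegetal", "vegetal", "animal"))
  motifs <- motif_set(motif_from_iupac("ttcac", "TTCAC"),
                      motif_from_iupac("baseA", "A"))
  pres <- presence_summary(utrs, cats, motifs)
  veg <- dplyr::filter(pres, motif_id == "ttcac", category == "vegetal")
  expect_equal(veg$proportion, 2 / 3)
  expect_equal(veg$n_with_hit, 2L)
  expect_equal(dplyr::filter(pres, motif_id == "ttcac", category == "animal")$proportion, 0)
  expect_equal(dplyr::filter(pres, motif_id == "baseA", category == "animal")$proportion, 1)
  # occurrences per kbp counts all overlapping hits
  expect_equal(dplyr::filter(pres, motif_id == "baseA", category == "animal")$occ_per_kbp,
               7 / 7 * 1000)
})

test_that("Fisher enrichment equals the hypergeometric tail", {
  expect_equal(fisher_enrichment(0, 10, 0, 10)$p_value, 1)
  extreme <- fisher_enrichment(10, 0, 0, 10)
  expect_equal(extreme$p_value, 1 / choose(20, 10))
  worked <- fisher_enrichment(10, 10, 2, 18)
  expect_equal(worked$p_value, enumerate_fisher_tail(10, 10, 2, 18),
               tolerance = 1e-12)
  # agreement with the conditional one-sided test
  expect_equal(worked$p_value,
               fisher.test(matrix(c(10, 10, 2, 18), 2, byrow = TRUE),
                           alternative = "greater")$p.value, tolerance = 1e-9)
  # Haldane-corrected odds ratio under a zero cell
  expect_equal(extreme$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
  expect_error(fisher_enrichment(0, 0, 0, 0), "all-zero")
  expect_error(fisher_enrichment(1.5, 2, 3, 4), "integer")
})

test_that("position maps are sorted and keep overlaps", {
  motifs <- motif_set(motif_from_iupac("aa", "AA"), motif_from_iupac("cc", "CC"))
  pm <- position_map(c(u1 = "AAACCAA"), motifs)
  expect_equal(pm$start[pm$motif_id == "aa"], c(0L, 1L, 5L))
  expect_equal(pm$start[pm$motif_id == "cc"], 3L)
  expect_equal(nrow(position_map(c(u1 = "GGGG"), motifs)), 0)
})
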