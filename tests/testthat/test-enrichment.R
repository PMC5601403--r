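test_that("TPM follows the rate-normalisation formula", {
  tpm <- tpm_from_counts(matrix(c(10, 10), ncol = 1,
                                dimnames = list(c("g1", "g2"), "s1")),
                         lengths = c(1000, 2000))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  eq <- tpm_from_counts(matrix(5, 4, 2), lengths = rep(500, 4))
  expect_true(all(abs(eq - 2.5e5) < 1e-9))
  expect_equal(colSums(eq), c(1e6, 1e6), ignore_attr = TRUE)

  single <- tpm_from_counts(matrix(3, 1, 1), lengths = 100)
  expect_equal(as.numeric(single), 1e6)

  expect_warning(z <- tpm_from_counts(matrix(0, 2, 1), lengths = c(10, 10)),
                 "zero counts")
  expect_equal(as.numeric(z), c(0, 0))
  expect_error(tpm_from_counts(matrix(1, 2, 1), lengths = c(10, 0)), "positive")
})

test_that("expressed background uses a strict median-TPM threshold", {
  tpm <- rbind(at_cut = c(1, 1, 1), above = c(1.01, 1.01, 1.01),
               zero = c(0, 0, 0), mixed = c(0, 5, 5))
  expect_equal(expressed_background(tpm), c("above", "mixed"))
})

test_that("hypergeometric overlap matches explicit summation and degenerate limits", {
  u <- paste0("g", 1:20)
  r <- hypergeom_overlap(u[1:5], u[1:5], u)
  expect_equal(r$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(r$overlap, 5L)

  r0 <- hypergeom_overlap(u[1:5], u[6:10], u)
  expect_equal(r0$overlap, 0L)
  expect_equal(r0$p_value, 1)

  rall <- hypergeom_overlap(u, u, u)
  expect_equal(rall$p_value, 1)

  expect_error(hypergeom_overlap(u[1:2], u[1:2], character()), "empty universe")
  expect_warning(hypergeom_overlap(c(u[1:3], "outside"), u[1:5], u), "outside")

  set.seed(61)
  for (i in 1:10) {
    nu <- sample(10:30, 1)
    uu <- paste0("x", seq_len(nu))
    a <- sample(uu, sample(2:nu, 1)); b <- sample(uu, sample(2:nu, 1))
    got <- hypergeom_overlap(a, b, uu)$p_value
    want <- oracle_hyper_upper(length(intersect(a, b)), length(a), length(b), nu)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("length-aware enrichment reduces to the hypergeometric test for equal lengths", {
  set.seed(62)
  u <- paste0("g", 1:120)
  lens <- setNames(rep(300, 120), u)
  hits <- sample(u, 30)
  cat1 <- sample(u, 25)
  p_hyper <- hypergeom_overlap(hits, cat1, u)$p_value
  res <- length_aware_enrichment(hits, list(c1 = cat1), u, lens,
                                 method = "resampling", n_resamples = 10000)
  se <- sqrt(p_hyper * (1 - p_hyper) / 10000)
  expect_lt(abs(res$p_value - p_hyper), 2 * se + 2e-4)
  # Wallenius route with odds 1 is the plain hypergeometric
  res_w <- length_aware_enrichment(hits, list(c1 = cat1), u, lens,
                                   method = "wallenius")
  expect_equal(res_w$p_value, p_hyper, tolerance = 1e-6)
})

test_that("length-aware enrichment discounts categories explained by length bias", {
  set.seed(63)
  n <- 400
  u <- sprintf("g%03d", 1:n)
  lens <- setNames(seq(200, 4000, length.out = n), u)
  # hits drawn proportional to length: long genes over-called
  hits <- sample(u, 80, prob = lens)
  longest <- u[order(-lens)][1:40]
  p_naive <- hypergeom_overlap(hits, longest, u)$p_value
  res <- length_aware_enrichment(hits, list(long = longest), u, lens,
                                 method = "resampling", n_resamples = 4000)
  expect_lt(p_naive, 0.05)
  expect_gt(res$p_value, 10 * p_naive)
  expect_error(length_aware_enrichment(hits, list(long = longest), u, lens,
                                       method = "resampling", n_resamples = 0),
               "n_resamples")
})

test_that("GSEA enrichment score: closed-form extremes, balance, antisymmetry, oracle", {
  ranked <- paste0("g", 1:100)
  expect_equal(gsea_enrichment_score(ranked, ranked[1:15]), 1)
  expect_equal(gsea_enrichment_score(rev(ranked), ranked[1:15]), -1)
  spread <- ranked[seq(5, 100, by = 10)]
  expect_lt(abs(gsea_enrichment_score(ranked, spread)), 0.15)
  set.seed(64)
  for (i in 1:10) {
    s <- sample(ranked, 12)
    es <- gsea_enrichment_score(ranked, s)
    expect_equal(es, oracle_es(ranked, s), tolerance = 1e-12)
    expect_equal(gsea_enrichment_score(rev(ranked), s), -es, tolerance = 1e-12)
    expect_lte(abs(es), 1)
  }
})

test_that("GSEA ES agrees with fgsea's unweighted statistic", {
  skip_if_not_installed("fgsea")
  set.seed(65)
  stats <- sort(rnorm(80), decreasing = TRUE)
  names(stats) <- paste0("g", 1:80)
  idx <- sort(sample(80, 15))
  es_pkg <- gsea_enrichment_score(names(stats), names(stats)[idx])
  es_ref <- fgsea::calcGseaStat(stats, idx, gseaParam = 0)
  expect_equal(es_pkg, es_ref, tolerance = 1e-9)
})

test_that("PDUI-input GSEA detects a set of shifted genes and enforces min_size", {
  set.seed(66)
  sim <- simulate_pdui_matrix(120, 6, 6, c(0.5, 0.5), 30, seed = 67)
  m <- sim$matrix
  # genes 1..20 get a strong distal shift in group B
  m[1:20, 7:12] <- pmin(m[1:20, 7:12] + 0.35, 1)
  sets <- list(shifted = rownames(m)[1:20],
               random = rownames(m)[51:75],
               tiny = rownames(m)[1:9])
  res <- gsea_pdui(m, sim$groups, sets, min_size = 10, n_perms = 500)
  expect_false("tiny" %in% res$set) # size 9 excluded at min_size 10
  sh <- res[res$set == "shifted", ]
  expect_equal(sh$enriched_group, "B")
  expect_gt(sh$es, 0.8)
  # phenotype permutation with 6+6 samples: label splits nearly aligned with
  # the true grouping (~8% of them) also score high, bounding p from below
  expect_lt(sh$p_value, 0.12)
  expect_lt(sh$p_value, res$p_value[res$set == "random"])
  expect_gt(res$p_value[res$set == "random"], 0.05)
  expect_true(all(abs(res$es) <= 1))
  expect_warning(gsea_pdui(m, sim$groups, list(tiny = rownames(m)[1:5])),
                 "min_size")
})

test_that("GSEA falls back to gene-set permutation for tiny cohorts and finds a shifted set", {
  set.seed(68)
  sim <- simulate_pdui_matrix(60, 3, 3, c(0.5, 0.5), 50, seed = 69)
  m <- sim$matrix
  m[1:15, 4:6] <- pmin(m[1:15, 4:6] + 0.3, 1)
  expect_message(
    res <- gsea_pdui(m, sim$groups,
                     list(s = rownames(m)[1:15]), n_perms = 500),
    "gene-set permutation")
  expect_equal(nrow(res), 1L)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$enriched_group, "B")
})

test_that("motif scanning handles the palindromic CRE, strands and IUPAC codes", {
  hits <- scan_motif(c(a = "TGACGTCA"))
  expect_equal(hits$a, 0L) # one hit despite palindromy
  expect_equal(scan_motif(c(b = "AAAATTTT"))$b, integer(0))
  expect_equal(scan_motif(c(c = "GGTGACGTCAGG"))$c, 2L)
  # non-palindromic motif found via reverse complement
  expect_equal(scan_motif(c(d = "CCCCATCCC"), motif = "GGATG")$d, 3L)
  expect_equal(scan_motif(c(d = "CCCCATCCC"), motif = "GGATG",
                          both_strands = FALSE)$d, integer(0))
  # IUPAC degeneracy: R = A or G
  expect_equal(scan_motif(c(e = "GATCAATC"), motif = "RAT",
                          both_strands = FALSE)$e, c(0L, 4L))
  expect_error(scan_motif(c(f = "ACGT"), motif = "TGAXGTCA"), "IUPAC")
})

test_that("motif enrichment reduces to the documented combinatorial identity", {
  u <- paste0("g", 1:100)
  bearing <- u[1:50]
  apa <- u[1:10] # all motif-bearing
  r <- motif_enrichment(bearing, apa, u)
  expect_equal(r$p_value, choose(50, 10) / choose(100, 10), tolerance = 1e-12)
  # equal motif frequency in list and universe: no signal
  set.seed(70)
  apa2 <- sample(u, 20)
  r2 <- motif_enrichment(bearing, apa2, u)
  expect_gt(r2$p_value, 0.1)
  r3 <- motif_enrichment(character(0), apa, u)
  expect_equal(r3$overlap, 0L)
  expect_equal(r3$p_value, 1)
})
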