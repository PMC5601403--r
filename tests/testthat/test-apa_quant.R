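test_that("two-site fit recovers noise-free step parameters in closed form", {
  m <- matrix(rep(c(rep(30, 40), rep(10, 60)), each = 3), nrow = 3)
  f <- fit_two_site_model(m, min_mean_coverage = 10)
  expect_equal(f$status, "ok")
  expect_equal(f$breakpoint, 40L)
  expect_equal(f$samples$w_long, rep(10, 3))
  expect_equal(f$samples$w_short, rep(20, 3))
  expect_equal(f$samples$pdui, rep(1 / 3, 3))
})

test_that("PDUI boundary identities: all-distal gives 1, all-proximal gives 0", {
  uni <- matrix(10, nrow = 2, ncol = 100)
  f1 <- fit_two_site_model(uni, min_mean_coverage = 5)
  expect_equal(f1$samples$pdui, c(1, 1))
  expect_equal(f1$samples$w_short, c(0, 0))

  prox <- matrix(rep(c(rep(20, 40), rep(0, 60)), each = 2), nrow = 2)
  f0 <- fit_two_site_model(prox, min_mean_coverage = 5)
  expect_equal(f0$samples$pdui, c(0, 0))
  expect_equal(f0$samples$w_long, c(0, 0))
})

test_that("fitted breakpoint and weights match an independent exhaustive oracle", {
  set.seed(17)
  for (i in 1:10) {
    L <- sample(60:150, 1)
    n <- sample(1:4, 1)
    b_true <- sample(20:(L - 20), 1)
    m <- t(vapply(seq_len(n), function(s) {
      depth <- runif(1, 20, 60)
      pd <- runif(1)
      pmax(0, depth * c(rep(1, b_true), rep(pd, L - b_true)) +
             rnorm(L, 0, 3))
    }, numeric(L)))
    em <- max(10L, ceiling(0.01 * L))
    f <- fit_two_site_model(m, min_mean_coverage = 0, edge_margin = em)
    o <- oracle_two_site(m, em)
    expect_equal(f$breakpoint, o$breakpoint)
    expect_equal(f$samples$w_long, unname(o$w_long), tolerance = 1e-9)
    expect_equal(f$samples$w_short, unname(o$w_short), tolerance = 1e-9)
  }
})

test_that("PDUI is invariant to scaling a sample's coverage", {
  set.seed(23)
  L <- 120
  cov1 <- pmax(0, 50 * c(rep(1, 50), rep(0.4, 70)) + rnorm(L, 0, 4))
  f1 <- fit_two_site_model(rbind(cov1), min_mean_coverage = 0)
  f2 <- fit_two_site_model(rbind(3.7 * cov1), min_mean_coverage = 0)
  expect_equal(f1$breakpoint, f2$breakpoint)
  expect_equal(f1$samples$pdui, f2$samples$pdui, tolerance = 1e-12)
  # scaling every sample jointly leaves the shared breakpoint unchanged too
  m <- rbind(cov1, pmax(0, 40 * c(rep(1, 50), rep(0.7, 70)) + rnorm(L, 0, 4)))
  fa <- fit_two_site_model(m, min_mean_coverage = 0)
  fb <- fit_two_site_model(2.5 * m, min_mean_coverage = 0)
  expect_equal(fa$breakpoint, fb$breakpoint)
  expect_equal(fa$samples$pdui, fb$samples$pdui, tolerance = 1e-12)
})

test_that("coverage preconditions: exclusion, insufficient-coverage status, unequal lengths", {
  m <- matrix(rep(c(rep(30, 40), rep(10, 60)), each = 4), nrow = 4,
              dimnames = list(c("A1", "A2", "B1", "B2"), NULL))
  m["B2", ] <- 0.1 # mean far below threshold
  g <- setNames(c("A", "A", "B", "B"), rownames(m))
  f <- fit_two_site_model(m, groups = g, min_mean_coverage = 10)
  expect_equal(f$status, "insufficient_coverage")
  expect_true(is.na(f$breakpoint))
  f2 <- fit_two_site_model(m, groups = g, min_mean_coverage = 0.01)
  expect_equal(f2$status, "ok")
  expect_error(fit_two_site_model(list(a = 1:10, b = 1:11)), "unequal length")
})

test_that("Benjamini-Hochberg adjustment matches the hand step-up rule", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.42), 0.42)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.2, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(benjamini_hochberg(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("differential APA builds read-mass tables, tests them and applies both filters", {
  g <- setNames(c("A", "A", "B", "B"), c("A1", "A2", "B1", "B2"))
  # group A totals (long 800, short 200); group B (200, 800): L=100, b=20
  fitA <- make_fit("g1", 20L, 100L, names(g),
                   w_long = c(5, 5, 1.25, 1.25),
                   w_short = c(5, 5, 20, 20))
  # identical groups: p = 1, not significant
  fitB <- make_fit("g2", 20L, 100L, names(g),
                   w_long = rep(5, 4), w_short = rep(5, 4))
  res <- differential_apa(list(fitA, fitB), g)
  r1 <- res[res$gene_id == "g1", ]
  expect_lt(r1$p_value, 1e-6)
  expect_true(abs(r1$pdui_diff) > 0.2)
  expect_true(r1$significant)
  # oracle check of the Fisher p on the constructed table
  expect_equal(r1$p_value,
               oracle_fisher_two_sided(rbind(c(800, 200), c(200, 800))),
               tolerance = 1e-9)
  r2 <- res[res$gene_id == "g2", ]
  expect_equal(r2$p_value, 1)
  expect_false(r2$significant)
  expect_true(all(res$adj_p >= res$p_value))
})

test_that("significance requires the PDUI-difference filter, not just the adjusted p", {
  g <- setNames(c("A", "A", "B", "B"), c("A1", "A2", "B1", "B2"))
  # strong counts but small PDUI shift: 0.50 vs 0.42
  fit <- make_fit("g1", 50L, 100L, names(g),
                  w_long = c(50, 50, 42, 42), w_short = c(50, 50, 58, 58))
  res <- differential_apa(list(fit), g)
  expect_lt(res$adj_p, 0.05)
  expect_lt(abs(res$pdui_diff), 0.2)
  expect_false(res$significant)
})

test_that("undefined PDUI propagates as missing and genes need 2 defined samples per group", {
  g <- setNames(c("A", "A", "B", "B"), c("A1", "A2", "B1", "B2"))
  fit <- make_fit("g1", 20L, 100L, names(g),
                  w_long = c(5, 0, 5, 5), w_short = c(5, 0, 5, 5))
  expect_true(is.na(fit$samples$pdui[2]))
  res <- differential_apa(list(fit), g)
  expect_equal(nrow(res), 0L) # only one defined PDUI in group A
})

test_that("pdui_matrix assembles fits with excluded samples as NA", {
  g <- c("A1", "A2", "B1", "B2")
  f1 <- make_fit("g1", 20L, 100L, g, w_long = rep(5, 4), w_short = rep(5, 4))
  f1$samples$used[3] <- FALSE
  f2 <- make_fit("g2", 20L, 100L, g, w_long = rep(2, 4), w_short = rep(8, 4))
  m <- pdui_matrix(list(f1, f2))
  expect_equal(dim(m), c(2L, 4L))
  expect_true(is.na(m["g1", "B1"]))
  expect_equal(m["g2", "A1"], 0.2)
})
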