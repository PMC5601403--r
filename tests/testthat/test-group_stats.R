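test_that("KS shift test: identity, directional detection, preconditions", {
  # identical group means for every gene: D = 0, p = 1
  m <- cbind(A1 = c(.2, .5, .8, .4), A2 = c(.4, .5, .6, .2),
             B1 = c(.2, .5, .8, .4), B2 = c(.4, .5, .6, .2))
  rownames(m) <- paste0("g", 1:4)
  g <- setNames(c("A", "A", "B", "B"), colnames(m))
  r <- ks_group_shift(m, g, "greater")
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  # constructed distal shift of +0.3 in group B, 100 genes
  set.seed(41)
  base <- matrix(runif(100 * 3, 0.05, 0.6), 100, 3)
  shifted <- pmin(base + 0.3, 1)
  m2 <- cbind(base, shifted)
  dimnames(m2) <- list(paste0("g", 1:100),
                       c(paste0("A", 1:3), paste0("B", 1:3)))
  g2 <- setNames(rep(c("A", "B"), each = 3), colnames(m2))
  r2 <- ks_group_shift(m2, g2, "greater")
  expect_lt(r2$p.value, 0.01)
  expect_gt(ks_group_shift(m2, g2, "less")$p.value, 0.5)

  # permutation oracle: shuffle which group each gene-mean pair came from
  mA <- rowMeans(m2[, 1:3]); mB <- rowMeans(m2[, 4:6])
  d_obs <- oracle_ks(mB, mA)$D_x_above # one-sided deviation, B above A
  set.seed(42)
  perm <- replicate(2000, {
    swap <- runif(100) < 0.5
    pa <- ifelse(swap, mB, mA); pb <- ifelse(swap, mA, mB)
    oracle_ks(pb, pa)$D_x_above
  })
  expect_lt((1 + sum(perm >= d_obs)) / 2001, 0.01)

  expect_error(ks_group_shift(m2[1:2, ], g2, "greater"), "at least 3 genes")
})

test_that("KS shift statistic equals the brute-force one-sided D", {
  set.seed(43)
  m <- matrix(runif(60), 10, 6,
              dimnames = list(paste0("g", 1:10),
                              c(paste0("A", 1:3), paste0("B", 1:3))))
  g <- setNames(rep(c("A", "B"), each = 3), colnames(m))
  r <- ks_group_shift(m, g, "greater")
  o <- oracle_ks(rowMeans(m[, 4:6]), rowMeans(m[, 1:3]))
  expect_equal(r$statistic, o$D_x_above, tolerance = 1e-9)
})

test_that("KS shift is invariant to gene and within-group sample order", {
  set.seed(44)
  m <- matrix(runif(120), 20, 6,
              dimnames = list(paste0("g", 1:20),
                              c(paste0("A", 1:3), paste0("B", 1:3))))
  g <- setNames(rep(c("A", "B"), each = 3), colnames(m))
  r1 <- ks_group_shift(m, g, "greater")
  r2 <- ks_group_shift(m[sample(20), c(3, 1, 2, 6, 4, 5)], g, "greater")
  expect_equal(r1, r2)
})

test_that("variance contrast: symmetry, dominance detection, tie degeneracy", {
  set.seed(45)
  m1 <- simulate_pdui_matrix(100, 3, 3, c(.5, .5), 30, seed = 46)$matrix
  r_self <- variance_contrast(m1, m1)
  expect_gt(r_self$p.value, 0.4)
  expect_lt(r_self$p.value, 0.6)

  lo_k <- simulate_pdui_matrix(200, 3, 3, c(.5, .5), 5, seed = 47)$matrix
  hi_k <- simulate_pdui_matrix(200, 3, 3, c(.5, .5), 500, seed = 48)$matrix
  expect_lt(variance_contrast(lo_k, hi_k)$p.value, 1e-4)

  const <- matrix(0.5, 10, 4, dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  expect_equal(variance_contrast(const, const)$p.value, 0.5)

  expect_error(variance_contrast(m1[1:2, ], m1), "at least 3")
})

test_that("one-sided variance-contrast p-values are near-complementary", {
  set.seed(49)
  a <- simulate_pdui_matrix(15, 4, 4, c(.5, .5), 10, seed = 50)$matrix
  b <- simulate_pdui_matrix(15, 4, 4, c(.5, .5), 40, seed = 51)$matrix
  p1 <- variance_contrast(a, b)$p.value
  p2 <- variance_contrast(b, a)$p.value
  expect_lt(abs(p1 + p2 - 1), 0.05)
})

test_that("exact small-n rank-sum p matches full enumeration", {
  set.seed(52)
  for (i in 1:8) {
    x <- runif(sample(3:6, 1)); y <- runif(sample(3:6, 1))
    got <- apashift:::rank_sum_greater(x, y)$p.value
    expect_equal(got, oracle_wilcox_greater(x, y), tolerance = 1e-9)
  }
})

test_that("variability quartiles separate constructed high/low-variance genes", {
  set.seed(53)
  n <- 40
  sds <- c(rep(0.2, 20), rep(0.02, 20))
  deltas <- c(runif(20, 0.4, 0.6), runif(20, 0, 0.05))
  m <- t(vapply(1:n, function(i) {
    ctrl <- pmin(pmax(rnorm(4, 0.5, sds[i]), 0), 1)
    case <- pmin(pmax(rnorm(4, 0.5 + deltas[i], sds[i]), 0), 1)
    c(ctrl, case)
  }, numeric(8)))
  dimnames(m) <- list(sprintf("g%02d", 1:n),
                      c(paste0("A", 1:4), paste0("B", 1:4)))
  g <- setNames(rep(c("A", "B"), each = 4), colnames(m))
  r <- variability_quartiles(m, g, control = "A")
  expect_lt(r$p.value, 1e-3)
  expect_equal(sum(r$table$quartile == "top"), 10L)
  expect_equal(sum(r$table$quartile == "bottom"), 10L)
})

test_that("variability quartiles run at the minimal 8-gene boundary", {
  set.seed(54)
  m <- matrix(runif(8 * 6), 8, 6,
              dimnames = list(paste0("g", 1:8),
                              c(paste0("A", 1:3), paste0("B", 1:3))))
  g <- setNames(rep(c("A", "B"), each = 3), colnames(m))
  r <- variability_quartiles(m, g, control = "A")
  expect_true(is.finite(r$p.value))
  expect_equal(sum(r$table$quartile == "top"), 2L)
  expect_error(variability_quartiles(m[1:5, ], g, control = "A"), "at least 8")
})
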