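# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (enumeration, brute force, closed form) of a quantity the
# package computes by its production path.

# Exhaustive two-site step fit: naive double loop, no cumulative sums.
oracle_two_site <- function(mat, edge_margin) {
  L <- ncol(mat)
  cands <- edge_margin:(L - edge_margin - 1L)
  best_sse <- Inf; best_b <- NA_integer_
  for (b in cands) {
    sse <- 0
    for (s in seq_len(nrow(mat))) {
      cs <- mat[s, ]
      wl <- max(0, mean(cs[(b + 1):L]))
      ws <- max(0, mean(cs[1:b]) - wl)
      e <- sum((cs[1:b] - (wl + ws))^2) + sum((cs[(b + 1):L] - wl)^2)
      sse <- sse + e / sum(cs)
    }
    if (sse < best_sse - 1e-12) { best_sse <- sse; best_b <- b }
  }
  wl <- apply(mat[, (best_b + 1):L, drop = FALSE], 1, function(v) max(0, mean(v)))
  ws <- pmax(0, apply(mat[, 1:best_b, drop = FALSE], 1, mean) - wl)
  list(breakpoint = best_b, w_long = wl, w_short = ws,
       pdui = ifelse(wl + ws > 0, wl / (wl + ws), NA))
}

# BH step-up by hand.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric by explicit summation of the mass function.
oracle_hyper_upper <- function(k, size_a, size_b, size_u) {
  xs <- k:min(size_a, size_b)
  sum(choose(size_a, xs) * choose(size_u - size_a, size_b - xs)) /
    choose(size_u, size_b)
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration,
# using the point-probability rule (sum of all tables with probability not
# exceeding the observed one, within relative slack 1e-7 as in R).
oracle_fisher_two_sided <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  support <- max(0, kk - n):min(kk, m)
  d <- stats::dhyper(support, m, n, kk)
  obs <- stats::dhyper(tab[1, 1], m, n, kk)
  sum(d[d <= obs * (1 + 1e-7)])
}

# Exact one-sided (greater) rank-sum p by enumerating all group assignments.
oracle_wilcox_greater <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mean(ws >= w_obs)
}

# Two-sample KS D statistics by brute force over pooled points.
oracle_ks <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  list(D = max(abs(Fx - Fy)), D_x_above = max(Fy - Fx), D_x_below = max(Fx - Fy))
}

# Single-linkage clustering by pairwise transitive closure.
oracle_cluster <- function(pos, window) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= window
  lab <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(lab[adj[i, ]]), numeric(1))
    if (identical(new, lab)) break
    lab <- new
  }
  split(pos, lab)
}

# Unweighted KS running-sum enrichment score, re-derived step by step.
oracle_es <- function(ranked, set) {
  nh <- sum(ranked %in% set); N <- length(ranked)
  best <- 0; running <- 0; best_abs <- -1
  for (g in ranked) {
    running <- running + if (g %in% set) 1 / nh else -1 / (N - nh)
    if (abs(running) > best_abs) { best_abs <- abs(running); best <- running }
  }
  best
}

make_fit <- function(gene_id, breakpoint, L, sample_id, w_long, w_short) {
  structure(list(
    gene_id = gene_id, status = "ok", breakpoint = breakpoint,
    utr_length = L, fit_sse = 0,
    samples = data.frame(sample_id = sample_id, w_long = w_long,
                         w_short = w_short,
                         pdui = ifelse(w_long + w_short > 0,
                                       w_long / (w_long + w_short), NA_real_),
                         mean_coverage = 100, used = TRUE,
                         stringsAsFactors = FALSE)
  ), class = "apa_fit")
}
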