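rp10k_from_counts <- function(counts) {
  rp10k_normalize(make_counts(counts))
}

test_that("small-group rank-sum p-values equal exact enumeration", {
  # the canonical extreme split: all zeros vs all high
  m <- rp10k_from_counts(rbind(c(0, 0, 0, 5, 6, 7), rep(1, 6)))
  deg <- wilcoxon_deg(m, sprintf("c%02d", 1:3), sprintf("c%02d", 4:6),
                      min_pct = 0, logfc_min = 0)
  gA <- deg[deg$gene == "g01", ]
  expect_equal(gA$raw_p, oracle_wilcox_exact_p(c(0, 0, 0), c(5, 6, 7)))
  expect_equal(gA$raw_p, 0.1)  # 2 of the 20 assignments are as extreme

  # identical groups: no evidence, never a DEG
  m2 <- rp10k_from_counts(rbind(c(1, 2, 3, 1, 2, 3), c(9, 9, 9, 9, 9, 8)))
  deg2 <- wilcoxon_deg(m2, sprintf("c%02d", 1:3), sprintf("c%02d", 4:6),
                       min_pct = 0, logfc_min = 0)
  expect_gte(deg2$raw_p[deg2$gene == "g01"], 0.99)
  expect_false(any(deg2$is_deg))
})

test_that("raw p matches the enumeration oracle for every split of <= 10 cells", {
  set.seed(71)
  worst <- 0
  for (n_total in c(6, 8, 10)) {
    # sparse, tie-heavy values, as normalized single-cell data are
    counts <- matrix(rpois(3 * n_total, 2) * rbinom(3 * n_total, 1, 0.6),
                     3, n_total)
    counts[1, ] <- counts[1, ] + 1  # keep every cell at nonzero depth
    m <- rp10k_from_counts(counts)
    vals <- dense_values(m)
    for (na in 3:(n_total - 3)) {
      a <- m$unit_ids[seq_len(na)]
      b <- m$unit_ids[(na + 1):n_total]
      deg <- wilcoxon_deg(m, a, b, min_pct = 0, logfc_min = 0)
      for (g in deg$gene) {
        p_oracle <- oracle_wilcox_exact_p(vals[g, a], vals[g, b])
        worst <- max(worst, abs(deg$raw_p[deg$gene == g] - p_oracle))
      }
    }
  }
  expect_lt(worst, 0.02)
})

test_that("DEG calling is symmetric and respects filters", {
  set.seed(72)
  counts <- matrix(rnbinom(50 * 20, size = 5, mu = 4), 50, 20)
  counts[1, ] <- counts[1, ] + 1
  counts[2, 1:10] <- counts[2, 1:10] + 12   # planted shift
  m <- rp10k_from_counts(counts)
  a <- m$unit_ids[1:10]; b <- m$unit_ids[11:20]
  d_ab <- wilcoxon_deg(m, a, b, min_pct = 0, logfc_min = 0)
  d_ba <- wilcoxon_deg(m, b, a, min_pct = 0, logfc_min = 0)
  common <- intersect(d_ab$gene, d_ba$gene)
  ab <- d_ab[match(common, d_ab$gene), ]
  ba <- d_ba[match(common, d_ba$gene), ]
  expect_equal(ab$raw_p, ba$raw_p, tolerance = 1e-12)
  expect_equal(ab$log_fc, -ba$log_fc, tolerance = 1e-12)

  expect_error(wilcoxon_deg(m, a, c(b, a[1])), "overlap")
  expect_error(wilcoxon_deg(m, a[1:2], b), ">= 3 cells")
  expect_message(
    empty <- wilcoxon_deg(m, a, b, min_pct = 1.1, logfc_min = 99),
    "no gene passes")
  expect_identical(nrow(empty), 0L)
})

test_that("planted 2-fold DEGs are found with no false positives", {
  set.seed(1)
  ng <- 200; nc <- 200
  mu <- matrix(5, ng, nc)
  mu[1:5, 1:100] <- 10; mu[6:10, 101:200] <- 10
  counts <- matrix(rnbinom(ng * nc, size = 10, mu = mu), ng, nc)
  m <- rp10k_from_counts(counts)
  deg <- wilcoxon_deg(m, m$unit_ids[1:100], m$unit_ids[101:200])
  planted <- m$gene_ids[1:10]
  expect_gte(sum(deg$is_deg & deg$gene %in% planted), 8)
  expect_identical(sum(deg$is_deg & !deg$gene %in% planted), 0L)
  # direction matches the planted sign
  expect_identical(deg$direction[deg$gene == planted[1]], "up")
  expect_identical(deg$direction[deg$gene == planted[6]], "down")
  # bonferroni relation
  expect_equal(deg$bonferroni_p, pmin(1, deg$raw_p * nrow(deg)))
})

test_that("type-I error stays controlled under the null", {
  set.seed(123)
  hits <- 0
  for (rep in 1:20) {
    counts <- matrix(rnbinom(300 * 30, size = 2, mu = 3), 300, 30)
    counts[1, ] <- counts[1, ] + 1
    m <- rp10k_from_counts(counts)
    deg <- wilcoxon_deg(m, m$unit_ids[1:15], m$unit_ids[16:30])
    hits <- hits + sum(deg$is_deg)
  }
  expect_lte(hits, 0.05 * 20)
})

test_that("index correlation matches hand-computed Pearson and its t-based P", {
  u <- letters[1:4]
  a <- index_vector(u, c(1, 2, 3, 4), "A", "mean")
  b <- index_vector(u, c(2, 1, 4, 3), "B", "mean")
  got <- index_correlation(a, b)
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  t_stat <- r_hand * sqrt((4 - 2) / (1 - r_hand^2))
  expect_equal(got$p, 2 * pt(-abs(t_stat), df = 2), tolerance = 1e-12)

  # perfect anti-correlation
  neg <- index_vector(u, -c(1, 2, 3, 4), "negA", "mean")
  expect_equal(index_correlation(a, neg)$r, -1, tolerance = 1e-12)

  # independence: |r| < 0.4 in >= 95% of 200 seeds at n = 50
  ok <- vapply(1:200, function(s) {
    set.seed(s)
    aa <- index_vector(sprintf("u%02d", 1:50), rnorm(50), "a", "mean")
    bb <- index_vector(sprintf("u%02d", 1:50), rnorm(50), "b", "mean")
    abs(index_correlation(aa, bb)$r) < 0.4
  }, logical(1))
  expect_gte(mean(ok), 0.95)

  flat <- index_vector(u, rep(1, 4), "flat", "mean")
  expect_error(index_correlation(a, flat), "zero variance")
})

test_that("group t-tests use the Welch statistic with legend stars", {
  # 3+3 toy against the hand-computed Welch formula
  x <- c(1, 2, 3); y <- c(2, 4, 9)
  idx <- index_vector(letters[1:6], c(x, y), "Hep", "median")
  labels <- setNames(rep(c("lo", "hi"), each = 3), letters[1:6])
  res <- compare_groups_ttest(idx, labels, list(c("lo", "hi")))
  se <- sqrt(var(x) / 3 + var(y) / 3)
  expect_equal(res$t, (mean(x) - mean(y)) / se, tolerance = 1e-12)

  # identical groups: p ~ 1, no stars
  idx2 <- index_vector(letters[1:6], rep(c(1, 2, 3), 2), "Hep", "median")
  res2 <- compare_groups_ttest(idx2, labels)
  expect_gt(res2$p, 0.99)
  expect_identical(res2$stars, "")

  # well-separated groups earn three stars
  set.seed(77)
  n <- 50
  idx3 <- index_vector(sprintf("u%02d", 1:(2 * n)),
                       c(rnorm(n, 0, 1), rnorm(n, 3, 1)), "Hep", "median")
  lab3 <- rep(c("g1", "g2"), each = n)
  res3 <- compare_groups_ttest(idx3, lab3)
  expect_lt(res3$p, 0.001)
  expect_identical(res3$stars, "***")

  expect_error(compare_groups_ttest(idx, labels, list(c("lo", "nope"))),
               "unknown group")
  small <- index_vector(c("a", "b", "c"), 1:3, "Hep", "median")
  expect_error(compare_groups_ttest(small, c("g", "g", "h")), "< 2 units")
})
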