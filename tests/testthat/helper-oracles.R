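# Independent oracles and small fixture builders used across the suite.

# exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled values to group A; ranks are recomputed from the pooled values at
# each step (brute force on purpose)
oracle_wilcox_exact_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  idx_sets <- utils::combn(length(pooled), na, simplify = FALSE)
  u_of <- function(ix) {
    r <- rank(pooled)
    sum(r[ix]) - na * (na + 1) / 2
  }
  mu <- na * length(b) / 2
  obs <- u_of(seq_len(na))
  us <- vapply(idx_sets, u_of, numeric(1))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# greedy ward.D2 agglomeration recomputed from scratch at every step using
# the centroid form of the merge cost: d(A, B) = sqrt(2|A||B|/(|A|+|B|)) *
# ||centroid_A - centroid_B||; returns the sequence of merge heights and the
# partition after each merge
oracle_ward_d2 <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      a <- clusters[[i]]; b <- clusters[[j]]
      ca <- colMeans(x[a, , drop = FALSE])
      cb <- colMeans(x[b, , drop = FALSE])
      d <- sqrt(2 * length(a) * length(b) / (length(a) + length(b))) *
        sqrt(sum((ca - cb)^2))
      if (d < best[1]) best <- c(d, i, j)
    }
    i <- best[2]; j <- best[3]
    merged <- c(clusters[[i]], clusters[[j]])
    clusters <- c(clusters[-c(i, j)], list(merged))
    heights <- c(heights, best[1])
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# canonical string form of a partition (list of index vectors) for comparison
partition_key <- function(p) {
  paste(sort(vapply(p, function(g) paste(sort(g), collapse = ","),
                    character(1))), collapse = "|")
}

# partition of hclust tree at k clusters, as index groups
hclust_partition <- function(tree, k) {
  ct <- stats::cutree(tree, k = k)
  unname(lapply(split(seq_along(ct), ct), sort))
}

# small counts expression_matrix with default dimnames
make_counts <- function(values, genes = NULL, units = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(units)) units <- sprintf("c%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, units)
  expression_matrix(values, genes, units, modality = "counts")
}

# zscore expression_matrix straight from a numeric matrix
make_zscore <- function(values, genes = NULL, units = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(units)) units <- sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, units)
  n <- ncol(m)
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(s < 1e-12, Inf, s)
  expression_matrix(z, genes, units, modality = "zscore")
}
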