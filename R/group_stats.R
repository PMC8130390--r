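# Between-group statistics: Wilcoxon rank-sum DEG detection with Bonferroni
# control, Pearson correlation of indexes, and Welch t-test comparisons.

# Tie-aware exact two-sided rank-sum p by complete enumeration of group
# assignments: P(|U - E[U]| >= |U_obs - E[U]|) under the permutation null.
# Used for small groups, where a normal approximation cannot track the
# coarse exact p-grid (at 3 vs 3 the spacing is 0.1); cf. the exact
# small-sample default of stats::wilcox.test.
.wilcox_exact_p <- function(x, y, cmb = NULL) {
  na <- length(x)
  r <- rank(c(x, y))
  if (is.null(cmb)) cmb <- utils::combn(length(r), na)
  u <- colSums(matrix(r[cmb], nrow = na)) - na * (na + 1) / 2
  mu <- na * length(y) / 2
  obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mean(abs(u - mu) >= abs(obs - mu) - 1e-9)
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Emulates the conventional single-cell marker test at its defaults: genes
#' are pre-filtered to those detected (value > 0) in at least `min_pct` of
#' the cells of one group and with an absolute natural-log fold change of the
#' (+1 pseudocount) group means of at least `logfc_min`; the surviving genes
#' get a two-sided Wilcoxon rank-sum test and Bonferroni correction over the
#' number of genes actually tested. Genes with Bonferroni-corrected
#' P < `alpha` are flagged as DEGs.
#'
#' For small groups (`choose(n_a + n_b, n_a) <= exact_limit`) the p-value is
#' the tie-aware exact permutation-enumeration value; above that, the normal
#' approximation with tie correction and continuity correction is used (at
#' those sizes the two agree closely, while no normal approximation can track
#' the coarse exact p-grid of very small groups).
#'
#' @param m an [expression_matrix] with normalized values (modality
#'   `"rp10k"` or `"log2cpm"`).
#' @param group_a,group_b disjoint character vectors of unit IDs, each with
#'   at least 3 cells.
#' @param min_pct detection-fraction filter (default 0.1).
#' @param logfc_min absolute log fold-change filter, natural log
#'   (default 0.25).
#' @param alpha Bonferroni-corrected significance level (default 0.05).
#' @param exact_limit maximum number of group assignments enumerated for the
#'   exact p-value path (default 1e5, i.e. exact up to roughly 9 vs 9 cells);
#'   set to 0 to force the normal approximation.
#' @return data.frame with one row per tested gene: `gene`, `statistic`
#'   (rank-sum U for group A), `raw_p`, `bonferroni_p`, `log_fc`
#'   (A vs B, natural log), `pct_1`, `pct_2`, `direction` (`"up"` = higher
#'   in A), `is_deg`; sorted by `raw_p`. Zero surviving genes yields an
#'   empty table with a message.
#' @export
wilcoxon_deg <- function(m, group_a, group_b, min_pct = 0.1,
                         logfc_min = 0.25, alpha = 0.05,
                         exact_limit = 1e5) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!m$modality %in% c("rp10k", "log2cpm"))
    stop("wilcoxon_deg expects rp10k or log2cpm values, got '",
         m$modality, "'")
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ",
         paste(head(intersect(group_a, group_b), 3), collapse = ", "))
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("both groups need >= 3 cells")
  missing <- setdiff(c(group_a, group_b), m$unit_ids)
  if (length(missing))
    stop("unknown unit(s): ", paste(head(missing, 5), collapse = ", "))
  va <- as.matrix(m$values[, group_a, drop = FALSE])
  vb <- as.matrix(m$values[, group_b, drop = FALSE])
  pct1 <- rowMeans(va > 0)
  pct2 <- rowMeans(vb > 0)
  log_fc <- log(rowMeans(va) + 1) - log(rowMeans(vb) + 1)
  keep <- (pct1 >= min_pct | pct2 >= min_pct) & abs(log_fc) >= logfc_min
  if (!any(keep)) {
    message("no gene passes the min_pct/logfc filters; empty result")
    return(data.frame(gene = character(0), statistic = numeric(0),
                      raw_p = numeric(0), bonferroni_p = numeric(0),
                      log_fc = numeric(0), pct_1 = numeric(0),
                      pct_2 = numeric(0), direction = character(0),
                      is_deg = logical(0)))
  }
  genes <- m$gene_ids[keep]
  use_exact <- choose(length(group_a) + length(group_b),
                      length(group_a)) <= exact_limit
  cmb <- if (use_exact)
    utils::combn(length(group_a) + length(group_b), length(group_a))
  res <- t(vapply(genes, function(g) {
    wt <- suppressWarnings(
      wilcox.test(va[g, ], vb[g, ], alternative = "two.sided",
                  exact = FALSE, correct = TRUE))
    p <- if (use_exact) .wilcox_exact_p(va[g, ], vb[g, ], cmb) else wt$p.value
    c(statistic = unname(wt$statistic), raw_p = p)
  }, c(statistic = 0, raw_p = 0)))
  n_tested <- length(genes)
  out <- data.frame(
    gene = genes,
    statistic = res[, "statistic"],
    raw_p = res[, "raw_p"],
    bonferroni_p = pmin(1, res[, "raw_p"] * n_tested),
    log_fc = log_fc[keep],
    pct_1 = pct1[keep],
    pct_2 = pct2[keep],
    direction = ifelse(log_fc[keep] >= 0, "up", "down"),
    stringsAsFactors = FALSE)
  out$is_deg <- out$bonferroni_p < alpha
  out <- out[order(out$raw_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two signature indexes
#'
#' Standard Pearson r over the shared units, with the two-sided P value from
#' the t-distributed statistic \code{r * sqrt((n - 2) / (1 - r^2))} on
#' n - 2 degrees of freedom.
#'
#' @param a,b [index_vector]s over the same units, `n >= 3`.
#' @return list with `r`, `p`, `n`.
#' @export
index_correlation <- function(a, b) {
  stopifnot(inherits(a, "index_vector"), inherits(b, "index_vector"))
  if (!setequal(a$unit_ids, b$unit_ids))
    stop("index vectors cover different unit sets")
  x <- unname(a$scores[a$unit_ids])
  y <- unname(b$scores[a$unit_ids])
  n <- length(x)
  if (n < 3) stop("need >= 3 units")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in an index vector; correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Welch t-test comparisons of an index across labeled groups
#'
#' Two-sample two-sided Welch (unequal-variance) t-test per requested pair,
#' with the figure-legend star annotation: `***` for P < 0.001, `*` for
#' P < 0.05, empty otherwise.
#'
#' @param idx an [index_vector].
#' @param labels character vector mapping each unit to a group (named by
#'   unit_id or in `idx` order).
#' @param pairs list of length-2 character vectors of group names; default
#'   all pairs.
#' @return data.frame with `group_1`, `group_2`, `n_1`, `n_2`, `t`, `p`,
#'   `stars`.
#' @export
compare_groups_ttest <- function(idx, labels, pairs = NULL) {
  stopifnot(inherits(idx, "index_vector"))
  if (!is.null(names(labels))) {
    missing <- setdiff(idx$unit_ids, names(labels))
    if (length(missing))
      stop("unit(s) without group label: ",
           paste(head(missing, 5), collapse = ", "))
    labels <- labels[idx$unit_ids]
  } else if (length(labels) != length(idx$unit_ids)) {
    stop("labels length does not match number of units")
  }
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (is.null(pairs))
    pairs <- utils::combn(groups, 2, simplify = FALSE)
  bad <- unique(unlist(pairs)[!unlist(pairs) %in% groups])
  if (length(bad))
    stop("unknown group(s) in pairs: ", paste(bad, collapse = ", "))
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    stop("group(s) with < 2 units: ", paste(small, collapse = ", "))
  rows <- lapply(pairs, function(pr) {
    x <- unname(idx$scores[labels == pr[1]])
    y <- unname(idx$scores[labels == pr[2]])
    tt <- t.test(x, y, var.equal = FALSE, alternative = "two.sided")
    data.frame(group_1 = pr[1], group_2 = pr[2],
               n_1 = length(x), n_2 = length(y),
               t = unname(tt$statistic), p = tt$p.value,
               stars = if (tt$p.value < 0.001) "***"
                       else if (tt$p.value < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
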