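mk_idx <- function(scores, name = "Hep", agg = "mean") {
  index_vector(names(scores), scores, name, agg)
}

test_that("hepatocyte/proliferative classification applies strict thresholds", {
  hep <- mk_idx(c(a = 0.6, b = 0.5, c = 0.8, d = 0.2))
  s1 <- mk_idx(c(a = 0.2, b = 0.05, c = 0.05, d = 0.5), "S1")
  ann <- classify_hepatocytes(hep, s1)
  expect_identical(ann$cell_class,
                   c("proliferative_hepatocyte", "other", "hepatocyte",
                     "other"))
  # b sits exactly on the threshold: strict inequality keeps it out
  expect_false(ann$is_hepatocyte[ann$unit_id == "b"])
  # d is proliferative but not hepatocyte -> never proliferative_hepatocyte
  expect_true(ann$is_proliferative[ann$unit_id == "d"])
  expect_identical(ann$cell_class[ann$unit_id == "d"], "other")

  expect_error(classify_hepatocytes(hep, mk_idx(c(x = 1), "S1")),
               "different unit sets")
})

test_that("class counts equal an exhaustive recount on a random fixture", {
  set.seed(61)
  n <- 1000
  units <- sprintf("c%04d", 1:n)
  hep <- mk_idx(setNames(rnorm(n, 0.5, 0.5), units))
  s1 <- mk_idx(setNames(rexp(n, 10), units), "S1")
  ann <- classify_hepatocytes(hep, s1)
  for (u in sample(units, 50)) {
    h <- hep$scores[u] > 0.5; p <- s1$scores[u] > 0.1
    want <- if (h && p) "proliferative_hepatocyte"
            else if (h) "hepatocyte" else "other"
    expect_identical(ann$cell_class[ann$unit_id == u], want)
  }
  counts <- table(ann$cell_class)
  expect_equal(unname(counts["proliferative_hepatocyte"]),
               sum(hep$scores > 0.5 & s1$scores > 0.1))

  # threshold monotonicity: raising hep_threshold never adds hepatocytes
  hep_sets <- lapply(c(0.3, 0.5, 0.8), function(thr)
    classify_hepatocytes(hep, s1, hep_threshold = thr)$is_hepatocyte)
  expect_true(all(hep_sets[[2]] <= hep_sets[[1]]))
  expect_true(all(hep_sets[[3]] <= hep_sets[[2]]))
})

test_that("macrophage calling needs min_markers and respects hepatocyte precedence", {
  genes <- c("ITGAM", "CD68", "CD163", "CD14", "FCGR3A", "OTHER")
  counts <- matrix(0, 6, 4,
                   dimnames = list(genes, c("mac", "single", "hepmac",
                                            "none")))
  counts[c("CD68", "CD14"), "mac"] <- c(3, 1)
  counts["CD68", "single"] <- 5
  counts[c("CD68", "CD14", "CD163"), "hepmac"] <- 2
  counts["OTHER", ] <- 1
  m <- expression_matrix(counts, modality = "counts")
  hep <- mk_idx(c(mac = 0.1, single = 0.1, hepmac = 0.9, none = 0.0))
  s1 <- mk_idx(c(mac = 0, single = 0, hepmac = 0, none = 0), "S1")
  ann <- call_macrophages(m, classify_hepatocytes(hep, s1))
  got <- setNames(ann$cell_class, ann$unit_id)
  expect_identical(unname(got["mac"]), "macrophage")
  expect_identical(unname(got["single"]), "other")     # only 1 marker
  expect_identical(unname(got["hepmac"]), "hepatocyte") # precedence
  expect_identical(unname(got["none"]), "other")

  # missing markers are skipped with a message; all missing is fatal
  m_sub <- expression_matrix(counts[c("CD68", "CD14", "OTHER"), ],
                             modality = "counts")
  expect_message(call_macrophages(m_sub, classify_hepatocytes(hep, s1)),
                 "skipped")
  m_none <- expression_matrix(counts["OTHER", , drop = FALSE],
                              modality = "counts")
  expect_error(call_macrophages(m_none, classify_hepatocytes(hep, s1)),
               "none of the macrophage markers")
})

test_that("cluster-level macrophage mode flags whole clusters", {
  genes <- c("ITGAM", "CD68", "CD163", "CD14", "FCGR3A")
  counts <- matrix(0, 5, 6,
                   dimnames = list(genes, sprintf("c%d", 1:6)))
  counts[c("CD68", "CD14"), 1:2] <- 4  # cluster X: 2/3 marker-positive
  counts["CD68", 4] <- 1               # cluster Y: 1 marker in 1/3 cells
  m <- expression_matrix(counts, modality = "counts")
  hep <- mk_idx(setNames(rep(0, 6), colnames(counts)))
  s1 <- mk_idx(setNames(rep(0, 6), colnames(counts)), "S1")
  meta <- data.frame(unit_id = colnames(counts),
                     tissue = rep(c("tumor", "para"), 3),
                     sample = "s1",
                     cluster = rep(c("X", "Y"), each = 3))
  ann <- classify_hepatocytes(hep, s1, unit_meta = meta)
  ann <- call_macrophages(m, ann, mode = "cluster")
  expect_identical(ann$cell_class[ann$cluster == "X"], rep("macrophage", 3))
  expect_identical(ann$cell_class[ann$cluster == "Y"], rep("other", 3))
})

test_that("SLC40A1 strata follow tissue and expression, partition all macrophages", {
  genes <- c("ITGAM", "CD68", "CD163", "CD14", "FCGR3A", "SLC40A1")
  n <- 8
  counts <- matrix(0, 6, n, dimnames = list(genes, sprintf("c%d", 1:n)))
  counts[c("CD68", "CD14"), ] <- 2          # everyone macrophage-marked
  counts["SLC40A1", c(1, 3, 5)] <- 3
  m <- expression_matrix(counts, modality = "counts")
  hep <- mk_idx(setNames(rep(0, n), colnames(counts)))
  s1 <- mk_idx(setNames(rep(0, n), colnames(counts)), "S1")
  meta <- data.frame(unit_id = colnames(counts),
                     tissue = c("para", "para", "tumor", "tumor", "normal",
                                "para", "tumor", "para"),
                     sample = "s1", cluster = rep(c("k1", "k2"), 4))
  ann <- suppressWarnings(assign_slc40a1_groups(
    m, call_macrophages(m, classify_hepatocytes(hep, s1, unit_meta = meta))))
  got <- setNames(ann$slc40a1_group, ann$unit_id)
  expect_identical(unname(got["c1"]), "N_exp")   # para + expressed
  expect_identical(unname(got["c3"]), "T_exp")
  expect_identical(unname(got["c4"]), "T_noexp")
  expect_true(is.na(got["c5"]))                  # normal tissue -> NA

  # partition invariant: the four groups cover all tumor/para macrophages
  mac_tp <- ann$cell_class == "macrophage" & ann$tissue %in% c("tumor", "para")
  expect_identical(sum(table(ann$slc40a1_group)), sum(mac_tp))

  # warning path for off-tissue macrophages
  expect_warning(assign_slc40a1_groups(
    m, call_macrophages(m, classify_hepatocytes(hep, s1, unit_meta = meta))),
    "ungrouped")

  tab <- suppressWarnings(group_cluster_contingency(ann))
  expect_equal(unname(tab["Total", "Total"]), sum(mac_tp))
  expect_true(all(rowSums(tab[setdiff(rownames(tab), "Total"),
                              setdiff(colnames(tab), "Total"),
                              drop = FALSE]) ==
                  tab[setdiff(rownames(tab), "Total"), "Total"]))

  # permutation invariance of the contingency table
  ann_perm <- ann[sample(nrow(ann)), ]
  expect_identical(group_cluster_contingency(ann_perm), tab)

  ann_none <- ann; ann_none$cell_class <- "other"
  expect_error(group_cluster_contingency(ann_none), "no grouped macrophages")
})

test_that("marker-positive fractions count cells per gene and jointly", {
  counts <- rbind(A = c(1, 2, 0, 3), B = c(0, 1, 1, 0))
  m <- make_counts(counts, genes = c("A", "B"))
  cells <- m$unit_ids
  expect_equal(unname(marker_positive_fraction(m, cells, "A")), 0.75)
  # disjointly positive genes: nobody is positive for both
  expect_equal(marker_positive_fraction(
    make_counts(rbind(c(1, 0), c(0, 1)), genes = c("A", "B")),
    c("c01", "c02"), c("A", "B"), mode = "all_genes"), 0)
  pg <- marker_positive_fraction(m, cells, c("A", "B"))
  expect_equal(unname(pg), c(0.75, 0.5))
  expect_equal(marker_positive_fraction(m, cells, c("A", "B"), "all_genes"),
               mean(counts["A", ] > 0 & counts["B", ] > 0))
  expect_error(marker_positive_fraction(m, character(0), "A"), "empty")
  expect_error(marker_positive_fraction(m, cells, "NOPE"), "NOPE")
})

test_that("classification recovers planted macrophage strata on the fixture", {
  tp <- generate_tumor_para(seed = 4, n_cells = 1500)
  z <- zscore_by_gene(rp10k_normalize(tp$matrix))
  hep <- score_signature(z, tp$hep_signature, "mean")
  s1 <- score_signature(z, tp$s1_signature, "mean")
  ann <- classify_hepatocytes(hep, s1, unit_meta = tp$matrix$unit_meta)
  ann <- call_macrophages(tp$matrix, ann)
  truth_mac <- tp$truth$cell_type == "macrophage"
  pred_mac <- ann$cell_class[match(tp$truth$unit_id, ann$unit_id)] ==
    "macrophage"
  recall <- sum(pred_mac & truth_mac) / sum(truth_mac)
  expect_gte(recall, 0.9)

  ann <- assign_slc40a1_groups(tp$matrix, ann)
  # group sizes equal an exhaustive recount from matrix and truth
  expr <- as.numeric(tp$matrix$values["SLC40A1", ann$unit_id]) > 0
  for (tis in c("para", "tumor")) for (e in c(TRUE, FALSE)) {
    grp <- paste0(ifelse(tis == "para", "N", "T"),
                  ifelse(e, "_exp", "_noexp"))
    manual <- sum(ann$cell_class == "macrophage" & ann$tissue == tis &
                    expr == e)
    expect_identical(sum(ann$slc40a1_group == grp, na.rm = TRUE), manual)
  }
})
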