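# Cell classification from signature indexes and marker genes.
#
# The annotation table is a plain data.frame (one row per cell) with columns
# unit_id, hep_index, s1_index, is_hepatocyte, is_proliferative, cell_class,
# slc40a1_group, tissue, sample, cluster. Invariants:
#   proliferative_hepatocyte => is_hepatocyte & is_proliferative;
#   slc40a1_group != NA      <=> cell_class == "macrophage".

.MACROPHAGE_MARKERS <- c("ITGAM", "CD68", "CD163", "CD14", "FCGR3A")

#' Classify hepatocytes and proliferative hepatocytes
#'
#' A cell is a hepatocyte when its hepatocyte (Hep) index strictly exceeds
#' `hep_threshold`, and proliferative when its S1 index strictly exceeds
#' `s1_threshold`; a proliferative hepatocyte satisfies both. The defaults
#' (0.5 and 0.1) are the conventional manual choices for tumor/para-carcinoma
#' single-cell data; `hep_threshold` is normally replaced by the mixture-fit
#' [calling_threshold].
#'
#' @param hep an [index_vector] of hepatocyte-signature scores.
#' @param s1 an [index_vector] of proliferation-signature scores over the
#'   same units.
#' @param hep_threshold hepatocyte-calling threshold (default 0.5).
#' @param s1_threshold proliferation threshold (default 0.1).
#' @param unit_meta optional data.frame with `unit_id` plus `tissue`,
#'   `sample`, `cluster` columns merged into the annotation.
#' @return data.frame annotation table (one row per unit) described above,
#'   with `cell_class` in hepatocyte / proliferative_hepatocyte / other.
#' @export
classify_hepatocytes <- function(hep, s1, hep_threshold = 0.5,
                                 s1_threshold = 0.1, unit_meta = NULL) {
  stopifnot(inherits(hep, "index_vector"), inherits(s1, "index_vector"))
  if (!setequal(hep$unit_ids, s1$unit_ids))
    stop("hep and s1 index vectors cover different unit sets")
  units <- hep$unit_ids
  s1_scores <- s1$scores[units]
  ann <- data.frame(
    unit_id = units,
    hep_index = unname(hep$scores),
    s1_index = unname(s1_scores),
    stringsAsFactors = FALSE)
  ann$is_hepatocyte <- ann$hep_index > hep_threshold
  ann$is_proliferative <- ann$s1_index > s1_threshold
  ann$cell_class <- ifelse(ann$is_hepatocyte & ann$is_proliferative,
                           "proliferative_hepatocyte",
                           ifelse(ann$is_hepatocyte, "hepatocyte", "other"))
  ann$slc40a1_group <- NA_character_
  if (!is.null(unit_meta)) {
    unit_meta <- as.data.frame(unit_meta)
    stopifnot("unit_id" %in% names(unit_meta))
    keep <- intersect(c("unit_id", "tissue", "sample", "cluster"),
                      names(unit_meta))
    ann <- merge(ann, unit_meta[, keep, drop = FALSE], by = "unit_id",
                 all.x = TRUE, sort = FALSE)
    ann <- ann[match(units, ann$unit_id), , drop = FALSE]
    rownames(ann) <- NULL
  }
  attr(ann, "hep_threshold") <- hep_threshold
  attr(ann, "s1_threshold") <- s1_threshold
  ann
}

#' Call macrophages from marker-gene expression
#'
#' Flags cells expressing at least `min_markers` of the canonical macrophage
#' markers (ITGAM, CD68, CD163, CD14, FCGR3A; count > 0) as macrophages.
#' Hepatocyte status takes precedence: a cell already above the hepatocyte
#' threshold is never relabeled, which resolves doublet-like conflicts
#' deterministically. When `ann` carries a `cluster` column and
#' `mode = "cluster"`, whole clusters are flagged instead, when at least half
#' of a cluster's cells are marker-positive (the cluster-level analogue of
#' judging marker expression on an embedding).
#'
#' @param m an [expression_matrix] with modality `"counts"` covering the
#'   annotated cells.
#' @param ann annotation data.frame from [classify_hepatocytes].
#' @param markers marker gene IDs; markers absent from the matrix are
#'   reported and skipped, all-absent is an error.
#' @param min_markers minimum number of positive markers (default 2).
#' @param mode `"cell"` (per-cell rule) or `"cluster"` (whole-cluster rule).
#' @return the annotation table with `cell_class = "macrophage"` set where
#'   called.
#' @export
call_macrophages <- function(m, ann, markers = .MACROPHAGE_MARKERS,
                             min_markers = 2, mode = c("cell", "cluster")) {
  stopifnot(inherits(m, "expression_matrix"), is.data.frame(ann))
  mode <- match.arg(mode)
  missing_units <- setdiff(ann$unit_id, m$unit_ids)
  if (length(missing_units))
    stop("annotated unit(s) absent from matrix: ",
         paste(head(missing_units, 5), collapse = ", "))
  present <- intersect(markers, m$gene_ids)
  if (!length(present))
    stop("none of the macrophage markers (",
         paste(markers, collapse = ", "), ") is present in the matrix")
  if (length(present) < length(markers))
    message("marker(s) absent from matrix, skipped: ",
            paste(setdiff(markers, present), collapse = ", "))
  sub <- m$values[present, ann$unit_id, drop = FALSE]
  n_pos <- Matrix::colSums(sub > 0)
  marker_positive <- n_pos >= min_markers
  if (mode == "cell") {
    is_mac <- marker_positive & !ann$is_hepatocyte
  } else {
    if (is.null(ann$cluster))
      stop("cluster mode requires a `cluster` column in the annotation")
    frac_pos <- tapply(marker_positive, ann$cluster, mean)
    mac_clusters <- names(frac_pos)[frac_pos >= 0.5]
    is_mac <- as.character(ann$cluster) %in% mac_clusters &
      !ann$is_hepatocyte
  }
  ann$cell_class[is_mac] <- "macrophage"
  ann
}

#' Stratify macrophages by tissue and SLC40A1 expression
#'
#' Splits called macrophages into the four ferroportin strata: `N_exp` /
#' `N_noexp` are para-carcinoma macrophages with / without SLC40A1 expression
#' (count > 0) and `T_exp` / `T_noexp` the tumor-tissue counterparts.
#' Macrophages from tissues other than tumor/para keep group `NA` with a
#' warning. Non-macrophages always have group `NA`.
#'
#' @param m an [expression_matrix] with modality `"counts"`.
#' @param ann annotation data.frame with macrophages already called and a
#'   `tissue` column.
#' @param gene gene whose expression stratifies the groups
#'   (default `"SLC40A1"`).
#' @return the annotation table with `slc40a1_group` filled in.
#' @export
assign_slc40a1_groups <- function(m, ann, gene = "SLC40A1") {
  stopifnot(inherits(m, "expression_matrix"), is.data.frame(ann))
  if (!gene %in% m$gene_ids)
    stop("gene '", gene, "' not present in the matrix")
  if (is.null(ann$tissue))
    stop("annotation lacks a `tissue` column")
  expr <- as.numeric(m$values[gene, ann$unit_id]) > 0
  mac <- ann$cell_class == "macrophage"
  ok_tissue <- ann$tissue %in% c("tumor", "para")
  if (any(mac & !ok_tissue))
    warning(sum(mac & !ok_tissue), " macrophage(s) with tissue outside ",
            "tumor/para left ungrouped")
  prefix <- ifelse(ann$tissue == "para", "N", "T")
  suffix <- ifelse(expr, "exp", "noexp")
  ann$slc40a1_group <- ifelse(mac & ok_tissue,
                              paste(prefix, suffix, sep = "_"),
                              NA_character_)
  ann
}

#' Cluster-by-group contingency table for macrophages
#'
#' Counts macrophages in each (cluster, SLC40A1 group) combination, with
#' row and column margins, mirroring counting group membership per embedding
#' cluster.
#'
#' @param ann annotation data.frame with `cluster` and `slc40a1_group`
#'   columns filled for macrophages.
#' @return integer matrix cluster x group including `Total` margins.
#' @export
group_cluster_contingency <- function(ann) {
  stopifnot(is.data.frame(ann))
  mac <- ann[ann$cell_class == "macrophage" & !is.na(ann$slc40a1_group), ,
             drop = FALSE]
  if (!nrow(mac))
    stop("no grouped macrophages in the annotation table")
  if (is.null(mac$cluster) || all(is.na(mac$cluster)))
    stop("cluster labels required for the contingency table")
  tab <- table(cluster = as.character(mac$cluster),
               group = mac$slc40a1_group)
  tab <- unclass(tab)
  tab <- cbind(tab, Total = rowSums(tab))
  tab <- rbind(tab, Total = colSums(tab))
  tab
}

#' Fraction of cells expressing given genes
#'
#' For a subset of cells, the fraction expressing each gene (count > 0). In
#' `per_gene` mode one fraction per gene is returned; in `all_genes` mode the
#' single fraction of cells positive for every listed gene.
#'
#' @param m an [expression_matrix] with modality `"counts"`.
#' @param cells character vector of unit IDs (non-empty).
#' @param genes gene IDs; all must be present in the matrix.
#' @param mode `"per_gene"` or `"all_genes"`.
#' @return named numeric vector of fractions (`per_gene`) or a single
#'   fraction (`all_genes`).
#' @export
marker_positive_fraction <- function(m, cells, genes,
                                     mode = c("per_gene", "all_genes")) {
  stopifnot(inherits(m, "expression_matrix"))
  mode <- match.arg(mode)
  if (!length(cells)) stop("empty cell subset")
  missing_cells <- setdiff(cells, m$unit_ids)
  if (length(missing_cells))
    stop("unknown cell(s): ", paste(head(missing_cells, 5), collapse = ", "))
  missing <- setdiff(genes, m$gene_ids)
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  pos <- m$values[genes, cells, drop = FALSE] > 0
  if (mode == "per_gene")
    Matrix::rowSums(pos) / length(cells)
  else
    sum(Matrix::colSums(pos) == length(genes)) / length(cells)
}
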