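#' Reads-per-10K normalization
#'
#' Scales every cell so its gene values sum to 10,000: for a cell with read
#' depth x (sum of counts over genes), a gene with y reads gets y / x * 10000.
#' Depth-zero cells are an error rather than being dropped silently, so unit
#' metadata never desynchronizes; filter them out first (see
#' [filter_min_depth]).
#'
#' @param m an [expression_matrix] with modality `"counts"`.
#' @return an [expression_matrix] with modality `"rp10k"`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(1, 3, 0, 6), 4, 1,
#'        dimnames = list(paste0("g", 1:4), "c1")), modality = "counts")
#' dense_values(rp10k_normalize(m))[, 1]
rp10k_normalize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$modality != "counts")
    stop("rp10k_normalize expects counts, got modality '", m$modality, "'")
  depth <- Matrix::colSums(m$values)
  if (any(depth == 0))
    stop("unit(s) with zero total counts: ",
         paste(head(m$unit_ids[depth == 0], 5), collapse = ", "),
         if (sum(depth == 0) > 5) ", ..." else "")
  values <- m$values %*% Matrix::Diagonal(x = 10000 / depth)
  if (!inherits(m$values, "sparseMatrix")) values <- as.matrix(values)
  expression_matrix(values, m$gene_ids, m$unit_ids, modality = "rp10k",
                    unit_meta = m$unit_meta)
}

#' Drop units below a minimum read depth
#'
#' Cells with fewer than `min_depth` mapped reads carry too little signal for
#' clustering; 2000 is the conventional single-cell cutoff used here.
#'
#' @param m an [expression_matrix] with modality `"counts"`.
#' @param min_depth minimum column sum to keep (default 2000).
#' @return the filtered [expression_matrix] (unit_meta subset accordingly).
#' @export
filter_min_depth <- function(m, min_depth = 2000) {
  stopifnot(inherits(m, "expression_matrix"), m$modality == "counts")
  keep <- Matrix::colSums(m$values) >= min_depth
  expression_matrix(m$values[, keep, drop = FALSE], m$gene_ids,
                    m$unit_ids[keep], modality = "counts",
                    unit_meta = if (is.null(m$unit_meta)) NULL else
                      m$unit_meta[keep, , drop = FALSE])
}

#' Per-gene Z-score transform
#'
#' Standardizes every gene row to mean 0 and sample standard deviation 1
#' (n - 1 denominator). Genes constant across units map to all-zero rows, not
#' NaN, so downstream medians and means over signature genes stay defined.
#'
#' @param m an [expression_matrix] with at least two units (any modality).
#' @return an [expression_matrix] with modality `"zscore"`; the input
#'   modality is kept in attribute `source_modality`.
#' @export
zscore_by_gene <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  n <- ncol(m$values)
  if (n < 2)
    stop("zscore_by_gene needs at least 2 units, got ", n)
  v <- as.matrix(m$values)
  mu <- rowMeans(v)
  s <- sqrt(pmax(0, (rowSums(v^2) - n * mu^2) / (n - 1)))
  z <- (v - mu) / ifelse(s < 1e-12, Inf, s)  # constant genes -> 0
  out <- expression_matrix(z, m$gene_ids, m$unit_ids, modality = "zscore",
                           unit_meta = m$unit_meta)
  attr(out, "source_modality") <- m$modality
  out
}

#' Cell-type profile container
#'
#' @param fractions gene x type numeric matrix of fraction-of-cells-expressing
#'   values in \[0, 1\].
#' @param n_cells_per_type named positive integer vector, one per type.
#' @return object of class `celltype_profile` with elements `fractions`,
#'   `gene_ids`, `type_ids`, `n_cells_per_type`.
#' @export
celltype_profile <- function(fractions, n_cells_per_type) {
  fractions <- as.matrix(fractions)
  if (is.null(rownames(fractions)) || is.null(colnames(fractions)))
    stop("fractions must carry gene and type dimnames")
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  if (!all(colnames(fractions) %in% names(n_cells_per_type)))
    stop("n_cells_per_type must be named by type")
  n_cells_per_type <- n_cells_per_type[colnames(fractions)]
  if (any(n_cells_per_type < 1))
    stop("every type needs >= 1 cell")
  # each fraction must be consistent with an integer count of expressing cells
  counts <- sweep(fractions, 2, n_cells_per_type, `*`)
  if (any(abs(counts - round(counts)) > 0.5))
    stop("fractions inconsistent with integer expressing-cell counts")
  structure(list(fractions = fractions,
                 gene_ids = rownames(fractions),
                 type_ids = colnames(fractions),
                 n_cells_per_type = n_cells_per_type),
            class = "celltype_profile")
}

#' @export
print.celltype_profile <- function(x, ...) {
  cat(sprintf("celltype_profile: %d genes x %d types (%d cells)\n",
              length(x$gene_ids), length(x$type_ids),
              sum(x$n_cells_per_type)))
  invisible(x)
}

#' Fraction-of-cells-expressing profile per cell type
#'
#' For every gene and cell type, the fraction of that type's cells expressing
#' the gene. "Expressed" means raw count strictly greater than
#' `expressed_if` (default 0, i.e. any nonzero count; equivalently RP10K > 0).
#'
#' @param m an [expression_matrix] with modality `"counts"` (or `"rp10k"`,
#'   which preserves the zero pattern).
#' @param type_labels character vector mapping each unit to a cell type;
#'   either named by unit_id or in matrix column order.
#' @param expressed_if count threshold; a cell expresses a gene when its value
#'   is strictly greater than this (default 0).
#' @return a [celltype_profile].
#' @export
build_celltype_profile <- function(m, type_labels, expressed_if = 0) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!m$modality %in% c("counts", "rp10k"))
    stop("profile construction expects counts (or rp10k), got '",
         m$modality, "'")
  if (!is.null(names(type_labels))) {
    missing <- setdiff(m$unit_ids, names(type_labels))
    if (length(missing))
      stop("unit(s) without a type label: ",
           paste(head(missing, 5), collapse = ", "))
    type_labels <- type_labels[m$unit_ids]
  } else if (length(type_labels) != length(m$unit_ids)) {
    stop("type_labels length (", length(type_labels),
         ") does not match number of units (", length(m$unit_ids), ")")
  }
  if (anyNA(type_labels)) stop("NA type labels are not allowed")
  type_labels <- as.character(type_labels)
  types <- sort(unique(type_labels))
  expressing <- m$values > expressed_if
  frac <- vapply(types, function(t) {
    idx <- which(type_labels == t)
    Matrix::rowSums(expressing[, idx, drop = FALSE]) / length(idx)
  }, numeric(length(m$gene_ids)))
  rownames(frac) <- m$gene_ids
  n_cells <- vapply(types, function(t) sum(type_labels == t), integer(1))
  celltype_profile(frac, n_cells)
}
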