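#' Gene signature container
#'
#' A named gene set with derivation provenance, e.g. the 142-gene hepatocyte
#' ("Hep") signature or the 87-gene stem/progenitor-derived ("S1") signature.
#'
#' @param name signature name.
#' @param genes non-empty character vector of unique gene IDs.
#' @param provenance arbitrary named list recording thresholds, cluster
#'   counts, source datasets and similar derivation facts.
#' @return object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, provenance = list()) {
  genes <- as.character(genes)
  if (!length(genes)) stop("a gene signature must contain >= 1 gene")
  if (anyDuplicated(genes))
    stop("duplicate genes in signature: ",
         paste(head(unique(genes[duplicated(genes)]), 3), collapse = ", "))
  structure(list(name = name, genes = genes, provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes\n", x$name, length(x$genes)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

#' Write a gene signature as a plain gene list
#'
#' One gene per line, preceded by `#` comment lines carrying the name and
#' provenance; readable back with [read_gene_list].
#'
#' @param sig a [gene_signature].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_signature <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  prov <- vapply(names(sig$provenance), function(k)
    sprintf("# %s: %s", k,
            paste(format(sig$provenance[[k]]), collapse = " ")),
    character(1))
  writeLines(c(sprintf("# signature: %s", sig$name), prov, sig$genes), path)
  invisible(path)
}

#' Two-threshold specificity filter on a cell-type profile
#'
#' Keeps genes that are essentially silent in every excluded cell type
#' (fraction expressing < `low` in all of them) yet clearly expressed
#' somewhere else (fraction > `high` in at least one non-excluded type).
#' The excluded set is typically the stem/progenitor types, so the filter
#' removes genes tied to proliferative programs while keeping genes with a
#' strong differentiated-type pattern.
#'
#' @param p a [celltype_profile].
#' @param excluded_types character vector of type IDs to exclude; must be a
#'   non-empty proper subset of the profile's types.
#' @param low upper bound on the fraction in every excluded type
#'   (default 0.1).
#' @param high lower bound that must be exceeded in at least one non-excluded
#'   type (default 0.5).
#' @return character vector of kept gene IDs.
#' @export
threshold_filter <- function(p, excluded_types, low = 0.1, high = 0.5) {
  stopifnot(inherits(p, "celltype_profile"))
  if (!length(excluded_types))
    stop("excluded_types must be non-empty")
  unknown <- setdiff(excluded_types, p$type_ids)
  if (length(unknown))
    stop("unknown excluded type(s): ", paste(unknown, collapse = ", "))
  if (setequal(excluded_types, p$type_ids))
    stop("excluded_types cannot cover all types")
  if (!(low >= 0 && low < high && high <= 1))
    stop("need 0 <= low < high <= 1")
  excl <- p$fractions[, p$type_ids %in% excluded_types, drop = FALSE]
  rest <- p$fractions[, !p$type_ids %in% excluded_types, drop = FALSE]
  keep <- apply(excl, 1, function(r) all(r < low)) &
    apply(rest, 1, function(r) any(r > high))
  p$gene_ids[keep]
}

#' Ward (ward.D2) hierarchical clustering of gene rows
#'
#' Agglomerative clustering of gene expression rows on Euclidean distances
#' under the ward.D2 criterion (Lance-Williams update on squared distances,
#' heights reported on the distance scale), with the tree cut into `k` groups
#' by removing the k - 1 highest merges. Gene rows are sorted
#' lexicographically by ID before clustering so the result is invariant to
#' input order and merge ties resolve reproducibly.
#'
#' @param z an [expression_matrix] (typically modality `"zscore"`), a
#'   [celltype_profile] (clustered on its fraction values, as a
#'   percent-expressing atlas is), or a plain numeric matrix with gene
#'   rownames.
#' @param k number of groups, `1 <= k <= n_genes`.
#' @param return_tree also return the `hclust` tree (default `FALSE`).
#' @return named integer vector gene -> cluster index in 1..k; with
#'   `return_tree = TRUE`, a list with elements `clusters` and `tree`.
#' @export
cluster_genes <- function(z, k, return_tree = FALSE) {
  v <- if (inherits(z, "expression_matrix")) as.matrix(z$values)
       else if (inherits(z, "celltype_profile")) z$fractions
       else as.matrix(z)
  if (is.null(rownames(v))) stop("gene rownames required for clustering")
  if (!all(is.finite(v)))
    stop("non-finite values in the matrix; clean the input first")
  if (nrow(v) < 2) stop("need >= 2 genes to cluster")
  if (k < 1 || k > nrow(v))
    stop("k must lie in [1, n_genes]")
  v <- v[order(rownames(v)), , drop = FALSE]
  tree <- hclust(dist(v, method = "euclidean"), method = "ward.D2")
  clusters <- cutree(tree, k = k)
  if (return_tree) list(clusters = clusters, tree = tree) else clusters
}

#' Select the cluster most specific to a target cell type
#'
#' Scores each gene cluster by (mean fraction expressing in the target type)
#' minus (mean fraction across all other types), averaged over the cluster's
#' genes, and returns the genes of the top-scoring cluster. This
#' operationalizes the by-eye choice of the target-type block in a clustered
#' heatmap; exact ties are surfaced as an error so a human picks.
#'
#' @param clusters named gene -> cluster mapping from [cluster_genes].
#' @param p a [celltype_profile] covering the clustered genes.
#' @param target_type the cell type the signature should mark.
#' @return character vector: the member genes of the most target-specific
#'   cluster, with the score in attribute `specificity`.
#' @export
select_target_cluster <- function(clusters, p, target_type) {
  stopifnot(inherits(p, "celltype_profile"))
  if (!target_type %in% p$type_ids)
    stop("target_type '", target_type, "' not in profile types")
  genes <- names(clusters)
  missing <- setdiff(genes, p$gene_ids)
  if (length(missing))
    stop("clustered gene(s) absent from profile: ",
         paste(head(missing, 5), collapse = ", "))
  fr <- p$fractions[genes, , drop = FALSE]
  tgt <- fr[, target_type]
  oth <- rowMeans(fr[, p$type_ids != target_type, drop = FALSE])
  spec <- tgt - oth
  by_cluster <- tapply(spec, clusters, mean)
  top <- max(by_cluster)
  winners <- names(by_cluster)[abs(by_cluster - top) < 1e-12]
  if (length(winners) > 1)
    stop("specificity tie between clusters ",
         paste(winners, collapse = ", "),
         "; inspect the profile and select manually")
  out <- genes[clusters == as.integer(winners)]
  attr(out, "specificity") <- unname(top)
  out
}

#' Refine candidate genes by bulk-tissue specificity
#'
#' Clusters the candidate genes into two groups on a Z-scored bulk expression
#' panel (Euclidean + ward.D2) and keeps the group with the higher mean
#' Z-score in the target tissue's samples. This is the second derivation
#' stage: genes whose atlas pattern looked target-specific but that are
#' broadly expressed across bulk tissues fall into the other group and are
#' dropped.
#'
#' @param candidates character vector of candidate gene IDs (all must be
#'   present in the bulk matrix).
#' @param bulk_z an [expression_matrix] with modality `"zscore"` over bulk
#'   samples.
#' @param tissue_labels character vector mapping each bulk sample to a
#'   tissue; named by unit_id or in column order.
#' @param target_tissue tissue whose specific genes form the signature.
#' @param name name for the resulting signature (default the target tissue).
#' @return a [gene_signature]; provenance records both group sizes and the
#'   thresholds used.
#' @export
bulk_specificity_refine <- function(candidates, bulk_z, tissue_labels,
                                    target_tissue,
                                    name = paste0(target_tissue,
                                                  "_signature")) {
  stopifnot(inherits(bulk_z, "expression_matrix"))
  if (bulk_z$modality != "zscore")
    stop("bulk matrix must be zscore-normalized (see zscore_by_gene)")
  missing <- setdiff(candidates, bulk_z$gene_ids)
  if (length(missing))
    stop("candidate gene(s) absent from bulk matrix: ",
         paste(missing, collapse = ", "))
  if (!is.null(names(tissue_labels)))
    tissue_labels <- tissue_labels[bulk_z$unit_ids]
  if (length(tissue_labels) != length(bulk_z$unit_ids) ||
      anyNA(tissue_labels))
    stop("tissue_labels must cover every bulk sample")
  if (length(unique(tissue_labels)) < 2)
    stop("need >= 2 tissues in the bulk panel")
  if (!target_tissue %in% tissue_labels)
    stop("target tissue '", target_tissue, "' absent from labels")
  sub <- expression_matrix(bulk_z$values[candidates, , drop = FALSE],
                           candidates, bulk_z$unit_ids, modality = "zscore",
                           validate = FALSE)
  grp <- cluster_genes(sub, k = 2)
  in_target <- tissue_labels == target_tissue
  mean_z <- tapply(
    rowMeans(as.matrix(sub$values)[names(grp), in_target, drop = FALSE]),
    grp, mean)
  winner <- as.integer(names(mean_z)[which.max(mean_z)])
  genes <- names(grp)[grp == winner]
  gene_signature(name, genes, provenance = list(
    method = "bulk_specificity_refine",
    target_tissue = target_tissue,
    n_candidates = length(candidates),
    group_sizes = as.integer(table(grp)),
    selected_group = winner))
}

#' End-to-end signature derivation
#'
#' Runs the full derivation chain: two-threshold filter on the atlas
#' percent-expressing profile, Ward clustering of the surviving genes'
#' profiles cut into `k` groups, selection of the cluster most specific to
#' the target cell type, and bulk-tissue refinement (2-group Ward cut on the
#' Z-scored bulk panel, keeping the group with higher mean Z in the target
#' tissue).
#'
#' @param p a [celltype_profile] (atlas percent-expressing profile).
#' @param excluded_types progenitor-like types excluded by the filter.
#' @param target_type cell type whose signature is derived.
#' @param bulk an [expression_matrix] of bulk samples (any non-zscore
#'   modality; it is Z-scored internally, or passed through if already
#'   zscore).
#' @param tissue_labels bulk sample -> tissue mapping.
#' @param target_tissue bulk tissue corresponding to the target type.
#' @param low,high thresholds of [threshold_filter] (defaults 0.1 / 0.5).
#' @param k number of atlas cluster groups (default 12).
#' @param name signature name (default derived from `target_type`).
#' @return a [gene_signature] with full provenance.
#' @export
derive_signature <- function(p, excluded_types, target_type, bulk,
                             tissue_labels, target_tissue,
                             low = 0.1, high = 0.5, k = 12,
                             name = paste0(target_type, "_signature")) {
  candidates <- threshold_filter(p, excluded_types, low = low, high = high)
  if (length(candidates) < 2)
    stop("fewer than 2 genes survive the threshold filter")
  clusters <- cluster_genes(p$fractions[candidates, , drop = FALSE],
                            k = min(k, length(candidates)))
  target_genes <- select_target_cluster(clusters, p, target_type)
  bulk_z <- if (bulk$modality == "zscore") bulk else zscore_by_gene(bulk)
  sig <- bulk_specificity_refine(target_genes, bulk_z, tissue_labels,
                                 target_tissue, name = name)
  sig$provenance <- c(sig$provenance,
                      list(low = low, high = high, k = k,
                           excluded_types = excluded_types,
                           n_filtered = length(candidates),
                           n_target_cluster = length(target_genes)))
  sig
}
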