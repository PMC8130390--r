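#' Signature index container
#'
#' One score per unit: the median (bulk samples) or mean (single cells) of
#' the unit's Z-scores over a signature's genes.
#'
#' @param unit_ids character vector of unit IDs.
#' @param scores numeric vector, one finite score per unit.
#' @param signature_name name of the scored signature.
#' @param aggregation `"median"` or `"mean"`.
#' @param source_modality modality of the matrix the Z-scores came from.
#' @param n_genes_used number of signature genes present in the matrix.
#' @return object of class `index_vector`.
#' @export
index_vector <- function(unit_ids, scores, signature_name, aggregation,
                         source_modality = NA_character_,
                         n_genes_used = NA_integer_) {
  aggregation <- match.arg(aggregation, c("median", "mean"))
  if (length(unit_ids) != length(scores))
    stop("one score per unit required")
  if (!all(is.finite(scores))) stop("non-finite scores")
  structure(list(unit_ids = as.character(unit_ids),
                 scores = setNames(as.numeric(scores),
                                   as.character(unit_ids)),
                 signature_name = signature_name,
                 aggregation = aggregation,
                 source_modality = source_modality,
                 n_genes_used = n_genes_used),
            class = "index_vector")
}

#' @export
print.index_vector <- function(x, ...) {
  cat(sprintf("index_vector '%s' (%s of Z over %s genes): %d units\n",
              x$signature_name, x$aggregation,
              ifelse(is.na(x$n_genes_used), "?", x$n_genes_used),
              length(x$unit_ids)))
  print(summary(unname(x$scores)))
  invisible(x)
}

#' @export
as.data.frame.index_vector <- function(x, ...) {
  data.frame(unit_id = x$unit_ids, score = unname(x$scores),
             stringsAsFactors = FALSE)
}

#' Score units with a gene signature
#'
#' Per unit, the median or mean Z-score over the signature genes present in
#' the matrix. Median is the bulk-sample form; mean is used for single cells,
#' where sequencing depth is low enough that a median over a sparse signature
#' would collapse to zero for most cells. Signature genes absent from the
#' matrix are excluded from the aggregation (not imputed as zero) and their
#' count is reported with a message.
#'
#' @param z an [expression_matrix] with modality `"zscore"`.
#' @param sig a [gene_signature].
#' @param aggregation `"median"` or `"mean"`.
#' @return an [index_vector].
#' @export
score_signature <- function(z, sig, aggregation = c("median", "mean")) {
  stopifnot(inherits(z, "expression_matrix"), inherits(sig, "gene_signature"))
  aggregation <- match.arg(aggregation)
  if (z$modality != "zscore")
    stop("score_signature expects a zscore matrix (see zscore_by_gene)")
  present <- intersect(sig$genes, z$gene_ids)
  n_missing <- length(sig$genes) - length(present)
  if (!length(present))
    stop("no gene of signature '", sig$name, "' is present in the matrix")
  if (n_missing)
    message(n_missing, " of ", length(sig$genes), " '", sig$name,
            "' genes absent from the matrix; scoring over ",
            length(present))
  sub <- as.matrix(z$values)[present, , drop = FALSE]
  scores <- if (aggregation == "mean") colMeans(sub)
            else apply(sub, 2, median)
  index_vector(z$unit_ids, scores, sig$name, aggregation,
               source_modality = attr(z, "source_modality") %||% "zscore",
               n_genes_used = length(present))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
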