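#' Expression matrix container
#'
#' A light S3 container for a genes-by-units expression matrix with a declared
#' modality and optional per-unit metadata. Genes are rows, units (cell
#' barcodes or bulk sample IDs) are columns; readers transpose as needed so
#' this orientation is fixed throughout the package.
#'
#' Modalities and their invariants:
#' \describe{
#'   \item{counts}{all values are non-negative integers (raw reads/UMIs).}
#'   \item{rp10k}{reads per 10,000: every unit with nonzero depth sums to
#'     10,000 (within 1e-6 relative).}
#'   \item{zscore}{every gene row has mean 0 and, unless constant before the
#'     transform, standard deviation 1 (sample sd, within 1e-8).}
#'   \item{log2cpm, tpm, fpkm, rsem, quantile}{externally normalized bulk or
#'     single-cell values, accepted as-is.}
#' }
#'
#' @param values numeric matrix or \pkg{Matrix} sparse matrix, genes x units.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param unit_ids character vector of unique cell/sample identifiers
#'   (columns).
#' @param modality one of `"counts"`, `"rp10k"`, `"log2cpm"`, `"tpm"`,
#'   `"fpkm"`, `"rsem"`, `"quantile"`, `"zscore"`.
#' @param unit_meta optional data.frame with one row per unit; must contain a
#'   `unit_id` column and may carry `tissue` (one of tumor/para/normal/other),
#'   `sample` and `cluster` columns.
#' @param validate logical; run full invariant checks (default `TRUE`).
#'
#' @return an object of class `expression_matrix` with elements `values`,
#'   `gene_ids`, `unit_ids`, `modality`, `unit_meta`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(0:5, nrow = 3,
#'                               dimnames = list(paste0("g", 1:3), c("c1", "c2"))),
#'                        gene_ids = paste0("g", 1:3), unit_ids = c("c1", "c2"),
#'                        modality = "counts")
#' dim(m)
expression_matrix <- function(values, gene_ids = rownames(values),
                              unit_ids = colnames(values),
                              modality, unit_meta = NULL, validate = TRUE) {
  modality <- match.arg(modality, .MODALITIES)
  if (is.null(gene_ids) || is.null(unit_ids))
    stop("gene_ids and unit_ids are required (or set dimnames on `values`)")
  gene_ids <- as.character(gene_ids)
  unit_ids <- as.character(unit_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(unit_ids))
    stop("dimensions of `values` do not match gene_ids/unit_ids")
  rownames(values) <- gene_ids
  colnames(values) <- unit_ids
  if (!is.null(unit_meta)) {
    unit_meta <- as.data.frame(unit_meta)
    if (!"unit_id" %in% names(unit_meta))
      stop("unit_meta must contain a `unit_id` column")
    missing_meta <- setdiff(unit_ids, unit_meta$unit_id)
    if (length(missing_meta))
      stop("unit_meta lacks rows for ", length(missing_meta),
           " unit(s), e.g. ", paste(head(missing_meta, 3), collapse = ", "))
    unit_meta <- unit_meta[match(unit_ids, unit_meta$unit_id), , drop = FALSE]
    rownames(unit_meta) <- NULL
  }
  obj <- structure(list(values = values, gene_ids = gene_ids,
                        unit_ids = unit_ids, modality = modality,
                        unit_meta = unit_meta),
                   class = "expression_matrix")
  if (validate) validate_expression_matrix(obj)
  obj
}

#' Validate an expression matrix against its modality invariants
#'
#' @param m an [expression_matrix].
#' @return `m`, invisibly; errors describe the first violated invariant.
#' @export
validate_expression_matrix <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (anyDuplicated(m$gene_ids))
    stop("duplicate gene_ids: ",
         paste(head(unique(m$gene_ids[duplicated(m$gene_ids)]), 3),
               collapse = ", "))
  if (anyDuplicated(m$unit_ids))
    stop("duplicate unit_ids: ",
         paste(head(unique(m$unit_ids[duplicated(m$unit_ids)]), 3),
               collapse = ", "))
  v <- m$values
  if (m$modality == "counts") {
    x <- if (inherits(v, "sparseMatrix")) v@x else as.numeric(v)
    if (length(x) && (min(x) < 0 || any(abs(x - round(x)) > 1e-9)))
      stop("counts modality requires non-negative integer values")
  } else if (m$modality == "rp10k") {
    cs <- Matrix::colSums(v)
    bad <- cs > 0 & abs(cs - 10000) > 1e-6 * 10000
    if (any(bad))
      stop("rp10k columns do not sum to 10000: ",
           paste(head(m$unit_ids[bad], 3), collapse = ", "))
  } else if (m$modality == "zscore") {
    rm_ <- Matrix::rowMeans(v)
    if (any(abs(rm_) > 1e-8))
      stop("zscore rows must have mean 0")
    n <- ncol(v)
    rsd <- sqrt(pmax(0, (Matrix::rowSums(v^2) - n * rm_^2) / (n - 1)))
    ok <- abs(rsd - 1) < 1e-6 | rsd < 1e-12  # constant-gene rows stay 0
    if (!all(ok))
      stop("zscore rows must have sd 1 (or be all-zero constant rows)")
  }
  invisible(m)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d units [%s]\n",
              length(x$gene_ids), length(x$unit_ids), x$modality))
  if (!is.null(x$unit_meta))
    cat("  unit_meta columns:", paste(names(x$unit_meta), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Dense numeric values of an expression matrix
#'
#' @param m an [expression_matrix].
#' @return base numeric matrix (genes x units).
#' @export
dense_values <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  as.matrix(m$values)
}

#' Read an expression matrix from disk
#'
#' Supports the 10x-style MatrixMarket coordinate triplet (`matrix.mtx` with
#' `genes.tsv`/`barcodes.tsv` sidecars, 1-based indices) and dense delimited
#' tables with genes in rows and a header of unit IDs.
#'
#' Duplicate gene rows are collapsed by summation for `counts` input and
#' rejected for every other modality (summing normalized values has no
#' meaning). Duplicate unit IDs are always an error.
#'
#' @param path for `format = "mtx-triplet"`, either the `.mtx` file or the
#'   directory containing `matrix.mtx`; for `format = "dense-delimited"`, the
#'   table file (TSV or CSV, sniffed from the header line).
#' @param format `"mtx-triplet"` or `"dense-delimited"`.
#' @param modality declared modality of the stored values (see
#'   [expression_matrix]).
#' @param genes_file,barcodes_file sidecar file names for the triplet format,
#'   resolved relative to the matrix directory.
#' @param unit_meta optional unit metadata data.frame passed through.
#' @return an [expression_matrix].
#' @export
read_matrix <- function(path,
                        format = c("mtx-triplet", "dense-delimited"),
                        modality,
                        genes_file = "genes.tsv",
                        barcodes_file = "barcodes.tsv",
                        unit_meta = NULL) {
  format <- match.arg(format)
  modality <- match.arg(modality, .MODALITIES)
  if (format == "mtx-triplet") {
    if (dir.exists(path)) {
      dir <- path
      mtx <- file.path(dir, "matrix.mtx")
    } else {
      dir <- dirname(path)
      mtx <- path
    }
    gf <- file.path(dir, genes_file)
    bf <- file.path(dir, barcodes_file)
    for (f in c(mtx, gf, bf))
      if (!file.exists(f)) stop("missing file: ", f)
    values <- tryCatch(Matrix::readMM(mtx), error = function(e)
      stop("malformed MatrixMarket file ", mtx, ": ", conditionMessage(e)))
    values <- methods::as(values, "CsparseMatrix")
    genes <- read.delim(gf, header = FALSE, stringsAsFactors = FALSE)
    barcodes <- read.delim(bf, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(genes) != nrow(values))
      stop("genes sidecar has ", nrow(genes), " rows but matrix has ",
           nrow(values))
    if (nrow(barcodes) != ncol(values))
      stop("barcodes sidecar has ", nrow(barcodes), " rows but matrix has ",
           ncol(values), " columns")
    gene_ids <- as.character(genes[[ncol(genes)]])  # 10x: id, symbol
    unit_ids <- as.character(barcodes[[1]])
  } else {
    header <- readLines(path, n = 1)
    sep <- if (grepl(",", header) && !grepl("\t", header)) "," else "\t"
    tab <- read.delim(path, sep = sep, header = TRUE, row.names = NULL,
                      check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2)
      stop("malformed dense table (need gene column + >=1 unit column): ",
           path)
    gene_ids <- as.character(tab[[1]])
    values <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(values))
      stop("non-numeric values in dense table ", path)
    unit_ids <- colnames(tab)[-1]
  }
  if (anyDuplicated(unit_ids))
    stop("duplicate unit IDs: ",
         paste(head(unique(unit_ids[duplicated(unit_ids)]), 3),
               collapse = ", "))
  if (anyDuplicated(gene_ids)) {
    if (modality != "counts")
      stop("duplicate gene rows (", sum(duplicated(gene_ids)),
           ") cannot be collapsed for modality '", modality,
           "'; deduplicate upstream")
    # collapse duplicated count rows by sum
    grp <- factor(gene_ids, levels = unique(gene_ids))
    values <- rowsum(as.matrix(values), grp)
    gene_ids <- levels(grp)
  }
  expression_matrix(values, gene_ids, unit_ids, modality = modality,
                    unit_meta = unit_meta)
}

#' Read a gene list file
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of gene IDs.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Read per-unit metadata
#'
#' @param path TSV file with required columns `unit_id`, `tissue`, `sample`
#'   and any optional extras (e.g. `cluster`).
#' @return data.frame.
#' @export
read_unit_meta <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "tissue", "sample")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop("unit_meta file lacks required column(s): ",
         paste(missing, collapse = ", "))
  bad <- !meta$tissue %in% .TISSUES
  if (any(bad))
    stop("unknown tissue label(s): ",
         paste(unique(meta$tissue[bad]), collapse = ", "))
  meta
}

#' Write an expression matrix to disk
#'
#' Writes either an MTX triplet (matrix.mtx + genes.tsv + barcodes.tsv) into a
#' directory, or a single dense TSV with a gene column.
#'
#' @param m an [expression_matrix].
#' @param path output directory (`"mtx-triplet"`) or file
#'   (`"dense-delimited"`).
#' @param format output format.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path,
                         format = c("mtx-triplet", "dense-delimited")) {
  stopifnot(inherits(m, "expression_matrix"))
  format <- match.arg(format)
  if (format == "mtx-triplet") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(m$values, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(paste(m$gene_ids, m$gene_ids, sep = "\t"),
               file.path(path, "genes.tsv"))
    writeLines(m$unit_ids, file.path(path, "barcodes.tsv"))
  } else {
    tab <- data.frame(gene = m$gene_ids, as.matrix(m$values),
                      check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
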