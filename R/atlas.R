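#' Construct a cell atlas
#'
#' A `CellAtlas` bundles a sparse cell-by-gene count matrix with per-cell
#' annotations. It is the shared container consumed by the scoring,
#' composition and marker modules.
#'
#' @param counts non-negative integer matrix, cells in rows and genes in
#'   columns. Coerced to a sparse `dgCMatrix`.
#' @param gene_ids character vector of gene symbols, one per column of
#'   `counts`. Duplicate symbols are collapsed by summing their counts,
#'   with a warning.
#' @param cell_meta data frame with one row per cell and at least the
#'   columns `cell_id`, `subset_label`, `compartment_label`, `cancer_type`,
#'   `tissue` (values `"tumor"` or `"normal"`), `sample_id`, `patient_id`.
#'
#' @return An object of class `CellAtlas`: a list with elements `counts`
#'   (cells x genes `dgCMatrix` with dimnames), `gene_ids` and `cell_meta`.
#' @export
CellAtlas <- function(counts, gene_ids, cell_meta) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (length(gene_ids) != ncol(counts)) {
    stop("format error: ", length(gene_ids), " gene ids for ",
         ncol(counts), " count columns", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    warning("duplicate gene symbols collapsed by sum")
    grp <- factor(gene_ids, levels = unique(gene_ids))
    agg <- Matrix::sparseMatrix(i = as.integer(grp), j = seq_along(gene_ids),
                                x = 1, dims = c(nlevels(grp), length(gene_ids)))
    counts <- counts %*% Matrix::t(agg)
    gene_ids <- levels(grp)
  }
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  atlas <- structure(list(counts = counts, gene_ids = as.character(gene_ids),
                          cell_meta = cell_meta),
                     class = "CellAtlas")
  rownames(atlas$counts) <- cell_meta$cell_id
  colnames(atlas$counts) <- atlas$gene_ids
  validate_atlas(atlas)
  atlas
}

ATLAS_META_COLS <- c("cell_id", "subset_label", "compartment_label",
                     "cancer_type", "tissue", "sample_id", "patient_id")

#' Validate the invariants of a cell atlas
#'
#' Checks matrix/metadata agreement, uniqueness of cell ids, the
#' tumor/normal tissue vocabulary, and that every sample maps to a single
#' (cancer type, tissue) pair.
#'
#' @param atlas a [CellAtlas()].
#' @return the atlas, invisibly; errors describe the first violated invariant.
#' @export
validate_atlas <- function(atlas) {
  stopifnot(inherits(atlas, "CellAtlas"))
  meta <- atlas$cell_meta
  missing_cols <- setdiff(ATLAS_META_COLS, names(meta))
  if (length(missing_cols)) {
    stop("validation error: missing metadata columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(meta) != nrow(atlas$counts)) {
    stop("format error: ", nrow(meta), " metadata rows for ",
         nrow(atlas$counts), " cells", call. = FALSE)
  }
  if (length(atlas$gene_ids) != ncol(atlas$counts)) {
    stop("format error: gene id / count column mismatch", call. = FALSE)
  }
  if (anyDuplicated(meta$cell_id)) {
    stop("validation error: duplicate cell_id: ",
         paste(utils::head(meta$cell_id[duplicated(meta$cell_id)], 5),
               collapse = ", "), call. = FALSE)
  }
  bad_tissue <- which(!meta$tissue %in% c("tumor", "normal"))
  if (length(bad_tissue)) {
    stop("validation error: tissue must be 'tumor' or 'normal'; offending rows: ",
         paste(utils::head(bad_tissue, 10), collapse = ", "), call. = FALSE)
  }
  if (any(atlas$counts@x < 0)) {
    stop("validation error: negative counts", call. = FALSE)
  }
  pair <- unique(meta[, c("sample_id", "cancer_type", "tissue")])
  if (anyDuplicated(pair$sample_id)) {
    stop("validation error: sample_id mapped to multiple (cancer_type, tissue) pairs: ",
         paste(unique(pair$sample_id[duplicated(pair$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  invisible(atlas)
}

#' @export
print.CellAtlas <- function(x, ...) {
  cat("CellAtlas:", nrow(x$counts), "cells x", ncol(x$counts), "genes\n")
  cat("  cancer types:", paste(unique(x$cell_meta$cancer_type), collapse = ", "), "\n")
  cat("  subsets:", length(unique(x$cell_meta$subset_label)),
      " compartments:", length(unique(x$cell_meta$compartment_label)), "\n")
  invisible(x)
}

#' @export
dim.CellAtlas <- function(x) dim(x$counts)

#' Read a cell atlas from Matrix Market + TSV files
#'
#' The count matrix may be stored genes x cells or cells x genes; the
#' orientation is auto-detected from the dimensions (and, when square, from
#' a `% rows:` comment in the MTX header) and the matrix is stored
#' internally as cells x genes. Cells whose metadata rows are missing a
#' required field are dropped, and the number dropped is reported via a
#' warning.
#'
#' @param matrix_path Matrix Market (`.mtx`) count file.
#' @param genes_path TSV whose first column holds gene symbols (no header).
#' @param meta_path TSV of per-cell metadata with a header row containing at
#'   least the required columns (see [CellAtlas()]).
#' @return a validated [CellAtlas()].
#' @export
load_atlas <- function(matrix_path, genes_path, meta_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.delim(genes_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  meta <- utils::read.delim(meta_path, header = TRUE,
                            stringsAsFactors = FALSE)
  missing_cols <- setdiff(ATLAS_META_COLS, names(meta))
  if (length(missing_cols)) {
    stop("format error: metadata lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_cells <- nrow(meta)
  n_genes <- length(genes)
  if (nrow(m) == n_genes && ncol(m) == n_cells && nrow(m) != ncol(m)) {
    m <- Matrix::t(m)
  } else if (nrow(m) == n_cells && ncol(m) == n_genes) {
    if (nrow(m) == ncol(m)) {
      # square matrix: fall back on the header comment to fix orientation
      hdr <- readLines(matrix_path, n = 5L)
      if (any(grepl("rows:\\s*genes", hdr, ignore.case = TRUE))) m <- Matrix::t(m)
    }
  } else {
    stop("format error: matrix is ", nrow(m), " x ", ncol(m),
         " but there are ", n_genes, " genes and ", n_cells, " cells",
         call. = FALSE)
  }
  complete <- stats::complete.cases(meta[, ATLAS_META_COLS]) &
    rowSums(meta[, ATLAS_META_COLS] == "" | is.na(meta[, ATLAS_META_COLS])) == 0
  if (any(!complete)) {
    warning(sum(!complete), " cell(s) dropped for missing required metadata")
    meta <- meta[complete, , drop = FALSE]
    m <- m[complete, , drop = FALSE]
  }
  CellAtlas(m, genes, meta)
}

#' Write a cell atlas to Matrix Market + TSV files
#'
#' Inverse of [load_atlas()]; the round trip preserves counts bit-exactly.
#'
#' @param atlas a [CellAtlas()].
#' @param dir output directory (created if needed). Files written:
#'   `counts.mtx`, `genes.tsv`, `cell_meta.tsv`.
#' @return the three file paths, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  validate_atlas(atlas)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.mtx", "genes.tsv", "cell_meta.tsv"))
  Matrix::writeMM(atlas$counts, paths[1])
  utils::write.table(data.frame(gene = atlas$gene_ids), paths[2],
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(atlas$cell_meta, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Subset an atlas to a set of cells
#'
#' @param atlas a [CellAtlas()].
#' @param cells logical, integer or character (cell id) index.
#' @return a [CellAtlas()] containing only the selected cells.
#' @export
subset_cells <- function(atlas, cells) {
  if (is.character(cells)) cells <- match(cells, atlas$cell_meta$cell_id)
  meta <- atlas$cell_meta[cells, , drop = FALSE]
  rownames(meta) <- NULL
  CellAtlas(atlas$counts[cells, , drop = FALSE], atlas$gene_ids, meta)
}

#' Library-size normalize and log-transform counts
#'
#' Counts are scaled to a common library size (counts-per-10k by default)
#' and transformed with `log1p`. All expression-level operations in the
#' package work on this scale.
#'
#' @param atlas a [CellAtlas()], or a cells x genes matrix.
#' @param scale_factor target library size, default `1e4`.
#' @return dense cells x genes matrix of log-normalized expression.
#' @export
normalize_counts <- function(atlas, scale_factor = 1e4) {
  m <- if (inherits(atlas, "CellAtlas")) atlas$counts else atlas
  libsize <- Matrix::rowSums(m)
  libsize[libsize == 0] <- 1  # all-zero cells stay all-zero
  log1p(as.matrix(m / libsize * scale_factor))
}

#' Mean log-normalized expression per group of cells (pseudobulk)
#'
#' @param atlas a [CellAtlas()].
#' @param group_keys character vector of `cell_meta` column names; cells are
#'   grouped by their combination (joined with `"."`).
#' @param min_cells groups with fewer cells are dropped (with a message).
#' @param scale_factor passed to [normalize_counts()].
#' @return groups x genes matrix of mean log-normalized expression, with an
#'   attribute `n_cells` giving the group sizes.
#' @export
pseudobulk <- function(atlas, group_keys, min_cells = 20, scale_factor = 1e4) {
  bad <- setdiff(group_keys, names(atlas$cell_meta))
  if (length(bad)) {
    stop("parameter error: unknown metadata column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  grp <- interaction(atlas$cell_meta[group_keys], drop = TRUE, sep = ".")
  sizes <- table(grp)
  keep <- names(sizes)[sizes >= min_cells]
  if (!length(keep)) {
    stop("empty-result error: all ", length(sizes),
         " group(s) have fewer than ", min_cells, " cells", call. = FALSE)
  }
  dropped <- setdiff(names(sizes), keep)
  if (length(dropped)) {
    message("pseudobulk: dropped ", length(dropped),
            " group(s) below min_cells: ", paste(dropped, collapse = ", "))
  }
  expr <- normalize_counts(atlas, scale_factor)
  prof <- t(vapply(keep, function(g) colMeans(expr[grp == g, , drop = FALSE]),
                   numeric(ncol(expr))))
  colnames(prof) <- atlas$gene_ids
  attr(prof, "n_cells") <- as.integer(sizes[keep])
  prof
}
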