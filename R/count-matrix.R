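#' Coerce to a sparse gene-by-cell count matrix
#'
#' The canonical container throughout the package is a `dgCMatrix` with genes
#' on the rows and cells (or samples) on the columns, both with identifiers in
#' `dimnames`. Dense matrices and data frames are accepted and converted.
#'
#' @param x matrix-like object (dense matrix, `dgCMatrix`, or data frame of
#'   numeric columns), genes in rows.
#' @param genes,cells optional identifier vectors; taken from `dimnames(x)`
#'   when absent and synthesised (`g1..`, `c1..`) as a last resort.
#' @return a `dgCMatrix` with complete `dimnames`.
#' @export
as_count_matrix <- function(x, genes = NULL, cells = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!inherits(x, "CsparseMatrix")) {
    x <- as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("count matrix must have at least one gene and one cell", call. = FALSE)
  }
  if (any(x@x < 0)) {
    bad <- which(x@x < 0)[1L]
    stop("count matrix contains negative entries (first at stored element ",
         bad, ")", call. = FALSE)
  }
  if (is.null(genes)) genes <- rownames(x)
  if (is.null(cells)) cells <- colnames(x)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(x)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(x)))
  if (length(genes) != nrow(x) || length(cells) != ncol(x)) {
    stop("identifier lists do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(genes)) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(cells)) stop("duplicate cell identifiers", call. = FALSE)
  dimnames(x) <- list(as.character(genes), as.character(cells))
  x
}

#' Read a count matrix from disk
#'
#' Supports the 10x-style Matrix Market layout (a directory or a `matrix.mtx`
#' / `matrix.mtx.gz` path with companion `features.tsv`/`genes.tsv` and
#' `barcodes.tsv`, possibly gzipped; 1-based triplet indices per the MTX
#' standard) and dense TSV (genes in rows, first column gene ids, header row
#' of cell ids).
#'
#' Orientation is normalised to genes x cells: when the matrix dimensions
#' match the companion files only after transposition, the matrix is
#' transposed (override with `transpose`).
#'
#' @param path directory or file path.
#' @param format `"auto"` (default), `"mtx"` or `"tsv"`.
#' @param transpose force (`TRUE`) or forbid (`FALSE`) transposition;
#'   `NA` auto-detects from the companion identifier files.
#' @return a `dgCMatrix`, genes x cells.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "tsv"), transpose = NA) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "tsv"
  }
  if (format == "mtx") read_counts_mtx(path, transpose) else read_counts_tsv(path)
}

find_companion <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c(".tsv", ".tsv.gz", ".txt", ".txt.gz")) {
      f <- file.path(dir, paste0(stem, ext))
      if (file.exists(f)) return(f)
    }
  }
  NULL
}

read_id_column <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  as.character(x[[1L]])
}

read_counts_mtx <- function(path, transpose = NA) {
  if (dir.exists(path)) {
    dir <- path
    mtx <- find_companion(dir, "matrix")
    if (is.null(mtx)) {
      mtx <- file.path(dir, "matrix.mtx")
      if (!file.exists(mtx)) mtx <- file.path(dir, "matrix.mtx.gz")
    }
  } else {
    mtx <- path
    dir <- dirname(path)
  }
  if (!file.exists(mtx)) stop("no matrix.mtx[.gz] found at ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", mtx)) gzfile(mtx) else file(mtx)
  m <- tryCatch(Matrix::readMM(con),
                error = function(e) stop("malformed Matrix Market file ", mtx,
                                         ": ", conditionMessage(e), call. = FALSE))
  m <- as(as(m, "generalMatrix"), "CsparseMatrix")
  if (any(m@x < 0)) {
    bad <- which(m@x < 0)[1L]
    stop("negative count in ", mtx, " (stored entry ", bad, ")", call. = FALSE)
  }
  genes_f <- find_companion(dir, c("features", "genes"))
  cells_f <- find_companion(dir, "barcodes")
  genes <- if (!is.null(genes_f)) read_id_column(genes_f) else NULL
  cells <- if (!is.null(cells_f)) read_id_column(cells_f) else NULL
  flip <- transpose
  if (is.na(flip)) {
    flip <- !is.null(genes) && length(genes) != nrow(m) &&
      length(genes) == ncol(m)
  }
  if (isTRUE(flip)) m <- Matrix::t(m)
  as_count_matrix(m, genes = genes, cells = cells)
}

read_counts_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at data row ", bad[1L], ", column ", bad[2L] + 1L,
         " of ", path, call. = FALSE)
  }
  as_count_matrix(m, genes = genes, cells = colnames(m))
}

#' Write a matrix as TSV with row and column headers
#'
#' Integer matrices round-trip exactly through [read_counts()]; non-integer
#' values are written at 6 significant digits.
#'
#' @param m matrix (dense or sparse) with dimnames.
#' @param path output file.
#' @param id_col name of the leading identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  if (nrow(m) == 0L || ncol(m) == 0L) stop("refusing to write an empty matrix",
                                           call. = FALSE)
  dense <- as.matrix(m)
  if (!all(dense == round(dense))) dense <- signif(dense, 6L)
  out <- tibble::as_tibble(dense, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write counts in Matrix Market triplet layout
#'
#' Emits `matrix.mtx`, `features.tsv` and `barcodes.tsv` under `dir`.
#'
#' @param m sparse genes x cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- as_count_matrix(m)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(id = rownames(m)),
                   file.path(dir, "features.tsv"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(tibble::tibble(id = colnames(m)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE,
                   progress = FALSE)
  invisible(dir)
}
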