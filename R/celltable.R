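#' Construct a cell table
#'
#' The universal input container of the package: a sparse cells-by-genes
#' matrix of raw UMI counts plus per-cell metadata. Every downstream module
#' (QC, simulation, neighborhoods, differential testing, module discovery)
#' consumes and returns this structure.
#'
#' @param counts sparse (or dense) non-negative integer matrix, cells in rows,
#'   genes in columns. Coerced to \code{dgCMatrix}.
#' @param obs data.frame of per-cell metadata with at least columns
#'   \code{cell_id} and \code{sample}. Optional columns: \code{group}
#'   (per-sample covariate, constant within sample), \code{pseudotime}
#'   (real in \[0,1\]), \code{mito_frac} (real in \[0,1\]), plus arbitrary
#'   extra covariates.
#' @param var data.frame of per-gene metadata with at least column
#'   \code{gene_id}; defaults to the column names of \code{counts}.
#'
#' @return An object of class \code{cell_table}: a list with elements
#'   \code{counts}, \code{obs}, \code{var}.
#' @export
cell_table <- function(counts, obs, var = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(var)) {
    gid <- colnames(counts)
    if (is.null(gid)) gid <- sprintf("gene%d", seq_len(ncol(counts)))
    var <- data.frame(gene_id = gid, stringsAsFactors = FALSE)
  }
  obs <- as.data.frame(obs, stringsAsFactors = FALSE)
  var <- as.data.frame(var, stringsAsFactors = FALSE)
  if (nrow(counts) == nrow(obs) && ncol(counts) == nrow(var)) {
    rownames(counts) <- obs$cell_id
    colnames(counts) <- var$gene_id
  }
  ct <- structure(list(counts = counts, obs = obs, var = var),
                  class = "cell_table")
  validate_cell_table(ct)
  ct
}

#' Validate a cell table
#'
#' Checks the structural invariants: non-negative counts, matching
#' dimensions, unique ids, one group per sample, pseudotime in \[0,1\].
#'
#' @param ct a \code{cell_table}.
#' @return \code{ct}, invisibly; errors on violation.
#' @export
validate_cell_table <- function(ct) {
  stopifnot(inherits(ct, "cell_table"))
  counts <- ct$counts; obs <- ct$obs; var <- ct$var
  if (nrow(counts) != nrow(obs))
    stop("cell_table: counts has ", nrow(counts), " rows but obs has ",
         nrow(obs), " cells")
  if (ncol(counts) != nrow(var))
    stop("cell_table: counts has ", ncol(counts), " columns but var has ",
         nrow(var), " genes")
  if (!all(c("cell_id", "sample") %in% names(obs)))
    stop("cell_table: obs must contain columns 'cell_id' and 'sample'")
  if (!"gene_id" %in% names(var))
    stop("cell_table: var must contain column 'gene_id'")
  if (anyDuplicated(obs$cell_id))
    stop("cell_table: duplicated cell ids")
  if (anyDuplicated(var$gene_id))
    stop("cell_table: duplicated gene ids")
  x <- ct$counts@x
  if (length(x) && min(x) < 0)
    stop("cell_table: counts contains negative entries")
  if (length(x) && any(x != floor(x)))
    stop("cell_table: counts contains non-integer entries")
  if ("group" %in% names(obs)) {
    per_sample <- tapply(as.character(obs$group), obs$sample,
                         function(g) length(unique(g)))
    if (any(per_sample > 1))
      stop("cell_table: sample(s) ",
           paste(names(per_sample)[per_sample > 1], collapse = ", "),
           " map to more than one group")
  }
  if ("pseudotime" %in% names(obs)) {
    pt <- obs$pseudotime
    if (any(!is.na(pt) & (pt < 0 | pt > 1)))
      stop("cell_table: pseudotime outside [0,1]")
  }
  invisible(ct)
}

#' @export
print.cell_table <- function(x, ...) {
  cat("cell_table: ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes\n", sep = "")
  cat("  samples: ", paste(levels(factor(x$obs$sample)), collapse = ", "),
      "\n", sep = "")
  if ("group" %in% names(x$obs))
    cat("  groups:  ", paste(levels(factor(x$obs$group)), collapse = ", "),
        "\n", sep = "")
  if ("pseudotime" %in% names(x$obs))
    cat("  pseudotime: [", round(min(x$obs$pseudotime), 3), ", ",
        round(max(x$obs$pseudotime), 3), "]\n", sep = "")
  invisible(x)
}

#' Number of cells / genes in a cell table
#' @param ct a \code{cell_table}.
#' @return integer.
#' @export
n_cells <- function(ct) nrow(ct$counts)

#' @rdname n_cells
#' @export
n_genes <- function(ct) ncol(ct$counts)

#' Subset a cell table
#'
#' @param ct a \code{cell_table}.
#' @param cells logical/integer/character index over cells (optional).
#' @param genes logical/integer/character index over genes (optional).
#' @return a \code{cell_table}.
#' @export
subset_cells <- function(ct, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_len(n_cells(ct))
  if (is.null(genes)) genes <- seq_len(n_genes(ct))
  if (is.character(cells)) cells <- match(cells, ct$obs$cell_id)
  if (is.character(genes)) genes <- match(genes, ct$var$gene_id)
  cell_table(ct$counts[cells, genes, drop = FALSE],
             ct$obs[cells, , drop = FALSE],
             ct$var[genes, , drop = FALSE])
}

#' Stable sample order of a cell table
#'
#' Samples in order of first appearance in \code{obs}; this is the column
#' order used by all neighborhood count matrices.
#' @param ct a \code{cell_table}.
#' @return character vector of sample ids.
#' @export
sample_order <- function(ct) unique(as.character(ct$obs$sample))

#' Per-sample group labels
#'
#' @param ct a \code{cell_table} with a \code{group} column.
#' @return factor of group labels, one per sample, in \code{sample_order}.
#' @export
sample_groups <- function(ct) {
  if (!"group" %in% names(ct$obs)) stop("cell_table has no 'group' column")
  so <- sample_order(ct)
  g <- ct$obs$group[match(so, as.character(ct$obs$sample))]
  factor(g, levels = unique(as.character(ct$obs$group)))
}

#' Mitochondrial fraction from gene-name prefix
#'
#' Helper computing the per-cell fraction of counts on genes whose id matches
#' a prefix (default the conventional mitochondrial prefixes).
#'
#' @param ct a \code{cell_table}.
#' @param prefix regular expression matched against gene ids.
#' @return numeric vector in \[0,1\], one entry per cell.
#' @export
mito_frac_from_prefix <- function(ct, prefix = "^(MT-|mt-)") {
  mt <- grepl(prefix, ct$var$gene_id)
  tot <- Matrix::rowSums(ct$counts)
  mtc <- if (any(mt)) Matrix::rowSums(ct$counts[, mt, drop = FALSE]) else 0
  out <- rep(0, n_cells(ct))
  nz <- tot > 0
  out[nz] <- mtc[nz] / tot[nz]
  out
}

#' Read a cell table from a Matrix Market triple
#'
#' Reads the standard on-disk trio: an integer coordinate \code{.mtx} counts
#' matrix, a \code{cells.tsv} with per-cell metadata (header:
#' \code{cell_id}, \code{sample}, optional \code{group}, \code{pseudotime},
#' \code{mito_frac}, extra covariates) and a \code{genes.tsv} (header:
#' \code{gene_id}). Matrix orientation (cells-by-genes vs genes-by-cells) is
#' auto-detected from the metadata row counts; transposition is reported via
#' a message.
#'
#' @param counts_path path to the \code{.mtx} file.
#' @param cells_path path to the cell metadata TSV.
#' @param genes_path path to the gene metadata TSV.
#' @return a validated \code{cell_table}.
#' @export
read_cell_table <- function(counts_path, cells_path, genes_path) {
  for (p in c(counts_path, cells_path, genes_path))
    if (!file.exists(p)) stop("read_cell_table: file not found: ", p)
  m <- Matrix::readMM(counts_path)
  obs <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  var <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
  nc <- nrow(obs); ng <- nrow(var)
  if (nrow(m) == nc && ncol(m) == ng) {
    # cells x genes, nothing to do
  } else if (nrow(m) == ng && ncol(m) == nc && nc != ng) {
    message("read_cell_table: matrix stored genes x cells; transposing")
    m <- Matrix::t(m)
  } else if (nrow(m) != nc || ncol(m) != ng) {
    stop("read_cell_table: dimension mismatch: matrix ", nrow(m), "x",
         ncol(m), " in '", counts_path, "' vs ", nc, " cells in '",
         cells_path, "' and ", ng, " genes in '", genes_path, "'")
  }
  x <- m@x
  if (length(x) && (min(x) < 0 || any(x != floor(x))))
    stop("read_cell_table: '", counts_path,
         "' contains negative or non-integer entries")
  cell_table(m, obs, var)
}

#' Write a cell table as a Matrix Market triple
#'
#' Inverse of \code{\link{read_cell_table}}; round-trips counts exactly
#' (integer coordinate format).
#'
#' @param ct a \code{cell_table}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix, default \code{""}.
#' @return invisibly, the three paths written.
#' @export
write_cell_table <- function(ct, dir, prefix = "") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_counts <- file.path(dir, paste0(prefix, "counts.mtx"))
  p_cells <- file.path(dir, paste0(prefix, "cells.tsv"))
  p_genes <- file.path(dir, paste0(prefix, "genes.tsv"))
  Matrix::writeMM(ct$counts, p_counts)
  utils::write.table(ct$obs, p_cells, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ct$var, p_genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts = p_counts, cells = p_cells, genes = p_genes))
}
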