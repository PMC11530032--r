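#' Quality-control filtering of cells and genes
#'
#' First-round QC: cells failing any of the three cell rules are removed
#' first (fewer than \code{min_features} detected genes, fewer than
#' \code{min_counts} total counts, mitochondrial fraction above
#' \code{max_mito}); genes detected in fewer than \code{min_cells_per_gene}
#' of the surviving cells are then removed. The returned report itemizes
#' removals per rule. Idempotent: a second application removes nothing.
#'
#' @param ct a \code{cell_table}. The mitochondrial rule uses the
#'   \code{mito_frac} obs column when present, otherwise
#'   \code{\link{mito_frac_from_prefix}}.
#' @param min_features minimum number of detected genes per cell.
#' @param min_counts minimum total counts per cell.
#' @param max_mito maximum mitochondrial count fraction (strict inequality
#'   keeps a cell: removed iff \code{mito_frac > max_mito}).
#' @param min_cells_per_gene minimum surviving cells a gene must be
#'   detected in.
#' @return list with elements \code{ct} (the filtered \code{cell_table}) and
#'   \code{report} (a \code{qc_report}).
#' @export
qc_filter <- function(ct, min_features = 300, min_counts = 800,
                      max_mito = 0.20, min_cells_per_gene = 3) {
  validate_cell_table(ct)
  counts <- ct$counts
  n_feat <- Matrix::rowSums(counts > 0)
  n_tot <- Matrix::rowSums(counts)
  mito <- if ("mito_frac" %in% names(ct$obs)) ct$obs$mito_frac
          else mito_frac_from_prefix(ct)
  fail_feat <- n_feat < min_features
  fail_count <- n_tot < min_counts
  fail_mito <- mito > max_mito
  keep_cell <- !(fail_feat | fail_count | fail_mito)
  if (!any(keep_cell))
    stop("qc_filter: all ", n_cells(ct), " cells removed; ",
         "thresholds too strict for this table")
  surv <- counts[keep_cell, , drop = FALSE]
  det <- Matrix::colSums(surv > 0)
  keep_gene <- det >= min_cells_per_gene
  report <- structure(list(
    n_cells_in = n_cells(ct),
    n_cells_out = sum(keep_cell),
    n_genes_in = n_genes(ct),
    n_genes_out = sum(keep_gene),
    removed = c(low_features = sum(fail_feat),
                low_counts = sum(fail_count),
                high_mito = sum(fail_mito),
                cells_any_rule = sum(!keep_cell),
                low_detection_genes = sum(!keep_gene)),
    params = c(min_features = min_features, min_counts = min_counts,
               max_mito = max_mito, min_cells_per_gene = min_cells_per_gene)
  ), class = "qc_report")
  list(ct = subset_cells(ct, keep_cell, keep_gene), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report: ", x$n_cells_in, " -> ", x$n_cells_out, " cells, ",
      x$n_genes_in, " -> ", x$n_genes_out, " genes\n", sep = "")
  cat("  cells failing feature rule: ", x$removed["low_features"], "\n",
      "  cells failing count rule:   ", x$removed["low_counts"], "\n",
      "  cells failing mito rule:    ", x$removed["high_mito"], "\n",
      "  cells removed (any rule):   ", x$removed["cells_any_rule"], "\n",
      "  genes under detection floor:", x$removed["low_detection_genes"],
      "\n", sep = "")
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a \code{qc_report}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(metric = c("n_cells_in", "n_cells_out", "n_genes_in",
                              "n_genes_out", names(report$removed)),
                   value = c(report$n_cells_in, report$n_cells_out,
                             report$n_genes_in, report$n_genes_out,
                             unname(report$removed)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
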