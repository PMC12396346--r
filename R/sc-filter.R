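#' Filter cells by number of detected genes
#'
#' Cells with few detected genes are dropped. The cutoff is
#' platform-dependent: plate-based smart-seq2 libraries are deeper, so their
#' minimum is 2000 detected genes; droplet/UMI libraries use 1000. The
#' boundary is inclusive (a cell exactly at the cutoff is retained); cell
#' order is preserved.
#'
#' @param m an `ExpressionMatrix` with unit counts, cpm or tpm (pre-log).
#' @param cutoff_smartseq2,cutoff_umi minimum detected genes per platform.
#' @return the filtered `ExpressionMatrix`.
#' @seealso [filter_genes()]
#' @export
filter_cells <- function(m, cutoff_smartseq2 = 2000, cutoff_umi = 1000) {
  assert_that(inherits(m, "ExpressionMatrix"), "m must be an ExpressionMatrix")
  assert_that(m$unit %in% c("counts", "cpm", "tpm"),
              "filter_cells expects pre-log units (counts/cpm/tpm), got '",
              m$unit, "'")
  det <- detected_genes(m)
  platform <- unname(m$platform_of_sample[m$sample_of_cell])
  cutoff <- ifelse(platform == "smartseq2", cutoff_smartseq2, cutoff_umi)
  keep <- det >= cutoff
  if (!any(keep)) abort("all cells filtered out by the detected-genes cutoff")
  subset_matrix(m, cells = keep)
}

#' Keep the k genes of highest mean expression
#'
#' Ranks genes by mean expression across all retained cells and keeps the
#' top `k` (default 7000). When fewer than `k` genes exist the matrix is
#' returned unchanged. Ties at the boundary are broken by gene-id
#' lexicographic order so the result is deterministic. Gene order in the
#' output follows the input matrix.
#'
#' @param m an `ExpressionMatrix`.
#' @param k number of genes to keep.
#' @return the filtered `ExpressionMatrix`.
#' @export
filter_genes <- function(m, k = 7000) {
  assert_that(inherits(m, "ExpressionMatrix"), "m must be an ExpressionMatrix")
  assert_that(is_count(k), "k must be a positive integer")
  if (nrow(m$values) <= k) return(m)
  mu <- rowMeans(m$values)
  # order by decreasing mean, lexicographic gene id as tie-break
  ord <- order(-mu, rownames(m$values), method = "radix")
  keep_ids <- rownames(m$values)[ord[seq_len(k)]]
  keep <- sort(match(keep_ids, rownames(m$values)))
  subset_matrix(m, genes = keep)
}
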