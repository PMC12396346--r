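#' Gene-by-cell expression matrix with sample annotations
#'
#' The central container of the single-cell module: a dense gene x cell
#' matrix of non-negative expression values plus the per-cell annotations
#' every downstream operation needs (sample of origin, sequencing platform
#' of that sample, malignancy call). The unit tag records where the matrix
#' sits in the normalization pipeline and is checked by each operation.
#'
#' @param values numeric gene x cell matrix, non-negative; rownames are gene
#'   ids, colnames are cell ids (both unique).
#' @param sample_of_cell character vector, one sample label per cell.
#' @param platform_of_sample named character vector mapping each sample label
#'   to its platform, `"smartseq2"` or `"umi"`. Platform decides the
#'   detected-genes cutoff in [filter_cells()].
#' @param malignant logical per cell; used by [pseudo_bulk()]. Defaults to
#'   all `TRUE`.
#' @param unit one of `"counts"`, `"cpm"`, `"tpm"`, `"lognorm"`.
#' @param centered logical; `TRUE` once [center_within_sample()] has run.
#'
#' @return An object of class `ExpressionMatrix` (a list with elements
#'   `values`, `sample_of_cell`, `platform_of_sample`, `malignant`, `unit`,
#'   `centered`).
#' @examples
#' m <- expression_matrix(
#'   matrix(rpois(20, 5), 4, 5,
#'          dimnames = list(paste0("g", 1:4), paste0("c", 1:5))),
#'   sample_of_cell = rep(c("s1", "s2"), c(3, 2)),
#'   platform_of_sample = c(s1 = "umi", s2 = "umi"))
#' n_cells(m)
#' @export
expression_matrix <- function(values, sample_of_cell,
                              platform_of_sample,
                              malignant = rep(TRUE, ncol(values)),
                              unit = "counts",
                              centered = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(!anyNA(values) && all(values >= 0) || identical(centered, TRUE),
              "expression values must be non-negative and non-missing")
  assert_that(!is.null(rownames(values)) && !anyDuplicated(rownames(values)),
              "values must have unique rownames (gene ids)")
  assert_that(!is.null(colnames(values)) && !anyDuplicated(colnames(values)),
              "values must have unique colnames (cell ids)")
  assert_that(length(sample_of_cell) == ncol(values),
              "sample_of_cell must have one entry per cell")
  sample_of_cell <- as.character(sample_of_cell)
  assert_that(unit %in% c("counts", "cpm", "tpm", "lognorm"),
              "unit must be one of counts/cpm/tpm/lognorm")
  samples <- unique(sample_of_cell)
  assert_that(all(samples %in% names(platform_of_sample)),
              "every cell's sample needs an entry in platform_of_sample")
  platform_of_sample <- platform_of_sample[samples]
  assert_that(all(platform_of_sample %in% c("smartseq2", "umi")),
              "platforms must be 'smartseq2' or 'umi'")
  assert_that(is.logical(malignant) && length(malignant) == ncol(values) &&
                !anyNA(malignant),
              "malignant must be logical, one entry per cell")
  structure(
    list(values = values,
         sample_of_cell = sample_of_cell,
         platform_of_sample = platform_of_sample,
         malignant = malignant,
         unit = unit,
         centered = isTRUE(centered)),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d cells, %d sample(s), unit '%s'%s\n",
    nrow(x$values), ncol(x$values), length(x$platform_of_sample),
    x$unit, if (x$centered) " (centered)" else ""))
  invisible(x)
}

#' @rdname expression_matrix
#' @param m an `ExpressionMatrix`.
#' @export
n_cells <- function(m) ncol(m$values)

#' @rdname expression_matrix
#' @export
n_genes <- function(m) nrow(m$values)

#' @rdname expression_matrix
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname expression_matrix
#' @export
cell_ids <- function(m) colnames(m$values)

# subset keeping annotations consistent; `cells`/`genes` are indices,
# names, or logical masks
subset_matrix <- function(m, genes = NULL, cells = NULL) {
  v <- m$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  keep_cells <- if (is.null(cells)) seq_len(ncol(v)) else cells
  if (is.character(keep_cells)) keep_cells <- match(keep_cells, colnames(v))
  if (is.logical(keep_cells)) keep_cells <- which(keep_cells)
  v <- v[, keep_cells, drop = FALSE]
  expression_matrix(
    v,
    sample_of_cell = m$sample_of_cell[keep_cells],
    platform_of_sample = m$platform_of_sample,
    malignant = m$malignant[keep_cells],
    unit = m$unit, centered = m$centered)
}

#' Number of detected genes per cell
#'
#' A gene is "detected" in a cell when its expression entry is strictly
#' positive. This is the quantity thresholded by [filter_cells()].
#'
#' @param m an `ExpressionMatrix` with unit counts/cpm/tpm.
#' @return integer vector, one entry per cell.
#' @export
detected_genes <- function(m) {
  colSums(m$values > 0)
}
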