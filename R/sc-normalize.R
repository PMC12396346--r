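#' Log-normalize expression values
#'
#' Counts are first scaled per cell to counts-per-million (CPM); CPM or TPM
#' input is taken as-is. Every entry v then becomes `log2(v/10 + 1)`. The
#' division by 10 reflects the convention that true per-cell complexity is
#' closer to 100,000 than the nominal one million implied by C/TPM, so the
#' pseudocount is applied on that scale. The transform is strictly monotone
#' per entry and maps 0 to 0.
#'
#' @param m an `ExpressionMatrix` with unit counts, cpm or tpm.
#' @return an `ExpressionMatrix` with unit `"lognorm"`.
#' @export
normalize_log <- function(m) {
  assert_that(inherits(m, "ExpressionMatrix"), "m must be an ExpressionMatrix")
  assert_that(m$unit %in% c("counts", "cpm", "tpm"),
              "normalize_log expects counts/cpm/tpm, got '", m$unit, "'")
  v <- m$values
  if (m$unit == "counts") {
    tot <- colSums(v)
    if (any(tot == 0)) {
      abort("cell(s) with zero total counts: ",
            paste(colnames(v)[tot == 0], collapse = ", "))
    }
    v <- sweep(v, 2, tot / 1e6, "/")
  }
  out <- m
  out$values <- log2(v / 10 + 1)
  out$unit <- "lognorm"
  out$centered <- FALSE
  out
}

#' Center expression within each sample
#'
#' For each sample independently, subtracts each gene's mean expression
#' across that sample's cells, so every per-sample per-gene mean becomes 0.
#' Operates on log-normalized values; idempotent. Samples with a single
#' cell are allowed (they center to exactly zero) but trigger a warning.
#'
#' @param m an `ExpressionMatrix` with unit `"lognorm"`.
#' @return a centered `ExpressionMatrix` (the `centered` flag set).
#' @export
center_within_sample <- function(m) {
  assert_that(inherits(m, "ExpressionMatrix"), "m must be an ExpressionMatrix")
  assert_that(m$unit == "lognorm",
              "center_within_sample expects lognorm values, got '", m$unit, "'")
  v <- m$values
  for (s in unique(m$sample_of_cell)) {
    idx <- which(m$sample_of_cell == s)
    if (length(idx) == 1L) {
      warning("sample '", s, "' has a single cell; it centers to zero")
    }
    v[, idx] <- v[, idx, drop = FALSE] - rowMeans(v[, idx, drop = FALSE])
  }
  out <- m
  out$values <- v
  out$centered <- TRUE
  out
}

#' Pseudo-bulk expression per sample
#'
#' Averages pre-log expression across the malignant cells of each sample,
#' then applies the same log transform as [normalize_log()]
#' (`log2(mean/10 + 1)`); no centering. Counts input is converted to CPM
#' per cell before averaging. Samples without malignant cells are dropped
#' with a warning.
#'
#' @param m an `ExpressionMatrix` with unit counts/cpm/tpm and malignancy
#'   flags.
#' @return a sample x gene numeric matrix of log-scale pseudo-bulk values.
#' @export
pseudo_bulk <- function(m) {
  assert_that(inherits(m, "ExpressionMatrix"), "m must be an ExpressionMatrix")
  assert_that(m$unit %in% c("counts", "cpm", "tpm"),
              "pseudo_bulk expects pre-log units, got '", m$unit, "'")
  if (!any(m$malignant)) abort("no malignant cells in the matrix")
  v <- m$values
  if (m$unit == "counts") {
    tot <- colSums(v)
    if (any(tot == 0)) {
      abort("cell(s) with zero total counts: ",
            paste(colnames(v)[tot == 0], collapse = ", "))
    }
    v <- sweep(v, 2, tot / 1e6, "/")
  }
  samples <- unique(m$sample_of_cell)
  rows <- lapply(samples, function(s) {
    idx <- which(m$sample_of_cell == s & m$malignant)
    if (length(idx) == 0L) return(NULL)
    rowMeans(v[, idx, drop = FALSE])
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) {
    warning("dropping sample(s) with no malignant cells: ",
            paste(samples[empty], collapse = ", "))
  }
  pb <- do.call(rbind, rows[!empty])
  rownames(pb) <- samples[!empty]
  log2(pb / 10 + 1)
}
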