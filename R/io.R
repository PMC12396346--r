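#' Read an expression matrix from MTX or dense TSV plus metadata
#'
#' MTX input follows the 10x-style triplet layout: `matrix.mtx` with
#' `genes.tsv` (gene ids) and `barcodes.tsv` (cell ids) alongside. Dense
#' TSV input is genes x cells with gene ids in the first column and cell
#' ids in the header. Cell metadata is a TSV with columns `cell_id`,
#' `sample`, `platform` and optionally `malignant` (and extra columns,
#' ignored).
#'
#' @param path path to `matrix.mtx` or to the dense TSV.
#' @param meta path to the cell metadata TSV.
#' @param unit unit tag of the stored values.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, meta, unit = "counts") {
  if (grepl("\\.mtx$", path)) {
    v <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    genes <- read.table(file.path(dir, "genes.tsv"), sep = "\t",
                        stringsAsFactors = FALSE)[, 1]
    cells <- read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                        stringsAsFactors = FALSE)[, 1]
    dimnames(v) <- list(genes, cells)
  } else {
    df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                     check.names = FALSE)
    v <- as.matrix(df)
  }
  md <- read.table(meta, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  assert_that(all(c("cell_id", "sample", "platform") %in% names(md)),
              "metadata needs cell_id, sample, platform columns")
  md <- md[match(colnames(v), md$cell_id), ]
  assert_that(!anyNA(md$cell_id), "metadata is missing cells of the matrix")
  platform <- md$platform[!duplicated(md$sample)]
  names(platform) <- md$sample[!duplicated(md$sample)]
  malignant <- if ("malignant" %in% names(md)) as.logical(md$malignant)
               else rep(TRUE, ncol(v))
  expression_matrix(v, sample_of_cell = md$sample,
                    platform_of_sample = platform,
                    malignant = malignant, unit = unit)
}

#' Write an expression matrix as an MTX triplet plus cell metadata
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `cells.tsv`
#' (cell_id, sample, platform, malignant, plus any extra per-cell columns
#' supplied) into `dir`.
#'
#' @param m an [expression_matrix()].
#' @param dir output directory (created if missing).
#' @param extra optional `data.frame` of extra per-cell columns (e.g. the
#'   simulator's `true_state`).
#' @return `dir`, invisibly.
#' @export
write_expression <- function(m, dir, extra = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$values), file.path(dir, "genes.tsv"))
  writeLines(colnames(m$values), file.path(dir, "barcodes.tsv"))
  md <- data.frame(cell_id = colnames(m$values),
                   sample = m$sample_of_cell,
                   platform = unname(m$platform_of_sample[m$sample_of_cell]),
                   malignant = m$malignant, stringsAsFactors = FALSE)
  if (!is.null(extra)) md <- cbind(md, extra)
  write.table(md, file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read or write gene signatures in GMT format
#'
#' GMT is one signature per line: name, description, then tab-separated
#' gene ids. `read_gmt` de-duplicates each list and errors on signatures
#' that are empty after de-duplication.
#'
#' @param path file path.
#' @return `read_gmt`: named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  empty <- vapply(out, length, integer(1)) == 0
  if (any(empty)) {
    abort("empty signature(s) after de-duplication: ",
          paste(names(out)[empty], collapse = ", "))
  }
  out
}

#' @rdname read_gmt
#' @param signatures named list of gene-id vectors.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(names(signatures), function(nm) {
    paste(c(nm, "dmgquant", unique(signatures[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a photometry trace CSV
#'
#' The CSV has columns `time_s` and `F` (extra columns are kept as
#' attributes by `read_trace_csv` when named `F_405` or `stim`).
#'
#' @param path file path.
#' @param ... passed to [photometry_trace()] (e.g. `baseline_window`).
#' @return `read_trace_csv`: a [photometry_trace()].
#' @export
read_trace_csv <- function(path, ...) {
  df <- read.csv(path)
  assert_that(all(c("time_s", "F") %in% names(df)),
              "trace CSV needs time_s and F columns")
  photometry_trace(df$time_s, df$F, ...)
}

#' @rdname read_trace_csv
#' @param trace a [photometry_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(time_s = trace$t, F = trace$F), path,
            row.names = FALSE)
  invisible(path)
}

#' Read or write a puncta coordinate CSV
#'
#' Columns: `channel`, `x_um`, `y_um`, `z_um`. Reading returns one
#' [puncta_set()] per channel.
#'
#' @param path file path.
#' @return `read_puncta_csv`: named list of `PunctaSet`s.
#' @export
read_puncta_csv <- function(path) {
  df <- read.csv(path)
  assert_that(all(c("channel", "x_um", "y_um", "z_um") %in% names(df)),
              "puncta CSV needs channel, x_um, y_um, z_um columns")
  lapply(split(df, df$channel), function(sub) {
    puncta_set(as.matrix(sub[, c("x_um", "y_um", "z_um")]),
               channel = sub$channel[1])
  })
}

#' @rdname read_puncta_csv
#' @param sets list of [puncta_set()]s.
#' @export
write_puncta_csv <- function(sets, path) {
  rows <- lapply(sets, function(ps) {
    if (nrow(ps$coords) == 0) return(NULL)
    data.frame(channel = ps$channel, ps$coords, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
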