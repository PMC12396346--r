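#' Within-sample correlation of gene expression with a cell score
#'
#' For each gene, computes the correlation between the per-cell score
#' (e.g. the OPC signature score) and the gene's expression values within
#' each sample, then averages the per-sample correlation coefficients
#' arithmetically across samples (no Fisher transform). Samples with fewer
#' than `min_cells` cells are excluded; samples where either variable has
#' zero variance are skipped with a warning. A gene whose correlation could
#' be computed in no sample gets `NA` and is flagged.
#'
#' @param m an `ExpressionMatrix`; typically centered log-normalized
#'   values, but any unit is accepted (Pearson r is location/scale
#'   invariant so centering does not change it).
#' @param scores numeric per-cell score vector aligned with the matrix
#'   cells (names checked when present).
#' @param genes gene ids to screen; default all matrix genes.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_cells minimum cells for a sample to enter (default 3).
#' @return `data.frame` with columns `gene`, `mean_r`, `n_samples`,
#'   `all_skipped`.
#' @export
correlate_within_samples <- function(m, scores, genes = gene_ids(m),
                                     method = c("pearson", "spearman"),
                                     min_cells = 3) {
  assert_that(inherits(m, "ExpressionMatrix"), "m must be an ExpressionMatrix")
  method <- match.arg(method)
  assert_that(length(scores) == ncol(m$values),
              "scores must have one entry per cell")
  if (!is.null(names(scores))) {
    assert_that(identical(names(scores), colnames(m$values)),
                "score names do not match matrix cells")
  }
  missing <- setdiff(genes, rownames(m$values))
  if (length(missing) > 0) {
    abort("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  samples <- unique(m$sample_of_cell)
  keep <- samples[vapply(samples, function(s)
    sum(m$sample_of_cell == s) >= min_cells, logical(1))]
  if (length(keep) == 0L) abort("no sample has >= ", min_cells, " cells")
  r_mat <- matrix(NA_real_, length(genes), length(keep),
                  dimnames = list(genes, keep))
  for (s in keep) {
    idx <- which(m$sample_of_cell == s)
    sc <- scores[idx]
    if (sd(sc) == 0) {
      warning("sample '", s, "' skipped: zero score variance")
      next
    }
    expr <- m$values[genes, idx, drop = FALSE]
    v <- apply(expr, 1, sd)
    if (any(v == 0)) {
      warning("sample '", s, "' skipped for ", sum(v == 0),
              " zero-variance gene(s)")
    }
    ok <- v > 0
    if (any(ok)) {
      r_mat[ok, s] <- cor(t(expr[ok, , drop = FALSE]), sc, method = method)[, 1]
    }
  }
  mean_r <- rowMeans(r_mat, na.rm = TRUE)
  n_used <- rowSums(!is.na(r_mat))
  mean_r[n_used == 0] <- NA_real_
  data.frame(gene = genes, mean_r = unname(mean_r),
             n_samples = unname(n_used),
             all_skipped = unname(n_used == 0),
             stringsAsFactors = FALSE)
}

#' Across-sample pseudo-bulk correlation per study
#'
#' For each gene, correlates the pseudo-bulk sample scores with the
#' pseudo-bulk gene expression levels across the samples of each study,
#' then averages the per-study coefficients across studies. Studies with
#' fewer than `min_samples` samples are skipped with a warning.
#'
#' @param pb sample x gene matrix from [pseudo_bulk()].
#' @param sample_scores numeric per-sample score, aligned with `rownames(pb)`.
#' @param study_of_sample character per-sample study label; default one
#'   study.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_samples minimum samples per included study (default 3).
#' @return `data.frame` with columns `gene`, `mean_r`, `n_studies`,
#'   `all_skipped`.
#' @export
correlate_across_samples <- function(pb, sample_scores,
                                     study_of_sample = rep("study1", nrow(pb)),
                                     method = c("pearson", "spearman"),
                                     min_samples = 3) {
  method <- match.arg(method)
  assert_that(is.matrix(pb), "pb must be a sample x gene matrix")
  assert_that(length(sample_scores) == nrow(pb),
              "sample_scores must have one entry per sample (pb row)")
  assert_that(length(study_of_sample) == nrow(pb),
              "study_of_sample must have one entry per sample")
  studies <- unique(study_of_sample)
  genes <- colnames(pb)
  r_mat <- matrix(NA_real_, length(genes), length(studies),
                  dimnames = list(genes, studies))
  for (st in studies) {
    idx <- which(study_of_sample == st)
    if (length(idx) < min_samples) {
      warning("study '", st, "' skipped: fewer than ", min_samples, " samples")
      next
    }
    sc <- sample_scores[idx]
    if (sd(sc) == 0) {
      warning("study '", st, "' skipped: zero score variance")
      next
    }
    sub <- pb[idx, , drop = FALSE]
    v <- apply(sub, 2, sd)
    ok <- v > 0
    if (any(ok)) {
      r_mat[ok, st] <- cor(sub[, ok, drop = FALSE], sc, method = method)[, 1]
    }
  }
  mean_r <- rowMeans(r_mat, na.rm = TRUE)
  n_used <- rowSums(!is.na(r_mat))
  mean_r[n_used == 0] <- NA_real_
  data.frame(gene = genes, mean_r = unname(mean_r),
             n_studies = unname(n_used),
             all_skipped = unname(n_used == 0),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment: p-values are sorted
#' decreasingly, each is multiplied by n/rank, and a running minimum
#' (capped at 1) enforces monotonicity. Significance flags are
#' `q < alpha`.
#'
#' @param p numeric p-values in \[0, 1\] (NA passed through).
#' @param alpha significance level for the flags (default 0.05).
#' @return `data.frame` with columns `p`, `q`, `significant`.
#' @export
fdr_adjust <- function(p, alpha = 0.05) {
  assert_that(is.numeric(p), "p must be numeric")
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  n <- length(ok)
  if (n > 0) {
    ord <- order(p[ok], decreasing = TRUE)  # step-up from the largest p
    scaled <- p[ok][ord] * n / seq(n, 1)
    q[ok][ord] <- pmin(1, cummin(scaled))
  }
  data.frame(p = p, q = q, significant = !is.na(q) & q < alpha)
}
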