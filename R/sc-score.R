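#' Signature score with bin-matched control genes
#'
#' Scores each cell for a gene set on centered log-normalized expression.
#' The raw score is the mean centered expression over the signature genes;
#' from it, the mean over a control-gene set is subtracted to cancel
#' cell-complexity effects. Control genes are drawn per signature gene from
#' an expression bin: all genes are ranked by mean expression and split
#' into `n_bins` equal-size bins, and `n_ctrl` genes (seeded, without
#' replacement where the bin allows) are sampled from the bin containing
#' each signature gene. `n_ctrl = 0` disables the control subtraction,
#' which is the sensible setting for tiny matrices where bins would be
#' nearly empty.
#'
#' Scoring is performed per sample: each sample is centered independently
#' and its own gene means define the bins, so scores are comparable within
#' but not across samples. The RNG is re-seeded identically for every
#' sample, so duplicated samples receive identical scores.
#'
#' @param m an `ExpressionMatrix` with unit `"lognorm"`. Must be uncentered
#'   when `n_ctrl > 0` (binning needs pre-centering means); an
#'   already-centered matrix is accepted when `n_ctrl = 0`.
#' @param genes character vector of signature gene ids; must intersect the
#'   matrix genes.
#' @param n_bins number of expression bins (default 30).
#' @param n_ctrl control genes sampled per signature gene (default 100).
#' @param seed integer seed for control-gene sampling.
#' @return numeric vector of per-cell scores, named by cell id.
#' @export
signature_score <- function(m, genes, n_bins = 30, n_ctrl = 100, seed = 1L) {
  assert_that(inherits(m, "ExpressionMatrix"), "m must be an ExpressionMatrix")
  assert_that(m$unit == "lognorm",
              "signature_score expects lognorm values, got '", m$unit, "'")
  assert_that(is_count(n_bins), "n_bins must be a positive integer")
  assert_that(is_number(n_ctrl) && n_ctrl >= 0, "n_ctrl must be >= 0")
  if (m$centered && n_ctrl > 0) {
    abort("control-gene binning needs an uncentered lognorm matrix; ",
          "pass the matrix before center_within_sample() or set n_ctrl = 0")
  }
  genes <- unique(as.character(genes))
  sig <- intersect(genes, rownames(m$values))
  if (length(sig) == 0L) {
    abort("no signature genes found in the matrix; missing: ",
          paste(genes, collapse = ", "))
  }
  score <- numeric(ncol(m$values))
  names(score) <- colnames(m$values)
  for (s in unique(m$sample_of_cell)) {
    idx <- which(m$sample_of_cell == s)
    sub <- m$values[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    centered <- if (m$centered) sub else sub - mu
    raw <- colMeans(centered[sig, , drop = FALSE])
    if (n_ctrl > 0) {
      bin <- expression_bins(mu, n_bins)
      ctrl <- with_seed(seed, {
        unlist(lapply(sig, function(g) {
          pool <- setdiff(names(bin)[bin == bin[[g]]], sig)
          if (length(pool) == 0L) return(character(0))
          sample_safe(sort(pool), min(n_ctrl, length(pool)))
        }), use.names = FALSE)
      })
      if (length(ctrl) > 0) {
        raw <- raw - colMeans(centered[ctrl, , drop = FALSE])
      }
    }
    score[idx] <- raw
  }
  score
}

# equal-size expression bins by rank of mean expression; ties broken by
# gene id for determinism
expression_bins <- function(mu, n_bins) {
  ord <- order(mu, names(mu), method = "radix")
  bin <- integer(length(mu))
  bin[ord] <- ceiling(seq_along(mu) / (length(mu) / n_bins))
  names(bin) <- names(mu)
  bin
}

#' Score cells for the three glioma cell states
#'
#' Runs [signature_score()] for the OPC-like, OC-like and AC-like
#' signatures (per sample, as scoring and centering are per-sample
#' operations) and assembles the per-cell state table consumed by
#' [stemness_lineage()].
#'
#' @param m an `ExpressionMatrix` with unit `"lognorm"` (uncentered when
#'   `n_ctrl > 0`).
#' @param signatures named list of gene-id vectors containing at least
#'   `OPC`, `OC` and `AC`.
#' @inheritParams signature_score
#' @return a `data.frame` (one row per cell) with columns `cell_id`,
#'   `sample`, `opc_score`, `oc_score`, `ac_score`.
#' @export
state_scores <- function(m, signatures, n_bins = 30, n_ctrl = 100, seed = 1L) {
  assert_that(all(c("OPC", "OC", "AC") %in% names(signatures)),
              "signatures must contain OPC, OC and AC gene lists")
  data.frame(
    cell_id = colnames(m$values),
    sample = m$sample_of_cell,
    opc_score = unname(signature_score(m, signatures$OPC, n_bins, n_ctrl, seed)),
    oc_score  = unname(signature_score(m, signatures$OC, n_bins, n_ctrl, seed)),
    ac_score  = unname(signature_score(m, signatures$AC, n_bins, n_ctrl, seed)),
    stringsAsFactors = FALSE)
}

#' Stemness and lineage coordinates from state scores
#'
#' Maps the three state scores of each cell onto a two-dimensional
#' representation: the stemness score is the OPC score minus the larger of
#' the OC and AC scores, and the lineage score is that larger
#' differentiated-state score, negated when the AC score is the higher of
#' the two (AC on the negative half-axis, OC positive; an exact AC = OC tie
#' counts as OC). Cells whose OC and AC scores are both negative have no
#' meaningful lineage direction and receive a lineage value of 0 plus
#' seeded uniform jitter in `[-jitter_eps, jitter_eps]`, flagged in the
#' `jittered` column.
#'
#' @param tbl a state table from [state_scores()] (columns `opc_score`,
#'   `oc_score`, `ac_score`).
#' @param jitter_eps half-width of the jitter band around lineage 0.
#' @param seed integer seed for the jitter draw.
#' @return `tbl` with columns `stemness`, `lineage`, `jittered` appended.
#' @export
stemness_lineage <- function(tbl, jitter_eps = 0.05, seed = 1L) {
  assert_that(all(c("opc_score", "oc_score", "ac_score") %in% names(tbl)),
              "tbl must have opc_score, oc_score, ac_score columns")
  assert_that(is_number(jitter_eps) && jitter_eps >= 0,
              "jitter_eps must be a non-negative number")
  diff_max <- pmax(tbl$oc_score, tbl$ac_score)
  stemness <- tbl$opc_score - diff_max
  sign <- ifelse(tbl$ac_score > tbl$oc_score, -1, 1)
  lineage <- sign * diff_max
  jittered <- tbl$oc_score < 0 & tbl$ac_score < 0
  if (any(jittered)) {
    u <- with_seed(seed, runif(sum(jittered), -jitter_eps, jitter_eps))
    lineage[jittered] <- u
  }
  tbl$stemness <- stemness
  tbl$lineage <- lineage
  tbl$jittered <- jittered
  tbl
}

#' Flag cells with high centered expression of a gene
#'
#' Identifies receptor-high cells for highlighting on the stemness-lineage
#' map: a cell is flagged when its centered (per-sample) log-normalized
#' expression of `gene` exceeds `threshold` strictly.
#'
#' @param m a centered `ExpressionMatrix` (see [center_within_sample()]).
#' @param gene single gene id present in the matrix.
#' @param threshold strict lower bound on the centered value (default 1).
#' @return logical vector, one flag per cell, named by cell id.
#' @export
highlight_cells <- function(m, gene, threshold = 1.0) {
  assert_that(inherits(m, "ExpressionMatrix"), "m must be an ExpressionMatrix")
  assert_that(m$centered, "highlight_cells expects a centered matrix")
  if (!gene %in% rownames(m$values)) abort("gene '", gene, "' not in matrix")
  m$values[gene, ] > threshold
}
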