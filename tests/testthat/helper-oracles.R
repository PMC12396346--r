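# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: textbook formulas, scalar loops, naive enumeration.

# textbook Pearson correlation
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Benjamini-Hochberg step-up, written from the definition: q_i is the
# smallest value of p_(j) * n / j over all j >= rank(i), capped at 1
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(ord == i)
    cand <- sapply(rank_i:n, function(j) p[ord[j]] * n / j)
    q[i] <- min(1, min(cand))
  }
  q
}

# AUROC by pairwise enumeration (ties count 1/2)
auroc_oracle <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# scalar brute-force of the stemness/lineage mapping
stemness_lineage_oracle <- function(opc, oc, ac) {
  if (oc >= ac) {
    stemness <- opc - oc
    lineage <- oc
  } else {
    stemness <- opc - ac
    lineage <- -ac
  }
  if (oc < 0 && ac < 0) lineage <- NA  # jitter region: only the bound holds
  c(stemness = stemness, lineage = lineage)
}

# trapezoidal rule as an explicit loop
trapz_oracle <- function(t, y) {
  s <- 0
  for (i in seq_len(length(t) - 1)) {
    s <- s + (t[i + 1] - t[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

# naive all-pairs within-threshold count (the nearest-neighbor oracle)
nn_within_oracle <- function(post, pre, threshold) {
  n <- 0L
  for (i in seq_len(nrow(post))) {
    dmin <- Inf
    for (j in seq_len(nrow(pre))) {
      dmin <- min(dmin, sqrt(sum((post[i, ] - pre[j, ])^2)))
    }
    if (dmin <= threshold) n <- n + 1L
  }
  n
}

# small toy ExpressionMatrix builder
toy_matrix <- function(values, samples = rep("s1", ncol(values)),
                       platforms = NULL, unit = "counts",
                       malignant = rep(TRUE, ncol(values)),
                       centered = FALSE) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("c%03d", seq_len(ncol(values)))
  }
  if (is.null(platforms)) {
    platforms <- stats::setNames(rep("umi", length(unique(samples))),
                                 unique(samples))
  }
  expression_matrix(values, sample_of_cell = samples,
                    platform_of_sample = platforms,
                    malignant = malignant, unit = unit, centered = centered)
}
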