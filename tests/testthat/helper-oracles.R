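# Independent brute-force oracles, kept deliberately naive (explicit loops,
# definitional formulas) so they share no code path with the package.

# coefficient of bimodality from e1071's SAS-convention estimators
oracle_b <- function(x) {
  n <- length(x)
  g1 <- e1071::skewness(x, type = 2)
  g2 <- e1071::kurtosis(x, type = 2)
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

# composite abundance-occupancy ranking, from first principles
oracle_rank <- function(mat) {
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  occ <- apply(mat, 1, function(v) sum(v > 0) / length(v))
  rel <- apply(mat, 2, function(col) col / sum(col))
  ab <- apply(rel, 1, mean)
  r_occ <- rank(-occ, ties.method = "average")
  r_ab <- rank(-ab, ties.method = "average")
  comp <- (r_occ + r_ab) / 2
  ord <- order(comp, -ab, rownames(mat))
  rownames(mat)[ord]
}

# explained-beta-diversity curve by explicit iteration over pairs and k
oracle_curve <- function(mat, ranked_ids) {
  n <- ncol(mat)
  total <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    total <- total + sum(abs(mat[, a] - mat[, b]))
  }
  sapply(seq_along(ranked_ids), function(k) {
    top <- ranked_ids[seq_len(k)]
    num <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      num <- num + sum(abs(mat[top, a] - mat[top, b]))
    }
    num / total
  })
}

# Spearman rho: rank both series, then the definitional Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# per-date subcommunity contribution by explicit pair/taxon loops
oracle_contribution <- function(mat, site_of, sub_ids) {
  sites <- unique(site_of)
  num_sub <- 0
  num_full <- 0
  for (a in seq_along(sites)[-length(sites)]) for (b in (a + 1):length(sites)) {
    x <- mat[, which(site_of == sites[a])[1]]
    y <- mat[, which(site_of == sites[b])[1]]
    for (i in rownames(mat)) {
      d <- abs(x[i] - y[i])
      num_full <- num_full + d
      if (i %in% sub_ids) num_sub <- num_sub + d
    }
  }
  unname(100 * num_sub / num_full)
}

# small random count table with dimnames
random_table <- function(n_asv, n_samp, lambda = 5) {
  m <- matrix(rpois(n_asv * n_samp, lambda), n_asv, n_samp,
              dimnames = list(sprintf("t%02d", seq_len(n_asv)),
                              sprintf("s%02d", seq_len(n_samp))))
  m
}

# minimal metadata for a one-date multi-site toy design
toy_meta <- function(sample_ids, sites, dates) {
  data.frame(sample_id = sample_ids, site = sites,
             land_use_class = "agri_ditch", date = dates,
             stringsAsFactors = FALSE)
}
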