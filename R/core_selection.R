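#' Rank ASVs by combined abundance and occupancy
#'
#' Each ASV gets an occupancy rank (fraction of group samples with count > 0,
#' higher better) and a mean relative-abundance rank (higher better); the
#' composite score is the mean of the two criterion ranks and the composite
#' rank is its ascending order (1 = best). Ties are broken by higher mean
#' relative abundance, then lexicographic ASV id, so ranking is
#' deterministic. ASVs with zero total count in the group are excluded
#' (occupancy-0 taxa cannot be core).
#'
#' @param x count matrix.
#' @param samples optional character vector restricting the analysis group;
#'   default all samples.
#' @param occupancy_weight weight of the occupancy criterion rank in the
#'   composite score (abundance gets `1 - occupancy_weight`); default 0.5,
#'   i.e. symmetric.
#' @return data.frame (asv_id, occupancy, mean_relabund, composite_rank),
#'   ordered by composite rank.
#' @export
occupancy_abundance_rank <- function(x, samples = NULL, occupancy_weight = 0.5) {
  x <- validate_count_table(x)
  if (is.null(samples)) samples <- colnames(x)
  if (length(samples) == 0L) stop("analysis group is empty")
  miss <- setdiff(samples, colnames(x))
  if (length(miss)) stop("sample(s) not in table: ", paste(miss, collapse = ", "))
  sub <- x[, samples, drop = FALSE]
  sub <- sub[rowSums(sub) > 0, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no ASV has nonzero count in the group")
  rel <- suppressWarnings(relative_abundance(sub))
  occ <- rowMeans(sub > 0)
  ab <- rowMeans(rel)
  r_occ <- rank(-occ, ties.method = "average")
  r_ab <- rank(-ab, ties.method = "average")
  comp <- occupancy_weight * r_occ + (1 - occupancy_weight) * r_ab
  ord <- order(comp, -ab, rownames(sub))
  out <- data.frame(asv_id = rownames(sub)[ord], occupancy = occ[ord],
                    mean_relabund = ab[ord],
                    composite_rank = seq_along(ord),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

# Pooled per-taxon Bray-Curtis numerators over all unordered sample pairs:
# for each taxon with values v over n samples,
#   sum_{a<b} |v_a - v_b| = sum_k (2k - n - 1) v_(k)   (v sorted ascending).
pooled_pair_numerators <- function(m) {
  n <- ncol(m)
  wts <- 2 * seq_len(n) - n - 1
  apply(m, 1L, function(v) sum(wts * sort(v)))
}

#' Cumulative explained beta-diversity curve over ranked ASVs
#'
#' Bray-Curtis dissimilarity decomposes additively over taxa in its
#' numerator. Pooling numerators over all unordered sample pairs in the
#' group, the curve reports, for each k, the fraction of the pooled
#' whole-community numerator carried by the top-k ranked ASVs:
#' `explained(k) = sum_pairs sum_{i in top k} |x_i - y_i| /
#'  sum_pairs sum_{i} |x_i - y_i|`.
#' The curve is non-decreasing and reaches 1 at k = n.
#'
#' @param x count matrix.
#' @param ranked ranking from [occupancy_abundance_rank()] (or any data.frame
#'   with an `asv_id` column in rank order).
#' @param samples optional analysis group (>= 2 samples).
#' @return data.frame (k, asv_id, explained).
#' @export
explained_bc_curve <- function(x, ranked, samples = NULL) {
  x <- validate_count_table(x)
  if (is.null(samples)) samples <- colnames(x)
  if (length(samples) < 2L) stop("explained-beta-diversity curve needs >= 2 samples")
  ids <- if (is.data.frame(ranked)) ranked$asv_id else as.character(ranked)
  miss <- setdiff(ids, rownames(x))
  if (length(miss)) stop("ranked ASV(s) not in table: ", paste(miss, collapse = ", "))
  sub <- x[ids, samples, drop = FALSE]
  num <- pooled_pair_numerators(sub)
  # denominator spans *all* taxa present in the group, not just the ranked ones
  all_sub <- x[, samples, drop = FALSE]
  total <- sum(pooled_pair_numerators(all_sub))
  if (total <= 0) stop("degenerate community: all sample pairs identical (total Bray-Curtis dissimilarity is zero)")
  data.frame(k = seq_along(ids), asv_id = ids,
             explained = cumsum(num) / total,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the core set from an explained-beta-diversity curve
#'
#' Applies the marginal-gain stopping rule: the core is the top `k_sel`
#' ranked ASVs where `k_sel` is the largest k whose marginal gain
#' `explained(k) - explained(k - 1)` exceeds `threshold` (`explained(0) = 0`).
#' With the default threshold 0.005 the selection ends when the last included
#' ASV explains an additional 0.5% or less of whole-community beta-diversity.
#'
#' @param curve data.frame from [explained_bc_curve()].
#' @param threshold marginal explained-fraction cut-off, default 0.005.
#' @return list of class `"core_result"` with `core_set`, `k`, `threshold`,
#'   and the input `curve`.
#' @export
select_core <- function(curve, threshold = 0.005) {
  if (!is.data.frame(curve) || !all(c("asv_id", "explained") %in% names(curve)) ||
      nrow(curve) == 0L) {
    stop("`curve` must be a non-empty data.frame with columns asv_id, explained")
  }
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must lie in (0, 1)")
  expl <- curve$explained
  if (any(diff(expl) < -1e-9)) stop("internal inconsistency: explained curve is not non-decreasing")
  gains <- diff(c(0, expl))
  qual <- which(gains > threshold)
  if (length(qual) == 0L) {
    warning("no ASV exceeds the marginal threshold; core set is empty")
    k_sel <- 0L
  } else {
    k_sel <- max(qual)
  }
  structure(list(core_set = curve$asv_id[seq_len(k_sel)], k = k_sel,
                 threshold = threshold, curve = curve),
            class = "core_result")
}

#' One-call core-microbiome selection
#'
#' Convenience wrapper: rank ASVs by abundance-occupancy, build the explained
#' beta-diversity curve, and apply the marginal-gain stopping rule.
#'
#' @inheritParams occupancy_abundance_rank
#' @inheritParams select_core
#' @return a `"core_result"` (see [select_core()]) with the ranking attached
#'   as `$ranked`.
#' @export
core_microbiome <- function(x, samples = NULL, threshold = 0.005,
                            occupancy_weight = 0.5) {
  ranked <- occupancy_abundance_rank(x, samples, occupancy_weight)
  curve <- explained_bc_curve(x, ranked, samples)
  res <- select_core(curve, threshold)
  res$ranked <- ranked
  res
}

#' @export
print.core_result <- function(x, ...) {
  cat("Core selection: ", x$k, " of ", nrow(x$curve),
      " ranked ASVs (marginal threshold ", x$threshold, ")\n",
      "  explained beta-diversity at core boundary: ",
      if (x$k > 0) round(x$curve$explained[x$k], 4) else 0, "\n", sep = "")
  invisible(x)
}
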