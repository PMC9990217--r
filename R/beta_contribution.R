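#' Bray-Curtis dissimilarity between two samples
#'
#' `BC(x, y) = sum_i |x_i - y_i| / sum_i (x_i + y_i)`, on count (or relative
#' abundance) vectors of equal length. 0 for identical samples, 1 for
#' disjoint supports.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(6, 2), c(2, 2))  # 1/3
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  denom <- sum(x + y)
  if (denom == 0) stop("undefined dissimilarity: both samples are all-zero")
  sum(abs(x - y)) / denom
}

#' Additive per-taxon share of Bray-Curtis dissimilarity
#'
#' The Bray-Curtis numerator decomposes additively over taxa; the share of a
#' taxon subset is `sum_{i in subset} |x_i - y_i| / sum_i (x_i + y_i)` — the
#' subset's partial numerator over the full-community denominator. Shares
#' over a partition of the taxa sum exactly to `bray_curtis(x, y)`.
#'
#' @inheritParams bray_curtis
#' @param subset integer or logical index, or character names (when `x` is
#'   named), of the taxa whose share is wanted.
#' @return the subset's additive share of the full dissimilarity.
#' @export
partial_bray_curtis <- function(x, y, subset) {
  if (length(x) != length(y)) stop("vectors differ in length")
  denom <- sum(x + y)
  if (denom == 0) stop("undefined dissimilarity: both samples are all-zero")
  if (is.character(subset)) {
    if (is.null(names(x))) stop("character `subset` needs named vectors")
    subset <- match(subset, names(x))
    if (anyNA(subset)) stop("subset taxa not found in vectors")
  }
  sum(abs(x - y)[subset]) / denom
}

#' Per-date contribution of a subcommunity to community heterogeneity
#'
#' At each sampling date, all unordered pairs of samples (distinct sites, or
#' blocks when a block map is given) observed on that date within the group
#' are pooled: the contribution is
#' `100 * sum_pairs partial-numerator(subcommunity) / sum_pairs full-numerator`,
#' i.e. the percentage of whole-community Bray-Curtis dissimilarity at that
#' date attributable to the subcommunity. Pooling sums numerators before
#' dividing (sum/sum, not mean of ratios), which preserves exact additivity
#' over disjoint subcommunities. Dates with fewer than two samples, or where
#' every pair is identical, are skipped and listed in the `"skipped"`
#' attribute.
#'
#' @param x count matrix.
#' @param meta sample metadata (see [read_sample_metadata()]).
#' @param subcommunity character vector of ASV ids (e.g. the core set).
#' @param samples optional analysis group; default all samples in `meta`.
#' @param blocks optional named character vector mapping site -> block label;
#'   blocked sites' count vectors are averaged before pairing.
#' @return data.frame of class `"contribution_series"`: date, n_pairs,
#'   contribution_pct.
#' @export
contribution_series <- function(x, meta, subcommunity, samples = NULL,
                                blocks = NULL) {
  x <- validate_count_table(x)
  meta <- validate_sample_metadata(meta)
  if (is.null(samples)) samples <- intersect(meta$sample_id, colnames(x))
  meta <- meta[meta$sample_id %in% samples, , drop = FALSE]
  if (nrow(meta) == 0L) stop("analysis group is empty")
  sub_idx <- rownames(x) %in% subcommunity
  unit <- if (is.null(blocks)) meta$site else {
    u <- blocks[meta$site]
    ifelse(is.na(u), meta$site, u)
  }
  dates <- sort(unique(meta$date))
  rows <- list()
  skipped <- list()
  for (d in as.character(dates)) {
    sel <- meta$date == as.Date(d)
    units_d <- unique(unit[sel])
    if (length(units_d) < 2L) {
      skipped[[d]] <- "fewer_than_two_samples"
      next
    }
    # one count vector per unit: average over the unit's samples at this date
    vecs <- matrix(vapply(units_d, function(u) {
      cols <- meta$sample_id[sel & unit == u]
      rowMeans(x[, cols, drop = FALSE])
    }, numeric(nrow(x))), nrow = nrow(x))
    pr <- utils::combn(length(units_d), 2L)
    num_full <- 0
    num_sub <- 0
    for (j in seq_len(ncol(pr))) {
      ad <- abs(vecs[, pr[1L, j]] - vecs[, pr[2L, j]])
      num_full <- num_full + sum(ad)
      num_sub <- num_sub + sum(ad[sub_idx])
    }
    if (num_full == 0) {
      skipped[[d]] <- "zero_total_dissimilarity"
      next
    }
    rows[[d]] <- data.frame(date = as.Date(d), n_pairs = ncol(pr),
                            contribution_pct = 100 * num_sub / num_full)
  }
  if (length(rows) == 0L) stop("no date with >= 2 comparable samples and nonzero dissimilarity")
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "skipped") <- unlist(skipped)
  class(out) <- c("contribution_series", "data.frame")
  out
}
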