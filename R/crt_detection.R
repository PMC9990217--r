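# Sample skewness g1 and excess kurtosis g2 with small-sample (SAS-convention)
# corrections, vectorised over matrix rows:
#   g1 = n / ((n-1)(n-2)) * sum(z^3),             z = (x - mean) / sd (n-1 sd)
#   g2 = n(n+1) / ((n-1)(n-2)(n-3)) * sum(z^4) - 3(n-1)^2 / ((n-2)(n-3))
row_moments <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  dev <- m - mu
  s <- sqrt(rowSums(dev^2) / (n - 1))
  z <- dev / s
  g1 <- n / ((n - 1) * (n - 2)) * rowSums(z^3)
  g2 <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * rowSums(z^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
  list(g1 = g1, g2 = g2, sd = s, n = n)
}

#' Coefficient of bimodality
#'
#' `b = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))` where `g1` is the
#' sample skewness and `g2` the sample excess kurtosis, both with
#' small-sample (SAS-convention) corrections. Values near 1 indicate a
#' strongly bimodal (or heavily skewed two-state) distribution: for a large
#' balanced two-point sample, population skewness 0 and excess kurtosis -2
#' give b = 1. The statistic is invariant to affine transforms of the
#' series.
#'
#' @param series numeric vector, at least 4 non-constant values.
#' @return the coefficient of bimodality (scalar).
#' @export
#' @examples
#' bimodality_coefficient(c(rep(0, 10), rep(1, 10)))
bimodality_coefficient <- function(series) {
  series <- as.numeric(series)
  if (anyNA(series)) stop("series contains missing values")
  if (length(series) < 4L) {
    stop("bimodality coefficient needs >= 4 observations, got ", length(series))
  }
  if (stats::sd(series) == 0) stop("degenerate series: zero variance")
  mo <- row_moments(matrix(series, nrow = 1L))
  n <- mo$n
  unname((mo$g1^2 + 1) / (mo$g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3))))
}

#' Detect conditionally rare taxa (CRT)
#'
#' For every non-core ASV the per-sample relative-abundance series within the
#' group is screened: the ASV must reach `abundance_threshold` (default 0.1%)
#' in at least one sample, and its series must be bimodal with coefficient of
#' bimodality `b >= b_threshold` (default 0.90). Core ASVs are excluded
#' before screening (core and CRT are disjoint subcommunities); series that
#' are too short, constant, or below the abundance screen are reported with
#' `is_crt = FALSE` and a reason code rather than erroring.
#'
#' @param x count matrix.
#' @param samples optional analysis group; default all samples.
#' @param core_set character vector of core ASV ids to exclude.
#' @param b_threshold minimum coefficient of bimodality, default 0.90.
#' @param abundance_threshold minimum max per-sample relative abundance,
#'   default 0.001 (0.1%).
#' @param min_rare_fraction optional; when set, additionally require the ASV
#'   to be below `abundance_threshold` in at least this fraction of samples
#'   (a "conditional rarity" requirement, off by default).
#' @return data.frame of class `"crt_result"`: asv_id, b, skewness,
#'   excess_kurtosis, max_relabund, n_obs, is_crt, reason.
#' @export
detect_crt <- function(x, samples = NULL, core_set = character(),
                       b_threshold = 0.90, abundance_threshold = 0.001,
                       min_rare_fraction = NULL) {
  x <- validate_count_table(x)
  if (is.null(samples)) samples <- colnames(x)
  if (length(samples) == 0L) stop("analysis group is empty")
  sub <- x[, samples, drop = FALSE]
  rel <- suppressWarnings(relative_abundance(sub))
  n_obs <- ncol(rel)

  out <- data.frame(asv_id = rownames(rel), b = NA_real_, skewness = NA_real_,
                    excess_kurtosis = NA_real_,
                    max_relabund = apply(rel, 1L, max), n_obs = n_obs,
                    is_crt = FALSE, reason = "", stringsAsFactors = FALSE,
                    row.names = NULL)
  in_core <- out$asv_id %in% core_set
  out$reason[in_core] <- "in_core_set"
  below <- !in_core & out$max_relabund < abundance_threshold
  out$reason[below] <- "below_abundance_threshold"
  candidate <- !in_core & !below
  if (n_obs < 4L) {
    out$reason[candidate] <- "too_few_observations"
    return(structure(out, class = c("crt_result", "data.frame")))
  }
  const <- candidate & apply(rel, 1L, function(v) max(v) == min(v))
  out$reason[const] <- "constant_series"
  candidate <- candidate & !const
  if (any(candidate)) {
    mo <- row_moments(rel[candidate, , drop = FALSE])
    n <- mo$n
    b <- (mo$g1^2 + 1) / (mo$g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
    out$b[candidate] <- b
    out$skewness[candidate] <- mo$g1
    out$excess_kurtosis[candidate] <- mo$g2
    flag <- b >= b_threshold
    if (!is.null(min_rare_fraction)) {
      rare_frac <- rowMeans(rel[candidate, , drop = FALSE] < abundance_threshold)
      flag <- flag & rare_frac >= min_rare_fraction
      out$reason[candidate][b >= b_threshold & !flag] <- "insufficient_rarity"
    }
    out$is_crt[candidate] <- flag
    out$reason[candidate][!flag & out$reason[candidate] == ""] <- "below_b_threshold"
  }
  structure(out, class = c("crt_result", "data.frame"))
}

#' Partition analyzed ASVs into core / CRT / other
#'
#' Given a core set and a CRT detection result, returns the class of every
#' ASV in the detection table; each ASV lands in exactly one class.
#'
#' @param crt a `"crt_result"` from [detect_crt()].
#' @param core_set character vector of core ASV ids.
#' @return named character vector over the analyzed ASVs.
#' @export
partition_taxa <- function(crt, core_set) {
  cls <- ifelse(crt$asv_id %in% core_set, "core",
                ifelse(crt$is_crt, "crt", "other"))
  stats::setNames(cls, crt$asv_id)
}
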