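#' Temporal community stability (constancy) of a subcommunity
#'
#' For one unit (site or block) and year, sums the subcommunity's counts at
#' each sampling date and reports `stability = mean / sd` of the resulting
#' total-abundance series, using the sample (n-1) standard deviation. Larger
#' values mean a temporally steadier aggregate abundance; the statistic is
#' the reciprocal of the coefficient of variation and is invariant to
#' rescaling all counts. At least 3 sampling dates are required; a constant
#' series is flagged degenerate (stability undefined) instead of dividing by
#' zero.
#'
#' @param x count matrix.
#' @param meta sample metadata.
#' @param subcommunity character vector of ASV ids (e.g. combined core+CRT).
#' @param unit site (or block) identifier.
#' @param year sampling year.
#' @param blocks optional named map site -> block, as in
#'   [contribution_series()].
#' @return one-row data.frame: unit, year, n_timepoints, mean_total,
#'   sd_total, stability, degenerate.
#' @export
community_stability <- function(x, meta, subcommunity, unit, year,
                                blocks = NULL) {
  x <- validate_count_table(x)
  meta <- validate_sample_metadata(meta)
  u <- if (is.null(blocks)) meta$site else {
    b <- blocks[meta$site]
    ifelse(is.na(b), meta$site, b)
  }
  sel <- u == unit & meta$year == year & meta$sample_id %in% colnames(x)
  if (!any(sel)) stop("no samples for unit '", unit, "', year ", year)
  m <- meta[sel, , drop = FALSE]
  dates <- sort(unique(m$date))
  if (length(dates) < 3L) {
    stop("community stability needs >= 3 sampling dates; unit '", unit,
         "', year ", year, " has ", length(dates))
  }
  rows <- rownames(x) %in% subcommunity
  totals <- vapply(as.character(dates), function(d) {
    cols <- m$sample_id[m$date == as.Date(d)]
    sum(x[rows, cols, drop = FALSE])
  }, numeric(1L))
  mu <- mean(totals)
  s <- stats::sd(totals)
  data.frame(unit = unit, year = year, n_timepoints = length(dates),
             mean_total = mu, sd_total = s,
             stability = if (s > 0) mu / s else NA_real_,
             degenerate = s == 0, stringsAsFactors = FALSE)
}

#' Stability table over all units and years
#'
#' Applies [community_stability()] to every (unit, year) combination with at
#' least `min_timepoints` sampling dates; combinations with fewer are
#' skipped and listed in the `"skipped"` attribute.
#'
#' @inheritParams community_stability
#' @param min_timepoints minimum sampling dates per unit-year (default 3).
#' @return data.frame, one row per reported unit-year.
#' @export
stability_table <- function(x, meta, subcommunity, blocks = NULL,
                            min_timepoints = 3L) {
  meta <- validate_sample_metadata(meta)
  u <- if (is.null(blocks)) meta$site else {
    b <- blocks[meta$site]
    ifelse(is.na(b), meta$site, b)
  }
  combos <- unique(data.frame(unit = u, year = meta$year, stringsAsFactors = FALSE))
  rows <- list()
  skipped <- character()
  for (i in seq_len(nrow(combos))) {
    n_dates <- length(unique(meta$date[u == combos$unit[i] & meta$year == combos$year[i]]))
    key <- paste(combos$unit[i], combos$year[i], sep = "/")
    if (n_dates < min_timepoints) {
      skipped <- c(skipped, key)
      next
    }
    rows[[key]] <- community_stability(x, meta, subcommunity, combos$unit[i],
                                       combos$year[i], blocks)
  }
  if (length(rows) == 0L) stop("no unit-year has >= ", min_timepoints, " sampling dates")
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "skipped") <- skipped
  out
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean; scale-invariant. Undefined
#' for a zero mean. [community_stability()] is its reciprocal on the
#' total-abundance series.
#'
#' @param series numeric vector with at least 2 values.
#' @return `sd(series) / mean(series)`.
#' @export
coefficient_of_variation <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 2L) stop("coefficient of variation needs >= 2 values")
  m <- mean(series)
  if (m == 0) stop("undefined coefficient of variation: mean is zero")
  stats::sd(series) / m
}
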