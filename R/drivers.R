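#' Spearman correlations between a community series and covariates
#'
#' Matches a per-(site, date) response series — typically a subcommunity's
#' aggregate relative abundance or its beta-diversity contribution — against
#' each numeric covariate column, computing tie-corrected Spearman rank
#' correlations with two-sided p-values and Benjamini-Hochberg adjusted
#' q-values across the covariate family. Significance stars follow the usual
#' 0.05 / 0.01 / 0.001 / 0.0001 cuts on the adjusted q-value. Covariates
#' with fewer than `min_obs` complete pairs, or constant over the pairs, are
#' reported as `NA` with a reason.
#'
#' @param series data.frame with columns `site`, `date`, `value` (or
#'   `date`, `value` for a single pooled series).
#' @param covariates data.frame with `site` and/or `date` plus numeric
#'   covariate columns; merged with `series` on the shared key columns.
#' @param min_obs minimum complete pairs per covariate (default 5).
#' @return data.frame: covariate, n, rho, p, q, stars, reason.
#' @export
spearman_drivers <- function(series, covariates, min_obs = 5L) {
  if (!is.data.frame(series) || !"value" %in% names(series)) {
    stop("`series` must be a data.frame with a `value` column")
  }
  key <- intersect(intersect(c("site", "date"), names(series)), names(covariates))
  if (length(key) == 0L) stop("no shared key column (site, date) to match on")
  merged <- merge(series, covariates, by = key)
  cov_cols <- setdiff(names(covariates), c(key, "sample_id", "year",
                                           "land_use_class", "value"))
  cov_cols <- cov_cols[vapply(merged[cov_cols], is.numeric, logical(1L))]
  if (length(cov_cols) == 0L) stop("no numeric covariate columns found")
  res <- lapply(cov_cols, function(cn) {
    ok <- stats::complete.cases(merged$value, merged[[cn]])
    v <- merged$value[ok]
    w <- merged[[cn]][ok]
    if (length(v) < min_obs) {
      return(data.frame(covariate = cn, n = length(v), rho = NA_real_,
                        p = NA_real_, reason = "too_few_pairs",
                        stringsAsFactors = FALSE))
    }
    if (stats::sd(w) == 0 || stats::sd(v) == 0) {
      return(data.frame(covariate = cn, n = length(v), rho = NA_real_,
                        p = NA_real_, reason = "constant_series",
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(v, w, method = "spearman",
                                           exact = FALSE))
    data.frame(covariate = cn, n = length(v), rho = unname(ct$estimate),
               p = ct$p.value, reason = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$stars <- significance_stars(out$q)
  out[, c("covariate", "n", "rho", "p", "q", "stars", "reason")]
}

significance_stars <- function(q) {
  ifelse(is.na(q), "",
         ifelse(q <= 1e-4, "****",
                ifelse(q <= 1e-3, "***",
                       ifelse(q <= 0.01, "**",
                              ifelse(q <= 0.05, "*", "")))))
}
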