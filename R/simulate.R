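#' Configuration for the synthetic community generator
#'
#' Defaults emulate the study design the pipeline targets: several small
#' stream/ditch sites sampled bi-weekly from mid-April over the growing
#' season, for multiple years, rarefied to a fixed depth of 13,430 reads per
#' sample. Three taxon classes are planted: a persistent high-occupancy core
#' (per-sample lognormal abundance), conditionally rare taxa (CRT) that sit
#' at a rare baseline but surge on shared event dates, and a large tail of
#' sparse low-count background taxa.
#'
#' @param n_sites number of sites.
#' @param n_dates sampling dates per year (bi-weekly).
#' @param n_years number of sampling years.
#' @param n_core,n_crt,n_background planted taxon counts per class.
#' @param n_core_site number of additional site-specific core taxa: abundant
#'   and persistent only at `site_core_class` sites, sparse elsewhere
#'   (default 0; used to contrast group-restricted with cross-site core
#'   selection).
#' @param site_core_class land-use class hosting the site-specific core.
#' @param depth reads per sample (multinomial total; tables are generated
#'   "already rarefied" unless `variable_depth = TRUE`).
#' @param core_logmean,core_logsd lognormal parameters of the per-sample core
#'   latent weight (log relative-abundance scale before renormalisation).
#' @param crt_baseline latent proportion of each CRT taxon on non-event dates.
#' @param crt_spike_abundance median latent proportion of a CRT taxon on an
#'   event date (per-site, per-taxon lognormal scatter of `crt_spike_logsd`).
#' @param crt_spike_prob per-date probability of a spike event.
#' @param crt_spike_logsd lognormal sd of spike magnitudes across sites/taxa;
#'   kept small so the spike state is a tight upper mode and the planted
#'   series are genuinely two-state.
#' @param crt_spike_participation probability that a given (site, taxon)
#'   joins a spike event; values below 1 make sites differ on event dates.
#' @param covariate_coupling in `[0, 1]`; 0 = spike events independent of the
#'   discharge covariate, 1 = events confined to its top-decile dates.
#' @param bg_logmean,bg_logsd lognormal parameters of background weights when
#'   present; background occupancy is uniform on `bg_occupancy`.
#' @param bg_occupancy length-2 range of background per-taxon occupancy.
#' @param synchronize_spikes logical; `TRUE` (default) makes spike events
#'   shared across sites and CRT taxa (event dates), `FALSE` draws
#'   independent per-(taxon, sample) spikes.
#' @param variable_depth logical; if `TRUE` sample totals vary lognormally
#'   around `depth` (for exercising [rarefy()]).
#' @param seed integer RNG seed.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_sites = 8L, n_dates = 14L, n_years = 2L,
                       n_core = 50L, n_crt = 100L, n_background = 2000L,
                       n_core_site = 0L, site_core_class = "agri_ditch",
                       depth = 13430L,
                       core_logmean = log(0.01), core_logsd = 0.6,
                       crt_baseline = 1e-4, crt_spike_abundance = 5e-3,
                       crt_spike_prob = 0.12, crt_spike_logsd = 0.15,
                       crt_spike_participation = 0.7,
                       covariate_coupling = 0,
                       bg_logmean = log(3e-6), bg_logsd = 1.2,
                       bg_occupancy = c(0.01, 0.3),
                       synchronize_spikes = TRUE, variable_depth = FALSE,
                       seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites), n_dates = as.integer(n_dates),
              n_years = as.integer(n_years), n_core = as.integer(n_core),
              n_crt = as.integer(n_crt), n_background = as.integer(n_background),
              n_core_site = as.integer(n_core_site),
              site_core_class = site_core_class,
              depth = as.integer(depth), core_logmean = core_logmean,
              core_logsd = core_logsd, crt_baseline = crt_baseline,
              crt_spike_abundance = crt_spike_abundance,
              crt_spike_prob = crt_spike_prob, crt_spike_logsd = crt_spike_logsd,
              crt_spike_participation = crt_spike_participation,
              covariate_coupling = covariate_coupling,
              bg_logmean = bg_logmean, bg_logsd = bg_logsd,
              bg_occupancy = bg_occupancy,
              synchronize_spikes = isTRUE(synchronize_spikes),
              variable_depth = isTRUE(variable_depth), seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_core + n_crt + n_background < 1L) stop("at least one taxon must be simulated")
    if (depth <= 0L) stop("`depth` must be positive")
    if (n_sites < 1L || n_dates < 1L || n_years < 1L) stop("design dimensions must be >= 1")
    for (p in c(crt_spike_prob, crt_spike_participation, covariate_coupling)) {
      if (is.na(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
    }
    if (crt_baseline < 0 || crt_baseline > 1 || crt_spike_abundance < 0 ||
        crt_spike_abundance > 1) {
      stop("CRT proportions must lie in [0, 1]")
    }
  })
  invisible(cfg)
}

# Bi-weekly sampling dates starting mid-April, per year.
sim_dates <- function(cfg, start_year = 2016L) {
  unlist(lapply(seq_len(cfg$n_years), function(y) {
    as.character(as.Date(paste0(start_year + y - 1L, "-04-15")) +
                   14L * (seq_len(cfg$n_dates) - 1L))
  }))
}

#' Simulate seasonal environmental covariates and spike-event dates
#'
#' Generates per-(site, date) series for a small set of covariates named
#' after typical water-quality and hydrology measurements (discharge
#' `RU_DISM3S`, `NITRATE`, `TURBIDITY_NTU`, `AMIA_AMN`, air temperature
#' `AVG_TEMP_C`): a smooth seasonal component plus site offsets and noise.
#' Spike-event dates for the CRT class are drawn here so that, when
#' `covariate_coupling > 0`, events concentrate on dates of high discharge;
#' at coupling 1 they are confined to the top decile of site-mean discharge.
#'
#' @param cfg a [sim_config()].
#' @return list with `covariates` (data.frame: sample_id, site, date, year,
#'   one numeric column per covariate), `spike_dates` (character vector of
#'   event dates), and `is_spike_date` (named logical over all dates).
#' @export
simulate_covariates <- function(cfg) {
  validate_sim_config(cfg)
  withr::with_seed(cfg$seed, simulate_covariates_impl(cfg))
}

simulate_covariates_impl <- function(cfg) {
  sites <- sprintf("S%02d", seq_len(cfg$n_sites))
  dates <- sim_dates(cfg)
  doy <- as.integer(format(as.Date(dates), "%j"))
  grid <- expand.grid(site = sites, date = dates, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$site, grid$date), , drop = FALSE]
  gdoy <- doy[match(grid$date, dates)]
  n <- nrow(grid)
  season <- function(amp, phase, base) base + amp * cos(2 * pi * (gdoy - phase) / 365)
  site_off <- stats::rnorm(cfg$n_sites, 0, 0.3)[match(grid$site, sites)]
  cov <- data.frame(
    sample_id = paste(grid$site, grid$date, sep = "_"),
    site = grid$site, date = grid$date,
    year = as.integer(substr(grid$date, 1L, 4L)),
    # discharge: high in spring/fall, low mid-summer
    RU_DISM3S = pmax(0.01, exp(log(0.5) - 1.2 * cos(2 * pi * (gdoy - 10) / 365) +
                                 site_off + stats::rnorm(n, 0, 0.35))),
    NITRATE = pmax(0.01, season(1.0, 120, 2.0) + site_off + stats::rnorm(n, 0, 0.4)),
    TURBIDITY_NTU = pmax(0.1, exp(season(0.5, 200, 2.5) + 0.5 * site_off +
                                    stats::rnorm(n, 0, 0.5))),
    AMIA_AMN = pmax(0.001, exp(season(0.6, 210, -2.5) + stats::rnorm(n, 0, 0.5))),
    AVG_TEMP_C = season(10, 200, 14) + stats::rnorm(n, 0, 1.5),
    stringsAsFactors = FALSE)
  # spike events tied (optionally) to site-mean discharge
  mean_q <- tapply(cov$RU_DISM3S, cov$date, mean)[dates]
  pct <- rank(mean_q, ties.method = "first") / length(mean_q)
  cc <- cfg$covariate_coupling
  top <- pct > 0.9
  p_date <- (1 - cc) * cfg$crt_spike_prob +
    cc * ifelse(top, cfg$crt_spike_prob / 0.1, 0)
  p_date <- pmin(p_date, 1)
  is_spike <- stats::runif(length(dates)) < p_date
  names(is_spike) <- dates
  list(covariates = cov, spike_dates = dates[is_spike], is_spike_date = is_spike)
}

#' Simulate a multi-site, multi-year ASV count table with planted structure
#'
#' Latent per-sample expected proportions are built per taxon class — core:
#' lognormal at every date (occupancy ~ 1); CRT: `crt_baseline` off events
#' and a lognormal spike around `crt_spike_abundance` on event dates;
#' background: sparse occupancy with low lognormal weights — renormalised,
#' and counts drawn multinomially at fixed depth, so tables come out
#' "already rarefied". Identical seeds give identical output.
#'
#' @param cfg a [sim_config()].
#' @return list of class `"crt_sim"` with elements `counts` (count matrix),
#'   `metadata` (sample metadata incl. covariates), `truth` (data.frame
#'   asv_id, class in core/crt/background), `covariates`, `spike_dates`.
#' @export
simulate_community <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  withr::with_seed(cfg$seed, {
    env <- simulate_covariates_impl(cfg)
    cov <- env$covariates
    n_samp <- nrow(cov)
    spike_sample <- env$is_spike_date[cov$date]

    ids <- c(if (cfg$n_core) sprintf("core_%03d", seq_len(cfg$n_core)),
             if (cfg$n_core_site) sprintf("sitecore_%03d", seq_len(cfg$n_core_site)),
             if (cfg$n_crt) sprintf("crt_%03d", seq_len(cfg$n_crt)),
             if (cfg$n_background) sprintf("bg_%04d", seq_len(cfg$n_background)))
    classes <- rep(c("core", "site_core", "crt", "background"),
                   c(cfg$n_core, cfg$n_core_site, cfg$n_crt, cfg$n_background))
    w <- matrix(0, length(ids), n_samp, dimnames = list(ids, cov$sample_id))
    site_classes <- rep(c(rep("agri_ditch", ceiling(cfg$n_sites / 2)),
                          rep("mixed", max(cfg$n_sites - ceiling(cfg$n_sites / 2) - 1L, 0L)),
                          "forest")[seq_len(cfg$n_sites)],
                        length.out = cfg$n_sites)
    names(site_classes) <- sprintf("S%02d", seq_len(cfg$n_sites))
    sample_class <- site_classes[cov$site]

    if (cfg$n_core) {
      w[classes == "core", ] <- stats::rlnorm(cfg$n_core * n_samp,
                                              cfg$core_logmean, cfg$core_logsd)
    }
    if (cfg$n_core_site) {
      # abundant/persistent only at the hosting land-use class, sparse elsewhere
      at_home <- sample_class == cfg$site_core_class
      wsc <- matrix(0, cfg$n_core_site, n_samp)
      wsc[, at_home] <- stats::rlnorm(cfg$n_core_site * sum(at_home),
                                      cfg$core_logmean, cfg$core_logsd)
      away <- matrix(stats::runif(cfg$n_core_site * sum(!at_home)) < 0.2,
                     cfg$n_core_site) *
        stats::rlnorm(cfg$n_core_site * sum(!at_home), cfg$bg_logmean, cfg$bg_logsd)
      wsc[, !at_home] <- away
      w[classes == "site_core", ] <- wsc
    }
    if (cfg$n_crt) {
      base <- matrix(cfg$crt_baseline, cfg$n_crt, n_samp)
      if (cfg$synchronize_spikes) {
        # shared event dates; each (site, taxon) joins with fixed probability
        hit <- matrix(rep(spike_sample, each = cfg$n_crt), cfg$n_crt, n_samp) &
          matrix(stats::runif(cfg$n_crt * n_samp) < cfg$crt_spike_participation,
                 cfg$n_crt, n_samp)
      } else {
        hit <- matrix(stats::runif(cfg$n_crt * n_samp) <
                        cfg$crt_spike_prob * cfg$crt_spike_participation,
                      cfg$n_crt, n_samp)
      }
      mag <- matrix(stats::rlnorm(cfg$n_crt * n_samp, log(cfg$crt_spike_abundance),
                                  cfg$crt_spike_logsd), cfg$n_crt, n_samp)
      w[classes == "crt", ] <- ifelse(hit, mag, base)
    }
    if (cfg$n_background) {
      occ <- stats::runif(cfg$n_background, cfg$bg_occupancy[1L], cfg$bg_occupancy[2L])
      pres <- matrix(stats::runif(cfg$n_background * n_samp), cfg$n_background) <= occ
      wt <- matrix(stats::rlnorm(cfg$n_background * n_samp, cfg$bg_logmean,
                                 cfg$bg_logsd), cfg$n_background, n_samp)
      w[classes == "background", ] <- pres * wt
    }

    p <- sweep(w, 2L, colSums(w), "/")
    depths <- if (cfg$variable_depth) {
      pmax(100L, as.integer(round(cfg$depth * stats::rlnorm(n_samp, 0, 0.3))))
    } else rep(cfg$depth, n_samp)
    counts <- vapply(seq_len(n_samp),
                     function(j) stats::rmultinom(1L, depths[j], p[, j])[, 1L],
                     numeric(length(ids)))
    dimnames(counts) <- dimnames(w)

    meta <- data.frame(sample_id = cov$sample_id, site = cov$site,
                       land_use_class = sample_class,
                       date = as.Date(cov$date), year = cov$year,
                       cov[, setdiff(names(cov), c("sample_id", "site", "date", "year")),
                           drop = FALSE],
                       stringsAsFactors = FALSE, row.names = NULL)
    out <- list(counts = counts, metadata = meta,
                truth = data.frame(asv_id = ids, class = classes,
                                   stringsAsFactors = FALSE),
                covariates = cov, spike_dates = env$spike_dates, config = cfg)
    class(out) <- "crt_sim"
    out
  })
}

#' @export
print.crt_sim <- function(x, ...) {
  cat("Synthetic ASV community:", nrow(x$counts), "taxa x", ncol(x$counts),
      "samples\n  classes:", sum(x$truth$class == "core"), "core,",
      sum(x$truth$class == "crt"), "CRT,",
      sum(x$truth$class == "background"), "background\n  spike dates:",
      length(x$spike_dates), "of", length(unique(x$metadata$date)), "\n")
  invisible(x)
}
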