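#' Percentage share of a count within a total
#'
#' Small report helper used for composition summaries, e.g. the share of
#' ASVs classified core or CRT out of all ASVs in a table.
#'
#' @param n count in the numerator (non-negative).
#' @param total denominator count (positive, `>= n` not enforced — shares of
#'   overlapping sets may exceed their union's).
#' @return `100 * n / total`.
#' @export
pct_share <- function(n, total) {
  if (any(n < 0) || any(total <= 0)) stop("`n` must be >= 0 and `total` > 0")
  100 * n / total
}

#' Assemble a pipeline configuration
#'
#' Either `sim` (a [sim_config()]) or both `counts_path` and `metadata_path`
#' must be supplied. Thresholds default to the pipeline's standard
#' configuration: marginal explained beta-diversity 0.005 for core selection,
#' bimodality 0.90 and abundance screen 0.001 for CRT detection.
#'
#' @param sim optional [sim_config()] to generate the input tables.
#' @param counts_path,metadata_path optional TSV inputs (used when `sim` is
#'   `NULL`).
#' @param groups named list of analysis groups: each element is a character
#'   vector of `group_var` values (or `NULL` for all samples).
#' @param group_var metadata column defining groups, default
#'   `"land_use_class"`.
#' @param core_threshold,b_threshold,abundance_threshold stage thresholds.
#' @param depth optional rarefaction depth applied to file inputs; simulated
#'   tables are generated at fixed depth already.
#' @param seed integer seed governing rarefaction (and simulation when `sim`
#'   carries no seed of its own).
#' @param out_dir output directory for stage TSVs.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = NULL, counts_path = NULL, metadata_path = NULL,
                            groups = list(all = NULL),
                            group_var = "land_use_class",
                            core_threshold = 0.005, b_threshold = 0.90,
                            abundance_threshold = 0.001, depth = NULL,
                            seed = 1L, out_dir = tempfile("crtcore_run_")) {
  if (is.null(sim) && (is.null(counts_path) || is.null(metadata_path))) {
    stop("supply either `sim` or both `counts_path` and `metadata_path`")
  }
  for (th in c(core_threshold, b_threshold, abundance_threshold)) {
    if (th <= 0 || th >= 1) stop("thresholds must lie in (0, 1)")
  }
  structure(list(sim = sim, counts_path = counts_path,
                 metadata_path = metadata_path, groups = groups,
                 group_var = group_var, core_threshold = core_threshold,
                 b_threshold = b_threshold,
                 abundance_threshold = abundance_threshold, depth = depth,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

write_stage_tsv <- function(df, path, cfg, extra = character()) {
  hdr <- c(paste0("# crtcore ", as.character(utils::packageVersion("crtcore"))),
           paste0("# seed=", cfg$seed,
                  " core_threshold=", cfg$core_threshold,
                  " b_threshold=", cfg$b_threshold,
                  " abundance_threshold=", cfg$abundance_threshold),
           extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(df)
  df[] <- lapply(df, function(col) if (inherits(col, "Date")) as.character(col) else col)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full core/CRT analysis pipeline
#'
#' Executes, per analysis group: abundance-occupancy ranking, explained
#' beta-diversity curve and core selection, CRT detection, per-date
#' contribution series for the core, CRT, and combined subcommunities,
#' per-unit-year stability for the same three subcommunities, and Spearman
#' driver correlations of the combined subcommunity's aggregate relative
#' abundance against any numeric metadata covariates. Every stage table is
#' written as TSV under `cfg$out_dir` with header comments recording
#' version, seed, and thresholds; reruns with an identical configuration are
#' byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a summary list per group: core/CRT sizes and ASV-count
#'   percentages, mean contributions, and the stability table.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stop("`cfg` must be a pipeline_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(cfg$sim)) {
    sim <- simulate_community(cfg$sim)
    counts <- sim$counts
    meta <- sim$metadata
    write_stage_tsv(sim$truth, file.path(cfg$out_dir, "truth.tsv"), cfg)
  } else {
    counts <- read_count_table(cfg$counts_path)
    meta <- read_sample_metadata(cfg$metadata_path)
  }
  if (!is.null(cfg$depth)) counts <- rarefy(counts, cfg$depth, cfg$seed)
  meta <- validate_sample_metadata(meta)
  meta <- meta[meta$sample_id %in% colnames(counts), , drop = FALSE]
  write_count_table(counts, file.path(cfg$out_dir, "counts.tsv"))
  write_stage_tsv(meta, file.path(cfg$out_dir, "metadata.tsv"), cfg)

  summaries <- list()
  for (gname in names(cfg$groups)) {
    gval <- cfg$groups[[gname]]
    g_samples <- if (is.null(gval)) meta$sample_id else {
      if (!cfg$group_var %in% names(meta)) {
        stop("grouping column '", cfg$group_var, "' not in metadata")
      }
      meta$sample_id[meta[[cfg$group_var]] %in% gval]
    }
    if (length(g_samples) < 2L) stop("group '", gname, "' has fewer than 2 samples")
    prefix <- function(f) file.path(cfg$out_dir, paste0(gname, "_", f))

    core <- core_microbiome(counts, g_samples, cfg$core_threshold)
    ranked_out <- core$ranked
    ranked_out$explained <- core$curve$explained
    ranked_out$is_core <- ranked_out$composite_rank <= core$k
    write_stage_tsv(ranked_out, prefix("core.tsv"), cfg)

    crt <- detect_crt(counts, g_samples, core$core_set, cfg$b_threshold,
                      cfg$abundance_threshold)
    write_stage_tsv(crt, prefix("crt.tsv"), cfg)
    crt_set <- crt$asv_id[crt$is_crt]

    subsets <- list(core = core$core_set, crt = crt_set,
                    core_plus_crt = c(core$core_set, crt_set))
    contrib <- list()
    for (sname in names(subsets)) {
      cs <- contribution_series(counts, meta, subsets[[sname]], g_samples)
      cs <- data.frame(subcommunity = sname, cs, stringsAsFactors = FALSE)
      contrib[[sname]] <- cs
    }
    contrib_all <- do.call(rbind, c(contrib, list(make.row.names = FALSE)))
    write_stage_tsv(contrib_all, prefix("contribution.tsv"), cfg)

    g_meta <- meta[meta$sample_id %in% g_samples, , drop = FALSE]
    stab <- do.call(rbind, c(lapply(names(subsets), function(sname) {
      st <- stability_table(counts[, g_samples, drop = FALSE], g_meta,
                            subsets[[sname]])
      data.frame(subcommunity = sname, st, stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
    write_stage_tsv(stab, prefix("stability.tsv"), cfg)

    cov_cols <- setdiff(names(g_meta)[vapply(g_meta, is.numeric, logical(1L))],
                        "year")
    drivers <- NULL
    if (length(cov_cols) > 0L) {
      rel <- suppressWarnings(relative_abundance(counts[, g_samples, drop = FALSE]))
      agg <- colSums(rel[rownames(rel) %in% subsets$core_plus_crt, , drop = FALSE])
      series <- data.frame(site = g_meta$site, date = g_meta$date,
                           value = agg[g_meta$sample_id],
                           stringsAsFactors = FALSE)
      drivers <- spearman_drivers(series, g_meta[, c("site", "date", cov_cols)])
      write_stage_tsv(drivers, prefix("drivers.tsv"), cfg)
    }

    n_total <- sum(rowSums(counts[, g_samples, drop = FALSE]) > 0)
    summaries[[gname]] <- list(
      n_asv = n_total, n_core = core$k, n_crt = length(crt_set),
      core_pct = pct_share(core$k, n_total),
      crt_pct = pct_share(length(crt_set), n_total),
      combined_pct = pct_share(core$k + length(crt_set), n_total),
      mean_contribution_pct = vapply(contrib, function(d) {
        mean(d$contribution_pct)
      }, numeric(1L)),
      stability = stab, drivers = drivers)
    sum_df <- data.frame(group = gname, n_asv = n_total, n_core = core$k,
                         n_crt = length(crt_set),
                         core_pct = summaries[[gname]]$core_pct,
                         crt_pct = summaries[[gname]]$crt_pct,
                         combined_pct = summaries[[gname]]$combined_pct,
                         mean_core_contribution_pct = summaries[[gname]]$mean_contribution_pct[["core"]],
                         mean_crt_contribution_pct = summaries[[gname]]$mean_contribution_pct[["crt"]],
                         stringsAsFactors = FALSE)
    write_stage_tsv(sum_df, prefix("summary.tsv"), cfg)
  }
  invisible(summaries)
}
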