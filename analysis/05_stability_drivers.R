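#!/usr/bin/env Rscript
# Temporal constancy (mean/sd of summed abundance) per site and year for the
# core, CRT and combined subcommunities, and Spearman correlations of the
# combined subcommunity's aggregate relative abundance with the simulated
# environmental covariates.

library(crtcore)

counts <- read_count_table("results/synthetic/counts.tsv")
meta <- read_sample_metadata("results/synthetic/metadata.tsv")
ranked <- read.delim("results/core_ranked.tsv")
crt <- read.delim("results/crt.tsv")

subsets <- list(core = ranked$asv_id[ranked$is_core],
                crt = crt$asv_id[crt$is_crt])
subsets$core_plus_crt <- unlist(subsets, use.names = FALSE)

stab <- do.call(rbind, lapply(names(subsets), function(nm) {
  data.frame(subcommunity = nm, stability_table(counts, meta, subsets[[nm]]))
}))
write.table(stab, "results/stability.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("median stability by subcommunity:\n")
print(round(tapply(stab$stability, stab$subcommunity, median,
                   na.rm = TRUE), 2))

# environmental drivers of the CRT contribution: per-date contribution vs
# date-mean covariates (events are site-synchronized, so the date is the unit)
crt_contrib <- contribution_series(counts, meta, subsets$crt)
series <- data.frame(date = crt_contrib$date, value = crt_contrib$contribution_pct)
cov_cols <- c("RU_DISM3S", "NITRATE", "TURBIDITY_NTU", "AMIA_AMN", "AVG_TEMP_C")
by_date <- aggregate(meta[, cov_cols], by = list(date = meta$date), FUN = mean)
drivers <- spearman_drivers(series, by_date)
write.table(drivers, "results/drivers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(drivers)
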