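#!/usr/bin/env Rscript
# Step 4: the statistical layer. Re-estimates each culture's growth rate
# from its OD regrowth series, fits the volume-growth size law to the
# nutrient-titration cultures (including the base medium), tests whether
# ammonium- and glucose-limited cultures collapse onto one line, and
# classifies the per-class surface-to-volume trends.

library(rodsize)

in_dir <- "results/study"
out_dir <- "results/fits"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

summaries <- read_geometry_tsv(file.path(in_dir, "summaries.tsv"))
od <- read.csv(file.path(in_dir, "od_series.csv"))

# growth rates re-estimated from OD: ln(OD) ~ time per culture
gr <- do.call(rbind, lapply(split(od, od$culture_id), function(d) {
  f <- fit_growth_rate(d$time_h, d$od)
  data.frame(culture_id = d$culture_id[1], mu_hat = f$mu,
             mu_se = f$mu_se, r2 = f$r2)
}))
write.table(gr, file.path(out_dir, "growth_rates.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
m <- merge(summaries, gr, by = "culture_id")
cat(sprintf("growth-rate refit vs configured: max |d mu| = %.4f /h\n",
            max(abs(m$mu_hat - m$growth_rate))))

# size-law fits (one point per culture, unweighted OLS, 95% CI)
titr <- c("base", "ammonium_titration", "glucose_titration")
fits <- list(
  volume = fit_size_law(summaries, "mean_volume", classes = titr),
  surface = fit_size_law(summaries, "mean_surface", classes = titr),
  length = fit_size_law(summaries, "mean_length", classes = titr),
  width = fit_size_law(summaries, "mean_width", classes = titr),
  sv = fit_size_law(summaries, "mean_sv", classes = titr))
collapse <- test_collapse(summaries, "mean_volume")
write_fits_json(fits, collapse, file.path(out_dir, "size_law_fits.json"))

cat(sprintf("volume size law: V = %.1f mu + %.1f um^3 (slope CI [%.1f, %.1f])\n",
            fits$volume$slope, fits$volume$intercept,
            fits$volume$ci95_slope[1], fits$volume$ci95_slope[2]))
cat(sprintf("ammonium/glucose collapse: F(%d, %d) = %.2f, p = %.3f\n",
            collapse$df_num, collapse$df_den, collapse$f_stat,
            collapse$p_value))

trends <- classify_sv_trends(summaries)
write.table(trends$table, file.path(out_dir, "sv_trends.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("surface-to-volume trends vs growth rate:\n")
print(trends$table, row.names = FALSE)
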