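#!/usr/bin/env Rscript
# Step 5: figure panels. Culture-mean geometry against growth rate per
# modulation class (volume with the titration fit, surface-to-volume with
# per-class trend lines, surface, length, width) and the consistency
# panel of surface-to-volume against width.

library(rodsize)
library(ggplot2)

in_dir <- "results/study"
out_dir <- "results/figures"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

s <- read_geometry_tsv(file.path(in_dir, "summaries.tsv"))
pal <- c(base = "grey25", ammonium_titration = "#00a6c8",
         glucose_titration = "#3aa655", cycloheximide = "#e58a00",
         nitrogen_source = "grey65")

base_theme <- theme_bw(base_size = 10) +
  theme(legend.position = "bottom", legend.title = element_blank())

panel_vs_mu <- function(metric, ylab) {
  ggplot(s, aes(growth_rate, .data[[metric]], colour = modulation,
                shape = modulation)) +
    geom_point(size = 2.4) +
    labs(x = "growth rate (1/h)", y = ylab) +
    scale_colour_manual(values = pal) +
    base_theme
}

titr <- s[s$modulation %in% c("base", "ammonium_titration",
                              "glucose_titration"), ]
fit_v <- fit_size_law(s)
p_vol <- panel_vs_mu("mean_volume", "mean volume (um^3)") +
  geom_abline(slope = fit_v$slope, intercept = fit_v$intercept,
              colour = "grey25")
ggsave(file.path(out_dir, "volume_vs_mu.pdf"), p_vol, width = 5,
       height = 4)

trend <- classify_sv_trends(s)
ab <- do.call(rbind, lapply(names(trend$fits), function(cl)
  data.frame(modulation = cl, slope = trend$fits[[cl]]$slope,
             intercept = trend$fits[[cl]]$intercept)))
ab <- ab[ab$modulation != "nitrogen_source", ]
p_sv <- panel_vs_mu("mean_sv", "mean S/V (1/um)") +
  geom_abline(data = ab, aes(slope = slope, intercept = intercept,
                             colour = modulation), linetype = 2)
ggsave(file.path(out_dir, "sv_vs_mu.pdf"), p_sv, width = 5, height = 4)

for (m in c("mean_surface", "mean_length", "mean_width")) {
  p <- panel_vs_mu(m, sub("mean_", "mean ", m))
  ggsave(file.path(out_dir, paste0(m, "_vs_mu.pdf")), p, width = 5,
         height = 4)
}

p_svw <- ggplot(s, aes(mean_width, mean_sv, colour = modulation)) +
  geom_point(size = 2.4) +
  stat_function(fun = function(w) 4 / w, colour = "grey50",
                linetype = 3) +
  labs(x = "mean width (um)", y = "mean S/V (1/um)") +
  scale_colour_manual(values = pal) +
  base_theme
ggsave(file.path(out_dir, "sv_vs_width.pdf"), p_svw, width = 5,
       height = 4)

cat("wrote figure panels to", out_dir, "\n")
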