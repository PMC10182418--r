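#' Specify one steady-state culture
#'
#' @param modulation growth-rate modulation class: one of
#'   `"base"`, `"ammonium_titration"`, `"glucose_titration"`,
#'   `"cycloheximide"`, `"nitrogen_source"`.
#' @param dose_label free-text dose / condition label (e.g.
#'   `"NH4Cl 25 mg/L"` or `"proline 20 mM"`).
#' @param growth_rate steady-state specific growth rate, per hour.
#' @param n_cells number of division-stage cells sampled from the
#'   culture.
#' @param seed per-culture RNG seed.
#' @param on_line for `nitrogen_source` cultures: `TRUE` if the culture's
#'   mean volume lies on the titration volume-growth line (the
#'   proline-like case and the ammonium reference), `FALSE` if it carries
#'   the class volume offset. Ignored for other classes.
#' @return an object of class `"culture_spec"`.
#' @export
culture_spec <- function(modulation, dose_label, growth_rate,
                         n_cells = 50L, seed = 1L, on_line = NA) {
  modulation <- match.arg(modulation, modulation_classes())
  if (growth_rate <= 0) stop("growth_rate must be positive")
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("n_cells must be at least 1")
  structure(list(modulation = modulation, dose_label = dose_label,
                 growth_rate = growth_rate, n_cells = n_cells,
                 seed = as.integer(seed), on_line = on_line),
            class = "culture_spec")
}

#' Growth-rate modulation classes
#' @return character vector of the recognised class names.
#' @export
modulation_classes <- function() {
  c("base", "ammonium_titration", "glucose_titration", "cycloheximide",
    "nitrogen_source")
}

#' Specify the generative size law of a simulated study
#'
#' Defines how steady-state culture means depend on the growth rate: mean
#' division volume follows the line `slope_V * mu + intercept_V` for the
#' nutrient-titration classes and the base medium; cycloheximide cultures
#' follow their own shallow line (`slope_V_chx`, `intercept_V_chx`);
#' nitrogen-source cultures not flagged `on_line` sit
#' `offset_factor_nsource` times above the main line.
#' Mean cell width per class follows `w(mu) = a + b * mu` (the
#' `width_rules`), which induces the class-specific surface-to-volume
#' trends; length and surface then follow from spherocylinder geometry
#' under the slice formulas (volume `pi r^2 (L - 2r) + (4/3) pi r^3`,
#' surface `2 pi r (L - 2r) + pi^2 r^2` for half-width `r = w/2`).
#'
#' @param slope_V,intercept_V volume-growth line, um^3 per (1/h) and um^3.
#' @param slope_V_chx,intercept_V_chx separate volume line for
#'   translation-inhibited (cycloheximide) cultures, whose volume
#'   increases slightly as growth rate decreases; the default crosses the
#'   main titration line at the base-medium growth rate (~0.26/h).
#' @param cell_cv relative SD of per-cell volume (lognormal, mean
#'   preserved); must be < 0.5.
#' @param width_cv_factor per-cell width CV as a fraction of `cell_cv`
#'   (widths vary much less than volumes within a culture).
#' @param width_rules named list `class -> c(a, b)` of mean-width rules.
#' @param offset_factor_nsource multiplicative volume offset for
#'   nitrogen-source cultures off the line (observed range ~2-3).
#' @param od0 optical density at regrowth release.
#' @param od_noise multiplicative lognormal noise SD of OD readings.
#' @return an object of class `"size_law_spec"`.
#' @export
size_law_spec <- function(slope_V = 300, intercept_V = 30,
                          slope_V_chx = -50, intercept_V_chx = 121,
                          cell_cv = 0.1,
                          width_cv_factor = 0.2,
                          width_rules = default_width_rules(),
                          offset_factor_nsource = 2.5,
                          od0 = 0.3, od_noise = 0.02) {
  if (intercept_V <= 0) stop("intercept_V must be positive")
  if (cell_cv < 0 || cell_cv >= 0.5) stop("cell_cv must be in [0, 0.5)")
  if (od0 <= 0) stop("od0 must be positive")
  stopifnot(all(modulation_classes() %in% names(width_rules)))
  structure(list(slope_V = slope_V, intercept_V = intercept_V,
                 slope_V_chx = slope_V_chx,
                 intercept_V_chx = intercept_V_chx,
                 cell_cv = cell_cv, width_cv_factor = width_cv_factor,
                 width_rules = width_rules,
                 offset_factor_nsource = offset_factor_nsource,
                 od0 = od0, od_noise = od_noise),
            class = "size_law_spec")
}

#' Default mean-width rules per modulation class
#'
#' `w(mu) = a + b * mu` in micrometres. Ammonium-limited cells are
#' markedly thinner at low growth rates (steep positive b), glucose-limited
#' cells moderately so, cycloheximide-treated cells slightly wider at low
#' growth rates (negative b), nitrogen-source and base cultures hold a
#' constant width. All rules meet near w = 4 um at the base-medium growth
#' rate (~0.26/h), so the classes are continuous with the base culture.
#'
#' @return named list `class -> c(a, b)`.
#' @export
default_width_rules <- function() {
  list(base = c(4.0, 0),
       ammonium_titration = c(2.83, 4.5),
       glucose_titration = c(3.61, 1.5),
       cycloheximide = c(4.39, -1.5),
       nitrogen_source = c(4.0, 0))
}

# Spherocylinder length and surface given volume and width, under the
# slice formulas. Returns c(length, surface).
spherocyl_from_vw <- function(volume, width) {
  r <- width / 2
  lc <- (volume - 4 / 3 * pi * r^3) / (pi * r^2)
  if (any(lc < 0)) {
    warning("volume too small for width; clamping to a sphere-like cell")
    lc <- pmax(lc, 0)
  }
  cbind(length = lc + 2 * r, surface = 2 * pi * r * lc + pi^2 * r^2)
}

target_mean_volume <- function(culture, law) {
  if (culture$modulation == "cycloheximide")
    return(law$slope_V_chx * culture$growth_rate + law$intercept_V_chx)
  v <- law$slope_V * culture$growth_rate + law$intercept_V
  if (culture$modulation == "nitrogen_source" &&
      !isTRUE(culture$on_line)) v <- v * law$offset_factor_nsource
  v
}

#' Simulate one steady-state culture
#'
#' Draws `n_cells` division-stage cell geometries whose expected mean
#' volume sits on the configured size law (lognormal per-cell volumes,
#' mean-preserving, CV `cell_cv`), with class-rule mean width and
#' spherocylinder-derived length/surface, plus an optical-density regrowth
#' series `od0 * exp(mu t)` sampled every 0.5 h for 3 h with optional
#' multiplicative noise. Deterministic given the culture seed.
#'
#' @param culture a [culture_spec()].
#' @param law a [size_law_spec()].
#' @return list with `cells` (per-cell data.frame: `culture_id`,
#'   `modulation`, `dose_label`, `growth_rate`, `cell_id`, `length_um`,
#'   `width_um`, `surface_um2`, `volume_um3`, `sv_ratio_per_um`) and `od`
#'   (data.frame: `culture_id`, `time_h`, `od`).
#' @export
simulate_culture <- function(culture, law = size_law_spec()) {
  stopifnot(inherits(culture, "culture_spec"),
            inherits(law, "size_law_spec"))
  mu <- culture$growth_rate
  v_mean <- target_mean_volume(culture, law)
  rule <- law$width_rules[[culture$modulation]]
  w_mean <- rule[1L] + rule[2L] * mu
  if (w_mean <= 0) stop("width rule gives non-positive width at this mu")
  cid <- paste0(culture$modulation, ":", culture$dose_label)

  with_local_seed(culture$seed, {
    n <- culture$n_cells
    v <- if (law$cell_cv > 0) {
      sdl <- sqrt(log(1 + law$cell_cv^2))
      stats::rlnorm(n, log(v_mean) - sdl^2 / 2, sdl)
    } else rep(v_mean, n)
    w_cv <- law$cell_cv * law$width_cv_factor
    w <- if (w_cv > 0) {
      sdw <- sqrt(log(1 + w_cv^2))
      stats::rlnorm(n, log(w_mean) - sdw^2 / 2, sdw)
    } else rep(w_mean, n)
    ls <- spherocyl_from_vw(v, w)
    cells <- data.frame(culture_id = cid, modulation = culture$modulation,
                        dose_label = culture$dose_label, growth_rate = mu,
                        cell_id = sprintf("%s/c%03d", cid, seq_len(n)),
                        length_um = ls[, "length"], width_um = w,
                        surface_um2 = ls[, "surface"], volume_um3 = v,
                        sv_ratio_per_um = ls[, "surface"] / v)
    t_h <- seq(0, 3, by = 0.5)
    od <- law$od0 * exp(mu * t_h)
    if (law$od_noise > 0)
      od <- od * stats::rlnorm(length(t_h), -log(1 + law$od_noise^2) / 2,
                               sqrt(log(1 + law$od_noise^2)))
    list(cells = cells,
         od = data.frame(culture_id = cid, time_h = t_h, od = od))
  })
}

#' Default study panel of culture specifications
#'
#' Mirrors the study design: 17 titration-arm cultures (1 base medium +
#' 6 ammonium-chloride + 5 glucose + 5 cycloheximide doses, growth rates
#' ~0.09-0.26/h via saturating dose-to-mu maps) plus 6 nitrogen-source /
#' reference cultures (ammonium reference and proline-like on the volume
#' line; serine-, phenylalanine-, glycine- and tryptophan-like offset
#' above it).
#'
#' @param seed study seed; per-culture seeds are derived from it.
#' @param n_cells cells sampled per culture.
#' @return list of [culture_spec()] objects.
#' @export
default_panel <- function(seed = 1L, n_cells = 50L) {
  monod <- function(dose, mumax, k) mumax * dose / (dose + k)
  inhib <- function(dose, mu0, ki) mu0 / (1 + dose / ki)
  specs <- list(list("base", "EMM2", 0.26))
  for (d in c(10, 15, 20, 30, 40, 50))
    specs <- c(specs, list(list("ammonium_titration",
                                sprintf("NH4Cl %d mg/L", d),
                                monod(d, 0.30, 25))))
  for (d in c(0.5, 0.75, 1.0, 1.5, 2.0))
    specs <- c(specs, list(list("glucose_titration",
                                sprintf("glucose %.2f g/L", d),
                                monod(d, 0.30, 0.6))))
  for (d in c(0.5, 1.0, 1.5, 2.0, 3.0))
    specs <- c(specs, list(list("cycloheximide",
                                sprintf("cycloheximide %.1f mg/L", d),
                                inhib(d, 0.26, 3.0))))
  nsrc <- list(list("Amm 93.5 mM", 0.26, TRUE),
               list("Pro 20 mM", 0.11, TRUE),
               list("Ser 20 mM", 0.14, FALSE),
               list("Phe 20 mM", 0.12, FALSE),
               list("Gly 20 mM", 0.10, FALSE),
               list("Trp 20 mM", 0.06, FALSE))
  for (s in nsrc)
    specs <- c(specs, list(list("nitrogen_source", s[[1L]], s[[2L]],
                                s[[3L]])))
  lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    culture_spec(modulation = s[[1L]], dose_label = s[[2L]],
                 growth_rate = s[[3L]], n_cells = n_cells,
                 seed = as.integer((as.numeric(seed) * 131 + i) %%
                                     2147483647),
                 on_line = if (length(s) >= 4L) s[[4L]] else NA)
  })
}

#' Simulate a whole steady-state study
#'
#' Runs [simulate_culture()] for every culture in the panel and stacks
#' the per-cell tables, optical-density series and per-culture summaries.
#'
#' @param panel list of [culture_spec()] (default [default_panel()]).
#' @param law a [size_law_spec()].
#' @return list with `cells`, `od` (stacked data.frames) and `summaries`
#'   (one row per culture, from [summarize_culture()]).
#' @export
simulate_study <- function(panel = default_panel(),
                           law = size_law_spec()) {
  if (!length(panel)) stop("panel must contain at least one culture")
  sims <- lapply(panel, simulate_culture, law = law)
  cells <- do.call(rbind, lapply(sims, `[[`, "cells"))
  od <- do.call(rbind, lapply(sims, `[[`, "od"))
  list(cells = cells, od = od, summaries = summarize_study(cells))
}
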