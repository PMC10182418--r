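#' Fit a steady-state growth rate from an optical-density regrowth series
#'
#' Ordinary least squares of `log(OD)` on time: the slope is the specific
#' growth rate mu (per hour) and `exp(intercept)` the density at release.
#'
#' @param times time points in hours (strictly increasing, >= 3 points),
#'   or a data.frame with columns `time_h` and `od`.
#' @param od optical-density readings (positive) when `times` is a vector.
#' @return an object of class `"growth_rate_fit"`: list with `mu`,
#'   `mu_se`, `od0_hat`, `r2`, `n`.
#' @export
fit_growth_rate <- function(times, od = NULL) {
  if (is.data.frame(times)) {
    od <- times$od
    times <- times$time_h
  }
  if (length(times) < 3L) stop("need at least 3 time points")
  if (any(od <= 0)) stop("optical density must be positive")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  fit <- stats::lm(log(od) ~ times)
  sm <- suppressWarnings(summary(fit))   # exact exponentials fit perfectly
  ly <- log(od)
  tss <- sum((ly - mean(ly))^2)
  rss <- sum(stats::residuals(fit)^2)
  # a constant series is fitted exactly; avoid the 0/0 ratio
  r2 <- if (tss < 1e-15 * length(ly)) 1 else 1 - rss / tss
  structure(list(mu = unname(stats::coef(fit)[2L]),
                 mu_se = sm$coefficients[2L, 2L],
                 od0_hat = unname(exp(stats::coef(fit)[1L])),
                 r2 = r2, n = length(times)),
            class = "growth_rate_fit")
}

#' Summarise a culture's division-stage cell geometry
#'
#' Per-metric arithmetic mean and standard error of the mean over the
#' culture's cells. The surface-to-volume summary is the mean of per-cell
#' S/V ratios; the ratio of mean surface to mean volume is also reported
#' as a diagnostic column (`sv_of_means`).
#'
#' @param cells data.frame of per-cell geometry with columns `length_um`,
#'   `width_um`, `surface_um2`, `volume_um3`, `sv_ratio_per_um`, and
#'   (unless supplied via `meta`) `culture_id`, `modulation`,
#'   `growth_rate`.
#' @param meta optional named list overriding `culture_id`, `modulation`,
#'   `dose_label`, `growth_rate`.
#' @return one-row data.frame with `culture_id`, `modulation`,
#'   `dose_label`, `growth_rate`, `n_cells`, and `mean_` / `sem_` columns
#'   for `length`, `width`, `surface`, `volume`, `sv`.
#' @export
summarize_culture <- function(cells, meta = NULL) {
  if (!nrow(cells)) stop("empty cell table")
  pick <- function(field, default = NA) {
    if (!is.null(meta[[field]])) meta[[field]]
    else if (field %in% names(cells)) cells[[field]][1L]
    else default
  }
  n <- nrow(cells)
  sem <- function(x) if (n > 1L) stats::sd(x) / sqrt(n) else 0
  data.frame(culture_id = pick("culture_id", "culture"),
             modulation = pick("modulation"),
             dose_label = pick("dose_label"),
             growth_rate = pick("growth_rate"),
             n_cells = n,
             mean_length = mean(cells$length_um),
             sem_length = sem(cells$length_um),
             mean_width = mean(cells$width_um),
             sem_width = sem(cells$width_um),
             mean_surface = mean(cells$surface_um2),
             sem_surface = sem(cells$surface_um2),
             mean_volume = mean(cells$volume_um3),
             sem_volume = sem(cells$volume_um3),
             mean_sv = mean(cells$sv_ratio_per_um),
             sem_sv = sem(cells$sv_ratio_per_um),
             sv_of_means = mean(cells$surface_um2) / mean(cells$volume_um3))
}

#' Summarise every culture in a stacked per-cell table
#'
#' @param cells stacked per-cell geometry table with a `culture_id`
#'   column (as produced by [simulate_study()]).
#' @return data.frame, one row per culture.
#' @export
summarize_study <- function(cells) {
  parts <- split(cells, cells$culture_id)
  out <- do.call(rbind, lapply(parts, summarize_culture))
  rownames(out) <- NULL
  out[order(out$modulation, out$growth_rate), ]
}

#' Linear size-law fit of a culture-mean metric against growth rate
#'
#' Unweighted ordinary least squares with one point per culture
#' (optionally inverse-SEM^2 weighted), with 95% confidence intervals from
#' the t distribution on the residual degrees of freedom.
#'
#' @param summaries per-culture summary table ([summarize_study()]).
#' @param metric summary column to regress (default `"mean_volume"`).
#' @param classes modulation classes included; default the titration
#'   collapse set (ammonium + glucose, including the base medium).
#' @param weighted if `TRUE`, weight cultures by `1 / sem^2`.
#' @return an object of class `"size_law_fit"`: list with `metric`,
#'   `classes_included`, `slope`, `intercept`, `ci95_slope`,
#'   `ci95_intercept`, `residual_df`, `sigma`, `n_cultures`, `fit` (the
#'   underlying `lm`).
#' @export
fit_size_law <- function(summaries,
                         metric = "mean_volume",
                         classes = c("base", "ammonium_titration",
                                     "glucose_titration"),
                         weighted = FALSE) {
  stopifnot(metric %in% names(summaries))
  d <- summaries[summaries$modulation %in% classes, , drop = FALSE]
  if (nrow(d) < 3L)
    stop("need at least 3 cultures after class filtering")
  wts <- NULL
  if (weighted) {
    sem_col <- sub("^mean_", "sem_", metric)
    stopifnot(sem_col %in% names(d))
    wts <- 1 / pmax(d[[sem_col]], 1e-12)^2
  }
  d$.y <- d[[metric]]
  fit <- stats::lm(.y ~ growth_rate, data = d, weights = wts)
  # summary.lm warns on numerically perfect fits (noise-free input)
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  structure(list(metric = metric, classes_included = classes,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 ci95_slope = unname(ci[2L, ]),
                 ci95_intercept = unname(ci[1L, ]),
                 residual_df = stats::df.residual(fit),
                 sigma = sm$sigma,
                 n_cultures = nrow(d), fit = fit),
            class = "size_law_fit")
}

#' @export
print.size_law_fit <- function(x, ...) {
  cat(sprintf(
    "<size_law_fit: %s ~ mu over %d cultures (%s)>\n  slope %.4g [%.4g, %.4g], intercept %.4g [%.4g, %.4g]\n",
    x$metric, x$n_cultures, paste(x$classes_included, collapse = ", "),
    x$slope, x$ci95_slope[1L], x$ci95_slope[2L],
    x$intercept, x$ci95_intercept[1L], x$ci95_intercept[2L]))
  invisible(x)
}

#' Test whether two modulation classes share one size-law line
#'
#' Extra-sum-of-squares F-test comparing a single shared line (2
#' parameters) against separate per-class lines (4 parameters) for the
#' chosen culture-mean metric. A small F (large p) supports the collapse
#' of both classes onto one line.
#'
#' @param summaries per-culture summary table.
#' @param metric summary column (default `"mean_volume"`).
#' @param class_a,class_b the two modulation classes compared (each needs
#'   at least 3 cultures).
#' @param include_base if `TRUE`, base-medium cultures are appended to
#'   both the shared and per-class models as members of each class's fit
#'   set; default `FALSE` (classes compared on their own cultures).
#' @return an object of class `"collapse_test"`: list with `f_stat`,
#'   `p_value`, `df_num`, `df_den`, `shared_fit`, `separate_fits`.
#' @export
test_collapse <- function(summaries, metric = "mean_volume",
                          class_a = "ammonium_titration",
                          class_b = "glucose_titration") {
  stopifnot(metric %in% names(summaries))
  d <- summaries[summaries$modulation %in% c(class_a, class_b), ,
                 drop = FALSE]
  na <- sum(d$modulation == class_a)
  nb <- sum(d$modulation == class_b)
  if (na < 3L || nb < 3L)
    stop("each class needs at least 3 cultures")
  d$.y <- d[[metric]]
  d$.cls <- factor(d$modulation)
  m0 <- stats::lm(.y ~ growth_rate, data = d)
  m1 <- stats::lm(.y ~ growth_rate * .cls, data = d)
  an <- stats::anova(m0, m1)
  f <- an$F[2L]; p <- an$`Pr(>F)`[2L]
  # jointly collinear points: both models fit perfectly, F is 0 by
  # convention (guard against ratios of numerically-zero residuals)
  rss0 <- sum(stats::residuals(m0)^2)
  if (!is.finite(f) || rss0 < 1e-12 * sum(d$.y^2)) { f <- 0; p <- 1 }
  structure(list(f_stat = f, p_value = p,
                 df_num = an$Df[2L], df_den = an$Res.Df[2L],
                 shared_fit = fit_size_law(d, metric,
                                           classes = c(class_a, class_b)),
                 separate_fits = list(
                   fit_size_law(d, metric, classes = class_a),
                   fit_size_law(d, metric, classes = class_b))),
            class = "collapse_test")
}

#' @export
print.collapse_test <- function(x, ...) {
  cat(sprintf(
    "<collapse_test: F(%d, %d) = %.3f, p = %.4g (shared line %s)>\n",
    x$df_num, x$df_den, x$f_stat, x$p_value,
    if (x$p_value > 0.05) "not rejected" else "rejected"))
  invisible(x)
}

#' Classify per-class surface-to-volume trends against growth rate
#'
#' Fits `mean S/V ~ mu` separately for each titration class (each fit
#' including the base-medium culture, which anchors the unperturbed end
#' of every titration) and for the nitrogen-source cultures alone, and
#' labels each slope `"negative"`, `"positive"` or `"none"` by whether
#' its 95% confidence interval excludes zero.
#'
#' @param summaries per-culture summary table.
#' @param metric summary column (default `"mean_sv"`).
#' @return list with `table` (data.frame: `class`, `n_cultures`, `slope`,
#'   `ci_lo`, `ci_hi`, `label`) and `fits` (named list of
#'   `"size_law_fit"`).
#' @export
classify_sv_trends <- function(summaries, metric = "mean_sv") {
  sets <- list(
    ammonium_titration = c("ammonium_titration", "base"),
    glucose_titration = c("glucose_titration", "base"),
    cycloheximide = c("cycloheximide", "base"),
    nitrogen_source = "nitrogen_source")
  fits <- list()
  rows <- list()
  for (cls in names(sets)) {
    f <- fit_size_law(summaries, metric = metric, classes = sets[[cls]])
    lab <- if (f$ci95_slope[1L] > 0) "positive"
           else if (f$ci95_slope[2L] < 0) "negative"
           else "none"
    fits[[cls]] <- f
    rows[[cls]] <- data.frame(class = cls, n_cultures = f$n_cultures,
                              slope = f$slope, ci_lo = f$ci95_slope[1L],
                              ci_hi = f$ci95_slope[2L], label = lab)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}
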