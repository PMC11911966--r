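# Statistical layer: cross-sectional regressions per survey day, mixed
# models with plots nested in blocks, and a table-level generator used for
# parameter-recovery checks of the statistical machinery.

#' Cross-sectional regressions per survey day
#'
#' Ordinary least squares of \code{response} on \code{predictor} fitted
#' separately at each day of year; strictly positive variables may be
#' natural-log transformed first (volumes, diversities and stability
#' metrics are logged in the seasonal analyses; NBE, which can be negative,
#' never is).
#'
#' @param table data.frame with the response, predictor and \code{doy}
#'   columns (one row per plot per doy, or per plot if \code{by = NULL}).
#' @param response,predictor column names.
#' @param by grouping column, default \code{"doy"}; NULL fits one model.
#' @param log_response,log_predictor apply \code{log()} first.
#' @param min_n minimum rows per group (default 10).
#' @return data.frame with group, slope, intercept, r2, p, n.
#' @export
fit_cross_sections <- function(table, response, predictor, by = "doy",
                               log_response = FALSE, log_predictor = FALSE,
                               min_n = 10) {
  stopifnot(all(c(response, predictor) %in% names(table)))
  groups <- if (is.null(by)) list(all = table)
  else split(table, table[[by]])
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    y <- d[[response]]; x <- d[[predictor]]
    ok <- is.finite(y) & is.finite(x)
    if (log_response) ok <- ok & y > 0
    if (log_predictor) ok <- ok & x > 0
    y <- y[ok]; x <- x[ok]
    if (length(y) < min_n)
      stopf("fewer than %d usable plots in group %s", min_n, g)
    if (stats::sd(x) == 0) stopf("zero predictor variance in group %s", g)
    if (log_response) y <- log(y)
    if (log_predictor) x <- log(x)
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    data.frame(group = g, slope = sm$coefficients["x", "Estimate"],
               intercept = sm$coefficients["(Intercept)", "Estimate"],
               r2 = sm$r.squared,
               p = sm$coefficients["x", "Pr(>|t|)"],
               n = length(y), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(by)) names(out)[1] <- by
  out
}

#' Mixed model with plots nested in blocks
#'
#' Fits \code{response ~ predictor * doy + (1 | block/plot)} — the
#' repeated-measures structure for seasonal metric panels, with DOY as a
#' continuous covariate and its interaction with the predictor. A singular
#' nested fit falls back, with a warning, to a plot-only random intercept.
#'
#' @param table panel data.frame with columns \code{response},
#'   \code{predictor}, \code{doy}, \code{plot_id}, \code{block}.
#' @param response,predictor column names.
#' @param log_response,log_predictor apply \code{log()} first.
#' @return list with \code{fit} (the \code{lmerMod}), \code{fixed}
#'   (coefficient table incl. Satterthwaite p-values) and
#'   \code{interaction_p}.
#' @export
fit_mixed_model <- function(table, response, predictor,
                            log_response = FALSE, log_predictor = FALSE) {
  d <- data.frame(y = table[[response]], x = table[[predictor]],
                  doy = table$doy, plot_id = table$plot_id,
                  block = table$block)
  d <- d[is.finite(d$y) & is.finite(d$x) & !is.na(d$plot_id), ]
  if (log_response) { d <- d[d$y > 0, ]; d$y <- log(d$y) }
  if (log_predictor) { d <- d[d$x > 0, ]; d$x <- log(d$x) }
  if (stats::sd(d$y) == 0) stopf("degenerate fit: constant response")
  d$doy_c <- scale(d$doy)[, 1]  # center DOY for a well-scaled interaction
  fit <- suppressMessages(
    lmerTest::lmer(y ~ x * doy_c + (1 | block / plot_id), data = d))
  if (lme4::isSingular(fit)) {
    warnf("singular block/plot fit; falling back to plot-only random intercept")
    fit <- suppressMessages(
      lmerTest::lmer(y ~ x * doy_c + (1 | plot_id), data = d))
  }
  fixed <- stats::coef(summary(fit))
  list(fit = fit, fixed = fixed,
       interaction_p = fixed["x:doy_c", "Pr(>|t|)"])
}

#' Simulate an analysis table with a known causal chain
#'
#' Table-level generator for parameter-recovery checks of the regression,
#' mixed-model and SEM machinery. Two correlated latent axes (Diversity,
#' Variability) emit three indicators each; a stability core follows
#' \code{b_var_ss * Variability + b_div_ss * Diversity + noise}; the
#' stability metrics SS_dD and SS_FC express that core on a positive scale
#' while SS_HHcv is mostly noise; NBE follows
#' \code{b_ss_nbe * core + b_var_nbe * Variability + b_div_nbe * Diversity
#' + noise}. With all coefficients zero the generator is a null model. A
#' per-DOY metric panel with an optional volume x DOY interaction
#' (\code{b_vol_doy}) accompanies the plot table.
#'
#' @param n_plots number of plots (default 150).
#' @param doys survey days for the panel.
#' @param b_var_ss,b_div_ss,b_ss_nbe,b_var_nbe,b_div_nbe structural
#'   coefficients of the injected chain.
#' @param b_vol_doy volume x DOY interaction on the panel metric.
#' @param n_blocks blocks (default 3).
#' @param seed integer RNG seed.
#' @return list with \code{plot_table} and \code{panel}.
#' @export
simulate_analysis_table <- function(n_plots = 150,
                                    doys = c(100, 138, 163, 188, 215, 250,
                                             261, 297),
                                    b_var_ss = 0.6, b_div_ss = 0.2,
                                    b_ss_nbe = 0.6, b_var_nbe = 0.2,
                                    b_div_nbe = 0, b_vol_doy = 0,
                                    n_blocks = 3, seed = 1) {
  set.seed(derive_seed(seed, "table"))
  div <- stats::rnorm(n_plots)
  var_l <- 0.3 * div + sqrt(1 - 0.3^2) * stats::rnorm(n_plots)
  ind <- function(l) 0.8 * l + 0.6 * stats::rnorm(n_plots)
  core <- b_div_ss * div + b_var_ss * var_l + stats::rnorm(n_plots, 0, 0.6)
  nbe_v <- b_ss_nbe * core + b_var_nbe * var_l + b_div_nbe * div +
    stats::rnorm(n_plots, 0, 0.6)
  volume <- exp(1 + 0.5 * stats::rnorm(n_plots))
  plot_table <- data.frame(
    plot_id = sprintf("p%03d", seq_len(n_plots)),
    block = sprintf("b%d", (seq_len(n_plots) - 1) %% n_blocks + 1),
    richness = ind(div), pd = ind(div), fd = ind(div),
    var_tax = ind(var_l), var_phy = ind(var_l), var_fun = ind(var_l),
    volume = volume,
    ss_dD = exp(0.30 * core) * 8,
    ss_fc = exp(0.25 * core) * 5,
    ss_hhcv = exp(0.30 * (0.1 * core + stats::rnorm(n_plots))) * 4,
    nbe = nbe_v,
    stringsAsFactors = FALSE
  )
  doy_c <- (doys - mean(doys)) / stats::sd(doys)
  panel <- do.call(rbind, lapply(seq_along(doys), function(k) {
    data.frame(plot_id = plot_table$plot_id, block = plot_table$block,
               doy = doys[k],
               metric = 1 + 0.2 * log(volume) + 0.1 * doy_c[k] +
                 b_vol_doy * log(volume) * doy_c[k] +
                 0.3 * core + stats::rnorm(n_plots, 0, 0.3),
               stringsAsFactors = FALSE)
  }))
  list(plot_table = plot_table, panel = panel)
}
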