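# End-to-end pipeline: simulate (or ingest) the study, condition clouds,
# compute structural metrics and stability, ground-based productivity and
# NBE, diversity and variability, and fit the statistical layer.

#' Default pipeline configuration
#'
#' Study conditions of the synthetic pipeline: a 12-species pool (4
#' evergreen), three blocks, the eight survey days of the seasonal
#' campaign, and a 100 pulses/m^2 density (clouds are later decimated on a
#' 1 cm grid, so metric values are density-insensitive past this point).
#'
#' @param seed master seed.
#' @return named list of configuration entries.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    n_species = 12, n_evergreen = 4,
    n_blocks = 3, plots_per_richness = 2,
    richness_levels = c(1, 2, 4, 6, 12),
    doys = c(100, 138, 163, 188, 215, 250, 261, 297),
    density = 100,
    complementarity = 0.5, mortality = 0.05,
    buffer_m = -0.5, sor_k = 30, sor_quantile = 0.975, z_min = 0.25,
    decimate_edge = 0.01,
    q = 0.999, scales = default_scales(),
    fit_sem = FALSE, fit_mixed = TRUE
  )
}

#' Run the full synthetic-study pipeline
#'
#' Simulates the study under \code{config}, conditions every survey cloud
#' (normalize, clip with the negative buffer, SOR, decimate), computes the
#' three structural metrics per plot and survey, their seasonal stability,
#' wood volumes, AWP, NBE with its complementarity/selection partition,
#' diversity and variability, then assembles the per-plot analysis table
#' and fits the statistical layer. With a fixed seed, output is
#' deterministic.
#'
#' @param config list as from \code{\link{default_config}}; missing entries
#'   take their defaults.
#' @param out_dir optional directory: writes tidy CSV tables and a JSON
#'   summary.
#' @return list with \code{pool}, \code{design}, \code{truth},
#'   \code{metrics} (per plot x doy), \code{stability},
#'   \code{productivity}, \code{diversity}, \code{table} (merged analysis
#'   table), \code{fits}.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  pool <- stage("species_pool",
                generate_species_pool(cfg$n_species, cfg$n_evergreen,
                                      seed = cfg$seed))
  design <- stage("design",
                  generate_design(pool, cfg$n_blocks, cfg$plots_per_richness,
                                  cfg$richness_levels, seed = cfg$seed))
  invs <- stage("inventories",
                generate_inventories(design, pool,
                                     complementarity = cfg$complementarity,
                                     mortality = cfg$mortality,
                                     seed = cfg$seed))
  clouds <- stage("point_clouds",
                  simulate_cloud_series(design, pool, invs, doys = cfg$doys,
                                        density = cfg$density,
                                        seed = cfg$seed))

  metrics <- stage("metrics", {
    rows <- lapply(names(clouds), function(pid) {
      conditioned <- lapply(clouds[[pid]], function(cl)
        suppressWarnings(
          condition_cloud(cl, design$polygon, buffer_m = cfg$buffer_m,
                          k = cfg$sor_k, quantile = cfg$sor_quantile,
                          z_min = cfg$z_min, edge_m = cfg$decimate_edge)))
      ms <- metric_series(conditioned, cfg$doys, q = cfg$q,
                          scales = cfg$scales)
      cbind(plot_id = pid, ms, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  stability <- stage("stability", {
    rows <- lapply(split(metrics, metrics$plot_id), function(d) {
      pl <- design$plots[design$plots$plot_id == d$plot_id[1], ]
      pyears <- invs$inventory$planting_year[
        invs$inventory$plot_id == d$plot_id[1]]
      data.frame(
        plot_id = d$plot_id[1],
        ss_hhcv = as.numeric(structural_stability(d$hh_cv)),
        ss_fc = as.numeric(structural_stability(d$fc)),
        ss_dD = as.numeric(structural_stability(d$d_D)),
        n_surveys = nrow(d),
        keep = plot_inclusion_filter(d$max_height, pyears, pl$replanted),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  interior <- invs$inventory[invs$inventory$interior, ]
  productivity <- stage("productivity",
                        productivity_table(interior, design))

  diversity <- stage("diversity", {
    # realized communities: species with at least one surviving interior tree
    comm <- lapply(split(interior, interior$plot_id), function(d)
      sort(unique(d$species_id[d$alive2])))
    diversity_table(comm, pool$tree, pool$traits, pool$taxonomy)
  })

  table <- stage("assemble", {
    prod <- productivity
    # planted richness lives in the design; "richness" in the analysis
    # table is realized (post-mortality) species count from the diversity
    # layer
    names(prod)[names(prod) == "richness"] <- "richness_planted"
    t1 <- merge(stability, prod, by = "plot_id")
    t1 <- merge(t1, diversity, by = "plot_id")
    names(t1)[names(t1) == "volume2"] <- "volume"
    t1[t1$keep, ]
  })

  fits <- stage("fits", {
    out <- list()
    mix <- table[!is.na(table$nbe), ]
    if (nrow(mix) >= 10)
      out$nbe_on_ss <- fit_cross_sections(mix, "nbe", "ss_dD", by = NULL,
                                          log_predictor = TRUE)
    if (isTRUE(cfg$fit_mixed)) {
      panel <- merge(metrics, table[, c("plot_id", "volume")],
                     by = "plot_id")
      panel <- merge(panel,
                     design$plots[, c("plot_id", "block")], by = "plot_id")
      if (length(unique(panel$plot_id)) >= 10)
        out$fc_on_volume <- fit_mixed_model(panel, "fc", "volume",
                                            log_predictor = TRUE)
    }
    if (isTRUE(cfg$fit_sem)) {
      ok <- sum(stats::complete.cases(
        table[, c("richness", "pd", "fd", "var_tax", "var_phy", "var_fun",
                  "ss_dD", "nbe")]))
      if (ok >= 50) out$sem <- fit_sem(table, "ss_dD")
      else message("SEM skipped: fewer than 50 complete rows")
    }
    out
  })

  report <- list(pool = pool, design = design, truth = invs$truth,
                 metrics = metrics, stability = stability,
                 productivity = productivity, diversity = diversity,
                 table = table, fits = fits, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(table, file.path(out_dir, "analysis_table.csv"),
                     row.names = FALSE)
    ape::write.tree(pool$tree, file.path(out_dir, "phylogeny.nwk"))
    jsonlite::write_json(
      list(seed = cfg$seed,
           n_plots = nrow(table),
           truth = invs$truth$plots,
           nbe_on_ss = fits$nbe_on_ss),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
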