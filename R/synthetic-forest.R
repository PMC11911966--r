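# Synthetic study generator: species pool with phylogeny and traits,
# experimental design, two annual inventories with an injected diversity
# effect on growth, and per-plot per-survey point clouds with
# phenology-driven foliage density.

PLOT_SIDE <- 10      # m, plot edge length
TREE_SPACING <- 1    # m, planting grid
EDGE_MARGIN <- 0.5   # m, edge strip excluded from ground-based analyses

#' Double-sigmoid leaf phenology curve
#'
#' Foliage fraction of a deciduous crown as a function of day of year:
#' 0 before flush (hard zero at and before flush - 3 * sharpness), rising to
#' ~1 mid-season, and falling back to 0 after senescence. Evergreen crowns
#' use a constant 1.
#'
#' @param doy day(s) of year.
#' @param flush_doy,senesce_doy leaf flush and senescence midpoints (DOY).
#' @param sharpness transition width in days.
#' @return foliage fraction in [0, 1].
#' @export
phenology_curve <- function(doy, flush_doy, senesce_doy, sharpness = 7) {
  stopifnot(flush_doy < senesce_doy, sharpness > 0)
  raw <- stats::plogis((doy - flush_doy) / sharpness) *
    stats::plogis(-(doy - senesce_doy) / sharpness)
  raw[doy <= flush_doy - 3 * sharpness] <- 0
  raw[doy >= senesce_doy + 3 * sharpness] <- 0
  pmin(1, pmax(0, raw))
}

#' Generate a species pool with phylogeny and traits
#'
#' Builds an ultrametric tree (coalescent shape within clades) whose deepest
#' split separates an evergreen from a deciduous clade, and draws five
#' traits (wood density g/cm^3, leaf mass per area g/m^2, max height m,
#' relative growth rate 1/yr, shade tolerance index) as a mixture of
#' Brownian motion along the tree and independent noise, so traits are
#' partially phylogenetically autocorrelated. A synthetic taxonomy
#' (order/family/genus) consistent with the clades is attached for the
#' taxonomic-distinctness tree.
#'
#' @param n_species number of species (default 12).
#' @param n_evergreen number of evergreen species (0 < n_evergreen <
#'   n_species).
#' @param seed integer RNG seed.
#' @return list with \code{species} (data.frame of per-species parameters),
#'   \code{tree} (\code{phylo}), \code{traits} (standardized species x 5
#'   matrix), \code{taxonomy} (data.frame).
#' @export
generate_species_pool <- function(n_species = 12, n_evergreen = 4, seed = 1) {
  if (n_species < 2) stopf("need at least two species")
  if (n_evergreen <= 0 || n_evergreen >= n_species)
    stopf("need at least one evergreen and one deciduous species")
  set.seed(derive_seed(seed, "pool"))
  ids <- sprintf("sp%02d", seq_len(n_species))
  ever_ids <- ids[seq_len(n_evergreen)]
  decid_ids <- setdiff(ids, ever_ids)

  clade_newick <- function(tips) {
    if (length(tips) == 1) return(sprintf("%s:1", tips))
    tr <- ape::rcoal(length(tips), tip.label = tips)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth * 0.5
    sprintf("%s:0.5", sub(";$", "", ape::write.tree(tr)))
  }
  tree <- ape::read.tree(text = sprintf("(%s,%s);",
                                        clade_newick(ever_ids),
                                        clade_newick(decid_ids)))

  # Brownian trait + independent noise, mixed 70/30, then standardized
  bm_trait <- function() {
    z <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    z <- (z - mean(z)) / stats::sd(z)
    0.7 * z + 0.3 * stats::rnorm(length(z))
  }
  raw <- replicate(5, bm_trait())
  rownames(raw) <- tree$tip.label
  raw <- raw[ids, , drop = FALSE]
  colnames(raw) <- c("wood_density", "lma", "max_height", "rgr",
                     "shade_tolerance")
  evergreen <- ids %in% ever_ids
  # map standardized axes onto realistic ranges; evergreens carry higher LMA
  species <- data.frame(
    species_id = ids,
    leaf_habit = ifelse(evergreen, "evergreen", "deciduous"),
    wood_density = 0.50 + 0.08 * raw[, 1],
    lma = 120 + 40 * raw[, 2] + ifelse(evergreen, 60, 0),
    max_height = 25 + 5 * raw[, 3],
    rgr = 0.6 + 0.12 * raw[, 4],
    shade_tolerance = 3 + raw[, 5],
    crown_shape = ifelse(evergreen, "cone", "ellipsoid"),
    crown_ratio = stats::runif(n_species, 0.12, 0.22),
    flush_doy = ifelse(evergreen, NA, round(stats::runif(n_species, 112, 135))),
    senesce_doy = ifelse(evergreen, NA, round(stats::runif(n_species, 270, 292))),
    sharpness = ifelse(evergreen, NA, stats::runif(n_species, 5, 9)),
    height_increment = NA_real_,
    diameter_increment = NA_real_,
    stringsAsFactors = FALSE
  )
  species$height_increment <- pmax(0.25, 0.55 + 0.25 * raw[, 4])
  species$diameter_increment <- pmax(0.004, 0.010 + 0.004 * raw[, 4])

  traits <- standardize_traits(species[, c("wood_density", "lma",
                                           "max_height", "rgr",
                                           "shade_tolerance")])
  rownames(traits) <- ids

  # nested ranks: genera pair species and families group genera within
  # each leaf-habit order, so family membership determines order
  within <- stats::ave(seq_len(n_species), evergreen, FUN = seq_along)
  habit_tag <- ifelse(evergreen, "e", "d")
  taxonomy <- data.frame(
    species = ids,
    genus = paste0("gen_", habit_tag, (within - 1) %/% 2 + 1),
    family = paste0("fam_", habit_tag, (within - 1) %/% 4 + 1),
    order = ifelse(evergreen, "order_evergreen", "order_deciduous"),
    stringsAsFactors = FALSE
  )

  list(species = species, tree = tree, traits = traits, taxonomy = taxonomy)
}

#' Generate the experimental design
#'
#' Monocultures for every species (\code{plots_per_richness} replicates
#' each) plus mixtures at richness levels 2, 4, 6, ..., n_species;
#' proportions are equal within a plot, blocks are assigned cyclically, and
#' mixture draws alternate between fully random sets and sets forced to mix
#' the evergreen and deciduous clades so the design spans functional and
#' phylogenetic variability.
#'
#' @param pool species pool from \code{\link{generate_species_pool}}.
#' @param n_blocks number of spatial blocks (>= 2).
#' @param plots_per_richness monoculture replicates per species, and number
#'   of mixture plots per richness level and block.
#' @param richness_levels mixture sizes; defaults to
#'   \code{c(1, 2, 4, 6, 12)} truncated to the pool size.
#' @param seed integer RNG seed.
#' @return list with \code{plots} (data.frame with list-columns
#'   \code{species}, \code{proportions}) and \code{polygon} (the shared
#'   10 m x 10 m \code{plot_polygon} in plot-local coordinates).
#' @export
generate_design <- function(pool, n_blocks = 3, plots_per_richness = 2,
                            richness_levels = c(1, 2, 4, 6, 12), seed = 1) {
  if (plots_per_richness < 1) stopf("plots_per_richness must be >= 1")
  if (n_blocks < 2) stopf("need at least two blocks")
  ids <- pool$species$species_id
  n_sp <- length(ids)
  if (any(richness_levels > n_sp))
    stopf("richness level %d exceeds the %d-species pool",
          max(richness_levels), n_sp)
  set.seed(derive_seed(seed, "design"))
  ever <- pool$species$species_id[pool$species$leaf_habit == "evergreen"]
  decid <- setdiff(ids, ever)

  rows <- list()
  add_plot <- function(species_set, block) {
    i <- length(rows) + 1
    row <- data.frame(
      plot_id = sprintf("p%03d", i),
      block = sprintf("b%d", block),
      richness = length(species_set),
      planting_year = sample(2016:2018, 1),
      replanted = stats::runif(1) < 0.05,
      stringsAsFactors = FALSE
    )
    row$species <- list(species_set)
    row$proportions <- list(rep(1 / length(species_set),
                                length(species_set)))
    rows[[i]] <<- row
  }
  for (rep_i in seq_len(plots_per_richness))
    for (s in ids) add_plot(s, (length(rows) %% n_blocks) + 1)
  for (r in setdiff(richness_levels, 1)) {
    n_mix <- plots_per_richness * n_blocks
    for (j in seq_len(n_mix)) {
      if (r < n_sp && j %% 2 == 0 && length(ever) && length(decid)) {
        k_ev <- max(1, min(length(ever), round(r * length(ever) / n_sp)))
        set <- c(sample(ever, k_ev), sample(decid, r - k_ev))
      } else {
        set <- sample(ids, r)
      }
      add_plot(sort(set), (length(rows) %% n_blocks) + 1)
    }
  }
  plots <- do.call(rbind, rows)
  poly <- plot_polygon(rbind(c(0, 0), c(PLOT_SIDE, 0),
                             c(PLOT_SIDE, PLOT_SIDE), c(0, PLOT_SIDE)))
  list(plots = plots, polygon = poly)
}

#' Generate two annual inventories with an injected diversity effect
#'
#' Trees sit on a 1 m planting grid (100 per plot); the outer 0.5 m ring is
#' flagged non-interior and excluded from ground-based analyses. Year-1
#' size follows species base growth and stand age; year-2 growth is
#' base growth * (1 + complementarity * variability score) * lognormal
#' noise, where the variability score is the plot's functional-dendrogram
#' variability (0 for monocultures), so mixtures overyield in proportion to
#' their functional variability and \code{complementarity = 0} injects no
#' diversity effect. A configurable mortality rate zeroes year-2 records of
#' dead trees.
#'
#' @param design from \code{\link{generate_design}}.
#' @param pool from \code{\link{generate_species_pool}}.
#' @param complementarity injected complementarity multiplier (default 0.5).
#' @param mortality annual mortality probability (default 0.05).
#' @param growth_noise_sd sd of the lognormal growth noise (default 0.15).
#' @param seed integer RNG seed.
#' @return list with \code{inventory} (one row per tree, both years) and
#'   \code{truth} (per-plot injected multiplier and score, plus the seed).
#' @export
generate_inventories <- function(design, pool, complementarity = 0.5,
                                 mortality = 0.05, growth_noise_sd = 0.15,
                                 seed = 1) {
  set.seed(derive_seed(seed, "inventory"))
  plots <- design$plots
  sp_tab <- pool$species
  fun_tree <- functional_dendrogram(pool$traits)
  coords <- expand.grid(
    x = seq(TREE_SPACING / 2, PLOT_SIDE - TREE_SPACING / 2, by = TREE_SPACING),
    y = seq(TREE_SPACING / 2, PLOT_SIDE - TREE_SPACING / 2, by = TREE_SPACING))
  n_trees <- nrow(coords)
  interior <- coords$x > EDGE_MARGIN + 1e-9 & coords$y > EDGE_MARGIN + 1e-9 &
    coords$x < PLOT_SIDE - EDGE_MARGIN - 1e-9 &
    coords$y < PLOT_SIDE - EDGE_MARGIN - 1e-9

  inv_rows <- vector("list", nrow(plots))
  truth_rows <- vector("list", nrow(plots))
  for (i in seq_len(nrow(plots))) {
    pl <- plots[i, ]
    sp_set <- pl$species[[1]]
    score <- if (length(sp_set) >= 2)
      variability_psv(fun_tree, sp_set) else 0
    mult <- complementarity * score
    # equal planted proportions realized as an evenly filled, shuffled grid
    assign <- sample(rep_len(sp_set, n_trees))
    pars <- sp_tab[match(assign, sp_tab$species_id), ]
    age <- 2021 - pl$planting_year
    h1 <- pmax(0.3, pars$height_increment * age *
                 exp(stats::rnorm(n_trees, 0, growth_noise_sd)))
    d1 <- pmax(0.005, pars$diameter_increment * age *
                 exp(stats::rnorm(n_trees, 0, growth_noise_sd)))
    gh <- pars$height_increment * (1 + mult) *
      exp(stats::rnorm(n_trees, 0, growth_noise_sd))
    gd <- pars$diameter_increment * (1 + mult) *
      exp(stats::rnorm(n_trees, 0, growth_noise_sd))
    dead <- stats::runif(n_trees) < mortality
    h2 <- ifelse(dead, 0, h1 + gh)
    d2 <- ifelse(dead, 0, d1 + gd)
    # conical taper: diameter at breast height from root-collar diameter
    dbh_of <- function(h, d) ifelse(h > 1.3, d * (1 - 1.3 / h), NA_real_)
    inv_rows[[i]] <- data.frame(
      plot_id = pl$plot_id, tree_id = sprintf("%s_t%03d", pl$plot_id,
                                              seq_len(n_trees)),
      species_id = assign, planting_year = pl$planting_year,
      x = coords$x, y = coords$y, interior = interior,
      h1 = h1, d_rc1 = d1, dbh1 = dbh_of(h1, d1), alive1 = TRUE,
      h2 = h2, d_rc2 = d2, dbh2 = dbh_of(h2, d2), alive2 = !dead,
      stringsAsFactors = FALSE
    )
    truth_rows[[i]] <- data.frame(plot_id = pl$plot_id,
                                  variability_score = score,
                                  multiplier = mult,
                                  stringsAsFactors = FALSE)
  }
  list(inventory = do.call(rbind, inv_rows),
       truth = list(plots = do.call(rbind, truth_rows),
                    complementarity = complementarity,
                    mortality = mortality, seed = seed))
}

# vertical crown interval [zlo, zhi] of a pulse at horizontal distance d
# from the trunk; NA when the pulse misses the crown
crown_interval <- function(shape, d, h, ratio) {
  r_max <- pmin(1.5, ratio * h)
  base <- 0.25 * h
  miss <- d >= r_max | h <= 0
  if (shape == "cone") {
    # apex at the top: radius shrinks linearly from base to tip
    zhi <- h - d / r_max * (h - base)
    zlo <- rep(base, length(d))
  } else {
    zc <- (base + h) / 2
    c_ax <- (h - base) / 2
    half <- c_ax * sqrt(pmax(0, 1 - (d / r_max)^2))
    zlo <- zc - half
    zhi <- zc + half
  }
  zlo[miss] <- NA_real_
  zhi[miss] <- NA_real_
  list(zlo = zlo, zhi = zhi)
}

#' Simulate one survey point cloud for one plot
#'
#' Nadir pulses on a jittered grid at the requested density; each pulse
#' intersects the union of crown solids (cones for evergreens, ellipsoids
#' for deciduous trees). The per-crown interception probability is
#' 1 - exp(-k * L * phi) with path length L through the crown and foliage
#' fraction phi from \code{\link{phenology_curve}} (1 for evergreens).
#' Returns are numbered top-down per pulse; a ground return terminates the
#' pulse with probability exp(-total optical depth), and always when no
#' crown intercepted. A configurable fraction of high outliers is injected
#' above the canopy (classification \code{"noise"}, with a \code{source}
#' truth column) to exercise the SOR filter. \code{ground_offset} and
#' \code{ground_slope} shift true ground away from z = 0 to exercise height
#' normalization.
#'
#' @param plot_inventory inventory rows of one plot.
#' @param pool species pool.
#' @param doy survey day of year.
#' @param density pulse density, pulses/m^2 (default 100).
#' @param extinction attenuation coefficient k per meter of crown path
#'   (default 0.8).
#' @param wood_fraction leaf-off interceptable fraction of a deciduous
#'   crown (branches and stems, default 0.15); the effective foliage
#'   fraction is \code{wood + (1 - wood) * phi}, so leaf-off canopies
#'   still return sparse woody points as real winter LiDAR does.
#' @param noise_frac fraction of returns injected as high outliers
#'   (default 0.001).
#' @param ground_offset constant ground elevation (m, default 0).
#' @param ground_slope c(sx, sy) ground slope (m/m, default c(0, 0)).
#' @param seed integer RNG seed for this plot-survey stream.
#' @return a \code{point_cloud} with an extra \code{source} column
#'   (\code{canopy}, \code{ground} or \code{noise}).
#' @export
simulate_point_cloud <- function(plot_inventory, pool, doy, density = 100,
                                 extinction = 0.8, wood_fraction = 0.15,
                                 noise_frac = 0.001,
                                 ground_offset = 0, ground_slope = c(0, 0),
                                 seed = 1) {
  stopifnot(density > 0)
  set.seed(seed)
  a <- 1 / sqrt(density)
  nx <- ceiling(PLOT_SIDE / a)
  g <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(nx) - 1L)
  px <- (g$i + stats::runif(nrow(g))) * a
  py <- (g$j + stats::runif(nrow(g))) * a
  keep <- px < PLOT_SIDE & py < PLOT_SIDE
  px <- px[keep]; py <- py[keep]
  n_pulse <- length(px)

  trees <- plot_inventory[plot_inventory$alive2 & plot_inventory$h2 > 0, ]
  sp <- pool$species[match(trees$species_id, pool$species$species_id), ]
  hit_pulse <- integer(0); hit_z <- numeric(0); hit_tau <- numeric(0)
  if (nrow(trees) > 0) {
    phi <- rep(1, nrow(sp))
    dec <- which(sp$leaf_habit == "deciduous")
    for (t in dec)
      phi[t] <- wood_fraction + (1 - wood_fraction) *
        phenology_curve(doy, sp$flush_doy[t], sp$senesce_doy[t],
                        sp$sharpness[t])
    acc <- vector("list", nrow(trees))
    for (t in seq_len(nrow(trees))) {
      h <- trees$h2[t]
      r_max <- min(1.5, sp$crown_ratio[t] * h)
      cand <- which(abs(px - trees$x[t]) < r_max &
                      abs(py - trees$y[t]) < r_max)
      if (!length(cand)) next
      d <- sqrt((px[cand] - trees$x[t])^2 + (py[cand] - trees$y[t])^2)
      iv <- crown_interval(sp$crown_shape[t], d, h, sp$crown_ratio[t])
      ok <- which(is.finite(iv$zlo) & iv$zhi > iv$zlo)
      if (!length(ok)) next
      L <- iv$zhi[ok] - iv$zlo[ok]
      tau <- extinction * L * phi[t]
      hit <- stats::runif(length(ok)) < 1 - exp(-tau)
      z <- iv$zlo[ok] + stats::runif(length(ok)) * L
      acc[[t]] <- data.frame(pulse = cand[ok], z = z, tau = tau, hit = hit)
    }
    acc <- acc[!vapply(acc, is.null, logical(1))]
    if (length(acc)) {
      all_hits <- do.call(rbind, acc)
      hit_pulse <- all_hits$pulse[all_hits$hit]
      hit_z <- all_hits$z[all_hits$hit]
      hit_tau <- all_hits$tau[all_hits$hit]
      tau_dt <- data.table(pulse = all_hits$pulse, tau = all_hits$tau)
      tau_by_pulse <- tau_dt[, list(tau = sum(tau)), by = "pulse"]
      tau_all <- numeric(n_pulse)
      tau_all[tau_by_pulse$pulse] <- tau_by_pulse$tau
    } else {
      tau_all <- numeric(n_pulse)
    }
  } else {
    tau_all <- numeric(n_pulse)
  }

  # order hits top-down per pulse; a lower interception only registers if
  # the pulse survived the crowns above it (sequential energy thinning),
  # and the sensor keeps at most 2 vegetation returns (up to 3 incl. ground)
  if (length(hit_pulse)) {
    dt <- data.table(pulse = hit_pulse, z = hit_z, tau = hit_tau)
    data.table::setorder(dt, pulse, -z)
    dt[, above := cumsum(tau) - tau, by = "pulse"]
    dt <- dt[stats::runif(nrow(dt)) < exp(-dt$above), ]
    dt[, rank := seq_len(.N), by = "pulse"]
    dt <- dt[dt$rank <= 2L, ]
    veg_pulse <- dt$pulse; veg_z <- dt$z; veg_rank <- dt$rank
    nveg <- integer(n_pulse)
    cnt <- dt[, .N, by = "pulse"]
    nveg[cnt$pulse] <- cnt$N
  } else {
    veg_pulse <- integer(0); veg_z <- numeric(0); veg_rank <- integer(0)
    nveg <- integer(n_pulse)
  }
  ground_here <- stats::runif(n_pulse) < exp(-tau_all) | nveg == 0L
  nret <- nveg + as.integer(ground_here)

  gx <- px[ground_here]; gy <- py[ground_here]
  elev <- function(x, y) ground_offset + ground_slope[1] * x +
    ground_slope[2] * y
  pts <- data.frame(
    x = c(px[veg_pulse], gx),
    y = c(py[veg_pulse], gy),
    z = c(veg_z + elev(px[veg_pulse], py[veg_pulse]),
          elev(gx, gy) + stats::rnorm(length(gx), 0, 0.02)),
    return_number = c(veg_rank, nret[ground_here]),
    number_of_returns = c(nret[veg_pulse], nret[ground_here]),
    source = c(rep("canopy", length(veg_pulse)),
               rep("ground", length(gx))),
    stringsAsFactors = FALSE
  )

  n_noise <- round(noise_frac * nrow(pts))
  if (n_noise > 0) {
    zmax <- max(pts$z)
    noise <- data.frame(
      x = stats::runif(n_noise, 0, PLOT_SIDE),
      y = stats::runif(n_noise, 0, PLOT_SIDE),
      z = zmax + stats::runif(n_noise, 2, 10),
      return_number = 1L, number_of_returns = 1L,
      source = "noise", stringsAsFactors = FALSE
    )
    pts <- rbind(pts, noise)
  }
  cloud <- point_cloud(pts$x, pts$y, pts$z, pts$return_number,
                       pts$number_of_returns,
                       ifelse(pts$source == "noise", "noise", "unassigned"),
                       plot_id = plot_inventory$plot_id[1], doy = doy)
  cloud$source <- pts$source
  cloud
}

#' Simulate the full seasonal point-cloud series
#'
#' One cloud per plot per survey day, each from an independent RNG stream
#' derived by hashing (master seed, plot id, DOY), so any plot-survey can be
#' regenerated in isolation.
#'
#' @param design,pool study objects.
#' @param inventories result of \code{\link{generate_inventories}}.
#' @param doys survey days of year; the study schedule is
#'   \code{c(100, 138, 163, 188, 215, 250, 261, 297)}.
#' @param density pulses/m^2.
#' @param seed master seed.
#' @param ... passed to \code{\link{simulate_point_cloud}}.
#' @return nested list: clouds[[plot_id]][[as.character(doy)]].
#' @export
simulate_cloud_series <- function(design, pool, inventories,
                                  doys = c(100, 138, 163, 188, 215, 250,
                                           261, 297),
                                  density = 100, seed = 1, ...) {
  if (!length(doys)) stopf("doys must be nonempty")
  inv <- inventories$inventory
  out <- list()
  for (pid in unique(design$plots$plot_id)) {
    pinv <- inv[inv$plot_id == pid, ]
    out[[pid]] <- stats::setNames(lapply(doys, function(d) {
      simulate_point_cloud(pinv, pool, d, density = density,
                           seed = derive_seed(seed, pid, d), ...)
    }), as.character(doys))
  }
  out
}
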