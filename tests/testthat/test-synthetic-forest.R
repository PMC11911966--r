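test_that("species pool honours counts, ultrametry and determinism", {
  pool <- generate_species_pool(12, 4, seed = 1)
  expect_equal(ape::Ntip(pool$tree), 12)
  expect_equal(sum(pool$species$leaf_habit == "evergreen"), 4)
  expect_true(ape::is.ultrametric(pool$tree, tol = 1e-8))
  expect_true(all(is.finite(pool$traits)))
  dec <- pool$species[pool$species$leaf_habit == "deciduous", ]
  expect_true(all(dec$flush_doy < dec$senesce_doy))
  # deepest split separates the clades: evergreen MRCA excludes deciduous
  ever <- pool$species$species_id[pool$species$leaf_habit == "evergreen"]
  sub <- ape::extract.clade(pool$tree,
                            ape::getMRCA(pool$tree, ever))
  expect_setequal(sub$tip.label, ever)
  two <- generate_species_pool(2, 1, seed = 7)
  expect_equal(ape::Ntip(two$tree), 2)
  depths <- ape::node.depth.edgelength(two$tree)[1:2]
  expect_equal(depths[1], depths[2])
  again <- generate_species_pool(12, 4, seed = 1)
  expect_identical(pool, again)
  expect_error(generate_species_pool(1, 0), "two species")
  expect_error(generate_species_pool(5, 5), "evergreen")
})

test_that("phenology curve is bounded, zero pre-flush and high mid-season", {
  doys <- 1:365
  phi <- phenology_curve(doys, flush_doy = 120, senesce_doy = 280,
                         sharpness = 7)
  expect_true(all(phi >= 0 & phi <= 1))
  expect_true(all(phi[doys <= 120 - 21] == 0))
  expect_gt(phenology_curve(200, 120, 280, 7), 0.99)
  expect_error(phenology_curve(100, 280, 120), "flush_doy")
})

test_that("design covers monocultures, proportions and determinism", {
  pool <- generate_species_pool(12, 4, seed = 2)
  des <- generate_design(pool, 3, 2, seed = 2)
  mono <- des$plots[des$plots$richness == 1, ]
  counts <- table(vapply(mono$species, `[`, character(1), 1))
  expect_true(all(counts >= 2))
  expect_equal(length(counts), 12)
  for (i in seq_len(nrow(des$plots))) {
    expect_equal(sum(des$plots$proportions[[i]]), 1)
    expect_equal(length(des$plots$species[[i]]), des$plots$richness[i])
  }
  expect_gte(length(unique(des$plots$block)), 3)
  des2 <- generate_design(pool, 3, 2, seed = 2)
  expect_identical(des$plots, des2$plots)
  expect_error(generate_design(pool, 3, 1, richness_levels = c(1, 24)),
               "exceeds")
})

test_that("inventories mark dead trees and respond to the injected effect", {
  pool <- generate_species_pool(12, 4, seed = 3)
  des <- generate_design(pool, 3, 2, seed = 3)
  out <- generate_inventories(des, pool, complementarity = 0.6,
                              mortality = 0.1, seed = 3)
  inv <- out$inventory
  dead <- inv[!inv$alive2, ]
  expect_gt(nrow(dead), 0)
  expect_true(all(dead$h2 == 0 & dead$d_rc2 == 0))
  expect_true(all(is.na(inv$dbh2[inv$h2 <= 1.3])))
  expect_true(all(!is.na(inv$dbh2[inv$h2 > 1.3])))
  # truth: monocultures carry no injected multiplier, mixtures scale with
  # their functional variability
  tr <- merge(out$truth$plots, des$plots[, c("plot_id", "richness")])
  expect_true(all(tr$multiplier[tr$richness == 1] == 0))
  expect_true(all(tr$multiplier[tr$richness > 1] > 0))
  expect_identical(inv,
                   generate_inventories(des, pool, complementarity = 0.6,
                                        mortality = 0.1, seed = 3)$inventory)
})

test_that("the injected diversity effect is recoverable downstream", {
  # uniform plot age and no mortality isolate the growth channel; the
  # injected multiplier is relative, so the recovery statistic is relative
  # overyielding (NBE / expected AWP)
  pool <- generate_species_pool(12, 4, seed = 3)
  des <- generate_design(pool, 3, 3, seed = 3)
  des$plots$planting_year <- 2017L
  des$plots$replanted <- FALSE
  out <- generate_inventories(des, pool, complementarity = 0.5,
                              mortality = 0, seed = 3)
  pt <- productivity_table(out$inventory[out$inventory$interior, ], des)
  m <- merge(pt[!is.na(pt$nbe), ], out$truth$plots, by = "plot_id")
  expect_gt(nrow(m), 30)
  expect_gt(cor(m$variability_score, m$nbe / m$awp_expected,
                method = "spearman"), 0.3)
  # and the average mixture overyields
  expect_gt(mean(m$nbe), 0)
})

test_that("point clouds respect return-numbering and pulse-count scaling", {
  pool <- generate_species_pool(4, 1, seed = 4)
  des <- generate_design(pool, 2, 1, c(1, 2), seed = 4)
  inv <- generate_inventories(des, pool, seed = 4)
  pid <- des$plots$plot_id[1]
  pinv <- inv$inventory[inv$inventory$plot_id == pid, ]
  cl <- simulate_point_cloud(pinv, pool, 215, density = 50, seed = 6)
  # per pulse (shared x,y), return numbers are 1..k with no gaps
  key <- paste(cl$x, cl$y)
  for (g in split(cl$return_number, key)[1:200]) {
    expect_equal(sort(g), seq_along(g))
  }
  expect_true(all(cl$return_number <= cl$number_of_returns))
  # pulse count tracks density * area within Poisson-like error
  n_pulses <- sum(cl$return_number == 1 & cl$source != "noise")
  expect_lt(abs(n_pulses - 50 * 100), 4 * sqrt(50 * 100))
  expect_identical(cl,
                   simulate_point_cloud(pinv, pool, 215, density = 50,
                                        seed = 6))
})

test_that("phenology drives the seasonal vegetation-return signal", {
  pool <- generate_species_pool(4, 1, seed = 9)
  des <- generate_design(pool, 2, 2, c(1), seed = 9)
  inv <- generate_inventories(des, pool, seed = 9)
  habit <- vapply(des$plots$species, function(s)
    pool$species$leaf_habit[match(s[1], pool$species$species_id)],
    character(1))
  veg_fraction <- function(pid, doy) {
    cl <- simulate_point_cloud(
      inv$inventory[inv$inventory$plot_id == pid, ], pool, doy,
      density = 40, seed = derive_seed(9, pid, doy))
    mean(cl$source == "canopy")
  }
  dec_plot <- des$plots$plot_id[habit == "deciduous"][1]
  ev_plot <- des$plots$plot_id[habit == "evergreen"][1]
  expect_lt(veg_fraction(dec_plot, 100), veg_fraction(dec_plot, 215))
  ev_series <- vapply(c(100, 188, 297), function(d)
    veg_fraction(ev_plot, d), numeric(1))
  expect_lt(diff(range(ev_series)) / mean(ev_series), 0.25)
})

test_that("a null complementarity leaves NBE centred on zero", {
  pool <- generate_species_pool(8, 3, seed = 10)
  des <- generate_design(pool, 3, 3, c(1, 2, 4), seed = 10)
  inv <- generate_inventories(des, pool, complementarity = 0,
                              mortality = 0, seed = 10)
  pt <- productivity_table(inv$inventory[inv$inventory$interior, ], des)
  nbe_mix <- pt$nbe[!is.na(pt$nbe)]
  expect_gt(length(nbe_mix), 10)
  se <- sd(nbe_mix) / sqrt(length(nbe_mix))
  expect_lt(abs(mean(nbe_mix)), 2.5 * se + 1e-9)
})
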