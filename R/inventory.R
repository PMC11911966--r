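# Ground-based quantities: tree and plot wood volume, annual wood
# productivity (AWP), the net biodiversity effect (NBE), and its
# Loreau-Hector complementarity/selection partition.

BREAST_HEIGHT <- 1.3  # m, height of DBH measurement

#' Tree wood volume from field measurements
#'
#' Trees at most 1.3 m tall are modelled as a conoid (cone of revolution) on
#' the root-collar diameter: V = H * pi * D_rc^2 / 12. Taller trees combine a
#' conoid frustum from the root collar to breast height with a conoid above:
#' V = 1.3 * (D_rc^2 + DBH * D_rc + DBH^2) * pi / 12
#'     + (H - 1.3) * pi * DBH^2 / 12.
#' Dead trees have zero volume.
#'
#' @param height tree height H in meters (root collar to apical meristem).
#' @param d_rc root-collar diameter in meters.
#' @param dbh diameter at breast height in meters; required when
#'   \code{height > 1.3}.
#' @param alive logical; dead trees return 0.
#' @return volume in m^3. Vectorized over trees.
#' @export
tree_volume <- function(height, d_rc, dbh = NA_real_, alive = TRUE) {
  n <- max(length(height), length(d_rc), length(dbh), length(alive))
  height <- rep_len(height, n); d_rc <- rep_len(d_rc, n)
  dbh <- rep_len(dbh, n); alive <- rep_len(alive, n)
  if (any(height < 0, na.rm = TRUE) || any(d_rc < 0, na.rm = TRUE))
    stopf("height and diameters must be nonnegative")
  tall <- alive & height > BREAST_HEIGHT
  if (any(tall & !is.finite(dbh)))
    stopf("DBH required for trees taller than %.1f m", BREAST_HEIGHT)
  v <- numeric(n)
  short <- alive & !tall
  v[short] <- height[short] * pi * d_rc[short]^2 / 12
  v[tall] <- BREAST_HEIGHT *
    (d_rc[tall]^2 + dbh[tall] * d_rc[tall] + dbh[tall]^2) * pi / 12 +
    (height[tall] - BREAST_HEIGHT) * pi * dbh[tall]^2 / 12
  v
}

#' Plot wood volume and annual wood productivity
#'
#' Per-tree AWP is the volume difference between the two inventories divided
#' by the interval (years) and plot area (ha); plot volume and AWP are sums
#' over interior trees (the outer 0.5 m edge strip must already be
#' excluded). Mortality enters as a negative increment.
#'
#' @param inventory data.frame with one row per tree and columns
#'   \code{plot_id}, \code{tree_id}, \code{species_id},
#'   \code{h1, d_rc1, dbh1, alive1} and \code{h2, d_rc2, dbh2, alive2}
#'   for the two inventory years.
#' @param plot_area_ha plot area in hectares (default 0.0081, the 81 m^2
#'   interior of a 10 m plot).
#' @param interval_days days between inventories; converted at 365 d/yr.
#' @return data.frame keyed by plot with columns \code{plot_id},
#'   \code{volume1}, \code{volume2} (m^3/ha) and \code{awp}
#'   (m^3 yr^-1 ha^-1).
#' @export
plot_volume_and_awp <- function(inventory, plot_area_ha = 0.0081,
                                interval_days = 365) {
  if (interval_days <= 0) stopf("interval must be positive")
  interval_years <- interval_days / 365
  v1 <- tree_volume(inventory$h1, inventory$d_rc1, inventory$dbh1,
                    inventory$alive1)
  v2 <- tree_volume(inventory$h2, inventory$d_rc2, inventory$dbh2,
                    inventory$alive2)
  awp_tree <- (v2 - v1) / interval_years / plot_area_ha
  dt <- data.table(plot_id = inventory$plot_id, v1 = v1, v2 = v2,
                   awp = awp_tree)
  out <- dt[, list(volume1 = sum(v1) / plot_area_ha,
                   volume2 = sum(v2) / plot_area_ha,
                   awp = sum(awp)), by = "plot_id"]
  as.data.frame(out)
}

#' Per-species AWP within plots
#'
#' Species-level sums of per-tree AWP, the observed mixture yields Y_i of
#' the Loreau-Hector partition.
#'
#' @inheritParams plot_volume_and_awp
#' @return data.frame plot_id, species_id, awp.
#' @export
species_awp <- function(inventory, plot_area_ha = 0.0081,
                        interval_days = 365) {
  interval_years <- interval_days / 365
  v1 <- tree_volume(inventory$h1, inventory$d_rc1, inventory$dbh1,
                    inventory$alive1)
  v2 <- tree_volume(inventory$h2, inventory$d_rc2, inventory$dbh2,
                    inventory$alive2)
  dt <- data.table(plot_id = inventory$plot_id,
                   species_id = inventory$species_id,
                   awp = (v2 - v1) / interval_years / plot_area_ha)
  as.data.frame(dt[, list(awp = sum(awp)), by = c("plot_id", "species_id")])
}

#' Expected mixture productivity from monoculture means
#'
#' \eqn{AWP_{expected} = \sum_i \bar{AWP}_i p_i} with planted proportions
#' p_i and per-species mean monoculture AWP (monocultures planted before
#' 2019 only, grand mean across qualifying monocultures).
#'
#' @param proportions named numeric vector of planted proportions
#'   (names = species ids), summing to 1.
#' @param monoculture_means named numeric vector of mean monoculture AWP.
#' @return expected AWP in m^3 yr^-1 ha^-1.
#' @export
expected_awp <- function(proportions, monoculture_means) {
  sp <- names(proportions)
  missing_sp <- setdiff(sp, names(monoculture_means))
  if (length(missing_sp))
    stopf("no monoculture mean for species: %s",
          paste(missing_sp, collapse = ", "))
  sum(monoculture_means[sp] * proportions)
}

#' Net biodiversity effect
#'
#' NBE = observed plot AWP - expected AWP; positive values are overyielding.
#' Defined for mixtures only (report NA for monocultures upstream).
#'
#' @param observed_awp,expected_awp productivities in m^3 yr^-1 ha^-1.
#' @return NBE in the same units.
#' @export
nbe <- function(observed_awp, expected_awp) {
  observed_awp - expected_awp
}

#' Loreau-Hector additive partition of the NBE
#'
#' With observed per-species mixture yields Y_i, monoculture means M_i and
#' planted proportions p_i, the relative yield change is
#' \eqn{\Delta RY_i = Y_i/M_i - p_i}; the complementarity effect is
#' \eqn{CE = n \overline{\Delta RY} \, \overline{M}} and the selection
#' effect \eqn{SE = n \, cov(\Delta RY, M)} with the population (divide by
#' n) covariance, so that CE + SE = \eqn{\sum Y_i - \sum p_i M_i} = NBE
#' exactly.
#'
#' @param y observed per-species mixture AWP Y_i (named or ordered).
#' @param m per-species monoculture mean AWP M_i (> 0).
#' @param p planted proportions p_i.
#' @return list with \code{ce}, \code{se}, \code{nbe}.
#' @export
loreau_hector_partition <- function(y, m, p) {
  stopifnot(length(y) == length(m), length(m) == length(p))
  keep <- m > 0
  if (any(!keep)) {
    warnf("excluding %d species with zero monoculture yield from the partition",
          sum(!keep))
    y <- y[keep]; m <- m[keep]; p <- p[keep]
  }
  n <- length(y)
  if (n == 0) stopf("no species with positive monoculture yield")
  dry <- y / m - p
  ce <- n * mean(dry) * mean(m)
  se <- n * (mean(dry * m) - mean(dry) * mean(m))  # population covariance
  list(ce = ce, se = se, nbe = ce + se)
}

#' Productivity, NBE and partition for every plot
#'
#' End-to-end ground layer: plot volumes and AWP, monoculture means from
#' qualifying monocultures (planted before 2019, not replanted), expected
#' AWP, NBE and the CE/SE partition for mixtures.
#'
#' @param inventory per-tree two-year inventory (see
#'   \code{\link{plot_volume_and_awp}}); interior trees only.
#' @param design experiment design as returned by
#'   \code{\link{generate_design}} (needs \code{plots} with plot_id,
#'   species proportions, planting_year, replanted).
#' @inheritParams plot_volume_and_awp
#' @return data.frame keyed by plot: volumes, awp, awp_expected, nbe, ce,
#'   se (NA for monocultures and excluded plots).
#' @export
productivity_table <- function(inventory, design, plot_area_ha = 0.0081,
                               interval_days = 365) {
  pv <- plot_volume_and_awp(inventory, plot_area_ha, interval_days)
  sa <- species_awp(inventory, plot_area_ha, interval_days)
  plots <- design$plots
  mono <- plots[plots$richness == 1 & plots$planting_year < 2019 &
                  !plots$replanted, ]
  mono_awp <- pv$awp[match(mono$plot_id, pv$plot_id)]
  mono_sp <- vapply(mono$species, `[`, character(1), 1)
  mono_means <- tapply(mono_awp, mono_sp, mean)
  res <- lapply(seq_len(nrow(plots)), function(i) {
    pl <- plots[i, ]
    row <- pv[pv$plot_id == pl$plot_id, ]
    if (nrow(row) == 0) return(NULL)
    out <- data.frame(plot_id = pl$plot_id, block = pl$block,
                      richness = pl$richness, replanted = pl$replanted,
                      planting_year = pl$planting_year,
                      volume1 = row$volume1, volume2 = row$volume2,
                      awp = row$awp, awp_expected = NA_real_,
                      nbe = NA_real_, ce = NA_real_, se = NA_real_)
    sp <- pl$species[[1]]; pr <- pl$proportions[[1]]
    if (pl$richness > 1 && !pl$replanted &&
        all(sp %in% names(mono_means))) {
      mm <- mono_means[sp]
      out$awp_expected <- expected_awp(stats::setNames(pr, sp), mm)
      ys <- sa[sa$plot_id == pl$plot_id, ]
      y <- stats::setNames(rep(0, length(sp)), sp)
      y[ys$species_id] <- ys$awp
      part <- loreau_hector_partition(y, as.numeric(mm), pr)
      out$nbe <- row$awp - out$awp_expected
      out$ce <- part$ce; out$se <- part$se
    }
    out
  })
  do.call(rbind, res)
}
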