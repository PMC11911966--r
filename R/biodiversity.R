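# Taxonomic, phylogenetic and functional diversity (Hill q = 0) and
# Helmus-type species variability on three tree types: the time-calibrated
# phylogeny, a functional-trait dendrogram, and a taxonomic-distinctness
# tree.

#' Taxonomic Hill diversity of a community
#'
#' q = 0 is the species count after mortality; general q is supported via
#' \code{\link{hill_diversity}} on abundance shares.
#'
#' @param abundances named numeric vector of per-species abundances
#'   (presence counts or stems) for one community.
#' @param q Hill order (default 0).
#' @return effective species number.
#' @export
hill_taxa <- function(abundances, q = 0) {
  abundances <- abundances[abundances > 0]
  if (length(abundances) == 0) stopf("empty community")
  hill_diversity(abundances / sum(abundances), q)
}

#' Faith-type phylogenetic diversity
#'
#' Total branch length of the subtree spanning the community's tips and the
#' root of the supplied tree: the union of all root-to-tip paths, so shared
#' stem history is counted once and a single-species community returns its
#' root-to-tip path length.
#'
#' @param tree an \code{ape::phylo} tree whose tips include all species.
#' @param species character vector of community members.
#' @return summed branch length, in the tree's units.
#' @export
phylo_diversity <- function(tree, species) {
  species <- unique(species)
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown))
    stopf("species not in tree: %s", paste(unknown, collapse = ", "))
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  on_path <- logical(nrow(tree$edge))
  for (tip in match(species, tree$tip.label)) {
    node <- tip
    repeat {
      e <- match(node, child)
      if (is.na(e) || on_path[e]) break  # reached root or a marked path
      on_path[e] <- TRUE
      node <- parent[e]
    }
  }
  sum(tree$edge.length[on_path])
}

#' Standardize a trait table
#'
#' Columns scaled to zero mean and unit sd; trait units are incommensurable
#' so distances are only meaningful on z-scores.
#'
#' @param traits species x trait numeric matrix or data.frame with species
#'   as row names.
#' @return standardized matrix.
#' @export
standardize_traits <- function(traits) {
  m <- as.matrix(traits)
  if (any(!is.finite(m))) stopf("trait table contains missing values")
  scale(m)[, , drop = FALSE]
}

#' Functional diversity as total functional distance
#'
#' Effective total functional distance between species at q = 0: the sum of
#' pairwise Euclidean distances on standardized traits over ordered pairs
#' (twice the sum over unordered pairs). A singleton community has FD 0.
#'
#' @param traits standardized species x trait matrix (see
#'   \code{\link{standardize_traits}}); row names are species.
#' @param species community members.
#' @return total distance (squared-distance-sum units); 0 for singletons.
#' @export
functional_diversity <- function(traits, species) {
  species <- unique(species)
  if (length(species) < 1) stopf("empty community")
  unknown <- setdiff(species, rownames(traits))
  if (length(unknown))
    stopf("species not in trait table: %s", paste(unknown, collapse = ", "))
  if (length(species) == 1) return(structure(0, singleton = TRUE))
  d <- as.matrix(stats::dist(traits[species, , drop = FALSE]))
  sum(d)  # ordered pairs: diagonal is zero, off-diagonal counted both ways
}

#' Helmus phylogenetic species variability (PSV)
#'
#' Builds the covariance of shared root-to-tip branch lengths for the
#' community (pruning that retains the path to the tree's root, so shared
#' stem history is preserved), scales it to a correlation matrix, and
#' returns \eqn{(n \, tr(C) - \sum C) / (n (n - 1)) = 1 - } mean
#' off-diagonal correlation. 1 means phylogenetic independence (star tree),
#' values near 0 mean high relatedness. Monocultures are undefined
#' (n >= 2 required).
#'
#' @param tree ultrametric \code{ape::phylo} (phylogeny, functional
#'   dendrogram, or taxonomic-distinctness tree).
#' @param species community members, length >= 2.
#' @return PSV in [0, 1].
#' @export
variability_psv <- function(tree, species) {
  species <- unique(species)
  n <- length(species)
  if (n < 2) stopf("variability is undefined for monocultures")
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown))
    stopf("species not in tree: %s", paste(unknown, collapse = ", "))
  # subsetting the full-tree branch-length covariance keeps root-shared
  # history that ape's tip pruning would discard
  C <- ape::vcv(tree, corr = TRUE)[species, species]
  (n * sum(diag(C)) - sum(C)) / (n * (n - 1))
}

#' Taxonomic-distinctness tree
#'
#' Pairwise distance between species = number of rank levels (species,
#' genus, family, order) one must ascend before the two taxa join, each
#' level one unit step; UPGMA clustering of those distances, returned as an
#' ultrametric \code{phylo} usable by \code{\link{variability_psv}}.
#'
#' @param taxonomy data.frame with columns \code{species}, \code{genus},
#'   \code{family}, \code{order}; species unique.
#' @return an \code{ape::phylo}.
#' @export
taxonomic_distinctness_tree <- function(taxonomy) {
  req <- c("species", "genus", "family", "order")
  if (!all(req %in% names(taxonomy)))
    stopf("taxonomy needs columns: %s", paste(req, collapse = ", "))
  if (anyDuplicated(taxonomy$species))
    stopf("duplicated species labels in taxonomy")
  n <- nrow(taxonomy)
  d <- matrix(0, n, n, dimnames = list(taxonomy$species, taxonomy$species))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    steps <- if (taxonomy$genus[i] == taxonomy$genus[j]) 1
    else if (taxonomy$family[i] == taxonomy$family[j]) 2
    else if (taxonomy$order[i] == taxonomy$order[j]) 3
    else 4
    d[i, j] <- d[j, i] <- steps
  }
  upgma_phylo(stats::as.dist(d))
}

#' Functional dendrogram
#'
#' UPGMA dendrogram of Euclidean distances on standardized traits, forced
#' into phylogenetic-tree format; ultrametric by construction so the
#' variability metric applies.
#'
#' @param traits standardized species x trait matrix, species as row names.
#' @return an \code{ape::phylo}.
#' @export
functional_dendrogram <- function(traits) {
  if (nrow(traits) < 2) stopf("need at least two species")
  upgma_phylo(stats::dist(traits))
}

# UPGMA (average-linkage hclust) converted to an ultrametric phylo with
# edge lengths in the distance units (hclust heights are halved by
# as.phylo so root-to-tip depth = merge height / 2 = d/2 for a cherry).
upgma_phylo <- function(d) {
  ape::as.phylo(stats::hclust(d, method = "average"))
}

#' Community diversity and variability table
#'
#' Computes, per plot, richness, PD and FD (q = 0) and the three
#' variability values (taxonomic, phylogenetic, functional). Variability is
#' NA for monocultures.
#'
#' @param communities named list: plot_id -> character vector of species
#'   present (post-mortality).
#' @param tree phylogeny (\code{phylo}).
#' @param traits standardized trait matrix.
#' @param taxonomy taxonomy table for
#'   \code{\link{taxonomic_distinctness_tree}}; optional — when NULL the
#'   taxonomic variability column is NA.
#' @return data.frame keyed by plot_id.
#' @export
diversity_table <- function(communities, tree, traits, taxonomy = NULL) {
  fun_tree <- functional_dendrogram(traits)
  tax_tree <- if (!is.null(taxonomy)) taxonomic_distinctness_tree(taxonomy)
  rows <- lapply(names(communities), function(pid) {
    sp <- unique(communities[[pid]])
    multi <- length(sp) >= 2
    data.frame(
      plot_id = pid,
      richness = length(sp),
      pd = phylo_diversity(tree, sp),
      fd = as.numeric(functional_diversity(traits, sp)),
      var_phy = if (multi) variability_psv(tree, sp) else NA_real_,
      var_fun = if (multi) variability_psv(fun_tree, sp) else NA_real_,
      var_tax = if (multi && !is.null(tax_tree))
        variability_psv(tax_tree, sp) else NA_real_
    )
  })
  do.call(rbind, rows)
}
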