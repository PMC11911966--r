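example_tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")

test_that("taxonomic Hill diversity counts and weights species", {
  expect_equal(hill_taxa(c(a = 1, b = 2, c = 1, d = 5)), 4)
  expect_equal(hill_taxa(setNames(rep(3, 4), letters[1:4]), q = 1), 4)
  expect_equal(hill_taxa(c(a = 0.8, b = 0.2), q = 2), 1.4706,
               tolerance = 1e-4)
  expect_error(hill_taxa(c(a = 0)), "empty")
})

test_that("phylogenetic diversity sums pruned branch lengths to the root", {
  expect_equal(phylo_diversity(example_tree, c("A", "B")), 3)
  expect_equal(phylo_diversity(example_tree, c("A", "B", "C")),
               sum(example_tree$edge.length))
  expect_equal(phylo_diversity(example_tree, c("A", "B", "C")), 5)
  expect_equal(phylo_diversity(example_tree, "C"), 2)
  expect_error(phylo_diversity(example_tree, c("A", "X")), "X")
})

test_that("PD never decreases when a species is added", {
  set.seed(41)
  tr <- ape::rcoal(10)
  for (i in 1:20) {
    base <- sample(tr$tip.label, sample(1:8, 1))
    extra <- sample(setdiff(tr$tip.label, base), 1)
    expect_gte(phylo_diversity(tr, c(base, extra)),
               phylo_diversity(tr, base) - 1e-12)
  }
})

test_that("functional diversity is the ordered-pair distance total", {
  tr <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_equal(functional_diversity(tr, c("a", "b")), 4)
  same <- matrix(1, 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(as.numeric(functional_diversity(same, c("a", "b"))), 0)
  # three equidistant species at distance 1: six ordered pairs
  eq3 <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), 3, 2, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(functional_diversity(eq3, c("a", "b", "c")), 6,
               tolerance = 1e-9)
  expect_true(attr(functional_diversity(eq3, "a"), "singleton"))
  # brute-force double sum on random traits
  set.seed(42)
  tr5 <- matrix(rnorm(20), 5, 4, dimnames = list(letters[1:5], NULL))
  d <- as.matrix(dist(tr5))
  expect_equal(functional_diversity(tr5, letters[1:5]), sum(d))
})

test_that("PSV matches worked values, bounds and invariances", {
  expect_equal(variability_psv(example_tree, c("A", "B", "C")), 5 / 6,
               tolerance = 1e-9)
  expect_equal(variability_psv(example_tree, c("A", "B")), 0.5)
  # star trees: full independence at any richness
  for (n in 2:12) {
    star <- ape::read.tree(text = paste0(
      "(", paste(sprintf("t%d:1", 1:n), collapse = ","), ");"))
    expect_equal(variability_psv(star, star$tip.label), 1)
  }
  # branch-length rescaling leaves PSV unchanged
  scaled <- example_tree
  scaled$edge.length <- scaled$edge.length * 17.3
  expect_equal(variability_psv(scaled, c("A", "B", "C")),
               variability_psv(example_tree, c("A", "B", "C")))
  expect_error(variability_psv(example_tree, "A"), "monocultures")
})

test_that("PSV agrees with the picante reference implementation", {
  set.seed(43)
  tr <- ape::rcoal(12)
  for (i in 1:10) {
    sp <- sample(tr$tip.label, sample(2:12, 1))
    comm <- rbind(as.integer(tr$tip.label %in% sp),
                  rep(1L, length(tr$tip.label)))
    dimnames(comm) <- list(c("plot", "all"), tr$tip.label)
    ref <- picante::psv(comm, tr)$PSVs[1]
    expect_equal(variability_psv(tr, sp), unname(ref), tolerance = 1e-9)
  }
})

test_that("taxonomic distinctness uses unit rank steps", {
  tax <- data.frame(
    species = c("s1", "s2", "s3", "s4"),
    genus = c("g1", "g1", "g2", "g3"),
    family = c("f1", "f1", "f1", "f2"),
    order = rep("o1", 4))
  tr <- taxonomic_distinctness_tree(tax)
  expect_true(ape::is.ultrametric(tr))
  # congeners are closer than confamilials: pairwise PSV orders accordingly
  psv_congener <- variability_psv(tr, c("s1", "s2"))
  psv_confam <- variability_psv(tr, c("s1", "s3"))
  expect_lt(psv_congener, psv_confam)
  # cophenetic distances reproduce the step counts (UPGMA heights = d/2)
  d <- ape::cophenetic.phylo(tr)
  expect_equal(d["s1", "s2"], 1)
  expect_equal(d["s1", "s3"], 2)
  expect_equal(d["s1", "s4"], 3)
  expect_error(taxonomic_distinctness_tree(rbind(tax, tax[1, ])),
               "duplicated")
})

test_that("the distinctness tree is UPGMA on vegan-equivalent distances", {
  tax <- data.frame(
    species = sprintf("s%d", 1:6),
    genus = c("g1", "g1", "g2", "g3", "g4", "g4"),
    family = c("f1", "f1", "f1", "f2", "f3", "f3"),
    order = c("o1", "o1", "o1", "o1", "o2", "o2"))
  tr <- taxonomic_distinctness_tree(tax)
  # vegan taxa2dist with equal steps is our unit-step distance scaled to
  # 100 at the deepest split; UPGMA on it must reproduce our tree heights
  ref <- vegan::taxa2dist(
    data.frame(Genus = tax$genus, Family = tax$family, Order = tax$order,
               row.names = tax$species), varstep = FALSE)
  ref_tree <- ape::as.phylo(hclust(ref / 25, method = "average"))
  ours <- ape::cophenetic.phylo(tr)[tax$species, tax$species]
  theirs <- ape::cophenetic.phylo(ref_tree)[tax$species, tax$species]
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("functional dendrogram is UPGMA on standardized traits", {
  tr2 <- matrix(c(0, 0, 3, 0), 2, 2, dimnames = list(c("a", "b"), NULL))
  den <- functional_dendrogram(tr2)
  expect_equal(sort(den$edge.length), c(1.5, 1.5))
  tr3 <- matrix(c(0, 1, 4), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  den3 <- functional_dendrogram(tr3)
  # a and b (distance 1) join before c (distances 3 and 4)
  coph <- ape::cophenetic.phylo(den3)
  expect_lt(coph["a", "b"], coph["a", "c"])
  # duplicated species: zero-length cherry, PSV 0 for the pair
  dup <- matrix(c(0, 0, 0, 0, 5, 1), 3, 2, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), NULL))
  dend <- functional_dendrogram(dup)
  expect_equal(variability_psv(dend, c("a", "b")), 0, tolerance = 1e-12)
})

test_that("diversity table rises with richness, variability does not", {
  pool <- generate_species_pool(12, 4, seed = 8)
  des <- generate_design(pool, 3, 2, seed = 8)
  comm <- lapply(seq_len(nrow(des$plots)), function(i)
    des$plots$species[[i]])
  names(comm) <- des$plots$plot_id
  dt <- diversity_table(comm, pool$tree, pool$traits, pool$taxonomy)
  dt$planted_richness <- des$plots$richness
  expect_equal(dt$richness, des$plots$richness)
  # diversity grows with richness
  expect_gt(cor(dt$pd, dt$planted_richness, method = "spearman"), 0.8)
  expect_gt(cor(dt$fd, dt$planted_richness, method = "spearman"), 0.8)
  # variability is richness-independent by design: weak rank correlation
  mix <- dt[dt$planted_richness > 1 & dt$planted_richness < 12, ]
  rho <- cor(mix$var_phy, mix$planted_richness, method = "spearman")
  expect_lt(abs(rho), 0.5)
  expect_true(all(is.na(dt$var_fun[dt$planted_richness == 1])))
  expect_true(all(dt$var_phy >= 0 & dt$var_phy <= 1, na.rm = TRUE))
})
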