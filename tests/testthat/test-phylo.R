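star_tree <- function(n, bl = 1) {
  tr <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:%g", 1:n, bl), collapse = ","), ");"))
  tr
}

test_that("Brownian covariance matches path-length oracles", {
  st <- star_tree(5)
  expect_equal(unname(bm_covariance(st)), diag(5), ignore_attr = TRUE)
  # cherry splitting at depth 0.6 of a unit-depth tree
  tr <- ape::read.tree(text = "((A:0.4,B:0.4):0.6,C:1);")
  C <- bm_covariance(tr)
  expect_equal(C["A", "B"], 0.6)
  expect_equal(C["A", "A"], 1)
  expect_equal(C["A", "C"], 0)
  # brute-force path-enumeration oracle on a random tree
  tr2 <- simulate_tree_bm(20, seed = 3)$tree
  C2 <- bm_covariance(tr2)
  depth <- ape::node.depth.edgelength(tr2)
  mr <- ape::mrca(tr2)
  oracle <- matrix(depth[mr[tr2$tip.label, tr2$tip.label]], 20,
                   dimnames = dimnames(mr))
  expect_equal(C2, oracle[rownames(C2), colnames(C2)], tolerance = 1e-12)
})

test_that("Blomberg's K is exactly 1 on equal-branch star trees", {
  st <- star_tree(12)
  for (seed in 1:3) {
    set.seed(seed)
    y <- stats::setNames(rnorm(12), st$tip.label)
    expect_equal(blomberg_k(y, st, n_perm = 0)$statistic, 1, tolerance = 1e-10)
  }
})

test_that("K matches the independent reference implementation", {
  skip_if_not_installed("phytools")
  for (seed in c(9, 23)) {
    sim <- simulate_tree_bm(32, seed = seed)
    ours <- blomberg_k(sim$traits[, 1], sim$tree, n_perm = 0)$statistic
    ref <- as.numeric(phytools::phylosig(sim$tree, sim$traits[, 1],
                                         method = "K"))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("K and K_mult are invariant to trait scaling", {
  sim <- simulate_tree_bm(16, n_traits = 4, seed = 2)
  k1 <- blomberg_k(sim$traits[, 1], sim$tree, n_perm = 0)$statistic
  k2 <- blomberg_k(100 * sim$traits[, 1], sim$tree, n_perm = 0)$statistic
  expect_equal(k1, k2, tolerance = 1e-10)
  m1 <- k_mult(sim$traits, sim$tree, n_perm = 0)$statistic
  m2 <- k_mult(0.01 * sim$traits, sim$tree, n_perm = 0)$statistic
  expect_equal(m1, m2, tolerance = 1e-10)
})

test_that("K_mult reduces exactly to K for a single trait", {
  for (seed in 1:20) {
    sim <- simulate_tree_bm(10, seed = 300 + seed)
    y <- sim$traits[, 1] + stats::rnorm(10) * (seed %% 3 == 0)
    names(y) <- rownames(sim$traits)
    k <- blomberg_k(y, sim$tree, n_perm = 0)$statistic
    km <- k_mult(matrix(y, dimnames = list(names(y), NULL)), sim$tree,
                 n_perm = 0)$statistic
    expect_equal(km, k, tolerance = 1e-10)
  }
})

test_that("permutation test of K rejects for clustered data and is seeded", {
  sim <- simulate_tree_bm(32, bm_rate = 1, seed = 41)
  r1 <- blomberg_k(sim$traits[, 1], sim$tree, n_perm = 199, seed = 5)
  r2 <- blomberg_k(sim$traits[, 1], sim$tree, n_perm = 199, seed = 5)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$p, 0)
  expect_lte(r1$p, 1)
  # white-noise trait on the tree: no signal expected most of the time
  set.seed(6)
  y <- stats::setNames(rnorm(32), sim$tree$tip.label)
  r0 <- blomberg_k(y, sim$tree, n_perm = 199, seed = 7)
  expect_gte(r0$p, 1 / 200)
})

test_that("ancestral states match closed forms and the dense GLS oracle", {
  # star tree: root is the arithmetic mean
  st <- star_tree(8)
  y <- stats::setNames(1:8, st$tip.label)
  anc <- ancestral_states(y, st)
  expect_equal(unname(anc[1, 1]), mean(1:8), tolerance = 1e-10)
  # two-tip closed form: 1/v-weighted mean
  tr2 <- ape::read.tree(text = "(A:2,B:0.5);")
  y2 <- c(A = 1, B = 5)
  anc2 <- ancestral_states(y2, tr2)
  expect_equal(unname(anc2[1, 1]), (1 / 2 + 5 / 0.5) / (1 / 2 + 1 / 0.5),
               tolerance = 1e-12)
  # dense GLS oracle on a random tree: conditional expectation of internal
  # nodes given tips under BM with the GLS root mean
  sim <- simulate_tree_bm(15, seed = 8)
  tr <- sim$tree
  yv <- sim$traits[, 1]
  anc3 <- ancestral_states(sim$traits, tr)
  C <- bm_covariance(tr)
  Cinv <- solve(C)
  one <- rep(1, 15)
  a <- sum(Cinv %*% yv) / sum(Cinv)
  depth <- ape::node.depth.edgelength(tr)
  mrfull <- ape::mrca(tr, full = TRUE)
  for (node in 16:(15 + tr$Nnode)) {
    cvec <- depth[mrfull[node, 1:15]]
    gls <- a + sum(cvec %*% Cinv %*% (yv - a))
    expect_equal(unname(anc3[as.character(node), 1]), gls, tolerance = 1e-8)
  }
})

test_that("ancestral states agree with the reference implementation", {
  skip_if_not_installed("phytools")
  sim <- simulate_tree_bm(25, seed = 12)
  ours <- ancestral_states(sim$traits, sim$tree)
  ref <- phytools::fastAnc(sim$tree, sim$traits[, 1])
  expect_equal(unname(ours[names(ref), 1]), unname(as.numeric(ref)),
               tolerance = 1e-8)
})

test_that("phylogenetic MANCOVA reduces to ordinary MANCOVA on a star tree", {
  st <- star_tree(24)
  set.seed(14)
  Y <- matrix(rnorm(24 * 6), 24, dimnames = list(st$tip.label, NULL))
  df <- data.frame(size = rnorm(24),
                   trophic_mode = factor(rep(c("a", "b"), 12)),
                   row.names = st$tip.label)
  ord <- mancova(Y, ~ size * trophic_mode, df, n_perm = 99, seed = 3)
  phy <- phylo_lm(Y, ~ size * trophic_mode, df, st, n_perm = 99, seed = 3)
  expect_equal(phy$SS, ord$SS, tolerance = 1e-9)
  expect_equal(phy$F, ord$F, tolerance = 1e-9)
  expect_equal(phy$p, ord$p, tolerance = 1e-12)
})

test_that("whitening restores type-I error for phylogenetically correlated nulls", {
  # moderate simulation: BM null data, alpha = 0.05
  n_sim <- 120
  rej_phy <- rej_ord <- matrix(NA, n_sim, 1)
  for (i in seq_len(n_sim)) {
    sim <- simulate_tree_bm(24, seed = 5000 + i)
    tr <- sim$tree
    Y <- simulate_bm_traits(tr, n_traits = 3, seed = 6000 + i)
    x <- simulate_bm_traits(tr, n_traits = 1, seed = 7000 + i)
    df <- data.frame(size = as.vector(x), row.names = rownames(Y))
    phy <- phylo_lm(Y, ~ size, df, tr, n_perm = 99, seed = i)
    ord <- mancova(Y, ~ size, df, n_perm = 99, seed = i)
    rej_phy[i] <- phy$p[1] <= 0.05
    rej_ord[i] <- ord$p[1] <= 0.05
  }
  expect_lt(mean(rej_phy), 0.12)
  # the uncorrected test on the same data is anticonservative
  expect_gt(mean(rej_ord), mean(rej_phy))
})

test_that("phylogenetic regression has power against real effects", {
  hits <- vapply(1:25, function(i) {
    sim <- simulate_tree_bm(36, seed = 8000 + i)
    x <- simulate_bm_traits(sim$tree, n_traits = 1, seed = 8500 + i)
    Y <- outer(as.vector(x), rep(1, 3)) +
      simulate_bm_traits(sim$tree, bm_rate = 0.5, n_traits = 3,
                         seed = 9000 + i)
    rownames(Y) <- rownames(x)
    df <- data.frame(size = as.vector(x), row.names = rownames(x))
    phylo_lm(Y, ~ size, df, sim$tree, n_perm = 99, seed = i)$p[1] <= 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.8)
})

test_that("species missing from tree or data are handled explicitly", {
  sim <- simulate_tree_bm(10, seed = 1)
  y <- sim$traits[, 1]
  names(y)[1] <- "not_a_tip"
  expect_error(blomberg_k(y, sim$tree), "missing from the data")
  y2 <- c(sim$traits[, 1], extra = 1)
  expect_warning(blomberg_k(y2, sim$tree, n_perm = 0), "absent from the tree")
})

test_that("Newick I/O validates and round trips", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tmp)
  tr <- read_newick(tmp)
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(max(ape::node.depth.edgelength(tr)), 2)
  out <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, out)
  tr2 <- read_newick(out)
  expect_equal(ape::write.tree(tr2), ape::write.tree(tr))
  writeLines("((A:1,A:1):1,C:2);", tmp)
  expect_error(read_newick(tmp), "duplicate tip labels")
  writeLines("((A,B),C);", tmp)
  expect_error(read_newick(tmp), "branch lengths")
})

test_that("phylomorphospace coordinates cover tips and internal nodes", {
  sim <- simulate_species_set(population_params(n_species = 12, seed = 21))
  X <- shape_matrix(sim$outlines)
  m <- fit_pca(X)
  tr <- simulate_tree_bm(12, seed = 2)$tree
  tr$tip.label <- rownames(X)
  pm <- phylomorphospace_coords(m, tr)
  expect_equal(sum(pm$nodes$is_tip), 12)
  expect_equal(nrow(pm$nodes), 12 + tr$Nnode)
  tipsc <- pm$nodes[pm$nodes$is_tip, ]
  expect_equal(unname(as.matrix(tipsc[, 2:3])),
               unname(m$scores[tipsc$node_id, 1:2]), tolerance = 1e-12)
})
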