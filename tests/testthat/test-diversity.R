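test_that("shannon entropy matches direct evaluation and its bounds", {
  expect_equal(as.numeric(shannon(c(10, 0, 0))), 0)
  expect_equal(as.numeric(shannon(c(1, 1, 1, 1))), 2)
  # hand evaluation of -sum p log2 p for (0.5, 0.3, 0.2)
  expect_equal(as.numeric(shannon(c(5, 3, 2))), 1.4854753, tolerance = 1e-7)
  expect_error(shannon(c(0, 0)), "all-zero")

  # natural-log base option
  expect_equal(as.numeric(shannon(c(5, 3, 2), base = exp(1))),
               1.4854753 * log(2), tolerance = 1e-7)

  # entropy never exceeds log2 richness on random samples
  set.seed(1)
  for (i in 1:25) {
    x <- rmultinom(1, 100, runif(8))[, 1]
    expect_lte(as.numeric(shannon(x)), log2(sum(x > 0)) + 1e-12)
  }
})

test_that("weighted UniFrac handles the closed-form cases", {
  tr <- cherry_tree()
  tab <- rbind(A = c(feature_a = 10, feature_b = 0),
               B = c(feature_a = 0, feature_b = 10),
               C = c(feature_a = 10, feature_b = 0))
  d <- as.matrix(weighted_unifrac(tab, tr))
  expect_equal(d["A", "C"], 0)          # identical compositions
  expect_equal(d["A", "B"], 2)          # complete separation: both branches
  # normalized variant rescales to [0, 1]
  dn <- as.matrix(weighted_unifrac(tab, tr, normalized = TRUE))
  expect_equal(dn["A", "B"], 1)

  expect_error(weighted_unifrac(
    rbind(A = c(feature_x = 1)), tr), "missing from tree")
})

test_that("weighted UniFrac agrees with the per-branch enumeration oracle", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    n_leaves <- sample(3:10, 1)
    tr <- ape::rtree(n_leaves)
    tr$edge.length <- rexp(nrow(tr$edge)) + 0.05
    tab <- random_count_table(6, tr$tip.label)
    tab[1, ] <- tab[1, ] + 1            # guard all-zero rows
    d_impl <- as.matrix(weighted_unifrac(tab, tr))
    d_oracle <- unifrac_oracle(tab, tr)
    worst <- max(worst, max(abs(d_impl - d_oracle)))
    # metric sanity on every instance
    expect_true(all(d_impl >= 0))
    expect_equal(d_impl, t(d_impl))
    expect_true(all(diag(d_impl) == 0))
  }
  expect_lt(worst, 1e-10)

  # normalized variant against the same oracle
  set.seed(7)
  tr <- ape::rtree(8); tr$edge.length <- rexp(nrow(tr$edge)) + 0.05
  tab <- random_count_table(5, tr$tip.label)
  expect_equal(as.matrix(weighted_unifrac(tab, tr, normalized = TRUE)),
               unifrac_oracle(tab, tr, normalized = TRUE),
               tolerance = 1e-10)
})

test_that("weighted UniFrac matches the phyloseq implementation", {
  skip_if_not_installed("phyloseq")
  set.seed(3)
  tr <- ape::rtree(12); tr$edge.length <- rexp(nrow(tr$edge)) + 0.05
  tab <- random_count_table(6, tr$tip.label)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(t(tab), taxa_are_rows = TRUE), phyloseq::phy_tree(tr))
  ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = FALSE))
  got <- as.matrix(weighted_unifrac(tab, tr))
  expect_equal(got[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
})

test_that("pcoa reproduces hand-computed and Euclidean geometry", {
  # degenerate all-zero matrix
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  pz <- pcoa(z, 2)
  expect_true(all(pz$eigenvalues == 0))
  expect_true(all(pz$coordinates == 0))

  # three equidistant points: -1/2 J D^2 J has eigenvalues (0.5, 0.5, 0)
  D <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D) <- 0
  p3 <- pcoa(D, 3)
  expect_equal(sort(p3$eigenvalues, decreasing = TRUE), c(0.5, 0.5, 0),
               tolerance = 1e-12)

  # a Euclidean configuration is reconstructed exactly
  set.seed(10)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  D2 <- as.matrix(dist(X))
  p <- pcoa(D2, 2)
  expect_equal(as.matrix(dist(p$coordinates)), D2, tolerance = 1e-8)
  # proportion explained sums to <= 1 and uses positive eigenvalues only
  expect_lte(sum(p$proportion_explained), 1 + 1e-12)
  expect_equal(sum(p$proportion_explained), 1, tolerance = 1e-9)

  # agreement with cmdscale up to the fixed sign convention
  ref <- cmdscale(D2, k = 2)
  for (j in 1:2)
    expect_equal(abs(p$coordinates[, j]), abs(ref[, j]), tolerance = 1e-8)
  # sign convention: smallest sample ID non-negative on every axis
  lead <- sort(rownames(D2))[1]
  expect_true(all(p$coordinates[lead, ] >= 0))

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2,
                           dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("biplot features sit at abundance-weighted sample centroids", {
  set.seed(11)
  tab <- random_count_table(8, paste0("f", 1:6))
  rel <- relative_abundance(tab)
  D <- as.matrix(dist(rel))
  ord <- pcoa(D, 3)

  bp <- biplot_features(ord, rel)
  # brute-force weighted means
  for (f in bp$feature) {
    w <- rel[, f] / sum(rel[, f])
    expected <- colSums(ord$coordinates * w)
    got <- unlist(bp[bp$feature == f, paste0("PC", 1:3)])
    expect_equal(unname(got), unname(expected), tolerance = 1e-12)
  }
  expect_false(is.unsorted(rev(bp$importance)))

  # a feature present in exactly one sample lands on that sample
  tab2 <- cbind(tab, solo = 0)
  tab2[3, "solo"] <- 5
  rel2 <- relative_abundance(tab2)
  ord2 <- pcoa(as.matrix(dist(rel2)), 2)
  bp2 <- biplot_features(ord2, rel2)
  expect_equal(unname(unlist(bp2[bp2$feature == "solo", c("PC1", "PC2")])),
               unname(ord2$coordinates[3, ]), tolerance = 1e-12)

  # a uniformly distributed feature sits at the centered origin
  rel3 <- cbind(rel2 * 0.9, unif = 0.1)
  bp3 <- biplot_features(ord2, rel3)
  expect_equal(unname(unlist(bp3[bp3$feature == "unif", c("PC1", "PC2")])),
               c(0, 0), tolerance = 1e-10)

  # zero-abundance features are excluded with a warning
  rel4 <- cbind(rel2, ghost = 0)
  expect_warning(bp4 <- biplot_features(ord2, rel4), "ghost")
  expect_false("ghost" %in% bp4$feature)
})

test_that("permanova matches the distance-sum identity and the enumeration oracle", {
  set.seed(5)
  X <- matrix(rnorm(12), 6, 2)
  rownames(X) <- paste0("s", 1:6)
  D <- dist(X)
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     grp = rep(c("a", "b"), each = 3),
                     stringsAsFactors = FALSE)

  res <- permanova(D, meta, "grp", n_perm = 9999, seed = 1)
  # single-factor term SS equals the classical among-group SS
  oracle <- permanova_oracle_f(D, meta$grp)
  expect_equal(res$sum_sq[res$term == "grp"], oracle$ss_among,
               tolerance = 1e-9)
  expect_equal(res$f[res$term == "grp"], oracle$f, tolerance = 1e-9)
  # partition is conserved
  expect_equal(sum(res$sum_sq[res$term %in% c("grp", "Residual")]),
               res$sum_sq[res$term == "Total"], tolerance = 1e-9)

  # exact p by full enumeration of the 20 distinct relabelings
  groups <- meta$grp
  fs <- apply(combn(6, 3), 2, function(idx) {
    g <- rep("b", 6); g[idx] <- "a"
    permanova_oracle_f(D, g)$f
  })
  p_exact <- mean(fs >= oracle$f - 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 9999)
  expect_lt(abs(res$p[res$term == "grp"] - p_exact), 3 * se + 2e-4)
})

test_that("permanova separates groups maximally when structure is perfect", {
  # zero within-group, positive between-group distances
  D <- matrix(1, 6, 6)
  D[1:3, 1:3] <- 0
  D[4:6, 4:6] <- 0
  dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     grp = rep(c("a", "b"), each = 3))
  res <- permanova(D, meta, "grp", n_perm = 999, seed = 2)
  # only relabelings equivalent to the observed split attain F_obs:
  # 2 of choose(6,3) = 20 -> exact p = 0.1; permutation p within MC error
  expect_lt(res$p[res$term == "grp"], 0.2)
  expect_gt(res$f[res$term == "grp"], 1e6)

  expect_error(permanova(D, transform(meta, grp = "a"), "grp"), "constant")
  expect_warning(permanova(D, transform(meta, pid = paste0("s", 1:6)),
                           "grp", strata = "pid", n_perm = 99),
                 "degenerate")
})

test_that("strata-restricted permutations shuffle within participants only", {
  set.seed(6)
  n_pid <- 8
  meta <- data.frame(sample_id = sprintf("s%02d", 1:(2 * n_pid)),
                     pid = rep(sprintf("p%02d", 1:n_pid), each = 2),
                     week = rep(c(0, 24), n_pid))
  # strong participant effect, no week effect: without strata the pid
  # effect masks everything; within-pid permutation isolates week
  base <- rep(rnorm(n_pid, sd = 5), each = 2)
  y <- base + rnorm(2 * n_pid, sd = 0.1)
  D <- dist(y)
  attr(D, "Labels") <- meta$sample_id
  res <- permanova(D, meta, "week", strata = "pid", n_perm = 499, seed = 3)
  expect_true(res$p[res$term == "week"] > 0.05)   # null week effect
  # now plant a week effect inside each participant
  y2 <- base + rep(c(0, 3), n_pid)
  D2 <- dist(y2)
  attr(D2, "Labels") <- meta$sample_id
  res2 <- permanova(D2, meta, "week", strata = "pid", n_perm = 499, seed = 3)
  expect_lt(res2$p[res2$term == "week"], 0.05)
})
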