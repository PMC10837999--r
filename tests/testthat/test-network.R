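test_that("module binning groups correlated features and leaves the rest single", {
  set.seed(13)
  base <- random_count_table(30, paste0("f", 1:4), min_total = 200,
                             max_total = 400)
  # duplicate a feature exactly: r = 1, a guaranteed 2-member module
  tab <- cbind(base, f1_copy = base[, "f1"])
  bn <- bin_modules(tab, min_r = 0.35)
  mod <- bn$membership$module[bn$membership$feature == "f1"]
  expect_false(is.na(mod))
  expect_identical(mod, bn$membership$module[bn$membership$feature == "f1_copy"])
  expect_setequal(bn$modules[[mod]], c("f1", "f1_copy"))
  expect_equal(bn$table[, mod], 2 * base[, "f1"], ignore_attr = TRUE)

  # module members leave the single-feature list; totals are conserved
  expect_false("f1" %in% colnames(bn$table))
  expect_equal(rowSums(bn$table), rowSums(tab), ignore_attr = TRUE)
})

test_that("module binning recovers planted correlation blocks", {
  set.seed(17)
  n <- 60
  latent <- matrix(rnorm(3 * n), n, 3)
  feats <- do.call(cbind, lapply(1:3, function(b) {
    sapply(1:4, function(j) latent[, b] + rnorm(n, sd = 0.25))
  }))
  feats <- apply(exp(feats), 2, function(x) round(50 * x))
  dimnames(feats) <- list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:12))
  feats[1, ] <- feats[1, ] + 1
  bn <- bin_modules(feats, min_r = 0.5)
  expect_equal(length(bn$modules), 3)
  truth <- split(sprintf("f%02d", 1:12), rep(1:3, each = 4))
  for (m in bn$modules)
    expect_true(any(vapply(truth, function(t) setequal(m, t), logical(1))))

  # every within-module pair respects the correlation floor
  rel <- feats / rowSums(feats)
  r <- cor(rel, method = "spearman")
  for (m in bn$modules) {
    rm <- r[m, m]
    expect_true(all(rm[upper.tri(rm)] >= 0.5))
  }

  # binning is invariant to feature order, up to module labels
  perm <- sample(ncol(feats))
  bn2 <- bin_modules(feats[, perm], min_r = 0.5)
  sets1 <- lapply(bn$modules, sort)
  sets2 <- lapply(bn2$modules, sort)
  expect_true(all(vapply(sets1, function(s)
    any(vapply(sets2, identical, logical(1), s)), logical(1))))
})

test_that("independently shuffled features rarely form modules", {
  set.seed(19)
  hits <- vapply(1:100, function(i) {
    tab <- random_count_table(150, paste0("f", 1:15), min_total = 300,
                              max_total = 500)
    length(bin_modules(tab, min_r = 0.35)$modules) > 0
  }, logical(1))
  expect_gte(mean(!hits), 0.95)
})

test_that("constant features are left unbinned with a warning", {
  set.seed(41)
  # equal sample totals + equal counts -> constant relative abundance
  tab <- t(vapply(1:20, function(i) {
    x <- rmultinom(1, 90, runif(3))[, 1]
    c(x, flat = 10)
  }, numeric(4)))
  dimnames(tab) <- list(sprintf("s%02d", 1:20), c("f1", "f2", "f3", "flat"))
  expect_warning(bn <- bin_modules(tab, min_r = 0.35), "flat")
  expect_true(is.na(bn$membership$module[bn$membership$feature == "flat"]))
  expect_true("flat" %in% colnames(bn$table))
})

test_that("dffits matches the leave-one-out oracle and conventions", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(15:30, 1)
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- X %*% c(1, 2, -1) + rnorm(n)
    d <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3])
    fit <- lm(y ~ x1 + x2, data = d)
    got <- dffits_ols(fit)
    # leave-one-out oracle: change in fitted value over deleted-fit scale
    oracle <- vapply(seq_len(n), function(j) {
      fit_j <- lm(y ~ x1 + x2, data = d[-j, ])
      pred_j <- predict(fit_j, newdata = d[j, ])
      s_j <- summary(fit_j)$sigma
      h_j <- lm.influence(fit)$hat[j]
      (fitted(fit)[j] - pred_j) / (s_j * sqrt(h_j))
    }, numeric(1))
    expect_equal(got, oracle, tolerance = 1e-8, ignore_attr = TRUE)
  }

  # agreement with stats::dffits on a regular fit
  fit <- lm(dist ~ speed, data = cars)
  expect_equal(dffits_ols(fit), unname(dffits(fit)), tolerance = 1e-10)

  # exact fits have zero influence by the limit convention
  d0 <- data.frame(x = 1:10, y = 2 * (1:10) + 3)
  expect_equal(dffits_ols(lm(y ~ x, data = d0)), rep(0, 10))

  # a gross outlier is flagged past the |DFFITS| >= 2 screen
  set.seed(5)
  d1 <- data.frame(x = 1:20, y = 2 * (1:20) + rnorm(20, sd = 0.5))
  d1$y[20] <- d1$y[20] + 40
  expect_gt(max(abs(dffits_ols(lm(y ~ x, data = d1)))), 2)
})

test_that("pair models recover constructed per-cohort slopes", {
  set.seed(29)
  n <- 90
  cohort <- rep(c("Naive", "Exp", "HC"), each = n / 3)
  f <- runif(n, 0, 0.2)
  rc <- runif(n, 1000, 5000)
  # naive slope 2, zero elsewhere, no noise
  y <- 5 + 0.001 * rc + ifelse(cohort == "Naive", 2 * f, 0)
  pf <- fit_pair_model(y, f, cohort, rc)
  expect_equal(unname(pf$slopes[c("Naive", "Exp", "HC")]), c(2, 0, 0),
               tolerance = 1e-10)
  expect_lt(pf$slope_p[["Naive"]], 1e-10)
  expect_equal(pf$max_dffits, 0)

  # normal-equations oracle on noisy data
  y2 <- y + rnorm(n)
  pf2 <- fit_pair_model(y2, f, cohort, rc)
  cohort_f <- relevel(factor(cohort), "Naive")
  X <- model.matrix(~ rc + f * cohort_f)
  beta <- solve(crossprod(X), crossprod(X, y2))
  expect_equal(pf2$slopes[["Naive"]], unname(beta["f", 1]), tolerance = 1e-9)
  expect_equal(pf2$slopes[["Exp"]],
               unname(beta["f", 1] + beta["f:cohort_fExp", 1]),
               tolerance = 1e-9)

  # reference-coding invariance of the derived per-cohort slopes
  pf_exp <- fit_pair_model(y2, f, cohort, rc, reference = "Exp")
  expect_equal(pf_exp$slopes[names(pf2$slopes)], pf2$slopes,
               tolerance = 1e-10)

  # degenerate constant marker
  pf0 <- fit_pair_model(rep(3, n), f, cohort, rc)
  expect_true(pf0$degenerate)
  expect_equal(unname(pf0$slopes), rep(0, 3))

  expect_error(fit_pair_model(y, f, rep(c("Naive", "Exp", "HC"),
                                        c(2, 44, 44)), rc), ">= 3 samples")
})

test_that("the filter cascade keeps exactly the qualifying fits", {
  mk_fit <- function(marker, feature, p_overall = 1e-4, adj_r2 = 0.5,
                     ref_p = 0.01, int_exp = 0.01, int_hc = 0.5,
                     dff = 1, slope = 1) {
    data.frame(marker = marker, feature = feature, timepoint = 0L,
               p_overall = p_overall, adj_r2 = adj_r2, max_dffits = dff,
               n = 90, ref_slope = slope, ref_slope_p = ref_p,
               degenerate = FALSE, unusable = FALSE,
               slope_p_Naive = ref_p, slope_p_Exp = 0.5, slope_p_HC = 0.5,
               interaction_p_Exp = int_exp, interaction_p_HC = int_hc,
               stringsAsFactors = FALSE)
  }
  # exactly one of ten fits satisfies all five criteria
  fits <- rbind(
    mk_fit("il6", "f01"),                                   # passes
    mk_fit("il6", "f02", p_overall = 0.9),                  # FDR fails
    mk_fit("il6", "f03", adj_r2 = 0.1),                     # R2 fails
    mk_fit("il6", "f04", ref_p = 0.2),                      # slope fails
    mk_fit("il6", "f05", int_exp = 0.3, int_hc = 0.3),      # interaction fails
    mk_fit("il6", "f06", dff = 3),                          # DFFITS fails
    mk_fit("crp", "f07", p_overall = 0.8),
    mk_fit("crp", "f08", p_overall = 0.7),
    mk_fit("crp", "f09", ref_p = 0.9),
    mk_fit("crp", "f10", adj_r2 = 0.2))
  edges <- filter_cascade(fits, mode = "naive_specific")
  expect_equal(nrow(edges), 1)
  expect_equal(edges$feature, "f01")
  expect_equal(edges$sign, "+")

  # negative reference slope flips the sign
  neg <- filter_cascade(mk_fit("il6", "f01", slope = -2),
                        mode = "naive_specific")
  expect_equal(neg$sign, "-")

  # empty input gives an empty edge list, not an error
  expect_equal(nrow(filter_cascade(fits[0, ], mode = "naive_specific")), 0)

  # order invariance
  shuffled <- filter_cascade(fits[sample(nrow(fits)), ],
                             mode = "naive_specific")
  expect_equal(shuffled, edges)

  # mixing timepoints breaks the FDR family definition
  fits2 <- fits
  fits2$timepoint[1] <- 24L
  expect_error(filter_cascade(fits2), "timepoint")

  # two-cohort mode needs any slope significant plus a slope difference
  f2 <- mk_fit("il6", "f01")
  f2$slope_p_Naive <- NULL
  f2$ref_slope_p <- 0.5
  f2$slope_p_Exp <- 0.01
  edges2 <- filter_cascade(f2, mode = "exp_vs_hc")
  expect_equal(nrow(edges2), 1)
})

test_that("networks conserve edges and round-trip through JSON", {
  # empty network still declares the immune nodes
  net0 <- build_network(filter_cascade(NULL))
  expect_equal(nrow(net0$edges), 0)
  expect_setequal(net0$nodes$id[net0$nodes$type == "immune"],
                  immune_markers())
  expect_true(all(net0$degree$degree == 0))

  set.seed(37)
  markers <- c("cd4_pd1_pct", "cd8_pd1_pct", "il6", "crp")
  edges <- data.frame(
    marker = sample(markers, 29, TRUE),
    feature = sprintf("f%02d", 1:29),
    sign = sample(c("+", "-"), 29, TRUE),
    slope = rnorm(29), p_slope = runif(29, 1e-5, 0.05),
    fdr_p = runif(29, 0, 0.2), adj_r2 = runif(29, 0.25, 0.9),
    max_dffits = runif(29, 0, 2), stringsAsFactors = FALSE)
  net <- build_network(edges, markers = markers)
  # degree conservation: each edge contributes one immune + one microbe end
  expect_equal(sum(net$degree$degree), 2 * 29)
  expect_equal(sum(net$degree$degree[net$degree$id %in% markers]), 29)
  expect_equal(net$edges$width, -log10(net$edges$p_slope))

  path <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path, tsv = tsv)
  back <- read_network(path)
  expect_equal(back$edges[c("immune", "feature", "sign")],
               net$edges[c("immune", "feature", "sign")])
  expect_equal(back$edges$p_slope, net$edges$p_slope, tolerance = 1e-12)
  tsv_edges <- read.delim(tsv)
  expect_equal(nrow(tsv_edges), 29)

  dup <- rbind(edges, edges[1, ])
  expect_error(build_network(dup, markers = markers), "duplicate")
})

test_that("the cascade recovers planted edges across seeds and stays quiet under the null", {
  planted <- list(
    list(feature = 1, marker = "cd4_pd1_pct", cohort = "Naive", slope = 250),
    list(feature = 3, marker = "il6", cohort = "Naive", slope = 200))
  recovered <- 0; false_edges <- 0
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    cfg <- synth_config(seed = 100 + s, n_per_cell = 30, n_features = 40,
                        depth_mean = 5000, gradient_strength = 0,
                        planted_edges = planted,
                        immune_cohort_effects = FALSE)
    ds <- generate_dataset(cfg)
    res <- association_network(ds$counts, ds$meta, ds$immune, timepoint = 0)
    hit <- function(pe) {
      feat <- colnames(ds$counts)[pe$feature]
      any(res$edges$marker == pe$marker &
            vapply(res$edges$feature, function(f) {
              f == feat || (f %in% names(res$binning$modules) &&
                              feat %in% res$binning$modules[[f]])
            }, logical(1)))
    }
    hits <- vapply(planted, hit, logical(1))
    recovered <- recovered + sum(hits)
    false_edges <- false_edges + (nrow(res$edges) - sum(hits))
  }
  expect_gte(recovered / (2 * n_seeds), 0.8)
  expect_lte(false_edges / n_seeds, 0.2 * 2)
})
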