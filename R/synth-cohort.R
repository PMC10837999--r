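#' Immune marker names used throughout the package
#'
#' Six T-cell percentages (percent of parent CD4+ or CD8+ T cells) plus two
#' plasma inflammation markers: IL-6 (pg/mL) and CRP (mg/L).
#'
#' @return Character vector of the eight marker column names.
#' @export
immune_markers <- function() {
  c("cd4_cd38_hladr_pct", "cd8_cd38_hladr_pct",
    "cd4_pd1_pct", "cd8_pd1_pct",
    "cd4_cd103_pct", "cd8_cd103_pct",
    "il6", "crp")
}

# CD4-lineage markers: the only ones subject to missingness/imputation
cd4_markers <- function() {
  c("cd4_cd38_hladr_pct", "cd4_pd1_pct", "cd4_cd103_pct")
}

pct_markers <- function() setdiff(immune_markers(), c("il6", "crp"))

#' Configuration for the synthetic cohort generator
#'
#' Describes a two-timepoint (week 0, week 24), three-cohort (ART-naive,
#' ART-experienced, healthy control), two-location (rural, urban) study with
#' repeated measures per participant, Dirichlet-multinomial compositional
#' counts along a Prevotella-rich/Bacteroides-rich gradient, viral-load
#' distributions that drive the exclusion cascade, and optional planted
#' linear microbe-to-immune effects restricted to one cohort.
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param n_per_cell Participants per cohort x location cell. Either a single
#'   integer or a named vector over cohorts `c(Naive=, Exp=, HC=)`. The
#'   default mirrors an enrollment of 162 split roughly 81/39/42 across two
#'   locations.
#' @param n_features Number of ASV-like features (>= 2).
#' @param depth_mean,depth_dispersion Negative-binomial sequencing-depth
#'   model (mean and size).
#' @param gradient_strength Magnitude of the rural/urban compositional shift
#'   applied to the two designated feature blocks (log-scale multiplier;
#'   0 disables the gradient).
#' @param dirichlet_concentration Total concentration of the Dirichlet
#'   composition prior; lower values give more between-sample overdispersion.
#' @param planted_edges List of planted effects, each a list with elements
#'   `feature` (index), `marker` (name from [immune_markers()]), `cohort`
#'   and `slope`: the marker gains `slope` times the feature's relative
#'   abundance, in that cohort only.
#' @param immune_noise_sd Residual SD added to every immune value.
#' @param pid_intercept_sd SD of the participant-level random intercept
#'   (drawn per participant and marker).
#' @param missing_rate Fraction of CD4-lineage marker values set missing
#'   completely at random.
#' @param viremia_rates Named probabilities controlling exclusions:
#'   `naive_inconsistent` (naive baseline viral load < 20, inconsistent with
#'   declared status), `naive_week24` (naive week-24 viral load > 200,
#'   virologic failure), `exp_baseline` (experienced baseline viral
#'   load > 200).
#' @param dropout_rate Probability a participant misses the week-24 visit.
#' @param immune_cohort_effects Apply the built-in cohort and week shifts to
#'   the immune markers (default TRUE). Setting FALSE gives a
#'   no-nuisance-effect generator in which planted feature slopes are the
#'   only systematic immune signal — the configuration used for
#'   planted-edge recovery checks.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_per_cell = c(Naive = 34, Exp = 17, HC = 21),
                         n_features = 100L,
                         depth_mean = 25000, depth_dispersion = 10,
                         gradient_strength = 1.5,
                         dirichlet_concentration = 50,
                         planted_edges = list(),
                         immune_noise_sd = 3,
                         pid_intercept_sd = 2,
                         missing_rate = 0.07,
                         viremia_rates = c(naive_inconsistent = 14 / 81,
                                           naive_week24 = 15 / 67,
                                           exp_baseline = 6 / 39),
                         dropout_rate = 0.1,
                         immune_cohort_effects = TRUE) {
  cohorts <- c("Naive", "Exp", "HC")
  if (length(n_per_cell) == 1L && is.null(names(n_per_cell)))
    n_per_cell <- stats::setNames(rep(n_per_cell, 3L), cohorts)
  if (!all(cohorts %in% names(n_per_cell)))
    stop("n_per_cell must be a scalar or named over cohorts Naive/Exp/HC")
  n_per_cell <- n_per_cell[cohorts]
  stopifnot(all(n_per_cell >= 1), n_features >= 2,
            depth_mean > 0, depth_dispersion > 0,
            gradient_strength >= 0, dirichlet_concentration > 0,
            immune_noise_sd >= 0, pid_intercept_sd >= 0,
            missing_rate >= 0, missing_rate <= 1,
            all(viremia_rates >= 0), all(viremia_rates <= 1),
            dropout_rate >= 0, dropout_rate <= 1)
  needed <- c("naive_inconsistent", "naive_week24", "exp_baseline")
  if (!all(needed %in% names(viremia_rates)))
    stop("viremia_rates must name: ", paste(needed, collapse = ", "))
  for (pe in planted_edges) {
    if (!all(c("feature", "marker", "cohort", "slope") %in% names(pe)))
      stop("each planted edge needs feature, marker, cohort, slope")
    if (pe$feature < 1 || pe$feature > n_features)
      stop("planted edge references unknown feature index ", pe$feature)
    if (!pe$marker %in% immune_markers())
      stop("planted edge references unknown marker '", pe$marker, "'")
    if (!pe$cohort %in% cohorts)
      stop("planted edge references unknown cohort '", pe$cohort, "'")
  }
  structure(list(seed = as.integer(seed), n_per_cell = n_per_cell,
                 n_features = as.integer(n_features),
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 gradient_strength = gradient_strength,
                 dirichlet_concentration = dirichlet_concentration,
                 planted_edges = planted_edges,
                 immune_noise_sd = immune_noise_sd,
                 pid_intercept_sd = pid_intercept_sd,
                 missing_rate = missing_rate,
                 viremia_rates = viremia_rates,
                 dropout_rate = dropout_rate,
                 immune_cohort_effects = isTRUE(immune_cohort_effects)),
            class = "synth_config")
}

# Fixed offsets deriving stage sub-streams from the one configured seed, so
# e.g. changing n_features cannot reshuffle the metadata draws.
.seed_offsets <- c(tree = 1000003L, meta = 1L, counts = 2L,
                   immune = 3L, missing = 4L)

#' Generate a random rooted phylogeny over synthetic features
#'
#' Random binary topology with exponential(rate 1) branch lengths, leaves
#' labeled `feature_0001 ...`. Stands in for a real ASV insertion tree in
#' tests and simulations.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An [ape::phylo] rooted tree with positive branch lengths.
#' @export
generate_tree <- function(n_leaves, seed = 1L) {
  if (n_leaves < 2) stop("n_leaves must be >= 2")
  set.seed(seed)
  tree <- ape::rtree(n_leaves, rooted = TRUE, br = NULL)
  # leaves relabeled in tip order; topology already randomized
  tree$tip.label <- sprintf("feature_%04d", seq_len(n_leaves))
  set.seed(seed + .seed_offsets[["tree"]])
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1)
  tree
}

# Dirichlet draw via normalized gammas
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

.half <- function(p) stats::rbinom(length(p), 1L, p) == 1L

#' Generate a complete synthetic cohort dataset
#'
#' Produces the four linked tables every downstream stage consumes: a
#' samples x features count matrix, a rooted feature phylogeny, per-sample
#' metadata (participant, cohort, location, week, viral load, demographics)
#' and the eight-marker immune panel. Two designated feature blocks (10% of
#' features each, recorded in the ground truth) carry the rural/urban
#' compositional gradient, emulating the Prevotella/Bacteroides axis. Immune
#' values are a marker baseline plus cohort and week effects, any planted
#' feature slopes (applied in the planted cohort only, on relative
#' abundance from the non-rarefied counts), a participant random intercept,
#' and Gaussian noise; percentages are clipped to [0, 100] and
#' concentrations to >= 0.
#'
#' @param config A [synth_config()].
#' @return A list with elements `counts` (integer matrix, samples x
#'   features), `tree`, `meta` (data.frame), `immune` (data.frame keyed by
#'   sample_id), and `truth` (block membership and planted edges).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cohorts <- c("Naive", "Exp", "HC")
  locations <- c("rural", "urban")
  nf <- config$n_features
  vr <- config$viremia_rates

  ## ---- metadata ----
  set.seed(config$seed + .seed_offsets[["meta"]])
  cells <- expand.grid(cohort = cohorts, location = locations,
                       stringsAsFactors = FALSE)
  meta0 <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    n <- config$n_per_cell[[cells$cohort[i]]]
    data.frame(cohort = cells$cohort[i], location = cells$location[i],
               idx = seq_len(n), stringsAsFactors = FALSE)
  }))
  npid <- nrow(meta0)
  pid <- sprintf("P%04d", seq_len(npid))

  age_med <- c(Naive = 35, Exp = 46, HC = 35.5)
  age <- round(pmax(18, stats::rnorm(npid, age_med[meta0$cohort], 8)))
  sex <- ifelse(stats::runif(npid) < 0.55, "F", "M")
  bmi <- round(pmax(14.5, stats::rnorm(npid,
    c(Naive = 22.7, Exp = 20.2, HC = 22.6)[meta0$cohort], 2.5)), 1)
  cotri <- ifelse(meta0$cohort == "Exp",
                  round(pmax(0, stats::rnorm(npid, 84, 30)), 1),
                  ifelse(meta0$cohort == "Naive" & meta0$location == "rural" &
                           stats::runif(npid) < 0.3,
                         round(stats::runif(npid, 0, 7), 1), 0))
  art_years <- ifelse(meta0$cohort == "Exp",
                      round(pmax(1, stats::rnorm(npid, 7, 4)), 1), NA_real_)

  dropout <- .half(rep(config$dropout_rate, npid))
  naive <- meta0$cohort == "Naive"
  expd <- meta0$cohort == "Exp"
  inconsistent <- naive & .half(rep(vr[["naive_inconsistent"]], npid))
  failure24 <- naive & .half(rep(vr[["naive_week24"]], npid))
  exp_virem <- expd & .half(rep(vr[["exp_baseline"]], npid))

  vl0 <- rep(NA_real_, npid)
  vl24 <- rep(NA_real_, npid)
  # naive baseline: high viremia unless inconsistent with declared status
  vl0[naive] <- ifelse(inconsistent[naive],
                       round(stats::runif(sum(naive), 0, 19.9), 1),
                       pmax(36, round(stats::rlnorm(sum(naive), log(26491), 1.4))))
  vl24[naive] <- ifelse(failure24[naive],
                        round(201 + stats::rlnorm(sum(naive), log(2000), 1)),
                        ifelse(stats::runif(sum(naive)) < 0.6, 0,
                               round(stats::runif(sum(naive), 0, 199))))
  # experienced: suppressed (point mass at 0) unless baseline-viremic
  vl0[expd] <- ifelse(exp_virem[expd],
                      round(201 + stats::rlnorm(sum(expd), log(5000), 1)),
                      ifelse(stats::runif(sum(expd)) < 0.7, 0,
                             round(stats::runif(sum(expd), 0, 103))))
  vl24[expd] <- ifelse(stats::runif(sum(expd)) < 0.7, 0,
                       round(stats::runif(sum(expd), 0, 150)))

  weeks <- c(0L, 24L)
  meta <- do.call(rbind, lapply(1:2, function(w) {
    keep <- if (w == 2L) !dropout else rep(TRUE, npid)
    data.frame(sample_id = sprintf("%s_w%02d", pid[keep], weeks[w]),
               pid = pid[keep], cohort = meta0$cohort[keep],
               location = meta0$location[keep], week = weeks[w],
               viral_load = if (w == 1L) vl0[keep] else vl24[keep],
               age = age[keep], sex = sex[keep], bmi = bmi[keep],
               bmi_category = who_bmi_category(bmi[keep]),
               cotrimoxazole_months = cotri[keep],
               art_years = art_years[keep],
               stringsAsFactors = FALSE)
  }))
  meta <- meta[order(meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL

  ## ---- counts ----
  set.seed(config$seed + .seed_offsets[["counts"]])
  nb <- max(2L, ceiling(0.1 * nf))
  prev_block <- seq_len(nb)
  bact_block <- nb + seq_len(nb)
  base_alpha <- exp(-0.04 * seq_len(nf))        # decreasing mean abundances
  g <- config$gradient_strength
  alpha_loc <- function(loc) {
    a <- base_alpha
    s <- if (loc == "rural") g / 2 else -g / 2
    a[prev_block] <- a[prev_block] * exp(s)
    a[bact_block] <- a[bact_block] * exp(-s)
    a / sum(a) * config$dirichlet_concentration
  }
  ns <- nrow(meta)
  depth <- stats::rnbinom(ns, mu = config$depth_mean,
                          size = config$depth_dispersion)
  depth <- pmax(depth, 100L)                    # guard degenerate shallow draws
  counts <- matrix(0L, ns, nf,
                   dimnames = list(meta$sample_id,
                                   sprintf("feature_%04d", seq_len(nf))))
  for (loc in locations) {
    rows <- which(meta$location == loc)
    p <- .rdirichlet(length(rows), alpha_loc(loc))
    for (j in seq_along(rows))
      counts[rows[j], ] <- stats::rmultinom(1L, depth[rows[j]], p[j, ])[, 1L]
  }

  ## ---- immune panel ----
  set.seed(config$seed + .seed_offsets[["immune"]])
  mk <- immune_markers()
  baseline <- c(cd4_cd38_hladr_pct = 8, cd8_cd38_hladr_pct = 12,
                cd4_pd1_pct = 18, cd8_pd1_pct = 20,
                cd4_cd103_pct = 5, cd8_cd103_pct = 6, il6 = 2, crp = 2)
  cohort_eff <- rbind(
    Naive = c(8, 14, 14, 16, -2, -2.5, 4, 3),
    Exp   = c(2,  4,  5,  6,  1,  2.5, 1.5, 1),
    HC    = c(0,  0,  0,  0,  0,  0,   0,   0))
  colnames(cohort_eff) <- mk
  # week-24 change: naive improves on ART; others stable
  week_eff <- rbind(
    Naive = c(-4, -8, -7, -8, 1.5, 2, -2.5, -1.5),
    Exp   = c(0, 0, 0, 0, 0, 0, 0, 0),
    HC    = c(0, 0, 0, 0, 0, 0, 0, 0))
  colnames(week_eff) <- mk
  if (!config$immune_cohort_effects) {
    cohort_eff[] <- 0
    week_eff[] <- 0
  }

  pid_int <- matrix(stats::rnorm(npid * length(mk), 0, config$pid_intercept_sd),
                    npid, length(mk), dimnames = list(pid, mk))
  rel <- counts / rowSums(counts)
  immune <- matrix(NA_real_, ns, length(mk),
                   dimnames = list(meta$sample_id, mk))
  for (m in mk) {
    v <- baseline[[m]] + cohort_eff[meta$cohort, m] +
      week_eff[meta$cohort, m] * (meta$week == 24L) +
      pid_int[meta$pid, m] +
      stats::rnorm(ns, 0, config$immune_noise_sd)
    immune[, m] <- v
  }
  # planted effects are mean-centered within the planted cohort: a slope
  # changes the marker-microbe covariance without shifting the cohort's
  # marker mean, keeping planted slopes and cohort effects orthogonal
  for (pe in config$planted_edges) {
    in_cohort <- meta$cohort == pe$cohort
    x <- rel[in_cohort, pe$feature]
    immune[in_cohort, pe$marker] <- immune[in_cohort, pe$marker] +
      pe$slope * (x - mean(x))
  }
  for (m in pct_markers()) immune[, m] <- pmin(pmax(immune[, m], 0), 100)
  for (m in c("il6", "crp")) immune[, m] <- pmax(immune[, m], 0)

  ## ---- missingness (CD4-lineage only, MCAR) ----
  set.seed(config$seed + .seed_offsets[["missing"]])
  if (config$missing_rate > 0) {
    for (m in cd4_markers()) {
      miss <- stats::runif(ns) < config$missing_rate
      immune[miss, m] <- NA_real_
    }
  }
  immune <- data.frame(sample_id = meta$sample_id, immune,
                       row.names = NULL, stringsAsFactors = FALSE)

  tree <- generate_tree(nf, config$seed)

  list(counts = counts, tree = tree, meta = meta, immune = immune,
       truth = list(prev_block = colnames(counts)[prev_block],
                    bact_block = colnames(counts)[bact_block],
                    planted_edges = config$planted_edges,
                    seed = config$seed))
}

#' WHO BMI categories
#'
#' @param bmi Numeric BMI values (kg/m^2).
#' @return Character vector of WHO band labels.
#' @export
who_bmi_category <- function(bmi) {
  cut(bmi, c(-Inf, 16, 17, 18.5, 25, 30, Inf),
      labels = c("Severe Thinness", "Moderate Thinness", "Mild Thinness",
                 "Normal", "Overweight", "Obese"),
      right = FALSE) |> as.character()
}

#' Write a generated dataset to plain-text files
#'
#' Writes the feature table (features as rows, header row of sample IDs),
#' newick tree, metadata and immune-panel TSVs, and a JSON sidecar with the
#' simulation ground truth (block membership and planted edges).
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "feature_table.tsv"),
             tree = file.path(dir, "tree.nwk"),
             meta = file.path(dir, "metadata.tsv"),
             immune = file.path(dir, "immune.tsv"),
             truth = file.path(dir, "truth.json"))
  write_feature_table(dataset$counts, paths[["table"]])
  ape::write.tree(dataset$tree, paths[["tree"]])
  utils::write.table(dataset$meta, paths[["meta"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$immune, paths[["immune"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$truth, paths[["truth"]], auto_unbox = TRUE)
  invisible(paths)
}
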