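#' Bin co-correlated features into modules
#'
#' SCNIC-style module detection: pairwise Spearman correlation of feature
#' relative abundances, complete-linkage agglomerative clustering on
#' (1 - r), and a cut at height (1 - min_r), which with complete linkage
#' guarantees every within-cluster pairwise correlation is at least
#' `min_r`. Clusters with two or more members become modules whose
#' abundance is the element-wise sum of member counts; members are removed
#' from the single-feature list. Constant features cannot be correlated and
#' are left unbinned with a warning.
#'
#' @param counts Samples x features count matrix (>= 2 features).
#' @param min_r Minimum within-module Spearman correlation (default 0.35).
#' @return List of class `module_binning`: `membership` (data.frame
#'   feature/module; NA module = unbinned), `modules` (named list of member
#'   vectors), `table` (module + unbinned-single count matrix), `min_r`.
#' @export
bin_modules <- function(counts, min_r = 0.35) {
  counts <- validate_feature_table(counts)
  if (ncol(counts) < 2) stop("need >= 2 features to bin")
  rel <- relative_abundance(counts)
  constant <- apply(rel, 2L, function(x) stats::var(x) == 0)
  if (any(constant))
    warning("constant feature(s) left unbinned: ",
            paste(colnames(rel)[constant], collapse = ", "))
  active <- colnames(rel)[!constant]
  modules <- list()
  if (length(active) >= 2) {
    r <- suppressWarnings(stats::cor(rel[, active, drop = FALSE],
                                     method = "spearman"))
    cl <- stats::cutree(stats::hclust(stats::as.dist(1 - r),
                                      method = "complete"),
                        h = 1 - min_r)
    sizes <- table(cl)
    mod_ids <- names(sizes)[sizes >= 2]
    modules <- lapply(mod_ids, function(id) active[cl == id])
    # stable labels: order by first member's column position
    ord <- order(vapply(modules, function(m)
      min(match(m, colnames(counts))), numeric(1)))
    modules <- modules[ord]
    names(modules) <- sprintf("module_%03d", seq_along(modules))
  }
  binned <- unlist(modules, use.names = FALSE)
  singles <- setdiff(colnames(counts), binned)
  mod_tab <- if (length(modules))
    vapply(modules, function(m)
      rowSums(counts[, m, drop = FALSE]), numeric(nrow(counts)))
  else NULL
  table_out <- cbind(mod_tab, counts[, singles, drop = FALSE])
  membership <- data.frame(
    feature = colnames(counts),
    module = NA_character_, stringsAsFactors = FALSE)
  for (id in names(modules))
    membership$module[membership$feature %in% modules[[id]]] <- id
  structure(list(membership = membership, modules = modules,
                 table = table_out, min_r = min_r),
            class = "module_binning")
}

#' DFFITS influence diagnostics for an OLS fit
#'
#' DFFITS_i = t_i * sqrt(h_i / (1 - h_i)) with t_i the externally
#' studentized (deleted) residual and h_i the hat diagonal: the scaled
#' change in the i-th fitted value when observation i is deleted. A fit
#' with (numerically) zero residuals returns all zeros — the limit
#' convention, so perfect toy fits are not flagged as influential. Exact
#' leverage points (h_i = 1) are reported as infinite.
#'
#' @param fit An `lm` fit.
#' @return Numeric vector of per-observation DFFITS.
#' @export
dffits_ols <- function(fit) {
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  e <- stats::resid(fit)
  n <- length(e)
  k <- fit$rank
  if (n - k - 1 <= 0) stop("too few residual degrees of freedom for DFFITS")
  out <- numeric(n)
  lev <- h >= 1 - 1e-12
  s2 <- sum(e^2) / (n - k)
  scale0 <- mean(abs(stats::fitted(fit))) + mean(abs(e))
  if (s2 <= (1e-12 * max(scale0, 1))^2) {
    out[lev] <- Inf
    return(out)
  }
  s2_i <- ((n - k) * s2 - e^2 / (1 - h)) / (n - k - 1)
  s2_i <- pmax(s2_i, 0)
  t_i <- e / sqrt(s2_i * (1 - h))
  out <- t_i * sqrt(h / (1 - h))
  out[lev] <- Inf
  unname(out)
}

#' Five-criterion cascade thresholds
#'
#' Defaults: FDR-adjusted overall-F p < 0.2, adjusted R^2 > 0.25, slope
#' p < 0.05, interaction (slope-difference) p < 0.05, max |DFFITS| < 2.
#'
#' @param fdr_max,adj_r2_min,slope_p_max,interaction_p_max,dffits_max
#'   Threshold values (all > 0).
#' @return Named list of class `cascade_thresholds`.
#' @export
cascade_thresholds <- function(fdr_max = 0.2, adj_r2_min = 0.25,
                               slope_p_max = 0.05, interaction_p_max = 0.05,
                               dffits_max = 2) {
  thr <- list(fdr_max = fdr_max, adj_r2_min = adj_r2_min,
              slope_p_max = slope_p_max,
              interaction_p_max = interaction_p_max,
              dffits_max = dffits_max)
  stopifnot(all(unlist(thr) > 0))
  structure(thr, class = "cascade_thresholds")
}

#' Per-pair immune-microbe interaction regression
#'
#' Fits, by OLS, marker ~ read count + feature + cohort + feature:cohort on
#' non-rarefied relative abundances, the read-count covariate absorbing
#' depth differences. The reference cohort (ART-naive for the three-cohort
#' mode, experienced for the two-cohort mode) anchors the slope
#' parametrization: each non-reference cohort's slope is the reference
#' slope plus its interaction coefficient, tested by a Wald contrast from
#' the same fit. The overall F compares the full model against the
#' read-count-only null (read count is a nuisance term, not signal).
#'
#' @param marker Numeric immune-marker values.
#' @param feature Relative abundance of one feature (or module), same
#'   length.
#' @param cohort Cohort labels.
#' @param read_count Per-sample total (non-rarefied) read counts.
#' @param reference Reference cohort (default `"Naive"`).
#' @return List of class `pair_model_fit`: `slopes`, `slope_p`,
#'   `interaction_p` (per non-reference cohort), `p_overall`, `adj_r2`,
#'   `max_dffits`, `n`, `degenerate`, `unusable`, `reference`.
#' @export
fit_pair_model <- function(marker, feature, cohort, read_count,
                           reference = "Naive") {
  cohort <- factor(cohort)
  if (!reference %in% levels(cohort))
    stop("reference cohort '", reference, "' not present")
  ok <- is.finite(marker) & is.finite(feature) & is.finite(read_count) &
    !is.na(cohort)
  marker <- marker[ok]; feature <- feature[ok]
  cohort <- droplevels(cohort[ok]); read_count <- read_count[ok]
  if (any(table(cohort) < 3)) stop("every cohort needs >= 3 samples")
  cohort <- stats::relevel(cohort, ref = reference)
  n <- length(marker)
  if (n < nlevels(cohort) * 2 + 2 + 2) stop("too few samples for the model")

  d <- data.frame(y = marker, f = feature, cohort = cohort, rc = read_count)
  fit <- stats::lm(y ~ rc + f * cohort, data = d)
  null_fit <- stats::lm(y ~ rc, data = d)

  cohorts <- levels(cohort)
  others <- cohorts[-1L]
  degenerate <- stats::var(marker) == 0
  unusable <- anyNA(stats::coef(fit))
  if (unusable || degenerate) {
    zero <- stats::setNames(rep(0, length(cohorts)), cohorts)
    ones <- stats::setNames(rep(1, length(cohorts)), cohorts)
    return(structure(list(
      slopes = zero, slope_p = ones,
      interaction_p = stats::setNames(rep(1, length(others)), others),
      p_overall = 1, adj_r2 = 0, max_dffits = 0, n = n,
      degenerate = degenerate, unusable = unusable, reference = reference),
      class = "pair_model_fit"))
  }

  b <- stats::coef(fit)
  V <- suppressWarnings(stats::vcov(fit))   # vcov warns on exact toy fits
  df_res <- fit$df.residual
  slope_of <- function(ch) {
    if (ch == reference) {
      est <- b[["f"]]; se <- sqrt(V["f", "f"])
    } else {
      ic <- paste0("f:cohort", ch)
      est <- b[["f"]] + b[[ic]]
      se <- sqrt(V["f", "f"] + V[ic, ic] + 2 * V["f", ic])
    }
    c(est = est, p = 2 * stats::pt(-abs(est / se), df_res))
  }
  sl <- vapply(cohorts, slope_of, numeric(2))
  interaction_p <- vapply(others, function(ch) {
    ic <- paste0("f:cohort", ch)
    2 * stats::pt(-abs(b[[ic]] / sqrt(V[ic, ic])), df_res)
  }, numeric(1))
  an <- suppressWarnings(stats::anova(null_fit, fit))
  structure(list(
    slopes = stats::setNames(sl["est", ], cohorts),
    slope_p = stats::setNames(sl["p", ], cohorts),
    interaction_p = stats::setNames(interaction_p, others),
    p_overall = an$`Pr(>F)`[2L],
    adj_r2 = suppressWarnings(summary(fit))$adj.r.squared,
    max_dffits = max(abs(dffits_ols(fit))),
    n = n, degenerate = FALSE, unusable = FALSE, reference = reference),
    class = "pair_model_fit")
}

#' Fit all marker x feature pair models for one timepoint
#'
#' @param rel_abund Samples x features relative-abundance matrix (from the
#'   non-rarefied, prevalence-filtered table).
#' @param panel Immune panel for the same samples.
#' @param meta Metadata supplying cohort per sample.
#' @param read_count Named per-sample total read counts.
#' @param markers Marker columns to test (default all eight).
#' @param reference Reference cohort.
#' @param timepoint Week label attached to every fit (FDR families are
#'   per-timepoint).
#' @return data.frame with one row per (marker, feature) pair: slopes,
#'   slope p, interaction p per cohort, overall-F p, adjusted R^2, max
#'   |DFFITS|, n, timepoint.
#' @export
fit_pair_models <- function(rel_abund, panel, meta, read_count,
                            markers = immune_markers(),
                            reference = "Naive", timepoint = 0L) {
  samples <- rownames(rel_abund)
  cohort <- meta$cohort[match(samples, meta$sample_id)]
  rc <- read_count[samples]
  rows <- list()
  for (m in markers) {
    y <- panel[[m]][match(samples, panel$sample_id)]
    for (f in colnames(rel_abund)) {
      pf <- fit_pair_model(y, rel_abund[, f], cohort, rc,
                           reference = reference)
      others <- names(pf$interaction_p)
      row <- data.frame(marker = m, feature = f, timepoint = timepoint,
                        p_overall = pf$p_overall, adj_r2 = pf$adj_r2,
                        max_dffits = pf$max_dffits, n = pf$n,
                        ref_slope = unname(pf$slopes[reference]),
                        ref_slope_p = unname(pf$slope_p[reference]),
                        degenerate = pf$degenerate,
                        unusable = pf$unusable,
                        stringsAsFactors = FALSE)
      for (ch in names(pf$slopes)) {
        row[[paste0("slope_", ch)]] <- unname(pf$slopes[ch])
        row[[paste0("slope_p_", ch)]] <- unname(pf$slope_p[ch])
      }
      for (ch in others)
        row[[paste0("interaction_p_", ch)]] <- unname(pf$interaction_p[ch])
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  out
}

#' Five-criterion filter cascade
#'
#' Benjamini-Hochberg FDR is applied across the whole family of fits (all
#' marker x feature models of one timepoint) on the overall-F p-value; an
#' edge survives iff
#' \itemize{
#'   \item FDR-adjusted overall-F p < `fdr_max`,
#'   \item adjusted R^2 > `adj_r2_min`,
#'   \item mode `naive_specific`: reference (naive) slope p <
#'     `slope_p_max` and at least one interaction p < `interaction_p_max`
#'     (the naive slope differs from experienced and/or controls);
#'   \item mode `exp_vs_hc`: at least one cohort slope p < `slope_p_max`
#'     and the slope-difference p < `interaction_p_max`;
#'   \item max |DFFITS| < `dffits_max` (not outlier-driven).
#' }
#' Edges carry the sign of the reference-cohort slope.
#'
#' @param fits data.frame from [fit_pair_models()] (single timepoint).
#' @param thr A [cascade_thresholds()].
#' @param mode `"naive_specific"` or `"exp_vs_hc"`.
#' @return data.frame of surviving edges: marker, feature, sign, slope,
#'   p_slope, fdr_p, adj_r2, max_dffits.
#' @export
filter_cascade <- function(fits, thr = cascade_thresholds(),
                           mode = c("naive_specific", "exp_vs_hc")) {
  mode <- match.arg(mode)
  empty <- data.frame(marker = character(), feature = character(),
                      sign = character(), slope = numeric(),
                      p_slope = numeric(), fdr_p = numeric(),
                      adj_r2 = numeric(), max_dffits = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(fits) || nrow(fits) == 0) return(empty)
  if (length(unique(fits$timepoint)) > 1)
    stop("fits mix timepoints; the FDR family is per-timepoint")
  fits$fdr_p <- stats::p.adjust(fits$p_overall, method = "BH")
  icols <- grep("^interaction_p_", names(fits), value = TRUE)
  scols <- grep("^slope_p_", names(fits), value = TRUE)
  any_interaction <- apply(fits[icols] < thr$interaction_p_max, 1L, any)
  slope_rule <- if (mode == "naive_specific") {
    fits$ref_slope_p < thr$slope_p_max
  } else {
    apply(fits[scols] < thr$slope_p_max, 1L, any)
  }
  keep <- !fits$degenerate & !fits$unusable &
    fits$fdr_p < thr$fdr_max &
    fits$adj_r2 > thr$adj_r2_min &
    slope_rule & any_interaction &
    fits$max_dffits < thr$dffits_max
  if (!any(keep)) return(empty)
  kept <- fits[keep, , drop = FALSE]
  out <- data.frame(marker = kept$marker, feature = kept$feature,
                    sign = ifelse(kept$ref_slope >= 0, "+", "-"),
                    slope = kept$ref_slope, p_slope = kept$ref_slope_p,
                    fdr_p = kept$fdr_p, adj_r2 = kept$adj_r2,
                    max_dffits = kept$max_dffits,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble the bipartite immune-microbe association network
#'
#' Nodes are typed immune markers and microbial features (single ASVs or
#' modules); edges carry the sign of the reference-cohort slope, its
#' p-value, and a display width of -log10(p). Immune nodes listed in
#' `markers` appear even when isolated.
#'
#' @param edges Edge data.frame from [filter_cascade()].
#' @param markers Immune nodes to declare (default all eight).
#' @return List of class `association_network`: `nodes` (id, type),
#'   `edges`, `degree` (per-node edge counts).
#' @export
build_network <- function(edges, markers = immune_markers()) {
  if (anyDuplicated(edges[c("marker", "feature")]))
    stop("duplicate (marker, feature) edge")
  nodes <- rbind(
    data.frame(id = markers, type = "immune", stringsAsFactors = FALSE),
    if (nrow(edges))
      data.frame(id = unique(edges$feature), type = "microbe",
                 stringsAsFactors = FALSE))
  edges_out <- if (nrow(edges)) {
    data.frame(immune = edges$marker, feature = edges$feature,
               sign = edges$sign, p_slope = edges$p_slope,
               width = -log10(edges$p_slope), stringsAsFactors = FALSE)
  } else {
    data.frame(immune = character(), feature = character(),
               sign = character(), p_slope = numeric(), width = numeric(),
               stringsAsFactors = FALSE)
  }
  counts <- table(c(edges_out$immune, edges_out$feature))
  degree <- data.frame(id = nodes$id,
                       degree = as.integer(ifelse(nodes$id %in% names(counts),
                                                  counts[nodes$id], 0L)),
                       stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges_out, degree = degree),
            class = "association_network")
}

#' Write / read an association network
#'
#' JSON layout: `{"nodes":[{"id","type"}],"edges":[{"immune","feature",
#' "sign","p_slope","width"}]}`; the edge list is also written as TSV when
#' `tsv` is given.
#'
#' @param net An `association_network`.
#' @param path JSON output path.
#' @param tsv Optional edge-list TSV path.
#' @return `write_network`: the JSON path, invisibly; `read_network`: the
#'   re-assembled `association_network`.
#' @export
write_network <- function(net, path, tsv = NULL) {
  stopifnot(inherits(net, "association_network"))
  jsonlite::write_json(list(nodes = net$nodes, edges = net$edges), path,
                       dataframe = "rows", digits = NA)
  if (!is.null(tsv))
    utils::write.table(net$edges, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(x$nodes, stringsAsFactors = FALSE)
  edges <- if (length(x$edges)) as.data.frame(x$edges) else
    data.frame(immune = character(), feature = character(),
               sign = character(), p_slope = numeric(), width = numeric())
  ed <- data.frame(marker = edges$immune, feature = edges$feature,
                   sign = edges$sign, p_slope = edges$p_slope,
                   stringsAsFactors = FALSE)
  net <- build_network(
    data.frame(marker = ed$marker, feature = ed$feature, sign = ed$sign,
               p_slope = ed$p_slope, slope = NA_real_, fdr_p = NA_real_,
               adj_r2 = NA_real_, max_dffits = NA_real_,
               stringsAsFactors = FALSE),
    markers = nodes$id[nodes$type == "immune"])
  net
}

#' End-to-end association-network pipeline for one timepoint
#'
#' Runs the full chain on non-rarefied counts: prevalence filter (> 20% of
#' samples by default), module binning, relative-abundance conversion,
#' per-pair interaction regressions against every immune marker, the
#' five-criterion cascade, and network assembly.
#'
#' @param counts Non-rarefied samples x features counts (all samples).
#' @param meta Metadata; rows are subset to `timepoint`.
#' @param panel Immune panel.
#' @param timepoint Week (0 or 24).
#' @param mode Cascade mode; `"exp_vs_hc"` drops the naive cohort and uses
#'   the experienced cohort as reference.
#' @param min_prevalence Prevalence threshold (fraction).
#' @param min_r Module-binning correlation threshold.
#' @param thr Cascade thresholds.
#' @param markers Immune markers to test.
#' @return List: `network`, `edges`, `fits`, `binning`.
#' @export
association_network <- function(counts, meta, panel, timepoint = 0L,
                                mode = c("naive_specific", "exp_vs_hc"),
                                min_prevalence = 0.2, min_r = 0.35,
                                thr = cascade_thresholds(),
                                markers = immune_markers()) {
  mode <- match.arg(mode)
  reference <- if (mode == "naive_specific") "Naive" else "Exp"
  mw <- meta[meta$week == timepoint, , drop = FALSE]
  if (mode == "exp_vs_hc") mw <- mw[mw$cohort != "Naive", , drop = FALSE]
  keep <- intersect(rownames(counts), mw$sample_id)
  tab <- counts[keep, , drop = FALSE]
  read_count <- rowSums(tab)
  tab <- prevalence_filter(tab, min_prevalence)
  binning <- bin_modules(tab, min_r = min_r)
  rel <- relative_abundance(binning$table)
  fits <- fit_pair_models(rel, panel, mw, read_count, markers = markers,
                          reference = reference, timepoint = timepoint)
  edges <- filter_cascade(fits, thr = thr, mode = mode)
  list(network = build_network(edges, markers = markers),
       edges = edges, fits = fits, binning = binning)
}
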