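#' Kruskal-Wallis omnibus test with Dunn's post hoc
#'
#' Omnibus H (with tie correction, via [stats::kruskal.test()]) plus Dunn's
#' pairwise z statistics from mean ranks with tie-corrected variance,
#'
#'   z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j)),
#'
#' where T = sum over tie groups of (t^3 - t). Pairwise p-values are
#' adjusted within the family (Benjamini-Hochberg by default; `"none"`
#' gives unadjusted values). The sign of the group-mean difference is
#' exported for directionality displays.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 observations per group, >= 2 groups).
#' @param p_adjust Adjustment method for the pairwise family (default BH).
#' @return List: `H`, `df`, `p` (omnibus), `pairwise` data.frame (group1,
#'   group2, z, p, p_adj, direction), `degenerate` flag (all values tied).
#' @export
kruskal_dunn <- function(values, groups, p_adjust = "BH") {
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("need >= 2 observations per group")
  degenerate <- length(unique(values)) == 1L
  if (degenerate) {
    H <- 0; p_omni <- 1
  } else {
    kt <- stats::kruskal.test(values, groups)
    H <- unname(kt$statistic); p_omni <- kt$p.value
  }
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- table(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  cmb <- utils::combn(levels(groups), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    a <- cmb[1L, k]; b <- cmb[2L, k]
    se <- sqrt(v0 * (1 / n[[a]] + 1 / n[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    md <- mean(values[groups == a]) - mean(values[groups == b])
    data.frame(group1 = a, group2 = b, z = z,
               p = if (degenerate) 1 else 2 * stats::pnorm(-abs(z)),
               direction = sign(md), stringsAsFactors = FALSE)
  }))
  pw$p_adj <- stats::p.adjust(pw$p, method = p_adjust)
  list(H = H, df = nlevels(groups) - 1L, p = p_omni,
       pairwise = pw, degenerate = degenerate)
}

#' Paired two-timepoint rank test
#'
#' The within-participant comparison ("paired Mann-Whitney U" in common
#' loose usage) implemented as the Wilcoxon signed-rank test on the paired
#' differences: zero differences are dropped, the exact distribution is
#' used for n <= 25 untied differences, and the normal approximation with
#' tie correction otherwise.
#'
#' @param week0,week24 Paired numeric vectors (same participants, same
#'   order).
#' @return List: `statistic` (V), `p`, `n` (nonzero pairs), `degenerate`
#'   (all differences zero).
#' @export
paired_location_test <- function(week0, week24) {
  ok <- is.finite(week0) & is.finite(week24)
  d <- week24[ok] - week0[ok]
  if (length(d) < 3) stop("need at least 3 complete pairs")
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(statistic = NA_real_, p = 1, n = 0L, degenerate = TRUE))
  exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = length(d), degenerate = FALSE)
}

# Cluster-robust (sandwich) covariance with the G/(G-1) * (n-1)/(n-k)
# small-sample factor; bread = (X'X)^-1, meat = sum_g (X_g'e_g)(X_g'e_g)'.
cluster_robust_vcov <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  e <- stats::resid(fit)
  cluster <- droplevels(factor(cluster))
  if (nlevels(cluster) < 2) stop("need >= 2 clusters")
  n <- nrow(X); k <- ncol(X); G <- nlevels(cluster)
  scores <- rowsum(X * e, cluster)                 # G x k of X_g' e_g
  meat <- crossprod(scores)
  bread <- chol2inv(chol(crossprod(X)))
  adj <- (G / (G - 1)) * ((n - 1) / (n - k))
  V <- adj * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Longitudinal cohort-by-week model with cluster-robust errors
#'
#' Fits marker ~ cohort + week + cohort:week by OLS with reference levels
#' healthy controls and week 0, so coefficients read as: cohort offsets
#' from HC at baseline, change over time in HC, and each cohort's extra
#' change over time relative to HC. Standard errors are cluster-robust
#' (sandwich) grouped by participant with the G/(G-1)(n-1)/(n-k)
#' small-sample factor and t tests on G-1 degrees of freedom, accounting
#' for the repeated measures. Optionally stratified by location.
#'
#' @param panel Immune panel (sample_id + markers).
#' @param meta Metadata (sample_id, pid, cohort, week, location).
#' @param response Marker column name.
#' @param by_location Also fit within each location stratum?
#' @return data.frame with one row per coefficient (and per stratum when
#'   `by_location`): term, estimate, se, t, p, direction, stratum, n,
#'   n_clusters.
#' @export
fit_m1 <- function(panel, meta, response, by_location = FALSE) {
  stopifnot(response %in% names(panel))
  d <- merge(meta, panel[c("sample_id", response)], by = "sample_id")
  d <- d[is.finite(d[[response]]), , drop = FALSE]
  d$cohort <- factor(d$cohort, levels = c("HC", "Naive", "Exp"))
  d$week <- factor(d$week, levels = c(0, 24))
  strata <- if (by_location) split(d, d$location) else list(overall = d)
  out <- lapply(names(strata), function(s) {
    ds <- droplevels(strata[[s]])
    for (v in c("cohort", "week"))
      if (nlevels(ds[[v]]) < 2)
        stop("singular design in stratum '", s, "': term '", v,
             "' has a single level (aliased)")
    fml <- stats::reformulate(c("cohort", "week", "cohort:week"),
                              response = response)
    fit <- stats::lm(fml, data = ds)
    if (anyNA(stats::coef(fit)))
      stop("singular design in stratum '", s, "': aliased term(s) ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "))
    V <- cluster_robust_vcov(fit, ds$pid)
    est <- stats::coef(fit)
    se <- sqrt(diag(V))
    G <- length(unique(ds$pid))
    tval <- est / se
    tval[se == 0] <- 0
    data.frame(term = names(est), estimate = unname(est), se = unname(se),
               t = unname(tval),
               p = unname(2 * stats::pt(-abs(tval), df = G - 1)),
               direction = sign(unname(est)),
               stratum = s, n = nrow(ds), n_clusters = G,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Backward stepwise predictor selection with forced-in covariates
#'
#' Starting from the full OLS model (forced-in plus candidate predictors),
#' repeatedly removes the candidate whose removal most improves the
#' selection criterion — AIC by default, or a p-value rule that drops the
#' least significant candidate with p >= 0.05 — until no removal improves.
#' Forced-in predictors are never eliminated. The final model is refit and
#' reported with per-predictor p-values and an overall-model significance
#' flag (`model_ns` when the overall F-test p >= 0.05); every elimination
#' step is recorded in the trace.
#'
#' @param data data.frame holding response and predictors.
#' @param response Response column name.
#' @param candidates Candidate predictor names (removable).
#' @param forced Predictor names kept in every model (may be empty).
#' @param criterion `"AIC"` (default) or `"p"`.
#' @param p_threshold Removal threshold for the p-value criterion.
#' @return List: `fit` (final `lm`), `kept` (surviving candidates),
#'   `coefficients` (term, estimate, se, p), `model_p` (overall F p, NA
#'   when no predictor remains), `model_ns`, `trace` (data.frame of steps).
#' @export
stepwise_select <- function(data, response, candidates, forced = character(),
                            criterion = c("AIC", "p"), p_threshold = 0.05) {
  criterion <- match.arg(criterion)
  keep_cols <- unique(c(response, candidates, forced))
  data <- stats::na.omit(data[keep_cols])
  # single-level categorical candidates cannot be estimated
  usable <- vapply(candidates, function(v) {
    x <- data[[v]]
    !((is.character(x) || is.factor(x)) && length(unique(x)) < 2)
  }, logical(1))
  if (any(!usable))
    warning("dropping single-level candidate(s): ",
            paste(candidates[!usable], collapse = ", "))
  candidates <- candidates[usable]
  if (nrow(data) <= length(candidates) + length(forced) + 1L)
    stop("too few observations for the candidate set")

  refit <- function(cand) {
    rhs <- c(forced, cand)
    fml <- if (length(rhs)) stats::reformulate(rhs, response = response)
           else stats::reformulate("1", response = response)
    stats::lm(fml, data = data)
  }
  score <- function(fit) {
    if (criterion == "AIC") return(stats::AIC(fit))
    # p criterion: score = negative of worst candidate p (improve = drop it)
    NA_real_
  }

  current <- candidates
  fit <- refit(current)
  trace <- data.frame(step = 0L, action = "start",
                      term = NA_character_, aic = stats::AIC(fit),
                      n_terms = length(current), stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    if (!length(current)) break
    step_i <- step_i + 1L
    if (criterion == "AIC") {
      drops <- vapply(current, function(tm)
        stats::AIC(refit(setdiff(current, tm))), numeric(1))
      best <- names(which.min(drops))
      if (drops[[best]] >= stats::AIC(fit) - 1e-10) break
      current <- setdiff(current, best)
      fit <- refit(current)
      trace <- rbind(trace, data.frame(step = step_i, action = "drop",
                                       term = best, aic = stats::AIC(fit),
                                       n_terms = length(current),
                                       stringsAsFactors = FALSE))
    } else {
      sm <- summary(fit)$coefficients
      # worst candidate term by p (term may expand to several columns:
      # use the smallest p among its columns as the term's p)
      asg <- attr(stats::model.matrix(fit), "assign")
      labs <- attr(stats::terms(fit), "term.labels")
      term_p <- vapply(current, function(tm) {
        cols <- which(asg == match(tm, labs))
        min(sm[cols, "Pr(>|t|)"])
      }, numeric(1))
      worst <- names(which.max(term_p))
      if (term_p[[worst]] < p_threshold) break
      current <- setdiff(current, worst)
      fit <- refit(current)
      trace <- rbind(trace, data.frame(step = step_i, action = "drop",
                                       term = worst, aic = stats::AIC(fit),
                                       n_terms = length(current),
                                       stringsAsFactors = FALSE))
    }
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  model_p <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  co <- stats::coef(sm)
  list(fit = fit, kept = current,
       coefficients = data.frame(term = rownames(co),
                                 estimate = co[, "Estimate"],
                                 se = co[, "Std. Error"],
                                 p = co[, "Pr(>|t|)"],
                                 row.names = NULL, stringsAsFactors = FALSE),
       model_p = model_p,
       model_ns = is.na(model_p) || model_p >= 0.05,
       trace = trace)
}
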