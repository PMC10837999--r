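#' Reference-based dysbiosis score
#'
#' A sample's dysbiosis is its mean weighted-UniFrac (or any supplied)
#' distance to all healthy-control samples collected at the same timepoint:
#' a week-0 sample is referenced against week-0 controls only. Scores are
#' computed for the non-HC cohorts; with `include_hc = TRUE` each HC sample
#' additionally gets a score against the other HC samples of its week
#' (itself excluded), a documented extension used for control-side
#' correlates.
#'
#' @param dm `dist` or square distance matrix covering all samples.
#' @param meta Metadata with sample_id, pid, cohort, location, week.
#' @param include_hc Also score HC samples (self excluded)?
#' @return data.frame: sample_id, pid, cohort, location, week, score.
#' @export
dysbiosis_score <- function(dm, meta, include_hc = FALSE) {
  D <- as.matrix(dm)
  if (!all(meta$sample_id %in% rownames(D)))
    stop("distance matrix does not cover all metadata samples")
  res <- lapply(unique(meta$week), function(w) {
    mw <- meta[meta$week == w, , drop = FALSE]
    hc <- mw$sample_id[mw$cohort == "HC"]
    if (length(hc) == 0) stop("no HC sample at week ", w)
    target <- if (include_hc) mw else mw[mw$cohort != "HC", , drop = FALSE]
    score <- vapply(target$sample_id, function(s) {
      ref <- setdiff(hc, s)
      if (length(ref) == 0)
        stop("no HC reference left for sample ", s, " at week ", w)
      mean(D[s, ref])
    }, numeric(1))
    data.frame(target[c("sample_id", "pid", "cohort", "location", "week")],
               score = unname(score), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$sample_id), , drop = FALSE]
}

#' Delta-versus-baseline regressions
#'
#' For each participant with both timepoints, forms
#' delta = week-24 value - week-0 value and fits the ordinary least squares
#' regression delta ~ baseline independently within each stratum (by cohort,
#' or by cohort x location). A strongly negative slope indicates that
#' participants starting high lose the most — the regression-to-the-mean
#' signature — while a slope near zero indicates persistent values plus
#' independent noise.
#'
#' @param values data.frame with pid, cohort, location, week and a `value`
#'   column (e.g. Shannon entropy or dysbiosis score).
#' @param stratify `"cohort"` or `"cohort_location"`.
#' @param min_n Minimum complete pairs per stratum (default 3); smaller
#'   strata are skipped with a warning.
#' @return data.frame: stratum columns, intercept, slope, slope_se,
#'   slope_p, r2, n. An `excluded` attribute lists participants missing a
#'   timepoint.
#' @export
delta_regression <- function(values, stratify = c("cohort", "cohort_location"),
                             min_n = 3L) {
  stratify <- match.arg(stratify)
  stopifnot(all(c("pid", "cohort", "location", "week", "value") %in%
                  names(values)))
  w0 <- values[values$week == 0, , drop = FALSE]
  w24 <- values[values$week == 24, , drop = FALSE]
  both <- intersect(w0$pid, w24$pid)
  excluded <- setdiff(unique(values$pid), both)
  pairs <- data.frame(
    pid = both,
    cohort = w0$cohort[match(both, w0$pid)],
    location = w0$location[match(both, w0$pid)],
    baseline = w0$value[match(both, w0$pid)],
    delta = w24$value[match(both, w24$pid)] - w0$value[match(both, w0$pid)],
    stringsAsFactors = FALSE)
  key <- if (stratify == "cohort") pairs$cohort
         else paste(pairs$cohort, pairs$location, sep = ":")
  fits <- lapply(split(pairs, key), function(d) {
    if (nrow(d) < min_n) {
      warning("stratum with fewer than ", min_n, " pairs skipped: ",
              d$cohort[1])
      return(NULL)
    }
    fit <- stats::lm(delta ~ baseline, data = d)
    sm <- suppressWarnings(summary(fit))   # exact fits trip lm's perfection note
    co <- stats::coef(sm)
    r2 <- sm$r.squared
    slope_se <- if (nrow(co) > 1) co["baseline", "Std. Error"] else NA_real_
    slope_p <- if (nrow(co) > 1) co["baseline", "Pr(>|t|)"] else NA_real_
    data.frame(cohort = d$cohort[1],
               location = if (stratify == "cohort") NA_character_ else
                 d$location[1],
               intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)["baseline"]),
               slope_se = slope_se, slope_p = slope_p,
               r2 = if (is.finite(r2)) r2 else 0,
               n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Correlation of a diversity measure with antibiotic exposure
#'
#' Pearson and Spearman coefficients of a per-sample measure (dysbiosis
#' score or Shannon entropy) against months of cotrimoxazole exposure; both
#' are reported because either convention is common for this kind of
#' exposure correlate.
#'
#' @param measure Numeric per-sample values.
#' @param months Months of exposure, same length.
#' @return data.frame with one row per method: estimate and p-value.
#' @export
exposure_correlation <- function(measure, months) {
  ok <- is.finite(measure) & is.finite(months)
  do.call(rbind, lapply(c("pearson", "spearman"), function(m) {
    ct <- suppressWarnings(
      stats::cor.test(measure[ok], months[ok], method = m))
    data.frame(method = m, estimate = unname(ct$estimate),
               p = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  }))
}
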