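#' Label viremia and inconsistent-baseline flags
#'
#' Applies the study-design viral-load rules, with strict inequalities:
#' \itemize{
#'   \item ART-naive week 0: flagged `inconsistent_naive_baseline` iff viral
#'     load < 20 copies/mL (suppression inconsistent with declared
#'     treatment-naive status);
#'   \item ART-naive week 24: flagged `viremic` iff viral load > 200
#'     copies/mL (virologic failure after 24 weeks of therapy);
#'   \item ART-experienced week 0: flagged `viremic` iff viral load > 200;
#'   \item healthy controls: never flagged.
#' }
#'
#' @param meta Metadata data.frame (sample_id, pid, cohort, week,
#'   viral_load, ...).
#' @return `meta` with logical columns `inconsistent_naive_baseline` and
#'   `viremic` appended.
#' @export
label_viremia <- function(meta) {
  non_hc <- meta$cohort != "HC"
  if (any(non_hc & is.na(meta$viral_load))) {
    bad <- meta$sample_id[non_hc & is.na(meta$viral_load)]
    stop("missing viral_load on non-HC sample(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  vl <- meta$viral_load
  meta$inconsistent_naive_baseline <-
    meta$cohort == "Naive" & meta$week == 0 & !is.na(vl) & vl < 20
  meta$viremic <-
    (meta$cohort == "Naive" & meta$week == 24 & !is.na(vl) & vl > 200) |
    (meta$cohort == "Exp" & meta$week == 0 & !is.na(vl) & vl > 200)
  meta
}

.new_report <- function(stage, input, retained, excluded) {
  stopifnot(input == length(retained) + sum(lengths(excluded)))
  structure(list(stage = stage, input_n = input,
                 retained_n = length(retained),
                 excluded = excluded), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report: %s stage>\n", x$stage))
  cat(sprintf("  input: %d participants; retained: %d\n",
              x$input_n, x$retained_n))
  for (rule in names(x$excluded))
    cat(sprintf("  excluded (%s): %d\n", rule, length(x$excluded[[rule]])))
  invisible(x)
}

#' Baseline exclusion cascade
#'
#' Removes ART-naive participants whose baseline viral load is inconsistent
#' with their declared status, and ART-experienced participants viremic at
#' baseline, keeping everyone else for the cross-sectional (baseline)
#' analyses.
#'
#' @param meta Metadata with the flags from [label_viremia()].
#' @return List with `pids` (retained participant IDs) and `report`
#'   (a `filter_report`; retained + excluded counts are conserved).
#' @export
filter_baseline <- function(meta) {
  stopifnot(all(c("inconsistent_naive_baseline", "viremic") %in% names(meta)))
  pids <- unique(meta$pid)
  w0 <- meta[meta$week == 0, , drop = FALSE]
  excl_incons <- unique(w0$pid[w0$inconsistent_naive_baseline])
  excl_virem <- setdiff(unique(w0$pid[w0$cohort == "Exp" & w0$viremic]),
                        excl_incons)
  retained <- setdiff(pids, c(excl_incons, excl_virem))
  list(pids = retained,
       report = .new_report("baseline", length(pids), retained,
                            list(inconsistent_naive_baseline = excl_incons,
                                 exp_baseline_viremia = excl_virem)))
}

#' Longitudinal exclusion cascade
#'
#' Starting from the baseline-retained participants, removes those lost to
#' follow-up (a single visit) and ART-naive participants without virologic
#' control (viral load > 200) at week 24, yielding a strict
#' two-samples-per-participant dataset.
#'
#' @param meta Metadata with viremia flags.
#' @param baseline_pids Participants surviving [filter_baseline()].
#' @return List with `pids`, `sample_ids`, and `report`.
#' @export
filter_longitudinal <- function(meta, baseline_pids) {
  meta <- meta[meta$pid %in% baseline_pids, , drop = FALSE]
  visits <- table(meta$pid)
  if (any(visits > 2))
    stop("participant(s) with more than two samples: ",
         paste(names(visits)[visits > 2], collapse = ", "))
  lost <- names(visits)[visits < 2]
  w24 <- meta[meta$week == 24, , drop = FALSE]
  failed <- setdiff(unique(w24$pid[w24$cohort == "Naive" & w24$viremic]), lost)
  retained <- setdiff(baseline_pids, c(lost, failed))
  keep <- meta$pid %in% retained
  list(pids = retained, sample_ids = meta$sample_id[keep],
       report = .new_report("longitudinal", length(baseline_pids), retained,
                            list(lost_to_followup = lost,
                                 naive_week24_failure = failed)))
}

#' Impute missing CD4-lineage immune markers by stratum means
#'
#' Each missing CD4-lineage value (CD4 activation, PD-1 and CD103 percents)
#' is replaced by the average of the non-missing values of that marker,
#' by default within the same cohort x week stratum. A global-mean variant
#' is available for sensitivity checks. Non-missing values are never
#' touched.
#'
#' @param panel Immune panel data.frame (sample_id + markers).
#' @param meta Metadata supplying cohort and week per sample.
#' @param strata `"cohort_week"` (default) or `"global"`.
#' @return The panel with imputations applied; an `imputation_log`
#'   attribute records every filled cell.
#' @export
impute_immune <- function(panel, meta, strata = c("cohort_week", "global")) {
  strata <- match.arg(strata)
  idx <- match(panel$sample_id, meta$sample_id)
  if (anyNA(idx)) stop("panel samples absent from metadata")
  key <- if (strata == "global") rep("all", nrow(panel))
         else paste(meta$cohort[idx], meta$week[idx], sep = ":")
  log <- list()
  for (m in cd4_markers()) {
    x <- panel[[m]]
    miss <- which(is.na(x))
    if (!length(miss)) next
    means <- tapply(x, key, mean, na.rm = TRUE)
    for (i in miss) {
      v <- means[[key[i]]]
      if (!is.finite(v))
        stop("no non-missing values of ", m, " in stratum ", key[i])
      x[i] <- v
    }
    log[[m]] <- data.frame(sample_id = panel$sample_id[miss],
                           marker = m, stratum = key[miss],
                           imputed = x[miss], stringsAsFactors = FALSE)
    panel[[m]] <- x
  }
  attr(panel, "imputation_log") <- do.call(rbind, unname(log))
  panel
}

#' Rarefy a feature table to an even depth
#'
#' Samples with fewer total reads than `depth` are dropped (and logged in
#' the `dropped` attribute); the rest are subsampled without replacement to
#' exactly `depth` reads, one draw per sample in sample-ID sort order, so
#' output is deterministic given the seed.
#'
#' @param counts Samples x features count matrix.
#' @param depth Target depth (>= 1).
#' @param seed Integer seed.
#' @return Rarefied count matrix with attribute `dropped` naming removed
#'   samples.
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  if (depth <= 0) stop("depth must be >= 1")
  counts <- validate_feature_table(counts)
  counts <- counts[order(rownames(counts)), , drop = FALSE]
  totals <- rowSums(counts)
  dropped <- rownames(counts)[totals < depth]
  keep <- counts[totals >= depth, , drop = FALSE]
  if (nrow(keep) == 0) stop("no sample reaches the requested depth")
  set.seed(seed)
  out <- withCallingHandlers(
    vegan::rrarefy(keep, depth),
    # vegan's raw-counts heuristic misfires on small integer fixtures
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "double"
  attr(out, "dropped") <- dropped
  out
}

#' Prevalence filter
#'
#' Retains features with a nonzero count in strictly more than
#' `threshold` x n_samples samples (so a feature present in exactly 20% of
#' samples is dropped at the default threshold).
#'
#' @param counts Samples x features matrix.
#' @param threshold Fraction in [0, 1).
#' @return Filtered matrix.
#' @export
prevalence_filter <- function(counts, threshold = 0.2) {
  stopifnot(threshold >= 0, threshold < 1)
  counts <- validate_feature_table(counts)
  prevalence <- colSums(counts > 0)
  counts[, prevalence > threshold * nrow(counts), drop = FALSE]
}

#' Convert counts to relative abundance
#'
#' @param counts Samples x features matrix with positive sample totals.
#' @return Matrix of proportions; every row sums to 1 (within 1e-12).
#' @export
relative_abundance <- function(counts) {
  counts <- validate_feature_table(counts)
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop("zero-total sample(s): ",
         paste(rownames(counts)[totals == 0], collapse = ", "))
  counts / totals
}

#' Worked enrollment roster for the exclusion cascade
#'
#' A synthetic participant roster reconstructing a published cohort's
#' enrollment flow from its printed counts: 162 enrolled (81 ART-naive,
#' 39 ART-experienced, 42 healthy controls); 14 naive participants with
#' baseline viral load < 20 copies/mL (inconsistent with declared status);
#' 6 experienced participants viremic (> 200) at baseline; then, among the
#' 142 retained, 14 lost to follow-up and 15 naive participants without
#' virologic control at week 24. Individual viral-load values are
#' synthetic; only the rule-relevant thresholds are meaningful.
#'
#' @return Metadata data.frame ready for [label_viremia()].
#' @export
example_enrollment_roster <- function() {
  mk_pid <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  # cohort sizes at enrollment
  naive <- data.frame(pid = mk_pid("N", 81), cohort = "Naive",
                      stringsAsFactors = FALSE)
  expd <- data.frame(pid = mk_pid("E", 39), cohort = "Exp",
                     stringsAsFactors = FALSE)
  hc <- data.frame(pid = mk_pid("H", 42), cohort = "HC",
                   stringsAsFactors = FALSE)
  roster <- rbind(naive, expd, hc)
  roster$location <- rep_len(c("rural", "urban"), nrow(roster))

  # baseline viral loads
  vl0 <- numeric(nrow(roster))
  vl0[roster$cohort == "Naive"] <- 50000          # viremic, as expected untreated
  vl0[roster$cohort == "Naive"][1:14] <- 10       # inconsistent (< 20)
  vl0[roster$cohort == "Exp"] <- 0                # suppressed on ART
  vl0[roster$cohort == "Exp"][1:6] <- 5000        # baseline viremia (> 200)
  vl0[roster$cohort == "HC"] <- NA_real_

  # week-24 status among the 142 baseline-retained:
  # 14 lost to follow-up (7 naive, 1 exp, 6 HC), 15 naive failures (> 200)
  retained_naive <- roster$pid[roster$cohort == "Naive"][15:81]  # 67
  retained_exp <- roster$pid[roster$cohort == "Exp"][7:39]       # 33
  lost <- c(retained_naive[1:7], retained_exp[1], roster$pid[roster$cohort == "HC"][1:6])
  failed <- retained_naive[8:22]                                 # 15

  vl24 <- numeric(nrow(roster))
  vl24[roster$cohort == "Naive"] <- 40            # controlled (< 200)
  vl24[roster$pid %in% failed] <- 10000           # failure (> 200)
  vl24[roster$cohort == "Exp"] <- 0
  vl24[roster$cohort == "HC"] <- NA_real_

  has_w24 <- !(roster$pid %in% lost)
  w0 <- data.frame(sample_id = paste0(roster$pid, "_w00"), pid = roster$pid,
                   cohort = roster$cohort, location = roster$location,
                   week = 0L, viral_load = vl0, stringsAsFactors = FALSE)
  w24 <- data.frame(sample_id = paste0(roster$pid[has_w24], "_w24"),
                    pid = roster$pid[has_w24],
                    cohort = roster$cohort[has_w24],
                    location = roster$location[has_w24],
                    week = 24L, viral_load = vl24[has_w24],
                    stringsAsFactors = FALSE)
  rbind(w0, w24)
}
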