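#' Read a feature table
#'
#' TSV layout: features as rows, samples as columns, first column holding
#' feature IDs and the header row holding sample IDs (the common amplicon
#' export layout). Files ending in `.biom` are read with
#' \pkg{biomformat} when available. The table is returned transposed to the
#' package's working orientation: samples as rows, features as columns.
#'
#' @param path Path to a TSV or BIOM file.
#' @return Integer matrix, samples x features.
#' @export
read_feature_table <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")   # features x samples
    return(validate_feature_table(t(m)))
  }
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  validate_feature_table(t(as.matrix(df)))
}

#' Write a feature table as TSV (features as rows)
#'
#' @param counts Samples x features matrix.
#' @param path Output path.
#' @export
write_feature_table <- function(counts, path) {
  validate_feature_table(counts)
  out <- data.frame(feature_id = colnames(counts), t(counts),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_feature_table <- function(counts) {
  if (is.null(dim(counts)) || nrow(counts) < 1 || ncol(counts) < 1)
    stop("feature table is empty")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("feature table needs sample and feature IDs")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("feature table IDs must be unique on both axes")
  if (any(counts < 0)) stop("feature table has negative entries")
  storage.mode(counts) <- "double"
  counts
}

#' Read per-sample metadata
#'
#' @param path TSV with at least sample_id, pid, cohort, location, week.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "pid", "cohort", "location", "week")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata lacks required columns: ", paste(missing, collapse = ", "))
  validate_metadata(meta)
}

validate_metadata <- function(meta) {
  if (anyDuplicated(meta[c("pid", "week")]))
    stop("(pid, week) pairs must be unique")
  if (!all(meta$week %in% c(0, 24))) stop("week must be 0 or 24")
  if (any(!is.na(meta$viral_load) & meta$viral_load < 0))
    stop("viral_load must be >= 0")
  for (v in c("cohort", "location")) {
    bad <- tapply(meta[[v]], meta$pid, function(x) length(unique(x)) > 1)
    if (any(bad)) stop(v, " must be constant within pid: ",
                       paste(names(bad)[bad], collapse = ", "))
  }
  meta
}

#' Read the immune-marker panel
#'
#' @param path TSV with sample_id plus the eight columns of
#'   [immune_markers()].
#' @return data.frame.
#' @export
read_immune_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", immune_markers()), names(panel))
  if (length(missing))
    stop("immune panel lacks columns: ", paste(missing, collapse = ", "))
  for (m in pct_markers()) {
    x <- panel[[m]]
    if (any(!is.na(x) & (x < 0 | x > 100)))
      stop("marker ", m, " outside [0, 100]")
  }
  for (m in c("il6", "crp"))
    if (any(!is.na(panel[[m]]) & panel[[m]] < 0))
      stop("marker ", m, " must be >= 0")
  panel
}

#' Write / read a square distance matrix as TSV
#'
#' Square layout with a sample-ID header row and first column.
#'
#' @param dm `dist` or square matrix.
#' @param path File path.
#' @return `write_distance_matrix`: the path, invisibly;
#'   `read_distance_matrix`: a square numeric matrix.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as.matrix(dm)
  out <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  validate_distance_matrix(m)
}

validate_distance_matrix <- function(m) {
  if (!isTRUE(all.equal(rownames(m), colnames(m))))
    stop("distance matrix row/column IDs differ")
  if (any(!is.finite(m))) stop("distance matrix has non-finite entries")
  if (any(m < 0)) stop("distances must be non-negative")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix must be symmetric")
  m
}

# Align a feature table and metadata on shared samples; never silent.
align_samples <- function(counts, meta) {
  shared <- intersect(rownames(counts), meta$sample_id)
  drop_t <- setdiff(rownames(counts), shared)
  drop_m <- setdiff(meta$sample_id, shared)
  if (length(drop_t))
    warning("dropping ", length(drop_t), " table sample(s) absent from metadata: ",
            paste(utils::head(drop_t, 5), collapse = ", "))
  if (length(drop_m))
    warning("dropping ", length(drop_m), " metadata sample(s) absent from table: ",
            paste(utils::head(drop_m, 5), collapse = ", "))
  meta <- meta[match(shared, meta$sample_id), , drop = FALSE]
  list(counts = counts[shared, , drop = FALSE], meta = meta)
}

#' Round half-up
#'
#' Rounds half away from zero at `digits` decimals — the convention used
#' when printing percentages (e.g. 22.35 -> 22.4), unlike base R's
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
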