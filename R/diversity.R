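#' Shannon entropy of a sample
#'
#' H = -sum p_i log(p_i) over the sample's nonzero feature proportions,
#' in bits (log base 2) by default — the convention of the standard
#' amplicon core-metrics pipelines. The base is configurable and recorded
#' in the result's `base` attribute.
#'
#' @param counts Non-negative count (or proportion) vector for one sample,
#'   or a samples x features matrix (one value per row).
#' @param base Logarithm base (default 2).
#' @return Entropy value(s); `0 <= H <= log_base(richness)`.
#' @export
shannon <- function(counts, base = 2) {
  if (is.matrix(counts)) {
    out <- apply(counts, 1L, shannon, base = base)
    attr(out, "base") <- base
    return(out)
  }
  total <- sum(counts)
  if (total <= 0) stop("all-zero sample has undefined entropy")
  p <- counts[counts > 0] / total
  structure(-sum(p * log(p)) / log(base), base = base)
}

# leaves x edges indicator of descent, tips ordered as tree$tip.label
.edge_descendant_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  M <- matrix(0, ntip, nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge)))
    M[desc[[tree$edge[e, 2L]]], e] <- 1
  M
}

#' Weighted UniFrac distances
#'
#' For samples A and B, d = sum over branches of b_l * |p_A(l) - p_B(l)|,
#' where b_l is the branch length and p_X(l) the fraction of sample X's
#' reads on leaves descending from the branch. The default is the raw
#' (unnormalized) variant, matching the core-metrics default of the
#' standard amplicon pipelines; `normalized = TRUE` divides each pair by
#' sum b_l * (p_A(l) + p_B(l)) so distances lie in [0, 1].
#'
#' @param counts Samples x features matrix; every feature must be a tree
#'   leaf and every sample total positive.
#' @param tree Rooted [ape::phylo] with non-negative branch lengths.
#' @param normalized Use the normalized variant (default FALSE).
#' @return A `dist` object over the samples.
#' @export
weighted_unifrac <- function(counts, tree, normalized = FALSE) {
  counts <- validate_feature_table(counts)
  missing <- setdiff(colnames(counts), tree$tip.label)
  if (length(missing))
    stop("feature(s) missing from tree: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (any(rowSums(counts) <= 0))
    stop("zero-total sample(s): ",
         paste(rownames(counts)[rowSums(counts) <= 0], collapse = ", "))

  # align table columns to tips; tips absent from the table carry zero mass
  P <- matrix(0, nrow(counts), length(tree$tip.label),
              dimnames = list(rownames(counts), tree$tip.label))
  P[, colnames(counts)] <- counts
  P <- P / rowSums(P)
  B <- P %*% .edge_descendant_matrix(tree)          # samples x edges mass
  len <- tree$edge.length
  raw <- as.matrix(stats::dist(sweep(B, 2L, len, `*`), method = "manhattan"))
  if (normalized) {
    s <- drop(B %*% len)                            # per-sample depth-weighted mass
    denom <- outer(s, s, `+`)
    nz <- denom > 0
    raw[nz] <- raw[nz] / denom[nz]
  }
  diag(raw) <- 0
  stats::as.dist(raw)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of -D^2/2 followed by eigendecomposition.
#' Coordinates are eigenvector * sqrt(eigenvalue) for positive eigenvalues;
#' negative eigenvalues are dropped (no correction) and excluded from the
#' proportion-explained denominator. Each axis is oriented so that the
#' coordinate of the lexicographically smallest sample ID is non-negative
#' (ties broken by the next sample), which removes reflection
#' nondeterminism.
#'
#' @param dm `dist` or square symmetric matrix with zero diagonal.
#' @param n_axes Number of axes to return (default 4).
#' @return List of class `pcoa_result`: `eigenvalues` (all, non-increasing),
#'   `coordinates` (samples x axes, PC1...), `proportion_explained`.
#' @export
pcoa <- function(dm, n_axes = 4L) {
  if (n_axes < 1) stop("n_axes must be >= 1")
  D <- validate_distance_matrix(as.matrix(dm))
  n <- nrow(D)
  A <- -0.5 * D^2
  G <- A - rowMeans(A)[row(A)] - colMeans(A)[col(A)] + mean(A)
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  vals <- eig$values
  tol <- max(abs(vals), 1) * 1e-12
  pos <- which(vals > tol)
  k <- min(n_axes, length(pos))
  coords <- matrix(0, n, max(k, 1L),
                   dimnames = list(rownames(D),
                                   paste0("PC", seq_len(max(k, 1L)))))
  if (k > 0) {
    coords <- eig$vectors[, pos[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(vals[pos[seq_len(k)]]), k)
    dimnames(coords) <- list(rownames(D), paste0("PC", seq_len(k)))
    ord <- order(rownames(D))
    for (j in seq_len(k)) {
      # first sample (by ID) with a nonzero coordinate decides the sign
      lead <- ord[which(abs(coords[ord, j]) > tol)[1L]]
      if (!is.na(lead) && coords[lead, j] < 0) coords[, j] <- -coords[, j]
    }
  }
  prop <- if (length(pos)) vals[pos[seq_len(k)]] / sum(vals[pos]) else
    rep(0, ncol(coords))
  structure(list(eigenvalues = vals, coordinates = coords,
                 proportion_explained = prop), class = "pcoa_result")
}

#' Biplot feature coordinates on a PCoA ordination
#'
#' Each feature is placed at the abundance-weighted mean of the sample
#' coordinates, the weights being that feature's relative abundance across
#' samples normalized to sum one. Importance is the Euclidean norm of the
#' feature coordinate over the retained axes; a feature uniformly spread
#' over all samples sits at the origin (PCoA scores are centered).
#'
#' @param ord A [pcoa()] result.
#' @param rel_abund Samples x features relative-abundance matrix with the
#'   same samples as the ordination.
#' @return data.frame (feature, one column per axis, importance), ranked by
#'   decreasing importance. Features with zero total abundance are excluded
#'   with a warning.
#' @export
biplot_features <- function(ord, rel_abund) {
  stopifnot(inherits(ord, "pcoa_result"))
  Y <- ord$coordinates
  if (!setequal(rownames(Y), rownames(rel_abund)))
    stop("ordination and abundance samples differ")
  X <- rel_abund[rownames(Y), , drop = FALSE]
  totals <- colSums(X)
  if (any(totals == 0)) {
    warning("excluding feature(s) with zero total abundance: ",
            paste(utils::head(colnames(X)[totals == 0], 5), collapse = ", "))
    X <- X[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  W <- sweep(X, 2L, totals, `/`)                    # columns sum to 1
  coords <- t(W) %*% Y
  importance <- sqrt(rowSums(coords^2))
  out <- data.frame(feature = rownames(coords), coords,
                    importance = importance, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' PERMANOVA with optional strata-restricted permutations
#'
#' Sequential (Type-I) partition of the Gower-centered distance matrix over
#' the listed terms, with the permutation p-value
#' (1 + #\{F* >= F_obs\}) / (1 + n_perm). When `strata` is given,
#' permutations shuffle samples only within strata blocks (here typically
#' the participant ID, to respect repeated measures). Delegates the
#' partition and permutation machinery to [vegan::adonis2()], the canonical
#' implementation.
#'
#' @param dm `dist` or square matrix over the samples.
#' @param meta Metadata with one row per sample, same order as `dm` labels.
#' @param terms Character vector of model terms, in testing order; formula
#'   syntax such as `"location*week"` is allowed.
#' @param strata Optional metadata column name restricting permutations.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return data.frame of class `permanova_result`: term, df, sum of
#'   squares, R2, pseudo-F and permutation p per term, plus residual and
#'   total rows; attributes record `n_permutations` and `strata`.
#' @export
permanova <- function(dm, meta, terms, strata = NULL, n_perm = 999L,
                      seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  D <- stats::as.dist(dm)
  labs <- attr(D, "Labels")
  if (!is.null(labs)) {
    if (!setequal(labs, meta$sample_id))
      stop("distance matrix and metadata samples differ")
    meta <- meta[match(labs, meta$sample_id), , drop = FALSE]
  } else if (attr(D, "Size") != nrow(meta)) {
    stop("distance matrix size does not match metadata")
  }
  vars <- all.vars(stats::reformulate(terms))
  missing <- setdiff(vars, names(meta))
  if (length(missing))
    stop("term variable(s) absent from metadata: ",
         paste(missing, collapse = ", "))
  for (v in vars)
    if (length(unique(meta[[v]])) < 2)
      stop("term variable '", v, "' is constant across samples")
  strata_f <- NULL
  if (!is.null(strata)) {
    if (!strata %in% names(meta)) stop("strata variable absent from metadata")
    strata_f <- factor(meta[[strata]])
    if (all(table(strata_f) == 1L))
      warning("all strata blocks have size 1; the permutation test is degenerate")
  }
  fml <- stats::reformulate(terms, response = quote(D))
  set.seed(seed)
  # permute announces complete enumeration for small permutation sets
  fit <- suppressMessages(
    vegan::adonis2(fml, data = meta, permutations = n_perm,
                   by = "terms", strata = strata_f))
  out <- data.frame(term = rownames(fit), df = fit$Df,
                    sum_sq = fit$SumOfSqs, r2 = fit$R2,
                    f = fit$F, p = fit$`Pr(>F)`,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("permanova_result", "data.frame"),
            n_permutations = n_perm, strata = strata)
}
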