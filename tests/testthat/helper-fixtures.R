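# Shared fixture builders and independent oracles.

# Tree from explicit newick, so topology and branch lengths are hand-chosen.
tree_from_newick <- function(text) ape::read.tree(text = text)

# Two-leaf unit-branch tree used for the complete-separation case.
cherry_tree <- function() tree_from_newick("(feature_a:1,feature_b:1);")

random_count_table <- function(n_samples, features, min_total = 20,
                               max_total = 200) {
  m <- t(vapply(seq_len(n_samples), function(i) {
    total <- sample(min_total:max_total, 1)
    stats::rmultinom(1, total, prob = stats::runif(length(features)))[, 1]
  }, numeric(length(features))))
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)), features)
  m
}

# Brute-force weighted UniFrac: enumerate each branch's descendant leaf set
# by walking the edge list, then sum len * |pA - pB| pair by pair.
unifrac_oracle <- function(counts, tree, normalized = FALSE) {
  prop <- counts / rowSums(counts)
  tips <- tree$tip.label
  descend_tips <- function(node) {
    if (node <= length(tips)) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, descend_tips))
  }
  branch_sets <- lapply(tree$edge[, 2], descend_tips)
  n <- nrow(counts)
  D <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  mass <- function(i, set) {
    present <- intersect(set, colnames(prop))
    if (length(present)) sum(prop[i, present]) else 0
  }
  for (a in seq_len(n)) for (b in seq_len(n)) if (a < b) {
    d <- 0; denom <- 0
    for (e in seq_along(branch_sets)) {
      pa <- mass(a, branch_sets[[e]])
      pb <- mass(b, branch_sets[[e]])
      d <- d + tree$edge.length[e] * abs(pa - pb)
      denom <- denom + tree$edge.length[e] * (pa + pb)
    }
    D[a, b] <- D[b, a] <- if (normalized && denom > 0) d / denom else d
  }
  D
}

# Classical distance-based one-factor SS partition and pseudo-F.
permanova_oracle_f <- function(D, groups) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.factor(groups)
  ss_total <- sum(D[upper.tri(D)]^2) / n
  ss_within <- sum(vapply(levels(groups), function(g) {
    idx <- which(groups == g)
    sub <- D[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]^2) / length(idx)
  }, numeric(1)))
  ss_among <- ss_total - ss_within
  a <- nlevels(groups)
  list(f = (ss_among / (a - 1)) / (ss_within / (n - a)),
       ss_among = ss_among, ss_within = ss_within, ss_total = ss_total)
}

# Minimal two-timepoint metadata for prep/dysbiosis tests.
toy_meta <- function(n_per_cohort = 3) {
  grid <- expand.grid(cohort = c("Naive", "Exp", "HC"),
                      i = seq_len(n_per_cohort), week = c(0L, 24L),
                      stringsAsFactors = FALSE)
  pid <- sprintf("%s%02d", substr(grid$cohort, 1, 1), grid$i)
  data.frame(sample_id = sprintf("%s_w%02d", pid, grid$week), pid = pid,
             cohort = grid$cohort,
             location = ifelse(grid$i %% 2 == 0, "rural", "urban"),
             week = grid$week,
             viral_load = ifelse(grid$cohort == "HC", NA_real_,
                                 ifelse(grid$cohort == "Naive" & grid$week == 0,
                                        10000, 50)),
             stringsAsFactors = FALSE)
}
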