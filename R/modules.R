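# Consensus module detection: seeded k-medoids (PAM) under Euclidean
# distance, gap-statistic model selection with structure-preserving column
# permutations and the firstSEmax rule, hard least-squares consensus of PAM
# ensembles, and merging of correlated clusters.

#' Partitioning around medoids with a seeded random start
#'
#' k-medoids under Euclidean distance: initial medoids are drawn uniformly
#' from the data rows, then SWAP iterations run to a local optimum
#' (equal-cost swaps break to the lowest feature index, so the result is
#' deterministic given the seed).
#'
#' @param x numeric matrix (rows are clustered) or a precomputed distance
#'   matrix via `dist_matrix`.
#' @param k number of clusters (k <= rows).
#' @param seed integer seed for the random start (ignored if `init` given).
#' @param init optional integer vector of initial medoid row indices.
#' @param dist_matrix optional precomputed full distance matrix.
#' @return List (`labels`, `medoids`, `cost`, `wss`): labels 1..k ordered by
#'   medoid row index; `cost` is the sum of distances to medoids, `wss` the
#'   sum of squared distances.
#' @export
pam_cluster <- function(x, k, seed = 1L, init = NULL, dist_matrix = NULL) {
  d <- if (is.null(dist_matrix)) as.matrix(dist(x)) else dist_matrix
  n <- nrow(d)
  if (k > n) stop("k must be <= the number of rows")
  if (is.null(init)) {
    set.seed(derive_seed(seed, "pam"))
    init <- sample.int(n, k)
  }
  if (length(init) != k || anyDuplicated(init)) stop("invalid initial medoids")
  pam_fit_cpp(d, as.integer(init))
}

#' Gap-statistic selection of the number of clusters
#'
#' Runs PAM once per k on the data and on `B` reference datasets obtained by
#' independently permuting each column's values across rows (randomized data
#' with structure similar to the actual data). The gap at k is the mean
#' difference in log within-cluster sum of squared distances to medoids
#' between reference and data; `firstSEmax` picks the smallest k whose gap is
#' within one standard error of the maximal gap.
#'
#' @param x numeric matrix (rows clustered).
#' @param kmax largest k tried (k = 2..kmax; kmax < rows required).
#' @param B number of reference permutations (> 0).
#' @param seed integer seed.
#' @param reference `"permute"` (per-column value permutation) or
#'   `"uniform"` (uniform box resampling).
#' @return List (`k`, `gap`, `se`, `log_w`, `log_w_ref`, `k_selected`).
#' @export
gap_select_k <- function(x, kmax = 25, B = 100, seed = 1L,
                         reference = c("permute", "uniform")) {
  reference <- match.arg(reference)
  n <- nrow(x)
  if (B <= 0) stop("B must be > 0")
  if (kmax >= n) stop("kmax must be smaller than the number of rows")
  set.seed(derive_seed(seed, "gap"))
  ks <- 2:kmax
  run_all_k <- function(d) {
    vapply(ks, function(k) {
      init <- sample.int(nrow(d), k)
      log(pam_fit_cpp(d, init)$wss)
    }, numeric(1))
  }
  log_w <- run_all_k(as.matrix(dist(x)))
  log_w_ref <- matrix(NA_real_, B, length(ks))
  for (b in seq_len(B)) {
    xr <- if (reference == "permute") {
      apply(x, 2, function(col) col[sample.int(n)])
    } else {
      apply(x, 2, function(col) runif(n, min(col), max(col)))
    }
    log_w_ref[b, ] <- run_all_k(as.matrix(dist(xr)))
  }
  gap <- colMeans(log_w_ref) - log_w
  se <- apply(log_w_ref, 2, sd) * sqrt(1 + 1 / B)
  k_star <- which.max(gap)
  k_sel <- ks[which(gap >= gap[k_star] - se[k_star])[1]]
  list(k = ks, gap = gap, se = se, log_w = log_w,
       log_w_ref = colMeans(log_w_ref), k_selected = k_sel)
}

#' Hard least-squares consensus of an ensemble of partitions
#'
#' Finds the hard k-cluster partition minimizing the summed squared Frobenius
#' distance between its membership matrix and each member's, with the member
#' label permutation solved exactly per member (Hungarian assignment).
#' Optimized by alternating relabel/assign steps started from the best-scoring
#' ensemble member (which also guarantees the consensus objective never
#' exceeds that of any member used as a candidate) plus `restarts` random
#' label vectors; the best objective is kept.
#'
#' @param partitions list of label vectors (1..k) over the same features.
#' @param k number of clusters.
#' @param restarts number of additional random starts.
#' @param seed integer seed for the random starts.
#' @return List (`labels`, `objective`).
#' @export
consensus_partition <- function(partitions, k, restarts = 5, seed = 1L) {
  n <- unique(vapply(partitions, length, integer(1)))
  if (length(n) != 1) stop("ensemble members cover mismatched feature sets")
  lab <- vapply(partitions, as.integer, integer(n))
  if (max(lab) > k) stop("labels exceed k")
  set.seed(derive_seed(seed, "consensus"))
  fit <- consensus_core(lab, k, restarts)
  list(labels = as.integer(fit$labels), objective = fit$objective)
}

# Shared optimizer core: seed the alternating search with the best ensemble
# member (exact member objectives are cheap to evaluate) plus `restarts`
# random label vectors. Assumes the caller has set the RNG state.
consensus_core <- function(lab, k, restarts) {
  n <- nrow(lab)
  member_obj <- vapply(seq_len(ncol(lab)), function(j)
    consensus_objective_cpp(lab[, j], lab, as.integer(k)), numeric(1))
  best_member <- lab[, which.min(member_obj), drop = FALSE]
  rand <- if (restarts > 0)
    vapply(seq_len(restarts), function(r) sample.int(k, n, replace = TRUE),
           integer(n))
  starts <- cbind(best_member, if (restarts > 0) rand)
  consensus_fit_cpp(lab, as.integer(k), starts)
}

#' Objective of a candidate consensus against an ensemble
#'
#' @param labels candidate consensus label vector (1..k).
#' @param partitions list of member label vectors.
#' @param k number of clusters.
#' @return The summed squared membership-matrix distance.
#' @export
consensus_objective <- function(labels, partitions, k) {
  n <- length(labels)
  lab <- vapply(partitions, as.integer, integer(n))
  consensus_objective_cpp(as.integer(labels), lab, as.integer(k))
}

#' Detect consensus modules from a scaled matrix
#'
#' Outer loop: `n_outer` rounds of [`n_inner` seeded PAM runs followed by a
#' hard-Euclidean consensus]; the final partition is the consensus of the
#' `n_outer` round partitions. The co-assignment matrix records the fraction
#' of all `n_inner * n_outer` PAM runs pairing two features.
#'
#' @param scaled a `scaled_matrix` from [scale_assays()] or a plain matrix.
#' @param k number of modules (e.g. from [gap_select_k()]).
#' @param n_inner PAM runs per round.
#' @param n_outer rounds.
#' @param restarts consensus random restarts.
#' @param seed integer seed.
#' @return A `consensus_result`: list (`labels` named by feature, `k`,
#'   `medoids`, `profiles` module x condition means, `coassignment`,
#'   `merges`).
#' @export
detect_modules <- function(scaled, k, n_inner = 100, n_outer = 25,
                           restarts = 5, seed = 1L) {
  x <- if (inherits(scaled, "scaled_matrix")) scaled$values else scaled
  n <- nrow(x)
  d <- as.matrix(dist(x))
  set.seed(derive_seed(seed, "detect_modules"))
  coassign <- matrix(0, n, n)
  outer_parts <- vector("list", n_outer)
  for (o in seq_len(n_outer)) {
    inner <- vector("list", n_inner)
    for (i in seq_len(n_inner)) {
      fit <- pam_fit_cpp(d, sample.int(n, k))
      inner[[i]] <- as.integer(fit$labels)
      coassign <- coassign_add_cpp(coassign, inner[[i]])
    }
    outer_parts[[o]] <- as.integer(
      consensus_core(vapply(inner, identity, integer(n)), k, restarts)$labels)
  }
  final <- consensus_core(vapply(outer_parts, identity, integer(n)),
                          k, restarts)
  labels <- setNames(as.integer(final$labels), rownames(x))
  structure(list(labels = labels, k = k,
                 medoids = partition_medoids(d, labels),
                 profiles = module_profiles(x, labels),
                 coassignment = coassign / (n_inner * n_outer),
                 objective = final$objective, merges = NULL),
            class = "consensus_result")
}

# medoid (min total within-cluster distance, tie -> lowest index) per cluster
partition_medoids <- function(d, labels) {
  vapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    idx[which.min(rowSums(d[idx, idx, drop = FALSE]))]
  }, integer(1))
}

# mean condition profile per module
module_profiles <- function(x, labels) {
  cls <- sort(unique(labels))
  prof <- t(vapply(cls, function(cl)
    colMeans(x[labels == cl, , drop = FALSE]), numeric(ncol(x))))
  rownames(prof) <- paste0("M", cls)
  prof
}

#' Merge highly correlated modules
#'
#' Computes Pearson correlations between module mean condition-profiles,
#' applies average-linkage hierarchical clustering on 1 - r, cuts the tree at
#' height `1 - r_threshold`, and combines modules sharing a branch. The merge
#' record lists combined pairs with their correlations.
#'
#' @param result a `consensus_result` from [detect_modules()].
#' @param x the matrix the modules were detected on (for recomputing
#'   profiles); defaults to reusing `result$profiles`.
#' @param r_threshold correlation threshold in (0, 1).
#' @return The updated `consensus_result` (labels renumbered 1..k', `merges`
#'   filled in).
#' @export
merge_correlated <- function(result, x = NULL, r_threshold = 0.85) {
  if (r_threshold <= 0 || r_threshold >= 1)
    stop("r_threshold must lie in (0, 1)")
  if (inherits(x, "scaled_matrix")) x <- x$values
  prof <- if (is.null(x)) result$profiles else module_profiles(x, result$labels)
  if (nrow(prof) < 2) return(result)
  r <- cor(t(prof))
  hc <- hclust(as.dist(1 - r), method = "average")
  grp <- cutree(hc, h = 1 - r_threshold)
  merges <- list()
  for (g in unique(grp)) {
    members <- which(grp == g)
    if (length(members) < 2) next
    pairs <- combn(members, 2)
    merges[[length(merges) + 1L]] <- data.frame(
      module_a = rownames(prof)[pairs[1, ]],
      module_b = rownames(prof)[pairs[2, ]],
      r = r[cbind(pairs[1, ], pairs[2, ])],
      merged_into = paste0("M", g), stringsAsFactors = FALSE)
  }
  old_cluster <- as.integer(sub("^M", "", rownames(prof)))
  sizes <- as.numeric(table(factor(result$labels, levels = old_cluster)))
  new_of_old <- setNames(grp, old_cluster)
  labels <- setNames(as.integer(new_of_old[as.character(result$labels)]),
                     names(result$labels))
  # renumber merged groups densely, preserving order of first appearance
  dense <- setNames(seq_along(unique(labels)), unique(labels))
  labels <- setNames(as.integer(dense[as.character(labels)]), names(labels))
  result$labels <- labels
  result$k <- length(unique(labels))
  if (!is.null(x)) {
    result$profiles <- module_profiles(x, labels)
  } else {
    # size-weighted average of the old profiles within each merged group
    newg <- dense[as.character(new_of_old)]
    newprof <- t(vapply(sort(unique(newg)), function(g) {
      idx <- which(newg == g)
      colSums(prof[idx, , drop = FALSE] * sizes[idx]) / sum(sizes[idx])
    }, numeric(ncol(prof))))
    rownames(newprof) <- paste0("M", sort(unique(newg)))
    result$profiles <- newprof
  }
  result$medoids <- NULL
  if (length(merges)) {
    merges <- do.call(rbind, merges)
    gnum <- as.integer(sub("^M", "", merges$merged_into))
    merges$merged_into <- paste0("M", dense[as.character(gnum)])
    merges <- list(merges)
  }
  result$merges <- if (length(merges)) merges[[1]] else
    data.frame(module_a = character(), module_b = character(), r = numeric(),
               merged_into = character())
  result
}
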