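# Well-level phenotype quantification from single-cell tables and lineage
# tracks: fixed-radius neighbor counts, CSR-normalized k-nearest-neighbor
# distances, mean-shift cluster sizes, DAPI cell-cycle and EdU gates,
# lineage migration distance, and the associated group comparisons.

#' Neighbor counts within a fixed radius
#'
#' Counts cell centroids within `radius` of each focal cell's centroid
#' (excluding the cell itself). Cells closer than `radius` to any image
#' border are excluded as focal cells; cells in the margin still count as
#' neighbors of interior cells.
#'
#' @param cells data.frame with `x`, `y` columns.
#' @param radius neighborhood radius in pixels.
#' @param field `c(width, height)` of the image.
#' @return List with `per_cell` (focal rows with a `neighbors` column) and
#'   `well_mean`.
#' @export
neighbor_counts <- function(cells, radius = 100, field = c(1000, 1000)) {
  if (!nrow(cells))
    return(list(per_cell = cbind(cells, neighbors = integer(0)),
                well_mean = NA_real_))
  cnt <- radius_count_cpp(cells$x, cells$y, radius)
  focal <- cells$x >= radius & cells$x <= field[1] - radius &
    cells$y >= radius & cells$y <= field[2] - radius
  per_cell <- cbind(cells[focal, , drop = FALSE],
                    neighbors = cnt[focal])
  list(per_cell = per_cell,
       well_mean = if (any(focal)) mean(cnt[focal]) else NA_real_)
}

#' Expected mean k-NN distance under complete spatial randomness
#'
#' For a homogeneous Poisson process of intensity `lambda`, the distance to
#' the j-th nearest neighbor satisfies `lambda * pi * r_j^2 ~ Gamma(j, 1)`,
#' so `E[r_j] = Gamma(j + 1/2) / Gamma(j) / sqrt(lambda * pi)`. Returns the
#' mean of `E[r_j]` over j = 1..k (the CSR expectation of the mean k-NN
#' distance).
#'
#' @param k number of neighbors.
#' @param lambda point intensity (points per unit area).
#' @return Numeric scalar.
#' @export
knn_csr_expectation <- function(k, lambda) {
  j <- seq_len(k)
  mean(exp(lgamma(j + 0.5) - lgamma(j))) / sqrt(lambda * pi)
}

#' Normalized k-nearest-neighbor distance
#'
#' Observed mean distance of each focal cell to its `k` nearest neighbors,
#' normalized by the CSR expectation at the field's intensity. The default
#' normalizer is the k-matched CSR mean ([knn_csr_expectation()]); the
#' Clark-Evans variant normalizing by the 1-NN expectation only is returned
#' as `ratio_ce1`.
#'
#' @param cells data.frame with `x`, `y`.
#' @param k number of neighbors (k < number of cells).
#' @param field `c(width, height)`.
#' @param border_margin focal cells closer than this to a border are excluded
#'   (set 0 to keep all).
#' @return List (`ratio`, `ratio_ce1`, `observed`, `expected_k`,
#'   `expected_1`, `lambda`).
#' @export
normalized_neighbor_distance <- function(cells, k = 4, field = c(1000, 1000),
                                         border_margin = 100) {
  n <- nrow(cells)
  if (k >= n) stop("k must be smaller than the number of cells")
  kd <- knn_dist_cpp(cells$x, cells$y, as.integer(k))
  focal <- cells$x >= border_margin & cells$x <= field[1] - border_margin &
    cells$y >= border_margin & cells$y <= field[2] - border_margin
  if (!any(focal)) stop("no focal cells after border exclusion")
  obs <- mean(rowMeans(kd[focal, , drop = FALSE]))
  lambda <- n / (field[1] * field[2])
  ek <- knn_csr_expectation(k, lambda)
  e1 <- knn_csr_expectation(1, lambda)
  list(ratio = obs / ek, ratio_ce1 = obs / e1, observed = obs,
       expected_k = ek, expected_1 = e1, lambda = lambda)
}

#' Mean-shift clustering of cell centroids
#'
#' Flat-kernel mean shift: each point iterates to the mean of points within
#' `bandwidth` until convergence; modes closer than `bandwidth / 2` merge.
#' The default bandwidth is twice the CSR 1-NN expectation at the field's
#' density.
#'
#' @param cells data.frame with `x`, `y`.
#' @param bandwidth kernel radius in pixels (> 0); `NULL` for the default.
#' @param field `c(width, height)` (used for the default bandwidth).
#' @return List (`labels`, `n_clusters`, `mean_cells_per_cluster`,
#'   `bandwidth`).
#' @export
mean_shift_cluster_size <- function(cells, bandwidth = NULL,
                                    field = c(1000, 1000)) {
  n <- nrow(cells)
  if (is.null(bandwidth)) {
    lambda <- n / (field[1] * field[2])
    bandwidth <- 2 * knn_csr_expectation(1, lambda)
  }
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  ms <- mean_shift_cpp(cells$x, cells$y, bandwidth)
  k <- length(unique(ms$labels))
  list(labels = ms$labels, n_clusters = k,
       mean_cells_per_cluster = n / k, bandwidth = bandwidth)
}

#' Gate cells into G1/G2M by total DAPI intensity
#'
#' Two-group Forgy k-means on total nuclear DAPI (multinucleated cells -
#' `n_nuclei >= 2` - are removed first); the higher-mean cluster is G2M.
#' Best of `nstart` seeded restarts. If the two groups separate poorly
#' (mean silhouette < 0.5) a warning flags the gate as degenerate.
#'
#' @param dapi_total numeric vector of total nuclear DAPI intensities.
#' @param n_nuclei optional nuclei counts aligned with `dapi_total`.
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return List (`phase` factor over the retained cells, `kept` logical over
#'   the input, `g2m_fraction`, `threshold`, `silhouette`).
#' @export
gate_cell_cycle <- function(dapi_total, n_nuclei = NULL, seed = 1L,
                            nstart = 10) {
  kept <- rep(TRUE, length(dapi_total))
  if (!is.null(n_nuclei)) kept <- n_nuclei < 2
  x <- dapi_total[kept]
  if (length(x) < 2) stop("need >= 2 mono-nucleated cells")
  if (length(unique(x)) < 2) stop("constant DAPI intensities: gate undefined")
  set.seed(derive_seed(seed, "dapi_gate"))
  km <- kmeans(x, centers = 2, nstart = nstart, algorithm = "Forgy")
  g2m_cl <- which.max(km$centers)
  phase <- factor(ifelse(km$cluster == g2m_cl, "G2M", "G1"),
                  levels = c("G1", "G2M"))
  sil <- silhouette_1d(x, km$cluster)
  # a median split of unimodal data has a deceptively high silhouette, so the
  # quality check also requires the 4N/2N center ratio expected of a real gate
  ratio <- max(km$centers) / max(min(km$centers), 1e-12)
  if (sil < 0.5 || ratio < 1.3)
    warning(sprintf(paste("poor DAPI gate separation (mean silhouette %.2f,",
                          "center ratio %.2f)"), sil, ratio))
  list(phase = phase, kept = kept,
       g2m_fraction = mean(phase == "G2M"),
       threshold = mean(km$centers), silhouette = sil)
}

# mean silhouette of a 1-D grouping (R helper around the C++ kernel)
silhouette_1d <- function(x, groups) {
  g <- as.integer(factor(groups))
  silhouette_perm_cpp(as.numeric(x), g,
                      matrix(g, ncol = 1))$observed
}

#' Threshold for the EdU positive gate
#'
#' Two-means auto-gate on log intensity of a (plate-level, bimodal) reference
#' distribution: the threshold is the midpoint of the two cluster means on
#' the log scale.
#'
#' @param edu numeric vector of EdU intensities (> 0) pooled across wells.
#' @param seed integer seed.
#' @return Threshold on the original intensity scale.
#' @export
edu_gate_threshold <- function(edu, seed = 1L) {
  x <- log(edu[edu > 0])
  if (length(unique(x)) < 2) stop("constant EdU intensities: gate undefined")
  set.seed(derive_seed(seed, "edu_gate"))
  km <- kmeans(x, centers = 2, nstart = 10, algorithm = "Forgy")
  exp(mean(km$centers))
}

#' Fraction of EdU-positive cells
#'
#' With `threshold = NULL` the gate is learned from this well's own
#' distribution via [edu_gate_threshold()] (requires a bimodal well); wells
#' that may be all-negative or all-positive should be scored against a
#' plate-level threshold.
#'
#' @param edu numeric vector of EdU intensities.
#' @param threshold optional fixed gate.
#' @param seed integer seed (auto-gate only).
#' @return Fraction of cells above the gate.
#' @export
edu_fraction <- function(edu, threshold = NULL, seed = 1L) {
  if (is.null(threshold)) threshold <- edu_gate_threshold(edu, seed)
  mean(edu > threshold)
}

#' Accumulated migration distance per lineage
#'
#' For each founder lineage, one terminal descendant is chosen uniformly at
#' random (seeded) and traced back through mitotic events to time 0; the
#' migration distance is the sum of stepwise Euclidean displacements along
#' the path. Lineages whose path does not reach frame 0 are excluded with a
#' message.
#'
#' @param lineages output of [generate_tracks()] or a compatible list with a
#'   `tracks` long data.frame (`track_id`, `parent_id`, `frame`, `x`, `y`).
#' @param seed integer seed for the terminal-descendant draw.
#' @return data.frame (`lineage`, `track`, `distance`, `n_steps`).
#' @export
lineage_migration <- function(lineages, seed = 1L) {
  tracks <- if (is.data.frame(lineages)) lineages else lineages$tracks
  set.seed(derive_seed(seed, "migration"))
  info <- split(tracks, tracks$track_id)
  parent <- vapply(info, function(d) d$parent_id[1], numeric(1))
  ids <- as.numeric(names(info))
  has_child <- ids %in% parent
  founders <- ids[is.na(parent)]
  # founder of each track, walking up the parent chain; NA if the chain
  # breaks (orphan track whose ancestor is missing)
  root_of <- function(id) {
    repeat {
      p <- parent[as.character(id)]
      if (is.na(p)) {
        if (as.character(id) %in% names(info)) return(id)
        return(NA_real_)
      }
      if (!as.character(p) %in% names(info)) return(NA_real_)
      id <- p
    }
  }
  roots <- vapply(ids, root_of, numeric(1))
  if (anyNA(roots))
    message("excluded ", sum(is.na(roots)),
            " orphan track(s) with no path to frame 0")
  out <- list()
  for (f in founders) {
    terms <- ids[!has_child & !is.na(roots) & roots == f]
    if (!length(terms)) next
    pick <- terms[sample.int(length(terms), 1)]
    # back-trace: concatenate segments terminal -> founder
    path <- NULL
    id <- pick
    ok <- TRUE
    repeat {
      seg <- info[[as.character(id)]]
      seg <- seg[order(seg$frame), ]
      path <- rbind(seg, path)
      pid <- parent[as.character(id)]
      if (is.na(pid)) break
      id <- pid
      if (!as.character(id) %in% names(info)) { ok <- FALSE; break }
    }
    if (!ok || min(path$frame) != 0) {
      message("lineage ", f, " does not reach frame 0; excluded")
      next
    }
    path <- path[!duplicated(path$frame), ]
    path <- path[order(path$frame), ]
    d <- sum(sqrt(diff(path$x)^2 + diff(path$y)^2))
    out[[length(out) + 1L]] <- data.frame(lineage = f, track = pick,
                                          distance = d,
                                          n_steps = nrow(path) - 1L)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(lineage = numeric(), track = numeric(), distance = numeric(),
               n_steps = integer())
  rownames(res) <- NULL
  res
}

#' Compare well-level phenotypes across treatment groups
#'
#' Rank mode (imaging phenotypes): Kruskal-Wallis overall test plus pairwise
#' two-sided Wilcoxon rank-sum tests with BH correction. ANOVA mode
#' (migration): one-way ANOVA plus Tukey HSD. Pairs are flagged significant
#' at adjusted p < 0.05. Groups with fewer than `min_n` wells are dropped
#' with a warning.
#'
#' @param values numeric vector of well-level phenotype values.
#' @param groups grouping vector (ligand treatment).
#' @param mode `"rank"` or `"anova"`.
#' @param min_n minimum wells per group.
#' @param alpha significance threshold on adjusted p.
#' @return List (`overall_p`, `pairwise` data.frame, `mode`).
#' @export
compare_phenotypes <- function(values, groups, mode = c("rank", "anova"),
                               min_n = 3, alpha = 0.05) {
  mode <- match.arg(mode)
  g <- as.character(groups)
  tab <- table(g)
  small <- names(tab)[tab < min_n]
  if (length(small)) {
    warning("dropping group(s) with < ", min_n, " wells: ",
            paste(small, collapse = ", "))
    keep <- !g %in% small
    values <- values[keep]; g <- g[keep]
  }
  if (length(unique(g)) < 2) stop("need >= 2 groups")
  g <- factor(g)
  if (mode == "rank") {
    overall <- kruskal.test(values, g)$p.value
    prs <- combn(levels(g), 2)
    p <- apply(prs, 2, function(pr)
      wilcox.test(values[g == pr[1]], values[g == pr[2]],
                  exact = FALSE)$p.value)
    q <- bh_adjust(p)
    pairwise <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                           p = p, q = q, significant = q < alpha,
                           stringsAsFactors = FALSE)
  } else {
    fit <- aov(values ~ g)
    overall <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$g
    prs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    pairwise <- data.frame(group1 = prs[, 2], group2 = prs[, 1],
                           p = tk[, "p adj"], q = tk[, "p adj"],
                           significant = tk[, "p adj"] < alpha,
                           stringsAsFactors = FALSE)
  }
  rownames(pairwise) <- NULL
  list(overall_p = overall, pairwise = pairwise, mode = mode)
}
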