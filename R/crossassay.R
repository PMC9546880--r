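# Cross-assay comparisons: concordance of differential calls between two
# assays linked by gene-symbol cognates, and the matched-versus-mismatched
# sample-correlation test between two expression views.

# Per-feature direction call over all conditions: "up"/"down" if significant
# in any condition (direction taken from the significant condition with the
# largest |lfc|), else "ns".
feature_direction <- function(diff, q_max, lfc_min) {
  hit <- !is.na(diff$q) & diff$q <= q_max & abs(diff$lfc) >= lfc_min
  dirs <- vapply(split(seq_len(nrow(diff)), diff$feature), function(idx) {
    h <- idx[hit[idx]]
    if (!length(h)) return("ns")
    best <- h[which.max(abs(diff$lfc[h]))]
    if (diff$lfc[best] > 0) "up" else "down"
  }, character(1))
  dirs
}

#' Concordance counts between two assays
#'
#' Pairs features of two assays through a gene-symbol cognate map
#' (many-to-one allowed) and counts pairs significantly up-regulated in both,
#' down-regulated in both, and significant in neither, at assay-specific
#' thresholds (defaults: |lfc| >= 1.5 for assay A, 0.5 for assay B, q <= 0.01
#' for both).
#'
#' @param diff_a,diff_b long differential tables from [test_features()].
#' @param cognate_map data.frame with columns `feature_a`, `feature_b`.
#' @param q_max q-value threshold applied to both assays.
#' @param lfc_min_a,lfc_min_b absolute log2 fold-change thresholds.
#' @return List with `n_up_up`, `n_down_down`, `n_unchanged_both`, and
#'   `totals` (pairs, up in either, down in either).
#' @export
concordance_counts <- function(diff_a, diff_b, cognate_map, q_max = 0.01,
                               lfc_min_a = 1.5, lfc_min_b = 0.5) {
  if (is.null(cognate_map) || !nrow(cognate_map))
    stop("empty cognate map")
  dir_a <- feature_direction(diff_a, q_max, lfc_min_a)
  dir_b <- feature_direction(diff_b, q_max, lfc_min_b)
  da <- dir_a[cognate_map$feature_a]
  db <- dir_b[cognate_map$feature_b]
  ok <- !is.na(da) & !is.na(db)
  da <- da[ok]; db <- db[ok]
  list(n_up_up = sum(da == "up" & db == "up"),
       n_down_down = sum(da == "down" & db == "down"),
       n_unchanged_both = sum(da == "ns" & db == "ns"),
       totals = list(pairs = length(da),
                     up_either = sum(da == "up" | db == "up"),
                     down_either = sum(da == "down" | db == "down")))
}

#' Matched versus mismatched sample-correlation test
#'
#' Pearson correlations between every column of `za` and every column of `zb`
#' over their shared features; pairs of samples with the same (ligand, time)
#' are "matched". A two-sided Mann-Whitney U test compares matched and
#' mismatched correlation distributions.
#'
#' @param za,zb feature x sample z-score matrices; shared rownames (>= 10
#'   required) are used.
#' @param meta_a,meta_b sample metadata for the two matrices.
#' @return List with `r_matched`, `r_mismatched`, their means, and `p`.
#' @export
matched_correlation_test <- function(za, zb, meta_a, meta_b) {
  shared <- intersect(rownames(za), rownames(zb))
  if (length(shared) < 10) stop("need >= 10 shared transcripts")
  a <- za[shared, , drop = FALSE]
  b <- zb[shared, , drop = FALSE]
  key_a <- condition_key(meta_a$ligand[match(colnames(a), meta_a$sample_id)],
                         meta_a$time[match(colnames(a), meta_a$sample_id)])
  key_b <- condition_key(meta_b$ligand[match(colnames(b), meta_b$sample_id)],
                         meta_b$time[match(colnames(b), meta_b$sample_id)])
  r <- cor(a, b)
  matched <- outer(key_a, key_b, "==")
  if (!any(matched)) stop("no matched (ligand, time) sample pairs")
  rm_ <- r[matched]; rmm <- r[!matched]
  wt <- wilcox.test(rm_, rmm, alternative = "two.sided", exact = FALSE)
  list(r_matched = rm_, r_mismatched = rmm,
       mean_matched = mean(rm_), mean_mismatched = mean(rmm),
       p = wt$p.value)
}
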