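# Signature selection at the study's thresholds, per-assay module-feature
# selection, and unique/shared set analysis across ligands.

#' Select per-ligand differential signatures
#'
#' A feature enters a ligand's signature if, at either of the stated time
#' points, its q-value is at most `q_max` and its |log2 fold change| is at
#' least `lfc_min`. Both comparisons are inclusive.
#'
#' @param diff long differential table from [test_features()].
#' @param q_max q-value threshold (default 0.01).
#' @param lfc_min absolute log2 fold-change threshold (default 1.5).
#' @param times time points considered (default 24 and 48 hours).
#' @return A `signature_set`: named list ligand -> character vector of
#'   features, with the thresholds as attributes.
#' @export
select_signatures <- function(diff, q_max = 0.01, lfc_min = 1.5,
                              times = c(24, 48)) {
  d <- diff[diff$time %in% times, , drop = FALSE]
  hit <- !is.na(d$q) & d$q <= q_max & abs(d$lfc) >= lfc_min
  sig <- split(d$feature[hit], d$ligand[hit])
  sig <- lapply(sig, function(x) sort(unique(x)))
  # ligands with no hits keep an (empty) entry
  for (lg in setdiff(unique(d$ligand), names(sig))) sig[[lg]] <- character(0)
  structure(sig[order(names(sig))], class = "signature_set",
            q_max = q_max, lfc_min = lfc_min, times = times)
}

#' Unique/shared set analysis across ligands
#'
#' Features significant for exactly one ligand are `Unique`; features
#' significant for two or more ligands are `Shared` (for each of them).
#'
#' @param sigset a `signature_set` from [select_signatures()].
#' @return List with `labels` (feature, n_ligands, label) and `counts`
#'   (ligand, unique, total).
#' @export
set_analysis <- function(sigset) {
  if (length(sigset) < 2) stop("set analysis needs >= 2 ligands")
  feats <- sort(unique(unlist(sigset)))
  n_lig <- vapply(feats, function(f)
    sum(vapply(sigset, function(s) f %in% s, logical(1))), integer(1))
  labels <- data.frame(feature = feats, n_ligands = n_lig,
                       label = ifelse(n_lig == 1L, "Unique", "Shared"),
                       stringsAsFactors = FALSE, row.names = NULL)
  counts <- data.frame(
    ligand = names(sigset),
    unique = vapply(sigset, function(s)
      sum(labels$label[match(s, labels$feature)] == "Unique"), integer(1)),
    total = vapply(sigset, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(labels = labels, counts = counts)
}

#' Select the integrated feature set for module detection
#'
#' Per-assay rules: GCP and RPPA features in the lowest variance quartile are
#' removed first; CyCIF, RNAseq, and GCP features are then retained if
#' |log2 fold change| > 1.5 with p < 0.05 in any condition; RPPA uses a log
#' fold-change threshold of 0.75 (its distribution is tighter); all ATAC
#' motif-family scores are retained regardless.
#'
#' @param diff_list named list of long differential tables (one per assay;
#'   names must be among RNAseq, RPPA, CyCIF, GCP, ATAC, L1000).
#' @param lfc_matrices named list of feature x condition log2FC matrices used
#'   for the variance-quartile filter (required for GCP/RPPA).
#' @param times time points considered.
#' @return data.frame (`feature`, `assay`) of retained features.
#' @export
select_module_features <- function(diff_list, lfc_matrices = NULL,
                                   times = c(24, 48)) {
  known <- c("RNAseq", "RPPA", "CyCIF", "GCP", "ATAC", "L1000")
  bad <- setdiff(names(diff_list), known)
  if (length(bad)) stop("unknown assay label: ", paste(bad, collapse = ", "))
  keep <- list()
  for (a in names(diff_list)) {
    d <- diff_list[[a]]
    d <- d[d$time %in% times, , drop = FALSE]
    feats <- unique(d$feature)
    if (a %in% c("GCP", "RPPA")) {
      if (is.null(lfc_matrices[[a]]))
        stop("variance-quartile filter for ", a, " needs its lfc matrix")
      m <- lfc_matrices[[a]]
      v <- apply(m, 1, var)
      cut <- quantile(v, 0.25)
      feats <- intersect(feats, rownames(m)[v > cut])
      d <- d[d$feature %in% feats, , drop = FALSE]
    }
    if (a == "ATAC") {
      sel <- feats
    } else {
      thr <- if (a == "RPPA") 0.75 else 1.5
      hit <- !is.na(d$p) & d$p < 0.05 & abs(d$lfc) > thr
      sel <- sort(unique(d$feature[hit]))
    }
    if (length(sel))
      keep[[a]] <- data.frame(feature = sel, assay = a,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}
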