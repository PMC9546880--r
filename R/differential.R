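# Control-relative differential analysis: median-summarized log2 fold changes
# against the time-0 control, a self-contained per-feature Welch t-test (the
# package's declared stand-in for moderated empirical-Bayes tests), and BH
# correction within each assay x condition family.

log_values <- function(values, value_scale) {
  switch(value_scale,
         log2 = values,
         counts = log2(values + 1),
         linear = log2(values),
         stop("unknown value_scale: ", value_scale))
}

#' Log2 fold change versus the time-0 control
#'
#' Per feature and condition: the median over replicates of the log2 value
#' minus the median log2 value of the CTRL_0 replicates. Count assays are
#' offset by a pseudocount of 1 before the log; `linear` intensities are
#' logged; `log2` (and z-score) data are used as-is.
#'
#' @param values feature x sample matrix.
#' @param meta sample metadata with `sample_id`, `ligand`, `time` matching
#'   the columns of `values`.
#' @param value_scale `"log2"`, `"counts"`, or `"linear"`.
#' @return Feature x condition matrix of log2 fold changes, columns named
#'   `ligand_time`.
#' @export
log2fc_vs_control <- function(values, meta, value_scale = "log2") {
  meta <- meta[match(colnames(values), meta$sample_id), ]
  ctrl <- which(meta$ligand == "CTRL" & meta$time == 0)
  if (!length(ctrl)) stop("no CTRL_0 samples in the metadata")
  lv <- log_values(values, value_scale)
  ctrl_med <- apply(lv[, ctrl, drop = FALSE], 1, median)
  keys <- condition_key(meta$ligand, meta$time)
  conds <- unique(keys[-ctrl])
  out <- matrix(NA_real_, nrow(values), length(conds),
                dimnames = list(rownames(values), conds))
  for (cc in conds) {
    idx <- which(keys == cc)
    out[, cc] <- apply(lv[, idx, drop = FALSE], 1, median) - ctrl_med
  }
  out
}

# Welch t-test statistics for every row, group A vs group B, on log values.
# var_shrink w pulls each per-feature variance toward the assay-wide median
# (a near-constant target), so the shrunk estimator's sampling variance falls
# by (1-w)^2; the Welch df is scaled up accordingly (Satterthwaite matching
# of the first two moments of the shrunk variance).
welch_rows <- function(a, b, var_shrink = 0) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  if (var_shrink > 0) {
    va <- (1 - var_shrink) * va + var_shrink * median(va)
    vb <- (1 - var_shrink) * vb + var_shrink * median(vb)
  }
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  if (var_shrink > 0) df <- df / (1 - var_shrink)^2
  # degenerate rows: both groups constant
  zero <- se2 <= 0
  p <- rep(NA_real_, length(t))
  fin <- !zero & is.finite(t)
  p[fin] <- 2 * pt(-abs(t[fin]), df[fin])
  if (any(zero)) {
    same <- zero & (ma == mb)
    t[same] <- 0; p[same] <- 1
    diff <- zero & (ma != mb)
    t[diff] <- sign(ma - mb)[diff] * Inf; p[diff] <- 0
  }
  list(t = t, p = p)
}

#' Per-feature differential tests against CTRL_0
#'
#' Two-sided Welch t-test on log-scale replicate values of each treated
#' condition versus the CTRL_0 replicates, with the median-based log2 fold
#' change of [log2fc_vs_control()] and BH q-values computed within each
#' condition (the assay x condition testing family).
#'
#' @param values feature x sample matrix.
#' @param meta sample metadata (`sample_id`, `ligand`, `time`, `replicate`).
#' @param value_scale `"log2"`, `"counts"`, or `"linear"`.
#' @param assay assay label recorded in the result.
#' @param conditions optional subset of `ligand_time` keys to test.
#' @param var_shrink optional shrinkage weight of per-feature variances toward
#'   the assay-wide median variance (0 = plain Welch, the default).
#' @return Long data.frame (`assay`, `feature`, `ligand`, `time`, `lfc`,
#'   `p`, `q`).
#' @export
test_features <- function(values, meta, value_scale = "log2", assay = "assay",
                          conditions = NULL, var_shrink = 0) {
  meta <- meta[match(colnames(values), meta$sample_id), ]
  ctrl <- which(meta$ligand == "CTRL" & meta$time == 0)
  if (length(ctrl) < 2) stop("need >= 2 CTRL_0 replicates")
  lv <- log_values(values, value_scale)
  keys <- condition_key(meta$ligand, meta$time)
  conds <- unique(keys[-ctrl])
  if (!is.null(conditions)) conds <- intersect(conds, conditions)
  lfc <- log2fc_vs_control(values, meta, value_scale)
  out <- list()
  for (cc in conds) {
    idx <- which(keys == cc)
    if (length(idx) < 2) stop("need >= 2 replicates per group (", cc, ")")
    wt <- welch_rows(lv[, idx, drop = FALSE], lv[, ctrl, drop = FALSE],
                     var_shrink = var_shrink)
    lt <- strsplit(cc, "_(?=[^_]+$)", perl = TRUE)[[1]]
    out[[cc]] <- data.frame(assay = assay, feature = rownames(values),
                            ligand = lt[1], time = as.numeric(lt[2]),
                            lfc = lfc[, cc], p = wt$p, q = bh_adjust(wt$p),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
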