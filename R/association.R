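# Module expression scores and module-phenotype linear association.

#' Module expression scores
#'
#' Unweighted mean of member-feature scaled values per condition.
#'
#' @param scaled a `scaled_matrix` or plain feature x condition matrix.
#' @param partition a `consensus_result` or a named label vector over the
#'   matrix rows.
#' @return Matrix module x condition.
#' @export
module_scores <- function(scaled, partition) {
  x <- if (inherits(scaled, "scaled_matrix")) scaled$values else scaled
  labels <- if (inherits(partition, "consensus_result")) partition$labels
            else partition
  if (length(labels) != nrow(x)) stop("partition does not cover matrix rows")
  cls <- sort(unique(labels))
  sizes <- table(factor(labels, levels = cls))
  if (any(sizes == 0)) stop("empty module")
  prof <- t(vapply(cls, function(cl)
    colMeans(x[labels == cl, , drop = FALSE]), numeric(ncol(x))))
  rownames(prof) <- paste0("M", cls)
  colnames(prof) <- colnames(x)
  prof
}

#' Linear association between module scores and phenotypes
#'
#' Ordinary least-squares fit of each phenotype on each module score across
#' conditions (ligand x time cells; replicate wells are averaged per
#' condition first), with the two-sided slope p-value and BH q-values over
#' the full module x phenotype grid.
#'
#' @param scores module x condition matrix from [module_scores()].
#' @param phenotypes data.frame with `ligand`, `time`, and phenotype columns
#'   (one row per well).
#' @param min_conditions minimum shared conditions per pair (pairs with fewer
#'   are skipped with a warning).
#' @param method `"pearson"` (linear fit; default) or `"spearman"` (rank
#'   correlation; p from the correlation test).
#' @return data.frame (`module`, `phenotype`, `slope`, `r`, `n`, `p`, `q`).
#' @export
associate_modules <- function(scores, phenotypes, min_conditions = 4,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  meta_cols <- intersect(c("ligand", "time", "replicate"), names(phenotypes))
  ph_cols <- setdiff(names(phenotypes), meta_cols)
  key <- condition_key(phenotypes$ligand, phenotypes$time)
  agg <- lapply(ph_cols, function(ph)
    tapply(phenotypes[[ph]], key, mean, na.rm = TRUE))
  names(agg) <- ph_cols
  out <- list()
  for (m in rownames(scores)) {
    for (ph in ph_cols) {
      shared <- intersect(colnames(scores), names(agg[[ph]]))
      shared <- shared[!is.na(agg[[ph]][shared])]
      if (length(shared) < min_conditions) {
        warning("skipping ", m, " x ", ph, ": only ", length(shared),
                " shared conditions")
        next
      }
      x <- scores[m, shared]
      y <- agg[[ph]][shared]
      if (method == "pearson") {
        fit <- lm(y ~ x)
        sm <- summary(fit)$coefficients
        slope <- sm["x", "Estimate"]
        p <- sm["x", "Pr(>|t|)"]
        r <- cor(x, y)
      } else {
        ct <- cor.test(x, y, method = "spearman", exact = FALSE)
        slope <- NA_real_
        r <- unname(ct$estimate)
        p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        module = m, phenotype = ph, slope = slope, r = r,
        n = length(shared), p = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res$q <- bh_adjust(res$p)
  rownames(res) <- NULL
  res
}
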