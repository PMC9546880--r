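# Attribution of dataset variance to experimental covariates: winsorize and
# median-center within replicate, correlation-scale PCA with the 0.7
# eigenvalue retention cutoff, PC-to-covariate assignment (permutation-null
# silhouette for categorical covariates, cross-validated lasso for continuous
# ones), and weighted-variance summation with Venn-region overlaps.

#' Winsorize and median-center a matrix for variance attribution
#'
#' Per feature: two-sided winsorization at the 0.5/99.5 percentiles (the
#' symmetric reading of "winsorization at 99%"), then subtraction of the
#' within-replicate median. Percentiles use the inverted-ECDF quantile
#' (type 1), so winsorization clips only observations whose rank falls in the
#' extreme 0.5% tails and is the exact identity on outlier-free samples of
#' fewer than 200 observations.
#'
#' @param values feature x sample matrix.
#' @param meta sample metadata with `sample_id` and `replicate`.
#' @param probs lower/upper winsorization probabilities.
#' @return The normalized matrix.
#' @export
vc_preprocess <- function(values, meta, probs = c(0.005, 0.995)) {
  meta <- meta[match(colnames(values), meta$sample_id), ]
  if (is.null(meta$replicate)) stop("replicate labels required")
  x <- t(apply(values, 1, function(r) {
    qq <- quantile(r, probs, na.rm = TRUE, type = 1)
    pmin(pmax(r, qq[1]), qq[2])
  }))
  reps <- unique(meta$replicate)
  if (any(table(meta$replicate) < 2))
    warning("some replicates contain a single sample; centering is degenerate")
  for (rp in reps) {
    idx <- which(meta$replicate == rp)
    x[, idx] <- x[, idx, drop = FALSE] -
      apply(x[, idx, drop = FALSE], 1, median)
  }
  dimnames(x) <- dimnames(values)
  x
}

#' Correlation-scale PCA with an eigenvalue retention cutoff
#'
#' Features are standardized (correlation-scale PCA, so the Kaiser-style
#' eigenvalue cutoff of 0.7 is interpretable); PCs with eigenvalue below the
#' cutoff are flagged discarded. Zero-variance features are dropped with a
#' message.
#'
#' @param values feature x sample matrix (>= 3 samples).
#' @param cutoff eigenvalue retention cutoff (retained iff eigenvalue >=
#'   cutoff).
#' @param scale. standardize features (set `FALSE` for covariance-scale PCA).
#' @return List with `pc_table` (pc, eigenvalue, weight, retained) and
#'   `scores` (samples x PCs).
#' @export
pca_retain <- function(values, cutoff = 0.7, scale. = TRUE) {
  if (ncol(values) < 3) stop("need >= 3 samples")
  v <- apply(values, 1, var)
  if (any(v <= 0)) {
    message("dropping ", sum(v <= 0), " zero-variance feature(s)")
    values <- values[v > 0, , drop = FALSE]
  }
  pr <- prcomp(t(values), center = TRUE, scale. = scale.)
  eig <- pr$sdev^2
  pc_table <- data.frame(pc = paste0("PC", seq_along(eig)),
                         eigenvalue = eig, weight = eig / sum(eig),
                         retained = eig >= cutoff,
                         stringsAsFactors = FALSE)
  list(pc_table = pc_table, scores = pr$x)
}

#' Assign principal components to a covariate
#'
#' Categorical covariates: a PC is assigned if the mean silhouette width of
#' the covariate grouping on that PC's 1-D scores exceeds the `1 - alpha`
#' quantile of its label-permutation null. When `strata` is supplied (the
#' interaction of the other design covariates), labels are permuted within
#' strata: in a blocked design the covariate is balanced within conditions,
#' and unrestricted permutations break that balance, deflating the null
#' silhouette and making the test anti-conservative on structured PCs.
#' Continuous covariates: PCs with nonzero coefficients in a lasso regression
#' of the covariate on the PC scores, with the penalty chosen by
#' cross-validation.
#'
#' @param scores samples x PCs score matrix (retained PCs).
#' @param covariate vector over samples.
#' @param kind `"categorical"` or `"continuous"`.
#' @param B permutations for the categorical null.
#' @param alpha significance level of the permutation rule.
#' @param seed integer seed for permutations / CV folds.
#' @param strata optional blocking vector; permutations shuffle labels within
#'   each stratum.
#' @param group_center if `TRUE`, scores are re-centered by the median of the
#'   observed (or permuted) groups before the silhouette is taken. Use for
#'   the covariate whose groups were median-centered during preprocessing:
#'   centering couples that covariate's labels to the data (observed groups
#'   are artificially tight, inflating the plain null), and it has already
#'   removed the covariate's location effects, so the calibrated statistic is
#'   location-blind by construction.
#' @return Character vector of assigned PC names (possibly empty).
#' @export
assign_pcs <- function(scores, covariate, kind = c("categorical", "continuous"),
                       B = 1000, alpha = 0.05, seed = 1L, strata = NULL,
                       group_center = FALSE) {
  kind <- match.arg(kind)
  if (length(unique(covariate)) < 2) {
    warning("constant covariate: nothing assigned")
    return(character(0))
  }
  pcs <- colnames(scores)
  if (kind == "categorical") {
    g <- as.integer(factor(covariate))
    set.seed(derive_seed(seed, "assign_pcs"))
    n <- length(g)
    strat_idx <- if (is.null(strata)) list(seq_len(n))
                 else split(seq_len(n), strata)
    perms <- vapply(seq_len(B), function(b) {
      gp <- g
      for (pos in strat_idx)
        if (length(pos) > 1) gp[pos] <- g[pos][sample.int(length(pos))]
      gp
    }, integer(n))
    assigned <- vapply(pcs, function(pc) {
      sp <- silhouette_perm_cpp(scores[, pc], g, perms, group_center)
      sp$observed > quantile(sp$null, 1 - alpha)
    }, logical(1))
    pcs[assigned]
  } else {
    y <- as.numeric(covariate)
    if (ncol(scores) < 2) {
      fit <- lm(y ~ scores[, 1])
      p <- summary(fit)$coefficients[2, 4]
      return(if (p < alpha) pcs else character(0))
    }
    set.seed(derive_seed(seed, "assign_pcs_lasso"))
    cv <- glmnet::cv.glmnet(scores, y, alpha = 1, nfolds = 5)
    beta <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
    pcs[beta != 0]
  }
}

#' Sum assigned PC weights into covariate variance fractions
#'
#' Each covariate's fraction is the sum of the variance weights of its
#' assigned retained PCs; overlaps (PCs assigned to several covariates)
#' become Venn regions; the unexplained fraction is one minus the total
#' weight of PCs assigned to at least one covariate. Venn regions plus
#' unexplained sum to 1 exactly.
#'
#' @param pc_table from [pca_retain()].
#' @param assignments named list: covariate -> character vector of PC names.
#' @return List with `fractions`, `venn` (region label -> weight), and
#'   `unexplained`.
#' @export
attribute_variance <- function(pc_table, assignments) {
  w <- setNames(pc_table$weight, pc_table$pc)
  retained <- pc_table$pc[pc_table$retained]
  assignments <- lapply(assignments, intersect, retained)
  fractions <- vapply(assignments, function(a) sum(w[a]), numeric(1))
  regions <- list()
  for (pc in retained) {
    who <- names(assignments)[vapply(assignments, function(a) pc %in% a,
                                     logical(1))]
    if (!length(who)) next
    key <- paste(sort(who), collapse = "&")
    regions[[key]] <- (if (is.null(regions[[key]])) 0 else regions[[key]]) + w[[pc]]
  }
  venn <- unlist(regions)
  explained <- if (length(venn)) sum(venn) else 0
  list(fractions = fractions, venn = venn, unexplained = 1 - explained)
}

#' Full variance-attribution pipeline for one matrix
#'
#' Runs [vc_preprocess()], [pca_retain()], [assign_pcs()] per covariate, and
#' [attribute_variance()].
#'
#' @param values feature x sample matrix.
#' @param meta sample metadata.
#' @param covariates named character vector: covariate name -> kind
#'   (`"categorical"` or `"continuous"`).
#' @param cutoff eigenvalue retention cutoff.
#' @param B,alpha,seed passed to [assign_pcs()].
#' @param centered_covariate name of the covariate whose groups were
#'   median-centered in preprocessing (its test uses the group-centered
#'   statistic; see [assign_pcs()]).
#' @return List with `attribution`, `pc_table`, `assignments`.
#' @export
variance_attribution <- function(values, meta,
                                 covariates = c(ligand = "categorical",
                                                time = "categorical",
                                                replicate = "categorical"),
                                 cutoff = 0.7, B = 1000, alpha = 0.05,
                                 seed = 1L, centered_covariate = "replicate") {
  meta <- meta[match(colnames(values), meta$sample_id), ]
  x <- vc_preprocess(values, meta)
  pca <- pca_retain(x, cutoff = cutoff)
  keep <- pca$pc_table$pc[pca$pc_table$retained]
  scores <- pca$scores[, keep, drop = FALSE]
  assignments <- lapply(names(covariates), function(cv) {
    others <- setdiff(names(covariates), cv)
    strata <- if (length(others))
      interaction(meta[others], drop = TRUE) else NULL
    assign_pcs(scores, meta[[cv]], kind = covariates[[cv]], B = B,
               alpha = alpha, seed = derive_seed(seed, paste0("cov_", cv)),
               strata = strata,
               group_center = identical(cv, centered_covariate))
  })
  names(assignments) <- names(covariates)
  list(attribution = attribute_variance(pca$pc_table, assignments),
       pc_table = pca$pc_table, assignments = assignments)
}
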