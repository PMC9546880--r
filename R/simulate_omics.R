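# Synthetic multi-assay generator with planted ground truth. Two mutually
# exclusive worlds are supported:
#   * module world  - features grouped into co-regulated modules that share a
#     ligand x time effect profile (the input the consensus-clustering stage
#     is designed to recover);
#   * covariate world - matrices built from low-rank ligand/time/replicate
#     variance components scaled to planted variance fractions (the input the
#     PCA variance-attribution stage is designed to recover).
# Combining both in one matrix is over-constrained (module effects *are*
# ligand/time variance), so `covariate_fractions` requires null profiles.

ASSAY_DEFAULT_FEATURES <- c(RNAseq = 2000L, RPPA = 300L, CyCIF = 120L,
                            GCP = 60L, ATAC = 100L)

#' Construct a module specification for the synthetic generator
#'
#' @param n_modules number of planted co-regulated modules.
#' @param features_per_assay_per_module named integer vector: module features
#'   emitted per assay per module.
#' @param background_features named integer vector of unperturbed features per
#'   assay. Defaults fill each assay to a 10x-shrunk version of the real
#'   assays' feature counts (RNAseq 2000, RPPA 300, CyCIF 120, GCP 60,
#'   ATAC 100).
#' @param noise_sd named positive numeric: per-assay replicate noise, in log2
#'   units for intensity assays and z units for motif scores. RNAseq noise
#'   comes from the negative-binomial sampling instead.
#' @param effect_size magnitude of the planted module shifts (log2/z units) at
#'   the late time points.
#' @param effect_profiles optional matrix `n_modules x conditions` (columns
#'   named `ligand_time`) of mean shifts; `NULL` draws structured default
#'   profiles, `"null"` plants all-zero effects.
#' @param covariate_fractions optional named vector with elements `ligand`,
#'   `time`, `replicate` in `[0,1]` summing to <= 1; switches the generator to
#'   the covariate world (requires null effect profiles).
#' @param nb_dispersion negative-binomial dispersion for RNAseq counts.
#' @param libsize_sdlog log-normal sd of RNAseq library-size factors.
#' @return A `module_spec` list.
#' @export
module_spec <- function(n_modules = 6,
                        features_per_assay_per_module =
                          c(RNAseq = 60L, RPPA = 9L, CyCIF = 4L, GCP = 2L, ATAC = 3L),
                        background_features = NULL,
                        noise_sd = c(RNAseq = 0.2, RPPA = 1, CyCIF = 1, GCP = 1, ATAC = 1),
                        effect_size = 2,
                        effect_profiles = NULL,
                        covariate_fractions = NULL,
                        nb_dispersion = 0.1,
                        libsize_sdlog = 0.1) {
  # accept named lists (e.g. deserialized JSON configs) for the vector fields
  fpm <- unlist(features_per_assay_per_module)
  background_features <- if (!is.null(background_features))
    unlist(background_features)
  noise_sd <- unlist(noise_sd)
  covariate_fractions <- if (!is.null(covariate_fractions))
    unlist(covariate_fractions)
  if (is.null(names(fpm))) stop("`features_per_assay_per_module` must be named by assay")
  if (any(fpm < 0) || n_modules < 0) stop("all counts must be >= 0")
  if (is.null(background_features)) {
    background_features <- pmax(0L, ASSAY_DEFAULT_FEATURES[names(fpm)] -
                                  as.integer(n_modules * fpm))
    names(background_features) <- names(fpm)
  }
  if (any(background_features < 0)) stop("all counts must be >= 0")
  if (any(noise_sd[names(fpm)] <= 0) || anyNA(noise_sd[names(fpm)]))
    stop("`noise_sd` must be positive for every assay")
  if (!is.null(covariate_fractions)) {
    cf <- covariate_fractions[c("ligand", "time", "replicate")]
    if (anyNA(cf) || any(cf < 0) || any(cf > 1))
      stop("covariate fractions must each lie in [0, 1]")
    if (sum(cf) > 1) stop("infeasible covariate fractions: sum > 1")
    if (!(is.null(effect_profiles) && effect_size == 0) &&
        !identical(effect_profiles, "null"))
      stop("covariate_fractions requires null effect profiles ",
           "(set effect_profiles = \"null\" or effect_size = 0)")
    covariate_fractions <- cf
  }
  structure(list(n_modules = as.integer(n_modules),
                 features_per_assay_per_module = fpm,
                 background_features = background_features,
                 noise_sd = noise_sd, effect_size = effect_size,
                 effect_profiles = effect_profiles,
                 covariate_fractions = covariate_fractions,
                 nb_dispersion = nb_dispersion,
                 libsize_sdlog = libsize_sdlog),
            class = "module_spec")
}

# Smooth saturating time ramp: 0 at t = 0, ~1 from 24H onward.
effect_ramp <- function(time) pmin(1, time / 24)^0.7

# all-zero profile matrix (handles n_modules = 0, where matrix() with
# dimnames errors)
zero_profiles <- function(n_modules, keys) {
  prof <- matrix(0, max(n_modules, 1), length(keys))
  prof <- prof[seq_len(n_modules), , drop = FALSE]
  rn <- if (n_modules > 0) paste0("M", seq_len(n_modules))
  dimnames(prof) <- list(rn, keys)
  prof
}

#' Default module effect profiles
#'
#' Each module is driven by a distinct subset of 2-3 ligands with random
#' signs; shifts follow a saturating time ramp reaching `effect_size` at 24H.
#'
#' @param spec a [design_spec()].
#' @param n_modules number of modules.
#' @param effect_size late-time shift magnitude.
#' @param seed integer seed.
#' @return Matrix `n_modules x conditions`, columns named `ligand_time`.
#' @export
default_effect_profiles <- function(spec, n_modules, effect_size, seed) {
  set.seed(derive_seed(seed, "profiles"))
  post <- spec$times[spec$times > 0]
  keys <- as.vector(outer(spec$ligands, post, condition_key))
  prof <- zero_profiles(n_modules, keys)
  seen <- character(0)
  for (m in seq_len(n_modules)) {
    repeat {
      nd <- sample(2:3, 1)
      drivers <- sort(sample(spec$ligands, nd))
      signs <- sample(c(-1, 1), nd, replace = TRUE)
      sig <- paste(drivers, signs, collapse = ";")
      if (!sig %in% seen) break
    }
    seen <- c(seen, sig)
    for (i in seq_along(drivers)) {
      shift <- signs[i] * effect_size * effect_ramp(post)
      prof[m, condition_key(drivers[i], post)] <- shift
    }
  }
  prof
}

# internal: per-assay feature bookkeeping
make_features <- function(assay, mspec) {
  n_mod <- mspec$n_modules * mspec$features_per_assay_per_module[[assay]]
  n_bg <- mspec$background_features[[assay]]
  module <- c(rep(seq_len(mspec$n_modules),
                  each = mspec$features_per_assay_per_module[[assay]]),
              rep(NA_integer_, n_bg))
  data.frame(feature_id = sprintf("%s_f%04d", assay, seq_len(n_mod + n_bg)),
             assay = assay, module = module, stringsAsFactors = FALSE)
}

#' Generate a multi-assay perturbation dataset with planted ground truth
#'
#' Emits one feature x sample matrix per assay: RNAseq as negative-binomial
#' counts whose log2 means follow the planted profiles, RPPA/CyCIF/GCP as
#' Gaussian log2 intensities, ATAC motif-family scores as Gaussian z-scores,
#' and an L1000-like z-score view of the first RNAseq transcripts. Module
#' features share their module's ligand x time effect profile plus independent
#' replicate noise.
#'
#' @param design sample-metadata table from [generate_design()].
#' @param mspec a [module_spec()].
#' @param seed integer seed; output is a pure function of (design, mspec, seed).
#' @param l1000_features number of RNAseq transcripts mirrored in the
#'   L1000-like assay (0 disables it).
#' @return List with `assays` (named list; each has `values`, `features`,
#'   `scale`) and `truth` (feature -> module map, per-condition true log2
#'   fold changes, planted/realized covariate fractions).
#' @export
generate_multiomic <- function(design, mspec, seed = 1L, l1000_features = 200L) {
  stopifnot(inherits(mspec, "module_spec"))
  if (!any(design$ligand == "CTRL" & design$time == 0))
    stop("design must contain CTRL samples at time 0")
  if (!is.null(mspec$covariate_fractions))
    return(generate_multiomic_covariate(design, mspec, seed))

  spec_like <- list(ligands = setdiff(unique(design$ligand), "CTRL"),
                    times = sort(unique(design$time)))
  post <- spec_like$times[spec_like$times > 0]
  keys <- as.vector(outer(spec_like$ligands, post, condition_key))
  prof <- mspec$effect_profiles
  if (identical(prof, "null")) {
    prof <- zero_profiles(mspec$n_modules, keys)
  } else if (is.null(prof)) {
    prof <- default_effect_profiles(spec_like, mspec$n_modules,
                                    mspec$effect_size, seed)
  }
  if (!setequal(colnames(prof), keys))
    stop("effect profile conditions do not match the design")
  prof <- prof[, keys, drop = FALSE]

  sample_key <- condition_key(design$ligand, design$time)
  is_ctrl <- design$ligand == "CTRL"
  assays <- list()
  truth_map <- list()
  truth_lfc <- list()
  for (assay in names(mspec$features_per_assay_per_module)) {
    set.seed(derive_seed(seed, paste0("assay_", assay)))
    feats <- make_features(assay, mspec)
    p <- nrow(feats)
    n <- nrow(design)
    lfc <- matrix(0, p, length(keys), dimnames = list(feats$feature_id, keys))
    mod_rows <- which(!is.na(feats$module))
    if (length(mod_rows) && mspec$n_modules > 0)
      lfc[mod_rows, ] <- prof[feats$module[mod_rows], , drop = FALSE]
    shift <- matrix(0, p, n)
    treated <- which(!is_ctrl)
    if (length(treated))
      shift[, treated] <- lfc[, sample_key[treated], drop = FALSE]
    if (assay == "RNAseq") {
      mu0 <- runif(p, 3, 10)
      libf <- rlnorm(n, 0, mspec$libsize_sdlog)
      mu <- 2^(mu0 + shift) * rep(libf, each = p)
      vals <- matrix(rnbinom(p * n, mu = mu, size = 1 / mspec$nb_dispersion),
                     p, n)
      scale_lab <- "counts"
    } else {
      base <- if (assay == "ATAC") rep(0, p) else rnorm(p, 8, 1)
      vals <- base + shift +
        matrix(rnorm(p * n, 0, mspec$noise_sd[[assay]]), p, n)
      scale_lab <- if (assay == "ATAC") "zscore" else "log2"
    }
    dimnames(vals) <- list(feats$feature_id, design$sample_id)
    gene_symbol <- if (assay == "RNAseq") {
      sprintf("G%05d", seq_len(p))
    } else if (!"RNAseq" %in% names(mspec$features_per_assay_per_module)) {
      rep(NA_character_, p)
    } else {
      # cognates: module features map to the same-ranked RNAseq module
      # feature's symbol, backgrounds to RNAseq background symbols
      rna <- make_features("RNAseq", mspec)
      sym <- rep(NA_character_, p)
      for (m in seq_len(mspec$n_modules)) {
        mine <- which(feats$module %in% m)
        theirs <- which(rna$module %in% m)
        if (length(mine))
          sym[mine] <- sprintf("G%05d", theirs[seq_along(mine)])
      }
      bg_mine <- which(is.na(feats$module))
      bg_theirs <- which(is.na(rna$module))
      if (length(bg_mine))
        sym[bg_mine] <- sprintf("G%05d", bg_theirs[seq_along(bg_mine)])
      sym
    }
    feats$gene_symbol <- gene_symbol
    assays[[assay]] <- list(values = vals, features = feats, scale = scale_lab)
    truth_map[[assay]] <- feats[, c("feature_id", "assay", "module")]
    truth_lfc[[assay]] <- lfc
  }

  if (l1000_features > 0 && "RNAseq" %in% names(assays)) {
    set.seed(derive_seed(seed, "assay_L1000"))
    rna <- assays$RNAseq
    idx <- seq_len(min(l1000_features, nrow(rna$values)))
    p <- length(idx)
    n <- nrow(design)
    shift <- matrix(0, p, n)
    treated <- which(!is_ctrl)
    if (length(treated))
      shift[, treated] <- truth_lfc$RNAseq[idx, sample_key[treated], drop = FALSE]
    vals <- shift + matrix(rnorm(p * n, 0, 0.5), p, n)
    feats <- data.frame(feature_id = sprintf("L1000_f%04d", idx),
                        assay = "L1000",
                        module = rna$features$module[idx],
                        gene_symbol = rna$features$gene_symbol[idx],
                        stringsAsFactors = FALSE)
    dimnames(vals) <- list(feats$feature_id, design$sample_id)
    assays$L1000 <- list(values = vals, features = feats, scale = "zscore")
  }

  truth <- list(feature_modules = do.call(rbind, truth_map),
                lfc = truth_lfc, profiles = prof,
                covariate_fractions = NULL, realized_fractions = NULL)
  list(assays = assays, truth = truth)
}

# internal: one-way between-group variance share (unbiased epsilon-squared:
# (SSB - (G-1) MSW) / SST), averaged over features
oneway_share <- function(values, groups) {
  n <- ncol(values)
  gs <- unique(groups)
  gm <- rowMeans(values)
  tot <- apply(values, 1, function(r) sum((r - mean(r))^2))
  ssb <- rep(0, nrow(values))
  for (g in gs) {
    idx <- which(groups == g)
    ssb <- ssb + length(idx) * (rowMeans(values[, idx, drop = FALSE]) - gm)^2
  }
  msw <- (tot - ssb) / (n - length(gs))
  mean((ssb - (length(gs) - 1) * msw) / tot)
}

#' Generate a matrix with planted covariate variance fractions
#'
#' Builds each feature as a sum of centered low-rank ligand, time, and
#' replicate components plus Gaussian noise, with each component rescaled so
#' its realized sample variance equals the planted fraction of the feature's
#' unit total variance. Low-rank effects (a few shared response axes rather
#' than independent per-level shifts) keep the planted variance in a small
#' number of large-eigenvalue principal components, which is both how real
#' perturbation responses behave and what makes the planted fractions
#' identifiable by a PCA subspace method. The feature-loading vectors of all
#' components are orthogonalized (QR), so each principal axis carries exactly
#' one covariate's signal; without this, trace cross-contamination of the
#' large PCs is reliably detected by the permutation test and every covariate
#' would be credited with the big PCs' full weight.
#'
#' @param design sample-metadata table.
#' @param n_features number of features.
#' @param fractions named vector (`ligand`, `time`, `replicate`) in `[0,1]`,
#'   summing to <= 1.
#' @param component_shares named list: per covariate, the share of its planted
#'   fraction carried by each response axis. The default shares keep the
#'   planted eigenvalues well separated; near-degenerate eigenvalues across
#'   covariates make sample eigenvectors mix, and a whole-PC attribution
#'   method then credits the mixed PCs to several covariates at once.
#' @param seed integer seed.
#' @return List with `values` (features x samples), `fractions` (planted) and
#'   `realized` (one-way between-group variance shares, unbiased
#'   epsilon-squared).
#' @export
generate_covariate_matrix <- function(design, n_features = 100,
                                      fractions = c(ligand = 0.40, time = 0.15,
                                                    replicate = 0.02),
                                      component_shares =
                                        list(ligand = c(0.75, 0.25), time = 1,
                                             replicate = 1),
                                      seed = 1L) {
  fr <- fractions[c("ligand", "time", "replicate")]
  if (anyNA(fr) || any(fr < 0) || sum(fr) > 1)
    stop("infeasible covariate fractions")
  set.seed(derive_seed(seed, "covariate_matrix"))
  n <- nrow(design)
  p <- n_features
  covs <- list(ligand = design$ligand, time = design$time,
               replicate = design$replicate)
  scale_rows <- function(m, target_sd) {
    m <- m - rowMeans(m)
    s <- sqrt(pmax(apply(m, 1, var), 1e-12))
    m / s * target_sd
  }
  total_comp <- sum(lengths(component_shares[names(fr)[fr > 0]]))
  loadings <- qr.Q(qr(matrix(rnorm(p * total_comp), p))) * sqrt(p)
  li <- 0L
  x <- matrix(0, p, n)
  for (cv in names(fr)) {
    if (fr[[cv]] <= 0) next
    levs <- unique(covs[[cv]])
    shares <- component_shares[[cv]] / sum(component_shares[[cv]])
    comp <- matrix(0, p, n)
    for (q in seq_along(shares)) {
      li <- li + 1L
      sc <- rnorm(length(levs))
      comp <- comp +
        scale_rows(loadings[, li] %o% sc[match(covs[[cv]], levs)],
                   sqrt(fr[[cv]] * shares[q]))
    }
    x <- x + scale_rows(comp, sqrt(fr[[cv]]))
  }
  noise <- scale_rows(matrix(rnorm(p * n), p, n), sqrt(1 - sum(fr)))
  x <- x + noise
  dimnames(x) <- list(sprintf("f%04d", seq_len(p)), design$sample_id)
  realized <- vapply(names(fr), function(cv) oneway_share(x, covs[[cv]]),
                     numeric(1))
  off <- abs(realized - fr)
  if (any(off > 0.05))
    warning("realized covariate fractions deviate from the plan by > 0.05: ",
            paste(sprintf("%s %.3f vs %.3f", names(fr), realized, fr),
                  collapse = ", "))
  list(values = x, fractions = fr, realized = realized)
}

# internal: covariate-world multiomic output (one matrix per Gaussian assay)
generate_multiomic_covariate <- function(design, mspec, seed) {
  assays <- list()
  for (assay in names(mspec$features_per_assay_per_module)) {
    if (assay == "RNAseq") next  # fractions are planted on the z/log scale
    p <- mspec$n_modules * mspec$features_per_assay_per_module[[assay]] +
      mspec$background_features[[assay]]
    gm <- generate_covariate_matrix(design, n_features = p,
                                    fractions = mspec$covariate_fractions,
                                    seed = derive_seed(seed, paste0("cov_", assay)))
    feats <- data.frame(feature_id = rownames(gm$values), assay = assay,
                        module = NA_integer_, gene_symbol = NA_character_,
                        stringsAsFactors = FALSE)
    assays[[assay]] <- list(values = gm$values, features = feats,
                            scale = "log2", realized = gm$realized)
  }
  truth <- list(feature_modules = NULL, lfc = NULL, profiles = NULL,
                covariate_fractions = mspec$covariate_fractions,
                realized_fractions = lapply(assays, `[[`, "realized"))
  list(assays = assays, truth = truth)
}
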