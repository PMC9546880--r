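test_that("winsorization and replicate centering behave at their anchors", {
  meta <- make_meta2(3)
  set.seed(41)
  # no outliers at modest n: winsorization is the exact identity, so the
  # result is plain within-replicate median centering
  x <- matrix(c(1, 2, 4, 8, 16, 32), 1, dimnames = list("f1", meta$sample_id))
  w <- vc_preprocess(x, meta)
  manual <- x
  for (rp in 1:3) {
    idx <- which(meta$replicate == rp)
    manual[, idx] <- manual[, idx] - median(manual[, idx])
  }
  expect_equal(w, manual)
  # replicate-constant offsets are removed exactly by median centering
  x2 <- matrix(rnorm(5 * 6), 5, dimnames = list(paste0("f", 1:5),
                                                meta$sample_id))
  off <- setNames(c(10, -5, 3), 1:3)
  x2o <- x2 + matrix(off[as.character(meta$replicate)], 5, 6, byrow = TRUE)
  expect_equal(vc_preprocess(x2o, meta), vc_preprocess(x2, meta))
  # one extreme value among 200 is clipped to the upper percentile
  set.seed(40)
  x3 <- matrix(c(rnorm(199), 1e6), 1,
               dimnames = list("f1", paste0("s", 1:200)))
  meta3 <- data.frame(sample_id = paste0("s", 1:200),
                      replicate = rep(1:2, each = 100))
  w3 <- vc_preprocess(x3, meta3)
  expect_lt(max(w3), 100)
  expect_warning(vc_preprocess(x, data.frame(sample_id = meta$sample_id,
                                             replicate = seq_len(6))),
                 "single sample")
})

test_that("PC retention uses the inclusive 0.7 eigenvalue boundary", {
  pt <- data.frame(pc = c("PC1", "PC2", "PC3"),
                   eigenvalue = c(2, 0.70, 0.69),
                   weight = c(2, 0.7, 0.69) / 3.39,
                   retained = c(2, 0.70, 0.69) >= 0.7)
  expect_true(pt$retained[2])
  expect_false(pt$retained[3])
  # rank-1 signal + tiny noise: PC1 weight ~ the signal's variance share
  set.seed(42)
  n <- 40; p <- 30
  u <- rnorm(p); v <- rnorm(n)
  x <- u %o% v + matrix(rnorm(p * n, 0, 0.05), p)
  rownames(x) <- paste0("f", 1:p); colnames(x) <- paste0("s", 1:n)
  pca <- pca_retain(x)
  expect_gt(pca$pc_table$weight[1], 0.95)
  expect_true(all(abs(sum(pca$pc_table$weight) - 1) < 1e-9))
  expect_error(pca_retain(x[, 1:2]), ">= 3 samples")
})

test_that("PC assignment flags separated groups and calibrates on noise", {
  set.seed(43)
  n <- 60
  g <- rep(c("A", "B", "C"), each = n / 3)
  scores <- cbind(PC1 = rnorm(n, c(A = -5, B = 0, C = 5)[g], 0.5),
                  PC2 = rnorm(n))
  a <- assign_pcs(scores, g, "categorical", B = 300, seed = 1)
  expect_true("PC1" %in% a)
  expect_false("PC2" %in% a)
  # pure-noise PCs are assigned at ~ the nominal 5% rate
  fp <- 0
  for (s in 1:15) {
    sc0 <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("PC", 1:10)))
    fp <- fp + length(assign_pcs(sc0, g, "categorical", B = 200, seed = s))
  }
  expect_lt(abs(fp / 150 - 0.05), 0.045)
  expect_warning(a0 <- assign_pcs(scores, rep("A", n), "categorical"),
                 "constant covariate")
  expect_length(a0, 0)
})

test_that("lasso assignment finds an exact linear dependence", {
  set.seed(44)
  n <- 80
  scores <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("PC", 1:6)))
  y <- 2 * scores[, 3]
  a <- assign_pcs(scores, y, "continuous", seed = 2)
  expect_true("PC3" %in% a)
  expect_lte(length(a), 2)
})

test_that("attribution sums weights and conserves total variance", {
  pt <- data.frame(pc = paste0("PC", 1:4),
                   eigenvalue = c(4, 2, 1, 0.5),
                   weight = c(4, 2, 1, 0.5) / 7.5,
                   retained = c(TRUE, TRUE, TRUE, FALSE))
  # no PC assigned -> unexplained = 1
  at0 <- attribute_variance(pt, list(ligand = character(0),
                                     time = character(0)))
  expect_equal(at0$unexplained, 1)
  # one PC (weight 0.4) assigned to both ligand and time -> overlap = 0.4
  pt2 <- pt; pt2$weight <- c(0.4, 0.3, 0.2, 0.1)
  at <- attribute_variance(pt2, list(ligand = c("PC1", "PC2"),
                                     time = "PC1"))
  expect_equal(unname(at$fractions["ligand"]), 0.7)
  expect_equal(unname(at$fractions["time"]), 0.4)
  expect_equal(unname(at$venn[["ligand&time"]]), 0.4)
  expect_equal(sum(at$venn) + at$unexplained, 1, tolerance = 1e-12)
  # unretained PCs never count even if assigned
  at2 <- attribute_variance(pt2, list(ligand = "PC4"))
  expect_equal(unname(at2$fractions["ligand"]), 0)
})

test_that("attributed ligand fraction is monotone in planted separation", {
  d <- generate_design(design_spec(ligands = c("EGF", "OSM", "HGF"),
                                   times = c(0, 24, 48), replicates = 3))
  dt <- d[d$time > 0, ]
  lo <- hi <- numeric(3)
  for (s in 1:3) {
    # the small 18-sample world makes the generator's internal epsilon^2
    # check noisy; its warning is expected here
    g1 <- suppressWarnings(
      generate_covariate_matrix(dt, n_features = 60,
                                fractions = c(ligand = 0.2, time = 0.1,
                                              replicate = 0.02), seed = s))
    g2 <- suppressWarnings(
      generate_covariate_matrix(dt, n_features = 60,
                                fractions = c(ligand = 0.4, time = 0.1,
                                              replicate = 0.02), seed = s))
    lo[s] <- variance_attribution(g1$values, dt, B = 300,
                                  seed = s)$attribution$fractions["ligand"]
    hi[s] <- variance_attribution(g2$values, dt, B = 300,
                                  seed = s)$attribution$fractions["ligand"]
  }
  expect_true(all(hi >= lo))
})
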