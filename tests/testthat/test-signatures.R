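mk_diff <- function(feature, ligand, time, lfc, p = 1e-6, q = p) {
  data.frame(assay = "A", feature = feature, ligand = ligand, time = time,
             lfc = lfc, p = p, q = q, stringsAsFactors = FALSE)
}

test_that("signature thresholds use the stated inclusive boundaries", {
  d <- rbind(mk_diff("f1", "OSM", 24, 1.6, q = 0.005),   # kept
             mk_diff("f2", "OSM", 24, 1.6, q = 0.02),    # dropped (q)
             mk_diff("f3", "OSM", 48, -1.5, q = 0),      # kept (>= inclusive)
             mk_diff("f4", "OSM", 24, 1.49, q = 0.001),  # dropped (lfc)
             mk_diff("f5", "OSM", 8, 5, q = 0))          # dropped (time)
  sig <- select_signatures(d)
  expect_setequal(sig$OSM, c("f1", "f3"))
})

test_that("signature selection is monotone in its thresholds", {
  set.seed(21)
  d <- mk_diff(paste0("f", 1:300), sample(c("OSM", "EGF"), 300, TRUE),
               sample(c(24, 48), 300, TRUE), rnorm(300, 0, 2),
               q = runif(300, 0, 0.05))
  base <- select_signatures(d, q_max = 0.01, lfc_min = 1.5)
  relaxed <- select_signatures(d, q_max = 0.02, lfc_min = 1.0)
  for (lg in names(base))
    expect_true(all(base[[lg]] %in% relaxed[[lg]]))
})

test_that("set analysis labels unique and shared features as defined", {
  d <- rbind(mk_diff("f1", "OSM", 24, 3),                 # OSM only
             mk_diff("f2", "OSM", 24, 3),
             mk_diff("f2", "EGF", 48, -2),                # OSM and EGF
             mk_diff("f3", "EGF", 24, 0.2))               # significant nowhere
  sa <- set_analysis(select_signatures(d))
  expect_equal(sa$labels$label[sa$labels$feature == "f1"], "Unique")
  expect_equal(sa$labels$label[sa$labels$feature == "f2"], "Shared")
  expect_false("f3" %in% sa$labels$feature)
  cnt <- sa$counts
  expect_equal(cnt$unique[cnt$ligand == "OSM"], 1)
  expect_equal(cnt$total[cnt$ligand == "OSM"], 2)
  expect_error(set_analysis(select_signatures(mk_diff("f1", "OSM", 24, 3))),
               ">= 2 ligands")
})

test_that("module-feature selection applies the per-assay rules", {
  set.seed(22)
  conds <- c("OSM_24", "OSM_48")
  lfc_gcp <- matrix(c(3, 3, 0.1, 0.12, 2, 2.2, 1.8, 2.0), 4, byrow = TRUE,
                    dimnames = list(paste0("g", 1:4), conds))
  # g1 has high lfc but is in the lowest variance quartile -> removed
  lfc_gcp["g1", ] <- c(3, 3.000001)
  dg <- rbind(mk_diff(paste0("g", 1:4), "OSM", 24, lfc_gcp[, 1], p = 0.01),
              mk_diff(paste0("g", 1:4), "OSM", 48, lfc_gcp[, 2], p = 0.01))
  da <- mk_diff(paste0("a", 1:3), "OSM", 24, c(0, 0.1, -0.2), p = 0.9)
  dr <- rbind(mk_diff("r1", "OSM", 24, 1.0, p = 0.01),   # RPPA: 0.75 rule
              mk_diff("r2", "OSM", 24, 0.5, p = 0.01),
              mk_diff("r3", "OSM", 24, 2.0, p = 0.2),    # p too large
              mk_diff("r4", "OSM", 24, 2.0, p = 0.01))
  # r2 carries the lowest variance so the quartile rule removes it, not r1
  lfc_rppa <- matrix(c(1.0, 3.0, 0.5, 0.51, 2.0, -1.0, 2.0, 4.0), 4,
                    byrow = TRUE, dimnames = list(paste0("r", 1:4), conds))
  sel <- select_module_features(list(GCP = dg, ATAC = da, RPPA = dr),
                                lfc_matrices = list(GCP = lfc_gcp,
                                                    RPPA = lfc_rppa))
  expect_setequal(sel$feature[sel$assay == "ATAC"], paste0("a", 1:3))
  expect_false("g1" %in% sel$feature)        # quartile rule precedes lfc rule
  expect_true("r1" %in% sel$feature)         # |lfc| 1.0 > 0.75 at p < 0.05
  expect_false("r2" %in% sel$feature)        # lowest variance quartile
  expect_false("r3" %in% sel$feature)        # p too large
  expect_error(select_module_features(list(FOO = da)), "unknown assay")
})
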