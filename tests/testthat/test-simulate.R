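small_mspec <- function(...) {
  module_spec(n_modules = 2,
              features_per_assay_per_module = c(RPPA = 5L, ATAC = 3L),
              background_features = c(RPPA = 10L, ATAC = 4L),
              noise_sd = c(RPPA = 1, ATAC = 1), ...)
}

test_that("null effect profiles plant zero log2FC everywhere", {
  d <- generate_design(design_spec(replicates = 2))
  sim <- generate_multiomic(d, small_mspec(effect_profiles = "null"), seed = 1,
                            l1000_features = 0)
  for (a in names(sim$truth$lfc))
    expect_true(all(sim$truth$lfc[[a]] == 0))
})

test_that("a planted single-ligand shift is recovered at its stated scale", {
  # one module, +2 z for OSM only at 24/48H: mean OSM z-score of module
  # features ~ 2 within 3 SE of the generator's own noise model
  d <- generate_design(design_spec(replicates = 3))
  keys <- colnames(default_effect_profiles(
    list(ligands = setdiff(unique(d$ligand), "CTRL"),
         times = sort(unique(d$time))), 1, 2, 1))
  prof <- matrix(0, 1, length(keys), dimnames = list("M1", keys))
  prof[1, c("OSM_24", "OSM_48")] <- 2
  ms <- module_spec(n_modules = 1,
                    features_per_assay_per_module = c(ATAC = 40L),
                    background_features = c(ATAC = 0L),
                    noise_sd = c(ATAC = 1), effect_profiles = prof)
  sim <- generate_multiomic(d, ms, seed = 3, l1000_features = 0)
  v <- sim$assays$ATAC$values
  osm <- d$sample_id[d$ligand == "OSM" & d$time %in% c(24, 48)]
  m <- mean(v[, osm])
  se <- 1 / sqrt(length(osm) * nrow(v))
  expect_lt(abs(m - 2), 3 * se + 0.05)
  # CTRL carries no shift: its grand mean is noise of sd 1/sqrt(40 * 3)
  expect_lt(abs(mean(v[, d$ligand == "CTRL"])), 4 / sqrt(40 * 3))
})

test_that("generators are bit-identical under a fixed seed", {
  d <- generate_design(design_spec(replicates = 2))
  s1 <- generate_multiomic(d, small_mspec(), seed = 9)
  s2 <- generate_multiomic(d, small_mspec(), seed = 9)
  expect_identical(s1, s2)
  expect_identical(generate_cells("thomas", 50, seed = 4),
                   generate_cells("thomas", 50, seed = 4))
  expect_identical(generate_tracks(5, seed = 4), generate_tracks(5, seed = 4))
})

test_that("planted-truth bookkeeping matches emitted features", {
  d <- generate_design(design_spec(replicates = 2))
  ms <- small_mspec()
  sim <- generate_multiomic(d, ms, seed = 2, l1000_features = 0)
  fm <- sim$truth$feature_modules
  expect_equal(sum(!is.na(fm$module)),
               ms$n_modules * sum(ms$features_per_assay_per_module))
  for (a in names(sim$assays))
    expect_setequal(fm$feature_id[fm$assay == a],
                    rownames(sim$assays[[a]]$values))
})

test_that("module_spec rejects invalid configurations", {
  expect_error(module_spec(noise_sd = c(RNAseq = 0, RPPA = 1, CyCIF = 1,
                                        GCP = 1, ATAC = 1)), "positive")
  expect_error(module_spec(covariate_fractions =
                             c(ligand = 0.7, time = 0.4, replicate = 0)),
               "sum > 1")
  expect_error(module_spec(covariate_fractions =
                             c(ligand = 0.4, time = 0.1, replicate = 0)),
               "null effect profiles")
  # feasible fractions with null profiles are accepted
  ms <- module_spec(effect_profiles = "null",
                    covariate_fractions = c(ligand = 0.4, time = 0.15,
                                            replicate = 0.02))
  expect_s3_class(ms, "module_spec")
})

test_that("cell patterns realize their stated geometry", {
  # grid: pairwise minimum distance equals the lattice spacing
  g <- generate_cells("grid", 100, field = c(1000, 1000), seed = 1)
  dmin <- min(dist(cbind(g$x, g$y)))
  expect_equal(dmin, 100)
  # thomas with sigma -> 0: offspring coincide with parents
  th <- generate_cells("thomas", 200, params = list(n_parents = 8, sigma = 0),
                       seed = 2)
  expect_lte(length(unique(paste(th$x, th$y))), 8)
  # csr: empirical intensity is exact (n points placed in the field)
  cs <- generate_cells("csr", 5000, field = c(2000, 2000), seed = 3)
  expect_equal(nrow(cs) / (2000 * 2000), 5000 / 4e6)
  expect_true(all(cs$x >= 0 & cs$x <= 2000 & cs$y >= 0 & cs$y <= 2000))
  expect_error(generate_cells("grid", 101, field = c(1000, 1000)), "grid")
  expect_error(generate_cells("csr", 0), "n")
})

test_that("track generator honors degenerate limits and the step law", {
  tr0 <- generate_tracks(5, motility = list(speed = 0, persistence = 0),
                         division_rate = 0.05, horizon = 24, seed = 1)
  mig0 <- lineage_migration(tr0, seed = 1)
  expect_true(all(mig0$distance == 0))
  trd <- generate_tracks(5, division_rate = 0, horizon = 24, seed = 2)
  expect_equal(nrow(trd$mitoses), 0)
  expect_error(generate_tracks(5, motility = list(speed = -1, persistence = 0)),
               "speed")
  expect_error(generate_tracks(5, horizon = 0), "horizon")
  # uncorrelated walk, per-axis step sd s, 96 frames: mean accumulated
  # distance ~ 96 * s * sqrt(pi/2) (Rayleigh step-length expectation)
  tr <- generate_tracks(60, motility = list(speed = 3, persistence = 0),
                        division_rate = 0, horizon = 48, seed = 3)
  mig <- lineage_migration(tr, seed = 1)
  expected <- 96 * 3 * sqrt(pi / 2)
  expect_lt(abs(mean(mig$distance) / expected - 1), 0.05)
})

test_that("phenotype coupling follows the attenuation law", {
  d <- generate_design(design_spec())
  sim <- generate_multiomic(d, module_spec(n_modules = 3,
    features_per_assay_per_module = c(RPPA = 4L),
    background_features = c(RPPA = 0L), noise_sd = c(RPPA = 1)),
    seed = 5, l1000_features = 0)
  # zero coupling: phenotype uncorrelated with the module score
  ph0 <- generate_phenotypes(sim$truth, d, coupling = list(p = c(M1 = 0)),
                             noise_sd = 1, seed = 1)
  key <- condition_key(ph0$ligand, ph0$time)
  sc <- tapply(ph0$p, key, mean)
  prof <- sim$truth$profiles[1, names(sc)]
  expect_lt(abs(cor(sc, prof)), 0.6)
  # slope 1, noise 0: r = 1 exactly against the standardized profile
  ph1 <- generate_phenotypes(sim$truth, d, coupling = list(p = c(M2 = 1)),
                             noise_sd = 0, seed = 1)
  sc1 <- tapply(ph1$p, condition_key(ph1$ligand, ph1$time), mean)
  zprof <- scale(sim$truth$profiles[2, names(sc1)])[, 1]
  expect_equal(unname(cor(sc1, zprof)), 1)
  # slope 1, noise sd = signal sd: r ~ 1/sqrt(2) (attenuation), MC check
  rs <- sapply(1:40, function(s) {
    ph <- generate_phenotypes(sim$truth, d, coupling = list(p = c(M3 = 1)),
                              noise_sd = 1, seed = s)
    cor(ph$p, scale(sim$truth$profiles[3, ])[, 1][
      condition_key(ph$ligand, ph$time)])
  })
  expect_lt(abs(mean(rs) - 1 / sqrt(2)), 0.06)
})

test_that("null module world rejects per-feature tests at the nominal rate", {
  # distributional sanity: >= 5000 null features, one-sample t vs 0
  d <- generate_design(design_spec(replicates = 3))
  ms <- module_spec(n_modules = 0,
                    features_per_assay_per_module = c(ATAC = 0L),
                    background_features = c(ATAC = 5000L),
                    noise_sd = c(ATAC = 1), effect_profiles = "null")
  sim <- generate_multiomic(d, ms, seed = 8, l1000_features = 0)
  v <- sim$assays$ATAC$values
  n <- ncol(v)
  tt <- rowMeans(v) / (apply(v, 1, sd) / sqrt(n))
  p <- 2 * pt(-abs(tt), n - 1)
  rate <- mean(p < 0.05)
  ci <- 2.58 * sqrt(0.05 * 0.95 / nrow(v))
  expect_lt(abs(rate - 0.05), ci + 0.005)
})
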