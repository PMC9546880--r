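test_that("neighbor counts handle anchors and border exclusion", {
  field <- c(1000, 1000)
  cells <- data.frame(x = c(500, 550, 950), y = c(500, 500, 990))
  nc <- neighbor_counts(cells, radius = 100, field = field)
  # two cells 50 px apart count each other; the margin cell is not focal
  expect_equal(nrow(nc$per_cell), 2)
  expect_equal(nc$per_cell$neighbors, c(1, 1))
  iso <- neighbor_counts(data.frame(x = 500, y = 500), 100, field)
  expect_equal(iso$per_cell$neighbors, 0)
  empty <- neighbor_counts(data.frame(x = numeric(), y = numeric()), 100, field)
  expect_true(is.na(empty$well_mean))
})

test_that("CSR neighbor counts match the Poisson expectation", {
  set.seed(71)
  means <- sapply(1:5, function(s) {
    ce <- generate_cells("csr", 1000, field = c(2000, 2000), seed = s)
    neighbor_counts(ce, 100, c(2000, 2000))$well_mean
  })
  lambda_pi_r2 <- 1000 / (2000^2) * pi * 100^2
  expect_lt(abs(mean(means) / lambda_pi_r2 - 1), 0.05)
})

test_that("CSR k-NN expectation matches its closed form", {
  # E[r_j] * sqrt(lambda): 0.5, 0.75, 0.9375, 1.09375 for j = 1..4
  lam <- 1 / 400
  expect_equal(knn_csr_expectation(1, lam), 0.5 / sqrt(lam))
  coefs <- c(0.5, 0.75, 0.9375, 1.09375)
  for (k in 1:4)
    expect_equal(knn_csr_expectation(k, lam), mean(coefs[1:k]) / sqrt(lam))
})

test_that("normalized neighbor distance hits its geometric anchors", {
  # perfect grid, k = 1, interior cells: ratio exactly 2
  g <- generate_cells("grid", 100, field = c(1000, 1000), seed = 1)
  nd <- normalized_neighbor_distance(g, k = 1, field = c(1000, 1000))
  expect_equal(nd$ratio, 2, tolerance = 1e-9)
  # CSR: ratio ~ 1 at both normalizations for k = 1
  set.seed(72)
  r1 <- sapply(1:10, function(s) {
    ce <- generate_cells("csr", 2000, field = c(2000, 2000), seed = s)
    normalized_neighbor_distance(ce, k = 1, field = c(2000, 2000))$ratio
  })
  expect_lt(abs(mean(r1) - 1), 0.02)
  # ordering at matched density: thomas < csr < grid
  th <- generate_cells("thomas", 400, field = c(2000, 2000),
                       params = list(n_parents = 12, sigma = 40), seed = 3)
  cs <- generate_cells("csr", 400, field = c(2000, 2000), seed = 3)
  gr <- generate_cells("grid", 400, field = c(2000, 2000), seed = 3)
  f <- c(2000, 2000)
  expect_lt(normalized_neighbor_distance(th, 4, f)$ratio,
            normalized_neighbor_distance(cs, 4, f)$ratio)
  expect_lt(normalized_neighbor_distance(cs, 4, f)$ratio,
            normalized_neighbor_distance(gr, 4, f)$ratio)
  expect_error(normalized_neighbor_distance(cs[1:3, ], k = 4, f), "k must be")
})

test_that("mean shift recovers blob structure and degenerate cases", {
  set.seed(73)
  blob <- rbind(cbind(rnorm(30, 100, 5), rnorm(30, 100, 5)),
                cbind(rnorm(20, 800, 5), rnorm(20, 800, 5)))
  cells <- data.frame(x = blob[, 1], y = blob[, 2])
  ms <- mean_shift_cluster_size(cells, bandwidth = 60)
  expect_equal(ms$n_clusters, 2)
  expect_equal(ms$mean_cells_per_cluster, 25)
  expect_setequal(as.vector(table(ms$labels)), c(30, 20))
  same <- data.frame(x = rep(5, 10), y = rep(5, 10))
  expect_equal(mean_shift_cluster_size(same, bandwidth = 10)$n_clusters, 1)
  # thomas process with tight parents: mean size ~ n / n_parents
  th <- generate_cells("thomas", 300, field = c(1000, 1000),
                       params = list(n_parents = 10, sigma = 10), seed = 4)
  ms2 <- mean_shift_cluster_size(th, bandwidth = 60)
  expect_lt(abs(ms2$mean_cells_per_cluster - 30), 12)
})

test_that("DAPI gate separates the 2N/4N mixture and flags degeneracy", {
  ce <- generate_cells("csr", 2000, seed = 5)
  gt <- gate_cell_cycle(ce$dapi_total, ce$n_nuclei, seed = 1)
  mis <- mean((gt$phase == "G2M") != (ce$true_phase[gt$kept] == "G2M"))
  expect_lt(mis, 0.02)
  # multinucleated cells are removed before gating
  expect_equal(sum(gt$kept), sum(ce$n_nuclei < 2))
  # two points split into the two obvious groups (silhouette of singleton
  # clusters is 0 by convention, so the quality warning fires)
  g2 <- suppressWarnings(gate_cell_cycle(c(1, 2), seed = 1))
  expect_equal(as.character(g2$phase), c("G1", "G2M"))
  expect_error(gate_cell_cycle(rep(3, 20)), "constant")
  set.seed(2)
  expect_warning(gate_cell_cycle(rnorm(100, 1000, 10), seed = 1),
                 "separation")
})

test_that("EdU gate recovers the planted positive fraction", {
  ce <- generate_cells("csr", 2000, seed = 6)
  thr <- edu_gate_threshold(ce$edu, seed = 1)
  expect_lt(abs(edu_fraction(ce$edu, thr) - mean(ce$true_edu_pos)), 0.02)
  # plate-level threshold scores degenerate wells correctly
  neg <- generate_cells("csr", 300, params = list(edu_pos_frac = 0), seed = 7)
  pos <- generate_cells("csr", 300, params = list(edu_pos_frac = 1), seed = 8)
  expect_lt(edu_fraction(neg$edu, thr), 0.02)
  expect_gt(edu_fraction(pos$edu, thr), 0.98)
})

test_that("lineage migration matches hand-built paths and is rigid-motion invariant", {
  # stationary track -> 0; straight line, 10 steps of 5 px -> 50
  tr <- data.frame(track_id = c(rep(1, 11), rep(2, 11)),
                   parent_id = NA_integer_,
                   frame = rep(0:10, 2),
                   x = c(rep(3, 11), seq(0, 50, by = 5)),
                   y = c(rep(4, 11), rep(0, 11)))
  mig <- lineage_migration(tr, seed = 1)
  expect_equal(sort(mig$distance), c(0, 50))
  # back-tracing crosses a division at the parent's position
  tr2 <- data.frame(track_id = c(1, 1, 2, 2, 3, 3),
                    parent_id = c(NA, NA, 1, 1, 1, 1),
                    frame = c(0, 1, 1, 2, 1, 2),
                    x = c(0, 3, 3, 6, 3, 3), y = 0)
  mig2 <- lineage_migration(tr2, seed = 1)
  expect_true(mig2$distance %in% c(3, 6))
  # orphan tracks are excluded with a message
  orphan <- data.frame(track_id = 9, parent_id = 99, frame = 5:6, x = 0, y = 0)
  expect_message(m3 <- lineage_migration(rbind(tr, orphan), seed = 1),
                 "excluded")
  expect_equal(nrow(m3), 2)
  # global translation and rotation leave distances unchanged
  th <- 0.7
  rot <- function(x, y) cbind(cos(th) * x - sin(th) * y + 100,
                              sin(th) * x + cos(th) * y - 50)
  trr <- tr; trr[, c("x", "y")] <- rot(tr$x, tr$y)
  expect_equal(sort(lineage_migration(trr, seed = 1)$distance),
               sort(mig$distance))
})

test_that("phenotype comparisons report calibrated anchors", {
  # identical group distributions: overall p = 1 under rank ties
  v <- rep(1:8, 4)
  g <- rep(letters[1:4], each = 8)
  cp <- compare_phenotypes(v, g, "rank")
  expect_gt(cp$overall_p, 0.99)
  # two groups shifted 5 sd: flagged significant in both modes
  set.seed(74)
  v2 <- rnorm(32) + rep(c(0, 0, 0, 5), each = 8)
  for (mode in c("rank", "anova")) {
    cp2 <- compare_phenotypes(v2, g, mode)
    expect_lt(cp2$overall_p, 0.001)
    hit <- cp2$pairwise$significant[cp2$pairwise$group1 == "d" |
                                      cp2$pairwise$group2 == "d"]
    expect_true(all(hit))
  }
  expect_warning(compare_phenotypes(c(v2, 1), c(g, "e"), "rank"),
                 "dropping group")
  expect_error(compare_phenotypes(v2[1:8], g[1:8], "rank"), ">= 2 groups")
})
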