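# Shared fixtures and independent oracles used across test files.

# two-group metadata: n replicates of CTRL_0 and of one treated condition
make_meta2 <- function(n = 3, ligand = "EGF", time = 24) {
  data.frame(sample_id = paste0("s", seq_len(2 * n)),
             ligand = rep(c("CTRL", ligand), each = n),
             time = rep(c(0, time), each = n),
             replicate = rep(seq_len(n), 2),
             stringsAsFactors = FALSE)
}

# brute-force BH step-up oracle: literal definition, independent of bh_adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i)  # rank of p[i]
    q[i] <- min(1, min(p[o][j:m] * m / (j:m)))
  }
  q
}

# brute-force consensus oracle: enumerate all k^n hard label vectors
consensus_oracle <- function(partitions, k) {
  n <- length(partitions[[1]])
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  objs <- apply(grid, 1, function(g)
    consensus_objective(as.integer(g), partitions, k))
  min(objs)
}

# brute-force PAM oracle: enumerate all medoid sets, Euclidean cost
pam_oracle_cost <- function(x, k) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  sets <- combn(n, k)
  min(apply(sets, 2, function(m) sum(apply(d[, m, drop = FALSE], 1, min))))
}

# three well-separated spherical Gaussian clusters in 2-D
three_clusters <- function(n_per = 50, sep = 6, seed = 1) {
  set.seed(seed)
  ctr <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  do.call(rbind, lapply(1:3, function(i)
    cbind(rnorm(n_per, ctr[i, 1]), rnorm(n_per, ctr[i, 2]))))
}

# planted two-group differential matrix: first n_true features shifted
planted_matrix <- function(n_true, n_null, lfc = 3, noise = 0.3, n = 3,
                           seed = 1) {
  set.seed(seed)
  meta <- make_meta2(n)
  p <- n_true + n_null
  shift <- c(rep(lfc, ceiling(n_true / 2)), rep(-lfc, floor(n_true / 2)),
             rep(0, n_null))
  x <- matrix(rnorm(p * 2 * n, 0, noise), p) +
    outer(shift, as.numeric(meta$ligand != "CTRL"))
  dimnames(x) <- list(paste0("f", seq_len(p)), meta$sample_id)
  list(values = x, meta = meta, true = paste0("f", seq_len(n_true)))
}
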