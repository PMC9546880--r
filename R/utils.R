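# Shared utilities: deterministic seed substreams, adjusted Rand index, and
# the hand-rolled Benjamini-Hochberg step-up (kept self-contained so tests can
# check it against a brute-force oracle rather than a library call).

#' Derive a named substream seed from a root seed
#'
#' All generators draw their randomness from substreams derived from a single
#' root seed, so any one synthetic component can be regenerated independently
#' of the others. The derived seed is kept below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param name character scalar naming the substream.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 131 + cc) %% 1000003L
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% (2^31 - 1))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label permutation), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Benjamini-Hochberg adjusted p-values (step-up)
#'
#' Self-contained implementation of the BH step-up adjustment:
#' q_(i) = min_{j >= i} ( p_(j) * m / j ), capped at 1.
#'
#' @param p numeric vector of p-values (NA allowed; NA propagates).
#' @return Numeric vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(q)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  qq <- pmin(1, cummin(pv[o] * m / (m:1)))
  q[ok][o] <- qq
  q
}

# internal: condition key "ligand_time"
condition_key <- function(ligand, time) paste(ligand, time, sep = "_")
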