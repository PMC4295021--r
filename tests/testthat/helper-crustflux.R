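# Shared fixtures built in code.

# Partition equality up to relabelling, via co-membership comparison.
same_partition <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

# Random symmetric dissimilarity matrix with ids.
random_dm <- function(n, max_d = 0.1) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, max_d)
  d <- d + t(d)
  dimnames(d) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  d
}

# Exhaustive average-linkage oracle: hclust (UPGMA) cut at the cutoff.
oracle_cluster <- function(dm, cutoff) {
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  stats::cutree(hc, h = cutoff)
}

# Three coexisting populations emulating meso-/thermophilic optima.
three_populations <- function() {
  data.frame(t_opt = c(33, 50, 74), width = 6,
             peak_rate = c(0.12, 0.14, 0.10))
}
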