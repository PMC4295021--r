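aln <- function(...) tibble::tibble(id = sprintf("s%02d", seq_along(c(...))),
                                    aligned = c(...))

test_that("masking restricts columns and drops short records", {
  s <- aln("ACGTACGT", "ACG-ACGT", "--------")
  # identity mask keeps everything except the all-gap record at min_length
  m <- apply_mask(s, "all", min_length = 1)
  expect_equal(nrow(m), 2L)
  expect_equal(attr(m, "n_dropped"), 1L)
  m0 <- apply_mask(s, "all", min_length = 0)
  expect_equal(nrow(m0), 3L)
  expect_equal(m0$aligned, s$aligned)

  # column subset
  sub <- apply_mask(s[1:2, ], c(1L, 2L, 5L))
  expect_equal(sub$aligned, c("ACA", "ACA"))

  expect_error(apply_mask(s, integer(0)), "empty")
  expect_error(apply_mask(s, c(3L, 1L)), "strictly increasing")
  expect_error(apply_mask(aln("ACGT", "AC"), "all"), "differ in length")

  # a tuned min_length drops exactly the planted short records
  set <- sim_dsrb_sequences(n_otus = 2, n_sequences = 10, seed = 13)$sequences
  short_ids <- set$id[1:3]
  set$aligned[set$id %in% short_ids] <-
    paste0(substr(set$aligned[set$id %in% short_ids], 1, 100),
           strrep("-", 168))
  kept <- apply_mask(set, "all", min_length = 200)
  expect_equal(attr(kept, "n_dropped"), 3L)
  expect_false(any(short_ids %in% kept$id))
})

test_that("pairwise distances follow the gap and ambiguity conventions", {
  expect_equal(pairwise_distance("ACGTACGT", "ACGTACGT"), 0)
  expect_equal(pairwise_distance("AAAA", "TTTT"), 1)

  # 268 columns with 8 substitutions, no gaps
  a <- strrep("A", 268)
  b <- paste0(strrep("T", 8), strrep("A", 260))
  expect_equal(pairwise_distance(a, b), 8 / 268)

  expect_error(pairwise_distance("ACGT", "AC"), "length")

  # terminal gaps are excluded from the comparison
  expect_equal(pairwise_distance("--GTAC", "ACGTAC"), 0)

  # internal gap run: once under onegap, per-column under eachgap,
  # ignored under nogap
  x <- "AC--GT"
  y <- "ACAAGT"
  expect_equal(pairwise_distance(x, y, "onegap"), 1 / 5)
  expect_equal(pairwise_distance(x, y, "eachgap"), 2 / 6)
  expect_equal(pairwise_distance(x, y, "nogap"), 0)

  # both-gap columns are skipped entirely
  expect_equal(pairwise_distance("AC--GT", "AC--GT"), 0)

  # N never matches; N vs base is a mismatch, N vs N uncounted
  expect_equal(pairwise_distance("ANAA", "AAAA"), 1 / 4)
  expect_equal(pairwise_distance("ANAA", "ANAA"), 0 / 3)
})

test_that("distance matrices are symmetric with zero diagonal", {
  s <- sim_dsrb_sequences(n_otus = 3, n_sequences = 9, seed = 21)$sequences
  dm <- distance_matrix(s)
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), setNames(rep(0, 9), s$id))
  expect_true(all(dm >= 0 & dm <= 1))
})

test_that("average-neighbor clustering handles the degenerate extremes", {
  n <- 6
  zero <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  expect_equal(length(unique(average_neighbor_cluster(zero, 0.03)$assignments$otu)),
               1L)
  ones <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(ones) <- 0
  expect_equal(length(unique(average_neighbor_cluster(ones, 0.03)$assignments$otu)),
               n)
  expect_error(average_neighbor_cluster(zero, 1.5), "cutoff")
})

test_that("planted OTU structure is recovered perfectly at the 0.03 cutoff", {
  sim <- sim_dsrb_sequences(n_otus = 5, n_sequences = 40,
                            within_otu_divergence = 0.01,
                            between_otu_divergence = 0.10, seed = 31)
  dm <- distance_matrix(sim$sequences)
  res <- average_neighbor_cluster(dm, 0.03, samples = sim$sequences)
  got <- res$assignments$otu[match(sim$truth$id, res$assignments$id)]
  expect_equal(length(unique(got)), 5L)
  expect_true(same_partition(got, sim$truth$otu))
  # every sequence assigned exactly once; abundances sum to n
  expect_equal(sort(res$assignments$id), sort(sim$truth$id))
  expect_equal(sum(res$abundance$count), 40)
})

test_that("clustering matches the exhaustive average-linkage oracle", {
  withr::with_seed(17, {
    for (rep in 1:60) {
      n <- sample(4:12, 1)
      dm <- random_dm(n, max_d = 0.1)
      cutoff <- runif(1, 0.01, 0.08)
      mine <- average_neighbor_cluster(dm, cutoff)$assignments
      oracle <- oracle_cluster(dm, cutoff)
      expect_true(same_partition(mine$otu[match(names(oracle), mine$id)],
                                 oracle),
                  label = sprintf("oracle mismatch at rep %d", rep))
    }
  })
})

test_that("OTU count is monotone non-increasing in the cutoff", {
  withr::with_seed(23, {
    dm <- random_dm(15, max_d = 0.12)
    counts <- vapply(seq(0, 0.1, by = 0.01), function(cc)
      length(unique(average_neighbor_cluster(dm, cc)$assignments$otu)),
      numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("clustering is invariant under input permutation", {
  sim <- sim_dsrb_sequences(n_otus = 4, n_sequences = 16, seed = 41)
  dm <- distance_matrix(sim$sequences)
  base <- average_neighbor_cluster(dm, 0.03)$assignments
  withr::with_seed(5, {
    perm <- sample(nrow(dm))
    shuffled <- average_neighbor_cluster(dm[perm, perm], 0.03)$assignments
  })
  merged <- dplyr::inner_join(base, shuffled, by = "id")
  expect_true(same_partition(merged$otu.x, merged$otu.y))
})

test_that("diversity estimators match their defining formulas", {
  d <- estimate_diversity(c(4, 1, 1, 2))
  expect_equal(d$s_obs, 4)
  expect_equal(d$chao1, 4.5)  # 4 + 2*1/(2*(1+1))

  # chao1 = s_obs when no singletons
  d2 <- estimate_diversity(c(4, 2, 3, 2))
  expect_equal(d2$chao1, d2$s_obs)

  # np-Shannon of a single species is zero; equals plain Shannon when F1=0
  expect_equal(estimate_diversity(10)$np_shannon, 0)
  x <- c(10, 10, 10, 10)
  plain <- -sum(rep(0.25, 4) * log(0.25))
  expect_equal(estimate_diversity(x)$np_shannon, plain, tolerance = 1e-2)

  # perfectly even sample: evenness near 1 (clamped at 1)
  expect_gt(estimate_diversity(c(5, 5, 5, 5))$simpson_evenness, 0.95)
  expect_lte(estimate_diversity(c(5, 5, 5, 5))$simpson_evenness, 1)

  expect_error(estimate_diversity(c(0, 0)), "all-zero")
  expect_error(estimate_diversity(c(-1, 2)), ">= 0")
})

test_that("shared-OTU accounting covers disjoint, identical and planted cases", {
  ab <- function(s1, s2) {
    structure(list(cutoff = 0.03,
                   assignments = tibble::tibble(id = character(0),
                                                otu = character(0)),
                   abundance = dplyr::bind_rows(
                     tibble::tibble(sample = "A", otu = s1, count = 1L),
                     tibble::tibble(sample = "B", otu = s2, count = 1L))),
              class = "otu_result")
  }
  disjoint <- ab(c("o1", "o2"), c("o3", "o4"))
  expect_equal(shared_otus(disjoint, "A", "B"),
               list(n_shared = 0L, n_total = 4L))
  same <- ab(c("o1", "o2"), c("o1", "o2"))
  expect_equal(shared_otus(same, "A", "B"),
               list(n_shared = 2L, n_total = 2L))
  # planted overlap of 2 OTUs among 31 total
  planted <- ab(sprintf("o%02d", 1:16), sprintf("o%02d", 15:31))
  expect_equal(shared_otus(planted, "A", "B"),
               list(n_shared = 2L, n_total = 31L))
  expect_error(shared_otus(same, "A", "nope"), "unknown sample")
})

test_that("aligned FASTA round-trips through disk", {
  sim <- sim_dsrb_sequences(n_otus = 2, n_sequences = 6, seed = 3)
  dir <- withr::local_tempdir()
  write_sim_bundle(dir, sequences = sim)
  back <- read_aligned_fasta(file.path(dir, "sequences.fasta"),
                             file.path(dir, "membership.tsv"))
  expect_equal(back$id, sim$sequences$id)
  expect_equal(back$aligned, sim$sequences$aligned)
  expect_equal(back$sample, sim$sequences$sample)
})
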