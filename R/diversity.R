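# dsrB clone-library analysis: alignment masking, pairwise distances
# with configurable gap handling, average-neighbor OTU clustering at a
# distance cutoff, and nonparametric diversity estimators.

#' Read an aligned FASTA file into a tibble
#'
#' @param path Aligned FASTA file (gap character `-`).
#' @param membership Optional tibble/data frame (`id`, `sample`) or path
#'   to a TSV assigning records to samples.
#' @return A tibble with columns `id`, `aligned` and (when membership is
#'   supplied) `sample`.
#' @export
read_aligned_fasta <- function(path, membership = NULL) {
  dna <- Biostrings::readDNAStringSet(path)
  out <- tibble(id = names(dna), aligned = unname(as.character(dna)))
  if (!is.null(membership)) {
    if (is.character(membership) && length(membership) == 1L)
      membership <- readr::read_tsv(membership, col_types = "cc",
                                    progress = FALSE)
    out <- left_join(out, as_tibble(membership), by = "id")
  }
  out
}

#' Mask an alignment to unambiguous columns
#'
#' Restricts every record to the retained columns and drops records
#' whose retained, non-gap length falls below `min_length` (emulating a
#' curated mask keeping only unambiguously aligned positions and
#' discarding too-short fragments).
#'
#' @param seqs Tibble with columns `id` and `aligned` (equal-length
#'   aligned sequences over A/C/G/T/-/N).
#' @param mask `"all"` to keep every column, or an integer vector of
#'   1-based column indices (strictly increasing).
#' @param min_length Minimum retained non-gap length for a record to be
#'   kept.
#' @return The filtered tibble, with the mask stored in
#'   `attr(, "mask")` and the number of dropped records in
#'   `attr(, "n_dropped")`.
#' @export
apply_mask <- function(seqs, mask = "all", min_length = 0) {
  s <- as_tibble(seqs)
  if (!all(c("id", "aligned") %in% names(s)))
    .stopf("seqs need id and aligned columns")
  len <- unique(nchar(s$aligned))
  if (length(len) > 1L) .stopf("aligned sequences differ in length")
  if (identical(mask, "all")) mask <- seq_len(len)
  mask <- as.integer(mask)
  if (length(mask) == 0L) .stopf("mask is empty")
  if (any(mask < 1L | mask > len) || is.unsorted(mask, strictly = TRUE))
    .stopf("mask indices must be strictly increasing within 1..%d", len)
  mat <- do.call(rbind, strsplit(s$aligned, ""))[, mask, drop = FALSE]
  masked <- apply(mat, 1L, paste, collapse = "")
  keep <- nchar(gsub("-", "", masked)) >= min_length
  out <- s[keep, ]
  out$aligned <- masked[keep]
  attr(out, "mask") <- mask
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# Per-pair distance on character vectors; shared with pairwise_distance
# and distance_matrix. Terminal gaps of either sequence are excluded;
# both-gap and N-vs-(N or gap) columns are uncounted; N vs a determined
# base is a mismatch.
.pair_dist <- function(x, y, gap_mode) {
  n <- length(x)
  gx <- x == "-"; gy <- y == "-"
  # span outside either sequence's terminal gaps
  ng <- which(!gx & !gy)
  if (length(ng) == 0L) return(NA_real_)
  lo <- max(min(which(!gx)), min(which(!gy)))
  hi <- min(max(which(!gx)), max(which(!gy)))
  if (lo > hi) return(NA_real_)
  idx <- lo:hi
  x <- x[idx]; y <- y[idx]; gx <- gx[idx]; gy <- gy[idx]
  both_gap <- gx & gy
  one_gap <- xor(gx, gy)
  nx <- x == "N"; ny <- y == "N"
  amb_pair <- (nx & (ny | gy)) | (ny & (nx | gx))  # N vs N or N vs gap
  base_cols <- !gx & !gy & !amb_pair
  mm_sub <- sum(base_cols & x != y)
  n_base <- sum(base_cols)
  if (gap_mode == "nogap") {
    mism <- mm_sub; denom <- n_base
  } else if (gap_mode == "eachgap") {
    gap_cols <- sum(one_gap & !amb_pair)
    mism <- mm_sub + gap_cols; denom <- n_base + gap_cols
  } else {  # onegap: a contiguous gap run counts once
    runs <- rle(one_gap & !amb_pair)
    n_runs <- sum(runs$values)
    mism <- mm_sub + n_runs; denom <- n_base + n_runs
  }
  if (denom == 0L) return(NA_real_)
  mism / denom
}

#' Pairwise distance between two aligned sequences
#'
#' Uncorrected distance: mismatches over compared columns. Columns where
#' both sequences have gaps are skipped, as are terminal-gap columns.
#' Internal gaps follow `gap_mode`: `"onegap"` (default) counts each
#' contiguous single-sequence gap run as one mismatch over one column,
#' `"eachgap"` counts every gap column, `"nogap"` ignores gap columns.
#' An `N` never matches and counts as a mismatch only against a
#' determined base.
#'
#' @param a,b Aligned sequences of equal length (strings).
#' @param gap_mode Gap-handling convention.
#' @return Distance in `[0, 1]`.
#' @export
#' @examples
#' pairwise_distance("ACGT", "ACGA")
pairwise_distance <- function(a, b, gap_mode = c("onegap", "eachgap", "nogap")) {
  gap_mode <- match.arg(gap_mode)
  if (nchar(a) != nchar(b)) .stopf("sequences differ in length")
  d <- .pair_dist(strsplit(a, "")[[1L]], strsplit(b, "")[[1L]], gap_mode)
  if (is.na(d)) .stopf("sequences share no comparable columns")
  d
}

#' Pairwise distance matrix of an aligned sequence set
#'
#' @param seqs Tibble with columns `id` and `aligned`.
#' @inheritParams pairwise_distance
#' @return A symmetric numeric matrix with the sequence ids as dimnames.
#' @export
distance_matrix <- function(seqs, gap_mode = c("onegap", "eachgap", "nogap")) {
  gap_mode <- match.arg(gap_mode)
  s <- as_tibble(seqs)
  n <- nrow(s)
  chars <- strsplit(s$aligned, "")
  d <- matrix(0, n, n, dimnames = list(s$id, s$id))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dij <- .pair_dist(chars[[i]], chars[[j]], gap_mode)
    if (is.na(dij)) .stopf("sequences %s and %s share no comparable columns",
                           s$id[i], s$id[j])
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' Average-neighbor OTU clustering
#'
#' Agglomerative average-linkage clustering: repeatedly merges the pair
#' of clusters with the smallest mean pairwise inter-sequence distance,
#' while that mean is at most `cutoff` (0.03 corresponds to the 97%
#' sequence-similarity convention). Ties between equal-distance merge
#' candidates resolve to the pair whose sorted member ids are
#' lexicographically smallest, making the result deterministic and
#' invariant under input order.
#'
#' @param dm Symmetric distance matrix with id dimnames
#'   (from [distance_matrix()]).
#' @param cutoff Distance cutoff in `[0, 1]` (default 0.03).
#' @param samples Optional tibble/data frame (`id`, `sample`) for
#'   per-sample OTU abundances.
#' @return An object of class `otu_result`: list with `cutoff`,
#'   `assignments` (tibble `id`, `otu`) and `abundance` (tibble
#'   `sample`, `otu`, `count`; `NULL` without sample membership). OTUs
#'   are labelled `OTU_001`, ... in order of their smallest member id.
#' @export
average_neighbor_cluster <- function(dm, cutoff = 0.03, samples = NULL) {
  if (cutoff < 0 || cutoff > 1) .stopf("cutoff must be in [0, 1]")
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    .stopf("dm must be a square matrix")
  ids <- rownames(dm) %||% sprintf("seq%03d", seq_len(nrow(dm)))
  n <- nrow(dm)
  if (n == 0L) .stopf("empty distance matrix")
  if (max(abs(dm - t(dm))) > 1e-12) .stopf("dm must be symmetric")

  members <- lapply(seq_len(n), function(i) ids[i])
  sizes <- rep(1L, n)
  d <- dm
  diag(d) <- Inf
  active <- rep(TRUE, n)
  first_id <- ids  # lexicographically smallest member id per cluster

  while (sum(active) > 1L) {
    ai <- which(active)
    sub <- d[ai, ai, drop = FALSE]
    m <- min(sub)
    if (!is.finite(m) || m > cutoff) break
    cand <- which(sub <= m + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on sorted member ids of the candidate pair
    keys <- apply(cand, 1L, function(rc) {
      paste(sort(c(first_id[ai[rc[1]]], first_id[ai[rc[2]]])),
            collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- ai[pick[1]]; j <- ai[pick[2]]
    # merge j into i with size-weighted average distances (UPGMA)
    ni <- sizes[i]; nj <- sizes[j]
    upd <- setdiff(ai, c(i, j))
    d[i, upd] <- d[upd, i] <- (ni * d[i, upd] + nj * d[j, upd]) / (ni + nj)
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    first_id[i] <- min(first_id[i], first_id[j])
    active[j] <- FALSE
    d[j, ] <- d[, j] <- Inf
  }

  clusters <- members[active]
  ord <- order(vapply(clusters, min, character(1)))
  clusters <- clusters[ord]
  assignments <- bind_rows(lapply(seq_along(clusters), function(k)
    tibble(id = clusters[[k]], otu = sprintf("OTU_%03d", k)))) %>%
    arrange(.data$id)

  abundance <- NULL
  if (!is.null(samples)) {
    memb <- as_tibble(samples)
    if (!all(c("id", "sample") %in% names(memb)))
      .stopf("samples need id and sample columns")
    abundance <- assignments %>%
      inner_join(memb, by = "id") %>%
      dplyr::count(.data$sample, .data$otu, name = "count")
  }
  structure(list(cutoff = cutoff, assignments = assignments,
                 abundance = abundance),
            class = "otu_result")
}

#' @export
print.otu_result <- function(x, ...) {
  cat(sprintf("<otu_result> %d sequences in %d OTUs at cutoff %.3f\n",
              nrow(x$assignments), length(unique(x$assignments$otu)),
              x$cutoff))
  invisible(x)
}

#' Tidy an OTU clustering result
#'
#' @param x An `otu_result`.
#' @param ... Unused.
#' @return The per-sequence assignment tibble (`id`, `otu`).
#' @export
tidy.otu_result <- function(x, ...) x$assignments

#' Nonparametric diversity estimates for one sample
#'
#' From an OTU abundance vector computes observed richness, the
#' bias-corrected Chao1 richness estimate
#' S_obs + F1 (F1 - 1) / (2 (F2 + 1)) from singleton and doubleton
#' counts, Simpson evenness (1/D)/S_obs with the unbiased finite-sample
#' D = sum n_i (n_i - 1) / (N (N - 1)) (clamped at 1), and the
#' Chao-Shen coverage-adjusted (nonparametric) Shannon index with
#' coverage C = 1 - F1/N and Horvitz-Thompson correction.
#'
#' @param counts Nonnegative integer abundance vector with a positive
#'   sum; zeros are ignored.
#' @return A one-row tibble: `s_obs`, `chao1`, `simpson_evenness`,
#'   `np_shannon` (nats).
#' @export
#' @examples
#' estimate_diversity(c(4, 1, 1, 2))
estimate_diversity <- function(counts) {
  if (any(counts < 0)) .stopf("counts must be >= 0")
  x <- counts[counts > 0]
  if (length(x) == 0L) .stopf("all-zero abundance vector")
  N <- sum(x)
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))

  simpson_even <- if (N > 1) {
    D <- sum(x * (x - 1)) / (N * (N - 1))
    if (D == 0) 1 else min(1, (1 / D) / s_obs)
  } else 1

  C <- 1 - f1 / N
  p <- x / N
  np_shannon <- if (C == 0) 0 else {
    cp <- C * p
    -sum(cp * log(cp) / (1 - (1 - cp)^N))
  }
  tibble(s_obs = s_obs, chao1 = chao1,
         simpson_evenness = simpson_even, np_shannon = np_shannon)
}

#' Diversity estimates for every sample of an OTU result
#'
#' @param otus An `otu_result` with per-sample abundance.
#' @return A tibble with one row per sample: `sample`, `n_sequences`,
#'   `s_obs`, `chao1`, `simpson_evenness`, `np_shannon`.
#' @export
sample_diversity <- function(otus) {
  stopifnot(inherits(otus, "otu_result"))
  if (is.null(otus$abundance))
    .stopf("otu_result carries no sample abundances")
  otus$abundance %>%
    group_by(.data$sample) %>%
    dplyr::group_modify(function(d, key)
      mutate(estimate_diversity(d$count), n_sequences = sum(d$count),
             .before = 1)) %>%
    ungroup()
}

#' OTUs shared between two samples
#'
#' @param otus An `otu_result` with per-sample abundance.
#' @param sample_a,sample_b Sample labels present in the abundance
#'   table.
#' @return A list with `n_shared` (OTUs with nonzero counts in both
#'   samples) and `n_total` (OTUs with nonzero counts in either).
#' @export
shared_otus <- function(otus, sample_a, sample_b) {
  stopifnot(inherits(otus, "otu_result"))
  if (is.null(otus$abundance))
    .stopf("otu_result carries no sample abundances")
  ab <- otus$abundance
  for (s in c(sample_a, sample_b))
    if (!s %in% ab$sample) .stopf("unknown sample: %s", s)
  in_a <- unique(ab$otu[ab$sample == sample_a & ab$count > 0])
  in_b <- unique(ab$otu[ab$sample == sample_b & ab$count > 0])
  list(n_shared = length(intersect(in_a, in_b)),
       n_total = length(union(in_a, in_b)))
}
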