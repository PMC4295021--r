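# Synthetic-data generators emulating every pipeline input: 35S tracer
# incubation counts with Poisson counting noise, multimodal
# rate-vs-temperature profiles, log-linear qPCR dilution series, and
# dsrB sequence sets with planted OTU structure.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    .stopf("seed must be a single number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a 35S-sulfate incubation experiment
#'
#' Generates blank-uncorrected scintillation count records for replicate
#' vials incubated with 35S-labelled sulfate. The expected reduced-sulfur
#' (TRIS) fraction at time t for true rate r is
#' r t / ([SO4] x 1.06) with the sulfate pool in nmol/ml; hypothetical
#' bottom-seawater contamination adds
#' `seawater_contamination_fraction * seawater_rate` to the effective
#' rate. Raw counts over `counting_time_min` are Poisson; recorded count
#' rates are counts / counting time, so total tracer counts are conserved
#' in expectation.
#'
#' @param true_rate True sulfate reduction rate (nmol/ml/d, >= 0).
#' @param sulfate_mM Sulfate concentration (mM).
#' @param tracer_kBq_ml Tracer activity added (kBq per ml of fluid).
#' @param volume_ml Incubated fluid volume (ml).
#' @param sample_times Sampling times in days (strictly increasing,
#'   all > 0); default a single endpoint at 3 d.
#' @param counter_background_cpm,distillation_blank_cpm Background count
#'   rates added to the TRIS channel (cpm).
#' @param seawater_contamination_fraction Fraction of the sample volume
#'   assumed to be entrained bottom seawater, in `[0, 1]`.
#' @param seawater_rate Sulfate reduction rate carried by the
#'   contaminating seawater (nmol/ml/d).
#' @param counting_time_min Scintillation counting time per vial (min).
#' @param counting_efficiency Fraction of decays registered as counts.
#' @param n_replicates Replicate vials per time point.
#' @param temperature_C,amendment,borehole Metadata carried through.
#' @param fractionation 35S/32S correction factor used by the forward
#'   model (must match the analysis for round trips).
#' @param seed Optional RNG seed; fixed seeds give identical output.
#' @return A tibble of incubation records, one row per vial per time
#'   point, with the columns expected by [compute_srr()].
#' @export
#' @examples
#' sim_incubations(true_rate = 0.05, seed = 1)
sim_incubations <- function(true_rate = 0.05, sulfate_mM = 26.2,
                            tracer_kBq_ml = 100, volume_ml = 50,
                            sample_times = 3,
                            counter_background_cpm = 1,
                            distillation_blank_cpm = 1,
                            seawater_contamination_fraction = 0,
                            seawater_rate = 0,
                            counting_time_min = 10,
                            counting_efficiency = 1,
                            n_replicates = 2,
                            temperature_C = 39, amendment = "none",
                            borehole = "1025C",
                            fractionation = 1.06, seed = NULL) {
  if (true_rate < 0 || seawater_rate < 0) .stopf("rates must be >= 0")
  if (length(sample_times) == 0L || any(sample_times <= 0) ||
      is.unsorted(sample_times, strictly = TRUE))
    .stopf("sample_times must be strictly increasing and > 0")
  if (seawater_contamination_fraction < 0 ||
      seawater_contamination_fraction > 1)
    .stopf("seawater_contamination_fraction must be in [0, 1]")
  if (counter_background_cpm < 0 || distillation_blank_cpm < 0)
    .stopf("background count rates must be >= 0")

  # 1 kBq = 6e4 dpm; total activity in the vial
  total_cpm_true <- tracer_kBq_ml * volume_ml * 6e4 * counting_efficiency
  eff_rate <- true_rate * (1 - seawater_contamination_fraction) +
    seawater_contamination_fraction * seawater_rate
  s_nmol_ml <- sulfate_mM * 1000

  .with_seed(seed, {
    grid <- tidyr::expand_grid(replicate = seq_len(n_replicates),
                               duration_d = sample_times)
    frac <- eff_rate * grid$duration_d / (s_nmol_ml * fractionation)
    if (any(frac >= 1)) .stopf("expected reduced fraction >= 1; shorten the incubation")
    tris_cpm_true <- frac * total_cpm_true +
      counter_background_cpm + distillation_blank_cpm
    ct <- counting_time_min
    tibble(
      sample_id = sprintf("%s_T%02.0f_%s_r%d_d%g", borehole, temperature_C,
                          amendment, grid$replicate, grid$duration_d),
      borehole = borehole,
      temperature_C = temperature_C,
      amendment = amendment,
      duration_d = grid$duration_d,
      tris_cpm = rpois(nrow(grid), tris_cpm_true * ct) / ct,
      total_cpm = rpois(nrow(grid), (total_cpm_true +
                                       counter_background_cpm) * ct) / ct,
      replicate = grid$replicate,
      counting_time_min = ct
    )
  })
}

#' Noiseless multimodal rate-vs-temperature profile
#'
#' Sums one skewed-Gaussian response curve per population:
#' rate(T) = peak_rate * exp(-(T - t_opt)^2 / (2 sigma^2)), with sigma
#' equal to `width_left` below the optimum and `width_right` above it
#' (both default to `width`). Emulates thermal-gradient experiments in
#' which coexisting mesophilic and thermophilic sulfate reducers produce
#' several apparent optima.
#'
#' @param populations Tibble/data frame with columns `t_opt` (degC),
#'   `peak_rate` (nmol/ml/d) and `width` (degC; optionally `width_left`
#'   and `width_right`). Zero rows give a flat zero curve.
#' @param temperatures Temperature grid (degC, within 0-100); default the
#'   14-increment grid spanning 10-86 degC used in thermal-gradient
#'   blocks.
#' @return A tibble of `temperature_C` and `rate` (the noiseless true
#'   rate at each grid point).
#' @export
#' @examples
#' sim_thermal_profile(data.frame(t_opt = 44, width = 6, peak_rate = 0.14))
sim_thermal_profile <- function(populations,
                                temperatures = default_temperature_grid()) {
  if (length(temperatures) == 0L) .stopf("temperature grid is empty")
  if (any(temperatures < 0 | temperatures > 100))
    .stopf("temperature grid must lie within [0, 100] degC")
  pop <- as_tibble(populations)
  rate <- rep(0, length(temperatures))
  if (nrow(pop) > 0L) {
    if (!all(c("t_opt", "peak_rate") %in% names(pop)))
      .stopf("populations need t_opt and peak_rate columns")
    wl <- pop[["width_left"]] %||% pop[["width"]]
    wr <- pop[["width_right"]] %||% pop[["width"]]
    if (is.null(wl) || is.null(wr)) .stopf("populations need a width column")
    for (i in seq_len(nrow(pop))) {
      sigma <- ifelse(temperatures < pop$t_opt[i], wl[i], wr[i])
      rate <- rate + pop$peak_rate[i] *
        exp(-(temperatures - pop$t_opt[i])^2 / (2 * sigma^2))
    }
  }
  tibble(temperature_C = temperatures, rate = rate)
}

#' Default thermal-gradient temperature grid
#'
#' 14 evenly spaced increments spanning 10-86 degC.
#' @return Numeric vector of 14 temperatures.
#' @export
default_temperature_grid <- function() seq(10, 86, length.out = 14)

#' Simulate a qPCR dilution series
#'
#' Cq = intercept - log10(copies) / log10(1 + efficiency) + N(0, sd).
#' A perfect-doubling chemistry (efficiency 1) separates ten-fold
#' dilutions by 1/log10(2) = 3.3219 cycles.
#'
#' @param copies Copy numbers per reaction (all > 0); default an
#'   11-point decade series from 1e11 down to 10 copies.
#' @param efficiency Amplification efficiency as a fraction in (0, 1.1].
#' @param intercept Cq at one copy (cycles).
#' @param cq_noise_sd Gaussian Cq noise (cycles).
#' @param seed Optional RNG seed.
#' @return A tibble of `copies` and `cq`.
#' @export
#' @examples
#' sim_qpcr_series(efficiency = 0.9)
sim_qpcr_series <- function(copies = 10^(11:1), efficiency = 0.9,
                            intercept = 38, cq_noise_sd = 0, seed = NULL) {
  if (any(copies <= 0)) .stopf("copies must be > 0")
  if (efficiency <= 0 || efficiency > 1.1)
    .stopf("efficiency must be in (0, 1.1]")
  if (cq_noise_sd < 0) .stopf("cq_noise_sd must be >= 0")
  .with_seed(seed, {
    cq <- intercept - log10(copies) / log10(1 + efficiency) +
      rnorm(length(copies), 0, cq_noise_sd)
    tibble(copies = copies, cq = cq)
  })
}

#' Simulate aligned dsrB sequences with planted OTU structure
#'
#' Draws a random ancestral sequence, derives one seed sequence per OTU
#' by substituting a `between_otu_divergence / 2` fraction of sites
#' (expected pairwise seed divergence ~ `between_otu_divergence`), then
#' derives each member sequence from its OTU seed at
#' `within_otu_divergence / 2` (expected within-OTU pairwise divergence
#' ~ `within_otu_divergence`). Substitutions only, no indels, so the
#' alignment length is constant.
#'
#' @param n_otus Number of planted OTUs.
#' @param n_sequences Total sequences generated.
#' @param abundance_weights Relative OTU abundances (recycled to
#'   `n_otus`); default equal.
#' @param within_otu_divergence,between_otu_divergence Expected pairwise
#'   divergences (substitutions/site); planted structure requires
#'   within < between.
#' @param seq_length Alignment length (nt, default 268 unambiguously
#'   aligned positions).
#' @param samples Sample labels distributed round-robin over OTUs.
#' @param seed Optional RNG seed.
#' @return A list with `sequences` (tibble: `id`, `sample`, `aligned`)
#'   and `truth` (tibble: `id`, `otu`, `sample`).
#' @export
#' @examples
#' sim_dsrb_sequences(n_otus = 3, n_sequences = 12, seed = 1)
sim_dsrb_sequences <- function(n_otus = 5, n_sequences = 50,
                               abundance_weights = NULL,
                               within_otu_divergence = 0.01,
                               between_otu_divergence = 0.10,
                               seq_length = 268,
                               samples = c("1025C", "U1301A"),
                               seed = NULL) {
  if (seq_length <= 0) .stopf("seq_length must be > 0")
  if (n_otus < 1 || n_sequences < n_otus)
    .stopf("need n_sequences >= n_otus >= 1")
  if (within_otu_divergence >= between_otu_divergence && n_otus > 1)
    .stopf("planted structure requires within < between divergence")
  bases <- c("A", "C", "G", "T")
  w <- abundance_weights %||% rep(1, n_otus)
  w <- rep_len(w, n_otus)
  if (any(w <= 0)) .stopf("abundance_weights must be > 0")

  mutate_seq <- function(x, p) {
    n_mut <- rpois(1, p * length(x))
    if (n_mut == 0) return(x)
    pos <- sample.int(length(x), min(n_mut, length(x)))
    x[pos] <- vapply(x[pos], function(b) sample(setdiff(bases, b), 1),
                     character(1))
    x
  }

  .with_seed(seed, {
    ancestor <- sample(bases, seq_length, replace = TRUE)
    seeds <- lapply(seq_len(n_otus), function(i)
      mutate_seq(ancestor, between_otu_divergence / 2))
    # allocate members: at least one per OTU, remainder by weight
    extra <- n_sequences - n_otus
    alloc <- rep(1L, n_otus)
    if (extra > 0) {
      add <- table(factor(sample.int(n_otus, extra, replace = TRUE,
                                     prob = w), levels = seq_len(n_otus)))
      alloc <- alloc + as.integer(add)
    }
    otu_of <- rep(seq_len(n_otus), alloc)
    seqs <- vapply(otu_of, function(i)
      paste(mutate_seq(seeds[[i]], within_otu_divergence / 2),
            collapse = ""), character(1))
    ids <- sprintf("seq%03d", seq_along(seqs))
    samp <- rep_len(samples, length(seqs))
    list(
      sequences = tibble(id = ids, sample = samp, aligned = seqs),
      truth = tibble(id = ids, otu = sprintf("planted%02d", otu_of),
                     sample = samp)
    )
  })
}

#' Write a synthetic-data bundle to disk
#'
#' Emits the simulated inputs as plain-text files under one directory:
#' incubation and qPCR tables as TSV, sequences as aligned FASTA, the
#' OTU truth table as TSV, plus a JSON manifest recording the generating
#' configuration and seed. Re-running with the same inputs reproduces
#' the files byte for byte.
#'
#' @param dir Output directory (created if needed).
#' @param incubations,qpcr Optional tibbles from [sim_incubations()] /
#'   [sim_qpcr_series()].
#' @param sequences Optional list from [sim_dsrb_sequences()].
#' @param config List recorded in the manifest.
#' @param seed Seed recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_sim_bundle <- function(dir, incubations = NULL, qpcr = NULL,
                             sequences = NULL, config = list(),
                             seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wtsv <- function(x, f) {
    p <- file.path(dir, f)
    readr::write_tsv(x, p)
    p
  }
  if (!is.null(incubations)) paths <- c(paths, wtsv(incubations, "incubations.tsv"))
  if (!is.null(qpcr)) paths <- c(paths, wtsv(qpcr, "qpcr.tsv"))
  if (!is.null(sequences)) {
    fa <- file.path(dir, "sequences.fasta")
    dna <- Biostrings::DNAStringSet(sequences$sequences$aligned)
    names(dna) <- sequences$sequences$id
    Biostrings::writeXStringSet(dna, fa)
    paths <- c(paths, fa, wtsv(sequences$truth, "truth.tsv"),
               wtsv(select(sequences$sequences, "id", "sample"),
                    "membership.tsv"))
  }
  man <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(config = config, seed = seed,
                            files = basename(paths)),
                       man, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, man))
}
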