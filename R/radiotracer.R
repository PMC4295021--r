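# Sulfate reduction rates from 35S radiotracer incubations: the
# distillation rate equation, minimum detection limits from pooled count
# backgrounds, replicate aggregation, apparent temperature optima, and
# amendment comparisons.

#' Count-rate background model
#'
#' The background sources that contribute to the reduced-sulfur (TRIS)
#' count rate of a distilled sample: scintillation-counter background,
#' distillation blank, unreduced-tracer carryover blank, and the count
#' rate attributable to hypothetical contamination of the sample with
#' bottom seawater. All in counts per minute.
#'
#' @param counter,distillation,tracer,seawater Background count rates
#'   (cpm, all >= 0).
#' @return An object of class `background_model`.
#' @export
background_model <- function(counter = 0, distillation = 0, tracer = 0,
                             seawater = 0) {
  v <- c(counter = counter, distillation = distillation, tracer = tracer,
         seawater = seawater)
  if (any(!is.finite(v)) || any(v < 0))
    .stopf("background count rates must be finite and >= 0")
  structure(as.list(v), class = "background_model")
}

.background_sum <- function(background) {
  background$counter + background$distillation + background$tracer +
    background$seawater
}

#' Sulfate reduction rates from incubation count data
#'
#' Applies the single-step chromium distillation rate equation to each
#' incubation vial:
#' \deqn{SRR = [SO_4] \times 1.06 \times a_{TRIS} / (a_{TOT} \times t)}
#' with the sulfate pool in nmol/ml (mM x 1000), 1.06 the correction for
#' the kinetic fractionation of 35S vs 32S, `a_TRIS` the blank-corrected
#' reduced-sulfur count rate (TRIS counts minus the summed backgrounds,
#' clamped at zero) and `a_TOT` the counter-corrected total tracer count
#' rate. With `mode = "endpoint"` each replicate's rate comes from its
#' final time point; with `mode = "timecourse"` the reduced fraction
#' `a_TRIS/a_TOT` is regressed on time through the origin and the slope
#' converted to a rate.
#'
#' @param incubations Tibble of incubation records with columns
#'   `temperature_C`, `amendment`, `replicate`, `duration_d`, `tris_cpm`,
#'   `total_cpm`, `counting_time_min` (and optionally `borehole`).
#' @param sulfate_mM Sulfate concentration of the incubated fluid (mM).
#' @param background A [background_model()].
#' @param fractionation 35S/32S fractionation correction factor.
#' @param k Detection-limit multiplier passed to [detection_limit()].
#' @param mode Endpoint or time-course rate estimation.
#' @return A tibble with one row per (temperature, amendment, replicate):
#'   `rate_nmol_ml_d`, `mdl_nmol_ml_d`, `above_detection`, plus the
#'   grouping columns.
#' @export
compute_srr <- function(incubations, sulfate_mM,
                        background = background_model(),
                        fractionation = 1.06, k = 3,
                        mode = c("endpoint", "timecourse")) {
  mode <- match.arg(mode)
  inc <- as_tibble(incubations)
  need <- c("temperature_C", "amendment", "replicate", "duration_d",
            "tris_cpm", "total_cpm", "counting_time_min")
  miss <- setdiff(need, names(inc))
  if (length(miss)) .stopf("incubations lack columns: %s",
                           paste(miss, collapse = ", "))
  if (any(inc$duration_d <= 0)) .stopf("incubation duration must be > 0")
  if (sulfate_mM <= 0) .stopf("sulfate concentration must be > 0")
  if (any(inc$tris_cpm < 0 | inc$total_cpm < 0))
    .stopf("count rates must be >= 0")

  s_nmol_ml <- sulfate_mM * 1000
  bsum <- .background_sum(background)

  grp_cols <- intersect(c("borehole", "temperature_C", "amendment",
                          "replicate"), names(inc))
  inc %>%
    group_by(dplyr::across(dplyr::all_of(grp_cols))) %>%
    dplyr::group_modify(function(d, key) {
      d <- arrange(d, .data$duration_d)
      tot_corr <- d$total_cpm - background$counter
      if (any(tot_corr <= 0))
        .stopf("corrected total counts <= 0 (tracer accounting failure)")
      tris_corr <- pmax(0, d$tris_cpm - bsum)
      if (mode == "endpoint" || nrow(d) == 1L) {
        i <- which.max(d$duration_d)
        rate <- s_nmol_ml * fractionation * tris_corr[i] /
          (tot_corr[i] * d$duration_d[i])
        dur <- d$duration_d[i]; tot <- tot_corr[i]
        ct <- d$counting_time_min[i]
      } else {
        frac <- tris_corr / tot_corr
        slope <- coef(lm(frac ~ 0 + d$duration_d))[[1L]]
        rate <- max(0, s_nmol_ml * fractionation * slope)
        dur <- max(d$duration_d); tot <- tot_corr[which.max(d$duration_d)]
        ct <- d$counting_time_min[which.max(d$duration_d)]
      }
      mdl <- detection_limit(background, sulfate_mM, dur, tot, ct,
                             k = k, fractionation = fractionation)
      tibble(rate_nmol_ml_d = rate, mdl_nmol_ml_d = mdl,
             above_detection = rate > mdl, duration_d = dur)
    }) %>%
    ungroup()
}

#' Minimum detection limit of the rate measurement
#'
#' The rate equivalent of a TRIS count-rate signal equal to
#' B + k sqrt(B / counting_time), where B is the summed background count
#' rate (counter + distillation + tracer + seawater) and
#' sqrt(B / counting_time) its Poisson counting standard error. Passed
#' through the same algebra as [compute_srr()].
#'
#' @param background A [background_model()].
#' @param sulfate_mM Sulfate concentration (mM).
#' @param duration_d Incubation duration (days).
#' @param total_cpm Blank-corrected total tracer count rate (cpm).
#' @param counting_time_min Scintillation counting time (min).
#' @param k Multiplier on the background counting error (default 3).
#' @param fractionation 35S/32S correction factor.
#' @return MDL in nmol/ml/d (vectorized over the numeric arguments).
#' @export
#' @examples
#' detection_limit(background_model(counter = 100), 26.2, 3, 1e7, 10)
detection_limit <- function(background, sulfate_mM, duration_d, total_cpm,
                            counting_time_min = 10, k = 3,
                            fractionation = 1.06) {
  if (any(counting_time_min <= 0)) .stopf("counting time must be > 0")
  if (any(duration_d <= 0) || sulfate_mM <= 0 || any(total_cpm <= 0))
    .stopf("detection_limit inputs must be positive")
  if (k < 0) .stopf("k must be >= 0")
  B <- .background_sum(background)
  signal <- B + k * sqrt(B / counting_time_min)
  sulfate_mM * 1000 * fractionation * signal / (total_cpm * duration_d)
}

#' Aggregate replicate rate measurements
#'
#' Averages replicates within each (temperature, amendment) condition,
#' keeping the measurement range, as plotted in thermal-gradient rate
#' curves (mean of duplicates, min-max envelope).
#'
#' @param rates Tibble from [compute_srr()] (columns `temperature_C`,
#'   `amendment`, `rate_nmol_ml_d`, `mdl_nmol_ml_d`).
#' @return A tibble with one row per condition: mean `rate_nmol_ml_d`,
#'   `rate_min`, `rate_max`, pooled `mdl_nmol_ml_d`, `above_detection`,
#'   `n_replicates`, ordered by temperature.
#' @export
aggregate_replicates <- function(rates) {
  r <- as_tibble(rates)
  if (nrow(r) == 0L) .stopf("no replicate rates to aggregate")
  need <- c("temperature_C", "amendment", "rate_nmol_ml_d")
  miss <- setdiff(need, names(r))
  if (length(miss)) .stopf("rates lack columns: %s",
                           paste(miss, collapse = ", "))
  if (!"mdl_nmol_ml_d" %in% names(r)) r$mdl_nmol_ml_d <- 0
  grp_cols <- intersect(c("borehole", "temperature_C", "amendment"), names(r))
  r %>%
    group_by(dplyr::across(dplyr::all_of(grp_cols))) %>%
    summarise(rate_min = min(.data$rate_nmol_ml_d),
              rate_max = max(.data$rate_nmol_ml_d),
              mdl_nmol_ml_d = mean(.data$mdl_nmol_ml_d),
              n_replicates = dplyr::n(),
              rate_nmol_ml_d = mean(.data$rate_nmol_ml_d),
              .groups = "drop") %>%
    mutate(above_detection = .data$rate_nmol_ml_d > .data$mdl_nmol_ml_d) %>%
    select(dplyr::all_of(grp_cols), "rate_nmol_ml_d", "rate_min", "rate_max",
           "mdl_nmol_ml_d", "above_detection", "n_replicates") %>%
    arrange(dplyr::across(dplyr::all_of(grp_cols)))
}

#' Apparent temperature optima of a rate-vs-temperature curve
#'
#' Finds all strict local maxima of the rate curve: interior grid points
#' exceeding both neighbors, plateaus reported at their lowest
#' temperature, and endpoints that exceed their single interior neighbor
#' (peaks of rising segments at the grid edge count as optima). Points
#' below detection are excluded when the curve carries an
#' `above_detection` column. The global maximum is flagged.
#'
#' @param curve Tibble with columns `temperature_C` and a rate column
#'   (`rate_nmol_ml_d` or `rate`), e.g. from [aggregate_replicates()] or
#'   [sim_thermal_profile()].
#' @return A tibble of optima: `temperature_C`, `rate_nmol_ml_d`,
#'   `global`.
#' @export
find_topt <- function(curve) {
  cv <- as_tibble(curve)
  rate_col <- intersect(c("rate_nmol_ml_d", "rate"), names(cv))[1]
  if (is.na(rate_col) || !"temperature_C" %in% names(cv))
    .stopf("curve needs temperature_C and a rate column")
  cv <- arrange(cv, .data$temperature_C)
  if (anyDuplicated(cv$temperature_C))
    .stopf("temperatures must be strictly increasing")
  if (nrow(cv) < 3L) .stopf("need at least 3 curve points to find optima")
  r <- cv[[rate_col]]

  # collapse equal-rate runs so plateaus are single candidates
  runs <- rle(r)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  v <- runs$values
  nr <- length(v)
  is_max <- vapply(seq_len(nr), function(j) {
    left_ok <- j == 1L || v[j - 1L] < v[j]
    right_ok <- j == nr || v[j + 1L] < v[j]
    left_ok && right_ok
  }, logical(1))

  out <- tibble(temperature_C = cv$temperature_C[starts[is_max]],
                rate_nmol_ml_d = v[is_max])
  if ("above_detection" %in% names(cv)) {
    det <- cv$above_detection[starts[is_max]]
    out <- out[det, ]
  }
  if (nrow(out) == 0L) return(mutate(out, global = logical(0)))
  mutate(out, global = .data$rate_nmol_ml_d == max(.data$rate_nmol_ml_d))
}

#' Pointwise rate ratio between two amendment conditions
#'
#' Ratio of curve A over curve B at each shared grid temperature where
#' both measurements are above detection; other points are omitted.
#'
#' @param curve_a,curve_b Aggregated rate curves ([aggregate_replicates()]
#'   output) on a shared temperature grid.
#' @return A tibble of `temperature_C` and `ratio`.
#' @export
amendment_ratio <- function(curve_a, curve_b) {
  a <- as_tibble(curve_a); b <- as_tibble(curve_b)
  shared <- intersect(a$temperature_C, b$temperature_C)
  if (length(shared) == 0L) .stopf("curves share no temperature grid points")
  a <- filter(a, .data$temperature_C %in% shared)
  b <- filter(b, .data$temperature_C %in% shared)
  if (!"above_detection" %in% names(a)) a$above_detection <- TRUE
  if (!"above_detection" %in% names(b)) b$above_detection <- TRUE
  j <- inner_join(
    select(a, "temperature_C", rate_a = "rate_nmol_ml_d",
           det_a = "above_detection"),
    select(b, "temperature_C", rate_b = "rate_nmol_ml_d",
           det_b = "above_detection"),
    by = "temperature_C")
  j %>%
    filter(.data$det_a, .data$det_b) %>%
    mutate(ratio = .data$rate_a / .data$rate_b) %>%
    select("temperature_C", "ratio") %>%
    arrange(.data$temperature_C)
}
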