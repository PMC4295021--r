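# qPCR-based abundance of sulfate reducers, cell-specific respiration
# rates, stoichiometric carbon mineralization, and the comparison with
# recharge-based DOC removal estimates.

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Cq against log10(copies) over a dilution series.
#' Amplification efficiency is derived from the slope as
#' E = 10^(-1/slope) - 1 (a perfect-doubling chemistry has slope
#' -1/log10(2) = -3.3219 and E = 1).
#'
#' @param points Tibble/data frame with columns `copies` (template copies
#'   per reaction) and `cq` (quantification cycle), e.g. from
#'   [sim_qpcr_series()]. At least 3 distinct copy levels are required.
#' @param r_squared_warn Warn when the fit's R-squared falls below this
#'   threshold (default 0.98).
#' @return An object of class `standard_curve` with fields `slope`
#'   (cycles per log10 copies), `intercept` (cycles), `efficiency`
#'   (fraction), `r_squared`, `n_points`, `cq_range`, and the underlying
#'   `lm` fit. Supports [tidy()], [glance()] and `autoplot()`.
#' @export
#' @examples
#' fit_standard_curve(sim_qpcr_series(efficiency = 0.9))
fit_standard_curve <- function(points, r_squared_warn = 0.98) {
  p <- as_tibble(points)
  if (!all(c("copies", "cq") %in% names(p)))
    .stopf("points need copies and cq columns")
  if (any(p$copies <= 0)) .stopf("copies must be > 0")
  if (length(unique(p$copies)) < 3L)
    .stopf("standard curve needs >= 3 distinct copy levels")
  fit <- lm(cq ~ log10(copies), data = p)
  slope <- coef(fit)[[2L]]
  intercept <- coef(fit)[[1L]]
  if (!is.finite(slope) || slope >= -1e-8)
    .stopf("standard-curve slope must be negative (got %.4g)", slope)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noiseless fits are exact
  if (is.nan(r2)) r2 <- 1  # zero-noise series: no residual variance
  if (r2 < r_squared_warn)
    warn(sprintf("standard curve r^2 = %.4f below %.2f", r2, r_squared_warn))
  structure(list(slope = slope, intercept = intercept,
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = r2, n_points = nrow(p),
                 cq_range = range(p$cq), fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.4f cycles/log10(copies), intercept %.2f,\n  efficiency %.3f, r^2 %.4f, n = %d\n",
    x$slope, x$intercept, x$efficiency, x$r_squared, x$n_points))
  invisible(x)
}

#' Tidy a qPCR standard curve
#'
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @return A tibble with one row per fit term (`term`, `estimate`).
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' One-row summary of a qPCR standard curve
#'
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `efficiency`,
#'   `r_squared`, `n_points`.
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         efficiency = x$efficiency, r_squared = x$r_squared,
         n_points = x$n_points)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Volume normalization chain for qPCR quantification
#'
#' Converts copies per reaction to copies per ml of sampled fluid:
#' copies/ml = copies/reaction x (extract_ul / template_ul) /
#' filtered_ml.
#'
#' @param template_ul Template volume per qPCR reaction (ul).
#' @param extract_ul Total DNA-extract volume (ul).
#' @param filtered_ml Fluid volume filtered for the extraction (ml).
#' @param copies_per_cell Assumed marker-gene copies per cell (each
#'   sulfate-reducing cell is assumed to carry one dsrAB copy).
#' @return A list of class `volume_factors`.
#' @export
volume_factors <- function(template_ul = 1, extract_ul = 50,
                           filtered_ml = 1000, copies_per_cell = 1) {
  if (template_ul <= 0 || extract_ul <= 0 || filtered_ml <= 0 ||
      copies_per_cell <= 0)
    .stopf("volume factors must be > 0")
  structure(list(template_ul = template_ul, extract_ul = extract_ul,
                 filtered_ml = filtered_ml,
                 copies_per_cell = copies_per_cell),
            class = "volume_factors")
}

#' Quantify gene and cell abundance from Cq values
#'
#' Inverts the standard curve, copies = 10^((cq - intercept)/slope), and
#' applies the volume normalization chain; cell abundance follows from
#' the assumed copies per cell. Replicate reactions of the same sample
#' (a `replicate` column or repeated `sample` labels) are aggregated by
#' mean Cq first, with the SD retained. Cq values outside the calibrated
#' range +/- 2 cycles are flagged `extrapolated` with a warning rather
#' than rejected.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param data Tibble with columns `sample` and `cq`, or a bare numeric
#'   vector of Cq values.
#' @param volumes A [volume_factors()].
#' @return A tibble with one row per sample: `sample`, `cq` (mean),
#'   `cq_sd`, `n_reactions`, `copies_per_rxn`, `copies_per_ml`,
#'   `cells_per_ml`, `extrapolated`.
#' @export
quantify <- function(curve, data, volumes = volume_factors()) {
  stopifnot(inherits(curve, "standard_curve"),
            inherits(volumes, "volume_factors"))
  if (is.numeric(data))
    data <- tibble(sample = sprintf("sample%02d", seq_along(data)), cq = data)
  d <- as_tibble(data)
  if (!all(c("sample", "cq") %in% names(d)))
    .stopf("data needs sample and cq columns")
  agg <- d %>%
    group_by(.data$sample) %>%
    summarise(cq_sd = stats::sd(.data$cq), n_reactions = dplyr::n(),
              cq = mean(.data$cq), .groups = "drop")
  lo <- curve$cq_range[1] - 2; hi <- curve$cq_range[2] + 2
  out <- agg %>%
    mutate(
      copies_per_rxn = 10^((.data$cq - curve$intercept) / curve$slope),
      copies_per_ml = .data$copies_per_rxn *
        (volumes$extract_ul / volumes$template_ul) / volumes$filtered_ml,
      cells_per_ml = .data$copies_per_ml / volumes$copies_per_cell,
      extrapolated = .data$cq < lo | .data$cq > hi) %>%
    select("sample", "cq", "cq_sd", "n_reactions", "copies_per_rxn",
           "copies_per_ml", "cells_per_ml", "extrapolated")
  if (any(out$extrapolated))
    warn(sprintf("%d sample(s) outside the calibrated Cq range +/- 2 cycles",
                 sum(out$extrapolated)))
  out
}

#' Cell-specific sulfate reduction rate
#'
#' Rate per cell in fmol/cell/d: (srr / cells_per_ml) x 1e6
#' (nmol/ml -> fmol/cell given cells/ml).
#'
#' @param srr Bulk sulfate reduction rate (nmol/ml/d, >= 0).
#' @param cells_per_ml Cell abundance (cells/ml, > 0).
#' @return Cell-specific rate (fmol/cell/d), vectorized.
#' @export
#' @examples
#' cell_specific_srr(0.05, 1.6e4)
cell_specific_srr <- function(srr, cells_per_ml) {
  if (any(srr < 0)) .stopf("srr must be >= 0")
  if (any(cells_per_ml <= 0)) .stopf("cells_per_ml must be > 0")
  srr / cells_per_ml * 1e6
}

#' Carbon mineralization rate from sulfate reduction
#'
#' Organic carbon mineralized per unit sulfate reduced, assuming
#' `c_per_sulfate` moles of organic carbon oxidized per mole of sulfate
#' (default 2, the canonical organotrophic stoichiometry).
#'
#' @param srr Sulfate reduction rate (nmol/ml/d, >= 0).
#' @param c_per_sulfate Moles organic C per mole sulfate (> 0).
#' @return Carbon mineralization rate (nmol C/ml/d), vectorized.
#' @export
#' @examples
#' carbon_mineralization(c(0.05, 0.01))
carbon_mineralization <- function(srr, c_per_sulfate = 2) {
  if (any(srr < 0)) .stopf("srr must be >= 0")
  if (any(c_per_sulfate <= 0)) .stopf("c_per_sulfate must be > 0")
  srr * c_per_sulfate
}

#' Orders-of-magnitude excess over a DOC-removal reference
#'
#' log10 of the sulfate-driven carbon mineralization rate over a
#' recharge-based net DOC removal rate.
#'
#' @param c_mineralization Carbon mineralization rate (nmol/ml/d, > 0).
#' @param reference Reference DOC removal rate (nmol/ml/d, > 0).
#' @return log10 excess (dimensionless), vectorized.
#' @export
#' @examples
#' doc_removal_comparison(0.1, 6.0e-6)
doc_removal_comparison <- function(c_mineralization, reference) {
  if (any(c_mineralization <= 0) || any(reference <= 0))
    .stopf("rates must be > 0 for a log comparison")
  log10(c_mineralization / reference)
}
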