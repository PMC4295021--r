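#' Bundled borehole fluid chemistry
#'
#' Returns the bundled chemical composition of basement fluids from the two
#' CORK observatories on the Juan de Fuca Ridge flank (boreholes 1025C,
#' 1.2 Myr crust at 39 degC, and U1301A, 3.5 Myr crust at 63 degC), as a
#' long tibble of analyte concentrations with physical state rows
#' (depth, pressure, temperature, pH).
#'
#' @param borehole Optional borehole id to filter on (`"1025C"` or
#'   `"U1301A"`).
#' @return A tibble with columns `borehole`, `analyte`, `species`
#'   (thermodynamic species code, `NA` for non-species analytes), `value`
#'   and `unit`.
#' @export
#' @examples
#' fluid_chemistry("1025C")
fluid_chemistry <- function(borehole = NULL) {
  tab <- readr::read_tsv(crustflux_extdata("fluid_chemistry.tsv"),
                         col_types = readr::cols(
                           borehole = "c", analyte = "c", species = "c",
                           value = "d", unit = "c"),
                         na = "NA", progress = FALSE)
  if (!is.null(borehole)) {
    bh <- borehole
    tab <- filter(tab, .data$borehole %in% bh)
    if (nrow(tab) == 0L) .stopf("unknown borehole: %s", paste(bh, collapse = ", "))
  }
  tab
}

#' Bundled aqueous species properties
#'
#' Charge and Debye-Huckel ion-size parameter for the aqueous species used
#' by the activity and ionic-strength calculations.
#'
#' @return A tibble with columns `species`, `charge`, `ion_size_A`, `note`.
#' @export
species_table <- function() {
  readr::read_tsv(crustflux_extdata("species.tsv"),
                  col_types = readr::cols(
                    species = "c", charge = "d", ion_size_A = "d",
                    note = "c"),
                  progress = FALSE)
}

#' Assemble a fluid sample for thermodynamic calculations
#'
#' Converts a borehole's chemistry to molality-scale concentrations
#' (mol per kg fluid; molarity is treated as molality, an error below the
#' measurement uncertainty at these conditions) and applies the organic
#' matter and sulfide conventions needed by the sulfate-acetate energetics:
#'
#' * dissolved organic carbon (DOC, uM carbon) is mapped to the acetate
#'   proxy either per carbon atom (`doc_as_acetate = "per_carbon"`,
#'   DOC/2 since acetate carries two carbons; the default) or per molecule
#'   (`"per_molecule"`, DOC taken as acetate molarity directly);
#' * alkalinity (meq/L) is taken as bicarbonate molality (the carbonate
#'   system dominates alkalinity in these fluids);
#' * sulfide below detection is floored at `sulfide_floor` mol/kg so the
#'   reaction quotient stays finite.
#'
#' @param borehole Borehole id present in `chemistry`.
#' @param chemistry Long chemistry tibble as returned by
#'   [fluid_chemistry()].
#' @param doc_as_acetate DOC-to-acetate conversion convention.
#' @param sulfide_floor Minimum bisulfide molality (mol/kg) substituted for
#'   undetected sulfide.
#' @return An object of class `fluid_sample`: a list with `borehole`,
#'   `depth_m`, `pressure_kPa`, `temperature_C`, `pH`, `doc_uM`, and
#'   `concentrations`, a tibble of `species` and `molality` (mol/kg).
#' @export
#' @examples
#' fs <- fluid_sample("1025C")
#' fs$temperature_C
fluid_sample <- function(borehole,
                         chemistry = fluid_chemistry(),
                         doc_as_acetate = c("per_carbon", "per_molecule"),
                         sulfide_floor = 1e-9) {
  doc_as_acetate <- match.arg(doc_as_acetate)
  tab <- filter(chemistry, .data$borehole == !!borehole)
  if (nrow(tab) == 0L) .stopf("unknown borehole: %s", borehole)

  grab <- function(an) {
    v <- tab$value[tab$analyte == an]
    if (length(v) == 0L) NA_real_ else v[[1L]]
  }

  to_molal <- function(value, unit) {
    switch(unit,
           "mM"    = value * 1e-3,
           "uM"    = value * 1e-6,
           "meq/L" = value * 1e-3,  # monovalent carbonate alkalinity
           .stopf("unhandled concentration unit: %s", unit))
  }

  conc <- tab %>%
    filter(!is.na(.data$species)) %>%
    mutate(molality = mapply(to_molal, .data$value, .data$unit)) %>%
    group_by(.data$species) %>%
    summarise(molality = sum(.data$molality), .groups = "drop")

  doc_uM <- grab("DOC")
  acetate <- if (is.na(doc_uM)) 0 else switch(doc_as_acetate,
    per_carbon   = doc_uM / 2 * 1e-6,
    per_molecule = doc_uM * 1e-6)
  conc <- bind_rows(conc, tibble(species = "CH3COO-", molality = acetate)) %>%
    group_by(.data$species) %>%
    summarise(molality = sum(.data$molality), .groups = "drop")

  conc$molality[conc$species == "HS-"] <-
    pmax(conc$molality[conc$species == "HS-"], sulfide_floor)

  if (any(conc$molality < 0)) .stopf("negative concentration in %s", borehole)

  structure(list(
    borehole = borehole,
    depth_m = grab("seafloor_depth"),
    pressure_kPa = grab("pressure"),
    temperature_C = grab("temperature"),
    pH = grab("pH"),
    doc_uM = doc_uM,
    doc_as_acetate = doc_as_acetate,
    sulfide_floor = sulfide_floor,
    concentrations = conc
  ), class = "fluid_sample")
}

#' @export
print.fluid_sample <- function(x, ...) {
  cat(sprintf("<fluid_sample> %s: %.0f degC, pH %.1f, %.0f kPa\n",
              x$borehole, x$temperature_C, x$pH, x$pressure_kPa))
  print(x$concentrations, n = Inf)
  invisible(x)
}
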