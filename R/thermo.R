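# Gibbs-energy bioenergetics of organotrophic sulfate reduction:
# ionic strength -> B-dot activity coefficients -> reaction quotient ->
# dGr = dGr0 + RT ln Q, and energy density per kg fluid via the limiting
# reactant.

#' Canonical organotrophic sulfate reduction reaction
#'
#' Acetate as the organic-matter proxy, completely oxidized by sulfate:
#' CH3COO- + SO4-- -> 2 HCO3- + HS-. Reactants carry negative
#' coefficients.
#'
#' @return A `reaction_spec` object.
#' @export
sulfate_acetate_reaction <- function() {
  reaction_spec(c("CH3COO-" = -1, "SO4--" = -1, "HCO3-" = 2, "HS-" = 1),
                name = "acetate_sulfate")
}

#' Define a reaction by its stoichiometry
#'
#' @param stoichiometry Named numeric vector of signed stoichiometric
#'   coefficients (reactants negative, products positive), names being
#'   species codes from [species_table()].
#' @param name Reaction label.
#' @return A `reaction_spec` object (validated for charge balance).
#' @export
reaction_spec <- function(stoichiometry, name = "reaction") {
  if (length(stoichiometry) > 0) {
    if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
      .stopf("stoichiometry must be a named vector")
    sp <- species_table()
    miss <- setdiff(names(stoichiometry), sp$species)
    if (length(miss)) .stopf("species not in bundled table: %s",
                             paste(miss, collapse = ", "))
    z <- sp$charge[match(names(stoichiometry), sp$species)]
    bal <- sum(stoichiometry * z)
    if (abs(bal) > 1e-9) .stopf("reaction '%s' is not charge balanced (net %g)",
                                name, bal)
  }
  structure(list(stoichiometry = stoichiometry, name = name),
            class = "reaction_spec")
}

#' @export
print.reaction_spec <- function(x, ...) {
  s <- x$stoichiometry
  lhs <- s[s < 0]; rhs <- s[s > 0]
  term <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                   paste0(abs(v), " ", names(v))),
                            collapse = " + ")
  cat(sprintf("<reaction_spec> %s: %s -> %s\n", x$name, term(lhs), term(rhs)))
  invisible(x)
}

#' Ionic strength of a fluid
#'
#' I = 1/2 sum(c_i z_i^2) over the charged species of the sample, on the
#' molality scale.
#'
#' @param concentrations A `fluid_sample`, or a tibble/data frame with
#'   columns `species` and `molality` (mol/kg).
#' @return Ionic strength in mol/kg.
#' @export
#' @examples
#' ionic_strength(fluid_sample("U1301A"))
ionic_strength <- function(concentrations) {
  conc <- if (inherits(concentrations, "fluid_sample"))
    concentrations$concentrations else as_tibble(concentrations)
  if (nrow(conc) == 0L) return(0)
  sp <- species_table()
  idx <- match(conc$species, sp$species)
  if (anyNA(idx)) .stopf("unknown species charge: %s",
                         paste(conc$species[is.na(idx)], collapse = ", "))
  sum(conc$molality * sp$charge[idx]^2) / 2
}

#' Extended Debye-Huckel (B-dot) activity model
#'
#' Bundles the temperature-dependent Debye-Huckel A and B parameters and
#' the B-dot term (interpolated between tabulated nodes) together with the
#' per-species ion-size parameters.
#'
#' @return An object of class `bdot_model`.
#' @export
bdot_model <- function() {
  dh <- readr::read_tsv(crustflux_extdata("debye_huckel.tsv"),
                        col_types = "dddd", progress = FALSE)
  structure(list(
    A = splinefun(dh$temperature_C, dh$debye_A, method = "monoH.FC"),
    B = splinefun(dh$temperature_C, dh$debye_B, method = "monoH.FC"),
    bdot = splinefun(dh$temperature_C, dh$bdot, method = "monoH.FC"),
    t_range = range(dh$temperature_C),
    species = species_table()
  ), class = "bdot_model")
}

#' Individual ion activity coefficients
#'
#' Extended Debye-Huckel with B-dot correction:
#' log10(gamma) = -A z^2 sqrt(I) / (1 + a0 B sqrt(I)) + bdot I.
#' Neutral species are assigned gamma = 1.
#'
#' @param species Character vector of species codes.
#' @param ionic_strength_m Ionic strength, mol/kg.
#' @param temperature_C Temperature in degrees Celsius.
#' @param model A [bdot_model()].
#' @return Numeric vector of activity coefficients, one per species.
#' @export
#' @examples
#' activity_coefficient("Na+", 0.7, 25)
activity_coefficient <- function(species, ionic_strength_m, temperature_C,
                                 model = bdot_model()) {
  if (ionic_strength_m < 0) .stopf("ionic strength must be >= 0")
  tr <- model$t_range
  if (temperature_C < tr[1] || temperature_C > tr[2])
    .stopf("temperature %.1f degC outside activity-model range [%g, %g]",
           temperature_C, tr[1], tr[2])
  idx <- match(species, model$species$species)
  if (anyNA(idx)) .stopf("no ion-size parameter for species: %s",
                         paste(species[is.na(idx)], collapse = ", "))
  z <- model$species$charge[idx]
  a0 <- model$species$ion_size_A[idx]
  A <- model$A(temperature_C); B <- model$B(temperature_C)
  bd <- model$bdot(temperature_C)
  sqI <- sqrt(ionic_strength_m)
  log10g <- ifelse(z == 0, 0,
                   -A * z^2 * sqI / (1 + a0 * B * sqI) + bd * ionic_strength_m)
  10^log10g
}

#' Standard-state Gibbs energy of the bundled reaction
#'
#' Interpolates the bundled reference table of dGr0(T) for the
#' acetate-sulfate reaction at a nominal 27 MPa, using a monotone cubic
#' spline through 5 degC nodes (node queries reproduce the table exactly).
#'
#' @param temperature_C Temperatures in degrees Celsius, within the table
#'   range (0-100 degC).
#' @param reaction A `reaction_spec`; only the bundled acetate-sulfate
#'   reaction (or an empty reaction, which returns 0) is supported.
#' @return dGr0 in kJ/mol, one value per temperature.
#' @export
#' @examples
#' standard_gibbs(25)
standard_gibbs <- function(temperature_C,
                           reaction = sulfate_acetate_reaction()) {
  if (length(reaction$stoichiometry) == 0L)
    return(rep(0, length(temperature_C)))
  canon <- sulfate_acetate_reaction()$stoichiometry
  s <- reaction$stoichiometry[order(names(reaction$stoichiometry))]
  canon <- canon[order(names(canon))]
  if (!identical(names(s), names(canon)) || any(s != canon))
    .stopf("no bundled standard-state table for reaction '%s'", reaction$name)
  tab <- readr::read_tsv(crustflux_extdata("dgr0_acetate_sulfate.tsv"),
                         col_types = "dd", progress = FALSE)
  rng <- range(tab$temperature_C)
  if (any(temperature_C < rng[1] | temperature_C > rng[2]))
    .stopf("temperature outside bundled dGr0 table range [%g, %g] degC",
           rng[1], rng[2])
  f <- splinefun(tab$temperature_C, tab$dgr0_kJ_mol, method = "monoH.FC")
  f(temperature_C)
}

#' Reaction quotient
#'
#' Q = prod(a_i ^ nu_i) over the reaction species.
#'
#' @param reaction A `reaction_spec`.
#' @param activities Named numeric vector of species activities
#'   (dimensionless, all > 0).
#' @return The reaction quotient (dimensionless).
#' @export
reaction_quotient <- function(reaction, activities) {
  s <- reaction$stoichiometry
  if (length(s) == 0L) return(1)
  a <- activities[names(s)]
  if (anyNA(a)) .stopf("missing activity for: %s",
                       paste(names(s)[is.na(a)], collapse = ", "))
  if (any(a <= 0)) .stopf("non-positive activity for: %s",
                          paste(names(s)[a <= 0], collapse = ", "))
  prod(a^s)
}

#' Limiting reactant of a reaction in a fluid
#'
#' The reactant with the lowest concentration after accounting for
#' stoichiometry (argmin of c_i / |nu_i|). Ties resolve to the first
#' reactant in the reaction's species order.
#'
#' @param reaction A `reaction_spec`.
#' @param sample A `fluid_sample` or tibble of `species`/`molality`.
#' @return Species code of the limiting reactant.
#' @export
limiting_reactant <- function(reaction, sample) {
  conc <- if (inherits(sample, "fluid_sample"))
    sample$concentrations else as_tibble(sample)
  s <- reaction$stoichiometry
  reactants <- names(s)[s < 0]
  if (length(reactants) == 0L) .stopf("reaction has no reactants")
  c_r <- conc$molality[match(reactants, conc$species)]
  if (anyNA(c_r)) .stopf("missing concentration for reactant: %s",
                         paste(reactants[is.na(c_r)], collapse = ", "))
  if (all(c_r == 0)) .stopf("all reactant concentrations are zero")
  scaled <- c_r / abs(s[reactants])
  reactants[which.min(scaled)]
}

#' Gibbs energy and catabolic energy density in a fluid
#'
#' Composes ionic strength, B-dot activity coefficients, the reaction
#' quotient and the bundled standard-state table into
#' dGr = dGr0 + RT ln(Q), then normalizes per kg of fluid by the limiting
#' reactant: energy_density = -dGr * c_lim / |nu_lim| (J per kg fluid,
#' positive when the reaction is exergonic).
#'
#' @param sample A `fluid_sample`.
#' @param temperature_C Evaluation temperature; defaults to the sample's
#'   in situ temperature.
#' @param reaction A `reaction_spec` (bundled acetate-sulfate by default).
#' @param model A [bdot_model()].
#' @return A one-row tibble: `borehole`, `temperature_C`, `delta_g0_kJ_mol`,
#'   `q_r`, `delta_g_kJ_mol`, `limiting_species`, `energy_density_J_kg`.
#' @export
#' @examples
#' gibbs_energy(fluid_sample("1025C"))
gibbs_energy <- function(sample, temperature_C = sample$temperature_C,
                         reaction = sulfate_acetate_reaction(),
                         model = bdot_model()) {
  stopifnot(inherits(sample, "fluid_sample"), length(temperature_C) == 1L)
  conc <- sample$concentrations
  s <- reaction$stoichiometry
  miss <- setdiff(names(s), conc$species)
  if (length(miss)) .stopf("sample %s lacks concentrations for: %s",
                           sample$borehole, paste(miss, collapse = ", "))
  I <- ionic_strength(sample)
  gam <- activity_coefficient(names(s), I, temperature_C, model)
  m <- conc$molality[match(names(s), conc$species)]
  act <- setNames(gam * m, names(s))
  q <- reaction_quotient(reaction, act)
  dg0 <- standard_gibbs(temperature_C, reaction)
  tk <- temperature_C + 273.15
  dg <- dg0 + .R_KJ * tk * log(q)
  lim <- limiting_reactant(reaction, sample)
  # kJ/mol * mol/kg -> kJ/kg; report J/kg
  edens <- -dg * conc$molality[conc$species == lim] / abs(s[[lim]]) * 1000
  tibble(borehole = sample$borehole, temperature_C = temperature_C,
         delta_g0_kJ_mol = dg0, q_r = q, delta_g_kJ_mol = dg,
         limiting_species = lim, energy_density_J_kg = edens)
}

#' Energy density as a function of temperature
#'
#' Evaluates [gibbs_energy()] at each requested temperature with the fluid
#' composition held fixed, yielding the energy-vs-temperature curve for a
#' borehole.
#'
#' @inheritParams gibbs_energy
#' @param temperatures Numeric vector of temperatures (degC).
#' @return A tibble with one row per temperature (possibly empty).
#' @export
#' @examples
#' energy_density_curve(fluid_sample("1025C"), c(10, 39, 86))
energy_density_curve <- function(sample, temperatures,
                                 reaction = sulfate_acetate_reaction(),
                                 model = bdot_model()) {
  if (length(temperatures) == 0L)
    return(gibbs_energy(sample, sample$temperature_C, reaction, model)[0, ])
  purrr::map_dfr(temperatures, function(t)
    gibbs_energy(sample, t, reaction, model))
}
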