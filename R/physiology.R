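#' Reference physiology
#'
#' Organ blood flows, organ-site CYP3A abundances, hematocrit, and body
#' weight for a reference adult. Abundances are dimensionless relative
#' scalars: 1 is the population reference expressor level at that organ
#' site, and a CYP3A5 non-expressor has all three CYP3A5 abundances equal to
#' 0. The enterocytic flow `q_ent` is the nominal flow term of the
#' flow-limited ("Qgut") intestinal extraction model, not total splanchnic
#' flow.
#'
#' @param hepatic_blood_flow Hepatic blood flow, L/h.
#' @param enterocytic_blood_flow Nominal enterocytic (Qgut) flow, L/h.
#' @param liver_cyp3a4,liver_cyp3a5 Relative hepatic abundances.
#' @param gut_cyp3a4,gut_cyp3a5 Relative small-intestinal abundances.
#' @param colon_cyp3a5 Relative colonic CYP3A5 abundance.
#' @param hematocrit Hematocrit fraction, in (0.1, 0.6).
#' @param body_weight Body weight, kg.
#' @return A `physiology` object (named list).
#' @export
reference_physiology <- function(hepatic_blood_flow = 87,
                                 enterocytic_blood_flow = 18,
                                 liver_cyp3a4 = 1, liver_cyp3a5 = 0,
                                 gut_cyp3a4 = 1, gut_cyp3a5 = 0,
                                 colon_cyp3a5 = 0,
                                 hematocrit = 0.45, body_weight = 70) {
  x <- list(
    hepatic_blood_flow = hepatic_blood_flow,
    enterocytic_blood_flow = enterocytic_blood_flow,
    liver_cyp3a4 = liver_cyp3a4, liver_cyp3a5 = liver_cyp3a5,
    gut_cyp3a4 = gut_cyp3a4, gut_cyp3a5 = gut_cyp3a5,
    colon_cyp3a5 = colon_cyp3a5,
    hematocrit = hematocrit, body_weight = body_weight
  )
  class(x) <- "physiology"
  validate_physiology(x)
}

validate_physiology <- function(x) {
  fail <- function(field, why) {
    abort(sprintf("Invalid physiology field `%s`: %s.", field, why),
          class = "tacswitch_validation_error")
  }
  for (f in c("hepatic_blood_flow", "enterocytic_blood_flow", "body_weight")) {
    if (!is.numeric(x[[f]]) || x[[f]] <= 0) fail(f, "must be > 0")
  }
  for (f in c("liver_cyp3a4", "liver_cyp3a5", "gut_cyp3a4", "gut_cyp3a5",
              "colon_cyp3a5")) {
    if (!is.numeric(x[[f]]) || x[[f]] < 0) fail(f, "must be >= 0")
  }
  if (x$hematocrit <= 0.1 || x$hematocrit >= 0.6) {
    fail("hematocrit", "must lie in (0.1, 0.6)")
  }
  x
}

## Physiology for one row of a population tibble; engine-facing.
individual_physiology <- function(individual,
                                  base = reference_physiology()) {
  ind <- as.list(individual)
  for (f in c("liver_cyp3a4", "liver_cyp3a5", "gut_cyp3a4", "gut_cyp3a5",
              "colon_cyp3a5", "hematocrit")) {
    if (!is.null(ind[[f]]) && !is.na(ind[[f]])) base[[f]] <- ind[[f]]
  }
  if (!is.null(ind$weight) && !is.na(ind$weight)) base$body_weight <- ind$weight
  validate_physiology(base)
}
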