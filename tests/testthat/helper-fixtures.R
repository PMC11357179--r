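## Deterministic individuals (no sampled variability).
ref_individual <- function(liver5 = 0, gut5 = 0, hct = 0.45, weight = 70) {
  tibble::tibble(
    id = 1L, trial = 1L, age = 35, sex = "female",
    weight = weight, height = 165, hematocrit = hct,
    liver_cyp3a4 = 1, liver_cyp3a5 = liver5,
    gut_cyp3a4 = 1, gut_cyp3a5 = gut5, colon_cyp3a5 = gut5,
    expressor_liver = liver5 > 0, expressor_gut = gut5 > 0, ka_mult = 1
  )
}

## A compound with renal-only elimination and one-compartment disposition:
## Fg = Fh = 1, CL = cl_renal, V = vss * weight. Used as the closed-form
## oracle target.
one_cpt_compound <- function(cl = 2, vss = 1, ka = 0.8, fa = 1) {
  compound_params(
    name = "oracle", molecular_weight = 500, fu_plasma = 0.5,
    bp_ratio_ref = 1, hct_ref = 0.45, fa = fa, ka = ka, fu_gut = 1,
    clint_cyp3a4_liver = 0, clint_cyp3a5_liver = 0,
    clint_cyp3a4_gut = 0, clint_cyp3a5_gut = 0,
    cl_renal = cl, vss = vss, k12 = 0, k21 = 0
  )
}

## Closed-form one-compartment concentrations (ng/mL) for repeated oral
## dosing (doses at 0, tau, 2 tau, ... < duration) and for a constant-rate
## infusion started at time 0.
oral_1cpt_conc <- function(t, dose, tau, fa, ka, cl, v) {
  k <- cl / v
  td <- seq(0, max(t), by = tau)
  sapply(t, function(ti) {
    past <- td[td <= ti]
    if (!length(past)) return(0)
    s <- sum(exp(-k * (ti - past)) - exp(-ka * (ti - past)))
    fa * dose * ka / (v * (ka - k)) * s * 1000
  })
}

infusion_1cpt_conc <- function(t, rate, cl, v) {
  k <- cl / v
  rate / cl * (1 - exp(-k * t)) * 1000
}

scaled_reference_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scns <- reference_scenarios(seed = 1, n_trials = 10, n_per_trial = 20)
      scns$twin_liver10 <- scenario(
        "twin_liver10", scns$virtual_twin$population,
        liver_function_fraction = 0.1
      )
      cache <<- run_scenarios(scns)
    }
    cache
  }
})
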