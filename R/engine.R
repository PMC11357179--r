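#' Competitive inhibition multiplier
#'
#' Fractional activity remaining for one enzyme exposed to an unbound
#' inhibitor concentration under reversible competitive inhibition:
#' `1 / (1 + I / Ki)`. Applied multiplicatively to that enzyme's intrinsic
#' clearance wherever it acts.
#'
#' @param i_unbound Unbound inhibitor concentration, ng/mL (>= 0).
#' @param ki Unbound competitive inhibition constant, ng/mL (> 0).
#' @return Multiplier in (0, 1].
#' @examples
#' inhibition_factor(0, 5)    # 1
#' inhibition_factor(5, 5)    # 0.5
#' @export
inhibition_factor <- function(i_unbound, ki) {
  if (any(!is.finite(ki)) || any(ki <= 0)) abort("`ki` must be > 0.")
  if (any(!is.finite(i_unbound)) || any(i_unbound < 0)) {
    abort("`i_unbound` must be >= 0.")
  }
  1 / (1 + i_unbound / ki)
}

#' Intestinal availability (Qgut model)
#'
#' Fraction of the absorbed dose escaping gut-wall CYP3A metabolism under
#' the flow-limited gut-extraction model:
#' `Fg = Q_ent / (Q_ent + fu_gut * CLu_int_gut)` with
#' `CLu_int_gut = clint_cyp3a4_gut * abundance_3A4 * inh_3A4 +
#' clint_cyp3a5_gut * abundance_3A5 * inh_3A5`.
#'
#' @param compound A `compound_params` object.
#' @param physiology A `physiology` object (gut abundances, Qgut flow).
#' @param gut_inhibitor_unbound Inhibitor exposure at the gut site, ng/mL,
#'   as `c(cyp3a4 = ..., cyp3a5 = ...)` or a single number for both.
#' @param ki Inhibition constants `c(cyp3a4 = ..., cyp3a5 = ...)`, ng/mL;
#'   only needed when the exposure is non-zero.
#' @return Fg in (0, 1].
#' @export
gut_availability <- function(compound, physiology = reference_physiology(),
                             gut_inhibitor_unbound = 0, ki = NULL) {
  inh <- site_inhibition(gut_inhibitor_unbound, ki)
  clu <- compound$clint_cyp3a4_gut * physiology$gut_cyp3a4 * inh[["cyp3a4"]] +
    compound$clint_cyp3a5_gut * physiology$gut_cyp3a5 * inh[["cyp3a5"]]
  q <- physiology$enterocytic_blood_flow
  q / (q + compound$fu_gut * clu)
}

#' Hepatic blood clearance and availability (well-stirred model)
#'
#' `CL_h = Q_h * fu_b * CLu_int_H / (Q_h + fu_b * CLu_int_H)` and
#' `Fh = 1 - CL_h / Q_h`, with the unbound blood fraction derived from the
#' individual's hematocrit via [blood_partition()] and
#' `CLu_int_H = sum(clint * abundance * inhibition)` over CYP3A4 and CYP3A5.
#'
#' @inheritParams gut_availability
#' @param hepatic_inhibitor_unbound Unbound inhibitor blood concentration at
#'   the liver, ng/mL, as for `gut_inhibitor_unbound`.
#' @param hematocrit Hematocrit fraction; defaults to the physiology's.
#' @return A list with `cl_h` (L/h, blood) and `fh` in (0, 1].
#' @export
hepatic_clearance <- function(compound, physiology = reference_physiology(),
                              hepatic_inhibitor_unbound = 0, ki = NULL,
                              hematocrit = physiology$hematocrit) {
  inh <- site_inhibition(hepatic_inhibitor_unbound, ki)
  clu <- compound$clint_cyp3a4_liver * physiology$liver_cyp3a4 * inh[["cyp3a4"]] +
    compound$clint_cyp3a5_liver * physiology$liver_cyp3a5 * inh[["cyp3a5"]]
  fu_b <- blood_partition(compound, hematocrit)$fu_blood
  q <- physiology$hepatic_blood_flow
  x <- fu_b * clu
  cl_h <- q * x / (q + x)
  list(cl_h = cl_h, fh = 1 - cl_h / q)
}

site_inhibition <- function(i_unbound, ki) {
  if (length(i_unbound) == 1L && is.null(names(i_unbound))) {
    i_unbound <- c(cyp3a4 = i_unbound, cyp3a5 = i_unbound)
  }
  if (all(i_unbound == 0)) return(c(cyp3a4 = 1, cyp3a5 = 1))
  if (is.null(ki)) abort("`ki` is required when inhibitor exposure is non-zero.")
  if (length(ki) == 1L && is.null(names(ki))) {
    ki <- c(cyp3a4 = ki, cyp3a5 = ki)
  }
  c(cyp3a4 = inhibition_factor(i_unbound[["cyp3a4"]], ki[["cyp3a4"]]),
    cyp3a5 = inhibition_factor(i_unbound[["cyp3a5"]], ki[["cyp3a5"]]))
}

## Pack one compound's engine parameters (internal units: mg, L, h, mg/L).
pack_compound <- function(compound, phys, regimen, ka_mult = 1) {
  part <- blood_partition(compound, phys$hematocrit)
  v_blood <- compound$vss * (compound$bp_ratio_ref / part$bp_ratio) *
    phys$body_weight
  ratio <- if (compound$k21 > 0) compound$k12 / compound$k21 else 0
  v1 <- v_blood / (1 + ratio)

  rate <- 0; r_int <- 0; r_dur <- 0; r_end <- 0
  if (!is.null(regimen) && regimen$route == "iv_infusion") {
    if (is.null(regimen$infusion_duration)) {
      rate <- regimen$dose / 24
      r_end <- regimen$duration
    } else {
      rate <- regimen$dose / regimen$infusion_duration
      r_int <- regimen$interval
      r_dur <- regimen$infusion_duration
      r_end <- regimen$duration
    }
  }
  list(
    v1 = v1, k12 = compound$k12, k21 = compound$k21,
    ka = compound$ka * ka_mult, cl_renal = compound$cl_renal,
    fu_blood = part$fu_blood,
    h4 = compound$clint_cyp3a4_liver * phys$liver_cyp3a4,
    h5 = compound$clint_cyp3a5_liver * phys$liver_cyp3a5,
    g4 = compound$fu_gut * compound$clint_cyp3a4_gut * phys$gut_cyp3a4,
    g5 = compound$fu_gut * compound$clint_cyp3a5_gut * phys$gut_cyp3a5,
    rate = rate, r_int = r_int, r_dur = r_dur, r_end = r_end
  )
}

#' Simulate whole-blood concentration-time profiles
#'
#' Integrates the coupled victim (+ optional perpetrator) system over
#' `[0, duration]`. Oral doses enter the gut lumen as `fa * dose` at each
#' dosing time; the absorption flux `ka * A_lumen` reaches the systemic
#' circulation scaled by the instantaneous gut availability `Fg(t)` and
#' hepatic availability `Fh(t)`; systemic elimination uses the instantaneous
#' well-stirred hepatic clearance plus renal clearance. Continuous IV
#' infusion adds a constant-rate input to central blood. A perpetrator is
#' co-simulated with its own linear PK; its gut-site exposure is the
#' absorption-flux estimate `ka_p * fa_p * dose_p / Q_ent` while drug
#' remains in its gut lumen (oral route) and its unbound systemic blood
#' concentration otherwise (and for both sites with IV administration),
#' while its hepatic-site exposure is always the unbound systemic blood
#' concentration.
#'
#' @param individual A single individual: one row of [sample_population()]
#'   output (or a named list with any of the abundance / hematocrit /
#'   weight / `ka_mult` fields). `NULL` uses the reference physiology.
#' @param victim `compound_params` for the victim drug.
#' @param victim_regimen [regimen()] for the victim.
#' @param perpetrator Optional `compound_params` carrying Ki values.
#' @param perpetrator_regimen [regimen()] for the perpetrator; required when
#'   `perpetrator` is given.
#' @param physiology Base physiology; individual fields override it.
#' @param nca_window Window (h) over which the output grid is refined to
#'   `window_step` (0.5 h elsewhere).
#' @param window_step Output grid step inside `nca_window`, h.
#' @param rtol,atol Solver tolerances (relative; absolute on amounts, mg).
#' @param return_states Keep the raw state matrix (amounts in mg, including
#'   cumulative elimination) as attribute `"states"`.
#' @return A `sim_profile` tibble with columns `time` (h), `compound`, and
#'   `conc` (whole-blood ng/mL), with attributes `aux` (time courses of
#'   victim `fg`, `fh`, `cl_h`, and gut inhibitor exposure `i_gut` ng/mL)
#'   and `dosing` (event table).
#' @examples
#' tac <- load_compound("tacrolimus")
#' prof <- simulate_profile(NULL, tac, regimen("oral", 1, 12, 168))
#' dplyr::filter(prof, time >= 156)
#' @export
simulate_profile <- function(individual, victim, victim_regimen,
                             perpetrator = NULL, perpetrator_regimen = NULL,
                             physiology = reference_physiology(),
                             nca_window = c(156, 168), window_step = 0.1,
                             rtol = 1e-8, atol = 1e-12,
                             return_states = FALSE) {
  stopifnot(inherits(victim, "compound_params"),
            inherits(victim_regimen, "regimen"))
  phys <- if (is.null(individual)) physiology else
    individual_physiology(individual, physiology)
  ka_mult <- 1
  if (!is.null(individual)) {
    km <- as.list(individual)$ka_mult
    if (!is.null(km) && !is.na(km)) ka_mult <- km
  }

  vic <- pack_compound(victim, phys, victim_regimen, ka_mult)

  has_p <- !is.null(perpetrator)
  if (has_p) {
    stopifnot(inherits(perpetrator, "compound_params"))
    if (is.null(perpetrator_regimen)) {
      abort("A perpetrator requires `perpetrator_regimen`.")
    }
    if (!is_perpetrator(perpetrator)) {
      abort(sprintf(
        "Compound '%s' has no inhibition constants and cannot be used as a perpetrator.",
        perpetrator$name
      ))
    }
    perp <- pack_compound(perpetrator, phys, perpetrator_regimen)
  } else {
    perp <- list(v1 = 1, k12 = 0, k21 = 0, ka = 0, cl_renal = 0, fu_blood = 0,
                 h4 = 0, h5 = 0, g4 = 0, g5 = 0,
                 rate = 0, r_int = 0, r_dur = 0, r_end = 0)
  }

  p_oral <- has_p && perpetrator_regimen$route == "oral"
  igut_flux <- 0; lum_thr <- 0
  if (p_oral) {
    igut_flux <- perp$ka * perpetrator$fa * perpetrator_regimen$dose /
      phys$enterocytic_blood_flow            # mg/L
    lum_thr <- 0.001 * perpetrator$fa * perpetrator_regimen$dose
  }
  ki4 <- if (has_p) perpetrator$ki_cyp3a4 / 1000 else 1  # ng/mL -> mg/L
  ki5 <- if (has_p) perpetrator$ki_cyp3a5 / 1000 else 1

  parms <- c(
    phys$hepatic_blood_flow, phys$enterocytic_blood_flow,
    vic$v1, vic$k12, vic$k21, vic$ka, vic$cl_renal, vic$fu_blood,
    vic$h4, vic$h5, vic$g4, vic$g5,
    vic$rate, vic$r_int, vic$r_dur, vic$r_end,
    as.numeric(has_p),
    perp$v1, perp$k12, perp$k21, perp$ka, perp$cl_renal, perp$fu_blood,
    perp$h4, perp$h5, perp$g4, perp$g5,
    perp$rate, perp$r_int, perp$r_dur, perp$r_end,
    ki4, ki5, igut_flux, lum_thr, as.numeric(p_oral)
  )

  duration <- victim_regimen$duration
  ev <- dosing_events(victim_regimen, victim, state = 1L)
  if (has_p) {
    ev <- rbind(ev, dosing_events(perpetrator_regimen, perpetrator,
                                  state = 5L, duration = duration))
  }
  ev <- ev[ev$time < duration, , drop = FALSE]
  ev <- ev[order(ev$time, ev$var), , drop = FALSE]

  times <- sort(unique(c(
    seq(0, duration, by = 0.5),
    if (nca_window[1] < duration) {
      seq(max(0, nca_window[1]), min(duration, nca_window[2]),
          by = window_step)
    },
    duration, ev$time
  )))

  out <- deSolve::lsoda(
    y = setNames(numeric(8), paste0("y", 1:8)),
    times = times, func = "tacswitch_derivs", parms = parms,
    dllname = "tacswitch", initfunc = "tacswitch_initparms",
    nout = 4, outnames = c("fg", "fh", "cl_h", "i_gut"),
    rtol = rtol, atol = atol, maxsteps = 50000,
    events = if (nrow(ev)) list(data = ev) else NULL
  )
  if (attr(out, "istate")[1] < 0) {
    abort(sprintf(
      "ODE solver failed for victim '%s' (%s regimen, duration %g h).",
      victim$name, victim_regimen$route, duration
    ))
  }
  st <- out[, 2:9, drop = FALSE]
  if (min(st) < -1e-6) {
    abort(sprintf(
      "Negative state encountered (min %.3g mg); integration is unreliable.",
      min(st)
    ))
  }
  conc_v <- pmax(st[, 2], 0) / vic$v1 * 1000   # mg/L -> ng/mL
  prof <- tibble(time = out[, 1], compound = victim$name, conc = conc_v)
  if (has_p) {
    prof <- bind_rows(prof, tibble(
      time = out[, 1], compound = perpetrator$name,
      conc = pmax(st[, 6], 0) / perp$v1 * 1000
    ))
  }
  aux <- tibble(time = out[, 1], fg = out[, "fg"], fh = out[, "fh"],
                cl_h = out[, "cl_h"], i_gut = out[, "i_gut"] * 1000)
  attr(prof, "aux") <- aux
  attr(prof, "dosing") <- ev
  attr(prof, "victim") <- victim$name
  attr(prof, "regimen") <- victim_regimen
  if (return_states) {
    colnames(st) <- c("lumen_v", "central_v", "peripheral_v", "eliminated_v",
                      "lumen_p", "central_p", "peripheral_p", "eliminated_p")
    attr(prof, "states") <- cbind(time = out[, 1], st)
  }
  class(prof) <- c("sim_profile", class(prof))
  prof
}

## Event table for one compound: oral doses are lumen additions of fa*dose;
## intermittent infusions get zero-magnitude events so the solver restarts
## at the rate discontinuities.
dosing_events <- function(reg, compound, state, duration = reg$duration) {
  if (reg$route == "oral") {
    tt <- oral_dose_times(reg)
    if (!length(tt)) {
      return(data.frame(var = integer(), time = numeric(),
                        value = numeric(), method = character()))
    }
    return(data.frame(var = state, time = tt,
                      value = compound$fa * reg$dose, method = "add"))
  }
  if (!is.null(reg$infusion_duration)) {
    starts <- event_starts(duration, reg$interval)
    edges <- sort(unique(c(starts, starts + reg$infusion_duration)))
    edges <- edges[edges < duration]
    return(data.frame(var = state + 1L, time = edges, value = 0,
                      method = "add"))
  }
  data.frame(var = integer(), time = numeric(), value = numeric(),
             method = character())
}

#' @export
print.sim_profile <- function(x, ...) {
  reg <- attr(x, "regimen")
  cat(sprintf("<sim_profile: %s, %s, %g h, %d time points>\n",
              attr(x, "victim"), reg$route, reg$duration,
              length(unique(x$time))))
  NextMethod()
}
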