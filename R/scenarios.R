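#' Clinical scenario definition
#'
#' A scenario pairs a virtual population with the transplant-specific
#' CYP3A5 geography and any comedication. In a liver transplant the graft
#' (donor) genotype governs hepatic CYP3A5 while the recipient genotype
#' governs the native intestine and colon, so expression is toggled per
#' organ site: `donor_expressor` keeps or zeroes hepatic CYP3A5 and
#' `recipient_expressor` keeps or zeroes intestinal/colonic CYP3A5.
#' `liver_function_fraction` scales hepatic CYP3A4 and CYP3A5 abundance
#' jointly to emulate reduced graft function.
#'
#' @param name Scenario label.
#' @param population A [population_spec()].
#' @param donor_expressor Liver-site CYP3A5 expression kept?
#' @param recipient_expressor Gut/colon-site CYP3A5 expression kept?
#' @param liver_function_fraction Multiplier in (0, 1] on hepatic CYP3A4/5
#'   abundance.
#' @param perpetrator `NULL`, or a list with `compound` (name or
#'   `compound_params`), `route` (`"oral"` or `"iv_infusion"`), `dose` (mg
#'   per administration), and `interval` (h).
#' @param po_regimen The oral victim [regimen()] being matched.
#' @return A `scenario` object.
#' @export
scenario <- function(name, population,
                     donor_expressor = TRUE, recipient_expressor = TRUE,
                     liver_function_fraction = 1, perpetrator = NULL,
                     po_regimen = regimen("oral", dose = 1, interval = 12,
                                          duration = 168)) {
  stopifnot(inherits(population, "population_spec"),
            inherits(po_regimen, "regimen"))
  if (po_regimen$route != "oral") abort("`po_regimen` must be oral.")
  if (po_regimen$duration < 168) {
    abort("Steady-state analyses need `duration` >= 168 h.")
  }
  if (liver_function_fraction <= 0 || liver_function_fraction > 1) {
    abort("`liver_function_fraction` must lie in (0, 1].")
  }
  if (!is.null(perpetrator)) {
    need <- setdiff(c("compound", "route", "dose", "interval"),
                    names(perpetrator))
    if (length(need)) {
      abort(sprintf("Perpetrator spec missing: %s.",
                    paste(need, collapse = ", ")))
    }
    if (!perpetrator$route %in% c("oral", "iv_infusion")) {
      abort("Perpetrator route must be 'oral' or 'iv_infusion'.")
    }
  }
  structure(
    list(name = name, population = population,
         donor_expressor = isTRUE(donor_expressor),
         recipient_expressor = isTRUE(recipient_expressor),
         liver_function_fraction = liver_function_fraction,
         perpetrator = perpetrator, po_regimen = po_regimen),
    class = "scenario"
  )
}

#' Apply a scenario's CYP3A5 geography to sampled individuals
#'
#' Zeroes the organ sites whose genotype does not express CYP3A5
#' (donor-only keeps the liver and zeroes intestine/colon; recipient-only
#' the opposite; neither zeroes all sites) and then scales hepatic CYP3A4
#' and CYP3A5 abundance by `liver_function_fraction`.
#'
#' @param individuals Tibble from [sample_population()] (or one row).
#' @param scn A [scenario()].
#' @return The modified individuals tibble.
#' @export
apply_scenario <- function(individuals, scn) {
  stopifnot(inherits(scn, "scenario"))
  out <- individuals
  if (!scn$donor_expressor) out$liver_cyp3a5 <- 0
  if (!scn$recipient_expressor) {
    out$gut_cyp3a5 <- 0
    out$colon_cyp3a5 <- 0
  }
  lff <- scn$liver_function_fraction
  out$liver_cyp3a4 <- out$liver_cyp3a4 * lff
  out$liver_cyp3a5 <- out$liver_cyp3a5 * lff
  out
}

resolve_perpetrator <- function(scn, duration) {
  if (is.null(scn$perpetrator)) return(list(compound = NULL, regimen = NULL))
  p <- scn$perpetrator
  cmp <- if (inherits(p$compound, "compound_params")) p$compound else
    load_compound(p$compound)
  reg <- if (p$route == "oral") {
    regimen("oral", dose = p$dose, interval = p$interval,
            duration = duration)
  } else {
    regimen("iv_infusion", dose = p$dose, interval = p$interval,
            duration = duration,
            infusion_duration = p$infusion_duration %||% 1)
  }
  list(compound = cmp, regimen = reg)
}

#' Find the continuous IV rate matching an oral steady-state AUC
#'
#' Simulates a probe continuous infusion (1 mg/24 h by default), scales the
#' dose by `target_auc / probe_auc` (exact under linear kinetics), and
#' verifies by re-simulation that the achieved window AUC is within
#' `tolerance` of the target; if not, falls back to bracketed root-finding
#' on the dose.
#'
#' @param individual One individual (row) or `NULL` for the reference.
#' @param victim `compound_params` for the victim.
#' @param target_auc Oral steady-state AUC over `window`, ng/mL*h (> 0).
#' @param perpetrator,perpetrator_regimen Optional co-simulated inhibitor.
#' @param duration Simulated time, h.
#' @param window NCA window, h.
#' @param probe_dose Probe infusion dose, mg/24 h.
#' @param tolerance Acceptable `|AUC ratio - 1|`.
#' @param verify Re-simulate at the matched dose? (The verification profile
#'   is returned for downstream NCA.)
#' @param physiology Base physiology.
#' @return A list: `dose` (mg/24 h), `auc_iv`, `ratio` (achieved/target),
#'   and `profile` (the simulation at the matched dose, `NULL` if
#'   `verify = FALSE`).
#' @export
match_iv_dose <- function(individual, victim, target_auc,
                          perpetrator = NULL, perpetrator_regimen = NULL,
                          duration = 168, window = c(156, 168),
                          probe_dose = 1, tolerance = 0.01, verify = TRUE,
                          physiology = reference_physiology()) {
  if (!is.numeric(target_auc) || target_auc <= 0) {
    abort("`target_auc` must be > 0.")
  }
  iv_auc <- function(dose) {
    prof <- simulate_profile(
      individual, victim,
      regimen("iv_infusion", dose = dose, duration = duration),
      perpetrator, perpetrator_regimen, physiology = physiology
    )
    list(profile = prof,
         auc = nca_summary(prof, regimen("iv_infusion", dose = dose,
                                         duration = duration),
                           window = window)$auc_tau)
  }
  probe <- iv_auc(probe_dose)
  dose <- probe_dose * target_auc / probe$auc
  if (!verify) {
    return(list(dose = dose, auc_iv = dose / probe_dose * probe$auc,
                ratio = 1, profile = NULL))
  }
  chk <- iv_auc(dose)
  ratio <- chk$auc / target_auc
  if (abs(ratio - 1) > tolerance) {
    root <- uniroot(function(d) iv_auc(d)$auc - target_auc,
                    lower = dose / 10, upper = dose * 10,
                    tol = tolerance * dose)
    dose <- root$root
    chk <- iv_auc(dose)
    ratio <- chk$auc / target_auc
    if (abs(ratio - 1) > tolerance) {
      abort(sprintf(
        "IV dose matching did not converge (residual %.3g).", ratio - 1
      ))
    }
  }
  list(dose = dose, auc_iv = chk$auc, ratio = ratio, profile = chk$profile)
}

#' Geometric mean and 90% interval
#'
#' `GM = exp(mean(log(x)))`. The default interval is the empirical 5th-95th
#' percentile of the individual values; `interval = "trial_ci"` instead
#' gives a t-based confidence interval of the geometric mean computed from
#' per-trial geometric means (the trial-level convention of population
#' simulators).
#'
#' @param values Positive values.
#' @param level Interval coverage (default 0.90).
#' @param interval `"percentile"` or `"trial_ci"`.
#' @param trial Trial index per value; required for `"trial_ci"`.
#' @return A list with `gm`, `lo`, `hi`.
#' @examples
#' geometric_stats(c(1, 10))$gm   # sqrt(10)
#' @export
geometric_stats <- function(values, level = 0.90,
                            interval = c("percentile", "trial_ci"),
                            trial = NULL) {
  interval <- match.arg(interval)
  values <- values[!is.na(values)]
  if (!length(values) || any(values <= 0)) {
    abort("Geometric statistics need strictly positive values.")
  }
  lx <- log(values)
  gm <- exp(mean(lx))
  a <- (1 - level) / 2
  if (interval == "percentile" || is.null(trial) ||
      length(unique(trial)) < 2) {
    qs <- quantile(values, c(a, 1 - a), names = FALSE, type = 7)
    return(list(gm = gm, lo = qs[1], hi = qs[2]))
  }
  tm <- tapply(lx, trial, mean)
  se <- stats::sd(tm) / sqrt(length(tm))
  tq <- stats::qt(1 - a, df = length(tm) - 1)
  list(gm = gm, lo = exp(mean(tm) - tq * se), hi = exp(mean(tm) + tq * se))
}

#' Run one clinical scenario
#'
#' Samples the scenario's population, applies the CYP3A5 geography, and for
#' every subject simulates the oral regimen, extracts AUC and trough by
#' NCA, finds the AUC-matched continuous IV rate, and extracts the matched
#' infusion's AUC and steady-state concentration. Population summaries are
#' geometric means with 90% intervals; the headline ratios are computed
#' from the geometric means (`GM(Css)/GM(Cmin)`, oral daily dose over
#' `GM(matched IV daily dose)`).
#'
#' @param scn A [scenario()].
#' @param victim Victim `compound_params` (default: built-in tacrolimus).
#' @param window NCA window, h.
#' @param interval_method Passed to [geometric_stats()].
#' @param verify Verify every matched dose by re-simulation.
#' @param physiology Base physiology.
#' @param max_failure_fraction Scenario fails if more subjects than this
#'   fraction error.
#' @return A `scenario_result`: list with `scenario`, `subjects` (per-
#'   subject tibble), and `summary` (one-row tibble). Use [tidy()] /
#'   [glance()] to extract them.
#' @examples
#' \donttest{
#' scn <- scenario("healthy", population_spec("healthy", 2, 5, seed = 7))
#' res <- run_scenario(scn)
#' glance(res)
#' }
#' @export
run_scenario <- function(scn, victim = load_compound("tacrolimus"),
                         window = c(156, 168),
                         interval_method = c("percentile", "trial_ci"),
                         verify = TRUE,
                         physiology = reference_physiology(),
                         max_failure_fraction = 0.01) {
  stopifnot(inherits(scn, "scenario"))
  interval_method <- match.arg(interval_method)
  duration <- scn$po_regimen$duration
  perp <- resolve_perpetrator(scn, duration)

  pop <- apply_scenario(sample_population(scn$population), scn)

  one_subject <- function(ind) {
    oral <- simulate_profile(ind, victim, scn$po_regimen,
                             perp$compound, perp$regimen,
                             physiology = physiology)
    nca_po <- nca_summary(oral, scn$po_regimen, window = window)
    m <- match_iv_dose(ind, victim, nca_po$auc_tau,
                       perp$compound, perp$regimen,
                       duration = duration, window = window,
                       verify = verify, physiology = physiology)
    if (is.null(m$profile)) {
      m$profile <- simulate_profile(
        ind, victim, regimen("iv_infusion", dose = m$dose,
                             duration = duration),
        perp$compound, perp$regimen, physiology = physiology
      )
    }
    iv_reg <- regimen("iv_infusion", dose = m$dose, duration = duration)
    nca_iv <- nca_summary(m$profile, iv_reg, window = window)
    tibble(
      id = ind$id, trial = ind$trial,
      auc_po = nca_po$auc_tau, cmin = nca_po$cmin,
      matched_iv_dose = m$dose, auc_iv = nca_iv$auc_tau,
      css = nca_iv$css, match_residual = m$ratio - 1,
      steady_state_ok = nca_po$steady_state_ok
    )
  }

  rows <- vector("list", nrow(pop))
  failures <- character(0)
  for (i in seq_len(nrow(pop))) {
    ind <- pop[i, ]
    rows[[i]] <- tryCatch(one_subject(ind), error = function(e) {
      failures <<- c(failures,
                     sprintf("subject %d: %s", ind$id, conditionMessage(e)))
      NULL
    })
  }
  if (length(failures) > max_failure_fraction * nrow(pop)) {
    abort(paste0(
      sprintf("Scenario '%s' failed for %d of %d subjects:\n", scn$name,
              length(failures), nrow(pop)),
      paste(head(failures, 5), collapse = "\n")
    ))
  }
  subjects <- list_rbind(rows[!vapply(rows, is.null, logical(1))])

  gs <- function(col) {
    geometric_stats(subjects[[col]], interval = interval_method,
                    trial = subjects$trial)
  }
  s_auc_po <- gs("auc_po"); s_cmin <- gs("cmin")
  s_dose <- gs("matched_iv_dose"); s_auc_iv <- gs("auc_iv")
  s_css <- gs("css")
  daily_po <- scn$po_regimen$dose * 24 / scn$po_regimen$interval

  summary <- tibble(
    scenario = scn$name, n_subjects = nrow(subjects),
    dose_po = scn$po_regimen$dose,
    gm_auc_po = s_auc_po$gm, auc_po_lo = s_auc_po$lo, auc_po_hi = s_auc_po$hi,
    gm_cmin = s_cmin$gm, cmin_lo = s_cmin$lo, cmin_hi = s_cmin$hi,
    gm_dose_iv = s_dose$gm, dose_iv_lo = s_dose$lo, dose_iv_hi = s_dose$hi,
    gm_auc_iv = s_auc_iv$gm, auc_iv_lo = s_auc_iv$lo, auc_iv_hi = s_auc_iv$hi,
    gm_css = s_css$gm, css_lo = s_css$lo, css_hi = s_css$hi,
    ratio_auc = s_auc_iv$gm / s_auc_po$gm,
    po_iv_dose_ratio = daily_po / s_dose$gm,
    css_cmin_ratio = s_css$gm / s_cmin$gm
  )
  structure(list(scenario = scn, subjects = subjects, summary = summary),
            class = "scenario_result")
}

#' Run several scenarios
#'
#' @param scenarios A list of [scenario()] objects.
#' @param ... Passed to [run_scenario()].
#' @return A named list of `scenario_result` objects.
#' @export
run_scenarios <- function(scenarios, ...) {
  res <- map(scenarios, run_scenario, ...)
  names(res) <- vapply(scenarios, function(s) s$name, character(1))
  res
}

#' Assemble a dose-conversion report table
#'
#' One row per scenario with the oral dose, AUC / trough / steady-state
#' concentration summaries (geometric mean and 90% interval), the matched
#' IV dose, and the three headline ratios. Values are rounded in this
#' report layer only; the per-subject values in each result stay exact.
#'
#' @param results A `scenario_result` or list of them (from
#'   [run_scenarios()]).
#' @param digits Rounding for the ratio columns.
#' @return A tibble with one row per scenario.
#' @export
scenario_report <- function(results, digits = 2) {
  if (inherits(results, "scenario_result")) results <- list(results)
  fmt <- function(gm, lo, hi) {
    sprintf("%.2f [%.2f-%.2f]", gm, lo, hi)
  }
  map(results, function(r) {
    s <- r$summary
    tibble(
      scenario = s$scenario,
      dose_po_mg_12h = s$dose_po,
      auc_po = fmt(s$gm_auc_po, s$auc_po_lo, s$auc_po_hi),
      cmin = fmt(s$gm_cmin, s$cmin_lo, s$cmin_hi),
      dose_iv_mg_24h = round(s$gm_dose_iv, digits),
      auc_iv = fmt(s$gm_auc_iv, s$auc_iv_lo, s$auc_iv_hi),
      css = fmt(s$gm_css, s$css_lo, s$css_hi),
      ratio_auc = round(s$ratio_auc, digits),
      ratio_po_iv_dose = round(s$po_iv_dose_ratio, digits),
      ratio_css_cmin = round(s$css_cmin_ratio, digits)
    )
  }) |> list_rbind()
}

#' Reference scenario set
#'
#' The seven standard clinical scenarios of the dose-conversion analysis:
#' healthy volunteers (17% CYP3A5 expressors), the virtual twin, the three
#' donor/recipient CYP3A5 expression splits (expressor frequency 100%
#' before site-zeroing), and itraconazole 200 mg once daily given orally or
#' as a 1-h IV infusion.
#'
#' @param seed Master seed.
#' @param n_trials,n_per_trial Population size per scenario.
#' @param twin_covariates Virtual-twin covariates (defaults to the
#'   70-year-old female case with hematocrit 23.7%, CYP3A5 non-expressor).
#' @return A named list of [scenario()] objects.
#' @export
reference_scenarios <- function(seed = 1, n_trials = 10, n_per_trial = 100,
                                twin_covariates = list(
                                  age = 70, sex = "female", weight = 70,
                                  height = 163, hematocrit = 0.237,
                                  cyp3a5_expressor = FALSE)) {
  pop <- function(freq, offset) {
    population_spec("healthy", n_trials, n_per_trial,
                    expressor_frequency = freq,
                    seed = trial_seed(seed, offset))
  }
  twin <- population_spec("twin", n_trials = n_trials, n_per_trial = 1,
                          seed = trial_seed(seed, 2),
                          twin_covariates = twin_covariates)
  itz <- function(route) {
    list(compound = "itraconazole", route = route, dose = 200, interval = 24)
  }
  list(
    healthy = scenario("healthy", pop(0.17, 1)),
    virtual_twin = scenario("virtual_twin", twin),
    both_expressor = scenario("both_expressor", pop(1, 3)),
    donor_expressor = scenario("donor_expressor", pop(1, 4),
                               recipient_expressor = FALSE),
    recipient_expressor = scenario("recipient_expressor", pop(1, 5),
                                   donor_expressor = FALSE),
    itraconazole_po = scenario("itraconazole_po", pop(0.17, 6),
                               perpetrator = itz("oral")),
    itraconazole_iv = scenario("itraconazole_iv", pop(0.17, 7),
                               perpetrator = itz("iv_infusion"))
  )
}
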