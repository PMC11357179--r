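#' Tidy a scenario result
#'
#' Per-subject values: one row per virtual subject with the oral AUC,
#' trough, matched IV dose, IV AUC, steady-state concentration, and the
#' AUC-match residual.
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return A tibble, one row per subject.
#' @export
tidy.scenario_result <- function(x, ...) {
  mutate(x$subjects, scenario = x$scenario$name, .before = 1)
}

#' One-row summary of a scenario result
#'
#' Geometric means with 90% intervals plus the three headline ratios
#' (AUC ratio, PO/IV dose ratio, Css/Cmin ratio).
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.scenario_result <- function(x, ...) {
  x$summary
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<scenario_result: %s, %d subjects>\n", s$scenario,
              s$n_subjects))
  cat(sprintf("  oral %g mg q%gh: AUCtau %.2f ng/mL*h, Cmin %.2f ng/mL\n",
              s$dose_po, x$scenario$po_regimen$interval, s$gm_auc_po,
              s$gm_cmin))
  cat(sprintf("  matched IV %.3f mg/24h: AUCtau %.2f, Css %.2f ng/mL\n",
              s$gm_dose_iv, s$gm_auc_iv, s$gm_css))
  cat(sprintf("  ratios: AUC %.2f | PO/IV dose %.2f | Css/Cmin %.2f\n",
              s$ratio_auc, s$po_iv_dose_ratio, s$css_cmin_ratio))
  invisible(x)
}

#' Plot a simulated profile
#'
#' Whole-blood concentration against time, one panel per compound.
#'
#' @param object A `sim_profile`.
#' @param window Optional time window to restrict the plot to, h.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sim_profile <- function(object, window = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(window)) d <- filter(d, .data$time >= window[1],
                                    .data$time <= window[2])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$conc)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~compound, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = "Whole-blood concentration (ng/mL)") +
    ggplot2::theme_minimal()
}

#' Steady-state window overlay of matched oral and IV profiles
#'
#' Re-simulates a representative subject of a scenario result under its
#' oral regimen and its geometric-mean matched continuous infusion, and
#' overlays the two whole-blood traces over the analysis window: the
#' oscillating oral curve crossing the flat infusion plateau at matched
#' AUC is the visual core of the Css/Cmin conversion.
#'
#' @param result A `scenario_result`.
#' @param victim Victim compound (default built-in tacrolimus).
#' @param window Time window, h.
#' @param physiology Base physiology.
#' @return A ggplot.
#' @export
plot_steady_state <- function(result, victim = load_compound("tacrolimus"),
                              window = c(156, 168),
                              physiology = reference_physiology()) {
  stopifnot(inherits(result, "scenario_result"))
  scn <- result$scenario
  perp <- resolve_perpetrator(scn, scn$po_regimen$duration)
  pop <- apply_scenario(sample_population(scn$population), scn)
  ind <- pop[1, ]
  po <- simulate_profile(ind, victim, scn$po_regimen, perp$compound,
                         perp$regimen, physiology = physiology)
  iv_reg <- regimen("iv_infusion", dose = result$summary$gm_dose_iv,
                    duration = scn$po_regimen$duration)
  iv <- simulate_profile(ind, victim, iv_reg, perp$compound, perp$regimen,
                         physiology = physiology)
  d <- bind_rows(
    mutate(filter(as_tibble(po), .data$compound == victim$name), route = "PO"),
    mutate(filter(as_tibble(iv), .data$compound == victim$name), route = "IV")
  ) |>
    filter(.data$time >= window[1], .data$time <= window[2])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$conc,
                                  colour = .data$route)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(title = scn$name, x = "Time (h)",
                  y = "Whole-blood tacrolimus (ng/mL)", colour = NULL) +
    ggplot2::theme_minimal()
}
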