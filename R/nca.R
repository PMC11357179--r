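#' Log-trapezoidal AUC over a window
#'
#' Area under the concentration-time curve between `window[1]` and
#' `window[2]`. Each declining segment with positive endpoints
#' (`C1 > C2 > 0`) contributes `(C1 - C2) * dt / log(C1 / C2)`, which is
#' exact for mono-exponential decline; rising, flat, or zero-touching
#' segments fall back to the linear trapezoid `(C1 + C2) * dt / 2`. Window
#' endpoints off the sampling grid are interpolated (log-linearly on
#' declining segments, linearly otherwise).
#'
#' @param times Sampling times, h, strictly increasing.
#' @param concs Concentrations, ng/mL (>= 0), same length as `times`.
#' @param window Length-2 numeric `c(start, end)`, h.
#' @return AUC in ng/mL*h.
#' @examples
#' auc_log_trapezoid(c(0, 12), c(10, 10 * exp(-1.2)), c(0, 12))  # 69.881
#' @export
auc_log_trapezoid <- function(times, concs, window = c(156, 168)) {
  if (length(times) != length(concs)) {
    abort("`times` and `concs` must have equal length.")
  }
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  if (any(concs < 0)) abort("Negative concentrations are not allowed.")
  if (window[2] <= window[1]) abort("`window` must satisfy start < end.")
  if (window[1] < times[1] || window[2] > times[length(times)]) {
    abort("`window` must lie inside the sampled time range.")
  }

  tt <- times; cc <- concs
  for (w in window) {
    if (!any(tt == w)) {
      i <- max(which(tt < w))
      cw <- interp_conc(tt[i], tt[i + 1], cc[i], cc[i + 1], w)
      tt <- append(tt, w, after = i)
      cc <- append(cc, cw, after = i)
    }
  }
  keep <- tt >= window[1] & tt <= window[2]
  tt <- tt[keep]; cc <- cc[keep]
  if (length(tt) < 2L) abort("Fewer than 2 samples inside the window.")

  c1 <- cc[-length(cc)]; c2 <- cc[-1]; dt <- diff(tt)
  log_ok <- c1 > c2 & c2 > 0
  seg <- ifelse(log_ok, (c1 - c2) * dt / log(ifelse(log_ok, c1 / c2, 1)),
                (c1 + c2) * dt / 2)
  sum(seg)
}

interp_conc <- function(t1, t2, c1, c2, t) {
  f <- (t - t1) / (t2 - t1)
  if (c1 > c2 && c2 > 0) exp(log(c1) + f * (log(c2) - log(c1)))
  else c1 + f * (c2 - c1)
}

#' Steady-state NCA of a simulated profile
#'
#' Computes the dosing-interval AUC by [auc_log_trapezoid()] over `window`,
#' plus the route-specific concentration summary: the trough concentration
#' `cmin` at the end of the window (the pre-dose instant; doses fall at 0,
#' interval, ..., so the window end is a trough) for oral regimens, and the
#' window-average `css = AUC / width` for infusions. `steady_state_ok`
#' flags whether the AUC over the preceding same-width window agrees within
#' 2%, i.e. whether accumulation is complete.
#'
#' @param profile A `sim_profile` from [simulate_profile()] (or any tibble
#'   with `time`, `compound`, `conc`).
#' @param regimen The victim [regimen()] the profile was simulated under.
#' @param window Analysis window `c(start, end)`, h.
#' @param compound_name Which compound to analyse; defaults to the
#'   profile's victim.
#' @return A one-row tibble: `auc_tau`, `cmin`, `css`, `window_start`,
#'   `window_end`, `steady_state_ok`.
#' @export
nca_summary <- function(profile, regimen, window = c(156, 168),
                        compound_name = attr(profile, "victim")) {
  if (is.null(compound_name)) compound_name <- profile$compound[1]
  d <- profile[profile$compound == compound_name, ]
  if (!nrow(d) || min(d$time) > window[1] || max(d$time) < window[2]) {
    abort("Profile does not cover the analysis window.")
  }
  auc <- auc_log_trapezoid(d$time, d$conc, window)
  width <- diff(window)

  prev_window <- window - width
  ss_ok <- NA
  if (prev_window[1] >= min(d$time)) {
    auc_prev <- auc_log_trapezoid(d$time, d$conc, prev_window)
    ss_ok <- is.finite(auc_prev) && auc_prev > 0 &&
      abs(auc / auc_prev - 1) < 0.02
  }

  cmin <- NA_real_; css <- NA_real_
  if (regimen$route == "oral") {
    cmin <- approx(d$time, d$conc, xout = window[2])$y
  } else {
    css <- auc / width
  }
  tibble(auc_tau = auc, cmin = cmin, css = css,
         window_start = window[1], window_end = window[2],
         steady_state_ok = ss_ok)
}
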