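#' Dosing regimens
#'
#' Oral regimens give `dose` mg every `interval` hours from time 0 until
#' `duration`. Infusion regimens are continuous by default (`dose` is then mg
#' per 24 h delivered at constant rate over the whole duration); setting
#' `infusion_duration` together with `interval` gives repeated short
#' infusions of `dose` mg per administration (used for the IV perpetrator).
#'
#' @param route `"oral"` or `"iv_infusion"`.
#' @param dose mg per administration (oral, intermittent infusion) or mg per
#'   24 h (continuous infusion).
#' @param interval Dosing interval, h. Required for oral regimens; `NULL`
#'   for a continuous infusion.
#' @param duration Total simulated time, h.
#' @param infusion_duration Length of each infusion, h, for intermittent IV
#'   dosing; `NULL` for a continuous infusion.
#' @return A `regimen` object.
#' @examples
#' regimen("oral", dose = 1, interval = 12, duration = 168)
#' regimen("iv_infusion", dose = 0.47, duration = 168)
#' regimen("iv_infusion", dose = 200, interval = 24, duration = 168,
#'         infusion_duration = 1)
#' @export
regimen <- function(route = c("oral", "iv_infusion"), dose, interval = NULL,
                    duration = 168, infusion_duration = NULL) {
  route <- match.arg(route)
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0) {
    abort("`dose` must be a single number >= 0.")
  }
  if (!is.numeric(duration) || duration <= 0) {
    abort("`duration` must be > 0.")
  }
  if (route == "oral") {
    if (is.null(interval) || !is.numeric(interval) || interval <= 0) {
      abort("Oral regimens require `interval` > 0.")
    }
    if (!is.null(infusion_duration)) {
      abort("`infusion_duration` does not apply to oral regimens.")
    }
  } else {
    if (!is.null(infusion_duration)) {
      if (is.null(interval) || interval <= 0) {
        abort("Intermittent infusions require `interval` > 0.")
      }
      if (infusion_duration <= 0 || infusion_duration > interval) {
        abort("`infusion_duration` must lie in (0, interval].")
      }
    } else if (!is.null(interval)) {
      abort("Continuous infusions take no `interval`; set `infusion_duration` for intermittent IV dosing.")
    }
  }
  structure(
    list(route = route, dose = dose, interval = interval,
         duration = duration, infusion_duration = infusion_duration),
    class = "regimen"
  )
}

#' @export
print.regimen <- function(x, ...) {
  if (x$route == "oral") {
    cat(sprintf("<regimen: %g mg oral q%gh for %g h>\n",
                x$dose, x$interval, x$duration))
  } else if (is.null(x$infusion_duration)) {
    cat(sprintf("<regimen: continuous IV infusion %g mg/24h for %g h>\n",
                x$dose, x$duration))
  } else {
    cat(sprintf("<regimen: IV infusion %g mg over %g h q%gh for %g h>\n",
                x$dose, x$infusion_duration, x$interval, x$duration))
  }
  invisible(x)
}

oral_dose_times <- function(reg) {
  if (reg$route != "oral" || reg$dose <= 0) return(numeric(0))
  event_starts(reg$duration, reg$interval)
}

## 0, interval, 2*interval, ... strictly below duration (robust to the
## floating-point fuzz of seq(..., by =)).
event_starts <- function(duration, interval) {
  n <- ceiling(duration / interval - 1e-9)
  (seq_len(max(n, 1)) - 1) * interval
}
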