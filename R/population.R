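#' Virtual population specification
#'
#' Defines how virtual subjects are sampled. Organ-site CYP3A abundances are
#' drawn log-normally with median 1 at the stated coefficients of variation;
#' each subject is a CYP3A5 expressor (positive sampled abundance at liver,
#' small intestine, and colon) with probability `expressor_frequency`, and a
#' non-expressor (all three CYP3A5 abundances 0) otherwise. Demographics use
#' documented ranges: healthy adults aged 20-50, the geriatric variant
#' 65-85 (otherwise identical physiology), and the virtual twin fixed
#' covariates supplied through `twin_covariates`.
#'
#' Default dispersions for open populations (liver abundance CV 35%, gut
#' abundance CV 60%, absorption-rate CV 30%) are typical population-PBPK
#' variabilities; the emulated population libraries are named but not
#' parameterised in the sources. The twin mode fixes the patient's
#' covariates, so only residual system variability remains across its
#' one-subject trials: its abundance CVs default to 12%, calibrated to the
#' narrow trial-to-trial spread reported for virtual-twin simulations.
#'
#' @param kind `"healthy"`, `"geriatric"`, or `"twin"`.
#' @param n_trials Number of simulated trials.
#' @param n_per_trial Subjects per trial (must be 1 for `"twin"`).
#' @param expressor_frequency CYP3A5 expressor probability, in \[0, 1\].
#' @param cv_liver_abundance,cv_gut_abundance,cv_ka Coefficients of
#'   variation (>= 0); `NULL` uses the kind-specific defaults above.
#' @param seed Master RNG seed; per-trial child seeds are derived as
#'   `(seed + 104729 * trial) mod (2^31 - 1)`.
#' @param twin_covariates Named list with `age`, `sex`, `weight`, `height`,
#'   `hematocrit`, `cyp3a5_expressor` for the twin.
#' @return A `population_spec` object.
#' @export
population_spec <- function(kind = c("healthy", "geriatric", "twin"),
                            n_trials = 10, n_per_trial = 100,
                            expressor_frequency = 0.17,
                            cv_liver_abundance = NULL,
                            cv_gut_abundance = NULL,
                            cv_ka = NULL, seed = 1,
                            twin_covariates = NULL) {
  kind <- match.arg(kind)
  cv_liver_abundance <- cv_liver_abundance %||%
    if (kind == "twin") 0.12 else 0.35
  cv_gut_abundance <- cv_gut_abundance %||%
    if (kind == "twin") 0.12 else 0.60
  cv_ka <- cv_ka %||% 0.30
  if (n_trials < 1 || n_per_trial < 1) abort("Counts must be >= 1.")
  if (expressor_frequency < 0 || expressor_frequency > 1) {
    abort("`expressor_frequency` must lie in [0, 1].")
  }
  for (f in c(cv_liver_abundance, cv_gut_abundance, cv_ka)) {
    if (f < 0) abort("Coefficients of variation must be >= 0.")
  }
  if (kind == "twin") {
    if (n_per_trial != 1) abort("Twin populations use n_per_trial = 1.")
    twin_covariates <- check_twin_covariates(twin_covariates)
  }
  structure(
    list(kind = kind, n_trials = as.integer(n_trials),
         n_per_trial = as.integer(n_per_trial),
         expressor_frequency = expressor_frequency,
         cv_liver_abundance = cv_liver_abundance,
         cv_gut_abundance = cv_gut_abundance,
         cv_ka = cv_ka, seed = as.integer(seed),
         twin_covariates = twin_covariates),
    class = "population_spec"
  )
}

twin_fields <- c("age", "sex", "weight", "height", "hematocrit",
                 "cyp3a5_expressor")

check_twin_covariates <- function(cov) {
  if (is.null(cov)) abort("Twin populations require `twin_covariates`.")
  missing <- setdiff(twin_fields, names(cov))
  if (length(missing)) {
    abort(sprintf("Missing twin covariate(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (cov$hematocrit <= 0.1 || cov$hematocrit >= 0.6) {
    abort("Twin `hematocrit` must lie in (0.1, 0.6).")
  }
  cov
}

trial_seed <- function(seed, trial) {
  as.integer((as.numeric(seed) + 104729 * trial) %% 2147483647)
}

rlnorm_med1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

#' Sample a virtual population
#'
#' Draws `n_trials * n_per_trial` virtual individuals grouped by trial,
#' fully reproducible from the seed in the population specification. Returns one row per individual
#' with demographics, hematocrit, organ-site enzyme abundances, expressor
#' flags, and the subject-level absorption-rate multiplier `ka_mult`.
#'
#' @param spec A [population_spec()].
#' @return A tibble with one row per individual, columns `id`, `trial`,
#'   `age`, `sex`, `weight`, `height`, `hematocrit`, `liver_cyp3a4`,
#'   `liver_cyp3a5`, `gut_cyp3a4`, `gut_cyp3a5`, `colon_cyp3a5`,
#'   `expressor_liver`, `expressor_gut`, `ka_mult`.
#' @examples
#' pop <- sample_population(population_spec("healthy", 2, 10, seed = 42))
#' mean(pop$expressor_liver)
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  trials <- map(seq_len(spec$n_trials), function(tr) {
    set.seed(trial_seed(spec$seed, tr))
    n <- spec$n_per_trial
    if (spec$kind == "twin") {
      ind <- sample_twin_trial(spec)
    } else {
      ind <- sample_open_trial(spec, n)
    }
    ind$trial <- tr
    ind
  })
  pop <- list_rbind(trials)
  pop$id <- seq_len(nrow(pop))
  pop <- select(pop, "id", "trial", everything())
  class(pop) <- c("vt_population", class(pop))
  attr(pop, "spec") <- spec
  pop
}

sample_open_trial <- function(spec, n) {
  age_range <- if (spec$kind == "geriatric") c(65, 85) else c(20, 50)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  is_f <- sex == "female"
  weight <- ifelse(is_f, 61, 70) * rlnorm_med1(n, 0.15)
  height <- rnorm(n, mean = ifelse(is_f, 163, 176), sd = 7)
  hct <- pmin(pmax(rnorm(n, ifelse(is_f, 0.41, 0.46), 0.03), 0.30), 0.55)

  expressor <- rbinom(n, 1, spec$expressor_frequency) == 1
  liver5 <- ifelse(expressor, rlnorm_med1(n, spec$cv_liver_abundance), 0)
  gut5 <- ifelse(expressor, rlnorm_med1(n, spec$cv_gut_abundance), 0)
  colon5 <- ifelse(expressor, rlnorm_med1(n, spec$cv_gut_abundance), 0)

  tibble(
    age = runif(n, age_range[1], age_range[2]), sex = sex,
    weight = weight, height = height, hematocrit = hct,
    liver_cyp3a4 = rlnorm_med1(n, spec$cv_liver_abundance),
    liver_cyp3a5 = liver5,
    gut_cyp3a4 = rlnorm_med1(n, spec$cv_gut_abundance),
    gut_cyp3a5 = gut5, colon_cyp3a5 = colon5,
    expressor_liver = expressor, expressor_gut = expressor,
    ka_mult = rlnorm_med1(n, spec$cv_ka)
  )
}

sample_twin_trial <- function(spec) {
  cov <- spec$twin_covariates
  expr <- isTRUE(cov$cyp3a5_expressor)
  tibble(
    age = cov$age, sex = cov$sex, weight = cov$weight, height = cov$height,
    hematocrit = cov$hematocrit,
    liver_cyp3a4 = rlnorm_med1(1, spec$cv_liver_abundance),
    liver_cyp3a5 = if (expr) 1 else 0,
    gut_cyp3a4 = rlnorm_med1(1, spec$cv_gut_abundance),
    gut_cyp3a5 = if (expr) 1 else 0,
    colon_cyp3a5 = if (expr) 1 else 0,
    expressor_liver = expr, expressor_gut = expr,
    ka_mult = rlnorm_med1(1, spec$cv_ka)
  )
}

#' Build a virtual twin individual
#'
#' A single individual with fixed (unsampled) covariates, as used to
#' replicate one patient: demographics, hematocrit, and CYP3A5 genotype are
#' set exactly; CYP3A5 abundances are 0 at every site for a non-expressor
#' and 1 (the reference expressor level) at every site otherwise.
#'
#' @param age Years.
#' @param sex `"female"` or `"male"`.
#' @param weight kg.
#' @param height cm.
#' @param hematocrit Fraction in (0.1, 0.6).
#' @param cyp3a5_expressor Logical genotype flag (applies to all sites).
#' @return A one-row individual tibble as in [sample_population()].
#' @examples
#' make_virtual_twin(age = 70, sex = "female", weight = 70, height = 163,
#'                   hematocrit = 0.237, cyp3a5_expressor = FALSE)
#' @export
make_virtual_twin <- function(age, sex, weight, height, hematocrit,
                              cyp3a5_expressor = FALSE) {
  absent <- c("age", "sex", "weight", "height", "hematocrit")[
    c(missing(age), missing(sex), missing(weight), missing(height),
      missing(hematocrit))]
  if (length(absent)) {
    abort(sprintf("Missing twin covariate(s): %s.",
                  paste(absent, collapse = ", ")))
  }
  cov <- check_twin_covariates(as.list(environment())[twin_fields])
  expr <- isTRUE(cyp3a5_expressor)
  tibble(
    id = 1L, trial = 1L, age = age, sex = sex, weight = weight,
    height = height, hematocrit = hematocrit,
    liver_cyp3a4 = 1, liver_cyp3a5 = if (expr) 1 else 0,
    gut_cyp3a4 = 1, gut_cyp3a5 = if (expr) 1 else 0,
    colon_cyp3a5 = if (expr) 1 else 0,
    expressor_liver = expr, expressor_gut = expr, ka_mult = 1
  )
}
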