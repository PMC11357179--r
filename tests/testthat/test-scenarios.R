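tac <- load_compound("tacrolimus")

twin_cov <- list(age = 70, sex = "female", weight = 70, height = 163,
                 hematocrit = 0.237, cyp3a5_expressor = FALSE)

det_scenario <- function(name = "det", expressor = FALSE, ...) {
  cov <- twin_cov
  cov$hematocrit <- 0.45
  cov$cyp3a5_expressor <- expressor
  spec <- population_spec("twin", n_trials = 1, n_per_trial = 1,
                          cv_liver_abundance = 0, cv_gut_abundance = 0,
                          cv_ka = 0, seed = 1, twin_covariates = cov)
  scenario(name, spec, ...)
}

test_that("apply_scenario implements the donor/recipient site logic", {
  pop <- ref_individual(liver5 = 1.3, gut5 = 0.8)
  donor <- apply_scenario(pop, det_scenario(recipient_expressor = FALSE))
  expect_equal(donor$liver_cyp3a5, 1.3)
  expect_equal(donor$gut_cyp3a5 + donor$colon_cyp3a5, 0)
  recip <- apply_scenario(pop, det_scenario(donor_expressor = FALSE))
  expect_equal(recip$liver_cyp3a5, 0)
  expect_equal(recip$gut_cyp3a5, 0.8)
  neither <- apply_scenario(pop, det_scenario(donor_expressor = FALSE,
                                              recipient_expressor = FALSE))
  expect_equal(neither$liver_cyp3a5 + neither$gut_cyp3a5 +
                 neither$colon_cyp3a5, 0)
  both <- apply_scenario(pop, det_scenario())
  expect_identical(as.data.frame(both), as.data.frame(pop))
  frac <- apply_scenario(pop, det_scenario(liver_function_fraction = 0.1))
  expect_equal(frac$liver_cyp3a4, pop$liver_cyp3a4 * 0.1)
  expect_equal(frac$liver_cyp3a5, pop$liver_cyp3a5 * 0.1)
  expect_equal(frac$gut_cyp3a4, pop$gut_cyp3a4)
})

test_that("geometric statistics match closed forms", {
  expect_equal(geometric_stats(c(4, 4, 4))$gm, 4)
  expect_equal(geometric_stats(c(4, 4, 4))$lo, 4)
  expect_equal(geometric_stats(c(1, 10))$gm, sqrt(10), tolerance = 1e-12)
  expect_equal(geometric_stats(c(1, 2, 4, 8))$gm, 2^1.5, tolerance = 1e-12)
  expect_error(geometric_stats(c(1, 0, 2)), "positive")
  # trial-level CI collapses toward the GM as trials agree
  x <- rep(c(2, 2.2), each = 10)
  tr <- rep(1:4, each = 5)
  ci <- geometric_stats(x, interval = "trial_ci", trial = tr)
  expect_true(ci$lo <= ci$gm && ci$gm <= ci$hi)
})

test_that("IV dose matching is exact under linear kinetics", {
  probe <- match_iv_dose(NULL, tac, target_auc = 50)
  half <- match_iv_dose(NULL, tac, target_auc = 25)
  expect_equal(half$dose, probe$dose / 2, tolerance = 1e-6)
  expect_lt(abs(probe$ratio - 1), 0.01)
  expect_lt(abs(half$ratio - 1), 0.01)
  # probe AUC equal to target returns the probe dose
  prof <- simulate_profile(NULL, tac,
                           regimen("iv_infusion", 1, duration = 168))
  auc1 <- nca_summary(prof, regimen("iv_infusion", 1, duration = 168))$auc_tau
  m <- match_iv_dose(NULL, tac, auc1)
  expect_equal(m$dose, 1, tolerance = 1e-9)
  expect_error(match_iv_dose(NULL, tac, target_auc = -1), "target_auc")
})

test_that("deterministic scenario results are reproducible", {
  scn <- det_scenario()
  r1 <- run_scenario(scn)
  r2 <- run_scenario(scn)
  expect_identical(as.data.frame(tidy(r1)), as.data.frame(tidy(r2)))
  expect_equal(r1$summary$ratio_auc, 1, tolerance = 0.01)
  expect_equal(nrow(tidy(r1)), 1)
})

test_that("dose ratio equals inverse oral bioavailability for one subject", {
  scn <- det_scenario()
  res <- run_scenario(scn)
  fg <- gut_availability(tac, reference_physiology())
  fh <- hepatic_clearance(tac, reference_physiology())$fh
  theory <- 1 / (tac$fa * fg * fh)
  expect_lt(abs(glance(res)$po_iv_dose_ratio / theory - 1), 0.05)
})

test_that("genotype geography orders oral exposure as expected", {
  aucs <- vapply(
    list(both = c(1, 1), donor = c(1, 0), recipient = c(0, 1),
         none = c(0, 0)),
    function(g) {
      ind <- ref_individual(liver5 = g[1], gut5 = g[2])
      po <- regimen("oral", 1, 12, 168)
      nca_summary(simulate_profile(ind, tac, po), po)$auc_tau
    },
    numeric(1)
  )
  expect_true(aucs[["both"]] < aucs[["donor"]])
  expect_true(aucs[["donor"]] < aucs[["recipient"]])
  expect_true(aucs[["recipient"]] < aucs[["none"]])
})

test_that("oral exposure rises monotonically as liver function falls", {
  aucs <- vapply(c(1, 0.5, 0.25, 0.1), function(lff) {
    scn <- det_scenario(liver_function_fraction = lff)
    glance(run_scenario(scn, verify = FALSE))$gm_auc_po
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("oral itraconazole shrinks the dose ratio more than IV", {
  po_itz <- det_scenario(perpetrator = list(compound = "itraconazole",
                                            route = "oral", dose = 200,
                                            interval = 24))
  iv_itz <- det_scenario(perpetrator = list(compound = "itraconazole",
                                            route = "iv_infusion",
                                            dose = 200, interval = 24))
  none <- det_scenario()
  r <- vapply(list(po_itz, iv_itz, none),
              function(s) glance(run_scenario(s))$po_iv_dose_ratio,
              numeric(1))
  expect_lt(r[1], r[2])
  expect_lt(r[2], r[3])
})

test_that("gut CYP3A5 is irrelevant in a non-expressor", {
  # zeroing an already-zero gut CYP3A5 site must change nothing
  base <- det_scenario()
  zeroed <- det_scenario(recipient_expressor = FALSE)
  r1 <- run_scenario(base)
  r2 <- run_scenario(zeroed)
  expect_identical(as.data.frame(tidy(r1)[-1]), as.data.frame(tidy(r2)[-1]))
})

test_that("scenario report carries the dose-conversion columns", {
  res <- run_scenario(det_scenario())
  rep <- scenario_report(res)
  expect_named(rep, c("scenario", "dose_po_mg_12h", "auc_po", "cmin",
                      "dose_iv_mg_24h", "auc_iv", "css", "ratio_auc",
                      "ratio_po_iv_dose", "ratio_css_cmin"))
  expect_equal(rep$ratio_auc, 1)
})
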