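test_that("expressor frequency matches the requested probability", {
  spec <- population_spec("healthy", n_trials = 10, n_per_trial = 1000,
                          expressor_frequency = 0.17, seed = 101)
  pop <- sample_population(spec)
  n <- nrow(pop)
  se <- sqrt(0.17 * 0.83 / n)
  expect_lt(abs(mean(pop$expressor_liver) - 0.17), 3 * se)
  # expressor status is consistent across organ sites and with abundances
  expect_identical(pop$expressor_liver, pop$expressor_gut)
  expect_true(all((pop$liver_cyp3a5 > 0) == pop$expressor_liver))
  expect_true(all((pop$gut_cyp3a5 > 0) == pop$expressor_gut))
  expect_true(all(pop$liver_cyp3a5[!pop$expressor_liver] == 0))
  expect_true(all(pop$colon_cyp3a5[!pop$expressor_gut] == 0))
})

test_that("degenerate spec yields identical individuals", {
  spec <- population_spec("healthy", n_trials = 1, n_per_trial = 50,
                          expressor_frequency = 0,
                          cv_liver_abundance = 0, cv_gut_abundance = 0,
                          cv_ka = 0, seed = 3)
  pop <- sample_population(spec)
  expect_true(all(pop$liver_cyp3a5 == 0))
  expect_true(all(pop$liver_cyp3a4 == 1))
  expect_true(all(pop$gut_cyp3a4 == 1))
  expect_true(all(pop$ka_mult == 1))
})

test_that("sampling is reproducible from the seed and ids are unique", {
  spec <- population_spec("healthy", n_trials = 4, n_per_trial = 25, seed = 77)
  p1 <- sample_population(spec)
  p2 <- sample_population(spec)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_equal(nrow(p1), 100)
  expect_false(any(duplicated(p1$id)))
  expect_equal(sort(unique(p1$trial)), 1:4)
  p3 <- sample_population(population_spec("healthy", 4, 25, seed = 78))
  expect_false(identical(as.data.frame(p1), as.data.frame(p3)))
})

test_that("log-normal abundance sampling preserves the median near 1", {
  spec <- population_spec("healthy", n_trials = 1, n_per_trial = 20000,
                          seed = 5)
  pop <- sample_population(spec)
  # sdlog for CV 0.35 is ~0.34; median MC error ~ 1.25*sd/sqrt(n)
  expect_lt(abs(median(pop$liver_cyp3a4) - 1), 0.02)
  expect_lt(abs(median(pop$gut_cyp3a4) - 1), 0.03)
})

test_that("age ranges distinguish healthy and geriatric populations", {
  h <- sample_population(population_spec("healthy", 1, 200, seed = 9))
  g <- sample_population(population_spec("geriatric", 1, 200, seed = 9))
  expect_true(all(h$age >= 20 & h$age <= 50))
  expect_true(all(g$age >= 65 & g$age <= 85))
  expect_true(all(h$hematocrit > 0.1 & h$hematocrit < 0.6))
})

test_that("virtual twin fixes covariates and genotype", {
  tw <- make_virtual_twin(age = 70, sex = "female", weight = 70,
                          height = 163, hematocrit = 0.237,
                          cyp3a5_expressor = FALSE)
  expect_equal(tw$hematocrit, 0.237)
  expect_equal(tw$liver_cyp3a5 + tw$gut_cyp3a5 + tw$colon_cyp3a5, 0)
  expect_error(
    make_virtual_twin(age = 70, sex = "female", weight = 70, height = 163),
    "hematocrit"
  )
  expr_tw <- make_virtual_twin(age = 40, sex = "male", weight = 80,
                               height = 180, hematocrit = 0.45,
                               cyp3a5_expressor = TRUE)
  expect_equal(unlist(expr_tw[c("liver_cyp3a5", "gut_cyp3a5",
                                "colon_cyp3a5")], use.names = FALSE),
               c(1, 1, 1))
})

test_that("twin population specs demand n_per_trial 1 and full covariates", {
  cov <- list(age = 70, sex = "female", weight = 70, height = 163,
              hematocrit = 0.237, cyp3a5_expressor = FALSE)
  expect_error(population_spec("twin", n_trials = 10, n_per_trial = 5,
                               twin_covariates = cov), "n_per_trial")
  expect_error(population_spec("twin", n_trials = 10, n_per_trial = 1,
                               twin_covariates = cov[-5]), "hematocrit")
  spec <- population_spec("twin", n_trials = 10, n_per_trial = 1,
                          twin_covariates = cov, seed = 4)
  pop <- sample_population(spec)
  expect_equal(nrow(pop), 10)
  expect_true(all(pop$hematocrit == 0.237))
  expect_true(all(pop$liver_cyp3a5 == 0))
  # abundance variability persists across twin trials
  expect_gt(stats::sd(pop$liver_cyp3a4), 0)
})
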