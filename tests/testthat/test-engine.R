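tac <- load_compound("tacrolimus")
itz <- load_compound("itraconazole")
po_1mg <- regimen("oral", dose = 1, interval = 12, duration = 168)

test_that("inhibition factor follows competitive kinetics", {
  expect_equal(inhibition_factor(0, 5), 1)
  expect_equal(inhibition_factor(5, 5), 0.5)
  expect_equal(inhibition_factor(15, 5), 0.25)   # I = 3 Ki -> 1/(1+3)
  expect_error(inhibition_factor(1, 0), "ki")
  expect_error(inhibition_factor(-1, 5), "i_unbound")
})

test_that("gut availability follows the flow-limited extraction model", {
  phys <- reference_physiology()
  none <- load_compound("tacrolimus",
                        overrides = list(clint_cyp3a4_gut = 0,
                                         clint_cyp3a5_gut = 0))
  expect_equal(gut_availability(none, phys), 1)
  half <- load_compound("tacrolimus",
                        overrides = list(clint_cyp3a4_gut = 18,
                                         clint_cyp3a5_gut = 0, fu_gut = 1))
  expect_equal(gut_availability(half, phys), 0.5)  # Q/(Q + CLint), Q = 18
  # zero CYP3A5 abundance: the CYP3A5 term cannot contribute
  p0 <- reference_physiology(gut_cyp3a5 = 0)
  big5 <- load_compound("tacrolimus",
                        overrides = list(clint_cyp3a5_gut = 1e6))
  expect_equal(gut_availability(big5, p0), gut_availability(tac, p0))
})

test_that("hepatic clearance follows the well-stirred model", {
  none <- load_compound("tacrolimus",
                        overrides = list(clint_cyp3a4_liver = 0,
                                         clint_cyp3a5_liver = 0))
  hc <- hepatic_clearance(none)
  expect_equal(hc$cl_h, 0)
  expect_equal(hc$fh, 1)
  # closed form: Qh = 90, fu_b * CLint = 100 -> CL = 9000/190
  cust <- compound_params(
    name = "x", molecular_weight = 500, fu_plasma = 0.1, bp_ratio_ref = 1,
    fa = 1, ka = 1, fu_gut = 1, clint_cyp3a4_liver = 1000,
    clint_cyp3a5_liver = 0, clint_cyp3a4_gut = 0, clint_cyp3a5_gut = 0,
    vss = 1
  )
  phys90 <- reference_physiology(hepatic_blood_flow = 90)
  hc2 <- hepatic_clearance(cust, phys90)   # fu_b = 0.1, CLint = 1000
  expect_equal(hc2$cl_h, 9000 / 190, tolerance = 1e-12)
  expect_equal(hc2$fh, 1 - (9000 / 190) / 90, tolerance = 1e-12)
  # flow limit
  sat <- hepatic_clearance(cust, phys90, hematocrit = 0.45)
  huge <- compound_params(
    name = "x", molecular_weight = 500, fu_plasma = 1, bp_ratio_ref = 1,
    fa = 1, ka = 1, fu_gut = 1, clint_cyp3a4_liver = 1e9,
    clint_cyp3a5_liver = 0, clint_cyp3a4_gut = 0, clint_cyp3a5_gut = 0,
    vss = 1
  )
  expect_equal(hepatic_clearance(huge, phys90)$cl_h, 90, tolerance = 1e-6)
})

test_that("zero dose yields an identically zero profile", {
  prof <- simulate_profile(NULL, tac, regimen("oral", 0, 12, 168))
  expect_true(all(prof$conc == 0))
})

test_that("infusion reaches the analytic plateau R/CL", {
  cmp <- one_cpt_compound(cl = 2, vss = 0.5)   # t1/2 ~ 12 h
  reg <- regimen("iv_infusion", dose = 24, duration = 400)  # 1 mg/h
  prof <- simulate_profile(NULL, cmp, reg, nca_window = c(380, 400))
  plateau <- 1 / 2 * 1000   # R/CL in ng/mL
  tail_conc <- prof$conc[prof$time >= 390]
  expect_true(all(abs(tail_conc / plateau - 1) < 1e-3))
})

test_that("engine matches the one-compartment oral closed form", {
  cmp <- one_cpt_compound(cl = 3, vss = 0.8, ka = 0.9, fa = 0.7)
  prof <- simulate_profile(NULL, cmp, po_1mg)
  v <- 0.8 * 70
  expected <- oral_1cpt_conc(prof$time, dose = 1, tau = 12, fa = 0.7,
                             ka = 0.9, cl = 3, v = v)
  sel <- expected > max(expected) * 1e-6
  expect_true(all(abs(prof$conc[sel] / expected[sel] - 1) < 1e-3))
})

test_that("doubling the dose doubles every concentration", {
  p1 <- simulate_profile(NULL, tac, po_1mg)
  p2 <- simulate_profile(NULL, tac, regimen("oral", 2, 12, 168))
  sel <- p1$conc > max(p1$conc) * 1e-9
  expect_true(all(abs(p2$conc[sel] / p1$conc[sel] - 2) < 2e-3))
})

test_that("mass balance closes after a single oral dose", {
  prof <- simulate_profile(NULL, tac, regimen("oral", 1, 600, 600),
                           return_states = TRUE)
  st <- attr(prof, "states")
  final <- st[nrow(st), ]
  total <- final[["lumen_v"]] + final[["central_v"]] +
    final[["peripheral_v"]] + final[["eliminated_v"]]
  expect_equal(total, tac$fa * 1, tolerance = 1e-3)
  # and most of the absorbed dose has been eliminated by 600 h
  expect_gt(final[["eliminated_v"]] / (tac$fa * 1), 0.95)
})

test_that("oral perpetrator exposes the gut more than IV at equal dose", {
  po <- simulate_profile(NULL, tac, po_1mg, itz,
                         regimen("oral", 200, 24, 168))
  iv <- simulate_profile(NULL, tac, po_1mg, itz,
                         regimen("iv_infusion", 200, 24, 168,
                                 infusion_duration = 1))
  none <- simulate_profile(NULL, tac, po_1mg)
  mean_fg <- function(p) mean(attr(p, "aux")$fg)
  expect_gte(mean(attr(po, "aux")$i_gut), mean(attr(iv, "aux")$i_gut))
  expect_gte(mean_fg(po), mean_fg(iv))
  expect_gte(mean_fg(iv), mean_fg(none))
})

test_that("organ-site CYP3A5 separation is exact", {
  expressor <- ref_individual(liver5 = 1, gut5 = 1)
  gut_only <- ref_individual(liver5 = 0, gut5 = 1)
  liver_only <- ref_individual(liver5 = 1, gut5 = 0)
  aux <- function(ind) attr(simulate_profile(ind, tac, po_1mg), "aux")
  a_expr <- aux(expressor); a_gut <- aux(gut_only); a_liv <- aux(liver_only)
  # zeroing liver CYP3A5 changes Fh only
  expect_equal(a_gut$fg, a_expr$fg)
  expect_true(all(a_gut$fh > a_expr$fh))
  # zeroing gut CYP3A5 changes Fg only
  expect_equal(a_liv$fh, a_expr$fh)
  expect_true(all(a_liv$fg > a_expr$fg))
})

test_that("perpetrators without inhibition constants are rejected", {
  expect_error(
    simulate_profile(NULL, tac, po_1mg, tac, regimen("oral", 1, 24, 168)),
    "cannot be used as a perpetrator"
  )
  expect_error(simulate_profile(NULL, tac, po_1mg, itz), "perpetrator_regimen")
})
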