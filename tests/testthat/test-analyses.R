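test_that("removing the sole substrate kills the yield; passthrough-only \
compounds are neutral", {
  s <- sensitivity_scan(toy_setup_single(toy_media("M2")))
  # glucose is TOY-A's only substrate
  expect_equal(s$relative_yield_max_pct[s$compound == "glc"], 0,
               tolerance = 1e-6)
  # xylose only passes through: removing it changes nothing
  expect_equal(s$relative_yield_max_pct[s$compound == "xyl"], 100,
               tolerance = 1e-6)
  expect_true(all(s$status == "ok"))
})

# Organism whose growth needs two precursors: bmA from glucose and bmX from
# either 'aux' (abundant) or 'nit' (scarce). Removing aux lowers BM_MAX to
# the nit-limited level, freeing glucose for fermentation — the mechanism
# behind relative yields above 100%.
make_auxotroph <- function() {
  metabolic_model(list(
    list(id = "FERM", stoich = c(glc = -1, etoh = 2, co2 = 2),
         lb = 0, ub = 1000),
    list(id = "GP", stoich = c(glc = -1, bmA = 1), lb = 0, ub = 1000),
    list(id = "AX", stoich = c(aux = -1, bmX = 1), lb = 0, ub = 1000),
    list(id = "NX", stoich = c(nit = -1, bmX = 1), lb = 0, ub = 1000),
    list(id = "GROW", stoich = c(bmA = -1, bmX = -1), lb = 0, ub = 1000),
    list(id = "EX_etoh", stoich = c(etoh = -1), lb = 0, ub = 1000),
    list(id = "EX_co2", stoich = c(co2 = -1), lb = 0, ub = 1000)),
    growth_id = "GROW", id = "AUXO")
}

auxotroph_registry <- function() {
  compound_registry(c("glc", "aux", "nit", "etoh", "co2"), "AUXO",
                    c("glc", "aux", "nit", "etoh", "co2"),
                    mw = c(180, 100, 60, 46, 44))
}

test_that("sensitivity values above 100% are legal and not clamped", {
  # glc 4 mmol, aux 2 mmol, nit 0.5 mmol: BM_MAX 2.5 eats 2.5 glc, leaving
  # 1.5 for ethanol. Without aux BM_MAX drops to 0.5, leaving 3.5.
  md <- media_composition(c("glc", "aux", "nit"), c(720, 200, 30),
                          c(180, 100, 60))
  setup <- fermentation_setup(list(make_auxotroph()), md, "etoh",
                              auxotroph_registry())
  s <- sensitivity_scan(setup)
  expect_equal(
    s$relative_yield_max_pct[s$compound == "aux"],
    100 * (2 * (4 - 0.5)) / (2 * (4 - 2.5)), tolerance = 1e-4)
  expect_gt(s$relative_yield_max_pct[s$compound == "aux"], 100)
})

test_that("a zero baseline marks rows undefined instead of dividing by zero", {
  # glc 2.5 mmol is exactly what growth consumes: baseline max yield 0;
  # removing aux frees glucose, so new/0 is undefined, not infinite
  md <- media_composition(c("glc", "aux", "nit"), c(450, 200, 30),
                          c(180, 100, 60))
  setup <- fermentation_setup(list(make_auxotroph()), md, "etoh",
                              auxotroph_registry())
  s <- sensitivity_scan(setup)
  aux <- s[s$compound == "aux", ]
  expect_true(is.na(aux$relative_yield_max_pct))
  expect_identical(aux$status, "undefined")
  # glc removal keeps the product at zero: 0/0 reads as unchanged
  expect_equal(s$relative_yield_max_pct[s$compound == "glc"], 100,
               tolerance = 1e-6)
  expect_identical(s$status[s$compound == "glc"], "ok")
})

test_that("sensitivity scan is idempotent after removal", {
  md <- toy_media("M2")
  md$mass_mg[md$compound_id == "xyl"] <- 0
  s <- sensitivity_scan(
    fermentation_setup(list(make_toy_A()), md, "etoh", toy_registry()))
  expect_equal(s$relative_yield_max_pct[s$compound == "xyl"], 100,
               tolerance = 1e-9)
})

test_that("the glucose gradient matches the closed-form marginal yield", {
  g <- gradient_scan(toy_setup_single(toy_media("M1")))
  # marginal glucose converts at 2 * 46 / 180 mg ethanol per mg glucose
  expect_equal(g$gradient_max[g$compound == "glc"], 2 * 46 / 180,
               tolerance = 1e-4)
  expect_equal(g$gradient_min[g$compound == "glc"], 0, tolerance = 1e-6)
})

test_that("an unusable compound has gradient zero", {
  g <- gradient_scan(toy_setup_single(toy_media("M2")))
  expect_equal(g$gradient_max[g$compound == "xyl"], 0, tolerance = 1e-6)
  expect_equal(g$gradient_min[g$compound == "xyl"], 0, tolerance = 1e-6)
})

test_that("gradient-sensitivity consistency on the toys", {
  # a compound neutral under removal (relative yield 100, no alternative
  # use) must have zero gradient
  s <- sensitivity_scan(toy_setup_single(toy_media("M2")))
  g <- gradient_scan(toy_setup_single(toy_media("M2")))
  neutral <- s$compound[abs(s$relative_yield_max_pct - 100) < 1e-6]
  expect_true("xyl" %in% neutral)
  for (cmp in neutral) {
    expect_equal(g$gradient_max[g$compound == cmp], 0, tolerance = 1e-6,
                 label = cmp)
  }
})

test_that("scenario enumeration counts (n1+1)(n2+1)", {
  expect_identical(enumerate_knockout_scenarios(2280, 2914), 6649115)
  expect_identical(enumerate_knockout_scenarios(0, 0), 1)
  expect_identical(enumerate_knockout_scenarios(2, 3), 12)
  grid <- knockout_scenario_grid(c("r1", "r2"), c("q1", "q2", "q3"))
  expect_equal(nrow(grid), 12)
  expect_equal(unname(unlist(grid[1, ])), c("none", "none"))
  expect_equal(anyDuplicated(paste(grid$ko1, grid$ko2)), 0)
})

test_that("knockout scan covers the grid and normalizes to the wild type", {
  setup <- toy_setup_pair()
  scan <- knockout_scan(setup)
  n1 <- length(organism_reactions(
    build_module(make_toy_A(), toy_media("M2"), "etoh", toy_registry())))
  n2 <- length(organism_reactions(
    build_module(make_toy_B(), toy_media("M2"), "etoh", toy_registry(),
                 index = 2)))
  expect_equal(nrow(scan), (n1 + 1) * (n2 + 1))
  wt <- scan[scan$ko1 == "none" & scan$ko2 == "none", ]
  expect_equal(wt$yield_min_rel_pct, 100)
  expect_equal(wt$yield_max_rel_pct, 100)
  # knocking FERM in organism 1 leaves only step 2's contribution
  f <- scan[scan$ko1 == "FERM" & scan$ko2 == "none", ]
  step2 <- (500 / 150 - 0.5) * (5 / 3) * 46
  expect_equal(f$yield_max_rel_pct,
               100 * step2 / (TWO_STEP_M2_YIELD_MAX * 10), tolerance = 1e-3)
  # knocking both fermentation routes kills the yield
  ff <- scan[scan$ko1 == "FERM" & scan$ko2 == "FERMX", ]
  expect_equal(ff$yield_max_rel_pct, 0, tolerance = 1e-6)
  expect_true(all(scan$status == "done"))
})

test_that("scan results are independent of worker count, byte for byte", {
  dir <- withr::local_tempdir()
  setup <- toy_setup_pair()
  s1 <- knockout_scan(setup, workers = 1)
  s4 <- knockout_scan(setup, workers = 4)
  p1 <- write_knockout_csv(s1, file.path(dir, "w1.csv"))
  p4 <- write_knockout_csv(s4, file.path(dir, "w4.csv"))
  expect_identical(readLines(p1), readLines(p4))
})

test_that("single-organism scans work with ko2 pinned to none", {
  scan <- knockout_scan(toy_setup_single())
  expect_equal(nrow(scan), 4) # 3 reactions + WT
  expect_true(all(scan$ko2 == "none"))
  expect_equal(scan$yield_max_rel_pct[scan$ko1 == "FERM"], 0,
               tolerance = 1e-6)
})

test_that("base knockouts merge into every scenario (nested scheme)", {
  setup <- toy_setup_pair()
  scan <- knockout_scan(setup, base_knockouts = list("FERM", character(0)))
  wt <- scan[scan$ko1 == "none" & scan$ko2 == "none", ]
  expect_equal(wt$yield_max_rel_pct, 100) # WT of the nested stage
  # step 1 can no longer ferment anywhere in this stage
  attr_wt <- attr(scan, "wild_type")
  expect_equal(unname(attr_wt["yield_max_pct"]) * 10,
               (500 / 150 - 0.5) * (5 / 3) * 46, tolerance = 1e-3)
})

test_that("campaign planning enumerates pipes x media x targets x conditions", {
  cp <- plan_campaign(3, 5, 4, 2)
  expect_identical(cp$n_configurations, 240L)
  expect_identical(cp$n_tasks, 480L)
  cp1 <- plan_campaign("hydrolysate", "etoh", "yeast", "anaerobic")
  expect_identical(cp1$n_configurations, 1L)
  expect_identical(cp1$n_tasks, 1L)
  # n singles + n(n-1) ordered pairs
  cp2 <- plan_campaign(1, 1, 3, 1)
  expect_identical(cp2$n_configurations, 9L)
  expect_error(plan_campaign(1, 1, c("a", "a")), "duplicate")
})
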