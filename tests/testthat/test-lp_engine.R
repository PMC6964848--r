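toyA_module <- function(media = toy_media("M1")) {
  build_module(make_toy_A(), media, "etoh", toy_registry())
}

test_that("FBA on TOY-A reproduces the hand-derived optimum", {
  mod <- toyA_module()
  fba <- solve_fba(mod)
  expect_identical(fba$status, "optimal")
  expect_equal(fba$bm_max, 1, tolerance = 1e-9) # capped by the growth UB
  # witness satisfies S v = 0 and the bounds
  lp <- serialferm:::module_lp(mod)
  expect_lt(max(abs(lp$S %*% fba$fluxes)), 1e-6)
  expect_true(all(fba$fluxes >= lp$lb - 1e-7 & fba$fluxes <= lp$ub + 1e-7))
})

test_that("a module with zero feed cannot grow", {
  md <- media_composition("glc", 0, 180)
  fba <- solve_fba(build_module(make_toy_A(), md, "etoh", toy_registry()))
  expect_equal(fba$bm_max, 0, tolerance = 1e-9)
})

test_that("FVA of the ethanol transporter matches the hand LP", {
  mod <- toyA_module()
  fba <- solve_fba(mod)
  fva <- solve_fva(mod, bm_max = fba$bm_max)
  expect_equal(fva$v_min, 0, tolerance = 1e-6)
  expect_equal(fva$v_max, TOYA_M1_ETOH_MAX, tolerance = 1e-4)
  expect_lte(fva$v_min, fva$v_max)
})

test_that("FVA of the growth reaction itself returns bm_max twice", {
  mod <- toyA_module()
  fba <- solve_fba(mod)
  fva <- solve_fva(mod, mod$growth_id, fba$bm_max)
  expect_equal(fva$v_min, fba$bm_max, tolerance = 1e-5)
  expect_equal(fva$v_max, fba$bm_max, tolerance = 1e-5)
})

test_that("a dead-end target has zero variability", {
  # xylose uptake does not exist for TOY-A; use the pass transporter of a
  # compound that is entirely unused: range pins to the full passthrough
  m <- metabolic_model(list(
    list(id = "FERM", stoich = c(glc = -1, etoh = 2, co2 = 2), lb = 0,
         ub = 0), # fermentation disabled: ethanol is a dead end
    list(id = "GROW_PRE", stoich = c(glc = -1, bmA = 1), lb = 0, ub = 1000),
    list(id = "GROW", stoich = c(bmA = -1), lb = 0, ub = 1),
    list(id = "EX_etoh", stoich = c(etoh = -1), lb = 0, ub = 1000)),
    growth_id = "GROW", id = "TOYA")
  mod <- build_module(m, toy_media("M1"), "etoh", toy_registry())
  fba <- solve_fba(mod)
  fva <- solve_fva(mod, bm_max = fba$bm_max)
  expect_equal(c(fva$v_min, fva$v_max), c(0, 0), tolerance = 1e-9)
})

test_that("knockouts nullify bounds on a copy and respect unknown ids", {
  mod <- toyA_module()
  ko <- apply_knockouts(mod, "FERM")
  expect_equal(c(ko$reactions$FERM$lb, ko$reactions$FERM$ub), c(0, 0))
  expect_equal(mod$reactions$FERM$ub, 1000) # original untouched
  expect_identical(apply_knockouts(mod, character(0)), mod)
  expect_error(apply_knockouts(mod, "NOPE"), "NOPE")
})

test_that("knockout of the growth route or fermentation route acts as derived", {
  mod <- toyA_module()
  expect_equal(solve_fba(apply_knockouts(mod, "GROW_PRE"))$bm_max, 0,
               tolerance = 1e-9)
  ko <- apply_knockouts(mod, "FERM")
  fba <- solve_fba(ko)
  expect_equal(fba$bm_max, 1, tolerance = 1e-9)
  fva <- solve_fva(ko, bm_max = fba$bm_max)
  expect_equal(fva$v_max, 0, tolerance = 1e-9)
})

test_that("knocking out a blocked reaction changes nothing", {
  # add a reaction that can never carry flux (consumes a dead metabolite)
  m <- make_toy_A()
  rxns <- c(unname(m$reactions),
            list(list(id = "BLOCKED", stoich = c(deadmet = -1, co2 = 1),
                      lb = 0, ub = 1000)))
  m2 <- metabolic_model(rxns, growth_id = "GROW", id = "TOYA")
  mod <- build_module(m2, toy_media("M1"), "etoh", toy_registry())
  base_fba <- solve_fba(mod)
  base_fva <- solve_fva(mod, bm_max = base_fba$bm_max)
  ko <- apply_knockouts(mod, "BLOCKED")
  ko_fba <- solve_fba(ko)
  ko_fva <- solve_fva(ko, bm_max = ko_fba$bm_max)
  expect_equal(ko_fba$bm_max, base_fba$bm_max, tolerance = 1e-9)
  expect_equal(ko_fva$v_max, base_fva$v_max, tolerance = 1e-9)
  # and the oracle agrees on both
  expect_equal(oracle_fba(mod)$bm_max, base_fba$bm_max, tolerance = 1e-6)
  expect_equal(oracle_fba(ko)$bm_max, ko_fba$bm_max, tolerance = 1e-6)
})

test_that("FBA agrees with the independent oracle on random networks", {
  # trimmed-down version of the acceptance sweep: 25 seeds here
  for (seed in 1:25) {
    net <- make_random_network(3 + seed %% 6, seed)
    mod <- build_module(net$model, net$media, net$target, net$registry)
    mine <- solve_fba(mod)
    ref <- oracle_fba(mod)
    expect_identical(mine$status, "optimal")
    expect_identical(ref$status, "optimal")
    expect_equal(mine$bm_max, ref$bm_max, tolerance = 1e-6,
                 label = paste("seed", seed))
  }
})

test_that("FVA brackets the FBA witness and the oracle's FVA", {
  for (seed in c(3, 7, 21)) {
    net <- make_random_network(6, seed)
    mod <- build_module(net$model, net$media, net$target, net$registry)
    fba <- solve_fba(mod)
    tgt <- mod$product_id
    fva <- solve_fva(mod, tgt, fba$bm_max)
    expect_lte(fva$v_min - 1e-6, fba$fluxes[[tgt]])
    expect_gte(fva$v_max + 1e-6, fba$fluxes[[tgt]])
    ref <- oracle_fva(mod, tgt, fba$bm_max)
    expect_equal(fva$v_min, ref$v_min, tolerance = 1e-6)
    expect_equal(fva$v_max, ref$v_max, tolerance = 1e-6)
  }
})

test_that("adding a knockout never increases bm_max", {
  mod <- toyA_module(toy_media("M2"))
  ids <- organism_reactions(mod)
  base <- solve_fba(mod)$bm_max
  for (id in ids) {
    one <- solve_fba(apply_knockouts(mod, id))$bm_max
    expect_lte(one, base + 1e-9)
    for (id2 in setdiff(ids, id)) {
      expect_lte(solve_fba(apply_knockouts(mod, c(id, id2)))$bm_max,
                 one + 1e-9)
    }
  }
})

test_that("repeated solves return identical optima", {
  mod <- toyA_module()
  b <- replicate(5, solve_fba(mod)$bm_max)
  expect_true(all(b == b[1]))
})

test_that("organism_reactions excludes envelope transporters by default", {
  mod <- toyA_module()
  expect_setequal(organism_reactions(mod), c("FERM", "GROW_PRE", "GROW"))
  with_tr <- organism_reactions(mod, include_transporters = TRUE)
  expect_true(all(c("feed__glc__1", "uptake__glc__1", "pass__glc__1",
                    "product__etoh__1") %in% with_tr))
})
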