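# Independent LP oracle. Deliberately NOT the package's solver: the module
# LP is re-derived from scratch into boot::simplex's standard form
# (x = v - lb >= 0, equality rows sign-flipped to a non-negative RHS, upper
# bounds as inequality rows), so agreement checks two formulations *and*
# two simplex implementations against each other.

oracle_lp <- function(module, objective_rxn, maximize = TRUE,
                      overrides = NULL) {
  lp <- serialferm:::module_lp(module, overrides)
  obj <- as.numeric(lp$rids == objective_rxn)
  u <- lp$ub - lp$lb
  # presolve: fixed variables (u = 0) stay at lb; their contribution is
  # already inside -S lb. Rows with no remaining support must have rhs 0.
  act <- u > 1e-12
  A3 <- lp$S[, act, drop = FALSE]
  b3 <- as.numeric(-lp$S %*% lp$lb)
  live <- apply(abs(A3), 1, max) > 1e-12
  if (any(!live & abs(b3) > 1e-7)) {
    return(list(status = "infeasible", value = NA_real_))
  }
  A3 <- A3[live, , drop = FALSE]
  b3 <- b3[live]
  neg <- b3 < 0
  A3[neg, ] <- -A3[neg, , drop = FALSE]
  b3 <- abs(b3)
  # boot::simplex needs zero-RHS rows oriented with a positive coefficient
  flip <- b3 < 1e-12 & apply(A3, 1, max) <= 0
  A3[flip, ] <- -A3[flip, , drop = FALSE]
  n <- sum(act)
  r <- boot::simplex(a = obj[act], A1 = diag(n), b1 = u[act], A3 = A3,
                     b3 = b3, maxi = maximize, n.iter = 500 * n, eps = 1e-10)
  if (r$solved != 1) {
    return(list(status = "infeasible", value = NA_real_))
  }
  list(status = "optimal", value = as.numeric(r$value) + sum(obj * lp$lb))
}

oracle_fba <- function(module) {
  r <- oracle_lp(module, module$growth_id, maximize = TRUE)
  list(status = r$status, bm_max = r$value)
}

oracle_fva <- function(module, target, bm_max, epsilon = 1e-6) {
  gr <- module$reactions[[module$growth_id]]
  ov <- list()
  ov[[module$growth_id]] <- c(max(gr$lb, bm_max * (1 - epsilon)), gr$ub)
  list(v_min = oracle_lp(module, target, FALSE, ov)$value,
       v_max = oracle_lp(module, target, TRUE, ov)$value)
}

# shared toy fixtures
toy_setup_single <- function(media = toy_media("M1")) {
  fermentation_setup(list(make_toy_A()), media, "etoh", toy_registry())
}

toy_setup_pair <- function(media = toy_media("M2"), first = "A") {
  models <- if (first == "A") list(make_toy_A(), make_toy_B())
    else list(make_toy_B(), make_toy_A())
  fermentation_setup(models, media, "etoh", toy_registry())
}

# hand-LP constants for the toy suite (derived before the build; see the
# methods vignette): glucose feed 1000/180 mmol, growth cap 1 mmol/h,
# surplus fermented at 2 ethanol per glucose.
TOYA_M1_FEED <- 1000 / 180
TOYA_M1_ETOH_MAX <- 2 * (1000 / 180 - 1) # 9.1111 mmol/h
TOYA_M1_YIELD_MAX <- 100 * 46 * TOYA_M1_ETOH_MAX / 1000 # 41.911 %
TWO_STEP_M2_YIELD_MAX <-
  100 * ((500 / 180 - 1) * 2 * 46 + (500 / 150 - 0.5) * (5 / 3) * 46) / 1000
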