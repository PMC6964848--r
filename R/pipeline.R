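# ---------------------------------------------------------------------------
# Single-step and serial two-step fermentation runs. Yields are accounted in
# percent of the original input media mass (the 1 g basis), computed from the
# FVA min/max of the product transporter with growth fixed at BM_MAX.
#
# Inter-step coupling under alternate optima: for each chain (min and max),
# the residual of a media compound equals fed minus the FVA-maximal uptake
# with both growth and the chain's product flux fixed; secreted by-product
# masses are the FVA-minima of the secrete transporters under the same
# fixes. This is the most conservative (least-transferred) solver-independent
# reading of the serial combination.
# ---------------------------------------------------------------------------

MASS_TOL <- 1e-6

#' Define a fermentation setup
#'
#' @param models list of one or two `fm_model` (step order is process order).
#' @param media an `fm_media`: the feedstock composition on the 1 g basis.
#' @param target canonical id of the product compound (must have a molecular
#'   weight in the media or registry).
#' @param registry a shared `fm_registry` (use the model_id column for
#'   per-organism mappings).
#' @param oxygen a single policy applied to every step, or a list with one
#'   policy per step.
#' @param transfer_biomass also feed the first organism's cell biomass to the
#'   second step (off by default; the conservative reading of serial
#'   transfer).
#' @return an object of class `fm_setup`.
#' @export
fermentation_setup <- function(models, media, target, registry,
                               oxygen = oxygen_policy("anaerobic"),
                               transfer_biomass = FALSE) {
  if (inherits(models, "fm_model")) models <- list(models)
  stopifnot(length(models) %in% 1:2, inherits(media, "fm_media"),
            inherits(registry, "fm_registry"))
  for (m in models) validate_model(m)
  if (!inherits(oxygen, "fm_oxygen_policy") && !is.list(oxygen)) {
    oxygen <- as_oxygen_policy(oxygen)
  }
  if (inherits(oxygen, "fm_oxygen_policy")) {
    oxygen <- rep(list(oxygen), length(models))
  }
  oxygen <- lapply(oxygen, as_oxygen_policy)
  stopifnot(length(oxygen) == length(models))
  if (is.na(compound_mw(target, media, registry))) {
    stop("target '", target, "' has no molecular weight in media or registry")
  }
  structure(list(models = models, media = media, target = target,
                 registry = registry, oxygen = oxygen,
                 transfer_biomass = isTRUE(transfer_biomass)),
            class = "fm_setup")
}

# Zero chain: organism does not grow; nothing is consumed or produced.
zero_chain <- function(module, flag) {
  fed_mg <- stats::setNames(module$media$mass_mg, module$media$compound_id)
  list(bm = 0, v_product = 0, product_mg = 0,
       consumed_mg = fed_mg * 0, residual_mg = fed_mg,
       secreted_mg = stats::setNames(numeric(0), character(0)),
       flags = flag)
}

# One chain (sense = "max" or "min") of one step: FBA, product FVA, then
# uptake/secretion FVA at the fixed growth+product optimum.
step_chain <- function(module, sense = c("max", "min"),
                       knockouts = character(0)) {
  sense <- match.arg(sense)
  module <- apply_knockouts(module, knockouts)
  fba <- solve_fba(module)
  if (fba$status != "optimal") return(zero_chain(module, "infeasible"))
  if (fba$bm_max <= MASS_TOL) return(zero_chain(module, "no-growth"))
  fva <- solve_fva(module, module$product_id, fba$bm_max)
  vt <- if (sense == "max") fva$v_max else fva$v_min
  # fix growth and the chain's product flux, then bound what moved
  slack <- FVA_EPSILON * (1 + abs(vt))
  fix <- list()
  fix[[module$product_id]] <- c(max(0, vt - slack), vt + slack)
  gr <- module$reactions[[module$growth_id]]
  fix[[module$growth_id]] <- c(max(gr$lb, fba$bm_max * (1 - FVA_EPSILON)),
                               gr$ub)
  cmp <- module$media$compound_id
  consumed <- stats::setNames(numeric(length(cmp)), cmp)
  for (cc in cmp) {
    uid <- paste0("uptake__", cc, "__", module$index)
    if (!uid %in% names(module$reactions)) next
    uf <- solve_fva(module, uid, fba$bm_max, overrides = fix)
    consumed[cc] <- uf$v_max
  }
  secreted <- stats::setNames(numeric(0), character(0))
  sids <- names(module$reactions)[vapply(module$reactions, function(r)
    r$role == "secrete", logical(1))]
  for (sid in sids) {
    sf <- solve_fva(module, sid, fba$bm_max, overrides = fix)
    if (sf$v_min > MASS_TOL) {
      lab <- module$reactions[[sid]]$compound
      if (is.na(lab)) lab <- sub("__[0-9]+$", "", sub("^secrete__", "", sid))
      mwc <- module$mw[lab]
      if (is.na(mwc)) {
        stop("secreted compound '", lab, "' (", sf$v_min, " mmol/h) has no ",
             "molecular weight; cannot account its mass")
      }
      secreted[lab] <- sf$v_min * mwc
    }
  }
  fed_mg <- stats::setNames(module$media$mass_mg, module$media$compound_id)
  consumed_mg <- consumed * stats::setNames(module$media$mw, cmp)[names(consumed)]
  residual_mg <- pmax(fed_mg - consumed_mg, 0)
  list(bm = fba$bm_max, v_product = vt,
       product_mg = vt * module$target_mw,
       consumed_mg = consumed_mg, residual_mg = residual_mg,
       secreted_mg = secreted, flags = character(0))
}

#' Derive the transfer media fed to the next fermentation step
#'
#' Combines the residual (non-consumed) media compounds with the secreted
#' by-products of a completed chain, keeping only transferable entries. The
#' product itself is always excluded (it is removed between steps), as are
#' volatile by-products (CO2, H2, ...) and, unless enabled in the setup,
#' the first organism's cell biomass.
#'
#' @param chain a chain result from a completed step (internal structure).
#' @param media the media the step was fed with.
#' @param target canonical product id.
#' @param registry an `fm_registry` (molecular weights for secreted
#'   compounds).
#' @return an `fm_media` for the next step (possibly zero-mass).
#' @export
derive_transfer_media <- function(chain, media, target, registry) {
  keep <- media$transferable & media$compound_id != target
  ids <- media$compound_id[keep]
  mass <- stats::setNames(chain$residual_mg[ids], ids)
  mw <- stats::setNames(media$mw[keep], ids)
  trans <- stats::setNames(media$transferable[keep], ids)
  for (cmp in names(chain$secreted_mg)) {
    if (cmp == target || cmp %in% VOLATILE_COMPOUNDS) next
    m <- chain$secreted_mg[[cmp]]
    if (m <= MASS_TOL) next
    mwc <- compound_mw(cmp, media, registry)
    if (is.na(mwc)) {
      stop("secreted compound '", cmp, "' has no molecular weight")
    }
    if (cmp %in% names(mass)) {
      mass[cmp] <- mass[cmp] + m
    } else {
      mass[cmp] <- m; mw[cmp] <- mwc; trans[cmp] <- TRUE
    }
  }
  if (!length(mass)) {
    return(media_composition(character(0), numeric(0), numeric(0), logical(0)))
  }
  media_composition(names(mass), unname(mass), unname(mw), unname(trans))
}

#' Run a single-step fermentation
#'
#' @param setup an `fm_setup` with one organism.
#' @param knockouts optional character vector of reaction ids to knock out.
#' @return an `fm_pipeline_result`.
#' @export
run_single_step <- function(setup, knockouts = character(0)) {
  stopifnot(inherits(setup, "fm_setup"), length(setup$models) == 1)
  run_serial(setup, list(knockouts))
}

#' Run a serial two-step fermentation
#'
#' Step 1 is solved on the input media; the transfer media (residual plus
#' transferable by-products) derived from the chain's fixed optimum feeds
#' step 2 at its transferred mass (no renormalization to 1 g), so total
#' yields stay in percent of the original input mass. Min totals chain the
#' step FVA minima, max totals the maxima.
#'
#' @param setup an `fm_setup` with two organisms.
#' @param knockouts list of two character vectors of reaction ids, one per
#'   organism.
#' @return an `fm_pipeline_result`.
#' @export
run_two_step <- function(setup, knockouts = list(character(0), character(0))) {
  stopifnot(inherits(setup, "fm_setup"), length(setup$models) == 2)
  run_serial(setup, knockouts)
}

#' Run a fermentation setup (one or two steps)
#' @param setup an `fm_setup`.
#' @param knockouts list of per-organism knockout id vectors.
#' @return an `fm_pipeline_result` with `yield_min_pct`, `yield_max_pct`,
#'   per-step chain details in `steps`, and `flags`.
#' @export
run_pipeline <- function(setup, knockouts = NULL) {
  if (is.null(knockouts)) {
    knockouts <- rep(list(character(0)), length(setup$models))
  }
  run_serial(setup, knockouts)
}

run_serial <- function(setup, knockouts) {
  n_steps <- length(setup$models)
  stopifnot(length(knockouts) == n_steps)
  input_mass <- media_total_mass(setup$media)
  flags <- character(0)
  steps <- vector("list", n_steps)
  if (input_mass <= MASS_TOL) {
    return(pipeline_result(steps, 0, 0, input_mass, "no-growth"))
  }
  chains <- list()
  for (sense in c("min", "max")) {
    media_k <- setup$media
    per_step <- vector("list", n_steps)
    for (k in seq_len(n_steps)) {
      if (media_total_mass(media_k) <= MASS_TOL) {
        per_step[[k]] <- zero_chain(
          list(media = media_composition(character(0), numeric(0), numeric(0),
                                         logical(0), check_total = FALSE)),
          "no-growth")
        per_step[[k]]$residual_mg <- stats::setNames(numeric(0), character(0))
        next
      }
      mod <- build_module(setup$models[[k]], media_k, setup$target,
                          setup$registry, setup$oxygen[[k]], index = k)
      ch <- step_chain(mod, sense, knockouts[[k]])
      per_step[[k]] <- ch
      flags <- union(flags, ch$flags)
      if (k < n_steps) {
        media_k <- derive_transfer_media(ch, media_k, setup$target,
                                         setup$registry)
        if (setup$transfer_biomass && ch$bm > MASS_TOL) {
          media_k <- add_biomass_to_media(media_k, setup, k, ch)
        }
      }
    }
    chains[[sense]] <- per_step
  }
  for (k in seq_len(n_steps)) {
    steps[[k]] <- list(
      bm_max = chains$max[[k]]$bm,
      product_min_mg = chains$min[[k]]$product_mg,
      product_max_mg = chains$max[[k]]$product_mg,
      consumed_mg = chains$max[[k]]$consumed_mg,
      residual_mg = chains$max[[k]]$residual_mg,
      secreted_mg = chains$max[[k]]$secreted_mg,
      chain_min = chains$min[[k]], chain_max = chains$max[[k]])
  }
  ymin <- 100 * sum(vapply(chains$min, `[[`, numeric(1), "product_mg")) /
    input_mass
  ymax <- 100 * sum(vapply(chains$max, `[[`, numeric(1), "product_mg")) /
    input_mass
  pipeline_result(steps, ymin, ymax, input_mass, flags)
}

# Feed the grown cell mass of step k to the next step, if the registry knows
# a canonical id and molecular weight for the growth precursor.
add_biomass_to_media <- function(media_k, setup, k, ch) {
  model <- setup$models[[k]]
  gr <- model$reactions[[model$growth_id]]
  pre <- names(gr$stoich)[gr$stoich < 0]
  for (met in pre) {
    cmp <- registry_reverse(setup$registry, model$id, met)
    if (is.na(cmp)) next
    mwc <- compound_mw(cmp, setup$media, setup$registry)
    if (is.na(mwc)) next
    mass <- ch$bm * abs(gr$stoich[[met]]) * mwc
    if (mass <= MASS_TOL) next
    if (cmp %in% media_k$compound_id) {
      media_k$mass_mg[media_k$compound_id == cmp] <-
        media_k$mass_mg[media_k$compound_id == cmp] + mass
    } else {
      add <- media_composition(cmp, mass, mwc, TRUE, check_total = FALSE)
      media_k <- rbind_media(media_k, add)
    }
  }
  media_k
}

rbind_media <- function(a, b) {
  m <- rbind(as.data.frame(a), as.data.frame(b))
  class(m) <- c("fm_media", "data.frame")
  m
}

pipeline_result <- function(steps, ymin, ymax, input_mass, flags) {
  structure(list(steps = steps,
                 yield_min_pct = ymin, yield_max_pct = ymax,
                 input_mass_mg = input_mass,
                 flags = flags),
            class = "fm_pipeline_result")
}

#' @export
print.fm_pipeline_result <- function(x, ...) {
  cat("Fermentation pipeline result (", length(x$steps), " step",
      if (length(x$steps) != 1) "s", "):\n", sep = "")
  for (k in seq_along(x$steps)) {
    s <- x$steps[[k]]
    if (is.null(s)) next
    cat(sprintf("  step %d: bm_max = %.4f /h, product %.2f..%.2f mg/h\n",
                k, s$bm_max, s$product_min_mg, s$product_max_mg))
  }
  cat(sprintf("  yield: %.2f%% .. %.2f%% of input media mass (%g mg)\n",
              x$yield_min_pct, x$yield_max_pct, x$input_mass_mg))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Write pipeline results as CSV rows
#' @param results named list of `fm_pipeline_result`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(results, path) {
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    step_rows <- lapply(seq_along(r$steps), function(k) {
      s <- r$steps[[k]]
      if (is.null(s)) return(NULL)
      data.frame(setup_id = id, step = as.character(k),
                 bm_max = fmt_num(s$bm_max),
                 yield_min_pct = fmt_num(100 * s$product_min_mg /
                                           r$input_mass_mg),
                 yield_max_pct = fmt_num(100 * s$product_max_mg /
                                           r$input_mass_mg),
                 flags = "")
    })
    rbind(do.call(rbind, step_rows),
          data.frame(setup_id = id, step = "total",
                     bm_max = NA_real_,
                     yield_min_pct = fmt_num(r$yield_min_pct),
                     yield_max_pct = fmt_num(r$yield_max_pct),
                     flags = paste(r$flags, collapse = ";")))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_num <- function(x) as.numeric(sprintf("%.8g", x))
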