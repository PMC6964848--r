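# ---------------------------------------------------------------------------
# The five-chamber envelope. A wrapped organism module partitions the system
# into Media / Internal / Growth / Product / Waste; all inter-chamber
# transporters are unidirectional and the Internal chamber never touches the
# outside directly. Growth, Product and Waste are terminal chambers: their
# transporters are sink reactions whose fluxes measure chamber accumulation.
#
# Feed transporters carry a *fixed* flux equal to the molar equivalent of the
# compound's media mass fraction, so the MW-weighted feed sum equals the
# composition total (<= 1000 mg per gDW media per hour, the 1 g media uptake
# basis). Whatever the organism does not take up drains through per-compound
# passthrough transporters into Waste.
# ---------------------------------------------------------------------------

TRANSPORTER_ROLES <- c("feed", "uptake", "passthrough", "product", "secrete")
VOLATILE_COMPOUNDS <- c("co2", "h2", "o2", "ch4") # not transferable by default
OXYGEN_CANONICAL <- "o2"

#' Oxygen policy of a module
#'
#' @param mode "anaerobic" (no oxygen feed), "bounded" (feed up to `max`
#'   mmol/gDW/h) or "open" (default large bound).
#' @param max upper bound for the bounded mode, mmol/gDW/h.
#' @return an `fm_oxygen_policy`.
#' @export
oxygen_policy <- function(mode = c("anaerobic", "bounded", "open"), max = NA) {
  mode <- match.arg(mode)
  if (mode == "bounded") {
    if (!is.finite(max) || max < 0) {
      stop("bounded oxygen policy needs a finite bound >= 0")
    }
  } else {
    max <- if (mode == "anaerobic") 0 else DEFAULT_BOUND
  }
  structure(list(mode = mode, max = as.numeric(max)),
            class = "fm_oxygen_policy")
}

as_oxygen_policy <- function(x) {
  if (inherits(x, "fm_oxygen_policy")) return(x)
  if (is.character(x) && length(x) == 1) return(oxygen_policy(x))
  if (is.numeric(x) && length(x) == 1) return(oxygen_policy("bounded", x))
  stop("cannot interpret oxygen policy")
}

module_rxn <- function(id, stoich, lb, ub, role, compound = NA_character_) {
  list(id = id, stoich = stoich, lb = lb, ub = ub, role = role,
       compound = compound)
}

#' Wrap a metabolic model in the five-chamber envelope
#'
#' Generates the transporter reactions connecting the chambers for the given
#' media composition, production target and oxygen policy. Boundary
#' (exchange) reactions of the base model are removed and replaced by
#' envelope transporters: their metabolites define the set that may be
#' secreted to Waste. Media compounds mapped by the registry get an uptake
#' transporter bounded by the fed amount; unmapped compounds only a
#' passthrough to Waste.
#'
#' @param model an `fm_model`.
#' @param media an `fm_media`.
#' @param target canonical id of the product compound.
#' @param registry an `fm_registry` covering this model.
#' @param oxygen an [oxygen_policy()], or "anaerobic"/"open"/a number.
#' @param index module position in a pipeline (keeps transporter ids unique
#'   across serially combined modules).
#' @return an object of class `fm_module`.
#' @export
build_module <- function(model, media, target, registry,
                         oxygen = oxygen_policy("anaerobic"), index = 1L) {
  validate_model(model)
  stopifnot(inherits(media, "fm_media"), nrow(media) >= 1,
            inherits(registry, "fm_registry"))
  oxygen <- as_oxygen_policy(oxygen)
  k <- as.integer(index)

  if (OXYGEN_CANONICAL %in% media$compound_id) {
    stop("oxygen is dosed through the oxygen policy, not the media composition")
  }
  if (any(is.na(media$mw))) {
    stop("media compounds without molecular weight: ",
         paste(media$compound_id[is.na(media$mw)], collapse = ", "))
  }

  # target must map to an existing model metabolite
  target_met <- registry_lookup(registry, model$id, target)
  if (is.na(target_met) || !target_met %in% model$metabolites$id) {
    stop("target compound '", target, "' is not mapped to a metabolite of ",
         "model '", model$id, "'")
  }
  target_mw <- compound_mw(target, media, registry)
  if (is.na(target_mw)) {
    stop("no molecular weight known for target compound '", target, "'")
  }

  # split base reactions into internal ones and boundary (exchange) reactions
  rxns <- list()
  excretable <- character(0)
  for (r in model$reactions) {
    if (length(r$stoich) == 1 && r$id != model$growth_id) {
      met <- names(r$stoich)
      coef <- unname(r$stoich)
      if ((coef < 0 && r$ub > 0) || (coef > 0 && r$lb < 0)) {
        excretable <- c(excretable, met)
      }
      next # dropped: the envelope replaces boundary traffic
    }
    role <- if (r$id == model$growth_id) "growth" else "internal"
    lb <- if (role == "growth") max(r$lb, 0) else r$lb
    rxns[[r$id]] <- module_rxn(r$id, r$stoich, lb, r$ub, role)
  }
  excretable <- unique(excretable)
  if (!length(rxns) || !model$growth_id %in% names(rxns)) {
    stop("model '", model$id, "' has no growth reaction left after removing ",
         "boundary reactions")
  }

  # growth-reaction products with no consumer need a drain into Growth
  growth_products <- names(rxns[[model$growth_id]]$stoich)[
    rxns[[model$growth_id]]$stoich > 0]
  consumed_somewhere <- unique(unlist(lapply(rxns, function(r)
    names(r$stoich)[r$stoich < 0])))
  for (met in setdiff(growth_products, consumed_somewhere)) {
    gid <- paste0("gsink__", met, "__", k)
    rxns[[gid]] <- module_rxn(gid, stats::setNames(-1, met), 0, DEFAULT_BOUND,
                              "growth_sink")
  }

  mwmap <- stats::setNames(media$mw, media$compound_id)
  mwmap[target] <- target_mw
  fed <- stats::setNames(numeric(nrow(media)), media$compound_id)

  # media chamber: feed (fixed), uptake (if mapped), passthrough
  for (i in seq_len(nrow(media))) {
    cmp <- media$compound_id[i]
    mm <- paste0("media__", cmp, "__", k)
    f <- mmol_from_mass(media$mass_mg[i], media$mw[i])
    fed[cmp] <- f
    fid <- paste0("feed__", cmp, "__", k)
    rxns[[fid]] <- module_rxn(fid, stats::setNames(1, mm), f, f, "feed", cmp)
    met <- registry_lookup(registry, model$id, cmp)
    if (!is.na(met) && met %in% model$metabolites$id) {
      uid <- paste0("uptake__", cmp, "__", k)
      rxns[[uid]] <- module_rxn(uid, stats::setNames(c(-1, 1), c(mm, met)),
                                0, f, "uptake", cmp)
    }
    pid <- paste0("pass__", cmp, "__", k)
    rxns[[pid]] <- module_rxn(pid, stats::setNames(-1, mm), 0, DEFAULT_BOUND,
                              "passthrough", cmp)
  }

  # oxygen: fed outside the media mass basis, capped by the policy
  o2_met <- registry_lookup(registry, model$id, OXYGEN_CANONICAL)
  if (!is.na(o2_met) && o2_met %in% model$metabolites$id) {
    mm <- paste0("media__", OXYGEN_CANONICAL, "__", k)
    fid <- paste0("feed__", OXYGEN_CANONICAL, "__", k)
    uid <- paste0("uptake__", OXYGEN_CANONICAL, "__", k)
    rxns[[fid]] <- module_rxn(fid, stats::setNames(1, mm), 0, oxygen$max,
                              "feed", OXYGEN_CANONICAL)
    rxns[[uid]] <- module_rxn(uid, stats::setNames(c(-1, 1), c(mm, o2_met)),
                              0, DEFAULT_BOUND, "uptake", OXYGEN_CANONICAL)
  }

  # product chamber
  prod_id <- paste0("product__", target, "__", k)
  rxns[[prod_id]] <- module_rxn(prod_id, stats::setNames(-1, target_met),
                                0, DEFAULT_BOUND, "product", target)

  # waste chamber: secretion of every excretable metabolite
  for (met in excretable) {
    cmp <- registry_reverse(registry, model$id, met)
    label <- if (is.na(cmp)) met else cmp
    sid <- paste0("secrete__", label, "__", k)
    rxns[[sid]] <- module_rxn(sid, stats::setNames(-1, met), 0, DEFAULT_BOUND,
                              "secrete",
                              if (is.na(cmp)) NA_character_ else cmp)
    if (!is.na(cmp) && is.na(mwmap[label])) {
      mwc <- compound_mw(cmp, media, registry)
      if (!is.na(mwc)) mwmap[label] <- mwc
    }
  }

  mets <- sort(unique(unlist(lapply(rxns, function(r) names(r$stoich)))))
  chamber <- stats::setNames(
    ifelse(startsWith(mets, "media__"), "Media", "Internal"), mets)

  mod <- structure(list(
    model_id = model$id, index = k,
    reactions = rxns,
    chamber = chamber,
    media = media, target = target, target_mw = target_mw,
    registry = registry, oxygen = oxygen,
    fed = fed, mw = mwmap,
    growth_id = model$growth_id, product_id = prod_id
  ), class = "fm_module")
  validate_module(mod)
  mod
}

#' Validate envelope invariants of a module
#'
#' Checks that all transporter reactions are unidirectional (lb >= 0), that
#' no reaction connects the Internal chamber directly to the outside, and
#' that every media compound has an uptake or a passthrough transporter.
#'
#' @param module an `fm_module`.
#' @return the module, invisibly.
#' @export
validate_module <- function(module) {
  stopifnot(inherits(module, "fm_module"))
  for (r in module$reactions) {
    if (r$role %in% c(TRANSPORTER_ROLES, "growth", "growth_sink") &&
        r$lb < 0) {
      stop("inter-chamber transporter '", r$id, "' must be unidirectional")
    }
    one_sided <- all(r$stoich > 0) || all(r$stoich < 0)
    if (one_sided) {
      # reactions against the outside/terminal chambers
      touches_internal <- any(module$chamber[names(r$stoich)] == "Internal")
      if (touches_internal &&
          !r$role %in% c("product", "secrete", "growth", "growth_sink")) {
        stop("reaction '", r$id, "' connects the Internal chamber directly ",
             "to the outside")
      }
      if (!touches_internal && !r$role %in% c("feed", "passthrough")) {
        stop("reaction '", r$id, "' drains the Media chamber without a role")
      }
    }
  }
  for (cmp in module$media$compound_id) {
    ids <- vapply(module$reactions, function(r)
      identical(r$compound, cmp) && r$role %in% c("uptake", "passthrough"),
      logical(1))
    if (!any(ids)) stop("media compound '", cmp, "' has no outlet transporter")
  }
  invisible(module)
}

#' Set the oxygen policy of a built module
#'
#' Adjusts the oxygen feed transporter bound in place: 0 (anaerobic), the
#' given maximum influx (bounded), or the default large bound (open).
#' Modules of organisms whose model has no mapped oxygen metabolite are
#' returned unchanged apart from the recorded policy.
#'
#' @param module an `fm_module`.
#' @param policy an [oxygen_policy()] or shorthand.
#' @return the updated module.
#' @export
apply_oxygen <- function(module, policy) {
  stopifnot(inherits(module, "fm_module"))
  policy <- as_oxygen_policy(policy)
  fid <- paste0("feed__", OXYGEN_CANONICAL, "__", module$index)
  if (fid %in% names(module$reactions)) {
    module$reactions[[fid]]$ub <- policy$max
  }
  module$oxygen <- policy
  module
}

#' Chamber assignment of every metabolite in a module
#' @param module an `fm_module`.
#' @return named character vector, metabolite id -> chamber.
#' @export
module_chambers <- function(module) module$chamber

#' @export
print.fm_module <- function(x, ...) {
  roles <- table(vapply(x$reactions, `[[`, character(1), "role"))
  cat("Envelope module of '", x$model_id, "' (step ", x$index, "): target '",
      x$target, "', oxygen ", x$oxygen$mode, "\n  reactions: ",
      paste(names(roles), roles, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Dense LP data of a module: S (mets x rxns), bounds, ids.
module_lp <- function(module, overrides = NULL) {
  rxns <- module$reactions
  if (!is.null(overrides)) {
    for (id in names(overrides)) {
      if (!id %in% names(rxns)) stop("unknown reaction '", id, "'")
      rxns[[id]]$lb <- overrides[[id]][1]
      rxns[[id]]$ub <- overrides[[id]][2]
    }
  }
  rids <- names(rxns)
  mets <- names(module$chamber)
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  for (j in seq_along(rids)) {
    st <- rxns[[j]]$stoich
    S[names(st), j] <- st
  }
  list(S = S,
       lb = vapply(rxns, `[[`, numeric(1), "lb"),
       ub = vapply(rxns, `[[`, numeric(1), "ub"),
       rids = rids)
}
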