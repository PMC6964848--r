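# ---------------------------------------------------------------------------
# Core containers: metabolic models, media compositions, compound registries.
#
# A model is a plain list:
#   id          character scalar
#   metabolites data.frame(id, name, compartment, mw)  (mw in g/mol, NA allowed)
#   reactions   named list; each element list(id, stoich = named numeric,
#               lb, ub) with fluxes in mmol/gDW/h
#   growth_id   id of the designated growth reaction
# Stoichiometric coefficients are signed: negative = consumed.
# ---------------------------------------------------------------------------

DEFAULT_BOUND <- 1000 # mmol/gDW/h stand-in for "unknown" (+/- infinity) bounds

#' Construct a metabolic model
#'
#' Builds and validates the in-memory model container used throughout the
#' package. Metabolites are inferred from the reactions; molecular weights
#' (g/mol) may be attached for metabolites that cross the envelope interface.
#'
#' @param reactions list of reactions, each `list(id, stoich, lb, ub)` where
#'   `stoich` is a named numeric vector of signed coefficients
#'   (negative = consumed) and bounds are in mmol/gDW/h. Missing bounds
#'   default to +/-1000.
#' @param growth_id id of the designated growth reaction.
#' @param id model identifier.
#' @param mw optional named numeric vector of molecular weights (g/mol).
#' @param met_names optional named character vector of display names.
#' @param compartments optional named character vector of compartments.
#' @return an object of class `fm_model`.
#' @export
metabolic_model <- function(reactions, growth_id, id = "model",
                            mw = NULL, met_names = NULL, compartments = NULL) {
  stopifnot(is.list(reactions), length(reactions) >= 1)
  rxns <- lapply(reactions, function(r) {
    if (is.null(r$lb)) r$lb <- -DEFAULT_BOUND
    if (is.null(r$ub)) r$ub <- DEFAULT_BOUND
    r$stoich <- r$stoich[r$stoich != 0]
    r$stoich <- r$stoich[order(names(r$stoich))] # canonical ordering
    r
  })
  names(rxns) <- vapply(rxns, `[[`, character(1), "id")
  met_ids <- sort(unique(unlist(lapply(rxns, function(r) names(r$stoich)))))
  mets <- data.frame(
    id = met_ids,
    name = if (is.null(met_names)) met_ids else
      ifelse(is.na(met_names[met_ids]), met_ids, met_names[met_ids]),
    compartment = if (is.null(compartments)) "c" else
      ifelse(is.na(compartments[met_ids]), "c", compartments[met_ids]),
    mw = if (is.null(mw)) NA_real_ else unname(mw[met_ids]),
    stringsAsFactors = FALSE
  )
  model <- structure(
    list(id = id, metabolites = mets, reactions = rxns, growth_id = growth_id),
    class = "fm_model"
  )
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks the container invariants: unique reaction and metabolite ids,
#' non-empty finite stoichiometries, `lb <= ub`, an existing growth reaction,
#' and positive molecular weights where present.
#'
#' @param model an `fm_model`.
#' @return the model, invisibly. Errors on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "fm_model"))
  ids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  if (anyDuplicated(model$metabolites$id)) stop("duplicate metabolite ids")
  for (r in model$reactions) {
    if (length(r$stoich) == 0) stop("reaction '", r$id, "' has empty stoichiometry")
    if (!all(is.finite(r$stoich)) || any(r$stoich == 0)) {
      stop("reaction '", r$id, "' has non-finite or zero coefficients")
    }
    if (!is.finite(r$lb) || !is.finite(r$ub)) {
      stop("reaction '", r$id, "' has non-finite bounds (use +/-", DEFAULT_BOUND, ")")
    }
    if (r$lb > r$ub) stop("reaction '", r$id, "' has lb > ub")
    missing <- setdiff(names(r$stoich), model$metabolites$id)
    if (length(missing)) {
      stop("reaction '", r$id, "' references unknown metabolites: ",
           paste(missing, collapse = ", "))
    }
  }
  if (!model$growth_id %in% ids) {
    stop("growth reaction '", model$growth_id, "' not found in model '",
         model$id, "'")
  }
  mwv <- model$metabolites$mw
  if (any(!is.na(mwv) & mwv <= 0)) stop("molecular weights must be > 0")
  invisible(model)
}

#' @export
print.fm_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "': ", length(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, growth = '", x$growth_id, "'\n",
      sep = "")
  invisible(x)
}

#' Convert a mass to an amount of substance
#'
#' The mole-to-gram transformation on the milli scale: a mass in mg divided by
#' a molecular weight in g/mol yields mmol. Used to turn media mass fractions
#' (mg per gDW of media) into feed fluxes (mmol/gDW/h) on the 1 g media per
#' gDW cells per hour uptake basis.
#'
#' @param mass_mg mass in mg (vectorised, must be >= 0).
#' @param mw molecular weight in g/mol (must be > 0).
#' @return amount in mmol.
#' @examples
#' mmol_from_mass(1800, 180) # 10 mmol, the classic glucose uptake rate
#' @export
mmol_from_mass <- function(mass_mg, mw) {
  if (any(!is.finite(mw)) || any(mw <= 0)) {
    stop("molecular weight must be finite and > 0")
  }
  if (any(!is.finite(mass_mg)) || any(mass_mg < 0)) {
    stop("mass must be finite and >= 0")
  }
  mass_mg / mw
}

#' Stoichiometric matrix of a model
#'
#' @param model an `fm_model`.
#' @return a sparse `Matrix::dgCMatrix` with one row per referenced metabolite
#'   (sorted by id) and one column per reaction (model order); entry (m, r) is
#'   the signed coefficient of metabolite m in reaction r.
#' @export
stoichiometric_matrix <- function(model) {
  validate_model(model)
  rids <- names(model$reactions)
  mids <- model$metabolites$id
  if (length(rids) == 0 || length(mids) == 0) {
    return(Matrix::Matrix(0, 0, 0, sparse = TRUE))
  }
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(rids)) {
    st <- model$reactions[[k]]$stoich
    i <- c(i, match(names(st), mids))
    j <- c(j, rep(k, length(st)))
    x <- c(x, unname(st))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(mids), length(rids)),
                       dimnames = list(mids, rids))
}

# --- media compositions -----------------------------------------------------

#' Construct a media composition
#'
#' A feedstock media composition on the 1 gDW basis: each compound carries its
#' mass fraction in mg per gDW of media, its molecular weight, and whether it
#' is transferable to the second fermentation step. Compositions may be
#' partial (total < 1000 mg); unaccounted mass is treated as inert.
#'
#' @param compound_id character vector of canonical compound ids.
#' @param mass_mg mass fractions, mg per gDW of media (>= 0).
#' @param mw molecular weights, g/mol (> 0).
#' @param transferable logical; may the compound be carried to the next step?
#' @param check_total enforce the <= 1000 mg total of the 1 g basis
#'   (disabled internally for gradient perturbations).
#' @return an object of class `fm_media` (a data.frame).
#' @export
media_composition <- function(compound_id, mass_mg, mw,
                              transferable = TRUE, check_total = TRUE) {
  m <- data.frame(compound_id = as.character(compound_id),
                  mass_mg = as.numeric(mass_mg),
                  mw = as.numeric(mw),
                  transferable = rep_len(as.logical(transferable),
                                         length(compound_id)),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(m$compound_id)) stop("duplicate media compound ids")
  if (any(m$mass_mg < 0)) stop("media mass fractions must be >= 0")
  if (any(!is.na(m$mw) & m$mw <= 0)) stop("molecular weights must be > 0")
  if (check_total && sum(m$mass_mg) > 1000 + 1e-9) {
    stop("media composition exceeds the 1000 mg/gDW basis (total = ",
         format(sum(m$mass_mg)), " mg)")
  }
  class(m) <- c("fm_media", "data.frame")
  m
}

#' Total mass of a media composition
#' @param media an `fm_media`.
#' @return total mass in mg per gDW of media.
#' @export
media_total_mass <- function(media) sum(media$mass_mg)

# --- compound registry ------------------------------------------------------

#' Construct a compound registry
#'
#' The registry maps canonical compound ids to per-model metabolite ids,
#' answering the nomenclature problem between models of different organisms.
#' It may carry molecular weights for compounds that cross the envelope
#' interface (media compounds, products, secreted by-products).
#'
#' @param canonical_id canonical compound ids.
#' @param model_id model each mapping applies to.
#' @param model_metabolite_id metabolite id within that model, or "unmapped".
#' @param mw optional molecular weights (g/mol) per row; NA allowed.
#' @return an object of class `fm_registry` (a data.frame).
#' @export
compound_registry <- function(canonical_id, model_id, model_metabolite_id,
                              mw = NA_real_) {
  r <- data.frame(canonical_id = as.character(canonical_id),
                  model_id = as.character(model_id),
                  model_metabolite_id = as.character(model_metabolite_id),
                  mw = rep_len(as.numeric(mw), length(canonical_id)),
                  stringsAsFactors = FALSE)
  key <- paste(r$canonical_id, r$model_id)
  if (anyDuplicated(key)) {
    stop("registry maps a canonical compound twice for the same model")
  }
  class(r) <- c("fm_registry", "data.frame")
  r
}

#' Look up the model metabolite for a canonical compound
#' @param registry an `fm_registry`.
#' @param model_id model identifier.
#' @param canonical canonical compound id.
#' @return the metabolite id, or `NA_character_` if unmapped.
#' @export
registry_lookup <- function(registry, model_id, canonical) {
  hit <- registry$canonical_id == canonical &
    registry$model_id %in% c(model_id, "*")
  if (!any(hit)) return(NA_character_)
  v <- registry$model_metabolite_id[which(hit)[1]]
  if (identical(v, "unmapped")) NA_character_ else v
}

#' Reverse registry lookup: canonical compound of a model metabolite
#' @inheritParams registry_lookup
#' @param met_id metabolite id within the model.
#' @return the canonical id, or `NA_character_`.
#' @export
registry_reverse <- function(registry, model_id, met_id) {
  hit <- registry$model_metabolite_id == met_id &
    registry$model_id %in% c(model_id, "*")
  if (!any(hit)) return(NA_character_)
  registry$canonical_id[which(hit)[1]]
}

# Molecular weight of a canonical compound: media first, then registry.
compound_mw <- function(canonical, media = NULL, registry = NULL) {
  if (!is.null(media)) {
    i <- match(canonical, media$compound_id)
    if (!is.na(i) && !is.na(media$mw[i])) return(media$mw[i])
  }
  if (!is.null(registry)) {
    hit <- which(registry$canonical_id == canonical & !is.na(registry$mw))
    if (length(hit)) return(registry$mw[hit[1]])
  }
  NA_real_
}

# --- atomic composition -> molecular weight (for SBML chemical formulas) ----

ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.974,
                 S = 32.06, Na = 22.99, K = 39.098, Cl = 35.45, Fe = 55.845,
                 Mg = 24.305, Ca = 40.078, Zn = 65.38, Mn = 54.938,
                 Cu = 63.546, Co = 58.933, Mo = 95.95, Se = 78.971)

#' Molecular weight from a chemical formula
#' @param formula e.g. "C6H12O6".
#' @return mass in g/mol, or NA if the formula contains unknown elements.
#' @export
formula_mass <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NA_real_)
  parts <- regmatches(formula,
                      gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  total <- 0
  for (p in parts) {
    el <- sub("[0-9]+$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.numeric(n) else 1
    if (!el %in% names(ATOMIC_MASS)) return(NA_real_)
    total <- total + ATOMIC_MASS[[el]] * n
  }
  total
}
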