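# ---------------------------------------------------------------------------
# FBA / FVA on envelope modules. Only optima of explicit LPs (BM_MAX, FVA
# min/max) are contractual results; witness flux vectors are returned for
# inspection but alternate optima make them solver-dependent.
# ---------------------------------------------------------------------------

FVA_EPSILON <- 1e-6 # relative growth slack when fixing BM_MAX

#' Flux balance analysis of a module
#'
#' Maximizes the growth reaction flux subject to steady-state mass balance
#' `S v = 0`, the flux bounds, and the fixed media feed fluxes.
#'
#' @param module an `fm_module`.
#' @param overrides optional named list of `c(lb, ub)` bound overrides.
#' @return an `fm_fba` list: `status`, `bm_max` (h^-1, NA unless optimal),
#'   `fluxes` (one optimal witness, named by reaction id).
#' @export
solve_fba <- function(module, overrides = NULL) {
  lp <- module_lp(module, overrides)
  obj <- as.numeric(lp$rids == module$growth_id)
  r <- lp_solve_box(obj, lp$S, NULL, lp$lb, lp$ub, maximize = TRUE)
  structure(list(status = r$status,
                 bm_max = if (r$status == "optimal") r$objective else NA_real_,
                 fluxes = r$solution),
            class = "fm_fba")
}

#' Flux variability analysis of a target reaction
#'
#' With the growth flux fixed at its optimum (lower-bounded at
#' `bm_max * (1 - epsilon)` to absorb floating point), returns the minimum
#' and maximum attainable flux of the target reaction over the remaining
#' solution space. On numerical infeasibility the slack is escalated
#' tenfold, twice, before erroring.
#'
#' @param module an `fm_module`.
#' @param target_reaction reaction id to scan (defaults to the product
#'   transporter).
#' @param bm_max growth optimum from a prior [solve_fba()] on this module.
#' @param epsilon relative growth slack.
#' @param overrides optional bound overrides, as in [solve_fba()].
#' @return an `fm_fva` list: `target_id`, `v_min`, `v_max`.
#' @export
solve_fva <- function(module, target_reaction = module$product_id, bm_max,
                      epsilon = FVA_EPSILON, overrides = NULL) {
  stopifnot(is.finite(bm_max))
  if (!target_reaction %in% names(module$reactions)) {
    stop("unknown target reaction '", target_reaction, "'")
  }
  eps <- epsilon
  for (attempt in 1:3) {
    ov <- if (is.null(overrides)) list() else overrides
    gr <- module$reactions[[module$growth_id]]
    glb <- if (module$growth_id %in% names(ov)) ov[[module$growth_id]] else
      c(gr$lb, gr$ub)
    ov[[module$growth_id]] <- c(max(glb[1], bm_max * (1 - eps)), glb[2])
    lp <- module_lp(module, ov)
    obj <- as.numeric(lp$rids == target_reaction)
    rmax <- lp_solve_box(obj, lp$S, NULL, lp$lb, lp$ub, maximize = TRUE)
    rmin <- lp_solve_box(obj, lp$S, NULL, lp$lb, lp$ub, maximize = FALSE)
    if (rmax$status == "optimal" && rmin$status == "optimal") {
      return(structure(list(target_id = target_reaction,
                            v_min = rmin$objective, v_max = rmax$objective),
                       class = "fm_fva"))
    }
    eps <- eps * 10
  }
  stop("FVA infeasible for '", target_reaction, "' even with relaxed growth ",
       "fixing (module '", module$model_id, "')")
}

#' Apply reaction knockouts to a module
#'
#' Knockout semantics: both bounds of each listed reaction are set to zero.
#' The input module is left untouched.
#'
#' @param module an `fm_module`.
#' @param reaction_ids character vector of reaction ids (possibly empty).
#' @return a modified copy of the module.
#' @export
apply_knockouts <- function(module, reaction_ids) {
  stopifnot(inherits(module, "fm_module"))
  if (!length(reaction_ids)) return(module)
  unknown <- setdiff(reaction_ids, names(module$reactions))
  if (length(unknown)) {
    stop("knockout of unknown reaction(s): ", paste(unknown, collapse = ", "))
  }
  for (id in reaction_ids) {
    module$reactions[[id]]$lb <- 0
    module$reactions[[id]]$ub <- 0
  }
  module
}

#' Organism reaction ids of a module
#'
#' The knockout search space: base-model reactions (internal plus the growth
#' reaction). Envelope transporters are artifacts of the wrapper, not
#' organism genes, and are excluded unless requested.
#'
#' @param module an `fm_module`.
#' @param include_transporters include envelope transporter reactions.
#' @return character vector of reaction ids.
#' @export
organism_reactions <- function(module, include_transporters = FALSE) {
  roles <- vapply(module$reactions, `[[`, character(1), "role")
  keep <- roles %in% c("internal", "growth")
  if (include_transporters) keep <- keep | roles %in% TRANSPORTER_ROLES
  names(module$reactions)[keep]
}
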