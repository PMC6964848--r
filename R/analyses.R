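# ---------------------------------------------------------------------------
# Analyses on top of the pipeline: media sensitivity (one-at-a-time compound
# removal), media gradient (finite difference with delta = 1 mg/gDW),
# knockout screening over one or two organisms, and campaign planning.
# Min and max chain yields are always treated separately.
# ---------------------------------------------------------------------------

setup_with_media <- function(setup, media) {
  setup$media <- media
  setup
}

# Product masses below this are artifacts of the relative growth slack used
# when fixing BM_MAX (1e-6 of a ~1000 mg/h flux scale) and count as zero in
# relative-yield ratios.
PRODUCT_TOL <- 1e-3 # mg/h

relative_pct <- function(new_mg, base_mg) {
  if (base_mg <= PRODUCT_TOL) {
    if (new_mg <= PRODUCT_TOL) 100 else NA_real_
  } else 100 * new_mg / base_mg
}

#' Media sensitivity analysis
#'
#' Removes media compounds one at a time (the compound's feed flux is
#' nullified; the composition is not renormalized) and reruns the full
#' pipeline. Reported is the relative yield, 100 * new / original, for the
#' min and max chains independently. Values above 100 are legal (removing a
#' growth-promoting compound can free other compounds for product formation)
#' and are not clamped.
#'
#' @param setup an `fm_setup`.
#' @param compounds compounds to scan (default: all media compounds).
#' @return data.frame with columns compound, relative_yield_min_pct,
#'   relative_yield_max_pct, status ("ok" or "undefined" when the baseline
#'   yield is zero).
#' @export
sensitivity_scan <- function(setup, compounds = setup$media$compound_id) {
  base <- run_pipeline(setup)
  # compare product masses: the percent denominator changes when a
  # compound's mass is nullified, the product flux ratio must not
  base_min <- base$yield_min_pct * base$input_mass_mg / 100
  base_max <- base$yield_max_pct * base$input_mass_mg / 100
  rows <- lapply(compounds, function(cmp) {
    stopifnot(cmp %in% setup$media$compound_id)
    media2 <- setup$media
    media2$mass_mg[media2$compound_id == cmp] <- 0
    r <- run_pipeline(setup_with_media(setup, media2))
    vmin <- relative_pct(r$yield_min_pct * r$input_mass_mg / 100, base_min)
    vmax <- relative_pct(r$yield_max_pct * r$input_mass_mg / 100, base_max)
    data.frame(compound = cmp,
               relative_yield_min_pct = vmin,
               relative_yield_max_pct = vmax,
               status = if (anyNA(c(vmin, vmax))) "undefined" else "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_product_mg") <- c(min = base_min, max = base_max)
  out
}

#' Media gradient analysis
#'
#' Adds a small mass `delta` (default 1 mg/gDW of media) of one compound at a
#' time — the feed flux grows by delta/MW mmol and the total media mass by
#' delta, without renormalization — reruns the pipeline, and reports the
#' finite difference (new - original product mass) / delta for the min and
#' max chains independently (mg product per mg compound; dimensionless).
#'
#' @param setup an `fm_setup`.
#' @param delta mass increment in mg.
#' @param compounds compounds to scan (default: all media compounds).
#' @return data.frame with columns compound, gradient_min, gradient_max.
#' @export
gradient_scan <- function(setup, delta = 1,
                          compounds = setup$media$compound_id) {
  stopifnot(delta > 0)
  base <- run_pipeline(setup)
  base_mass <- base$input_mass_mg
  base_min_mg <- base$yield_min_pct * base_mass / 100
  base_max_mg <- base$yield_max_pct * base_mass / 100
  rows <- lapply(compounds, function(cmp) {
    i <- match(cmp, setup$media$compound_id)
    if (is.na(i)) stop("compound '", cmp, "' is not in the media")
    if (is.na(setup$media$mw[i])) {
      stop("compound '", cmp, "' has no molecular weight")
    }
    media2 <- setup$media
    media2$mass_mg[i] <- media2$mass_mg[i] + delta
    r <- run_pipeline(setup_with_media(setup, media2))
    new_mass <- r$input_mass_mg
    data.frame(compound = cmp,
               gradient_min = (r$yield_min_pct * new_mass / 100 -
                                 base_min_mg) / delta,
               gradient_max = (r$yield_max_pct * new_mass / 100 -
                                 base_max_mg) / delta,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Count pairwise single-knockout scenarios
#'
#' Each organism independently carries either no knockout or exactly one
#' single-reaction knockout: `(n1 + 1) * (n2 + 1)` scenarios including the
#' wild type. For the published genome-scale model sizes 2,280 and 2,914
#' this gives 6,649,115.
#'
#' @param n1,n2 reaction counts of the two organisms (use `n2 = 0` for a
#'   single-organism screen).
#' @return scenario count (numeric, exact for counts below 2^53).
#' @export
enumerate_knockout_scenarios <- function(n1, n2 = 0) {
  stopifnot(length(n1) == 1, length(n2) == 1, n1 >= 0, n2 >= 0,
            n1 == floor(n1), n2 == floor(n2))
  (n1 + 1) * (n2 + 1)
}

#' Materialize the knockout scenario grid
#'
#' @param ids1,ids2 reaction id vectors of the two organisms; each scenario
#'   choice is "none" or one id.
#' @return data.frame with columns ko1, ko2; the first row is the wild type
#'   ("none", "none"). Row count equals
#'   [enumerate_knockout_scenarios()]`(length(ids1), length(ids2))`.
#' @export
knockout_scenario_grid <- function(ids1, ids2 = character(0)) {
  g <- expand.grid(ko1 = c("none", ids1), ko2 = c("none", ids2),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[order(match(g$ko1, c("none", ids1)), match(g$ko2, c("none", ids2))), ,
    drop = FALSE] -> g
  rownames(g) <- NULL
  g
}

#' Exhaustive (or scoped) knockout screen of a fermentation pipeline
#'
#' Runs the pipeline once per scenario — each organism carrying "none" or one
#' knocked-out reaction — and reports yields relative to the wild type min
#' and max yields. Scenario failures are recorded per row and never abort
#' the scan. A base knockout specification is merged into every scenario
#' (the nested screening scheme).
#'
#' @param setup an `fm_setup` (one or two organisms).
#' @param scope1,scope2 reaction id vectors to scan per organism; defaults to
#'   all base-model reactions (envelope transporters excluded).
#' @param base_knockouts list of per-organism id vectors applied to every
#'   scenario, the wild type included.
#' @param workers parallel worker count for the task runner.
#' @param checkpoint optional checkpoint CSV path for resumable scans.
#' @return data.frame: ko1, ko2, yield_min_rel_pct, yield_max_rel_pct,
#'   status; attribute "wild_type" carries the WT absolute yields.
#' @export
knockout_scan <- function(setup, scope1 = NULL, scope2 = NULL,
                          base_knockouts = NULL, workers = 1L,
                          checkpoint = NULL) {
  n_org <- length(setup$models)
  scopes <- vector("list", n_org)
  for (k in seq_len(n_org)) {
    sc <- if (k == 1) scope1 else scope2
    if (is.null(sc)) {
      mod <- build_module(setup$models[[k]], setup$media, setup$target,
                          setup$registry, setup$oxygen[[k]], index = k)
      sc <- organism_reactions(mod)
    }
    scopes[[k]] <- sc
  }
  if (is.null(base_knockouts)) {
    base_knockouts <- rep(list(character(0)), n_org)
  }
  grid <- knockout_scenario_grid(scopes[[1]],
                                 if (n_org == 2) scopes[[2]] else character(0))
  wt <- run_pipeline(setup, base_knockouts)
  wt_min <- wt$yield_min_pct * wt$input_mass_mg / 100
  wt_max <- wt$yield_max_pct * wt$input_mass_mg / 100

  payloads <- lapply(seq_len(nrow(grid)), function(i) {
    list(op = "knockout", ko1 = grid$ko1[i], ko2 = grid$ko2[i])
  })
  tasks <- make_tasks(payloads)
  fn <- function(payload) {
    kos <- base_knockouts
    if (payload$ko1 != "none") kos[[1]] <- union(kos[[1]], payload$ko1)
    if (n_org == 2 && payload$ko2 != "none") {
      kos[[2]] <- union(kos[[2]], payload$ko2)
    }
    r <- run_pipeline(setup, kos)
    list(ko1 = payload$ko1, ko2 = payload$ko2,
         yield_min_rel_pct = fmt_num(
           relative_pct(r$yield_min_pct * r$input_mass_mg / 100, wt_min)),
         yield_max_rel_pct = fmt_num(
           relative_pct(r$yield_max_pct * r$input_mass_mg / 100, wt_max)))
  }
  run <- run_tasks(tasks, fn, workers = workers, checkpoint = checkpoint)
  res <- run$results
  # restore scenario order of the grid
  key_grid <- paste(grid$ko1, grid$ko2)
  key_res <- paste(res$ko1, res$ko2)
  res <- res[match(key_grid, key_res), , drop = FALSE]
  rownames(res) <- NULL
  out <- data.frame(ko1 = res$ko1, ko2 = res$ko2,
                    yield_min_rel_pct = as.numeric(res$yield_min_rel_pct),
                    yield_max_rel_pct = as.numeric(res$yield_max_rel_pct),
                    status = res$status, stringsAsFactors = FALSE)
  attr(out, "wild_type") <- c(yield_min_pct = wt$yield_min_pct,
                              yield_max_pct = wt$yield_max_pct)
  attr(out, "report") <- run$report
  out
}

#' Write a knockout scan CSV
#' @param scan result of [knockout_scan()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_knockout_csv <- function(scan, path) {
  utils::write.csv(scan, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plan a simulation campaign
#'
#' Enumerates fermentation configurations — every single-organism pipe and
#' every ordered pair of distinct organisms, crossed with media and targets —
#' and tasks (configurations crossed with oxygen conditions).
#'
#' @param media character vector of media names, or a count.
#' @param targets character vector of target names, or a count.
#' @param organisms character vector of organism names, or a count; ids must
#'   be unique.
#' @param conditions condition names (default aerobic/anaerobic), or a count.
#' @return an `fm_campaign` list: `configurations` and `tasks` data.frames
#'   plus `n_configurations` and `n_tasks`.
#' @export
plan_campaign <- function(media, targets, organisms,
                          conditions = c("aerobic", "anaerobic")) {
  aslist <- function(x, prefix) {
    if (is.numeric(x) && length(x) == 1) paste0(prefix, seq_len(x))
    else as.character(x)
  }
  media <- aslist(media, "media"); targets <- aslist(targets, "target")
  organisms <- aslist(organisms, "org")
  conditions <- aslist(conditions, "condition")
  stopifnot(length(media) >= 1, length(targets) >= 1, length(organisms) >= 1,
            length(conditions) >= 1)
  if (anyDuplicated(organisms)) stop("duplicate organism ids")
  singles <- data.frame(org1 = organisms, org2 = NA_character_,
                        stringsAsFactors = FALSE)
  pairs <- expand.grid(org1 = organisms, org2 = organisms,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$org1 != pairs$org2, , drop = FALSE]
  pipes <- rbind(singles, pairs)
  pipes$pipe <- ifelse(is.na(pipes$org2), pipes$org1,
                       paste(pipes$org1, pipes$org2, sep = ">"))
  cfg <- merge(merge(pipes, data.frame(media = media), by = NULL),
               data.frame(target = targets), by = NULL)
  cfg <- cfg[order(cfg$pipe, cfg$media, cfg$target), , drop = FALSE]
  rownames(cfg) <- NULL
  tasks <- merge(cfg, data.frame(condition = conditions), by = NULL)
  tasks <- tasks[order(tasks$pipe, tasks$media, tasks$target,
                       tasks$condition), , drop = FALSE]
  rownames(tasks) <- NULL
  structure(list(configurations = cfg, tasks = tasks,
                 n_configurations = nrow(cfg), n_tasks = nrow(tasks)),
            class = "fm_campaign")
}

#' @export
print.fm_campaign <- function(x, ...) {
  cat("Campaign:", x$n_configurations, "configurations,",
      x$n_tasks, "tasks\n")
  invisible(x)
}
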