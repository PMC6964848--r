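# ---------------------------------------------------------------------------
# Deterministic toy organisms and media. Molecular weights are chosen so all
# mass checks are exact rationals: glucose 180, xylose 150, ethanol 46,
# CO2 44, biomass precursors 180 (A) and 150 (B); e.g. the TOY-A
# fermentation 180 = 2*46 + 2*44 balances exactly.
#
# TOY-A is a glucose-only fermenter (think S. cerevisiae), TOY-B a
# xylose-only fermenter (think an engineered E. coli): together they make
# the smallest serial pipeline in which order and transfer matter.
# ---------------------------------------------------------------------------

TOY_MW <- c(glc = 180, xyl = 150, etoh = 46, co2 = 44, bmA = 180, bmB = 150)

#' The glucose-fermenting toy organism TOY-A
#'
#' Reactions: FERM glc -> 2 etoh + 2 co2; GROW_PRE glc -> bmA; GROW bmA ->
#' (the growth reaction, capped at 1 mmol/gDW/h); boundary reactions EX_etoh
#' and EX_co2 declare which metabolites the organism can excrete (the
#' envelope replaces them with secrete transporters at wrap time).
#'
#' @return an `fm_model`.
#' @export
make_toy_A <- function() {
  metabolic_model(list(
    list(id = "FERM", stoich = c(glc = -1, etoh = 2, co2 = 2),
         lb = 0, ub = DEFAULT_BOUND),
    list(id = "GROW_PRE", stoich = c(glc = -1, bmA = 1),
         lb = 0, ub = DEFAULT_BOUND),
    list(id = "GROW", stoich = c(bmA = -1), lb = 0, ub = 1),
    list(id = "EX_etoh", stoich = c(etoh = -1), lb = 0, ub = DEFAULT_BOUND),
    list(id = "EX_co2", stoich = c(co2 = -1), lb = 0, ub = DEFAULT_BOUND)
  ), growth_id = "GROW", id = "TOYA", mw = TOY_MW)
}

#' The xylose-fermenting toy organism TOY-B
#'
#' Reactions: FERMX xyl -> 5/3 etoh + 5/3 co2 (150 = 5/3*46 + 5/3*44);
#' GROW_PRE xyl -> bmB; GROW bmB -> capped at 0.5 mmol/gDW/h; EX_etoh and
#' EX_co2 boundary reactions. TOY-B cannot use glucose.
#'
#' @return an `fm_model`.
#' @export
make_toy_B <- function() {
  metabolic_model(list(
    list(id = "FERMX", stoich = c(xyl = -1, etoh = 5 / 3, co2 = 5 / 3),
         lb = 0, ub = DEFAULT_BOUND),
    list(id = "GROW_PRE", stoich = c(xyl = -1, bmB = 1),
         lb = 0, ub = DEFAULT_BOUND),
    list(id = "GROW", stoich = c(bmB = -1), lb = 0, ub = 0.5),
    list(id = "EX_etoh", stoich = c(etoh = -1), lb = 0, ub = DEFAULT_BOUND),
    list(id = "EX_co2", stoich = c(co2 = -1), lb = 0, ub = DEFAULT_BOUND)
  ), growth_id = "GROW", id = "TOYB", mw = TOY_MW)
}

#' Registry for the toy suite
#'
#' Maps the canonical compounds glc, xyl, etoh, co2 and the biomass
#' precursors to TOY-A/TOY-B metabolites, with molecular weights. Xylose is
#' unmapped for TOY-A and glucose for TOY-B.
#'
#' @return an `fm_registry`.
#' @export
toy_registry <- function() {
  compound_registry(
    canonical_id = c("glc", "etoh", "co2", "bmA",
                     "xyl", "etoh", "co2", "bmB"),
    model_id = c("TOYA", "TOYA", "TOYA", "TOYA",
                 "TOYB", "TOYB", "TOYB", "TOYB"),
    model_metabolite_id = c("glc", "etoh", "co2", "bmA",
                            "xyl", "etoh", "co2", "bmB"),
    mw = c(180, 46, 44, 180, 150, 46, 44, 150))
}

#' Toy media compositions
#'
#' M1: 1000 mg glucose per gDW of media. M2: 500 mg glucose + 500 mg xylose.
#'
#' @param which "M1" or "M2".
#' @return an `fm_media`.
#' @export
toy_media <- function(which = c("M1", "M2")) {
  which <- match.arg(which)
  if (which == "M1") {
    media_composition("glc", 1000, 180, TRUE)
  } else {
    media_composition(c("glc", "xyl"), c(500, 500), c(180, 150), TRUE)
  }
}

#' Generate a random mass-balanced, growth-feasible toy network
#'
#' Builds a linear substrate conversion chain with a biomass branch and a
#' fermentation branch, with randomized molecular weights, split ratios and
#' growth caps; product and by-product weights are derived from the split so
#' every reaction is exactly mass balanced. The same seed always yields the
#' same network. Used to drive the LP oracle-equivalence suite.
#'
#' @param n_reactions number of internal reactions (>= 3): a chain of
#'   `n_reactions - 3` conversions plus fermentation, biomass precursor
#'   synthesis and growth.
#' @param seed RNG seed.
#' @return list with `model` (`fm_model`), `media` (`fm_media`, 1000 mg of
#'   the substrate), `registry` (`fm_registry`) and `target` ("prod").
#' @export
make_random_network <- function(n_reactions, seed) {
  stopifnot(n_reactions >= 3)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  mw_s <- sample(100:300, 1)
  n_conv <- n_reactions - 3
  chain <- c("sub", if (n_conv > 0) paste0("x", seq_len(n_conv)) else
    character(0))
  rxns <- list()
  if (n_conv > 0) {
    for (i in seq_len(n_conv)) {
      id <- paste0("CONV", i)
      rxns[[id]] <- list(
        id = id,
        stoich = stats::setNames(c(-1, 1), c(chain[i], chain[i + 1])),
        lb = 0, ub = round(stats::runif(1, 50, DEFAULT_BOUND), 3))
    }
  }
  last <- chain[length(chain)]
  ratio <- round(stats::runif(1, 0.3, 0.7), 3)
  a <- sample(1:2, 1); b <- sample(1:2, 1)
  mw_p <- mw_s * ratio / a
  mw_w <- mw_s * (1 - ratio) / b
  rxns[["FERM"]] <- list(
    id = "FERM",
    stoich = stats::setNames(c(-1, a, b), c(last, "prod", "wst")),
    lb = 0, ub = DEFAULT_BOUND)
  rxns[["GROW_PRE"]] <- list(
    id = "GROW_PRE", stoich = stats::setNames(c(-1, 1), c(last, "bm")),
    lb = 0, ub = DEFAULT_BOUND)
  rxns[["GROW"]] <- list(
    id = "GROW", stoich = c(bm = -1),
    lb = 0, ub = round(stats::runif(1, 0.2, 2), 3))
  rxns[["EX_prod"]] <- list(id = "EX_prod", stoich = c(prod = -1),
                            lb = 0, ub = DEFAULT_BOUND)
  rxns[["EX_wst"]] <- list(id = "EX_wst", stoich = c(wst = -1),
                           lb = 0, ub = DEFAULT_BOUND)
  mw <- c(sub = mw_s, prod = mw_p, wst = mw_w, bm = mw_s)
  if (n_conv > 0) {
    mw <- c(mw, stats::setNames(rep(mw_s, n_conv), paste0("x", 1:n_conv)))
  }
  model <- metabolic_model(rxns, growth_id = "GROW",
                           id = paste0("RAND", seed), mw = mw)
  media <- media_composition("sub", 1000, mw_s, TRUE)
  registry <- compound_registry(
    canonical_id = c("sub", "prod", "wst", "bm"),
    model_id = model$id,
    model_metabolite_id = c("sub", "prod", "wst", "bm"),
    mw = c(mw_s, mw_p, mw_w, mw_s))
  list(model = model, media = media, registry = registry, target = "prod")
}

#' Write the toy suite to a directory
#'
#' Emits TOY-A and TOY-B in the tabular dialect, the M1/M2 media CSVs and
#' the registry CSV, so the whole stack (reader, envelope, LP, pipeline) can
#' be exercised end-to-end from files.
#'
#' @param dir destination directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_toy_suite <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    toyA = file.path(dir, "toyA.tsv"),
    toyB = file.path(dir, "toyB.tsv"),
    M1 = file.path(dir, "media_M1.csv"),
    M2 = file.path(dir, "media_M2.csv"),
    registry = file.path(dir, "registry.csv"))
  write_model(make_toy_A(), paths[["toyA"]])
  write_model(make_toy_B(), paths[["toyB"]])
  write_media(toy_media("M1"), paths[["M1"]])
  write_media(toy_media("M2"), paths[["M2"]])
  write_registry(toy_registry(), paths[["registry"]])
  invisible(paths)
}
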