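# ---------------------------------------------------------------------------
# Minimal SBML Level 3 + FBC v2 reader/writer, enough for exchanging
# flux-bounded models. Namespace handling is prefix-agnostic (local-name()
# XPath), so files from other exporters parse as long as the FBC attributes
# are present; absent bounds fall back to +/-1000 mmol/gDW/h.
# ---------------------------------------------------------------------------

FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"

xattr <- function(node, name) {
  a <- xml2::xml_attrs(node)
  hit <- which(sub("^.*:", "", names(a)) == name)
  if (!length(hit)) NA_character_ else unname(a[hit[1]])
}

read_sbml_model <- function(path, mw = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse failure in '", path, "': ", conditionMessage(e))
  })
  model_node <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  if (is.na(xml2::xml_name(model_node))) stop("no <model> element in ", path)
  mid <- xattr(model_node, "id")
  if (is.na(mid)) mid <- tools::file_path_sans_ext(basename(path))

  # global flux-bound parameters
  pars <- xml2::xml_find_all(doc, "//*[local-name()='parameter']")
  parval <- stats::setNames(
    as.numeric(vapply(pars, xattr, character(1), "value")),
    vapply(pars, xattr, character(1), "id"))

  # species: compartment, name, chemical formula -> molecular weight
  spp <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  sp_id <- vapply(spp, xattr, character(1), "id")
  sp_name <- vapply(spp, xattr, character(1), "name")
  sp_comp <- vapply(spp, xattr, character(1), "compartment")
  sp_form <- vapply(spp, xattr, character(1), "chemicalFormula")
  sp_mw <- vapply(sp_form, formula_mass, numeric(1))
  names(sp_mw) <- sp_id
  if (!is.null(mw)) sp_mw[names(mw)] <- mw
  sp_boundary <- vapply(spp, xattr, character(1), "boundaryCondition")

  rnodes <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  if (!length(rnodes)) stop("no reactions in SBML file ", path)
  rxns <- vector("list", length(rnodes))
  for (k in seq_along(rnodes)) {
    rn <- rnodes[[k]]
    rid <- xattr(rn, "id")
    if (is.na(rid)) stop("reaction ", k, " in '", path, "' lacks an id")
    st <- numeric(0)
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(
        rn, paste0("./*[local-name()='", tag,
                   "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        sp <- xattr(ref, "species")
        coef <- as.numeric(xattr(ref, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        # species flagged boundaryCondition are not balanced: skip them
        bidx <- match(sp, sp_id)
        if (!is.na(bidx) && identical(sp_boundary[bidx], "true")) next
        st[sp] <- (if (sp %in% names(st)) st[[sp]] else 0) + side * coef
      }
    }
    st <- st[st != 0]
    lbp <- xattr(rn, "lowerFluxBound")
    ubp <- xattr(rn, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]] else {
      if (identical(xattr(rn, "reversible"), "false")) 0 else -DEFAULT_BOUND
    }
    ub <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else
      DEFAULT_BOUND
    lb <- max(lb, -DEFAULT_BOUND); ub <- min(ub, DEFAULT_BOUND)
    if (!length(st)) next # pure boundary pseudo-reaction against a constant pool
    rxns[[k]] <- list(id = rid, stoich = st, lb = lb, ub = ub)
  }
  rxns <- Filter(Negate(is.null), rxns)

  # growth reaction: active FBC objective
  fobj <- xml2::xml_find_first(doc, "//*[local-name()='fluxObjective']")
  growth <- if (!is.na(xml2::xml_name(fobj))) xattr(fobj, "reaction")
    else NA_character_
  if (is.na(growth)) {
    stop("SBML file '", path,
         "' declares no growth objective (fbc:fluxObjective)")
  }
  metabolic_model(rxns, growth_id = growth, id = mid,
                  mw = sp_mw[!is.na(sp_mw)],
                  met_names = stats::setNames(sp_name, sp_id),
                  compartments = stats::setNames(sp_comp, sp_id))
}

write_sbml_model <- function(model, path) {
  validate_model(model)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- fmt17
  bounds <- sort(unique(c(vapply(model$reactions, `[[`, numeric(1), "lb"),
                          vapply(model$reactions, `[[`, numeric(1), "ub"))))
  pid <- stats::setNames(paste0("fb_", seq_along(bounds)), num(bounds))
  comps <- unique(model$metabolites$compartment)
  L <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_NS, '" xmlns:fbc="', FBC_NS,
           '" level="3" version="1" fbc:required="false">'),
    paste0('<model id="', esc(model$id), '" fbc:strict="true">'),
    "<listOfCompartments>",
    paste0('<compartment id="', esc(comps), '" constant="true"/>'),
    "</listOfCompartments>",
    "<listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    L <- c(L, paste0('<species id="', esc(m$id), '" name="', esc(m$name),
                     '" compartment="', esc(m$compartment),
                     '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
                     ' constant="false"/>'))
  }
  L <- c(L, "</listOfSpecies>", "<listOfParameters>",
         paste0('<parameter id="', pid, '" value="', names(pid),
                '" constant="true"/>'),
         "</listOfParameters>", "<listOfReactions>")
  for (r in model$reactions) {
    L <- c(L, paste0('<reaction id="', esc(r$id), '" reversible="',
                     if (r$lb < 0) "true" else "false",
                     '" fast="false" fbc:lowerFluxBound="', pid[[num(r$lb)]],
                     '" fbc:upperFluxBound="', pid[[num(r$ub)]], '">'))
    for (side in c(-1, 1)) {
      sel <- if (side < 0) r$stoich < 0 else r$stoich > 0
      if (!any(sel)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      L <- c(L, paste0("<", tag, ">"),
             paste0('<speciesReference species="', esc(names(r$stoich)[sel]),
                    '" stoichiometry="', num(abs(r$stoich[sel])),
                    '" constant="true"/>'),
             paste0("</", tag, ">"))
    }
    L <- c(L, "</reaction>")
  }
  L <- c(L, "</listOfReactions>",
         '<fbc:listOfObjectives fbc:activeObjective="obj">',
         '<fbc:objective fbc:id="obj" fbc:type="maximize">',
         "<fbc:listOfFluxObjectives>",
         paste0('<fbc:fluxObjective fbc:reaction="', esc(model$growth_id),
                '" fbc:coefficient="1"/>'),
         "</fbc:listOfFluxObjectives>", "</fbc:objective>",
         "</fbc:listOfObjectives>", "</model>", "</sbml>")
  writeLines(L, path)
  invisible(path)
}
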