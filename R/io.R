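# ---------------------------------------------------------------------------
# File formats.
#
# Tabular model dialect (TSV):
#   # comment/header lines start with '#'; '#growth=<id>' is mandatory,
#   # '#model_id=<id>' optional.
#   columns: reaction_id  equation  lb  ub
#   equation: "1 glc -> 2 etoh + 2 co2"; coefficients optional (default 1) and
#   may be small fractions like "5/3"; either side may be empty (boundary
#   reactions, e.g. "1 co2 ->").
#
# Media CSV: compound_id, mass_mg_per_gDW, molecular_weight_g_per_mol,
#            transferable (0/1)
# Registry CSV: canonical_id, model_id, model_metabolite_id
#               [, molecular_weight_g_per_mol]
# ---------------------------------------------------------------------------

parse_coef <- function(tok) {
  if (grepl("^[0-9.]+/[0-9.]+$", tok)) {
    ab <- strsplit(tok, "/", fixed = TRUE)[[1]]
    return(as.numeric(ab[1]) / as.numeric(ab[2]))
  }
  suppressWarnings(as.numeric(tok))
}

# "2 etoh + 2 co2" -> named numeric c(etoh = 2, co2 = 2); "" -> empty vector
parse_side <- function(side, where) {
  side <- trimws(side)
  if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
  out <- numeric(0)
  for (term in strsplit(side, "+", fixed = TRUE)[[1]]) {
    toks <- strsplit(trimws(term), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 1) {
      coef <- 1; met <- toks[1]
    } else if (length(toks) == 2) {
      coef <- parse_coef(toks[1]); met <- toks[2]
    } else {
      stop("cannot parse equation term '", term, "' in ", where)
    }
    if (is.na(coef)) stop("bad coefficient in term '", term, "' in ", where)
    out[met] <- (if (met %in% names(out)) out[[met]] else 0) + coef
  }
  out
}

parse_equation <- function(eq, where = "equation") {
  if (!grepl("->", eq, fixed = TRUE)) {
    stop("equation '", eq, "' in ", where, " lacks '->'")
  }
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  lhs <- parse_side(sides[1], where)
  rhs <- parse_side(sides[2], where)
  st <- c(-lhs, rhs)
  st <- tapply(st, names(st), sum)
  st <- stats::setNames(as.numeric(st), names(st))
  st[st != 0]
}

# scalar-exact decimal formatter: round-trips doubles, no padding
fmt17 <- function(x) vapply(x, function(v) sprintf("%.17g", v), character(1))

format_equation <- function(stoich) {
  fmt <- function(v, ids) {
    if (!length(ids)) return("")
    paste(paste(fmt17(v), ids), collapse = " + ")
  }
  lhs <- stoich[stoich < 0]; rhs <- stoich[stoich > 0]
  paste(fmt(-unname(lhs), names(lhs)), "->", fmt(unname(rhs), names(rhs)))
}

#' Read a metabolic model from disk
#'
#' @param path file path.
#' @param format "tabular", "sbml", or "auto" (by extension: .xml/.sbml are
#'   SBML, everything else tabular).
#' @param mw optional named numeric molecular weights to attach.
#' @return an `fm_model`.
#' @export
read_model <- function(path, format = c("auto", "tabular", "sbml"), mw = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("xml", "sbml"))
      "sbml" else "tabular"
  }
  if (format == "sbml") read_sbml_model(path, mw = mw)
  else read_tabular_model(path, mw = mw)
}

#' Write a metabolic model to disk
#' @param model an `fm_model`.
#' @param path destination path.
#' @param format "tabular" or "sbml".
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  if (format == "sbml") write_sbml_model(model, path)
  else write_tabular_model(model, path)
  invisible(path)
}

read_tabular_model <- function(path, mw = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  gm <- sub("^#growth=", "", grep("^#growth=", headers, value = TRUE))
  if (length(gm) != 1) {
    stop("tabular model '", path, "' needs exactly one '#growth=<id>' header")
  }
  mid <- sub("^#model_id=", "", grep("^#model_id=", headers, value = TRUE))
  if (length(mid) != 1) mid <- tools::file_path_sans_ext(basename(path))
  if (!length(body)) stop("tabular model '", path, "' has no reactions")
  rxns <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) {
      stop("line ", i, " of '", path,
           "': expected tab-separated reaction_id, equation[, lb, ub]")
    }
    lb <- if (length(f) >= 3 && nzchar(f[3])) as.numeric(f[3]) else -DEFAULT_BOUND
    ub <- if (length(f) >= 4 && nzchar(f[4])) as.numeric(f[4]) else DEFAULT_BOUND
    if (is.na(lb) || is.na(ub)) {
      stop("line ", i, " of '", path, "': non-numeric bounds")
    }
    rxns[[i]] <- list(id = f[1],
                      stoich = parse_equation(f[2], paste0(path, ":", i)),
                      lb = lb, ub = ub)
  }
  metabolic_model(rxns, growth_id = gm, id = mid, mw = mw)
}

write_tabular_model <- function(model, path) {
  validate_model(model)
  lines <- c(paste0("#model_id=", model$id),
             paste0("#growth=", model$growth_id),
             "#reaction_id\tequation\tlb\tub")
  for (r in model$reactions) {
    lines <- c(lines, paste(r$id, format_equation(r$stoich),
                            fmt17(r$lb), fmt17(r$ub), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a media composition CSV
#'
#' Columns: compound_id, mass_mg_per_gDW, molecular_weight_g_per_mol,
#' transferable (0/1).
#' @param path file path.
#' @return an `fm_media`.
#' @export
read_media <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "mass_mg_per_gDW", "molecular_weight_g_per_mol",
            "transferable")
  if (!all(need %in% names(d))) {
    stop("media CSV '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  }
  media_composition(d$compound_id, d$mass_mg_per_gDW,
                    d$molecular_weight_g_per_mol,
                    as.logical(as.integer(d$transferable)))
}

#' Write a media composition CSV
#' @param media an `fm_media`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_media <- function(media, path) {
  d <- data.frame(compound_id = media$compound_id,
                  mass_mg_per_gDW = media$mass_mg,
                  molecular_weight_g_per_mol = media$mw,
                  transferable = as.integer(media$transferable))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a compound registry CSV
#'
#' Columns: canonical_id, model_id, model_metabolite_id and optionally
#' molecular_weight_g_per_mol.
#' @param path file path.
#' @return an `fm_registry`.
#' @export
read_registry <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("canonical_id", "model_id", "model_metabolite_id")
  if (!all(need %in% names(d))) {
    stop("registry CSV '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  }
  mw <- if ("molecular_weight_g_per_mol" %in% names(d))
    d$molecular_weight_g_per_mol else NA_real_
  compound_registry(d$canonical_id, d$model_id, d$model_metabolite_id, mw)
}

#' Write a compound registry CSV
#' @param registry an `fm_registry`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  d <- data.frame(canonical_id = registry$canonical_id,
                  model_id = registry$model_id,
                  model_metabolite_id = registry$model_metabolite_id,
                  molecular_weight_g_per_mol = registry$mw)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
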