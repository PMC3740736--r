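# SBML import/export.
#
# The writer emits Level 2 Version 4 with the classic constraint-based
# conventions: per-reaction kineticLaw parameters LOWER_BOUND, UPPER_BOUND
# and OBJECTIVE_COEFFICIENT. The reader additionally understands the
# Level 3 fbc dialect (fbc:lowerFluxBound / fbc:upperFluxBound attributes
# resolving to model parameters, fbc:listOfFluxBounds, and fbc
# objectives), so models from either era load.

.sbml_compartment <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_character_)
  lx <- tolower(x)
  if (lx %in% .compartments) return(lx)
  if (grepl("^e($|xt)", lx)) return("extracellular")
  if (grepl("^m($|ito)", lx)) return("mitochondrion")
  if (grepl("^c($|yto)", lx)) return("cytosol")
  NA_character_
}

#' Read a stoichiometric model from SBML
#'
#' Accepts Level 2 (bounds as kineticLaw parameters named
#' `LOWER_BOUND`/`UPPER_BOUND`, objective via `OBJECTIVE_COEFFICIENT`)
#' and Level 3 fbc (bound attributes resolving to model parameters,
#' `fbc:listOfFluxBounds`, fbc objectives). Reactions without explicit
#' bounds fall back on the reversibility flag: reversible maps to
#' `(-unbounded_cap, unbounded_cap)`, irreversible to
#' `(0, unbounded_cap)`. Species lacking a recognizable compartment are
#' assigned to the cytosol with a warning; `boundaryCondition` flags are
#' ignored (every species takes part in the steady-state constraint).
#'
#' @param path SBML file
#' @param unbounded_cap bound used for "unlimited" fluxes, default 99999
#' @return an `mf_model`
#' @export
read_sbml <- function(path, unbounded_cap = 99999) {
  doc <- xml2::read_xml(path)  # malformed XML errors out here
  find <- function(node, what)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  attr1 <- function(node, what) {
    v <- xml2::xml_attr(node, what)
    if (length(v) == 0L) NA_character_ else v
  }

  # model-level parameters (fbc bound values live here in L3)
  pars <- new.env(parent = emptyenv())
  for (p in find(doc, "parameter")) {
    id <- attr1(p, "id")
    v <- suppressWarnings(as.numeric(attr1(p, "value")))
    if (!is.na(id) && !is.na(v)) assign(id, v, envir = pars)
  }

  n_warn <- 0L
  mets <- list()
  for (sp in find(doc, "species")) {
    id <- attr1(sp, "id")
    nm <- attr1(sp, "name")
    comp <- .sbml_compartment(attr1(sp, "compartment"))
    if (is.na(comp)) {
      n_warn <- n_warn + 1L
      comp <- "cytosol"
    }
    mets[[length(mets) + 1L]] <-
      metabolite(id, if (is.na(nm)) id else nm, comp)
  }
  if (n_warn > 0L)
    warning(n_warn, " species without a recognizable compartment",
            " assigned to cytosol")

  # legacy fbc flux-bound list: reaction id -> (op, value)
  fb_lo <- new.env(parent = emptyenv())
  fb_hi <- new.env(parent = emptyenv())
  for (fb in find(doc, "fluxBound")) {
    rid <- attr1(fb, "reaction")
    op <- attr1(fb, "operation")
    v <- suppressWarnings(as.numeric(attr1(fb, "value")))
    if (is.na(rid) || is.na(v)) next
    if (op %in% c("greaterEqual", "equal")) assign(rid, v, envir = fb_lo)
    if (op %in% c("lessEqual", "equal")) assign(rid, v, envir = fb_hi)
  }

  objective_id <- NA_character_
  # fbc objective (first active flux objective wins)
  fo <- find(doc, "fluxObjective")
  if (length(fo) > 0L) {
    rid <- xml2::xml_attr(fo[[1L]], "reaction")
    if (is.na(rid))  # namespaced attribute
      rid <- attr1(fo[[1L]], "reaction")
    objective_id <- rid
  }

  rxns <- list()
  for (rx in find(doc, "reaction")) {
    id <- attr1(rx, "id")
    nm <- attr1(rx, "name")
    reversible <- !identical(attr1(rx, "reversible"), "false")
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sign <- if (side == "listOfReactants") -1 else 1
      lst <- xml2::xml_find_first(rx,
        sprintf(".//*[local-name()='%s']", side))
      if (inherits(lst, "xml_missing")) next
      for (sr in find(lst, "speciesReference")) {
        sid <- attr1(sr, "species")
        coef <- suppressWarnings(as.numeric(attr1(sr, "stoichiometry")))
        if (is.na(coef)) coef <- 1
        st[sid] <- (if (sid %in% names(st)) st[[sid]] else 0) + sign * coef
      }
    }
    st <- st[st != 0]
    if (length(st) == 0L)
      stop("reaction '", id, "' has an empty stoichiometry")

    lb <- ub <- NA_real_
    oc <- NA_real_
    for (p in find(rx, "parameter")) {
      pid <- attr1(p, "id")
      if (is.na(pid)) pid <- attr1(p, "name")
      v <- suppressWarnings(as.numeric(attr1(p, "value")))
      if (identical(pid, "LOWER_BOUND")) lb <- v
      if (identical(pid, "UPPER_BOUND")) ub <- v
      if (identical(pid, "OBJECTIVE_COEFFICIENT")) oc <- v
    }
    # L3 fbc attributes referencing model parameters
    lref <- attr1(rx, "lowerFluxBound")
    uref <- attr1(rx, "upperFluxBound")
    if (is.na(lb) && !is.na(lref) && exists(lref, envir = pars))
      lb <- get(lref, envir = pars)
    if (is.na(ub) && !is.na(uref) && exists(uref, envir = pars))
      ub <- get(uref, envir = pars)
    if (is.na(lb) && exists(id, envir = fb_lo)) lb <- get(id, envir = fb_lo)
    if (is.na(ub) && exists(id, envir = fb_hi)) ub <- get(id, envir = fb_hi)
    if (is.na(lb)) lb <- if (reversible) -unbounded_cap else 0
    if (is.na(ub)) ub <- unbounded_cap
    lb <- max(lb, -unbounded_cap)
    ub <- min(ub, unbounded_cap)
    if (!is.na(oc) && oc != 0 && is.na(objective_id)) objective_id <- id

    subsystem <- ""
    notes <- xml2::xml_find_first(rx, ".//*[local-name()='notes']")
    if (!inherits(notes, "xml_missing")) {
      txt <- xml2::xml_text(notes)
      mt <- regmatches(txt, regexpr("SUBSYSTEM:\\s*[^\n]*", txt))
      if (length(mt)) subsystem <- trimws(sub("SUBSYSTEM:\\s*", "", mt))
    }

    rxns[[length(rxns) + 1L]] <-
      reaction(id, st, lb, ub, name = if (is.na(nm)) id else nm,
               subsystem = subsystem)
  }
  stoichiometric_model(mets, rxns, objective_id)
}

#' Write a stoichiometric model as SBML Level 2
#'
#' Bounds and the objective are stored as the conventional kineticLaw
#' parameters (`LOWER_BOUND`, `UPPER_BOUND`, `OBJECTIVE_COEFFICIENT`),
#' which [read_sbml()] and the classic constraint-based toolchains
#' understand. The emitted file re-reads to a model with an identical
#' stoichiometry matrix, bounds and objective.
#'
#' @param model an `mf_model`
#' @param path output file
#' @return the path, invisibly
#' @export
write_sbml <- function(model, path) {
  rep <- validate_model(model)
  rep <- rep[rep$type != "orphan_metabolite", , drop = FALSE]
  if (nrow(rep) > 0L)
    stop("refusing to write invalid model: ", rep$type[1L])
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, useBytes = FALSE)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">')
  w('  <model id="model" name="stoichiometric model">')
  w('    <listOfCompartments>')
  for (cp in .compartments)
    w('      <compartment id="', cp, '" size="1"/>')
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites)))
    w('      <species id="', esc(model$metabolites$id[i]),
      '" name="', esc(model$metabolites$name[i]),
      '" compartment="', model$metabolites$compartment[i],
      '" initialConcentration="0"/>')
  w('    </listOfSpecies>')
  w('    <listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    st <- model$stoichiometry[[rid]]
    reactants <- st[st < 0]
    products <- st[st > 0]
    lb <- model$reactions$lower_bound[i]
    w('      <reaction id="', esc(rid),
      '" name="', esc(model$reactions$name[i]),
      '" reversible="', if (lb < 0) "true" else "false", '">')
    if (nzchar(model$reactions$subsystem[i]))
      w('        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>',
        'SUBSYSTEM: ', esc(model$reactions$subsystem[i]),
        '</p></body></notes>')
    if (length(reactants)) {
      w('        <listOfReactants>')
      for (sid in names(reactants))
        w('          <speciesReference species="', esc(sid),
          '" stoichiometry="', format(-reactants[[sid]], digits = 15), '"/>')
      w('        </listOfReactants>')
    }
    if (length(products)) {
      w('        <listOfProducts>')
      for (sid in names(products))
        w('          <speciesReference species="', esc(sid),
          '" stoichiometry="', format(products[[sid]], digits = 15), '"/>')
      w('        </listOfProducts>')
    }
    oc <- if (!is.na(model$objective_id) && rid == model$objective_id) 1 else 0
    w('        <kineticLaw>')
    w('          <math xmlns="http://www.w3.org/1998/Math/MathML">',
      '<ci> FLUX_VALUE </ci></math>')
    w('          <listOfParameters>')
    w('            <parameter id="LOWER_BOUND" value="',
      format(lb, digits = 15), '"/>')
    w('            <parameter id="UPPER_BOUND" value="',
      format(model$reactions$upper_bound[i], digits = 15), '"/>')
    w('            <parameter id="OBJECTIVE_COEFFICIENT" value="', oc, '"/>')
    w('          </listOfParameters>')
    w('        </kineticLaw>')
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('  </model>')
  w('</sbml>')
  invisible(path)
}
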