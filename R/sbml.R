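## SBML Level 3 Version 1 input/output with the flux-balance-constraints
## (fbc) extension: species with formulas/charges, parameter-backed flux
## bounds, an active linear objective, and gene products. Built directly on
## xml2; only the subset of SBML needed for constraint-based models is
## supported.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_num <- function(x) {
  if (is.na(x)) return(NA_real_)
  if (x == "INF") return(Inf)
  if (x == "-INF") return(-Inf)
  as.numeric(x)
}

num_sbml <- function(x) {
  if (is.infinite(x)) {
    if (x > 0) "INF" else "-INF"
  } else {
    format(x, digits = 17, scientific = FALSE)
  }
}

#' Read a metabolic model from SBML
#'
#' Parses an SBML Level 3 Version 1 document with the fbc extension:
#' compartments, species (with `fbc:chemicalFormula` and `fbc:charge`),
#' reactions with parameter-backed flux bounds, gene products, and the
#' active objective. Identifiers are preserved verbatim.
#'
#' @param path path to the SBML file.
#' @return a [metabolic_model()].
#' @export
read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mnode <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mnode, "xml_missing")) {
    stop("malformed SBML: no <model> element in ", path)
  }
  model_id <- xml2::xml_attr(mnode, "id")
  if (is.na(model_id)) model_id <- "model"

  comp_nodes <- xml2::xml_find_all(mnode, "./s:listOfCompartments/s:compartment", ns)
  comp_ids <- xml2::xml_attr(comp_nodes, "id")
  comp_names <- xml2::xml_attr(comp_nodes, "name")
  comp_names[is.na(comp_names)] <- comp_ids[is.na(comp_names)]
  model <- metabolic_model(model_id,
                           compartments = stats::setNames(comp_names, comp_ids))

  sp <- xml2::xml_find_all(mnode, "./s:listOfSpecies/s:species", ns)
  if (length(sp)) {
    ids <- xml2::xml_attr(sp, "id")
    if (anyNA(ids)) stop("malformed SBML: species without id")
    nm <- xml2::xml_attr(sp, "name"); nm[is.na(nm)] <- ids[is.na(nm)]
    charge <- suppressWarnings(as.numeric(xml2::xml_attr(sp, "charge", ns = ns)))
    fbc_charge <- suppressWarnings(
      as.numeric(xml2::xml_attr(sp, "fbc:charge", ns = ns)))
    charge <- ifelse(is.na(fbc_charge), charge, fbc_charge)
    charge[is.na(charge)] <- 0
    model$metabolites <- data.frame(
      id = ids, name = nm,
      compartment = xml2::xml_attr(sp, "compartment"),
      formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns = ns),
      charge = charge, stringsAsFactors = FALSE)
  }

  par_nodes <- xml2::xml_find_all(mnode, "./s:listOfParameters/s:parameter", ns)
  par_vals <- stats::setNames(
    vapply(xml2::xml_attr(par_nodes, "value"), sbml_num, numeric(1)),
    xml2::xml_attr(par_nodes, "id"))

  gp <- xml2::xml_find_all(
    mnode, "./fbc:listOfGeneProducts/fbc:geneProduct", ns)
  model$genes <- xml2::xml_attr(gp, "fbc:id", ns = ns)

  rx <- xml2::xml_find_all(mnode, "./s:listOfReactions/s:reaction", ns)
  rids <- xml2::xml_attr(rx, "id")
  if (anyNA(rids)) stop("malformed SBML: reaction without id")
  rnames <- xml2::xml_attr(rx, "name"); rnames[is.na(rnames)] <- rids[is.na(rnames)]
  lower <- upper <- numeric(length(rx))
  gprs <- character(length(rx))
  stoich <- vector("list", length(rx))
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    lb_ref <- xml2::xml_attr(r, "fbc:lowerFluxBound", ns = ns)
    ub_ref <- xml2::xml_attr(r, "fbc:upperFluxBound", ns = ns)
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    lower[i] <- if (!is.na(lb_ref) && lb_ref %in% names(par_vals))
      par_vals[[lb_ref]] else if (rev) -Inf else 0
    upper[i] <- if (!is.na(ub_ref) && ub_ref %in% names(par_vals))
      par_vals[[ub_ref]] else Inf
    s <- numeric()
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(r, paste0("./s:", tag, "/s:speciesReference"), ns)
      if (length(refs)) {
        sid <- xml2::xml_attr(refs, "species")
        coef <- suppressWarnings(as.numeric(xml2::xml_attr(refs, "stoichiometry")))
        coef[is.na(coef)] <- 1
        for (j in seq_along(sid)) {
          s[sid[j]] <- (if (sid[j] %in% names(s)) s[[sid[j]]] else 0) +
            side * coef[j]
        }
      }
    }
    stoich[[i]] <- s
    ga <- xml2::xml_find_all(r, ".//fbc:geneProductRef", ns)
    gprs[i] <- paste(xml2::xml_attr(ga, "fbc:geneProduct", ns = ns),
                     collapse = " ")
  }
  bad <- setdiff(unique(unlist(lapply(stoich, names))), model$metabolites$id)
  if (length(bad)) {
    stop("malformed SBML: speciesReference to undeclared species: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  model$reactions <- data.frame(id = rids, name = rnames, lower = lower,
                                upper = upper, gpr = gprs,
                                stringsAsFactors = FALSE)
  model$stoichiometry <- stats::setNames(stoich, rids)

  active <- xml2::xml_attr(
    xml2::xml_find_first(mnode, "./fbc:listOfObjectives", ns),
    "fbc:activeObjective", ns = ns)
  objective <- numeric()
  if (!is.na(active)) {
    fo <- xml2::xml_find_all(mnode, paste0(
      "./fbc:listOfObjectives/fbc:objective[@fbc:id='", active,
      "']/fbc:listOfFluxObjectives/fbc:fluxObjective"), ns)
    if (length(fo)) {
      objective <- stats::setNames(
        as.numeric(xml2::xml_attr(fo, "fbc:coefficient", ns = ns)),
        xml2::xml_attr(fo, "fbc:reaction", ns = ns))
    }
  }
  if (length(objective) == 0) {
    warning("SBML model has no active objective; objective left empty")
  } else {
    model <- set_objective(model, objective)
  }
  model
}

#' Write a metabolic model to SBML
#'
#' Serializes to SBML Level 3 Version 1 with the fbc (version 2) extension.
#' Flux bounds become shared parameters; infinite bounds are encoded as
#' `INF`/`-INF`. Coupling constraints are not part of core SBML and are not
#' serialized.
#'
#' @param model a [metabolic_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    "    <listOfCompartments>")
  for (i in seq_along(model$compartments)) {
    lines <- c(lines, sprintf(
      '      <compartment id="%s" name="%s" constant="true"/>',
      esc(names(model$compartments)[i]), esc(model$compartments[i])))
  }
  lines <- c(lines, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    fstr <- if (is.na(m$formula) || m$formula == "") "" else
      sprintf(' fbc:chemicalFormula="%s"', esc(m$formula))
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" name="%s" compartment="%s"%s',
             ' fbc:charge="%g" hasOnlySubstanceUnits="false"',
             ' boundaryCondition="false" constant="false"/>'),
      esc(m$id), esc(m$name), esc(m$compartment), fstr, m$charge))
  }
  ## deduplicated bound parameters
  bounds <- unique(c(model$reactions$lower, model$reactions$upper))
  bid <- function(v) {
    s <- gsub("-", "m", gsub("\\.", "p", num_sbml(v)))
    paste0("bnd_", s)
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (v in bounds) {
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      bid(v), num_sbml(v)))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    s <- model$stoichiometry[[r$id]]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" name="%s" reversible="%s" fast="false"',
             ' fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(r$id), esc(r$name), if (r$lower < 0) "true" else "false",
      bid(r$lower), bid(r$upper)))
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>")
      for (j in seq_along(reac)) {
        lines <- c(lines, sprintf(
          paste0('          <speciesReference species="%s" stoichiometry=',
                 '"%s" constant="true"/>'),
          esc(names(reac)[j]), format(-reac[j], digits = 15)))
      }
      lines <- c(lines, "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>")
      for (j in seq_along(prod)) {
        lines <- c(lines, sprintf(
          paste0('          <speciesReference species="%s" stoichiometry=',
                 '"%s" constant="true"/>'),
          esc(names(prod)[j]), format(prod[j], digits = 15)))
      }
      lines <- c(lines, "        </listOfProducts>")
    }
    genes <- if (!is.na(r$gpr) && nzchar(r$gpr))
      strsplit(r$gpr, "\\s+")[[1]] else character()
    if (length(genes) == 1) {
      lines <- c(lines,
                 "        <fbc:geneProductAssociation>",
                 sprintf('          <fbc:geneProductRef fbc:geneProduct="%s"/>',
                         esc(genes)),
                 "        </fbc:geneProductAssociation>")
    } else if (length(genes) > 1) {
      lines <- c(lines,
                 "        <fbc:geneProductAssociation>", "          <fbc:and>",
                 sprintf('            <fbc:geneProductRef fbc:geneProduct="%s"/>',
                         esc(genes)),
                 "          </fbc:and>", "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  if (length(model$objective)) {
    lines <- c(lines,
               '    <fbc:listOfObjectives fbc:activeObjective="obj">',
               '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
               "        <fbc:listOfFluxObjectives>")
    for (i in seq_along(model$objective)) {
      lines <- c(lines, sprintf(
        paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
               'fbc:coefficient="%g"/>'),
        esc(names(model$objective)[i]), model$objective[i]))
    }
    lines <- c(lines,
               "        </fbc:listOfFluxObjectives>",
               "      </fbc:objective>", "    </fbc:listOfObjectives>")
  }
  genes <- unique(model$genes)
  if (length(genes)) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>",
               sprintf(paste0('      <fbc:geneProduct fbc:id="%s" ',
                              'fbc:label="%s"/>'), esc(genes), esc(genes)),
               "    </fbc:listOfGeneProducts>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
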