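## In-memory representation of a constraint-based metabolic model:
## stoichiometry, bounds, objective, compartments, annotations, plus the
## linear coupling constraints used for the physiological ratio couplings
## and the photon cap.

#' Construct an empty metabolic model
#'
#' A `metabolic_model` holds metabolites, reactions with bounds and
#' gene-protein-reaction strings, per-reaction stoichiometry maps, a linear
#' objective, compartments, and a list of extra linear coupling constraints
#' over fluxes (rows appended to the steady-state system when solving).
#'
#' @param id model identifier.
#' @param compartments named character vector (id -> name).
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id = "model", compartments = c(c = "cytosol")) {
  structure(list(
    id = id,
    compartments = compartments,
    metabolites = data.frame(id = character(), name = character(),
                             compartment = character(), formula = character(),
                             charge = numeric(), stringsAsFactors = FALSE),
    reactions = data.frame(id = character(), name = character(),
                           lower = numeric(), upper = numeric(),
                           gpr = character(), stringsAsFactors = FALSE),
    stoichiometry = list(),
    objective = numeric(),
    genes = character(),
    couplings = list()
  ), class = "metabolic_model")
}

#' Add a metabolite
#'
#' @param model a `metabolic_model`.
#' @param id metabolite identifier (unique).
#' @param compartment compartment id.
#' @param formula chemical formula (`NA` for massless species, e.g. photons).
#' @param name display name.
#' @param charge formal charge.
#' @return the updated model.
#' @export
add_metabolite <- function(model, id, compartment, formula = NA_character_,
                           name = id, charge = 0) {
  stopifnot(inherits(model, "metabolic_model"))
  if (id %in% model$metabolites$id) stop("duplicate metabolite id: ", id)
  if (!compartment %in% names(model$compartments)) {
    stop("unknown compartment: ", compartment)
  }
  model$metabolites <- rbind(model$metabolites, data.frame(
    id = id, name = name, compartment = compartment,
    formula = formula, charge = charge, stringsAsFactors = FALSE))
  model
}

#' Add a reaction
#'
#' @param model a `metabolic_model`.
#' @param id reaction identifier (unique).
#' @param stoichiometry named numeric vector, metabolite id -> coefficient
#'   (negative = consumed). All names must be declared metabolites.
#' @param lower,upper flux bounds (mmol gCDM^-1 h^-1).
#' @param name display name.
#' @param gpr gene association string.
#' @return the updated model.
#' @export
add_reaction <- function(model, id, stoichiometry, lower = 0, upper = Inf,
                         name = id, gpr = "") {
  stopifnot(inherits(model, "metabolic_model"))
  if (id %in% model$reactions$id) stop("duplicate reaction id: ", id)
  if (lower > upper) stop("lower bound exceeds upper bound for ", id)
  missing <- setdiff(names(stoichiometry), model$metabolites$id)
  if (length(missing)) {
    stop("reaction ", id, " references undeclared metabolites: ",
         paste(missing, collapse = ", "))
  }
  model$reactions <- rbind(model$reactions, data.frame(
    id = id, name = name, lower = lower, upper = upper, gpr = gpr,
    stringsAsFactors = FALSE))
  model$stoichiometry[[id]] <- stoichiometry
  model
}

#' Set flux bounds of a reaction
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lower,upper new bounds (omit to keep).
#' @return the updated model.
#' @export
set_bounds <- function(model, id, lower = NULL, upper = NULL) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("no such reaction: ", id)
  if (!is.null(lower)) model$reactions$lower[i] <- lower
  if (!is.null(upper)) model$reactions$upper[i] <- upper
  if (model$reactions$lower[i] > model$reactions$upper[i]) {
    stop("lower bound exceeds upper bound for ", id)
  }
  model
}

#' Set the (linear) objective
#'
#' @param model a `metabolic_model`.
#' @param objective named numeric vector, reaction id -> coefficient.
#' @return the updated model.
#' @export
set_objective <- function(model, objective) {
  missing <- setdiff(names(objective), model$reactions$id)
  if (length(missing)) stop("objective references unknown reactions: ",
                            paste(missing, collapse = ", "))
  model$objective <- objective
  model
}

#' Append a linear flux coupling constraint
#'
#' Couplings are extra rows `sum_j coef_j v_j {sense} rhs` enforced together
#' with the steady-state balance whenever the model is solved.
#'
#' @param model a `metabolic_model`.
#' @param coefs named numeric vector over reaction ids.
#' @param sense one of `"="`, `"<="`, `">="`.
#' @param rhs right-hand side.
#' @param name label used in reports.
#' @return the updated model.
#' @export
add_coupling <- function(model, coefs, sense = "=", rhs = 0, name = "") {
  missing <- setdiff(names(coefs), model$reactions$id)
  if (length(missing)) stop("coupling references unknown reactions: ",
                            paste(missing, collapse = ", "))
  stopifnot(sense %in% c("=", "<=", ">="))
  model$couplings <- c(model$couplings,
                       list(list(coefs = coefs, sense = sense, rhs = rhs,
                                 name = name)))
  model
}

#' Stoichiometric matrix
#'
#' Dense metabolite-by-reaction matrix `N` with `N[i, j]` the coefficient of
#' metabolite `i` in reaction `j`.
#'
#' @param model a `metabolic_model`.
#' @return numeric matrix with dimnames (metabolites, reactions).
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  N <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    s <- model$stoichiometry[[rxns[j]]]
    if (length(s)) N[names(s), j] <- s
  }
  N
}

## a reaction is an exchange if it touches at most one metabolite
is_exchange <- function(model, id) {
  vapply(id, function(r) length(model$stoichiometry[[r]]) <= 1L, logical(1))
}

## biomass reactions: carry objective weight or match the id convention
is_biomass <- function(model, id) {
  id %in% names(model$objective)[model$objective != 0] |
    grepl("biomass", id, ignore.case = TRUE)
}

## metabolites without an assigned formula (photons etc.)
massless_metabolites <- function(model) {
  model$metabolites$id[is.na(model$metabolites$formula) |
                         model$metabolites$formula == ""]
}

## photon species: massless and named as light quanta
photon_metabolites <- function(model) {
  ml <- massless_metabolites(model)
  idx <- match(ml, model$metabolites$id)
  pat <- "photon|light|^hv(_|$)|_hv(_|$)"
  ml[grepl(pat, ml, ignore.case = TRUE) |
       grepl(pat, model$metabolites$name[idx], ignore.case = TRUE)]
}

#' Parse a chemical formula into element counts
#'
#' Handles plain element-count formulas such as `"C10H12N5O13P3"`; element
#' symbols are an upper-case letter plus optional lower-case letters.
#'
#' @param formula character scalar.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || formula == "") return(numeric())
  m <- gregexpr("([A-Z][a-z]*)([0-9]*\\.?[0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("^([A-Z][a-z]*).*$", "\\1", parts)
  cnt <- sub("^[A-Z][a-z]*", "", parts)
  cnt <- ifelse(cnt == "", 1, as.numeric(cnt))
  agg <- tapply(cnt, el, sum)
  stats::setNames(as.numeric(agg[unique(el)]), unique(el))
}

#' Elemental mass-balance check
#'
#' Verifies per-element conservation for every reaction that is checkable:
#' exchange reactions, biomass reactions and reactions touching massless
#' species (photons) are skipped; reactions with a metabolite lacking a
#' formula are reported as uncheckable, not failed.
#'
#' @param model a `metabolic_model`.
#' @param tol residual below which an element is considered balanced.
#' @return data.frame of unbalanced reactions (`reaction`, `element`,
#'   `residual`), with attributes `skipped` and `uncheckable` listing the
#'   reaction ids excluded from the check and `checked` the ids verified.
#' @export
check_mass_balance <- function(model, tol = 1e-6) {
  photons <- photon_metabolites(model)
  rxns <- model$reactions$id
  skip <- is_exchange(model, rxns) | is_biomass(model, rxns) |
    vapply(rxns, function(r) any(names(model$stoichiometry[[r]]) %in% photons),
           logical(1))
  out <- list()
  uncheckable <- character()
  checked <- character()
  fmap <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  cmap <- stats::setNames(model$metabolites$charge, model$metabolites$id)
  for (r in rxns[!skip]) {
    s <- model$stoichiometry[[r]]
    fs <- fmap[names(s)]
    if (any(is.na(fs) | fs == "")) {
      uncheckable <- c(uncheckable, r)
      next
    }
    counts <- lapply(fs, parse_formula)
    els <- unique(unlist(lapply(counts, names)))
    resid <- vapply(els, function(e) {
      sum(s * vapply(counts, function(x) if (e %in% names(x)) x[[e]] else 0,
                     numeric(1)))
    }, numeric(1))
    resid <- c(resid, charge = sum(s * cmap[names(s)]))
    bad <- which(abs(resid) > tol)
    checked <- c(checked, r)
    if (length(bad)) {
      out[[r]] <- data.frame(reaction = r, element = names(resid)[bad],
                             residual = unname(resid[bad]),
                             stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else
    data.frame(reaction = character(), element = character(),
               residual = numeric(), stringsAsFactors = FALSE)
  attr(res, "skipped") <- rxns[skip]
  attr(res, "uncheckable") <- uncheckable
  attr(res, "checked") <- checked
  res
}

#' Summary statistics of a reconstruction
#'
#' Counts reactions, metabolites, unique metabolites (identical after
#' stripping a trailing `_<compartment>` suffix matching a declared
#' compartment id), genes, compartments, and mass-balanced intracellular
#' reactions (balanced per [check_mass_balance()], i.e. excluding exchanges,
#' biomass and photon-carrying reactions).
#'
#' @param model a `metabolic_model`.
#' @return object of class `model_summary` (a named list of six counts).
#' @export
model_summary <- function(model) {
  comp_pat <- paste0("_(", paste(names(model$compartments), collapse = "|"),
                     ")$")
  base_ids <- sub(comp_pat, "", model$metabolites$id)
  mb <- check_mass_balance(model)
  n_balanced <- length(attr(mb, "checked")) -
    length(unique(mb$reaction))
  structure(list(
    n_reactions = nrow(model$reactions),
    n_metabolites = nrow(model$metabolites),
    n_unique_metabolites = length(unique(base_ids)),
    n_genes = length(model$genes),
    n_compartments = length(model$compartments),
    n_mass_balanced_intracellular = n_balanced
  ), class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Reactions:                     %d\n",
    "Metabolites:                   %d\n",
    "Unique metabolites:            %d\n",
    "Genes:                         %d\n",
    "Compartments:                  %d\n",
    "Mass-balanced intracellular:   %d\n"),
    x$n_reactions, x$n_metabolites, x$n_unique_metabolites,
    x$n_genes, x$n_compartments, x$n_mass_balanced_intracellular))
  invisible(x)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("Metabolic model '%s': %d reactions, %d metabolites, %d compartments\n",
              x$id, nrow(x$reactions), nrow(x$metabolites),
              length(x$compartments)))
  if (length(x$objective)) {
    cat("Objective:", paste(sprintf("%g*%s", x$objective, names(x$objective)),
                            collapse = " + "), "\n")
  }
  if (length(x$couplings)) {
    cat(length(x$couplings), "coupling constraint(s)\n")
  }
  invisible(x)
}
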