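## Physiological ratio couplings, the light constraints (photon cap and
## photodamage ATP drain), and light-dependent biomass objective functions.

#' Reaction roles
#'
#' Maps the functional roles the light constraints and the downstream
#' physiology need onto model reaction identifiers.
#'
#' @param photon_consuming ids of the photon-utilizing reactions (PSII and
#'   PSI, or a lumped electron-transport reaction).
#' @param psii id of the PSII O2-producing reaction.
#' @param psii_o2_coefficient O2 stoichiometric coefficient of that reaction.
#' @param rubisco_carboxylase,rubisco_oxygenase RuBisCO reaction ids.
#' @param mehler_like,mehler_psi,mehler_psii Mehler-type O2-reducing ids.
#' @param oxidase terminal oxidase reaction id(s) (a set is summed).
#' @param ngam ATP-maintenance (ATP hydrolysis) reaction id.
#' @param atpase,fnr thylakoid ATPase (full cycle) and FNR ids.
#' @param o2_exchange O2 exchange reaction id (positive flux = export).
#' @param carbon_exchanges inorganic-carbon exchange ids (uptake counted as
#'   assimilation).
#' @param biomass biomass reaction id.
#' @return object of class `reaction_roles`.
#' @export
reaction_roles <- function(photon_consuming, psii, psii_o2_coefficient = 1,
                           rubisco_carboxylase = NULL, rubisco_oxygenase = NULL,
                           mehler_like = NULL, mehler_psi = NULL,
                           mehler_psii = NULL, oxidase = NULL, ngam = NULL,
                           atpase = NULL, fnr = NULL, o2_exchange = NULL,
                           carbon_exchanges = NULL, biomass = NULL) {
  structure(list(photon_consuming = photon_consuming, psii = psii,
                 psii_o2_coefficient = psii_o2_coefficient,
                 rubisco_carboxylase = rubisco_carboxylase,
                 rubisco_oxygenase = rubisco_oxygenase,
                 mehler_like = mehler_like, mehler_psi = mehler_psi,
                 mehler_psii = mehler_psii, oxidase = oxidase, ngam = ngam,
                 atpase = atpase, fnr = fnr, o2_exchange = o2_exchange,
                 carbon_exchanges = carbon_exchanges, biomass = biomass),
            class = "reaction_roles")
}

check_roles <- function(model, roles, needed) {
  for (nm in needed) {
    ids <- roles[[nm]]
    if (is.null(ids) || !all(ids %in% model$reactions$id)) {
      stop("reaction role '", nm, "' is missing or not in the model")
    }
  }
  invisible(TRUE)
}

#' Physiological flux constraints
#'
#' The ratio couplings and maintenance minima applied identically across all
#' light intensities. All fractions are relative to O2 production at PSII
#' except the RuBisCO oxygenase fraction, which is relative to total RuBisCO
#' flux. Modes select equality versus lower-bound enforcement; by default
#' the Mehler-type and RuBisCO couplings are equalities and the terminal
#' oxidase is a lower bound.
#'
#' @param rubisco_oxygenase_fraction fraction of total RuBisCO flux routed
#'   through the oxygenase (default 0.03).
#' @param ngam_min minimal non-growth-associated ATP maintenance flux,
#'   mmol gCDM^-1 h^-1 (default 1.5).
#' @param mehler_like_fraction,mehler_psi_fraction,mehler_psii_fraction
#'   Mehler-type fractions of PSII O2 (defaults 0.10, 0.005, 0.005).
#' @param terminal_oxidase_fraction oxidase fraction of PSII O2
#'   (default 0.091).
#' @param modes named character vector with entries in
#'   `c("equality", "lower")` for `rubisco`, `mehler_like`, `mehler_psi`,
#'   `mehler_psii`, `oxidase`.
#' @return object of class `physiological_constraints`.
#' @export
physiological_constraints <- function(rubisco_oxygenase_fraction = 0.03,
                                      ngam_min = 1.5,
                                      mehler_like_fraction = 0.10,
                                      mehler_psi_fraction = 0.005,
                                      mehler_psii_fraction = 0.005,
                                      terminal_oxidase_fraction = 0.091,
                                      modes = NULL) {
  frac <- c(rubisco = rubisco_oxygenase_fraction,
            mehler_like = mehler_like_fraction,
            mehler_psi = mehler_psi_fraction,
            mehler_psii = mehler_psii_fraction,
            oxidase = terminal_oxidase_fraction)
  if (any(frac < 0) || any(frac >= 1)) stop("fractions must lie in [0, 1)")
  if (ngam_min < 0) stop("ngam_min must be non-negative")
  default_modes <- c(rubisco = "equality", mehler_like = "equality",
                     mehler_psi = "equality", mehler_psii = "equality",
                     oxidase = "lower")
  if (!is.null(modes)) default_modes[names(modes)] <- modes
  stopifnot(all(default_modes %in% c("equality", "lower")))
  structure(list(rubisco_oxygenase_fraction = rubisco_oxygenase_fraction,
                 ngam_min = ngam_min,
                 mehler_like_fraction = mehler_like_fraction,
                 mehler_psi_fraction = mehler_psi_fraction,
                 mehler_psii_fraction = mehler_psii_fraction,
                 terminal_oxidase_fraction = terminal_oxidase_fraction,
                 modes = default_modes),
            class = "physiological_constraints")
}

## photon consumption coefficient of each photon-consuming reaction
photon_consumption_coefs <- function(model, roles) {
  photons <- photon_metabolites(model)
  vapply(roles$photon_consuming, function(r) {
    s <- model$stoichiometry[[r]]
    used <- s[names(s) %in% photons & s < 0]
    if (length(used) == 0) {
      stop("reaction ", r, " does not consume a photon species")
    }
    -sum(used)
  }, numeric(1))
}

#' Apply the light constraints to a model
#'
#' Installs (i) the photon cap: the total photon utilization over the
#' photon-consuming reactions is bounded by the effective uptake `J_I*`,
#' and (ii) the photodamage ATP drain: a dedicated pseudo-reaction with the
#' same stoichiometry as the NGAM ATP hydrolysis, both bounds fixed to
#' `v_D`, so that maintenance and photodamage remain separately reportable.
#' Uptake of other nutrients is left unconstrained.
#'
#' @param model a [metabolic_model()].
#' @param state a `light_state` from [compute_light_state()].
#' @param roles a [reaction_roles()] with `photon_consuming` and `ngam`
#'   resolved.
#' @return the constrained model.
#' @export
apply_light_constraints <- function(model, state, roles) {
  check_roles(model, roles, c("photon_consuming", "ngam"))
  coefs <- photon_consumption_coefs(model, roles)
  ## drop a stale photon cap before appending the new one
  keep <- vapply(model$couplings, function(cc) cc$name != "photon_cap",
                 logical(1))
  model$couplings <- model$couplings[keep]
  model <- add_coupling(model, coefs, "<=", state$J_I_star, name = "photon_cap")
  dmg <- model$stoichiometry[[roles$ngam]]
  if (!"PHOTODAMAGE" %in% model$reactions$id) {
    model <- add_reaction(model, "PHOTODAMAGE", dmg,
                          lower = state$v_D, upper = state$v_D,
                          name = "photodamage ATP drain")
  } else {
    i <- match("PHOTODAMAGE", model$reactions$id)
    model$reactions$lower[i] <- state$v_D
    model$reactions$upper[i] <- state$v_D
  }
  model
}

#' Apply the physiological ratio couplings
#'
#' Adds the flux couplings: RuBisCO oxygenase at a fixed fraction of total
#' RuBisCO flux (`(1-f) v_oxy - f v_carb = 0`), Mehler-type fluxes and the
#' terminal-oxidase sum at fractions of the PSII O2 production flux (the
#' PSII flux scaled by its O2 stoichiometric coefficient), each enforced as
#' an equality or a lower bound per `constraints$modes`, and the NGAM lower
#' bound. Couplings with fraction 0 and mode `"lower"` (or equality against
#' an absent optional role) are omitted; a nonzero fraction for an absent
#' role is a configuration error.
#'
#' @param model a [metabolic_model()].
#' @param constraints a [physiological_constraints()].
#' @param roles a [reaction_roles()].
#' @return the constrained model.
#' @export
apply_physiological_constraints <- function(model, constraints, roles) {
  check_roles(model, roles, c("psii", "ngam"))
  psii_o2 <- stats::setNames(roles$psii_o2_coefficient, roles$psii)
  modes <- constraints$modes

  couple_fraction <- function(model, ids, f, mode, label) {
    if (f == 0 && mode == "lower") return(model)
    if (is.null(ids)) {
      if (f == 0) return(model)
      stop("fraction set for absent reaction role: ", label)
    }
    check_roles(model, stats::setNames(list(ids), label), label)
    coefs <- c(stats::setNames(rep(1, length(ids)), ids), -f * psii_o2)
    sense <- if (mode == "equality") "=" else ">="
    add_coupling(model, coefs, sense, 0, name = label)
  }

  f_rub <- constraints$rubisco_oxygenase_fraction
  if (f_rub > 0 || modes[["rubisco"]] == "equality") {
    if (f_rub > 0) {
      check_roles(model, roles, c("rubisco_carboxylase", "rubisco_oxygenase"))
      coefs <- stats::setNames(c(1 - f_rub, -f_rub),
                               c(roles$rubisco_oxygenase,
                                 roles$rubisco_carboxylase))
      sense <- if (modes[["rubisco"]] == "equality") "=" else ">="
      model <- add_coupling(model, coefs, sense, 0, name = "rubisco_oxygenase")
    }
  }
  model <- couple_fraction(model, roles$mehler_like,
                           constraints$mehler_like_fraction,
                           modes[["mehler_like"]], "mehler_like")
  model <- couple_fraction(model, roles$mehler_psi,
                           constraints$mehler_psi_fraction,
                           modes[["mehler_psi"]], "mehler_psi")
  model <- couple_fraction(model, roles$mehler_psii,
                           constraints$mehler_psii_fraction,
                           modes[["mehler_psii"]], "mehler_psii")
  model <- couple_fraction(model, roles$oxidase,
                           constraints$terminal_oxidase_fraction,
                           modes[["oxidase"]], "oxidase")
  i <- match(roles$ngam, model$reactions$id)
  model$reactions$lower[i] <- max(model$reactions$lower[i],
                                  constraints$ngam_min)
  model
}

#' Biomass composition
#'
#' Mass fractions per macromolecular class (g per gCDM, summing to 1) plus
#' the growth-associated ATP coefficient (mmol per gCDM).
#'
#' @param fractions named numeric vector of class mass fractions.
#' @param gam growth-associated ATP coefficient.
#' @return object of class `biomass_composition`.
#' @export
biomass_composition <- function(fractions, gam = 0) {
  if (any(fractions < 0)) stop("class fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("class fractions must sum to 1 (got ", sum(fractions), ")")
  }
  structure(list(fractions = fractions, gam = gam),
            class = "biomass_composition")
}

## standard atomic weights for the elements appearing in biomass components
ATOMIC_WEIGHTS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, Mg = 24.305, Fe = 55.845,
                    K = 39.098, Na = 22.99, Ca = 40.078, Cl = 35.45)

molar_mass <- function(formula) {
  counts <- parse_formula(formula)
  w <- ATOMIC_WEIGHTS[names(counts)]
  if (any(is.na(w))) {
    stop("no atomic weight for element(s): ",
         paste(names(counts)[is.na(w)], collapse = ", "))
  }
  sum(w * counts)
}

#' Extract the reference biomass composition from a model
#'
#' Reads the model's biomass reaction and aggregates the consumed
#' metabolites into macromolecular classes via a class-membership map. The
#' growth-associated ATP coefficient is taken from the ATP drawn by the
#' biomass reaction. Fractions are normalized to the total drawn mass.
#'
#' @param model a [metabolic_model()].
#' @param class_map named character vector, metabolite id -> class name.
#'   Metabolites of the ATP-hydrolysis set (identified from the NGAM
#'   stoichiometry) and the biomass product are handled automatically.
#' @param roles a [reaction_roles()] with `biomass` and `ngam` resolved.
#' @return a [biomass_composition()].
#' @export
biomass_composition_from_model <- function(model, class_map, roles) {
  check_roles(model, roles, c("biomass", "ngam"))
  s <- model$stoichiometry[[roles$biomass]]
  gam_set <- names(model$stoichiometry[[roles$ngam]])
  atp_id <- {
    ng <- model$stoichiometry[[roles$ngam]]
    names(ng)[which.min(ng)]   # the hydrolysed species (coef -1)
  }
  gam <- if (atp_id %in% names(s)) -s[[atp_id]] else 0
  drawn <- s[s < 0 & !names(s) %in% gam_set]
  unmapped <- setdiff(names(drawn), names(class_map))
  if (length(unmapped)) {
    stop("biomass components without a class mapping: ",
         paste(unmapped, collapse = ", "))
  }
  fmap <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  mass <- -drawn * vapply(fmap[names(drawn)], molar_mass, numeric(1)) / 1000
  cls <- class_map[names(drawn)]
  fractions <- tapply(mass, cls, sum)
  fractions <- fractions / sum(fractions)
  biomass_composition(fractions[sort(names(fractions))], gam = gam)
}

#' Build a light-dependent biomass composition
#'
#' Sets the protein and glycogen classes to the measured mass fractions and
#' scales every other class by `(1 - p - g) / (1 - p_ref - g_ref)` so that
#' the result sums to 1. The growth-associated ATP coefficient scales with
#' the protein fraction (`gam_scaling = "protein"`) or is kept constant
#' (`"constant"`).
#'
#' @param protein_frac,glycogen_frac measured mass fractions, g per gCDM,
#'   with `0 <= protein_frac + glycogen_frac < 1`.
#' @param reference a [biomass_composition()] with classes `protein` and/or
#'   `glycogen` present (absent classes are treated as reference fraction 0,
#'   in which case the measured fraction must also be 0).
#' @param gam_scaling `"protein"` or `"constant"`.
#' @return a [biomass_composition()].
#' @export
build_biomass_composition <- function(protein_frac, glycogen_frac, reference,
                                      gam_scaling = c("protein", "constant")) {
  gam_scaling <- match.arg(gam_scaling)
  if (protein_frac < 0 || glycogen_frac < 0 ||
      protein_frac + glycogen_frac >= 1) {
    stop("protein and glycogen fractions must be in [0, 1) and sum to < 1")
  }
  f <- reference$fractions
  p_ref <- if ("protein" %in% names(f)) f[["protein"]] else 0
  g_ref <- if ("glycogen" %in% names(f)) f[["glycogen"]] else 0
  if (p_ref == 0 && protein_frac > 0) {
    stop("reference has no protein class to rescale")
  }
  if (g_ref == 0 && glycogen_frac > 0) {
    stop("reference has no glycogen class to rescale")
  }
  others <- setdiff(names(f), c("protein", "glycogen"))
  rest_ref <- 1 - p_ref - g_ref
  rest_new <- 1 - protein_frac - glycogen_frac
  out <- f
  if (p_ref > 0) out[["protein"]] <- protein_frac
  if (g_ref > 0) out[["glycogen"]] <- glycogen_frac
  if (length(others)) {
    if (rest_ref <= 0) stop("reference leaves no mass for the other classes")
    out[others] <- f[others] * rest_new / rest_ref
  } else if (abs(rest_new) > 1e-6) {
    stop("no other classes to absorb the remaining mass fraction")
  }
  gam <- if (gam_scaling == "constant" || p_ref == 0) reference$gam else
    reference$gam * protein_frac / p_ref
  biomass_composition(out, gam = gam)
}

#' Install a biomass composition as the model objective
#'
#' Rescales the biomass reaction coefficients class by class so that the
#' drawn dry mass per unit flux is distributed according to the composition
#' (total drawn mass preserved from the reference reaction, 1 gCDM for a
#' normalized reconstruction), replaces the ATP-hydrolysis set with the
#' composition's growth-associated ATP coefficient, and points the
#' objective at the biomass reaction.
#'
#' @param model a [metabolic_model()].
#' @param composition a [biomass_composition()].
#' @param class_map named character vector, metabolite id -> class.
#' @param roles a [reaction_roles()] with `biomass` and `ngam` resolved.
#' @return the updated model.
#' @export
set_biomass_objective <- function(model, composition, class_map, roles) {
  check_roles(model, roles, c("biomass", "ngam"))
  s <- model$stoichiometry[[roles$biomass]]
  ngam_s <- model$stoichiometry[[roles$ngam]]
  gam_set <- names(ngam_s)
  drawn <- s[s < 0 & !names(s) %in% gam_set]
  unmapped <- setdiff(names(drawn), names(class_map))
  if (length(unmapped)) {
    stop("biomass components without a class mapping: ",
         paste(unmapped, collapse = ", "))
  }
  fmap <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  mass <- -drawn * vapply(fmap[names(drawn)], molar_mass, numeric(1)) / 1000
  cls <- class_map[names(drawn)]
  class_mass <- tapply(mass, cls, sum)
  total <- sum(class_mass)
  missing_cls <- setdiff(names(composition$fractions), names(class_mass))
  if (length(missing_cls) &&
      any(composition$fractions[missing_cls] > 0)) {
    stop("composition classes absent from the biomass reaction: ",
         paste(missing_cls, collapse = ", "))
  }
  ## start from class metabolites and products; GAM set is rebuilt below
  new_s <- s[!(names(s) %in% gam_set)]
  for (i in seq_along(drawn)) {
    k <- cls[[i]]
    scale <- composition$fractions[[k]] * total / class_mass[[k]]
    new_s[[names(drawn)[i]]] <- drawn[[i]] * scale
  }
  if (composition$gam != 0) {
    for (mid in gam_set) {
      base <- if (mid %in% names(new_s)) new_s[[mid]] else 0
      new_s[[mid]] <- base + composition$gam * ngam_s[[mid]]
    }
  }
  model$stoichiometry[[roles$biomass]] <- new_s[new_s != 0]
  set_objective(model, stats::setNames(1, roles$biomass))
}
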