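## The LP layer: growth maximization, parsimonious flux selection, flux
## variability, and the derived physiology (overall stoichiometry, PQ,
## yields, O2 accounting, ATP/NADPH ratio, light scans).

## assemble the constraint system: steady state plus coupling rows
lp_system <- function(model) {
  N <- stoichiometric_matrix(model)
  A <- N
  sense <- rep("=", nrow(N))
  rhs <- rep(0, nrow(N))
  for (cc in model$couplings) {
    row <- stats::setNames(rep(0, ncol(N)), colnames(N))
    row[names(cc$coefs)] <- cc$coefs
    A <- rbind(A, row)
    sense <- c(sense, cc$sense)
    rhs <- c(rhs, cc$rhs)
  }
  list(A = A, sense = sense, rhs = rhs,
       lower = model$reactions$lower, upper = model$reactions$upper,
       obj = {
         o <- stats::setNames(rep(0, ncol(N)), colnames(N))
         o[names(model$objective)] <- model$objective
         o
       })
}

#' Maximize growth (flux balance analysis)
#'
#' Solves `max c'v` subject to `N v = 0`, the flux bounds, and any coupling
#' constraints. Infeasible or unbounded problems are reported as such,
#' never silently zeroed.
#'
#' @param model a [metabolic_model()] with an objective.
#' @return object of class `flux_solution`: `status`, `mu` (objective
#'   value), and the named flux vector `fluxes`.
#' @export
#' @examples
#' m <- toy_phototroph_model()
#' m <- apply_light_constraints(m, compute_light_state(
#'   light_conditions(100), light_parameters(0.1)), toy_reaction_roles())
#' maximize_growth(m)
maximize_growth <- function(model) {
  if (length(model$objective) == 0) stop("model has no objective")
  sys <- lp_system(model)
  r <- solve_lp(sys$obj, sys$A, sys$sense, sys$rhs, sys$lower, sys$upper,
                maximize = TRUE)
  structure(list(status = r$status,
                 mu = if (r$status == "optimal") r$objective else NA_real_,
                 fluxes = stats::setNames(r$x, model$reactions$id)),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, n = 10, ...) {
  cat(sprintf("Flux solution: status %s, objective %.6g\n", x$status, x$mu))
  if (x$status == "optimal") {
    nz <- x$fluxes[abs(x$fluxes) > 1e-9]
    show <- utils::head(nz[order(-abs(nz))], n)
    for (i in seq_along(show)) {
      cat(sprintf("  %-12s %12.6g\n", names(show)[i], show[i]))
    }
    if (length(nz) > n) cat("  ...", length(nz) - n, "more nonzero fluxes\n")
  }
  invisible(x)
}

#' Parsimonious flux selection
#'
#' Fixes growth at the previously found optimum (relative tolerance
#' `tol`) and minimizes the total absolute flux, resolving the degeneracy
#' of the optimal flux distribution. All reported per-reaction quantities
#' use this representative; the objective value is kept from the
#' maximization step.
#'
#' @param model a [metabolic_model()].
#' @param mu_opt optimal objective value from [maximize_growth()].
#' @param tol relative tolerance on the fixed growth (widened once to
#'   `1e-4` if the fixed problem is infeasible).
#' @return a `flux_solution` with `mu = mu_opt`.
#' @export
parsimonious_solution <- function(model, mu_opt, tol = 1e-6) {
  sys <- lp_system(model)
  n <- length(sys$obj)
  ## split v = v_pos - v_neg, both non-negative
  A2 <- cbind(sys$A, -sys$A)
  lower2 <- c(pmax(sys$lower, 0), pmax(-sys$upper, 0))
  upper2 <- c(pmax(sys$upper, 0), pmax(-sys$lower, 0))
  obj2 <- rep(1, 2 * n)
  solve_at <- function(slack) {
    A3 <- rbind(A2, c(sys$obj, -sys$obj))
    sense3 <- c(sys$sense, ">=")
    rhs3 <- c(sys$rhs, mu_opt - slack * max(1, abs(mu_opt)))
    solve_lp(obj2, A3, sense3, rhs3, lower2, upper2, maximize = FALSE)
  }
  r <- solve_at(tol)
  if (r$status != "optimal") r <- solve_at(1e-4)
  if (r$status != "optimal") {
    stop("parsimonious step failed with status: ", r$status)
  }
  v <- r$x[seq_len(n)] - r$x[n + seq_len(n)]
  structure(list(status = "optimal", mu = mu_opt,
                 fluxes = stats::setNames(v, model$reactions$id)),
            class = "flux_solution")
}

#' Flux variability analysis
#'
#' Per-reaction minimal and maximal flux with the objective fixed at
#' `fraction_of_optimum` times the optimum (relative tolerance `1e-6`).
#'
#' @param model a [metabolic_model()].
#' @param reactions reaction ids to scan (default: all).
#' @param mu_opt optimum from [maximize_growth()] (computed if missing).
#' @param fraction_of_optimum fraction of the optimum to fix (default 1).
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, reactions = model$reactions$id,
                             mu_opt = NULL, fraction_of_optimum = 1) {
  if (is.null(mu_opt)) {
    sol <- maximize_growth(model)
    if (sol$status != "optimal") stop("FVA requires an optimal base solution")
    mu_opt <- sol$mu
  }
  sys <- lp_system(model)
  target <- fraction_of_optimum * mu_opt
  A <- rbind(sys$A, sys$obj)
  sense <- c(sys$sense, ">=")
  rhs <- c(sys$rhs, target - 1e-6 * max(1, abs(target)))
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_)
  for (i in seq_along(reactions)) {
    j <- match(reactions[i], model$reactions$id)
    if (is.na(j)) stop("no such reaction: ", reactions[i])
    e <- stats::setNames(rep(0, length(sys$obj)), names(sys$obj))
    e[j] <- 1
    lo <- solve_lp(e, A, sense, rhs, sys$lower, sys$upper, maximize = FALSE)
    hi <- solve_lp(e, A, sense, rhs, sys$lower, sys$upper, maximize = TRUE)
    out$min[i] <- if (lo$status == "optimal") lo$objective else
      if (lo$status == "unbounded") -Inf else NA_real_
    out$max[i] <- if (hi$status == "optimal") hi$objective else
      if (hi$status == "unbounded") Inf else NA_real_
  }
  out
}

#' Overall stoichiometry of growth
#'
#' Divides every nonzero exchange flux by the growth rate, giving the
#' signed per-gCDM exchange amounts (mmol per gCDM; negative = consumed).
#' Byproducts are carbon-containing exports other than the declared
#' products.
#'
#' @param solution an optimal `flux_solution` with `mu > 0`.
#' @param model the model it came from.
#' @param products exchange reaction ids whose exports are declared
#'   products (O2, biomass) rather than byproducts.
#' @return object of class `overall_stoichiometry`: data.frame (`reaction`,
#'   `metabolite`, `per_gcdm`) with attribute `byproducts`.
#' @export
overall_stoichiometry <- function(solution, model, products = character()) {
  if (is.na(solution$mu) || solution$mu <= 0) {
    stop("overall stoichiometry requires positive growth")
  }
  ## normalize by the solution's own objective flux so the per-gCDM
  ## amounts are exact even under the parsimonious growth tolerance
  obj <- model$objective
  mu_eff <- sum(obj * solution$fluxes[names(obj)])
  if (mu_eff <= 0) mu_eff <- solution$mu
  ex <- model$reactions$id[is_exchange(model, model$reactions$id)]
  v <- solution$fluxes[ex]
  keep <- abs(v) > 1e-9
  ex <- ex[keep]; v <- v[keep]
  met <- vapply(ex, function(r) {
    s <- model$stoichiometry[[r]]
    if (length(s)) names(s)[1] else NA_character_
  }, character(1))
  ## exchange written as "met ->": positive flux = export, so per-gCDM
  ## consumption is negative flux
  out <- data.frame(reaction = ex, metabolite = met,
                    per_gcdm = v / mu_eff, row.names = NULL)
  fmap <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  carbon <- vapply(out$metabolite, function(mm) {
    f <- fmap[[mm]]
    if (is.na(f) || f == "") return(FALSE)
    "C" %in% names(parse_formula(f))
  }, logical(1))
  attr(out, "byproducts") <- out[carbon & out$per_gcdm > 0 &
                                   !out$reaction %in% products, , drop = FALSE]
  class(out) <- c("overall_stoichiometry", class(out))
  out
}

#' Photosynthetic quotient
#'
#' Mol O2 evolved per mol CO2 (inorganic carbon) assimilated.
#'
#' @param solution an optimal `flux_solution`.
#' @param roles a [reaction_roles()] with `o2_exchange` and
#'   `carbon_exchanges` resolved.
#' @return dimensionless PQ.
#' @export
photosynthetic_quotient <- function(solution, roles) {
  o2 <- solution$fluxes[[roles$o2_exchange]]
  co2 <- -sum(solution$fluxes[roles$carbon_exchanges])
  if (abs(co2) < 1e-12) stop("no CO2 assimilation flux")
  o2 / co2
}

#' Biomass yield per photon
#'
#' Growth rate divided by the rate of photon absorption, in gCDM per mol
#' photons (`J_I` given in mmol gCDM^-1 h^-1).
#'
#' @param mu growth rate, h^-1.
#' @param J_I absorbed photon flux, mmol gCDM^-1 h^-1 (> 0).
#' @return yield, gCDM per mol photons.
#' @export
biomass_yield <- function(mu, J_I) {
  if (any(J_I <= 0)) stop("J_I must be strictly positive")
  mu / (J_I / 1000)
}

#' O2 accounting
#'
#' Splits PSII O2 production into net export, Mehler-type consumption, and
#' the remaining non-light-associated consumption (terminal oxidase plus O2
#' used as a metabolic substrate): `nonlight = psii_o2 - net_export -
#' mehler_sum`. The non-light term is the model proxy for O2 consumption
#' measured in darkness.
#'
#' @param solution an optimal `flux_solution`.
#' @param roles a [reaction_roles()].
#' @return list with `psii_o2`, `net_export`, `mehler_sum`,
#'   `nonlight_consumption` (all mmol O2 gCDM^-1 h^-1).
#' @export
o2_accounting <- function(solution, roles) {
  if (is.null(roles$psii) || is.null(roles$o2_exchange)) {
    stop("roles psii and o2_exchange must be resolved")
  }
  psii <- solution$fluxes[[roles$psii]] * roles$psii_o2_coefficient
  net <- solution$fluxes[[roles$o2_exchange]]
  mehler_ids <- c(roles$mehler_like, roles$mehler_psi, roles$mehler_psii)
  mehler <- if (length(mehler_ids)) sum(solution$fluxes[mehler_ids]) else 0
  list(psii_o2 = psii, net_export = net, mehler_sum = mehler,
       nonlight_consumption = psii - net - mehler)
}

#' Optimal ATP/NADPH synthesis ratio via flux variability
#'
#' Flux variability of the thylakoid ATPase and FNR at growth fixed to
#' `fraction_of_optimum` times the optimum; the ratio of ATP to NADPH
#' synthesis is `3 J_ATPase / J_FNR` (3 ATP per full ATPase cycle). The
#' lower bound pairs the minimal ATPase with the maximal FNR flux (NADPH as
#' the primary redox carrier), the upper bound the reverse.
#'
#' @param model a constrained [metabolic_model()].
#' @param roles a [reaction_roles()] with `atpase` and `fnr`.
#' @param mu_opt optimum (computed if missing).
#' @param fraction_of_optimum growth fraction at which to evaluate.
#' @return list `ratio_min`, `ratio_max`, `atpase` and `fnr` ranges, and
#'   `unbounded` flag (TRUE when the FNR range touches 0).
#' @export
atp_nadph_ratio <- function(model, roles, mu_opt = NULL,
                            fraction_of_optimum = 1) {
  check_roles(model, roles, c("atpase", "fnr"))
  fv <- flux_variability(model, c(roles$atpase, roles$fnr), mu_opt,
                         fraction_of_optimum)
  atpase <- fv[fv$reaction == roles$atpase, ]
  fnr <- fv[fv$reaction == roles$fnr, ]
  unbounded <- fnr$min <= 1e-9
  ratio_min <- 3 * atpase$min / fnr$max
  ratio_max <- if (unbounded) Inf else 3 * atpase$max / fnr$min
  list(ratio_min = ratio_min, ratio_max = ratio_max,
       atpase = c(min = atpase$min, max = atpase$max),
       fnr = c(min = fnr$min, max = fnr$max),
       unbounded = unbounded)
}

#' One forward-pipeline evaluation at a light condition
#'
#' Light state, light constraints, physiological constraints, growth
#' maximization, parsimonious fluxes, O2 accounting.
#'
#' @param model a [metabolic_model()] (unconstrained template).
#' @param p a [light_parameters()].
#' @param constraints a [physiological_constraints()].
#' @param roles a [reaction_roles()].
#' @param light a [light_conditions()].
#' @param parsimonious compute the parsimonious representative for the
#'   per-reaction quantities (default TRUE).
#' @return list `mu`, `o2_dark` (non-light O2 consumption), `o2_net`,
#'   `state` (the light state), `solution`, `feasible`.
#' @export
simulate_condition <- function(model, p, constraints, roles, light,
                               parsimonious = TRUE) {
  state <- compute_light_state(light, p)
  m <- apply_light_constraints(model, state, roles)
  m <- apply_physiological_constraints(m, constraints, roles)
  sol <- maximize_growth(m)
  if (sol$status != "optimal") {
    return(list(mu = 0, o2_dark = 0, o2_net = 0, state = state,
                solution = sol, feasible = FALSE))
  }
  rep_sol <- if (parsimonious && sol$mu > 1e-12)
    parsimonious_solution(m, sol$mu) else sol
  acc <- o2_accounting(rep_sol, roles)
  list(mu = sol$mu, o2_dark = acc$nonlight_consumption,
       o2_net = acc$net_export, state = state, solution = rep_sol,
       feasible = TRUE)
}

#' Growth and physiology over a light-intensity scan
#'
#' One constrained LP per grid point, recording growth, photon fluxes, net
#' O2 evolution and yield; the optimal intensity is located by grid argmax
#' refined by golden-section search in the bracketing interval.
#'
#' @param model a [metabolic_model()].
#' @param p a [light_parameters()].
#' @param constraints a [physiological_constraints()].
#' @param roles a [reaction_roles()].
#' @param I0_grid ascending red-light intensities (umol m^-2 s^-1).
#' @param Ib constant blue background intensity.
#' @param refine_opt refine the argmax by golden-section search.
#' @param parsimonious use parsimonious fluxes for O2 reporting (slower).
#' @return object of class `light_scan`: data.frame (`I0`, `mu`, `J_I`,
#'   `J_I_star`, `o2_net`, `yield`) with attributes `I0_opt` and `mu_opt`.
#' @export
light_scan <- function(model, p, constraints, roles, I0_grid, Ib = 0,
                       refine_opt = TRUE, parsimonious = TRUE) {
  if (is.unsorted(I0_grid)) stop("I0_grid must be sorted ascending")
  res <- lapply(I0_grid, function(I0) {
    sim <- simulate_condition(model, p, constraints, roles,
                              light_conditions(I0, Ib),
                              parsimonious = parsimonious)
    data.frame(I0 = I0, mu = sim$mu, J_I = sim$state$J_I,
               J_I_star = sim$state$J_I_star, o2_net = sim$o2_net,
               yield = if (sim$state$J_I > 0)
                 biomass_yield(sim$mu, sim$state$J_I) else NA_real_,
               feasible = sim$feasible)
  })
  tab <- do.call(rbind, res)
  mu_of <- function(I0) simulate_condition(model, p, constraints, roles,
                                           light_conditions(I0, Ib),
                                           parsimonious = FALSE)$mu
  k <- which.max(tab$mu)
  I0_opt <- tab$I0[k]
  mu_opt <- tab$mu[k]
  if (refine_opt && length(I0_grid) >= 3 && k > 1 && k < length(I0_grid)) {
    gs <- golden_section_max(mu_of, tab$I0[k - 1], tab$I0[k + 1])
    if (gs$value >= mu_opt) {
      I0_opt <- gs$argmax
      mu_opt <- gs$value
    }
  }
  structure(tab, I0_opt = I0_opt, mu_opt = mu_opt, class = c("light_scan",
                                                             class(tab)))
}

golden_section_max <- function(f, a, b, tol = 0.5, max_iter = 60) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  iter <- 0
  while (b - a > tol && iter < max_iter) {
    iter <- iter + 1
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    }
  }
  if (f1 >= f2) list(argmax = x1, value = f1) else list(argmax = x2, value = f2)
}

#' Extrapolated maximal growth rate
#'
#' The maximal capacity of light utilization bounds the growth rate at
#' `mu_max = Y_max K_L` (with `K_L` converted to mol photons gCDM^-1 h^-1);
#' the associated minimal division time is `ln 2 / mu_max`.
#'
#' @param K_L maximal capacity, mmol photons gCDM^-1 h^-1.
#' @param yield maximal biomass yield, gCDM per mol photons (> 0).
#' @return list `mu_max` (h^-1) and `division_time` (h).
#' @export
extrapolated_max_growth <- function(K_L, yield) {
  if (yield <= 0) stop("yield must be strictly positive")
  mu_max <- yield * K_L / 1000
  list(mu_max = mu_max, division_time = log(2) / mu_max)
}
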