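## A minimal, analytically solvable phototrophic network. It exposes every
## process class the physiological constraints touch -- photon-consuming
## electron transport (lumped PSII+PSI with an explicit PSII O2
## coefficient), FNR, thylakoid ATPase (3 ATP per full cycle), cyclic
## electron transport, RuBisCO carboxylase/oxygenase, Mehler-type O2 sinks,
## a terminal oxidase, NGAM, and a biomass drain -- while staying small
## enough that its optimum has a closed form.
##
## Energy bookkeeping of the default network, per unit flux:
##   PSET:   8 hv + 2 H2O + 4 Fd_ox + 9 H+(c) -> O2 + 4 Fd_red + 9 H+(u)
##   FNR:    2 Fd_red + NADP+ -> 2 Fd_ox + NADPH + H+(c)
##   ATPase: 9 H+(u) + 3 ADP + 3 Pi -> 3 ATP + 3 H2O + 6 H+(c)
##   CET:    2 hv + 3 H+(c) -> 3 H+(u)
##   RBC:    CO2 + 3 ATP + 2 NADPH + 2 H2O -> CH2O + 3 ADP + 3 Pi + 2 NADP+ + H+
## so linear electron transport supplies 3 ATP + 2 NADPH per 8 photons and
## 1 O2, cyclic transport 1 ATP per 2 photons, and one CH2O costs exactly
## 8 photons. A biomass drawing n_C CH2O and n_A ATP therefore costs
## 8 n_C + 2 n_A mmol photons per gCDM (360 for the defaults n_C = 40,
## n_A = 20).

#' Specification of the toy phototroph network
#'
#' @param n_C biomass carbohydrate demand, mmol CH2O per gCDM.
#' @param n_A biomass (growth-associated) ATP demand, mmol per gCDM.
#' @return object of class `toy_spec` with the derived closed-form photon
#'   cost (`photon_cost`, mmol photons per gCDM) and maximal yield
#'   (`max_yield`, gCDM per mol photons).
#' @export
toy_spec <- function(n_C = 40, n_A = 20) {
  if (n_C <= 0 || n_A < 0) stop("n_C must be positive and n_A non-negative")
  cost <- 8 * n_C + 2 * n_A
  structure(list(n_C = n_C, n_A = n_A,
                 photon_cost = cost, max_yield = 1000 / cost),
            class = "toy_spec")
}

#' Build the toy phototroph model
#'
#' Constructs the balanced toy network for a given [toy_spec()]. All
#' non-photon, non-biomass reactions are elementally balanced by
#' construction (verified at build time); photons are massless species. The
#' closed-form photon cost is attached as attribute `photon_cost`.
#'
#' @param spec a [toy_spec()].
#' @return a [metabolic_model()] with objective on the biomass drain.
#' @export
#' @examples
#' m <- toy_phototroph_model()
#' model_summary(m)
toy_phototroph_model <- function(spec = toy_spec()) {
  m <- metabolic_model("toy_phototroph",
                       compartments = c(e = "extracellular",
                                        c = "cytoplasm",
                                        u = "thylakoid lumen"))
  sp <- list(
    list("hv_e",     "e", NA),
    list("co2_e",    "e", "CO2"),
    list("o2_e",     "e", "O2"),
    list("hv_c",     "c", NA),
    list("co2_c",    "c", "CO2"),
    list("o2_c",     "c", "O2"),
    list("h2o_c",    "c", "H2O"),
    list("h_c",      "c", "H"),
    list("pi_c",     "c", "HO4P"),
    list("adp_c",    "c", "C10H12N5O10P2"),
    list("atp_c",    "c", "C10H12N5O13P3"),
    list("nadp_c",   "c", "C21H25N7O17P3"),
    list("nadph_c",  "c", "C21H26N7O17P3"),
    list("fdx_ox_c", "c", "Fd"),
    list("fdx_red_c","c", "FdH"),
    list("ch2o_c",   "c", "CH2O"),
    list("biomass_c","c", NA),
    list("h_u",      "u", "H"))
  for (s in sp) m <- add_metabolite(m, s[[1]], s[[2]], s[[3]])

  rxn <- function(m, id, s, lower = 0, upper = Inf) {
    add_reaction(m, id, s, lower = lower, upper = upper)
  }
  m <- rxn(m, "PSET", c(hv_c = -8, h2o_c = -2, fdx_ox_c = -4, h_c = -9,
                        o2_c = 1, fdx_red_c = 4, h_u = 9))
  m <- rxn(m, "FNR", c(fdx_red_c = -2, nadp_c = -1,
                       fdx_ox_c = 2, nadph_c = 1, h_c = 1))
  m <- rxn(m, "ATPase", c(h_u = -9, adp_c = -3, pi_c = -3,
                          atp_c = 3, h2o_c = 3, h_c = 6))
  m <- rxn(m, "CET", c(hv_c = -2, h_c = -3, h_u = 3))
  m <- rxn(m, "RBC", c(co2_c = -1, atp_c = -3, nadph_c = -2, h2o_c = -2,
                       ch2o_c = 1, adp_c = 3, pi_c = 3, nadp_c = 2, h_c = 1))
  m <- rxn(m, "RBO", c(ch2o_c = -1, o2_c = -1, co2_c = 1, h2o_c = 1))
  m <- rxn(m, "CYO", c(o2_c = -1, nadph_c = -2, h_c = -2,
                       nadp_c = 2, h2o_c = 2))
  mehler <- c(o2_c = -1, fdx_red_c = -4, fdx_ox_c = 4, h2o_c = 2)
  m <- rxn(m, "MEHLER", mehler)
  m <- rxn(m, "MEHLER_PSI", mehler)
  m <- rxn(m, "MEHLER_PSII", mehler)
  m <- rxn(m, "NGAM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1))
  m <- rxn(m, "BIOMASS", c(ch2o_c = -spec$n_C, atp_c = -spec$n_A,
                           h2o_c = -spec$n_A, adp_c = spec$n_A,
                           pi_c = spec$n_A, h_c = spec$n_A, biomass_c = 1))
  m <- rxn(m, "T_HV", c(hv_e = -1, hv_c = 1))
  m <- rxn(m, "T_CO2", c(co2_e = -1, co2_c = 1), lower = -Inf)
  m <- rxn(m, "T_O2", c(o2_c = -1, o2_e = 1), lower = -Inf)
  m <- rxn(m, "EX_hv", c(hv_e = -1), lower = -Inf, upper = 0)
  m <- rxn(m, "EX_co2", c(co2_e = -1), lower = -Inf)
  m <- rxn(m, "EX_o2", c(o2_e = -1), lower = -Inf)
  m <- rxn(m, "EX_h2o", c(h2o_c = -1), lower = -Inf)
  m <- rxn(m, "EX_h", c(h_c = -1), lower = -Inf)
  m <- rxn(m, "EX_biomass", c(biomass_c = -1))
  m <- set_objective(m, c(BIOMASS = 1))

  bal <- check_mass_balance(m)
  if (nrow(bal) > 0) {
    stop("toy network is not elementally balanced: ",
         paste(unique(bal$reaction), "(", bal$element, ")", collapse = ", "))
  }
  attr(m, "photon_cost") <- spec$photon_cost
  attr(m, "toy_spec") <- spec
  m
}

#' Reaction roles of the toy network
#'
#' The named reaction identifiers the physiological constraints and the
#' downstream O2/ATP accounting need, resolved for [toy_phototroph_model()].
#'
#' @return a [reaction_roles()] object.
#' @export
toy_reaction_roles <- function() {
  reaction_roles(
    photon_consuming = c("PSET", "CET"),
    psii = "PSET", psii_o2_coefficient = 1,
    rubisco_carboxylase = "RBC", rubisco_oxygenase = "RBO",
    mehler_like = "MEHLER", mehler_psi = "MEHLER_PSI",
    mehler_psii = "MEHLER_PSII",
    oxidase = "CYO", ngam = "NGAM", atpase = "ATPase", fnr = "FNR",
    o2_exchange = "EX_o2", carbon_exchanges = "EX_co2",
    biomass = "BIOMASS")
}

#' Specification of a synthetic growth-irradiance dataset
#'
#' @param I0 intensity grid, umol m^-2 s^-1 (strictly increasing).
#' @param Ib constant blue background intensity.
#' @param parameters true [light_parameters()] (including `ngam_min` and
#'   `oxidase_fraction` when the toy forward model is used).
#' @param sigma_mu,sigma_o2 Gaussian noise standard deviations for the
#'   growth rate (h^-1) and the dark O2 consumption.
#' @param seed random seed; a fixed seed makes generation byte-identical.
#' @return object of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(I0, Ib = 27.5, parameters,
                                   sigma_mu = 0, sigma_o2 = 0, seed = 1L) {
  if (is.unsorted(I0, strictly = TRUE)) stop("I0 grid must be strictly increasing")
  if (sigma_mu < 0 || sigma_o2 < 0) stop("noise standard deviations must be >= 0")
  structure(list(I0 = I0, Ib = Ib, parameters = parameters,
                 sigma_mu = sigma_mu, sigma_o2 = sigma_o2,
                 seed = as.integer(seed)),
            class = "synthetic_dataset_spec")
}

#' Generate a synthetic growth-irradiance dataset
#'
#' Rows of per-intensity observations (growth rate and dark O2 consumption)
#' produced either by the full toy-FBA forward pipeline at the true
#' parameters, or by the Haldane/Aiba closed form, plus zero-mean Gaussian
#' noise clipped at zero. Deterministic for a fixed seed.
#'
#' @param spec a [synthetic_dataset_spec()].
#' @param forward `"toy"` (full pipeline on [toy_phototroph_model()]) or
#'   `"haldane"` (closed form; `spec$parameters` must then be a named vector
#'   `c(mu_star=, K_A=, gamma=)`).
#' @param model optional model to use for the toy forward pipeline.
#' @param constraints [physiological_constraints()] for the toy pipeline;
#'   defaults to all-zero couplings plus the spec's `ngam_min` and
#'   `oxidase_fraction`.
#' @return a growth dataset `data.frame` with columns `I0`, `Ib`, `mu_obs`,
#'   `o2_dark_obs`.
#' @export
synthetic_growth_dataset <- function(spec, forward = c("toy", "haldane"),
                                     model = NULL, constraints = NULL) {
  forward <- match.arg(forward)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- length(spec$I0)
  if (forward == "haldane") {
    p <- spec$parameters
    mu <- haldane_growth(spec$I0, p[["mu_star"]], p[["K_A"]], p[["gamma"]])
    o2 <- rep(NA_real_, n)
  } else {
    if (is.null(model)) model <- toy_phototroph_model()
    p <- spec$parameters
    if (is.null(constraints)) {
      constraints <- physiological_constraints(
        rubisco_oxygenase_fraction = 0, mehler_like_fraction = 0,
        mehler_psi_fraction = 0, mehler_psii_fraction = 0,
        ngam_min = if (is.null(p$ngam_min)) 0 else p$ngam_min,
        terminal_oxidase_fraction = if (is.null(p$oxidase_fraction)) 0 else
          p$oxidase_fraction)
    }
    roles <- toy_reaction_roles()
    mu <- numeric(n); o2 <- numeric(n)
    for (i in seq_len(n)) {
      sim <- simulate_condition(model, p, constraints, roles,
                                light_conditions(spec$I0[i], spec$Ib))
      mu[i] <- sim$mu
      o2[i] <- sim$o2_dark
    }
  }
  mu_obs <- pmax(mu + stats::rnorm(n, 0, spec$sigma_mu), 0)
  o2_obs <- if (all(is.na(o2))) o2 else
    pmax(o2 + stats::rnorm(n, 0, spec$sigma_o2), 0)
  data.frame(I0 = spec$I0, Ib = spec$Ib, mu_obs = mu_obs, o2_dark_obs = o2_obs)
}

## save/restore the global RNG state so generators are side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read or write a growth-irradiance dataset
#'
#' Tab-separated text with a mandatory header. Recognized columns: `I0`,
#' `Ib`, `mu_obs`, `o2_dark_obs`, `o2_net_obs`, `protein_frac`,
#' `glycogen_frac`, `I_Z`, `rho_A`; `I0` and `mu_obs` are required.
#'
#' @param path file path.
#' @return `read_growth_dataset`: a `data.frame`.
#' @export
read_growth_dataset <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("I0", "mu_obs")
  if (!all(req %in% names(d))) {
    stop("growth dataset must have columns: ", paste(req, collapse = ", "))
  }
  if (is.unsorted(d$I0, strictly = TRUE)) {
    stop("I0 must be strictly increasing across rows")
  }
  if (any(d$mu_obs < 0, na.rm = TRUE)) stop("mu_obs must be non-negative")
  d
}

#' @rdname read_growth_dataset
#' @param data a growth dataset `data.frame`.
#' @export
write_growth_dataset <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
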