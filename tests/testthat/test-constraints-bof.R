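roles <- toy_reaction_roles()

test_that("photon cap and photodamage drain behave as light constraints", {
  m <- toy_phototroph_model()

  ## no utilizable photons: no growth on a photon-requiring network
  m0 <- apply_light_constraints(m, fixed_light_state(0, 0), roles)
  m0 <- apply_physiological_constraints(m0, zero_constraints(), roles)
  expect_equal(maximize_growth(m0)$mu, 0, tolerance = 1e-9)

  ## the cap binds at the optimum: photon use equals J_I*
  m1 <- apply_light_constraints(m, fixed_light_state(36, 0), roles)
  m1 <- apply_physiological_constraints(m1, zero_constraints(), roles)
  sol <- parsimonious_solution(m1, maximize_growth(m1)$mu)
  used <- 8 * sol$fluxes[["PSET"]] + 2 * sol$fluxes[["CET"]]
  expect_equal(used, 36, tolerance = 1e-4)

  ## LP homogeneity: doubling the cap doubles growth below saturation
  m2 <- apply_light_constraints(m, fixed_light_state(72, 0), roles)
  m2 <- apply_physiological_constraints(m2, zero_constraints(), roles)
  expect_equal(maximize_growth(m2)$mu, 2 * maximize_growth(m1)$mu,
               tolerance = 1e-9)

  ## photodamage: fixed ATP drain, reported separately from NGAM
  m3 <- apply_light_constraints(m, fixed_light_state(36, 3), roles)
  m3 <- apply_physiological_constraints(m3, zero_constraints(), roles)
  sol3 <- maximize_growth(m3)
  expect_equal(sol3$fluxes[["PHOTODAMAGE"]], 3)
  expect_equal(sol3$mu, toy_oracle_mu(36, v_D = 3), tolerance = 1e-9)
  ## photodamage can only reduce growth
  expect_lt(sol3$mu, maximize_growth(m1)$mu)

  ## re-applying with a new state replaces, not stacks, the cap
  m4 <- apply_light_constraints(m3, fixed_light_state(72, 0), roles)
  expect_equal(sum(vapply(m4$couplings, function(x) x$name == "photon_cap",
                          logical(1))), 1)
})

test_that("ratio couplings enforce the configured fractions at the optimum", {
  m <- toy_phototroph_model()
  m <- apply_light_constraints(m, fixed_light_state(36, 0), roles)

  ## RuBisCO 97/3 split of total flux
  mc <- apply_physiological_constraints(
    m, physiological_constraints(ngam_min = 0, mehler_like_fraction = 0,
                                 mehler_psi_fraction = 0,
                                 mehler_psii_fraction = 0,
                                 terminal_oxidase_fraction = 0), roles)
  sol <- parsimonious_solution(mc, maximize_growth(mc)$mu)
  expect_equal(sol$fluxes[["RBO"]] /
                 (sol$fluxes[["RBO"]] + sol$fluxes[["RBC"]]), 0.03,
               tolerance = 1e-6)

  ## Mehler-like at 10% of PSII O2 (equality mode)
  mm <- apply_physiological_constraints(
    m, physiological_constraints(rubisco_oxygenase_fraction = 0,
                                 ngam_min = 0, mehler_like_fraction = 0.10,
                                 mehler_psi_fraction = 0,
                                 mehler_psii_fraction = 0,
                                 terminal_oxidase_fraction = 0), roles)
  solm <- parsimonious_solution(mm, maximize_growth(mm)$mu)
  expect_equal(solm$fluxes[["MEHLER"]], 0.10 * solm$fluxes[["PSET"]],
               tolerance = 1e-6)

  ## all couplings and NGAM at zero: identical to the unconstrained optimum
  m_free <- apply_light_constraints(toy_phototroph_model(),
                                    fixed_light_state(36, 0), roles)
  mz <- apply_physiological_constraints(m_free, zero_constraints(), roles)
  expect_equal(maximize_growth(mz)$mu, maximize_growth(m_free)$mu,
               tolerance = 1e-9)

  ## coupling rows have zero residual at the reported solution
  for (cc in mm$couplings) {
    resid <- sum(cc$coefs * solm$fluxes[names(cc$coefs)])
    if (cc$sense == "=") expect_equal(resid, cc$rhs, tolerance = 1e-6)
    if (cc$sense == "<=") expect_lte(resid, cc$rhs + 1e-6)
    if (cc$sense == ">=") expect_gte(resid, cc$rhs - 1e-6)
  }

  ## a nonzero fraction for an absent role is a configuration error
  roles_no_mehler <- roles
  roles_no_mehler$mehler_like <- NULL
  expect_error(apply_physiological_constraints(
    m, physiological_constraints(), roles_no_mehler), "mehler_like")
})

test_that("growth is monotone non-increasing in maintenance and couplings", {
  m <- toy_phototroph_model()
  m <- apply_light_constraints(m, fixed_light_state(36, 0), roles)
  mu_at <- function(ngam = 0, ox = 0, mehler = 0) {
    mc <- apply_physiological_constraints(
      m, physiological_constraints(rubisco_oxygenase_fraction = 0,
                                   ngam_min = ngam,
                                   mehler_like_fraction = mehler,
                                   mehler_psi_fraction = 0,
                                   mehler_psii_fraction = 0,
                                   terminal_oxidase_fraction = ox), roles)
    maximize_growth(mc)$mu
  }
  ngam_sweep <- vapply(c(0, 1, 2, 4, 8), function(x) mu_at(ngam = x),
                       numeric(1))
  expect_true(all(diff(ngam_sweep) < 0))
  ox_sweep <- vapply(c(0, 0.05, 0.1, 0.2), function(x) mu_at(ox = x),
                     numeric(1))
  expect_true(all(diff(ox_sweep) < 0))
  mehler_sweep <- vapply(c(0, 0.06, 0.1), function(x) mu_at(mehler = x),
                         numeric(1))
  expect_true(all(diff(mehler_sweep) < 0))
})

test_that("biomass composition building preserves normalization", {
  ref <- biomass_composition(c(protein = 0.5, glycogen = 0.1, lipid = 0.25,
                               rna = 0.15), gam = 30)
  ## identity when the measured fractions equal the reference
  same <- build_biomass_composition(0.5, 0.1, ref)
  expect_equal(same$fractions, ref$fractions)
  expect_equal(same$gam, ref$gam)

  ## the condition measured at high light: 23% protein, 20% glycogen
  b <- build_biomass_composition(0.23, 0.20, ref)
  expect_equal(sum(b$fractions), 1)
  expect_equal(b$fractions[["protein"]], 0.23)
  expect_equal(b$fractions[["glycogen"]], 0.20)
  ## other classes keep their mutual ratios
  expect_equal(b$fractions[["lipid"]] / b$fractions[["rna"]],
               ref$fractions[["lipid"]] / ref$fractions[["rna"]])
  ## GAM scales with protein by default, constant on request
  expect_equal(b$gam, 30 * 0.23 / 0.5)
  expect_equal(build_biomass_composition(0.23, 0.2, ref, "constant")$gam, 30)

  set.seed(3)
  for (i in 1:20) {
    p <- stats::runif(1, 0, 0.6); g <- stats::runif(1, 0, 1 - p - 0.05)
    out <- build_biomass_composition(p, g, ref)
    expect_equal(sum(out$fractions), 1, tolerance = 1e-9)
  }
  expect_error(build_biomass_composition(0.7, 0.4, ref), "sum")
})

test_that("installing a composition rescales the biomass drain coherently", {
  m <- toy_phototroph_model()
  class_map <- c(ch2o_c = "glycogen")
  ref <- biomass_composition_from_model(m, class_map, roles)
  expect_equal(ref$fractions, c(glycogen = 1))
  expect_equal(ref$gam, 20)

  ## round trip: re-applying the reference reproduces the coefficients
  m2 <- set_biomass_objective(m, ref, class_map, roles)
  s1 <- m$stoichiometry$BIOMASS
  s2 <- m2$stoichiometry$BIOMASS
  expect_equal(s2[sort(names(s2))], s1[sort(names(s1))], tolerance = 1e-9)

  ## doubling the ATP coefficient changes the closed-form photon cost
  ## from 8 n_C + 2 n_A to 8 n_C + 4 n_A
  comp2 <- ref
  comp2$gam <- 40
  m3 <- set_biomass_objective(m, comp2, class_map, roles)
  m3 <- apply_light_constraints(m3, fixed_light_state(36, 0), roles)
  m3 <- apply_physiological_constraints(m3, zero_constraints(), roles)
  expect_equal(maximize_growth(m3)$mu, 36 / (8 * 40 + 2 * 40),
               tolerance = 1e-9)

  ## an unmapped biomass component is reported by name
  expect_error(set_biomass_objective(m, ref, c(), roles), "ch2o_c")
})
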