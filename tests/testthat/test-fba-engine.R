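roles <- toy_reaction_roles()

constrained_toy <- function(J_star, v_D = 0, ngam = 0, oxidase = 0,
                            spec = toy_spec()) {
  m <- toy_phototroph_model(spec)
  m <- apply_light_constraints(m, fixed_light_state(J_star, v_D), roles)
  apply_physiological_constraints(m, zero_constraints(ngam, oxidase), roles)
}

test_that("toy optima match the hand-derived closed form", {
  expect_equal(maximize_growth(constrained_toy(36))$mu, 0.100,
               tolerance = 1e-6)
  expect_equal(maximize_growth(constrained_toy(36, ngam = 2))$mu,
               toy_oracle_mu(36, ngam = 2), tolerance = 1e-6)  # 0.08889
  expect_equal(maximize_growth(constrained_toy(0))$mu, 0, tolerance = 1e-9)

  ## random toy specifications: optimum equals the stored photon cost
  set.seed(21)
  for (i in 1:20) {
    spec <- toy_spec(n_C = sample(10:80, 1), n_A = sample(0:50, 1))
    J <- stats::runif(1, 5, 100)
    m <- constrained_toy(J, spec = spec)
    expect_equal(maximize_growth(m)$mu, J / attr(m, "photon_cost"),
                 tolerance = 1e-6)
  }
})

test_that("steady state holds at every reported optimum", {
  m <- constrained_toy(36, v_D = 1, ngam = 1, oxidase = 0.05)
  sol <- maximize_growth(m)
  ps <- parsimonious_solution(m, sol$mu)
  N <- stoichiometric_matrix(m)
  expect_lt(max(abs(N %*% sol$fluxes)), 1e-6)
  expect_lt(max(abs(N %*% ps$fluxes)), 1e-6)
  expect_true(all(ps$fluxes >= m$reactions$lower - 1e-7))
  expect_true(all(ps$fluxes <= m$reactions$upper + 1e-7))
})

test_that("parsimonious selection is idempotent and objective-preserving", {
  m <- constrained_toy(36, ngam = 1)
  mu <- maximize_growth(m)$mu
  p1 <- parsimonious_solution(m, mu)
  p2 <- parsimonious_solution(m, mu)
  expect_equal(p1$fluxes, p2$fluxes, tolerance = 1e-8)
  expect_equal(p1$mu, mu)
  ## the hand-derived flux vector at the unique toy optimum
  want <- toy_oracle_fluxes(toy_oracle_mu(36, ngam = 1), ngam = 1)
  for (r in c("RBC", "PSET", "CET", "FNR", "ATPase")) {
    expect_equal(p1$fluxes[[r]], want[[r]], tolerance = 1e-4, info = r)
  }
})

test_that("overall stoichiometry, PQ and yield match the toy bookkeeping", {
  m <- constrained_toy(36)
  sol <- parsimonious_solution(m, maximize_growth(m)$mu)
  o <- overall_stoichiometry(sol, m, products = c("EX_o2", "EX_biomass"))
  per <- stats::setNames(o$per_gcdm, o$reaction)
  expect_equal(per[["EX_hv"]], -360, tolerance = 1e-6)
  expect_equal(per[["EX_co2"]], -40, tolerance = 1e-6)
  expect_equal(per[["EX_o2"]], 40, tolerance = 1e-6)
  expect_equal(nrow(attr(o, "byproducts")), 0)

  expect_equal(photosynthetic_quotient(sol, roles), 1, tolerance = 1e-6)
  ## scaling all fluxes leaves PQ unchanged
  scaled <- sol; scaled$fluxes <- 3 * sol$fluxes
  expect_equal(photosynthetic_quotient(scaled, roles),
               photosynthetic_quotient(sol, roles))

  expect_equal(biomass_yield(sol$mu, 36), 1000 / 360, tolerance = 1e-6)
  expect_error(biomass_yield(0.1, 0), "positive")
  zero <- sol; zero$mu <- 0
  expect_error(overall_stoichiometry(zero, m), "positive growth")
})

test_that("O2 accounting conserves PSII production", {
  ## zero oxidase/Mehler: everything produced is exported
  m <- constrained_toy(36)
  sol <- parsimonious_solution(m, maximize_growth(m)$mu)
  acc <- o2_accounting(sol, roles)
  expect_equal(acc$nonlight_consumption, 0, tolerance = 1e-6)
  expect_equal(acc$net_export, acc$psii_o2, tolerance = 1e-6)

  ## oxidase fraction f: non-light consumption is exactly f * PSII O2
  f <- 0.08
  mf <- constrained_toy(36, oxidase = f)
  solf <- parsimonious_solution(mf, maximize_growth(mf)$mu)
  accf <- o2_accounting(solf, roles)
  expect_equal(accf$nonlight_consumption, f * accf$psii_o2,
               tolerance = 1e-6)

  ## identity psii = export + mehler + nonlight on any optimal solution
  m2 <- toy_phototroph_model()
  m2 <- apply_light_constraints(m2, fixed_light_state(36, 0.5), roles)
  m2 <- apply_physiological_constraints(m2, physiological_constraints(),
                                        roles)
  sol2 <- parsimonious_solution(m2, maximize_growth(m2)$mu)
  acc2 <- o2_accounting(sol2, roles)
  expect_equal(acc2$psii_o2,
               acc2$net_export + acc2$mehler_sum + acc2$nonlight_consumption)
  expect_gt(acc2$mehler_sum, 0)
})

test_that("ATP/NADPH ratio follows the energy budget of the toy chain", {
  ## pure linear-electron-transport regime (no biomass ATP, no NGAM):
  ## 3 ATP per 2 NADPH, zero variability width
  m0 <- constrained_toy(36, spec = toy_spec(n_A = 0))
  r0 <- atp_nadph_ratio(m0, roles)
  expect_equal(r0$ratio_min, 1.5, tolerance = 1e-4)
  expect_equal(r0$ratio_max, 1.5, tolerance = 1e-4)
  expect_false(r0$unbounded)

  ## default biomass ATP demand: (3 n_C + n_A) / (2 n_C) = 1.75
  m1 <- constrained_toy(36)
  r1 <- atp_nadph_ratio(m1, roles)
  expect_equal(r1$ratio_min, 1.75, tolerance = 1e-4)

  ## extra ATP demand met by the cyclic route raises the ratio
  m2 <- constrained_toy(36, ngam = 2)
  r2 <- atp_nadph_ratio(m2, roles)
  expect_gt(r2$ratio_min, r1$ratio_min)
  expect_lte(r2$ratio_min, r2$ratio_max + 1e-9)
})

test_that("light scans locate the growth optimum and degrade to zero", {
  p <- light_parameters(0.2, 0.5, 80, 0.05)
  cstr <- zero_constraints(ngam = 1, oxidase = 0.05)
  grid <- seq(0, 1210, length.out = 25)
  sc <- light_scan(toy_phototroph_model(), p, cstr, roles, grid, Ib = 27.5,
                   parsimonious = FALSE)
  ## closed form: every grid point matches the oracle
  for (i in seq_len(nrow(sc))) {
    want <- toy_oracle_condition(sc$I0[i], 27.5, p, ngam = 1, oxidase = 0.05)
    expect_equal(sc$mu[i], want$mu, tolerance = 1e-6)
  }
  ## interior optimum: analytic argmax of the closed form
  oracle_mu <- function(I0) toy_oracle_condition(I0, 27.5, p, ngam = 1,
                                                 oxidase = 0.05)$mu
  I_fine <- seq(0, 1210, by = 0.25)
  I_best <- I_fine[which.max(vapply(I_fine, oracle_mu, numeric(1)))]
  expect_equal(attr(sc, "I0_opt"), I_best, tolerance = 2)
  expect_equal(attr(sc, "mu_opt"), oracle_mu(I_best), tolerance = 1e-5)

  ## without photoinhibition the scan is monotone non-decreasing
  p0 <- light_parameters(0.2, 0.5, 80, 0)
  sc0 <- light_scan(toy_phototroph_model(), p0, cstr, roles,
                    seq(0, 1210, length.out = 15), Ib = 27.5,
                    refine_opt = FALSE, parsimonious = FALSE)
  expect_true(all(diff(sc0$mu) > -1e-9))

  ## linear regime contract: no saturation, damage or maintenance gives
  ## mu = Y_max * J_I* exactly
  p_lin <- light_parameters(0.2, 0, Inf, 0)
  sc_lin <- light_scan(toy_phototroph_model(), p_lin, zero_constraints(),
                       roles, c(10, 50, 100), refine_opt = FALSE,
                       parsimonious = FALSE)
  expect_equal(sc_lin$mu, sc_lin$J_I_star / 360, tolerance = 1e-9)
})

test_that("growth is concave and non-decreasing in the photon cap", {
  caps <- seq(2, 80, length.out = 12)
  mu <- vapply(caps, function(J) {
    maximize_growth(constrained_toy(J, ngam = 1))$mu
  }, numeric(1))
  expect_true(all(diff(mu) > -1e-9))
  slopes <- diff(mu) / diff(caps)
  expect_true(all(diff(slopes) < 1e-8))
})

test_that("extrapolated maximal growth follows mu_max = Y_max K_L", {
  out <- extrapolated_max_growth(119.07, 1000 / 360)
  expect_equal(out$mu_max, 119.07 / 360)
  expect_equal(out$division_time, log(2) / out$mu_max)
  expect_equal(extrapolated_max_growth(2 * 119.07, 1000 / 360)$mu_max,
               2 * out$mu_max)
  expect_error(extrapolated_max_growth(100, 0), "positive")
})

test_that("infeasible and unbounded models are reported, not zeroed", {
  m <- toy_phototroph_model()
  ## force an infeasible bound pattern: NGAM above the photon-capped
  ## ATP supply
  m1 <- apply_light_constraints(m, fixed_light_state(1, 0), roles)
  m1 <- set_bounds(m1, "NGAM", lower = 100)
  expect_identical(maximize_growth(m1)$status, "infeasible")
  ## no photon cap at all: growth is unbounded
  expect_identical(maximize_growth(m)$status, "unbounded")
})
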