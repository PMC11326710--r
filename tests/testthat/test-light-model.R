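p_ref <- light_parameters(0.13, 0.66, 119.07, 0.07)

test_that("photon uptake composes red and weighted blue light", {
  l <- light_conditions(660, 27.5)
  expect_equal(photon_uptake_rate(l, p_ref),
               3.6 * 0.13 * (660 + 0.66 * 27.5))  # 317.3742
  expect_equal(photon_uptake_rate(l, light_parameters(0, 0.66, 100, 0)), 0)
  ## no blue background reduces to plain proportional absorption
  expect_equal(photon_uptake_rate(light_conditions(660), p_ref),
               3.6 * 0.13 * 660)
  expect_error(light_conditions(-1), "non-negative")
})

test_that("quantum yield and effective uptake follow the saturating form", {
  expect_equal(quantum_yield(0, 119.07), 1)
  expect_equal(quantum_yield(119.07, 119.07), 0.5)
  J <- 3.6 * 0.13 * (660 + 0.66 * 27.5)
  expect_equal(quantum_yield(J, 119.07), 119.07 / (119.07 + J))
  expect_equal(effective_uptake(J, 119.07), 119.07 * J / (119.07 + J))
  expect_equal(effective_uptake(119.07, 119.07), 119.07 / 2)
  ## saturation: within 1% of K_L at J = 100 K_L
  expect_equal(effective_uptake(100 * 119.07, 119.07), 119.07,
               tolerance = 0.01)
  expect_error(quantum_yield(1, 0), "positive")
})

test_that("eta is strictly decreasing, J_I* strictly increasing and capped", {
  set.seed(11)
  for (i in 1:25) {
    K_L <- stats::runif(1, 10, 500)
    J <- sort(stats::runif(50, 0, 2000))
    eta <- quantum_yield(J, K_L)
    Js <- effective_uptake(J, K_L)
    expect_true(all(diff(eta) < 0))
    expect_true(all(diff(Js) > 0))
    expect_true(all(Js <= pmin(J, K_L) + 1e-12))
    expect_equal(Js, eta * J)
  }
})

test_that("photodamage demand is proportional to absorbed photons", {
  J <- 3.6 * 0.13 * (660 + 0.66 * 27.5)
  expect_equal(photodamage_atp_demand(J, 0.07), 0.07 * J)  # 22.216
  expect_equal(photodamage_atp_demand(J, 0), 0)
  expect_equal(photodamage_atp_demand(2 * J, 0.07),
               2 * photodamage_atp_demand(J, 0.07))
  expect_error(photodamage_atp_demand(-1, 0.1), "non-negative")
})

test_that("compute_light_state composes the four quantities consistently", {
  s <- compute_light_state(light_conditions(660, 27.5), p_ref)
  expect_equal(s$J_I, 317.3742)
  expect_equal(s$eta, 119.07 / (119.07 + 317.3742))
  expect_equal(s$J_I_star, s$eta * s$J_I)
  expect_equal(s$v_D, 0.07 * 317.3742)

  s0 <- compute_light_state(light_conditions(0, 0), p_ref)
  expect_equal(unlist(s0[c("J_I", "eta", "J_I_star", "v_D")]),
               c(J_I = 0, eta = 1, J_I_star = 0, v_D = 0))

  set.seed(4)
  for (i in 1:100) {
    p <- light_parameters(stats::runif(1, 0.01, 1), stats::runif(1, 0, 2),
                          stats::runif(1, 10, 400), stats::runif(1, 0, 0.2))
    s <- compute_light_state(light_conditions(stats::runif(1, 0, 1500),
                                              stats::runif(1, 0, 50)), p)
    expect_equal(s$J_I_star, s$eta * s$J_I)
    expect_true(s$J_I_star <= min(s$J_I, p$K_L) + 1e-12)
  }
})

test_that("Haldane growth covers Monod as the gamma = 0 special case", {
  expect_equal(haldane_growth(0, 0.12, 200, 0.1), 0)
  expect_equal(haldane_growth(200, 0.12, 200, 0), 0.06)
  I0 <- seq(0, 2000, by = 50)
  expect_equal(haldane_growth(I0, 0.2, 150, 0), 0.2 * I0 / (150 + I0))
  expect_error(haldane_growth(10, 0.1, 0), "positive")
})

test_that("Haldane fit recovers generating parameters", {
  I0 <- c(25, 50, 100, 200, 400, 700, 1100)
  mu <- haldane_growth(I0, 0.12, 200, 0.1)
  fit <- fit_haldane(I0, mu)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(0.12, 200, 0.1), tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)

  ## all-zero observations drive mu_star to zero
  fit0 <- fit_haldane(I0, rep(0, length(I0)))
  expect_lt(coef(fit0)[["mu_star"]], 1e-6)

  ## noisy data: the three parameters are strongly correlated (sloppy), so
  ## the identifiable object is the fitted curve -- recovered within 10%
  ## of the true curve's maximum
  set.seed(1)
  I0_n <- rep(c(25, 50, 100, 150, 200, 300, 450, 600, 800, 1100), each = 2)
  mu_true <- haldane_growth(I0_n, 0.12, 200, 0.1)
  mu_n <- pmax(mu_true + stats::rnorm(length(I0_n), 0, 0.005), 0)
  fitn <- fit_haldane(I0_n, mu_n)
  grid <- seq(25, 1100, by = 25)
  truth <- haldane_growth(grid, 0.12, 200, 0.1)
  expect_lt(max(abs(predict(fitn, grid) - truth)), 0.1 * max(truth))

  expect_error(fit_haldane(c(10, 20), c(0.1, 0.2)), "at least 4")
})

test_that("Monod curve equals Y_max * eta(J_I) * J_I under the substitution", {
  mu_star <- 0.2; K_A <- 100; alpha <- 0.5
  eq <- monod_equivalence(mu_star, K_A, alpha)
  p <- light_parameters(alpha, 0, eq$K_L, 0)
  I0 <- seq(0, 2000, length.out = 101)
  J <- photon_uptake_rate(light_conditions(I0), p)
  lhs <- eq$Y_max * quantum_yield(J, eq$K_L) * J
  expect_equal(lhs, haldane_growth(I0, mu_star, K_A, 0), tolerance = 1e-12)
  expect_equal(eq$K_L * eq$Y_max, mu_star)
  eq2 <- monod_equivalence(mu_star, K_A, 2 * alpha)
  expect_equal(eq2$K_L, 2 * eq$K_L)
  expect_equal(eq2$Y_max, eq$Y_max / 2)
})

test_that("2-state relaxation flux equals the effective uptake", {
  expect_equal(two_state_activated(0, 1, 2, 3), 0)
  ## sigma I0 = k2 gives half saturation
  expect_equal(two_state_activated(5, 2, 10, 4), 2)
  set.seed(9)
  for (i in 1:30) {
    sigma <- stats::runif(1, 0.1, 5); k2 <- stats::runif(1, 1, 50)
    P_T <- stats::runif(1, 0.1, 10); I0 <- stats::runif(1, 0, 2000)
    K_L <- k2 * P_T
    J_I <- sigma * I0 * P_T
    v2 <- k2 * two_state_activated(I0, sigma, k2, P_T)
    expect_equal(v2, effective_uptake(J_I, K_L), tolerance = 1e-12)
  }
})

test_that("Lambert-Beer attenuation integrates to the transmitted-light form", {
  expect_equal(lambert_beer_intensity(500, 0.1, 10, 0), 500)
  expect_equal(lambert_beer_intensity(500, log(2), 1, 1), 250)
  ## depth-integrated absorption per biomass equals (I0 - I_Z) / rho_A
  I0 <- 660; eps <- 0.05; rho_V <- 120; Z <- 0.024
  absorbed <- stats::integrate(function(z) {
    eps * rho_V * lambert_beer_intensity(I0, eps, rho_V, z)
  }, 0, Z)$value
  I_Z <- lambert_beer_intensity(I0, eps, rho_V, Z)
  expect_equal(absorbed / (rho_V * Z), (I0 - I_Z) / (rho_V * Z),
               tolerance = 1e-8)
  expect_error(lambert_beer_intensity(10, 1, 1, -1), "non-negative")
})

test_that("light parameters round-trip through the key-value file format", {
  p <- light_parameters(0.13, 0.66, 119.07, 0.07, ngam_min = 1.45,
                        oxidase_fraction = 0.091)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_light_parameters(p, path)
  p2 <- read_light_parameters(path)
  expect_equal(p2, p)
  writeLines("alpha\t0.1", path)
  expect_error(read_light_parameters(path), "must define")
})

test_that("photobioreactor absorption rate matches the transmitted-light formula", {
  expect_equal(pbr_absorption_rate(660, 66, 10, blue_weight = 0),
               3.6 * (660 - 66) / 10)  # 213.84
  expect_equal(pbr_absorption_rate(660, 660, 10, blue_weight = 0), 0)
  w0 <- pbr_absorption_rate(660, 66, 10, blue_weight = 0, Ib = 27.5)
  w1 <- pbr_absorption_rate(660, 66, 10, blue_weight = 1, Ib = 27.5)
  expect_gte(w1, w0)
  expect_equal(w1 - w0, 3.6 * 27.5 * (1 - 66 / 660) / 10)
  expect_error(pbr_absorption_rate(660, 66, 0), "positive")
  expect_error(pbr_absorption_rate(10, 20, 1), "exceed")
})
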