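## Closed-form description of light absorption and utilization:
## photon uptake, saturating quantum yield, photodamage ATP demand,
## Haldane/Aiba growth, Lambert-Beer attenuation, and the equivalent
## 2-state photosynthetic-unit formulation.

## Intensities are in umol photons m^-2 s^-1; all specific fluxes in
## mmol gCDM^-1 h^-1. The factor 3.6 converts umol gCDM^-1 s^-1 to
## mmol gCDM^-1 h^-1 and is applied exactly once, when photons are absorbed.
HOUR_PER_SEC_MMOL <- 3.6

#' Light conditions
#'
#' Incident red light intensity `I0` plus a constant blue background `Ib`,
#' both in umol photons m^-2 s^-1.
#'
#' @param I0 incident red light intensity (>= 0).
#' @param Ib constant blue background intensity (>= 0).
#' @return object of class `light_conditions`.
#' @export
#' @examples
#' light_conditions(660, 27.5)
light_conditions <- function(I0, Ib = 0) {
  stopifnot(is.numeric(I0), is.numeric(Ib))
  if (any(I0 < 0) || any(Ib < 0)) {
    stop("light intensities must be non-negative")
  }
  structure(list(I0 = I0, Ib = Ib), class = "light_conditions")
}

#' Light absorption and utilization parameters
#'
#' The four constants of the light model: `alpha`, the effective absorption
#' cross-section (m^2 gCDM^-1); `alpha_b`, the dimensionless weight of blue
#' relative to red photons; `K_L`, the maximal capacity of light utilization
#' (mmol photons gCDM^-1 h^-1, `Inf` allowed for a strictly linear regime);
#' and `k_d`, the dimensionless photodamage proportionality (mmol ATP per
#' mmol absorbed photons). Optionally carries the maintenance minima
#' `ngam_min` (mmol ATP gCDM^-1 h^-1) and `oxidase_fraction` used when the
#' parameters come from a fit.
#'
#' @param alpha,alpha_b,K_L,k_d light model constants, all >= 0.
#' @param ngam_min,oxidase_fraction optional maintenance minima.
#' @return object of class `light_parameters`.
#' @export
light_parameters <- function(alpha, alpha_b = 0, K_L = Inf, k_d = 0,
                             ngam_min = NULL, oxidase_fraction = NULL) {
  vals <- c(alpha = alpha, alpha_b = alpha_b, K_L = K_L, k_d = k_d)
  if (any(!is.finite(vals[c("alpha", "alpha_b", "k_d")])) || any(vals < 0)) {
    stop("light parameters must be non-negative (K_L may be Inf)")
  }
  if (K_L <= 0) stop("K_L must be strictly positive")
  structure(list(alpha = alpha, alpha_b = alpha_b, K_L = K_L, k_d = k_d,
                 ngam_min = ngam_min, oxidase_fraction = oxidase_fraction),
            class = "light_parameters")
}

#' @export
print.light_parameters <- function(x, ...) {
  cat("Light model parameters:\n")
  cat(sprintf("  alpha   = %g m^2/gCDM\n", x$alpha))
  cat(sprintf("  alpha_b = %g (blue weight)\n", x$alpha_b))
  cat(sprintf("  K_L     = %g mmol photons/gCDM/h\n", x$K_L))
  cat(sprintf("  k_d     = %g (photodamage)\n", x$k_d))
  if (!is.null(x$ngam_min))
    cat(sprintf("  NGAM    = %g mmol ATP/gCDM/h\n", x$ngam_min))
  if (!is.null(x$oxidase_fraction))
    cat(sprintf("  oxidase = %g of PSII O2\n", x$oxidase_fraction))
  invisible(x)
}

#' Read or write light parameters as a flat key-value file
#'
#' Tab-separated `key<TAB>value` text with keys `alpha`, `alpha_b`, `K_L`,
#' `k_d` and optionally `ngam_min`, `oxidase_fraction`.
#'
#' @param path file path.
#' @return `read_light_parameters`: a [light_parameters()] object.
#' @export
read_light_parameters <- function(path) {
  kv <- utils::read.delim(path, header = FALSE,
                          col.names = c("key", "value"))
  vals <- stats::setNames(as.numeric(kv$value), kv$key)
  need <- c("alpha", "alpha_b", "K_L", "k_d")
  if (!all(need %in% names(vals))) {
    stop("parameter file must define: ", paste(need, collapse = ", "))
  }
  light_parameters(vals[["alpha"]], vals[["alpha_b"]], vals[["K_L"]],
                   vals[["k_d"]],
                   ngam_min = if ("ngam_min" %in% names(vals))
                     vals[["ngam_min"]] else NULL,
                   oxidase_fraction = if ("oxidase_fraction" %in% names(vals))
                     vals[["oxidase_fraction"]] else NULL)
}

#' @rdname read_light_parameters
#' @param p a [light_parameters()] object.
#' @export
write_light_parameters <- function(p, path) {
  vals <- c(alpha = p$alpha, alpha_b = p$alpha_b, K_L = p$K_L, k_d = p$k_d)
  if (!is.null(p$ngam_min)) vals[["ngam_min"]] <- p$ngam_min
  if (!is.null(p$oxidase_fraction)) {
    vals[["oxidase_fraction"]] <- p$oxidase_fraction
  }
  utils::write.table(data.frame(key = names(vals), value = unname(vals)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Rate of photon absorption
#'
#' `J_I = 3.6 alpha (I0 + alpha_b Ib)` in mmol photons gCDM^-1 h^-1. Blue
#' background photons contribute as weighted red photons; with `Ib = 0` this
#' is plain proportional absorption `J_I = 3.6 alpha I0`.
#'
#' @param light a [light_conditions()] object.
#' @param p a [light_parameters()] object.
#' @return absorbed photon flux, mmol photons gCDM^-1 h^-1.
#' @export
photon_uptake_rate <- function(light, p) {
  HOUR_PER_SEC_MMOL * p$alpha * (light$I0 + p$alpha_b * light$Ib)
}

#' Quantum yield of light utilization
#'
#' The fraction of absorbed photons that is productively utilized,
#' `eta = K_L / (K_L + J_I)`, a strictly decreasing function of the
#' absorption rate with `eta(0) = 1` and `eta(K_L) = 1/2`.
#'
#' @param J_I absorbed photon flux (mmol gCDM^-1 h^-1, >= 0).
#' @param K_L maximal capacity of light utilization (> 0; `Inf` gives 1).
#' @return dimensionless yield in (0, 1].
#' @export
quantum_yield <- function(J_I, K_L) {
  if (any(J_I < 0)) stop("J_I must be non-negative")
  if (any(K_L <= 0)) stop("K_L must be strictly positive")
  ## recycle across J_I; an infinite capacity gives a yield of 1
  ifelse(is.infinite(K_L + 0 * J_I), 1, K_L / (K_L + J_I))
}

#' Effective (utilizable) photon flux
#'
#' `J_I* = eta(J_I) J_I = K_L J_I / (K_L + J_I)`: monotone increasing in
#' `J_I` and saturating at the capacity `K_L`.
#'
#' @inheritParams quantum_yield
#' @return effective photon flux, mmol gCDM^-1 h^-1.
#' @export
effective_uptake <- function(J_I, K_L) {
  quantum_yield(J_I, K_L) * J_I
}

#' Photodamage ATP demand
#'
#' The light-proportional ATP drain for repair of photodamage,
#' `v_D = k_d J_I`, driven by the absorbed (not the utilized) photon flux.
#'
#' @param J_I absorbed photon flux (>= 0).
#' @param k_d dimensionless proportionality (>= 0).
#' @return ATP demand, mmol gCDM^-1 h^-1.
#' @export
photodamage_atp_demand <- function(J_I, k_d) {
  if (any(J_I < 0) || any(k_d < 0)) stop("J_I and k_d must be non-negative")
  k_d * J_I
}

#' Per-condition light state
#'
#' Composes absorption, quantum yield, effective uptake and photodamage into
#' one record: `J_I`, `eta`, `J_I_star` and `v_D`.
#'
#' @inheritParams photon_uptake_rate
#' @return object of class `light_state` with fields `J_I`, `eta`,
#'   `J_I_star`, `v_D`.
#' @export
#' @examples
#' p <- light_parameters(0.13, 0.66, 119.07, 0.07)
#' compute_light_state(light_conditions(660, 27.5), p)
compute_light_state <- function(light, p) {
  J_I <- photon_uptake_rate(light, p)
  eta <- quantum_yield(J_I, p$K_L)
  structure(list(J_I = J_I, eta = eta,
                 J_I_star = eta * J_I,
                 v_D = photodamage_atp_demand(J_I, p$k_d)),
            class = "light_state")
}

#' @export
print.light_state <- function(x, ...) {
  cat(sprintf("Light state: J_I = %.4g, eta = %.4g, J_I* = %.4g, v_D = %.4g\n",
              x$J_I, x$eta, x$J_I_star, x$v_D))
  invisible(x)
}

#' Haldane/Aiba growth-irradiance curve
#'
#' The phenomenological description of light-limited growth with
#' photoinhibition, `mu(I0) = mu_star I0 / (K_A + I0 + gamma I0^2 / K_A)`.
#' With `gamma = 0` this is the Monod equation.
#'
#' @param I0 incident light intensity (umol m^-2 s^-1).
#' @param mu_star scale growth rate (h^-1, >= 0).
#' @param K_A half-saturation intensity (> 0).
#' @param gamma dimensionless photoinhibition number (>= 0).
#' @return growth rate, h^-1.
#' @export
haldane_growth <- function(I0, mu_star, K_A, gamma = 0) {
  if (K_A <= 0) stop("K_A must be strictly positive")
  if (mu_star < 0 || gamma < 0) stop("mu_star and gamma must be non-negative")
  mu_star * I0 / (K_A + I0 + gamma * I0^2 / K_A)
}

#' Fit the Haldane/Aiba equation to a growth-irradiance curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, non-negative
#' parameters) of [haldane_growth()] against observed `(I0, mu)` pairs.
#'
#' @param I0,mu numeric vectors of intensities and observed growth rates.
#' @param init named initial values `c(mu_star=, K_A=, gamma=)`.
#' @return object of class `haldane_fit`: estimates, standard errors from the
#'   Jacobian at the optimum, residuals, and convergence information.
#' @export
fit_haldane <- function(I0, mu, init = c(mu_star = max(mu), K_A = stats::median(I0),
                                         gamma = 0.1)) {
  stopifnot(length(I0) == length(mu))
  if (length(I0) < 4) stop("need at least 4 (I0, mu) pairs")
  resid_fn <- function(par) {
    haldane_growth(I0, par[["mu_star"]], max(par[["K_A"]], 1e-12),
                   par[["gamma"]]) - mu
  }
  fit <- minpack.lm::nls.lm(par = init, fn = resid_fn,
                            lower = c(0, 1e-9, 0),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- fit$par
  J <- fit$fvec          # residuals at optimum
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  names(se) <- names(est)
  structure(list(coefficients = unlist(est), se = se,
                 residuals = as.numeric(J), rss = sum(J^2),
                 fitted = mu + as.numeric(J),
                 converged = fit$info %in% 1:4,
                 data = data.frame(I0 = I0, mu = mu)),
            class = "haldane_fit")
}

#' @export
coef.haldane_fit <- function(object, ...) object$coefficients

#' @export
residuals.haldane_fit <- function(object, ...) object$residuals

#' @export
predict.haldane_fit <- function(object, I0 = object$data$I0, ...) {
  p <- object$coefficients
  haldane_growth(I0, p[["mu_star"]], p[["K_A"]], p[["gamma"]])
}

#' @export
print.haldane_fit <- function(x, ...) {
  cat("Haldane/Aiba growth-irradiance fit\n")
  est <- cbind(Estimate = x$coefficients, `Std.Error` = x$se)
  print(round(est, 5))
  cat(sprintf("RSS: %.4g on %d points; converged: %s\n",
              x$rss, nrow(x$data), x$converged))
  invisible(x)
}

#' Monod / quantum-yield equivalence
#'
#' For `gamma = 0` the Haldane/Aiba curve is a Monod curve, which is
#' algebraically identical to `Y_max eta(J_I) J_I` under the substitutions
#' `K_L = alpha K_A` and `Y_max = mu_star / (alpha K_A)`. Returns those two
#' derived constants (with `Y_max` in gCDM per mmol photons when fluxes are
#' in mmol gCDM^-1 h^-1).
#'
#' @param mu_star,K_A Monod parameters (`gamma = 0` case).
#' @param alpha absorption cross-section (> 0), paired with the convention
#'   `J_I = 3.6 alpha I0` so that `K_L` comes out in flux units.
#' @return list with `Y_max` and `K_L`.
#' @export
monod_equivalence <- function(mu_star, K_A, alpha) {
  if (alpha <= 0) stop("alpha must be strictly positive")
  if (K_A <= 0) stop("K_A must be strictly positive")
  K_L <- HOUR_PER_SEC_MMOL * alpha * K_A
  list(Y_max = mu_star / K_L, K_L = K_L)
}

#' Steady-state activated photosynthetic units (2-state model)
#'
#' In the 2-state model a photosynthetic unit is activated by photon
#' absorption at rate `sigma I0 P0` and relaxes (driving metabolism) at rate
#' `k2 P*`. The steady-state activated concentration is
#' `P* = sigma I0 P_T / (k2 + sigma I0)`. Under `K_L = k2 P_T` and
#' `J_I = sigma I0 P_T` the relaxation flux `k2 P*` is exactly the effective
#' uptake `J_I* = K_L J_I / (K_L + J_I)`.
#'
#' @param I0 light intensity (>= 0).
#' @param sigma absorption area per photosynthetic unit (> 0).
#' @param k2 relaxation rate constant (> 0).
#' @param P_T total photosynthetic-unit concentration (> 0).
#' @return steady-state activated concentration, same units as `P_T`.
#' @export
two_state_activated <- function(I0, sigma, k2, P_T) {
  if (sigma <= 0 || k2 <= 0 || P_T <= 0) {
    stop("sigma, k2 and P_T must be strictly positive")
  }
  if (any(I0 < 0)) stop("I0 must be non-negative")
  sigma * I0 * P_T / (k2 + sigma * I0)
}

#' Lambert-Beer light attenuation
#'
#' Light intensity at depth `z` in a flat-panel culture,
#' `I(z) = I0 exp(-epsilon rho_V z)`.
#'
#' @param I0 incident intensity (>= 0).
#' @param epsilon absorption coefficient, m^2 gCDM^-1 (>= 0).
#' @param rho_V volumetric biomass density, gCDM m^-3 (>= 0).
#' @param z depth, m (>= 0).
#' @return intensity at depth `z`.
#' @export
lambert_beer_intensity <- function(I0, epsilon, rho_V, z) {
  if (any(z < 0)) stop("depth must be non-negative")
  if (any(I0 < 0) || any(epsilon < 0) || any(rho_V < 0)) {
    stop("arguments must be non-negative")
  }
  I0 * exp(-epsilon * rho_V * z)
}

#' Photobioreactor photon absorption rate from transmitted light
#'
#' The specific rate of photon absorption in a flat-panel photobioreactor,
#' obtained by depth-integrating Lambert-Beer attenuation:
#' `J_I^PBR = 3.6 (I0 - I_Z) / rho_A` with `I_Z` the transmitted intensity
#' and `rho_A` the areal biomass density (gCDM m^-2). A constant blue
#' background `Ib` is absorbed with the same fractional absorption as red
#' light and added with weight `blue_weight` in `[0, 1]`:
#' absorbed blue = `blue_weight * Ib * (1 - I_Z / I0)`.
#'
#' @param I0 incident red intensity.
#' @param I_Z transmitted intensity at the back of the reactor
#'   (`0 <= I_Z <= I0`).
#' @param rho_A areal biomass density (> 0).
#' @param blue_weight weight of blue photons in `[0, 1]` (default 0.5; the
#'   0 and 1 settings bracket the envelope).
#' @param Ib blue background intensity.
#' @return photon flux, mmol photons gCDM^-1 h^-1.
#' @export
pbr_absorption_rate <- function(I0, I_Z, rho_A, blue_weight = 0.5, Ib = 0) {
  if (any(rho_A <= 0)) stop("rho_A must be strictly positive")
  if (any(I_Z > I0)) stop("transmitted intensity cannot exceed incident")
  if (any(blue_weight < 0) || any(blue_weight > 1)) {
    stop("blue_weight must lie in [0, 1]")
  }
  frac_abs <- ifelse(I0 > 0, 1 - I_Z / I0, 0)
  HOUR_PER_SEC_MMOL * ((I0 - I_Z) + blue_weight * Ib * frac_abs) / rho_A
}
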