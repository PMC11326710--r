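## Weighted nonlinear least-squares estimation of the light parameters
## (alpha, alpha_b, K_L, k_d) and the maintenance minima (NGAM, terminal
## oxidase fraction) against a growth-irradiance dataset. Every model
## evaluation is one constrained LP solve.

#' Fit the light parameters to a growth-irradiance dataset
#'
#' Bounded (non-negative) Levenberg-Marquardt least squares over the
#' residual vector
#' `[ w_mu * (mu_model - mu_obs) for each row ;`
#' `  (o2_dark_model - o2_dark_obs) for rows with dark-O2 data ]`,
#' with the growth residuals weighted by `w_mu = 1000`. Net-O2 rows are
#' never part of the residual. For each row, one forward pipeline
#' evaluation (light state, constraints, LP, parsimonious fluxes, O2
#' accounting) produces the model predictions; rows carrying
#' `protein_frac`/`glycogen_frac` get a per-row biomass objective via
#' `bof_builder`, all other rows use the model's static reference biomass.
#'
#' @param model a [metabolic_model()] template.
#' @param data a growth dataset `data.frame` (see [read_growth_dataset()]):
#'   columns `I0`, `mu_obs`, optionally `Ib`, `o2_dark_obs`,
#'   `protein_frac`, `glycogen_frac`.
#' @param roles a [reaction_roles()].
#' @param init named initial values for any of `alpha`, `alpha_b`, `K_L`,
#'   `k_d`, `ngam`, `oxidase`; omitted parameters start from defaults.
#' @param fixed named values to hold fixed (excluded from estimation).
#' @param constraints baseline [physiological_constraints()]; the fitted
#'   `ngam` and `oxidase` entries override its `ngam_min` and
#'   `terminal_oxidase_fraction`.
#' @param weight_mu weight on the growth residuals (default 1000).
#' @param bof_builder optional `function(model, protein_frac,
#'   glycogen_frac)` returning the model with a per-row biomass objective.
#' @param multistart also run the local search from the package default
#'   and a capacity-shifted start and keep the best fit; guards the local
#'   optimizer against the flat zero-growth basin reachable from crude
#'   starting values.
#' @return object of class `light_fit`: estimated [light_parameters()],
#'   standard errors, residuals, per-row predictions, convergence flag.
#' @export
fit_light_parameters <- function(model, data, roles,
                                 init = c(alpha = 0.1, alpha_b = 0.5,
                                          K_L = 100, k_d = 0.05,
                                          ngam = 1, oxidase = 0.05),
                                 fixed = NULL,
                                 constraints = physiological_constraints(
                                   rubisco_oxygenase_fraction = 0,
                                   mehler_like_fraction = 0,
                                   mehler_psi_fraction = 0,
                                   mehler_psii_fraction = 0),
                                 weight_mu = 1000,
                                 bof_builder = NULL,
                                 multistart = TRUE) {
  par_names <- c("alpha", "alpha_b", "K_L", "k_d", "ngam", "oxidase")
  start <- c(alpha = 0.1, alpha_b = 0.5, K_L = 100, k_d = 0.05,
             ngam = 1, oxidase = 0.05)
  start[names(init)] <- init
  if (!is.null(fixed)) start[names(fixed)] <- fixed
  free <- setdiff(par_names, names(fixed))
  n_free <- length(free)
  if (nrow(data) < n_free) {
    stop("need at least as many intensities as free parameters (",
         n_free, ")")
  }
  if (!"Ib" %in% names(data)) data$Ib <- 0
  has_o2 <- "o2_dark_obs" %in% names(data) & TRUE
  o2_rows <- if (has_o2) which(!is.na(data$o2_dark_obs)) else integer()
  has_bof <- !is.null(bof_builder) &&
    all(c("protein_frac", "glycogen_frac") %in% names(data))

  predict_rows <- function(theta) {
    p <- light_parameters(theta[["alpha"]], theta[["alpha_b"]],
                          max(theta[["K_L"]], 1e-9), theta[["k_d"]])
    cstr <- constraints
    cstr$ngam_min <- theta[["ngam"]]
    cstr$terminal_oxidase_fraction <- min(theta[["oxidase"]], 0.999)
    mu <- numeric(nrow(data))
    o2 <- numeric(nrow(data))
    for (i in seq_len(nrow(data))) {
      m_i <- model
      if (has_bof && !is.na(data$protein_frac[i]) &&
          !is.na(data$glycogen_frac[i])) {
        m_i <- bof_builder(m_i, data$protein_frac[i], data$glycogen_frac[i])
      }
      sim <- simulate_condition(m_i, p, cstr, roles,
                                light_conditions(data$I0[i], data$Ib[i]),
                                parsimonious = length(o2_rows) > 0)
      mu[i] <- sim$mu
      o2[i] <- sim$o2_dark
    }
    list(mu = mu, o2 = o2)
  }

  run_lm <- function(start_vals, which_free, rows = seq_len(nrow(data))) {
    o2_sub <- intersect(o2_rows, rows)
    fn <- function(par_free) {
      theta <- start_vals
      theta[which_free] <- par_free
      pr <- predict_rows(theta)
      c(weight_mu * (pr$mu[rows] - data$mu_obs[rows]),
        if (length(o2_sub)) pr$o2[o2_sub] - data$o2_dark_obs[o2_sub])
    }
    minpack.lm::nls.lm(par = start_vals[which_free], fn = fn,
                       lower = rep(0, length(which_free)),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-12, ptol = 1e-10))
  }

  ## The residual surface has a spurious flat basin at zero growth
  ## (alpha or K_L driven to 0), so a single local search from a poor
  ## start can collapse. A small multistart -- the user's init, the
  ## package default, and a capacity-shifted variant -- makes the fit
  ## robust to crude starting values; the best weighted RSS wins.
  starts <- list(start)
  if (multistart) {
    default_start <- c(alpha = 0.1, alpha_b = 0.5, K_L = 100, k_d = 0.05,
                       ngam = 1, oxidase = 0.05)
    default_start[names(fixed)] <- fixed
    shifted <- start
    shifted[["K_L"]] <- start[["K_L"]] * 4
    shifted[["k_d"]] <- start[["k_d"]] / 4
    starts <- c(starts, list(default_start, shifted))
  }
  fits <- lapply(starts, function(s) run_lm(s, free))
  fit <- fits[[which.min(vapply(fits, function(f) f$deviance, numeric(1)))]]
  theta <- start
  theta[free] <- fit$par
  theta[["K_L"]] <- max(theta[["K_L"]], 1e-9)
  se_free <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                      error = function(e) rep(NA_real_, n_free))
  se <- stats::setNames(rep(0, length(par_names)), par_names)
  se[free] <- se_free
  at_bound <- free[abs(fit$par) < 1e-10]
  if (length(at_bound)) {
    warning("parameter(s) at the non-negativity bound: ",
            paste(at_bound, collapse = ", "))
  }
  pr <- predict_rows(theta)
  params <- light_parameters(theta[["alpha"]], theta[["alpha_b"]],
                             theta[["K_L"]], theta[["k_d"]],
                             ngam_min = theta[["ngam"]],
                             oxidase_fraction = theta[["oxidase"]])
  structure(list(
    parameters = params,
    coefficients = theta,
    se = se,
    free = free,
    residuals = as.numeric(fit$fvec),
    rss = sum(fit$fvec^2),
    predictions = data.frame(I0 = data$I0, Ib = data$Ib,
                             mu_obs = data$mu_obs, mu_pred = pr$mu,
                             o2_dark_obs = if (has_o2) data$o2_dark_obs else
                               NA_real_,
                             o2_dark_pred = pr$o2),
    converged = fit$info %in% 1:4,
    info = fit$info,
    init = start,
    data = data,
    model = model,
    roles = roles,
    constraints = constraints,
    weight_mu = weight_mu),
    class = "light_fit")
}

#' @export
coef.light_fit <- function(object, ...) object$coefficients

#' @export
residuals.light_fit <- function(object, ...) object$residuals

#' @export
print.light_fit <- function(x, ...) {
  cat("Light-limited growth model fit (FBA pipeline)\n")
  est <- cbind(Estimate = x$coefficients, `Std.Error` = x$se)
  print(round(est, 5))
  cat(sprintf("RSS (weighted): %.6g; converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' @export
summary.light_fit <- function(object, ...) {
  cat("Light-limited growth model fit\n")
  cat(sprintf("  %d observations, %d free parameters (%s)\n",
              nrow(object$data), length(object$free),
              paste(object$free, collapse = ", ")))
  est <- cbind(Estimate = object$coefficients, `Std.Error` = object$se)
  print(round(est, 5))
  cat(sprintf("  weighted RSS %.6g, growth-residual weight %g\n",
              object$rss, object$weight_mu))
  invisible(object)
}

#' Predict growth and dark O2 at new light intensities
#'
#' @param object a `light_fit`.
#' @param I0,Ib intensities to predict at (default: the fitted data's).
#' @param ... unused.
#' @return data.frame with `I0`, `Ib`, `mu_pred`, `o2_dark_pred`.
#' @export
predict.light_fit <- function(object, I0 = object$data$I0,
                              Ib = object$data$Ib, ...) {
  Ib <- rep_len(Ib, length(I0))
  cstr <- object$constraints
  cstr$ngam_min <- object$coefficients[["ngam"]]
  cstr$terminal_oxidase_fraction <- object$coefficients[["oxidase"]]
  out <- data.frame(I0 = I0, Ib = Ib, mu_pred = NA_real_,
                    o2_dark_pred = NA_real_)
  for (i in seq_along(I0)) {
    sim <- simulate_condition(object$model, object$parameters, cstr,
                              object$roles, light_conditions(I0[i], Ib[i]))
    out$mu_pred[i] <- sim$mu
    out$o2_dark_pred[i] <- sim$o2_dark
  }
  out
}
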