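## Normalized (scaled) sensitivity coefficients of the maximal growth rate
## with respect to the light parameters and the incident intensity,
## C_k = (k / mu) * (mu(k+) - mu(k-)) / (k+ - k-), with k+/- = k * (1 +/- 0.01),
## i.e. a symmetric 2% perturbation evaluated through the full pipeline.

#' Normalized sensitivity of the maximal growth rate
#'
#' Central finite difference with a fixed +/-1% step on one of `alpha`,
#' `alpha_b`, `K_L`, `k_d` or the red intensity `I0` (blue background held
#' constant). Dimensionless by construction.
#'
#' @param model a [metabolic_model()].
#' @param p a [light_parameters()].
#' @param constraints a [physiological_constraints()].
#' @param roles a [reaction_roles()].
#' @param light a [light_conditions()].
#' @param param one of `"alpha"`, `"alpha_b"`, `"K_L"`, `"k_d"`, `"I0"`.
#' @return the scaled sensitivity coefficient; `NA` (with a warning) when
#'   the unperturbed growth rate is 0.
#' @export
normalized_sensitivity <- function(model, p, constraints, roles, light,
                                   param = c("alpha", "alpha_b", "K_L",
                                             "k_d", "I0")) {
  param <- match.arg(param)
  k <- if (param == "I0") light$I0 else p[[param]]
  if (!is.finite(k) || k <= 0) {
    stop("sensitivity requires a positive, finite parameter value")
  }
  mu_at <- function(scale) {
    p2 <- p; l2 <- light
    if (param == "I0") l2$I0 <- k * scale else p2[[param]] <- k * scale
    simulate_condition(model, p2, constraints, roles, l2,
                       parsimonious = FALSE)$mu
  }
  mu0 <- mu_at(1)
  if (mu0 <= 1e-12) {
    warning("growth rate is zero at the evaluation point; sensitivity undefined")
    return(NA_real_)
  }
  (k / mu0) * (mu_at(1.01) - mu_at(0.99)) / (0.02 * k)
}

#' Sensitivity coefficients over a light-intensity scan
#'
#' @inheritParams normalized_sensitivity
#' @param I0_grid intensities at which to evaluate.
#' @param Ib constant blue background.
#' @param params parameters to scan.
#' @return data.frame: `I0` plus one coefficient column `C_<parameter>`
#'   per scanned parameter.
#' @export
sensitivity_scan <- function(model, p, constraints, roles, I0_grid, Ib = 0,
                             params = c("alpha", "alpha_b", "K_L", "k_d",
                                        "I0")) {
  rows <- lapply(I0_grid, function(I0) {
    light <- light_conditions(I0, Ib)
    cs <- vapply(params, function(pp) {
      tryCatch(suppressWarnings(
        normalized_sensitivity(model, p, constraints, roles, light, pp)),
        error = function(e) NA_real_)
    }, numeric(1))
    c(I0 = I0, stats::setNames(cs, paste0("C_", params)))
  })
  as.data.frame(do.call(rbind, rows))
}
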