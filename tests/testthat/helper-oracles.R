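# Independent oracles used across the suite.

# Closed-form optimum of the toy phototroph. Derived by hand from the toy
# stoichiometry (photon bookkeeping):
#   carboxylase flux  RBC = C * mu,  C = n_C (1 - r) / (1 - 2 r)
#   electron transport PSET = RBC / (1 - g_mehler - f_ox)
#   photons = 2 PSET + 6 RBC + 2 n_A mu + 2 (NGAM + v_D)  <= J_I*
# where r is the oxygenase fraction of total RuBisCO flux, g_mehler the
# summed Mehler fractions and f_ox the oxidase fraction of PSII O2.
toy_oracle_mu <- function(J_star, v_D = 0, ngam = 0, n_C = 40, n_A = 20,
                          rubisco = 0, mehler = 0, oxidase = 0) {
  C <- n_C * (1 - rubisco) / (1 - 2 * rubisco)
  denom <- 2 * C / (1 - mehler - oxidase) + 6 * C + 2 * n_A
  max((J_star - 2 * (ngam + v_D)) / denom, 0)
}

# Closed-form per-gCDM fluxes of the toy optimum (zero-fraction cases
# generalized as above).
toy_oracle_fluxes <- function(mu, v_D = 0, ngam = 0, n_C = 40, n_A = 20,
                              rubisco = 0, mehler = 0, oxidase = 0) {
  C <- n_C * (1 - rubisco) / (1 - 2 * rubisco)
  rbc <- C * mu
  rbo <- rbc * rubisco / (1 - rubisco)
  pset <- rbc / (1 - mehler - oxidase)
  atp_demand <- 3 * rbc + n_A * mu + ngam + v_D
  cet <- atp_demand - 3 * pset
  list(RBC = rbc, RBO = rbo, PSET = pset, CET = cet,
       FNR = 2 * rbc + 2 * oxidase * pset,
       ATPase = atp_demand / 3,
       o2_psii = pset,
       o2_nonlight = oxidase * pset + rbo,
       o2_net = pset * (1 - mehler - oxidase) - rbo,
       photons = 8 * pset + 2 * cet)
}

# Full forward oracle: light state plus toy optimum.
toy_oracle_condition <- function(I0, Ib, p, ngam = 0, oxidase = 0,
                                 n_C = 40, n_A = 20) {
  J <- 3.6 * p$alpha * (I0 + p$alpha_b * Ib)
  J_star <- if (is.infinite(p$K_L)) J else p$K_L * J / (p$K_L + J)
  v_D <- p$k_d * J
  mu <- toy_oracle_mu(J_star, v_D, ngam, n_C, n_A, oxidase = oxidase)
  fl <- toy_oracle_fluxes(mu, v_D, ngam, n_C, n_A, oxidase = oxidase)
  list(mu = mu, o2_dark = fl$o2_nonlight, o2_net = fl$o2_net,
       J_I = J, J_star = J_star, v_D = v_D)
}

# Brute-force LP oracle: enumerate all candidate vertices (every choice of
# m basic variables, every bound assignment of the nonbasic ones) and take
# the best feasible one. Only for small problems with finite bounds.
enum_lp <- function(obj, A, sense, rhs, lower, upper, maximize = TRUE) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  ineq <- which(sense != "=")
  for (i in ineq) {
    s <- rep(0, m); s[i] <- if (sense[i] == "<=") 1 else -1
    A <- cbind(A, s)
    # slack upper bound: generous finite cap keeps enumeration valid for
    # the bounded test problems used here
    lower <- c(lower, 0); upper <- c(upper, 1e4)
    obj <- c(obj, 0)
  }
  n <- ncol(A)
  best <- NULL
  for (basis in utils::combn(n, m, simplify = FALSE)) {
    nb <- setdiff(seq_len(n), basis)
    B <- A[, basis, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(nb)))
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      x[nb] <- ifelse(unlist(grid[g, ]), upper[nb], lower[nb])
      xb <- solve(B, rhs - A[, nb, drop = FALSE] %*% x[nb])
      x[basis] <- xb
      if (all(x >= lower - 1e-7) && all(x <= upper + 1e-7)) {
        val <- sum(obj * x)
        if (is.null(best) || (maximize && val > best) ||
            (!maximize && val < best)) {
          best <- val
        }
      }
    }
  }
  best   # NULL when no feasible vertex exists
}

# constraints object with every coupling switched off
zero_constraints <- function(ngam = 0, oxidase = 0) {
  physiological_constraints(rubisco_oxygenase_fraction = 0, ngam_min = ngam,
                            mehler_like_fraction = 0,
                            mehler_psi_fraction = 0,
                            mehler_psii_fraction = 0,
                            terminal_oxidase_fraction = oxidase)
}

# light state with the photon cap set directly (for hand LPs)
fixed_light_state <- function(J_star, v_D = 0) {
  structure(list(J_I = J_star, eta = 1, J_I_star = J_star, v_D = v_D),
            class = "light_state")
}
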