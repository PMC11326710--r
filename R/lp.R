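#' Solve a linear program with bounded variables
#'
#' Dense two-phase primal simplex for problems of the form
#' \deqn{\max\; c^T x \quad \text{s.t.}\quad A x \;\{=,\le,\ge\}\; b,\quad
#'   l \le x \le u,}
#' with possibly infinite bounds. Written for the moderate problem sizes of
#' constraint-based metabolic models used here; the basis is refactorized at
#' every iteration, trading speed for numerical transparency.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n), dense numeric.
#' @param sense character vector of length m, each `"="`, `"<="` or `">="`.
#' @param rhs numeric right-hand sides (length m).
#' @param lower,upper variable bounds, recycled to length n; `-Inf`/`Inf`
#'   allowed.
#' @param maximize if `FALSE`, minimize instead.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter iteration cap per phase.
#'
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"` or
#'   `"maxiter"`), `objective`, and `x` (primal solution of length n; `NA` if
#'   not optimal).
#' @keywords internal
solve_lp <- function(obj, A, sense, rhs, lower = 0, upper = Inf,
                     maximize = TRUE, tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(sense) == m, length(rhs) == m)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (any(lower > upper)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  sgn <- if (maximize) 1 else -1

  ## append slack columns for inequality rows
  ineq <- which(sense != "=")
  n_slack <- length(ineq)
  if (n_slack > 0) {
    S <- matrix(0, m, n_slack)
    for (k in seq_along(ineq)) {
      i <- ineq[k]
      S[i, k] <- if (sense[i] == "<=") 1 else -1
    }
    A <- cbind(A, S)
    lower <- c(lower, rep(0, n_slack))
    upper <- c(upper, rep(Inf, n_slack))
  }
  N <- ncol(A)

  ## initial nonbasic values at a finite bound (0 for free variables)
  x <- ifelse(is.finite(lower), lower, ifelse(is.finite(upper), upper, 0))
  ## artificial columns give an identity starting basis
  r0 <- rhs - as.vector(A %*% x)
  art_sign <- ifelse(r0 >= 0, 1, -1)
  A <- cbind(A, diag(art_sign, m, m))
  lower <- c(lower, rep(0, m))
  upper <- c(upper, rep(Inf, m))
  x <- c(x, abs(r0))
  art <- (N + 1L):(N + m)
  basis <- art

  run_phase <- function(cc, basis, x, upper, tol, max_iter) {
    ## maximizes cc' x; returns updated state
    Nn <- length(cc)
    iter <- 0L
    bland_after <- 3L * (Nn + m)
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        return(list(status = "maxiter", basis = basis, x = x))
      }
      B <- A[, basis, drop = FALSE]
      ## recompute basic values for numerical hygiene
      nb <- setdiff(seq_len(Nn), basis)
      bB <- rhs - as.vector(A[, nb, drop = FALSE] %*% x[nb])
      xb <- tryCatch(solve(B, bB), error = function(e) NULL)
      if (is.null(xb)) {
        return(list(status = "singular", basis = basis, x = x))
      }
      x[basis] <- xb
      y <- tryCatch(solve(t(B), cc[basis]), error = function(e) NULL)
      if (is.null(y)) {
        return(list(status = "singular", basis = basis, x = x))
      }
      d <- cc[nb] - as.vector(t(A[, nb, drop = FALSE]) %*% y)
      at_lo <- abs(x[nb] - lower[nb]) <= 1e-7 & is.finite(lower[nb])
      at_up <- abs(x[nb] - upper[nb]) <= 1e-7 & is.finite(upper[nb])
      free <- !at_lo & !at_up
      fixed <- upper[nb] - lower[nb] <= tol        # can never move
      up_dir <- (at_lo | free) & d > tol & !fixed  # increase improves
      dn_dir <- (at_up | free) & d < -tol & !fixed # decrease improves
      cand <- which(up_dir | dn_dir)
      if (length(cand) == 0) {
        return(list(status = "optimal", basis = basis, x = x))
      }
      if (iter > bland_after) {
        j <- cand[which.min(nb[cand])]
      } else {
        j <- cand[which.max(abs(d[cand]))]
      }
      q <- nb[j]
      dir <- if (up_dir[j]) 1 else -1
      w <- as.vector(solve(B, A[, q]))
      ## x_B(t) = x_B - t * dir * w ; find blocking t
      t_best <- upper[q] - lower[q]        # bound flip distance (may be Inf)
      leave <- 0L                          # 0 => bound flip
      bland <- iter > bland_after
      for (i in seq_len(m)) {
        wi <- dir * w[i]
        bi <- basis[i]
        ti <- NA_real_
        if (wi > tol) {
          if (is.finite(lower[bi])) ti <- (x[bi] - lower[bi]) / wi
        } else if (wi < -tol) {
          if (is.finite(upper[bi])) ti <- (upper[bi] - x[bi]) / (-wi)
        }
        if (is.na(ti)) next
        better <- ti < t_best - 1e-12 ||
          (bland && ti < t_best + 1e-12 &&
             (leave == 0L || basis[i] < basis[leave]))
        if (better) { t_best <- ti; leave <- i }
      }
      if (!is.finite(t_best)) {
        return(list(status = "unbounded", basis = basis, x = x))
      }
      t_best <- max(t_best, 0)
      x[q] <- x[q] + dir * t_best
      x[basis] <- x[basis] - t_best * dir * w
      if (leave > 0L) {
        p <- basis[leave]
        ## snap leaving variable to the bound it hit
        wl <- dir * w[leave]
        x[p] <- if (wl > 0) lower[p] else upper[p]
        basis[leave] <- q
      }
      ## else: bound-to-bound move, basis unchanged
    }
  }

  ## phase 1: minimize sum of artificials
  c1 <- c(rep(0, N), rep(-1, m))
  ph1 <- run_phase(c1, basis, x, upper, tol, max_iter)
  if (ph1$status %in% c("singular", "maxiter")) {
    return(list(status = ph1$status, objective = NA_real_, x = rep(NA_real_, n)))
  }
  infeas <- sum(ph1$x[art])
  if (infeas > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  ## pin artificials at zero for phase 2
  upper[art] <- 0
  ph1$x[art] <- 0
  c2 <- c(sgn * obj, rep(0, N - n), rep(0, m))
  ph2 <- run_phase(c2, ph1$basis, ph1$x, upper, tol, max_iter)
  if (ph2$status == "optimal") {
    xs <- ph2$x[seq_len(n)]
    list(status = "optimal", objective = sum(obj * xs), x = xs)
  } else if (ph2$status == "unbounded") {
    list(status = "unbounded", objective = if (maximize) Inf else -Inf,
         x = rep(NA_real_, n))
  } else {
    list(status = ph2$status, objective = NA_real_, x = rep(NA_real_, n))
  }
}
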