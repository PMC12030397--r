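#' Parameters of the convex tonic/phasic EDA decomposition
#'
#' @param alpha Sparsity weight on the non-negative sudomotor driver
#'   (default 0.008).
#' @param gamma Smoothness weight on the tonic spline coefficients
#'   (default 0.01).
#' @param tau1,tau2 Rise and decay time constants of the biexponential SCR
#'   response, seconds (defaults 0.7 and 2).
#' @param knot_spacing Tonic spline knot spacing in seconds (default 10).
#' @param solver_tolerance Relative KKT tolerance of the solver
#'   (default 1e-6).
#' @param max_iter Iteration cap of the operator-splitting solver.
#' @return A list of class `cvxeda_params`.
#' @export
cvxeda_params <- function(alpha = 0.008, gamma = 0.01, tau1 = 0.7, tau2 = 2,
                          knot_spacing = 10, solver_tolerance = 1e-6,
                          max_iter = 6000L) {
  if (any(c(alpha, gamma, tau1, tau2, knot_spacing, solver_tolerance) <= 0))
    stop("all cvxeda parameters must be positive")
  if (tau1 >= tau2) stop("convention: tau1 (rise) < tau2 (decay)")
  structure(list(alpha = alpha, gamma = gamma, tau1 = tau1, tau2 = tau2,
                 knot_spacing = knot_spacing,
                 solver_tolerance = solver_tolerance,
                 max_iter = as.integer(max_iter)),
            class = "cvxeda_params")
}

# banded lower-triangular convolution operator with coefficients co on
# diagonals 0, -1, -2
conv_band_matrix <- function(co, n) {
  Matrix::bandSparse(n, n, k = c(0, -1, -2),
                     diagonals = list(rep(co[1], n), rep(co[2], n - 1),
                                      rep(co[3], n - 2)))
}

# cubic B-spline tonic basis with knots every `spacing` seconds
tonic_spline_basis <- function(tt, spacing) {
  t0 <- tt[1]; t1 <- tt[length(tt)]
  inner <- seq(t0, t1, by = spacing)
  knots <- c(rep(t0, 3), inner, rep(t1, 3))
  Matrix::Matrix(splines::splineDesign(knots, tt, ord = 4, outer.ok = TRUE),
                 sparse = TRUE)
}

#' Convex-optimization decomposition of EDA into tonic and phasic parts
#'
#' Solves the convex program
#' \deqn{\min_{q,\ell,d}\; \tfrac12\|Mq + B\ell + Cd - y\|_2^2
#'       + \alpha \mathbf{1}^\top A q + \tfrac{\gamma}{2}\|\ell\|_2^2
#'       \quad \mathrm{s.t.}\; Aq \ge 0,}
#' where `A` and `M` are the AR and MA parts of the bilinear-transform
#' discretization of the biexponential SCR response (time constants `tau1`,
#' `tau2`, step 0.5 s at the required 2 Hz rate), `B` a cubic-spline tonic
#' basis (10 s knots), and `C` an offset-plus-linear-drift term.  `p = Aq` is
#' the sparse non-negative sudomotor driver and `r = Mq` the phasic signal.
#' The program is solved by ADMM with the non-negativity split onto the
#' driver; the KKT-style stopping tolerance is `solver_tolerance`.
#'
#' @param x A `uniform_signal` sampled at 2 Hz, duration >= 60 s.
#' @param params A `cvxeda_params` object.
#' @return A list of class `phasic_decomposition`: `tonic`, `phasic`,
#'   `residual` (each `uniform_signal`; they sum to the input exactly),
#'   `driver` (non-negative event intensity), `objective`, `iterations`.
#' @export
cvxeda <- function(x, params = cvxeda_params()) {
  stopifnot(inherits(x, "uniform_signal"))
  if (abs(x$fs - 2) > 1e-9)
    stop("cvxeda expects a 2 Hz signal; resample first")
  y <- x$values
  n <- length(y)
  if (n / x$fs < 60) stop("cvxeda needs at least 60 s of signal")
  delta <- 1 / x$fs
  tt <- signal_times(x)

  # ARMA discretization of h(t) = exp(-t/tau2) - exp(-t/tau1), bilinear
  af <- 1 / params$tau1   # fast (rise) rate
  as_ <- 1 / params$tau2  # slow (decay) rate
  den <- (af - as_) * delta^2
  ar <- c((af * delta + 2) * (as_ * delta + 2),
          2 * af * as_ * delta^2 - 8,
          (af * delta - 2) * (as_ * delta - 2)) / den
  ma <- c(1, 2, 1)
  A <- conv_band_matrix(ar, n)
  M <- conv_band_matrix(ma, n)
  B <- tonic_spline_basis(tt, params$knot_spacing)
  K <- ncol(B)
  C <- Matrix::Matrix(cbind(1, (tt - tt[1]) / (tt[length(tt)] - tt[1])),
                      sparse = TRUE)

  G <- cbind(M, B, C)
  Gty <- as.numeric(Matrix::crossprod(G, y))
  H0 <- Matrix::crossprod(G) +
    Matrix::bdiag(Matrix::Diagonal(n, 0), Matrix::Diagonal(K, params$gamma),
                  Matrix::Diagonal(2, 1e-12))
  AtA <- Matrix::crossprod(A)
  pad_rows <- K + 2L

  rho <- 1
  make_chol <- function(rho) {
    Matrix::Cholesky(Matrix::forceSymmetric(
      H0 + rho * Matrix::bdiag(AtA, Matrix::Diagonal(pad_rows, 0))), LDL = FALSE)
  }
  ch <- make_chol(rho)

  z <- numeric(n); u <- numeric(n)
  tol <- params$solver_tolerance
  converged <- FALSE
  it <- 0L
  q <- numeric(n)
  for (it in seq_len(params$max_iter)) {
    rhs <- Gty + c(rho * as.numeric(Matrix::crossprod(A, z - u)), numeric(pad_rows))
    xv <- as.numeric(Matrix::solve(ch, rhs))
    q <- xv[seq_len(n)]
    Aq <- as.numeric(A %*% q)
    z_old <- z
    z <- pmax(0, Aq + u - params$alpha / rho)
    u <- u + Aq - z
    r_pri <- sqrt(sum((Aq - z)^2))
    r_dua <- rho * sqrt(sum(as.numeric(Matrix::crossprod(A, z - z_old))^2))
    eps_pri <- sqrt(n) * 1e-9 + tol * max(sqrt(sum(Aq^2)), sqrt(sum(z^2)), 1)
    eps_dua <- sqrt(n) * 1e-9 + tol * max(rho * sqrt(sum(as.numeric(Matrix::crossprod(A, u))^2)), 1)
    if (r_pri < eps_pri && r_dua < eps_dua) { converged <- TRUE; break }
    if (it %% 25 == 0) {
      if (r_pri > 10 * r_dua) { rho <- rho * 2; u <- u / 2; ch <- make_chol(rho) }
      else if (r_dua > 10 * r_pri) { rho <- rho / 2; u <- u * 2; ch <- make_chol(rho) }
    }
  }
  if (!converged)
    stop(sprintf("cvxeda solver did not converge in %d iterations (primal %.2e, dual %.2e)",
                 params$max_iter, r_pri, r_dua))

  ell <- xv[n + seq_len(K)]
  d <- xv[n + K + 1:2]
  phasic <- as.numeric(M %*% q)
  tonic <- as.numeric(B %*% ell + C %*% d)
  driver <- pmax(0, z)
  resid <- y - phasic - tonic
  objective <- 0.5 * sum((phasic + tonic - y)^2) +
    params$alpha * sum(driver) + params$gamma / 2 * sum(ell^2)
  structure(list(
    tonic = uniform_signal(tonic, x$fs, x$t0, "tonic"),
    phasic = uniform_signal(phasic, x$fs, x$t0, "phasic"),
    residual = uniform_signal(resid + 0, x$fs, x$t0, "residual"),
    driver = uniform_signal(driver, x$fs, x$t0, "driver"),
    objective = objective, iterations = it),
    class = "phasic_decomposition")
}
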