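#' Discretization of the slit Fokker-Planck operator
#'
#' Parameters of the contour-evolution (Fokker-Planck) operator for a
#' wormlike chain between two hard walls. By the slit symmetry the chain
#' propagator depends only on the transverse position `y` and the cosine
#' `t = cos(theta)` of the tangent angle against the slit normal, so the
#' operator is
#' \deqn{\partial_s q = -t\,\partial_y q + \tfrac{1}{2L_p}
#'   \partial_t\big[(1-t^2)\,\partial_t q\big]}
#' with absorbing hard walls. Contour length and `y` are measured in units
#' of `Lp` throughout.
#'
#' The orientation variable is collocated at `l_max + 1` Gauss-Legendre
#' nodes; rotational diffusion is applied in the (orthonormal) Legendre modal
#' basis where it is diagonal with eigenvalues `-l(l+1)/2`. The transverse
#' direction uses a uniform grid with upwind transport differencing, which
#' realizes the kinetic half-range wall condition: at each wall the incoming
#' ghost value (orientations pointing from the wall into the channel) is
#' zero, while outgoing orientations are unconstrained.
#'
#' @param H_over_Lp slit height in units of persistence length, > 0
#' @param n_y number of interior transverse grid points (>= 8, and at least
#'   `8 / H_over_Lp^(1/3)` so the wall boundary layer is resolved)
#' @param l_max orientation expansion order (>= 4); `l_max + 1` Gauss nodes
#' @param ds contour step of the propagation filter, in units of `Lp`
#' @param tol relative convergence tolerance on the eigenvalue
#' @return object of class `slit_operator_spec`
#' @export
slit_operator_spec <- function(H_over_Lp, n_y = 200, l_max = 40,
                               ds = 0.05, tol = 1e-4) {
  if (!is.numeric(H_over_Lp) || length(H_over_Lp) != 1L || !is.finite(H_over_Lp) ||
      H_over_Lp <= 0)
    stop_domain("'H_over_Lp' must be a single positive number")
  if (n_y < 8) stop_config("'n_y' must be at least 8")
  floor_ny <- ceiling(8 / H_over_Lp^(1 / 3))
  if (n_y < floor_ny)
    stop_config(sprintf(
      "n_y = %d too coarse for H/Lp = %g: wall boundary layer needs n_y >= %d",
      n_y, H_over_Lp, floor_ny))
  if (l_max < 4) stop_config("'l_max' must be at least 4")
  if (!is.numeric(ds) || ds <= 0) stop_config("'ds' must be positive")
  if (!is.numeric(tol) || tol <= 0) stop_config("'tol' must be positive")
  structure(list(H_over_Lp = H_over_Lp, n_y = as.integer(n_y),
                 l_max = as.integer(l_max), ds = ds, tol = tol),
            class = "slit_operator_spec")
}

## Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1, idx]^2)
}

## orthonormal Legendre polynomials phi_l(t) = sqrt((2l+1)/2) P_l(t), columns l = 0..lmax
legendre_basis <- function(t, lmax) {
  P <- matrix(0, length(t), lmax + 1)
  P[, 1] <- 1
  if (lmax >= 1) P[, 2] <- t
  if (lmax >= 2) for (l in 1:(lmax - 1))
    P[, l + 2] <- ((2 * l + 1) * t * P[, l + 1] - l * P[, l]) / (l + 1)
  sweep(P, 2, sqrt((2 * (0:lmax) + 1) / 2), "*")
}

#' Build the discretized slit evolution operator
#'
#' Assembles the sparse generator acting on the scaled collocation state
#' \eqn{\sqrt{w_q}\,\psi(y_i, t_q)} (orientation-major ordering). With
#' `walls = FALSE` the transversally homogeneous sector is returned (a single
#' `y` degree of freedom with no transport), for which the isotropic state is
#' an exact null vector: removing the walls removes the confinement decay.
#'
#' @param spec [slit_operator_spec()]
#' @param walls keep the hard walls (default) or drop the transverse
#'   direction entirely
#' @param n_y_override internal: build at a different transverse resolution
#' @return object of class `slit_operator`: the generator `G`, its pieces
#'   `transport` and `rotation`, grids and quadrature weights
#' @export
build_slit_operator <- function(spec, walls = TRUE, n_y_override = NULL) {
  stopifnot(inherits(spec, "slit_operator_spec"))
  n_t <- spec$l_max + 1L
  gl <- gauss_legendre(n_t)
  t_q <- gl$nodes
  w_q <- gl$weights
  Phi <- legendre_basis(t_q, spec$l_max)
  V <- Phi * sqrt(w_q)                       # orthogonal modal <-> collocation
  l <- 0:spec$l_max
  Rrot <- V %*% (diag(-l * (l + 1) / 2) %*% t(V))  # symmetric, neg. semidefinite

  if (!walls) {
    n_y <- 1L
    h <- NA_real_
    transport <- Matrix::Matrix(0, n_t, n_t, sparse = TRUE)
    G <- Matrix::Matrix(Rrot, sparse = TRUE)
    y <- 0
  } else {
    n_y <- if (is.null(n_y_override)) spec$n_y else as.integer(n_y_override)
    H <- spec$H_over_Lp
    h <- H / (n_y + 1)
    y <- -H / 2 + seq_len(n_y) * h           # interior nodes
    ## upwind one-sided differences; absorbing ghost value 0 at the
    ## upstream wall implements the half-range condition
    Dm <- Matrix::bandSparse(n_y, n_y, k = c(0, -1),
                             diag = list(rep(1 / h, n_y), rep(-1 / h, n_y - 1)))
    Dp <- Matrix::bandSparse(n_y, n_y, k = c(0, 1),
                             diag = list(rep(-1 / h, n_y), rep(1 / h, n_y - 1)))
    blocks <- lapply(seq_len(n_t), function(q)
      if (t_q[q] > 0) -t_q[q] * Dm else -t_q[q] * Dp)
    transport <- Matrix::bdiag(blocks)
    G <- transport +
      Matrix::kronecker(Matrix::Matrix(Rrot, sparse = TRUE), Matrix::Diagonal(n_y))
  }
  structure(list(G = G, transport = transport, rotation = Rrot,
                 y = y, h = h, t = t_q, w = w_q, n_y = n_y, n_t = n_t,
                 walls = walls, spec = spec),
            class = "slit_operator")
}

## one inverse-propagation eigensolve on a built operator; returns raw pieces
solve_ground_state_raw <- function(op, ds, tol, maxit) {
  G <- op$G
  n <- nrow(G)
  LU <- Matrix::lu(Matrix::Diagonal(n) - ds * G)
  psi <- rep(1, n)
  mu_old <- Inf
  mu_prev <- NA_real_
  min_ratio <- Inf
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    psi_new <- as.numeric(Matrix::solve(LU, psi))
    g <- sqrt(sum(psi_new^2) / sum(psi^2))
    mu <- -2 * (1 - 1 / g) / ds        # mu0 normalization: q ~ exp(-mu0 s/(2 Lp))
    psi <- psi_new / sqrt(sum(psi_new^2))
    min_ratio <- min(min_ratio, min(psi) / max(psi))
    if (it > 10L && abs(mu - mu_old) <= tol * max(abs(mu), .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    if (it >= maxit) break
    mu_prev <- mu_old
    mu_old <- mu
  }
  list(mu0 = mu, mu0_prev = mu_old, psi = psi, iterations = it,
       converged = converged, min_ratio = min_ratio)
}

#' Ground state of the slit-confined chain
#'
#' Computes the dominant (slowest-decaying) eigenpair of the contour
#' evolution, normalized as \eqn{q \approx e^{-\mu_0 L/(2L_p)}\,\Psi_0}:
#' `mu0` is dimensionless and positive for any finite slit.
#'
#' The default method filters with the inverse of `(I - ds G)` (implicit
#' contour propagation, a strongly damped power iteration) and reads the
#' decay rate off the per-step growth factor; iteration stops when
#' successive estimates agree to `spec$tol` (relative). With
#' `richardson = TRUE` the solve is repeated at twice the transverse
#' resolution and the eigenvalue is extrapolated to zero grid spacing
#' (the upwind error is first order in the spacing); the eigenfunction is
#' kept from the fine grid. `method = "direct"` diagonalizes the dense
#' operator instead - an independent route intended for small bases.
#'
#' @param spec [slit_operator_spec()]
#' @param richardson extrapolate the transverse discretization error
#' @param method "propagation" (default) or "direct" (dense eigensolve,
#'   only for small `n_y * (l_max+1)`)
#' @param maxit iteration cap for the propagation method
#' @return object of class `wlc_ground_state`: fields `mu0`, `psi0` (matrix
#'   `n_y` x `l_max+1` of nonnegative collocation values, normalized to unit
#'   integral), `y`, `t`, weights, `iterations`, `converged`,
#'   `min_psi_ratio` (most negative value of the propagated state relative
#'   to its maximum, across all iterations), and the resolutions used
#' @examples
#' \donttest{
#' gs <- slit_ground_state(slit_operator_spec(0.2, n_y = 100, l_max = 24))
#' gs$mu0 / 2          # F Lp / (kBT L), between the modified and classical values
#' }
#' @export
slit_ground_state <- function(spec, richardson = TRUE,
                              method = c("propagation", "direct"),
                              maxit = 2000L) {
  stopifnot(inherits(spec, "slit_operator_spec"))
  method <- match.arg(method)
  op <- build_slit_operator(spec)

  if (method == "direct") {
    if (nrow(op$G) > 4000L)
      stop_config("direct diagonalization is limited to small bases (dim <= 4000)")
    ev <- eigen(as.matrix(op$G))
    i0 <- which.max(Re(ev$values))
    mu0 <- -2 * Re(ev$values[i0])
    psi <- Re(ev$vectors[, i0])
    if (sum(psi) < 0) psi <- -psi
    raw <- list(mu0 = mu0, psi = psi, iterations = NA_integer_,
                converged = TRUE, min_ratio = min(psi) / max(psi))
    mu_coarse <- NA_real_
  } else {
    raw <- solve_ground_state_raw(op, spec$ds, spec$tol, maxit)
    if (!raw$converged)
      stop_convergence(sprintf(
        "ground-state iteration did not converge in %d steps (last estimates %.8g, %.8g)",
        raw$iterations, raw$mu0_prev, raw$mu0),
        last_estimates = c(raw$mu0_prev, raw$mu0))
    mu_coarse <- NA_real_
    if (richardson) {
      op2 <- build_slit_operator(spec, n_y_override = 2L * spec$n_y + 1L)
      raw2 <- solve_ground_state_raw(op2, spec$ds, spec$tol, maxit)
      if (raw2$converged) {
        mu_coarse <- raw$mu0
        mu_fine <- raw2$mu0
        raw2$mu0 <- 2 * mu_fine - mu_coarse   # h, h/2 first-order extrapolation
        raw2$min_ratio <- min(raw$min_ratio, raw2$min_ratio)
        raw <- raw2
        op <- op2
      }
    }
  }

  ## unscale, clip quadrature sign noise, normalize to unit integral
  psi <- matrix(raw$psi, op$n_y, op$n_t)
  psi <- sweep(psi, 2, sqrt(op$w), "/")
  psi[psi < 0] <- 0
  Z <- sum(sweep(psi, 2, op$w, "*")) * (if (op$walls) op$h else 1)
  psi <- psi / Z
  structure(list(mu0 = raw$mu0, mu0_unextrapolated = mu_coarse,
                 psi0 = psi, y = op$y, t = op$t, w_t = op$w,
                 h_y = op$h, n_y = op$n_y, l_max = spec$l_max,
                 iterations = raw$iterations, converged = raw$converged,
                 min_psi_ratio = raw$min_ratio, method = method, spec = spec),
            class = "wlc_ground_state")
}

#' @export
print.wlc_ground_state <- function(x, ...) {
  cat(sprintf(
    "slit ground state: H/Lp = %g, mu0 = %.6g (F Lp/(kBT L) = %.6g)\n",
    x$spec$H_over_Lp, x$mu0, x$mu0 / 2))
  cat(sprintf("  %s method, n_y = %d, l_max = %d, %s after %s iterations\n",
              x$method, x$n_y, x$l_max,
              if (x$converged) "converged" else "NOT converged",
              if (is.na(x$iterations)) "-" else x$iterations))
  invisible(x)
}

#' Confinement free energy from the ground-state eigenvalue
#'
#' \eqn{F/k_BT = L \mu_0 / (2 L_p)}: ground-state dominance of the chain
#' partition function for long chains.
#'
#' @param gs [slit_ground_state()] result
#' @param chain [chain_spec()]
#' @return dimensionless free energy
#' @export
free_energy_from_ground_state <- function(gs, chain) {
  stopifnot(inherits(gs, "wlc_ground_state"), inherits(chain, "chain_spec"))
  if (!isTRUE(gs$converged))
    stop_convergence("ground state is not converged")
  chain$L * gs$mu0 / (2 * chain$Lp)
}

#' Deflection length from the ground-state eigenvalue
#'
#' Identifying the free energy `L mu0/(2 Lp)` with `L / lambda` gives
#' \eqn{\lambda = 2 L_p / \mu_0}.
#'
#' @inheritParams free_energy_from_ground_state
#' @return deflection length in the units of `Lp`
#' @export
deflection_from_ground_state <- function(gs, chain) {
  stopifnot(inherits(gs, "wlc_ground_state"), inherits(chain, "chain_spec"))
  if (!isTRUE(gs$converged))
    stop_convergence("ground state is not converged")
  if (gs$mu0 <= 0)
    stop_domain("mu0 must be positive: a free chain has no deflection length")
  2 * chain$Lp / gs$mu0
}

#' Estimate the Odijk free-energy prefactor from slit eigenvalues
#'
#' In the deflection regime \eqn{\mu_0/2 \to A\,\hat H^{-2/3}} as the slit
#' tightens. The estimator forms \eqn{v(\hat H) = (\mu_0/2)\,\hat H^{2/3}}
#' at several heights and extrapolates to \eqn{\hat H \to 0} by an affine
#' fit in \eqn{\hat H^{2/3}}, which absorbs the leading finite-height
#' correction; without the affine term (`affine = FALSE`) the plain mean of
#' `v` is returned, which is biased at finite heights.
#'
#' @param heights slit heights `H/Lp` (at least 3 for the affine fit),
#'   recommended within the deflection regime (`<= 0.2`)
#' @param ground_states optional list of precomputed [slit_ground_state()]
#'   objects matching `heights`; when `NULL` each height is solved with the
#'   template parameters
#' @param n_y,l_max,ds,tol solver parameters used when solving internally
#' @param richardson passed to [slit_ground_state()]
#' @param affine include the affine correction term
#' @return list with `A_box` (the extrapolated prefactor), `fit` (the `lm`
#'   object, or `NULL`), and `data` (per-height eigenvalues)
#' @export
extract_odijk_prefactor <- function(heights, ground_states = NULL,
                                    n_y = 200, l_max = 40, ds = 0.05,
                                    tol = 1e-4, richardson = TRUE,
                                    affine = TRUE) {
  if (length(heights) < 3L)
    stop_config("at least 3 slit heights are needed to extrapolate the prefactor")
  if (is.null(ground_states)) {
    ground_states <- lapply(heights, function(H)
      slit_ground_state(slit_operator_spec(H, n_y = n_y, l_max = l_max,
                                           ds = ds, tol = tol),
                        richardson = richardson))
  }
  if (length(ground_states) != length(heights))
    stop_config("'ground_states' must match 'heights'")
  if (!all(vapply(ground_states, function(g) isTRUE(g$converged), logical(1))))
    stop_convergence("all ground states must be converged")
  mu0 <- vapply(ground_states, `[[`, numeric(1), "mu0")
  x <- heights^(2 / 3)
  v <- mu0 / 2 * x
  dat <- data.frame(H_over_Lp = heights, mu0 = mu0, v = v)
  if (affine) {
    fit <- stats::lm(v ~ x, data = data.frame(v = v, x = x))
    A <- unname(stats::coef(fit)[1])
  } else {
    fit <- NULL
    A <- mean(v)
  }
  list(A_box = A, fit = fit, data = dat)
}
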