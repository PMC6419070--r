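#' Exact equilibrium sampler for the discrete wormlike chain
#'
#' Draws chain configurations directly from the Boltzmann distribution of
#' the discrete WLC bending energy: each joint's bending cosine follows the
#' density proportional to \eqn{\exp(\kappa\cos\theta)} with
#' \eqn{\kappa = L_p/b} (sampled by inverse CDF), the azimuth is uniform,
#' and the chain is assembled bond by bond. Used as an independent
#' equilibrium reference for the Brownian dynamics simulator and the
#' analysis estimators.
#'
#' @param N number of beads
#' @param b rod length (nm)
#' @param Lp persistence length (nm)
#' @param a bead radius (nm), carried through to the chain object
#' @return object of class `wlc_sampler`
#' @export
wlc_sampler <- function(N, b, Lp = 50, a = 1) {
  if (N < 3L) stop_domain("'N' must be at least 3")
  if (b <= 0 || b >= Lp) stop_domain("need 0 < b < Lp")
  structure(list(N = as.integer(N), b = b, Lp = Lp, a = a,
                 kappa = Lp / b), class = "wlc_sampler")
}

## inverse-CDF draw of cos(theta) ~ exp(kappa * cos), cos in [-1, 1]
sample_bend_cos <- function(n, kappa) {
  u <- stats::runif(n)
  ## F(c) = (exp(kappa c) - exp(-kappa)) / (exp(kappa) - exp(-kappa))
  1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
}

#' @rdname wlc_sampler
#' @param sampler a `wlc_sampler`
#' @return for `sample_equilibrium_wlc`, a [gbr_chain()] drawn from the
#'   discrete-WLC Boltzmann distribution (rod constraints hold exactly)
#' @export
sample_equilibrium_wlc <- function(sampler) {
  stopifnot(inherits(sampler, "wlc_sampler"))
  N <- sampler$N
  nb <- N - 1L
  cb <- sample_bend_cos(nb - 1L, sampler$kappa)
  phi <- stats::runif(nb - 1L, 0, 2 * pi)
  u <- matrix(0, nb, 3)
  u[1L, ] <- c(0, 0, 1)
  for (j in 2:nb) {
    up <- u[j - 1L, ]
    ## orthonormal frame around the previous bond direction
    ref <- if (abs(up[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- c(up[2] * ref[3] - up[3] * ref[2],
            up[3] * ref[1] - up[1] * ref[3],
            up[1] * ref[2] - up[2] * ref[1])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(up[2] * e1[3] - up[3] * e1[2],
            up[3] * e1[1] - up[1] * e1[3],
            up[1] * e1[2] - up[2] * e1[1])
    ct <- cb[j - 1L]
    st <- sqrt(max(0, 1 - ct^2))
    u[j, ] <- ct * up + st * (cos(phi[j - 1L]) * e1 + sin(phi[j - 1L]) * e2)
    u[j, ] <- u[j, ] / sqrt(sum(u[j, ]^2))
  }
  pos <- rbind(c(0, 0, 0), apply(u * sampler$b, 2, cumsum))
  pos <- sweep(pos, 2, colMeans(pos))
  gbr_chain(pos, b = sampler$b, a = sampler$a, Lp = sampler$Lp)
}

#' Closed-form discrete-WLC statistics
#'
#' Reference values for the equilibrium discrete wormlike chain with
#' `N - 1` bonds of length `b` and bending constant `kappa = Lp/b`:
#' the mean joint cosine is the Langevin-type expression
#' \eqn{\langle\cos\theta\rangle = \coth\kappa - 1/\kappa}, tangent
#' correlations decay as its powers,
#' \eqn{\langle u_i\cdot u_{i+j}\rangle = \langle\cos\theta\rangle^{j}},
#' and the mean squared end-to-end distance follows from the telescoping
#' double sum over bond pairs. `wlc_r2_continuous` is the continuous-chain
#' counterpart \eqn{\langle R^2\rangle = 2 L_p L - 2 L_p^2 (1 - e^{-L/L_p})}.
#'
#' @param kappa bending constant `Lp/b`
#' @return `discrete_wlc_mean_cos`: the mean joint cosine
#' @export
discrete_wlc_mean_cos <- function(kappa) {
  1 / tanh(kappa) - 1 / kappa
}

#' @rdname discrete_wlc_mean_cos
#' @param N bead count
#' @param b rod length
#' @param Lp persistence length
#' @return `discrete_wlc_r2`: mean squared end-to-end distance
#' @export
discrete_wlc_r2 <- function(N, b, Lp) {
  p <- discrete_wlc_mean_cos(Lp / b)
  nb <- N - 1
  b^2 * (nb * (1 + p) / (1 - p) - 2 * p * (1 - p^nb) / (1 - p)^2)
}

#' @rdname discrete_wlc_mean_cos
#' @param L contour length
#' @return `wlc_r2_continuous`: continuous-chain mean squared end-to-end
#'   distance
#' @export
wlc_r2_continuous <- function(L, Lp) {
  2 * Lp * L - 2 * Lp^2 * (1 - exp(-L / Lp))
}

#' Unit bond vectors of a configuration
#'
#' @param positions `N x 3` matrix
#' @return `(N-1) x 3` matrix of unit tangents
#' @export
bond_unit_vectors <- function(positions) {
  d <- diff(as.matrix(positions))
  d / sqrt(rowSums(d^2))
}

#' Tangent-tangent correlation by bond separation
#'
#' Average of \eqn{u_i \cdot u_{i+j}} over all bond pairs at separation `j`,
#' for one configuration.
#'
#' @param positions `N x 3` matrix
#' @param max_sep largest separation to report
#' @return numeric vector indexed by separation 1..`max_sep`
#' @export
tangent_correlation <- function(positions, max_sep = 10L) {
  u <- bond_unit_vectors(positions)
  nb <- nrow(u)
  max_sep <- min(max_sep, nb - 1L)
  vapply(seq_len(max_sep), function(j) {
    i <- seq_len(nb - j)
    mean(rowSums(u[i, , drop = FALSE] * u[i + j, , drop = FALSE]))
  }, numeric(1))
}
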