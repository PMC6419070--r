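#' Classical Odijk deflection length from the free energy
#'
#' The deflection length whose segment count `L/lambda` reproduces the
#' confinement free energy of a wormlike chain in a rectangular channel:
#' \deqn{\lambda_{fe} = A^{-1} L_p^{1/3} (H_h^{-2/3} + H_w^{-2/3})^{-1}.}
#' It is symmetric in the two channel dimensions and reduces to the slit
#' scaling \eqn{A^{-1} L_p^{1/3} H^{2/3}} when one dimension is removed
#' (`Hw = Inf`).
#'
#' @param geom [channel_geometry()]
#' @param chain [chain_spec()]
#' @param const [odijk_constants()]
#' @return deflection length, same units as the inputs
#' @export
classical_deflection_fe <- function(geom, chain, const = odijk_constants()) {
  h <- hhat(geom, chain)
  chain$Lp / (const$A_box * (h[["hh"]]^(-2 / 3) + h[["hw"]]^(-2 / 3)))
}

#' Classical Odijk deflection length from the average extension
#'
#' The deflection length tied to the classical extension relation,
#' \deqn{\lambda_{ext} = 2\alpha (L_p^{1/3} H_h^{2/3} + L_p^{1/3} H_w^{2/3}).}
#' Unlike [classical_deflection_fe()], this grows without bound as the wide
#' dimension opens up, which is why it cannot describe a slit: the open
#' direction dominates even though it no longer confines the chain.
#'
#' @inheritParams classical_deflection_fe
#' @return deflection length, same units as the inputs
#' @export
classical_deflection_ext <- function(geom, chain, const = odijk_constants()) {
  h <- hhat(geom, chain)
  if (!is.finite(h[["hw"]]))
    stop_domain("lambda_ext diverges for an infinitely wide channel; use a finite width")
  2 * const$alpha_box * chain$Lp * (h[["hh"]]^(2 / 3) + h[["hw"]]^(2 / 3))
}

#' Domain of the modified deflection length
#'
#' The modified deflection length involves
#' \eqn{\log[1 - \vartheta A^{-1} (\hat H_h^{-2/3}+\hat H_w^{-2/3})^{-1}]},
#' which requires \eqn{\hat H_h^{-2/3}+\hat H_w^{-2/3} > \vartheta/A}. This is
#' the hard boundary of the deflection picture: channels wider than it admit
#' no modified deflection length. Returns the margin by which the condition
#' holds so callers can report how close a geometry sits to the boundary.
#'
#' @inheritParams classical_deflection_fe
#' @return list with `ok` (logical), `lhs`, `bound` and `margin = lhs - bound`
#' @export
validity_check <- function(geom, chain, const = odijk_constants()) {
  h <- hhat(geom, chain)
  lhs <- h[["hh"]]^(-2 / 3) + h[["hw"]]^(-2 / 3)
  bound <- const$theta / const$A_box
  list(ok = lhs > bound, lhs = lhs, bound = bound, margin = lhs - bound)
}

## internal: epsilon = theta/A * (hh^-2/3 + hw^-2/3)^-1, checked
log_argument_eps <- function(geom, chain, const) {
  v <- validity_check(geom, chain, const)
  if (!v$ok)
    stop_validity(sprintf(
      paste0("channel too wide for the deflection picture: requires ",
             "Hh^-2/3 + Hw^-2/3 > theta/A = %.5g in units of Lp^-2/3 ",
             "(got %.5g, margin %.3g)"),
      v$bound, v$lhs, v$margin))
  eps <- const$theta / (const$A_box * v$lhs)
  if (eps >= 1)  # lhs > bound guarantees eps < 1; keep an explicit guard
    stop_validity("log argument non-positive: channel at the validity boundary")
  eps
}

#' Modified deflection length
#'
#' A single deflection length that is consistent with both the confinement
#' free energy and the average extension of a channel-confined wormlike
#' chain:
#' \deqn{\lambda_m/L_p = -\vartheta^{-1}
#'   \log[1 - \vartheta A^{-1} (\hat H_h^{-2/3}+\hat H_w^{-2/3})^{-1}].}
#' For tight channels it Taylor-reduces to [classical_deflection_fe()]; at
#' moderate channel sizes it exceeds it (\eqn{-\log(1-x) > x}), which is what
#' extends the validity range of the closed forms built on it.
#'
#' @inheritParams classical_deflection_fe
#' @return deflection length, same units as the inputs
#' @examples
#' g <- channel_geometry(10, 10); ch <- chain_spec(200, 50)
#' modified_deflection(g, ch) / 50   # ~0.1656 at Hh = Hw = 0.2 Lp
#' @export
modified_deflection <- function(geom, chain, const = odijk_constants()) {
  eps <- log_argument_eps(geom, chain, const)
  -chain$Lp * log1p(-eps) / const$theta
}

#' Confinement free energy from the classical deflection length
#'
#' \eqn{F/k_BT = L/\lambda_{fe} =
#' A\, L\, L_p^{-1/3} (H_h^{-2/3}+H_w^{-2/3})}: the channel contributes the
#' sum of two independent slit terms.
#'
#' @inheritParams classical_deflection_fe
#' @return dimensionless free energy \eqn{F/k_BT}
#' @export
free_energy_classical <- function(chain, geom, const = odijk_constants()) {
  chain$L / classical_deflection_fe(geom, chain, const)
}

#' Confinement free energy from the modified deflection length
#'
#' \eqn{F/k_BT = L/\lambda_m}; by construction this equals
#' \deqn{-\vartheta \frac{L}{L_p}
#'   \Big/ \log[1 - \vartheta A^{-1}(\hat H_h^{-2/3}+\hat H_w^{-2/3})^{-1}],}
#' extensive in `L` and everywhere below the classical value on the validity
#' domain.
#'
#' @inheritParams classical_deflection_fe
#' @return dimensionless free energy \eqn{F/k_BT}
#' @export
free_energy_modified <- function(chain, geom, const = odijk_constants()) {
  chain$L / modified_deflection(geom, chain, const)
}

#' Classical unstretched extension deficit
#'
#' The tight-confinement relation
#' \eqn{1 - R_\parallel/L = \alpha(\hat H_h^{2/3} + \hat H_w^{2/3})}.
#' Meaningful for tubes only: as the wide dimension opens the open-direction
#' term grows although that direction no longer confines the chain, so the
#' relation is not applicable to slits (it diverges as `Hw -> Inf`).
#'
#' @inheritParams classical_deflection_fe
#' @return dimensionless deficit \eqn{1 - R_\parallel/L}
#' @export
extension_deficit_classical <- function(geom, chain, const = odijk_constants()) {
  h <- hhat(geom, chain)
  if (!is.finite(h[["hw"]]))
    stop_domain("the classical extension relation diverges for Hw = Inf; tubes only")
  const$alpha_box * (h[["hh"]]^(2 / 3) + h[["hw"]]^(2 / 3))
}

#' Unstretched extension deficit from the modified deflection length
#'
#' From the segment picture with the modified deflection length, the average
#' extension is
#' \eqn{R_\parallel = L \frac{L_p}{\vartheta\lambda_m}(1 - e^{-\vartheta\lambda_m/L_p})},
#' which in terms of the log argument \eqn{\varepsilon} reads
#' \eqn{1 - R_\parallel/L = 1 - \varepsilon / (-\log(1-\varepsilon))}.
#' For tight square channels it agrees with
#' [extension_deficit_classical()]; for aspect ratio away from 1 the
#' classical form exceeds it by [aspect_ratio_factor()].
#'
#' @inheritParams classical_deflection_fe
#' @return dimensionless deficit \eqn{1 - R_\parallel/L}
#' @export
extension_deficit_modified <- function(geom, chain, const = odijk_constants()) {
  eps <- log_argument_eps(geom, chain, const)
  1 - eps / (-log1p(-eps))
}

#' Aspect-ratio discrepancy factor
#'
#' \eqn{\phi(\beta) = \frac14 (\beta^{1/3} + \beta^{-1/3})^2} with
#' \eqn{\beta = H_h/H_w}: the factor by which the classical tight-confinement
#' deficit exceeds the modified one for a rectangular cross-section. It is
#' invariant under \eqn{\beta \to 1/\beta}, has its single minimum
#' \eqn{\phi(1) = 1} at the square cross-section and diverges in the slit
#' limits.
#'
#' @param beta aspect ratio, > 0 (vectorized)
#' @return \eqn{\phi(\beta)}
#' @export
aspect_ratio_factor <- function(beta) {
  if (!is.numeric(beta) || any(!is.finite(beta)) || any(beta <= 0))
    stop_domain("'beta' must be positive and finite")
  0.25 * (beta^(1 / 3) + beta^(-1 / 3))^2
}

#' Force-extension relation without confinement
#'
#' Strong-stretching wormlike-chain relation
#' \eqn{1 - R_\parallel/L = 1/(2\sqrt{\hat f})}. Diverges at zero force,
#' where the stretching deflection picture no longer applies; confined chains
#' at zero force are handled by [force_confinement_extension()].
#'
#' @param force [force_state()] with `f_hat > 0`
#' @return dimensionless deficit
#' @export
force_extension_unconfined <- function(force) {
  stopifnot(inherits(force, "force_state"))
  if (force$f_hat <= 0)
    stop_domain("the unconfined relation requires f_hat > 0 (it diverges at 0)")
  1 / (2 * sqrt(force$f_hat))
}

#' Effective force exerted by strong confinement
#'
#' The confinement term that adds to the true tension in the
#' force-confinement-extension relation. As printed in the closed form,
#' \eqn{\hat f_c = \{-\log[1 - \vartheta A^{-1}
#' (\hat H_h^{-2/3}+\hat H_w^{-2/3})^{-1}]\}^{-2}} (`form = "as_printed"`,
#' the default): only this normalization reduces the stretched relation to
#' the unstretched modified deficit at zero force. The alternative reading
#' \eqn{\hat f_c = L_p^2/\lambda_m^2} differs by \eqn{\vartheta^2} and is
#' available as `form = "from_deflection_length"` for comparison.
#'
#' @inheritParams classical_deflection_fe
#' @param form which normalization of the effective force to use
#' @return [force_state()] carrying \eqn{\hat f_c}
#' @export
effective_confinement_force <- function(geom, chain, const = odijk_constants(),
                                        form = c("as_printed", "from_deflection_length")) {
  form <- match.arg(form)
  eps <- log_argument_eps(geom, chain, const)
  fc <- (-log1p(-eps))^(-2)
  if (form == "from_deflection_length") fc <- fc * const$theta^2
  force_state(f_hat = fc, Lp = chain$Lp)
}

#' Force-confinement-extension relation
#'
#' The central closed form for a chain simultaneously confined and
#' stretched:
#' \deqn{1 - \frac{R_\parallel}{L} = \frac12\Big[\hat f +
#'   \{-\log[1-\vartheta A^{-1}(\hat H_h^{-2/3}+\hat H_w^{-2/3})^{-1}]\}^{-2}
#'   \Big]^{-1/2}.}
#' At large force it goes over to [force_extension_unconfined()]; at zero
#' force and tight confinement it reduces to the unstretched modified
#' deficit. Tighter channels and larger forces both reduce the deficit.
#'
#' @inheritParams classical_deflection_fe
#' @param force [force_state()]; `f_hat = 0` is allowed
#' @param form see [effective_confinement_force()]
#' @return dimensionless deficit \eqn{1 - R_\parallel/L}
#' @examples
#' g <- channel_geometry(10, 10); ch <- chain_spec(200, 50)
#' force_confinement_extension(g, ch, force_state(f_hat = 0))  # ~0.0668
#' @export
force_confinement_extension <- function(geom, chain, force,
                                        const = odijk_constants(),
                                        form = c("as_printed", "from_deflection_length")) {
  stopifnot(inherits(force, "force_state"))
  fc <- effective_confinement_force(geom, chain, const, form)$f_hat
  0.5 / sqrt(force$f_hat + fc)
}

#' Force-confinement-extension with a classical deflection length
#'
#' The same additive-force structure as [force_confinement_extension()] but
#' with the effective confinement force taken from a classical deflection
#' length, \eqn{\hat f_c = L_p^2/\lambda^2} with \eqn{\lambda} either
#' [classical_deflection_fe()] or [classical_deflection_ext()]. Provided for
#' comparison against the modified relation in simulation benchmarks.
#'
#' @inheritParams force_confinement_extension
#' @param lambda which classical deflection length supplies the effective force
#' @return dimensionless deficit
#' @export
force_confinement_extension_classical <- function(geom, chain, force,
                                                  const = odijk_constants(),
                                                  lambda = c("fe", "ext")) {
  stopifnot(inherits(force, "force_state"))
  lambda <- match.arg(lambda)
  lam <- switch(lambda,
                fe = classical_deflection_fe(geom, chain, const),
                ext = classical_deflection_ext(geom, chain, const))
  fc <- (chain$Lp / lam)^2
  0.5 / sqrt(force$f_hat + fc)
}

#' Tangent-end projection of a free wormlike chain
#'
#' \eqn{\langle \mathbf r(s_2)\cdot\mathbf u(s_1)\rangle =
#' L_p (1 - e^{-\Delta s/L_p})} for a free chain segment of contour
#' separation \eqn{\Delta s}: the building block of the segment-wise
#' extension estimate behind the modified relations.
#'
#' @param s_gap contour separation, >= 0 (vectorized)
#' @param chain [chain_spec()]
#' @return projection length, same units as `Lp`
#' @export
wlc_tangent_projection <- function(s_gap, chain) {
  stopifnot(inherits(chain, "chain_spec"))
  if (any(s_gap < 0)) stop_domain("'s_gap' must be non-negative")
  chain$Lp * (1 - exp(-s_gap / chain$Lp))
}
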