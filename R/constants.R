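#' Odijk prefactors for rectangular-channel confinement
#'
#' Bundles the two dimensionless literature prefactors of the Odijk deflection
#' laws for rectangular channels: `A_box`, the free-energy prefactor in
#' \eqn{F/k_BT = A \, L\, L_p^{-1/3} (H_h^{-2/3}+H_w^{-2/3})}, and
#' `alpha_box`, the extension prefactor in
#' \eqn{1 - R_\parallel/L = \alpha (\hat H_h^{2/3}+\hat H_w^{2/3})}.
#' The combined constant \eqn{\vartheta = 8 A \alpha} fixes the modified
#' deflection length with no further adjustable parameters; it is derived on
#' construction and cannot be set independently.
#'
#' The defaults are the most precise eigenvalue-method determinations
#' available (A = 1.1032, alpha = 0.09143). Other literature values (e.g.
#' A = 1.1036 or 1.1038, alpha = 0.09137) can be supplied explicitly.
#'
#' @param A_box dimensionless free-energy prefactor, > 0
#' @param alpha_box dimensionless extension prefactor, > 0
#' @return object of class `odijk_constants` with fields `A_box`,
#'   `alpha_box` and `theta = 8 * A_box * alpha_box`
#' @examples
#' const <- odijk_constants()
#' const$theta # 0.80694...
#' @export
odijk_constants <- function(A_box = 1.1032, alpha_box = 0.09143) {
  if (!is.numeric(A_box) || length(A_box) != 1L || !is.finite(A_box) || A_box <= 0)
    stop_domain("'A_box' must be a single positive number")
  if (!is.numeric(alpha_box) || length(alpha_box) != 1L || !is.finite(alpha_box) ||
      alpha_box <= 0)
    stop_domain("'alpha_box' must be a single positive number")
  structure(
    list(A_box = A_box, alpha_box = alpha_box, theta = 8 * A_box * alpha_box),
    class = "odijk_constants"
  )
}

#' @export
print.odijk_constants <- function(x, ...) {
  cat(sprintf("Odijk prefactors: A = %.6g, alpha = %.6g, theta = 8*A*alpha = %.6g\n",
              x$A_box, x$alpha_box, x$theta))
  invisible(x)
}

#' Thermal energy in pN nm
#'
#' @param temperature absolute temperature in kelvin
#' @return \eqn{k_B T} in pN nm
#' @export
kBT_pN_nm <- function(temperature = 293) {
  if (!is.numeric(temperature) || any(temperature <= 0))
    stop_domain("'temperature' must be positive (kelvin)")
  1.380649e-23 * temperature * 1e21  # J -> pN nm
}

## ---- condition helpers (internal) ------------------------------------------

stop_wlctube <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "wlctube_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_domain      <- function(msg, ...) stop_wlctube(msg, "wlctube_domain_error", ...)
stop_validity    <- function(msg, ...) stop_wlctube(msg, "wlctube_validity_error", ...)
stop_config      <- function(msg, ...) stop_wlctube(msg, "wlctube_config_error", ...)
stop_convergence <- function(msg, ...) stop_wlctube(msg, "wlctube_convergence_error", ...)
stop_analysis    <- function(msg, ...) stop_wlctube(msg, "wlctube_analysis_error", ...)
stop_parse       <- function(msg, ...) stop_wlctube(msg, "wlctube_parse_error", ...)
stop_step        <- function(msg, ...) stop_wlctube(msg, "wlctube_step_error", ...)
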