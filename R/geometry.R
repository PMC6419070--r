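#' Rectangular channel cross-section
#'
#' A rectangular tube of height `Hh` (the y span) and width `Hw` (the x span);
#' the chain is stretched and extends along z. A slit is represented as a
#' rectangular tube whose width is much larger than its height, mirroring the
#' way slits are realized numerically (a finite, very large width rather than
#' a true infinity); `Hw = Inf` is also accepted and treated exactly in the
#' closed-form theory. Channel dimensions are the span accessible to bead
#' centers.
#'
#' @param Hh channel height (length units, conventionally nm)
#' @param Hw channel width (same units); may be `Inf`
#' @param kind one of "rectangular", "square", "slit"; inferred when `NULL`
#' @param slit_ratio minimum `Hw/Hh` for a geometry labelled "slit"
#' @return object of class `channel_geometry`
#' @examples
#' channel_geometry(10, 10)           # square tube
#' channel_geometry(15, 20)           # rectangular tube
#' slit_geometry(15)                  # slit, default width 1000 * 50 nm
#' @export
channel_geometry <- function(Hh, Hw, kind = NULL, slit_ratio = 100) {
  if (!is.numeric(Hh) || length(Hh) != 1L || is.na(Hh) || Hh <= 0)
    stop_domain("channel height 'Hh' must be a single positive number")
  if (!is.numeric(Hw) || length(Hw) != 1L || is.na(Hw) || Hw <= 0)
    stop_domain("channel width 'Hw' must be a single positive number")
  ratio <- max(Hw / Hh, Hh / Hw)
  if (is.null(kind)) {
    kind <- if (Hw == Hh) "square" else if (Hw / Hh >= slit_ratio) "slit"
            else "rectangular"
  }
  kind <- match.arg(kind, c("rectangular", "square", "slit"))
  if (kind == "square" && Hh != Hw)
    stop_domain("a square channel requires Hh == Hw")
  if (kind == "slit" && Hw / Hh < slit_ratio)
    stop_domain(sprintf(
      "a slit requires Hw/Hh >= %g (got %.3g); use kind = 'rectangular'",
      slit_ratio, Hw / Hh))
  structure(list(Hh = Hh, Hw = Hw, kind = kind), class = "channel_geometry")
}

#' @rdname channel_geometry
#' @param H slit height
#' @param Lp persistence length used to place the default far wall at
#'   `Hw = Hw_over_Lp * Lp`
#' @param Hw_over_Lp normalized width of the nearly-open direction
#' @export
slit_geometry <- function(H, Lp = 50, Hw_over_Lp = 1000) {
  channel_geometry(Hh = H, Hw = Hw_over_Lp * Lp, kind = "slit")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("%s channel: Hh = %g, Hw = %g (length units)\n",
              x$kind, x$Hh, x$Hw))
  invisible(x)
}

#' Continuous wormlike-chain parameters
#'
#' @param L contour length (length units)
#' @param Lp persistence length (same units); ~50 nm for double-stranded DNA
#' @return object of class `chain_spec`
#' @export
chain_spec <- function(L, Lp = 50) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L <= 0)
    stop_domain("contour length 'L' must be a single positive number")
  if (!is.numeric(Lp) || length(Lp) != 1L || is.na(Lp) || Lp <= 0)
    stop_domain("persistence length 'Lp' must be a single positive number")
  structure(list(L = L, Lp = Lp), class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("wormlike chain: L = %g, Lp = %g (L/Lp = %.3g)\n",
              x$L, x$Lp, x$L / x$Lp))
  invisible(x)
}

#' Axial stretching force
#'
#' Holds the dimensionless force \eqn{\hat f = f_s L_p / k_B T} together with
#' the physical force. Exactly one of `f_hat` and `fs` must be given; the
#' other is derived using `Lp` and `temperature`.
#'
#' @param f_hat dimensionless force, >= 0
#' @param fs physical force in pN
#' @param Lp persistence length in nm used for the conversion
#' @param temperature absolute temperature in kelvin
#' @return object of class `force_state` with fields `f_hat`, `fs`, `Lp`,
#'   `temperature`
#' @examples
#' force_state(f_hat = 25)
#' force_state(fs = 2.02, Lp = 50)   # about f_hat = 25 at 293 K
#' @export
force_state <- function(f_hat = NULL, fs = NULL, Lp = 50, temperature = 293) {
  if (is.null(f_hat) == is.null(fs))
    stop_config("give exactly one of 'f_hat' (dimensionless) or 'fs' (pN)")
  kT <- kBT_pN_nm(temperature)
  if (is.null(f_hat)) {
    if (!is.numeric(fs) || length(fs) != 1L || is.na(fs) || fs < 0)
      stop_domain("'fs' must be a single non-negative number (pN)")
    f_hat <- fs * Lp / kT
  } else {
    if (!is.numeric(f_hat) || length(f_hat) != 1L || is.na(f_hat) || f_hat < 0)
      stop_domain("'f_hat' must be a single non-negative number")
    fs <- f_hat * kT / Lp
  }
  structure(list(f_hat = f_hat, fs = fs, Lp = Lp, temperature = temperature),
            class = "force_state")
}

#' @export
print.force_state <- function(x, ...) {
  cat(sprintf("stretching force: f_hat = %.4g (fs = %.4g pN at T = %g K, Lp = %g nm)\n",
              x$f_hat, x$fs, x$temperature, x$Lp))
  invisible(x)
}

## internal: normalized heights (Hh/Lp, Hw/Lp) with basic checks
hhat <- function(geom, chain) {
  stopifnot(inherits(geom, "channel_geometry"), inherits(chain, "chain_spec"))
  c(hh = geom$Hh / chain$Lp, hw = geom$Hw / chain$Lp)
}
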