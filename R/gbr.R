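#' Discrete bead-rod chain
#'
#' A wormlike chain discretized as `N` beads of hydrodynamic radius `a`
#' joined by `N - 1` rigid rods of length `b`. Bending stiffness enters
#' through the discrete WLC energy \eqn{E/k_BT = (L_p/b)\sum_j(1-\cos\theta_j)}
#' over interior joints, which reproduces persistence length `Lp` for
#' `b << Lp`.
#'
#' @param positions `N x 3` matrix of bead positions (nm); columns x, y, z
#' @param b rod length (nm)
#' @param a bead radius (nm)
#' @param Lp persistence length (nm); must exceed `b`
#' @param tol relative tolerance on the rod lengths of `positions`
#' @return object of class `gbr_chain`
#' @export
gbr_chain <- function(positions, b, a, Lp = 50, tol = 1e-8) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop_domain("'positions' must have 3 columns")
  N <- nrow(positions)
  if (N < 3L) stop_domain("a bead-rod chain needs at least 3 beads")
  if (!is.numeric(b) || b <= 0) stop_domain("rod length 'b' must be positive")
  if (!is.numeric(a) || a <= 0) stop_domain("bead radius 'a' must be positive")
  if (b >= Lp)
    stop_domain("rod length must be well below the persistence length (b < Lp)")
  len <- sqrt(rowSums((positions[-1, , drop = FALSE] -
                       positions[-N, , drop = FALSE])^2))
  if (max(abs(len - b)) > tol * b)
    stop_domain(sprintf("rod lengths deviate from b by up to %.3g (tol %.3g)",
                        max(abs(len - b)) / b, tol))
  structure(list(positions = unname(positions), b = b, a = a, Lp = Lp, N = N),
            class = "gbr_chain")
}

#' @export
print.gbr_chain <- function(x, ...) {
  cat(sprintf("bead-rod chain: N = %d, b = %g nm, a = %g nm, Lp = %g nm (L = %g nm)\n",
              x$N, x$b, x$a, x$Lp, (x$N - 1) * x$b))
  invisible(x)
}

#' Straight initial configuration
#'
#' Beads collinear along the tube axis (z), centered both axially and in the
#' cross-section - the configuration simulations are started from before
#' confinement and tension are switched on.
#'
#' @param N number of beads (>= 3)
#' @param b rod length (nm)
#' @param a bead radius (nm)
#' @param Lp persistence length (nm)
#' @return [gbr_chain()]
#' @export
init_straight_chain <- function(N, b, a = 1.85, Lp = 50) {
  if (N < 3L) stop_domain("'N' must be at least 3")
  if (N > 10000L)
    warning("very long chain (N > 10000); runs will be slow", call. = FALSE)
  z <- (seq_len(N) - 1) * b
  z <- z - mean(z)
  gbr_chain(cbind(0, 0, z), b = b, a = a, Lp = Lp)
}

#' Integrator parameters for GBR Brownian dynamics
#'
#' The printed literature value of the solvent viscosity used with this
#' model family (1.005725e-4 Pa s) is an order of magnitude below tabulated
#' water viscosity at 293 K; because only equilibrium averages are of
#' interest here the choice rescales time without affecting them, and it is
#' kept as the default. Pass `viscosity = 1.005725e-3` (or any value) to
#' work on a physical water timescale.
#'
#' @param dt time step (ps)
#' @param steps number of steps
#' @param seed RNG seed applied at the start of a trajectory (`NULL`: leave
#'   the RNG state alone)
#' @param temperature absolute temperature (K)
#' @param viscosity solvent viscosity (Pa s)
#' @param hydrodynamics "free_draining" (independent beads, default) or
#'   "pairwise_mobility" (far-field pairwise mobility with correlated noise)
#' @param thin record the extension every `thin` steps
#' @param frame_every record full bead positions every so many steps (0: never)
#' @param max_retries per-step redraw attempts when the constraint
#'   projection fails before the step is declared rejected
#' @param rod_tol relative tolerance on rod lengths after projection
#' @param wall_tol absolute tolerance (nm) on wall containment after projection
#' @return object of class `integrator_params`
#' @export
integrator_params <- function(dt, steps, seed = NULL, temperature = 293,
                              viscosity = 1.005725e-4,
                              hydrodynamics = c("free_draining", "pairwise_mobility"),
                              thin = 1L, frame_every = 0L, max_retries = 10L,
                              rod_tol = 1e-10, wall_tol = 1e-9) {
  if (!is.numeric(dt) || dt <= 0) stop_config("'dt' must be positive (ps)")
  if (!is.numeric(steps) || steps < 0) stop_config("'steps' must be >= 0")
  if (!is.numeric(temperature) || temperature <= 0)
    stop_config("'temperature' must be positive (K)")
  if (!is.numeric(viscosity) || viscosity <= 0)
    stop_config("'viscosity' must be positive (Pa s)")
  hydrodynamics <- match.arg(hydrodynamics)
  structure(list(dt = dt, steps = as.integer(steps), seed = seed,
                 temperature = temperature, viscosity = viscosity,
                 hydrodynamics = hydrodynamics, thin = as.integer(thin),
                 frame_every = as.integer(frame_every),
                 max_retries = as.integer(max_retries),
                 rod_tol = rod_tol, wall_tol = wall_tol),
            class = "integrator_params")
}

## Stokes self-diffusion coefficient in nm^2/ps
stokes_diffusion <- function(a_nm, temperature, viscosity) {
  kBT_J <- 1.380649e-23 * temperature
  kBT_J / (6 * pi * viscosity * a_nm * 1e-9) * 1e6   # m^2/s -> nm^2/ps
}

## reduced tension (kBT/nm) carried by a force_state
reduced_tension <- function(force) {
  stopifnot(inherits(force, "force_state"))
  force$fs / kBT_pN_nm(force$temperature)
}

## channel half-spans for the simulator (x: width, y: height)
channel_halfspans <- function(geom) {
  if (is.null(geom)) return(c(w = Inf, h = Inf))
  stopifnot(inherits(geom, "channel_geometry"))
  c(w = geom$Hw / 2, h = geom$Hh / 2)
}

#' Bending forces of the discrete wormlike chain
#'
#' Negative gradient of \eqn{E/k_BT = (L_p/b)\sum_j (1-\cos\theta_j)} in
#' kBT/nm. Total force and torque vanish by translation and rotation
#' invariance of the energy.
#'
#' @param chain [gbr_chain()]
#' @return `N x 3` matrix of forces (kBT/nm)
#' @export
bending_forces <- function(chain) {
  stopifnot(inherits(chain, "gbr_chain"))
  bending_forces_cpp(chain$positions, chain$Lp / chain$b)
}

#' Tension forces on the chain ends
#'
#' Symmetric axial loading: `+fs z` on the last bead and `-fs z` on the
#' first, so the net force vanishes.
#'
#' @param chain [gbr_chain()]
#' @param force [force_state()]
#' @return `N x 3` matrix of forces (kBT/nm)
#' @export
external_forces <- function(chain, force) {
  stopifnot(inherits(chain, "gbr_chain"))
  f <- matrix(0, chain$N, 3)
  fr <- reduced_tension(force)
  f[1L, 3L] <- -fr
  f[chain$N, 3L] <- fr
  f
}

#' Translational diffusion matrix
#'
#' Free-draining: \eqn{D = k_BT/(6\pi\eta a)\, I} (independent beads).
#' Pairwise mobility: the far-field pairwise mobility tensor with
#' Stokes self-blocks, regularized at near contact (r < 2a) so the matrix
#' stays positive definite. Bead-major 3x3 block layout, units nm^2/ps.
#'
#' @param chain [gbr_chain()]
#' @param params [integrator_params()]
#' @return `3N x 3N` symmetric positive-definite matrix
#' @export
diffusion_matrix <- function(chain, params) {
  stopifnot(inherits(chain, "gbr_chain"), inherits(params, "integrator_params"))
  N <- chain$N
  D0 <- stokes_diffusion(chain$a, params$temperature, params$viscosity)
  if (params$hydrodynamics == "free_draining")
    return(diag(D0, 3 * N))
  a <- chain$a
  pos <- chain$positions
  D <- diag(D0, 3 * N)
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      rij <- pos[j, ] - pos[i, ]
      r <- sqrt(sum(rij^2))
      e <- rij / r
      ee <- outer(e, e)
      if (r >= 2 * a) {
        ## far-field pairwise mobility with finite-bead correction
        blk <- D0 * (3 * a / (4 * r)) * ((1 + 2 * a^2 / (3 * r^2)) * diag(3) +
                                         (1 - 2 * a^2 / r^2) * ee)
      } else {
        ## overlap regularization, continuous at r = 2a, PD down to r = 0
        blk <- D0 * ((1 - 9 * r / (32 * a)) * diag(3) + (3 * r / (32 * a)) * ee)
      }
      ii <- (3 * i - 2):(3 * i)
      jj <- (3 * j - 2):(3 * j)
      D[ii, jj] <- blk
      D[jj, ii] <- blk
    }
  }
  ev_min <- min(eigen(D, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0)
    stop_wlctube("diffusion matrix not positive definite (regularization failure)",
                 "wlctube_numerical_error")
  D
}

#' Correlated random displacements
#'
#' Gaussian displacements with zero mean and covariance `2 D dt`, realized
#' through the Cholesky factor of `D`. Draws come from R's RNG, so results
#' are reproducible with `set.seed()`.
#'
#' @param D diffusion matrix (`3N x 3N`, nm^2/ps)
#' @param dt time step (ps)
#' @return `N x 3` matrix of displacements (nm)
#' @export
random_displacements <- function(D, dt) {
  n <- nrow(D)
  Lc <- tryCatch(t(chol(2 * dt * D)), error = function(e)
    stop_wlctube(paste0("Cholesky factorization of the noise covariance failed: ",
                        conditionMessage(e)), "wlctube_numerical_error"))
  xi <- as.numeric(Lc %*% stats::rnorm(n))
  matrix(xi, ncol = 3, byrow = TRUE)    # bead-major blocks -> rows
}

#' Wall penalty displacements
#'
#' For every bead center outside the channel, the displacement that returns
#' it to the nearest wall plane, per coordinate independently; zero for
#' interior beads. The axial coordinate is never modified.
#'
#' @param positions `N x 3` matrix (nm)
#' @param geom [channel_geometry()] or `NULL` for no walls
#' @return `N x 3` matrix of displacements (nm)
#' @export
wall_penalty <- function(positions, geom) {
  hs <- channel_halfspans(geom)
  chi <- matrix(0, nrow(positions), 3)
  if (is.finite(hs[["w"]]))
    chi[, 1] <- pmin(pmax(positions[, 1], -hs[["w"]]), hs[["w"]]) - positions[, 1]
  if (is.finite(hs[["h"]]))
    chi[, 2] <- pmin(pmax(positions[, 2], -hs[["h"]]), hs[["h"]]) - positions[, 2]
  chi
}

#' Project positions back onto the rod-length manifold
#'
#' Realizes the constraint part of the GBR update: a projection built from
#' the tridiagonal Lagrange-multiplier system along the reference bond
#' directions (Newton iteration), followed by iterative correction along
#' current bond directions until every rod length is within `tol` of `b`.
#'
#' @param positions proposed positions (`N x 3`)
#' @param reference constraint-satisfying reference positions whose bond
#'   directions define the projection
#' @param b rod length
#' @param tol relative rod-length tolerance
#' @param newton_max,gs_max iteration caps for the two phases
#' @return corrected `N x 3` matrix
#' @export
constraint_projection <- function(positions, reference, b, tol = 1e-10,
                                  newton_max = 12L, gs_max = 60L) {
  out <- project_rods_cpp(as.matrix(positions), as.matrix(reference), b,
                          tol, newton_max, gs_max)
  len <- sqrt(rowSums((out[-1, , drop = FALSE] - out[-nrow(out), , drop = FALSE])^2))
  if (max(abs(len - b)) > tol * b)
    stop_step(sprintf(
      "constraint projection failed to converge (max rod error %.3g); reduce dt",
      max(abs(len - b)) / b))
  out
}

#' One GBR Brownian dynamics step
#'
#' Composes the update in the order: unconstrained displacement (wall
#' penalty of the current positions, deterministic drift `dt D F / kBT`,
#' Gaussian displacement with covariance `2 D dt`), then wall clamping
#' alternated with rod-constraint projection until both the constraints and
#' containment hold. If the projection cannot be converged the step is
#' redrawn (up to `params$max_retries`), then an error of class
#' `wlctube_step_error` is raised suggesting a smaller `dt`.
#'
#' @param chain [gbr_chain()]
#' @param geom [channel_geometry()] or `NULL` (no walls)
#' @param force [force_state()]
#' @param params [integrator_params()]
#' @return updated [gbr_chain()]
#' @export
gbr_step <- function(chain, geom, force, params) {
  stopifnot(inherits(chain, "gbr_chain"), inherits(params, "integrator_params"))
  N <- chain$N
  hs <- channel_halfspans(geom)
  free_drain <- params$hydrodynamics == "free_draining"
  D0 <- stokes_diffusion(chain$a, params$temperature, params$viscosity)
  if (!free_drain) D <- diffusion_matrix(chain, params)
  Fmat <- bending_forces(chain) + external_forces(chain, force)
  r <- chain$positions
  for (att in 0:params$max_retries) {
    if (free_drain) {
      xi <- matrix(stats::rnorm(3 * N), N, 3) * sqrt(2 * D0 * params$dt)
      drift <- params$dt * D0 * Fmat
    } else {
      xi <- random_displacements(D, params$dt)
      drift <- params$dt * matrix(as.numeric(D %*% as.numeric(t(Fmat))),
                                  ncol = 3, byrow = TRUE)
    }
    rnew <- r + wall_penalty(r, geom) + drift + xi
    ok <- FALSE
    for (w in 1:100) {
      if (is.finite(hs[["w"]]))
        rnew[, 1] <- pmin(pmax(rnew[, 1], -hs[["w"]]), hs[["w"]])
      if (is.finite(hs[["h"]]))
        rnew[, 2] <- pmin(pmax(rnew[, 2], -hs[["h"]]), hs[["h"]])
      rnew <- project_rods_cpp(rnew, r, chain$b, params$rod_tol, 12L, 60L)
      viol <- max(c(0, abs(rnew[, 1]) - hs[["w"]], abs(rnew[, 2]) - hs[["h"]]),
                  na.rm = TRUE)
      len <- sqrt(rowSums((rnew[-1, , drop = FALSE] -
                           rnew[-N, , drop = FALSE])^2))
      if (max(abs(len - chain$b)) <= params$rod_tol * chain$b &&
          viol <= params$wall_tol) { ok <- TRUE; break }
      if (max(abs(len - chain$b)) > params$rod_tol * chain$b) break
    }
    if (ok) {
      chain$positions <- rnew
      return(chain)
    }
  }
  stop_step("GBR step rejected repeatedly (constraint projection failed); reduce dt")
}

#' Run a GBR Brownian dynamics trajectory
#'
#' Iterates [gbr_step()], recording the axial end-to-end extension
#' `z_N - z_1` every `params$thin` steps. Free-draining runs use a compiled
#' fast path that draws from the same RNG stream in the same order as the R
#' step, so a trajectory is fully reproducible from `params$seed` (and a
#' single step agrees bitwise with [gbr_step()]). Pairwise-mobility runs
#' step in R and are intended for short validation runs.
#'
#' @param chain initial [gbr_chain()] (constraints must hold)
#' @param geom [channel_geometry()] or `NULL` for a free chain
#' @param force [force_state()]
#' @param params [integrator_params()]
#' @return object of class `wlc_trajectory`: `extension` series (nm),
#'   sampling interval `dt_sample = dt * thin` (ps), provenance (`seed`,
#'   parameter snapshot), optional `frames` array, and run diagnostics
#'   (`max_rod_err`, `max_wall_violation`, `n_rejected`)
#' @export
run_trajectory <- function(chain, geom = NULL, force = force_state(f_hat = 0),
                           params) {
  stopifnot(inherits(chain, "gbr_chain"), inherits(params, "integrator_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  hs <- channel_halfspans(geom)
  if (params$hydrodynamics == "free_draining") {
    D0 <- stokes_diffusion(chain$a, params$temperature, params$viscosity)
    res <- gbr_run_cpp(chain$positions, chain$b, chain$Lp / chain$b,
                       reduced_tension(force),
                       params$dt * D0, sqrt(2 * D0 * params$dt),
                       params$steps, hs[["w"]], hs[["h"]],
                       params$rod_tol, 12L, 60L, 100L, params$wall_tol,
                       params$max_retries, params$thin, params$frame_every)
    if (res$failed_step > 0)
      stop_step(sprintf(
        "GBR step %d rejected repeatedly (constraint projection failed); reduce dt",
        res$failed_step))
    frames <- NULL
    if (res$n_frames > 0)
      frames <- array(res$frames[seq_len(res$n_frames * chain$N * 3)],
                      dim = c(chain$N, 3, res$n_frames))
    ext <- as.numeric(res$extension)
    final <- res$positions
    diag_info <- list(max_rod_err = res$max_rod_err,
                      max_wall_violation = res$max_wall_violation,
                      n_rejected = res$n_rejected)
  } else {
    nrec <- if (params$thin > 0) params$steps %/% params$thin else 0L
    ext <- numeric(nrec)
    nfr <- if (params$frame_every > 0) params$steps %/% params$frame_every else 0L
    frames <- if (nfr > 0) array(NA_real_, dim = c(chain$N, 3, nfr)) else NULL
    irec <- 0L; ifr <- 0L
    cur <- chain
    max_rod <- 0; max_wall <- 0
    if (params$steps > 0) for (s in seq_len(params$steps)) {
      cur <- gbr_step(cur, geom, force, params)
      len <- sqrt(rowSums((cur$positions[-1, , drop = FALSE] -
                           cur$positions[-chain$N, , drop = FALSE])^2))
      max_rod <- max(max_rod, max(abs(len - chain$b)) / chain$b)
      max_wall <- max(max_wall, 0,
                      abs(cur$positions[, 1]) - hs[["w"]],
                      abs(cur$positions[, 2]) - hs[["h"]], na.rm = TRUE)
      if (params$thin > 0 && s %% params$thin == 0) {
        irec <- irec + 1L
        ext[irec] <- cur$positions[chain$N, 3] - cur$positions[1, 3]
      }
      if (params$frame_every > 0 && s %% params$frame_every == 0) {
        ifr <- ifr + 1L
        frames[, , ifr] <- cur$positions
      }
    }
    final <- cur$positions
    diag_info <- list(max_rod_err = max_rod, max_wall_violation = max_wall,
                      n_rejected = NA_integer_)
  }
  structure(list(extension = ext, dt_sample = params$dt * params$thin,
                 L = (chain$N - 1) * chain$b,
                 seed = params$seed, params = params,
                 chain = list(N = chain$N, b = chain$b, a = chain$a,
                              Lp = chain$Lp),
                 geom = geom, force = list(f_hat = force$f_hat, fs = force$fs),
                 frames = frames, final_positions = final,
                 diagnostics = diag_info),
            class = "wlc_trajectory")
}

#' @export
print.wlc_trajectory <- function(x, ...) {
  cat(sprintf("GBR trajectory: %d recorded extensions (dt_sample = %g ps), L = %g nm\n",
              length(x$extension), x$dt_sample, x$L))
  if (length(x$extension))
    cat(sprintf("  relative extension: mean %.4f, last %.4f\n",
                mean(x$extension) / x$L, x$extension[length(x$extension)] / x$L))
  cat(sprintf("  max rod error %.2e, max wall violation %.2e, seed %s\n",
              x$diagnostics$max_rod_err, x$diagnostics$max_wall_violation,
              if (is.null(x$seed)) "unset" else format(x$seed)))
  invisible(x)
}

#' @export
plot.wlc_trajectory <- function(x, ...) {
  t_ns <- seq_along(x$extension) * x$dt_sample / 1000
  plot(t_ns, x$extension / x$L, type = "l", xlab = "time (ns)",
       ylab = expression(R[parallel] / L), ...)
  invisible(x)
}
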