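#' Detect the equilibrated portion of an extension series
#'
#' Splits the series into `n_windows` windows and compares, for each
#' window, the forward running mean (from that window to the end) against
#' the mean of the final half of the series, on the scale of the standard
#' error implied by the scatter of adjacent window-mean differences. The
#' burn-in is the start of the first window whose forward mean enters that
#' band and stays near the final-half mean for the rest of the series;
#' resolution is therefore one window, and a series with a persistent
#' drift is reported as not equilibrated.
#'
#' @param series numeric vector (extension samples in time order)
#' @param n_windows number of windows used for the scan
#' @param min_length minimum usable series length
#' @return list with `burn_in` (number of leading samples to discard),
#'   `equilibrated` (logical), `window` (window size in samples)
#' @export
detect_equilibration <- function(series, n_windows = 20L, min_length = 40L) {
  n <- length(series)
  if (n < max(min_length, 2L * n_windows))
    stop_analysis(sprintf("series too short for equilibration detection (%d < %d)",
                          n, max(min_length, 2L * n_windows)))
  w <- n %/% n_windows
  K <- n_windows
  idx <- rep(seq_len(K), each = w)
  wm <- tapply(series[seq_len(K * w)], idx, mean)
  m_f <- mean(series[(n %/% 2 + 1L):n])
  ## window-mean noise scale from differences of adjacent window means:
  ## a smooth drift leaves the differences (hence the band) small and is
  ## flagged, while genuine noise is estimated without trend inflation
  s_w <- stats::sd(diff(wm)) / sqrt(2)
  ## forward running mean from each window, on the scale of its own SE
  dev <- se <- numeric(K)
  for (k in seq_len(K)) {
    dev[k] <- abs(mean(series[((k - 1L) * w + 1L):n]) - m_f)
    se[k] <- s_w / sqrt(K - k + 1L)
  }
  ## enter within 2 SE and stay within 3 SE for the rest of the series
  ## (the wider band keeps short late stretches, whose own SE is large,
  ## from vetoing a genuinely stationary series)
  stays <- rev(cumprod(rev(dev <= 3 * se + .Machine$double.eps))) > 0
  ok <- (dev <= 2 * se + .Machine$double.eps) & stays
  pass <- which(ok)
  if (length(pass) == 0L)
    return(list(burn_in = n, equilibrated = FALSE, window = w))
  list(burn_in = (pass[1L] - 1L) * w, equilibrated = TRUE, window = w)
}

#' Equilibrated mean relative extension of a trajectory ensemble
#'
#' Two-stage averaging: within each trajectory the extension is averaged
#' over time after discarding its burn-in (the larger of the detected
#' burn-in and a conservative floor of 10% of the series); across
#' trajectories the per-trajectory means are averaged and their scatter
#' gives the standard error. Trajectories are the independent units -
#' time samples within a trajectory are autocorrelated and carry no valid
#' per-sample error. Unequilibrated trajectories are excluded with a
#' warning.
#'
#' @param trajectories list of [run_trajectory()] results (>= 2)
#' @param burn_in_floor minimum fraction of each series discarded
#' @param ... passed to [detect_equilibration()]
#' @return object of class `extension_estimate` with fields
#'   `mean_rel_extension`, `std_error`, `n_traj`, `burn_in_steps`,
#'   `equilibrated`, `per_trajectory`
#' @export
average_extension <- function(trajectories, burn_in_floor = 0.1, ...) {
  if (!is.list(trajectories) || length(trajectories) < 2L)
    stop_analysis("need at least 2 trajectories")
  if (!all(vapply(trajectories, inherits, logical(1), "wlc_trajectory")))
    stop_analysis("'trajectories' must be run_trajectory() results")
  L <- unique(vapply(trajectories, `[[`, numeric(1), "L"))
  if (length(L) != 1L)
    stop_analysis("trajectories have inconsistent contour lengths")
  means <- numeric(0)
  burns <- integer(0)
  dropped <- 0L
  for (tr in trajectories) {
    eq <- detect_equilibration(tr$extension, ...)
    if (!eq$equilibrated) {
      dropped <- dropped + 1L
      next
    }
    burn <- max(eq$burn_in, floor(burn_in_floor * length(tr$extension)))
    means <- c(means, mean(tr$extension[(burn + 1L):length(tr$extension)]))
    burns <- c(burns, burn)
  }
  if (dropped > 0L)
    warning(sprintf("%d unequilibrated trajectorie(s) excluded", dropped),
            call. = FALSE)
  if (length(means) < 2L)
    stop_analysis("fewer than 2 equilibrated trajectories remain")
  structure(list(
    mean_rel_extension = mean(means) / L,
    std_error = stats::sd(means) / sqrt(length(means)) / L,
    n_traj = length(means),
    burn_in_steps = burns,
    equilibrated = TRUE,
    per_trajectory = means / L,
    L = L
  ), class = "extension_estimate")
}

#' @export
print.extension_estimate <- function(x, ...) {
  cat(sprintf(
    "mean relative extension R||/L = %.5f +- %.5f (SE over %d trajectories)\n",
    x$mean_rel_extension, x$std_error, x$n_traj))
  cat(sprintf("  deficit 1 - R||/L = %.5f, burn-in %s samples\n",
              1 - x$mean_rel_extension,
              paste(range(x$burn_in_steps), collapse = "-")))
  invisible(x)
}

#' Simulation-theory comparison table
#'
#' One row per (geometry, force) condition: the simulated extension deficit
#' with its standard error next to the three closed-form predictions - the
#' modified force-confinement-extension relation and the additive-force
#' relation evaluated with each classical deflection length - plus relative
#' errors of each prediction against the simulation.
#'
#' @param estimates list of [average_extension()] results
#' @param geoms list of [channel_geometry()], parallel to `estimates`
#' @param forces list of [force_state()], parallel to `estimates`
#' @param chain [chain_spec()] describing the simulated chains
#' @param const [odijk_constants()]
#' @return `data.frame` of class `wlc_comparison`
#' @export
build_comparison <- function(estimates, geoms, forces, chain,
                             const = odijk_constants()) {
  k <- length(estimates)
  if (length(geoms) != k || length(forces) != k || k == 0L)
    stop_analysis("'estimates', 'geoms' and 'forces' must be non-empty and matched")
  rows <- lapply(seq_len(k), function(i) {
    est <- estimates[[i]]; g <- geoms[[i]]; f <- forces[[i]]
    stopifnot(inherits(est, "extension_estimate"),
              inherits(g, "channel_geometry"), inherits(f, "force_state"))
    sim <- 1 - est$mean_rel_extension
    thr_mod <- force_confinement_extension(g, chain, f, const)
    thr_fe <- force_confinement_extension_classical(g, chain, f, const, "fe")
    thr_ext <- tryCatch(
      force_confinement_extension_classical(g, chain, f, const, "ext"),
      wlctube_domain_error = function(e) NA_real_)
    data.frame(
      kind = g$kind,
      Hh_over_Lp = g$Hh / chain$Lp, Hw_over_Lp = g$Hw / chain$Lp,
      f_hat = f$f_hat,
      sim_deficit = sim, sim_se = est$std_error, n_traj = est$n_traj,
      deficit_modified = thr_mod,
      deficit_classical_fe = thr_fe,
      deficit_classical_ext = thr_ext,
      rel_err_modified = abs(thr_mod - sim) / sim,
      rel_err_classical_fe = abs(thr_fe - sim) / sim,
      rel_err_classical_ext = abs(thr_ext - sim) / sim
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("wlc_comparison", "data.frame")
  out
}

#' Aggregate prediction errors of a comparison table
#'
#' Mean absolute relative error of each theory column across the rows of a
#' [build_comparison()] table (rows with an unavailable prediction are
#' dropped for that column only).
#'
#' @param tbl [build_comparison()] result
#' @return named numeric vector (`modified`, `classical_fe`, `classical_ext`)
#' @export
comparison_error_summary <- function(tbl) {
  stopifnot(inherits(tbl, "wlc_comparison"))
  c(modified = mean(tbl$rel_err_modified, na.rm = TRUE),
    classical_fe = mean(tbl$rel_err_classical_fe, na.rm = TRUE),
    classical_ext = mean(tbl$rel_err_classical_ext, na.rm = TRUE))
}
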