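## shared fixtures for the test suite

kk <- odijk_constants()          # default prefactors
Lp0 <- 50

sq_geom <- function(hhat, Lp = Lp0) channel_geometry(hhat * Lp, hhat * Lp)

## fabricate a minimal trajectory object for analysis tests
fake_traj <- function(extension, L = 100, dt_sample = 1) {
  structure(list(extension = extension, dt_sample = dt_sample, L = L,
                 seed = NA, params = NULL, chain = NULL, geom = NULL,
                 force = NULL, frames = NULL, final_positions = NULL,
                 diagnostics = list(max_rod_err = 0, max_wall_violation = 0,
                                    n_rejected = 0)),
            class = "wlc_trajectory")
}

## discrete-WLC bending energy, independent of the package force code
bend_energy <- function(pos, kappa) {
  u <- diff(pos)
  u <- u / sqrt(rowSums(u^2))
  nb <- nrow(u)
  kappa * sum(1 - rowSums(u[-nb, , drop = FALSE] * u[-1, , drop = FALSE]))
}

## central-difference gradient of the bending energy
bend_force_fd <- function(pos, kappa, h = 1e-6) {
  Ffd <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) for (c in 1:3) {
    p1 <- pos; p1[i, c] <- p1[i, c] + h
    p2 <- pos; p2[i, c] <- p2[i, c] - h
    Ffd[i, c] <- -(bend_energy(p1, kappa) - bend_energy(p2, kappa)) / (2 * h)
  }
  Ffd
}
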