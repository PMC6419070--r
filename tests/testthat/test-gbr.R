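## Bead-rod Brownian dynamics: forces, constraints, walls, stepping.

test_that("straight chain initialization satisfies every constraint exactly", {
  ch <- init_straight_chain(3, 2)
  expect_equal(ch$positions[, 3], c(-2, 0, 2))
  expect_true(all(ch$positions[, 1:2] == 0))
  ch <- init_straight_chain(25, 4)
  len <- sqrt(rowSums(diff(ch$positions)^2))
  expect_identical(max(abs(len - 4)), 0)
  expect_equal(ch$positions[25, 3] - ch$positions[1, 3], 24 * 4)
  expect_error(init_straight_chain(2, 1), class = "wlctube_domain_error")
  expect_error(gbr_chain(matrix(rnorm(9), 3), b = 60, a = 1, Lp = 50),
               class = "wlctube_domain_error")
})

test_that("bending forces: zero on straight chains, match finite differences", {
  ch <- init_straight_chain(10, 4)
  expect_true(all(bending_forces(ch) == 0))
  ## right angle, Lp/b = 25
  pos <- rbind(c(0, 0, 0), c(0, 0, 2), c(2, 0, 2))
  ch <- gbr_chain(pos, b = 2, a = 1, Lp = 50)
  Fb <- bending_forces(ch)
  expect_equal(Fb, bend_force_fd(pos, 25), tolerance = 1e-6)
  ## random bent configurations: gradient check + zero net force and torque
  set.seed(4)
  for (rep in 1:3) {
    ch <- sample_equilibrium_wlc(wlc_sampler(8, 5, Lp = 50))
    Fb <- bending_forces(ch)
    expect_equal(Fb, bend_force_fd(ch$positions, 10), tolerance = 1e-5)
    expect_lt(max(abs(colSums(Fb))), 1e-10)
    tau <- colSums(cbind(
      ch$positions[, 2] * Fb[, 3] - ch$positions[, 3] * Fb[, 2],
      ch$positions[, 3] * Fb[, 1] - ch$positions[, 1] * Fb[, 3],
      ch$positions[, 1] * Fb[, 2] - ch$positions[, 2] * Fb[, 1]))
    expect_lt(max(abs(tau)), 1e-10)
  }
})

test_that("tension acts on the end beads only, with zero net force", {
  ch <- init_straight_chain(7, 4)
  expect_true(all(external_forces(ch, force_state(f_hat = 0)) == 0))
  Fe <- external_forces(ch, force_state(f_hat = 25, Lp = 50))
  expect_equal(colSums(Fe), c(0, 0, 0))
  expect_true(all(Fe[2:6, ] == 0))
  ## f_hat = fs Lp / kBT at T = 293 K: 25 <-> about 2.02 pN for Lp = 50 nm
  fs <- force_state(f_hat = 25, Lp = 50)
  expect_equal(fs$fs, 25 * 1.380649e-23 * 293 * 1e21 / 50, tolerance = 1e-12)
  expect_equal(fs$fs, 2.0227, tolerance = 1e-4)
  expect_equal(Fe[7, 3], 25 / 50, tolerance = 1e-12)  # kBT/nm
})

test_that("diffusion matrix: Stokes diagonal and SPD pairwise mobility", {
  p_fd <- integrator_params(dt = 10, steps = 1)
  ch <- init_straight_chain(5, 4, a = 1.85)
  D <- diffusion_matrix(ch, p_fd)
  D0 <- 1.380649e-23 * 293 / (6 * pi * 1.005725e-4 * 1.85e-9) * 1e6
  expect_true(all(abs(diag(D) - D0) < 1e-12 * D0))
  expect_true(all(D[upper.tri(D)] == 0))
  p_hi <- integrator_params(dt = 10, steps = 1, hydrodynamics = "pairwise_mobility")
  set.seed(9)
  ch <- sample_equilibrium_wlc(wlc_sampler(8, 6, Lp = 50, a = 1.5))
  Dh <- diffusion_matrix(ch, p_hi)
  expect_equal(Dh, t(Dh), tolerance = 1e-12)
  expect_gt(min(eigen(Dh, symmetric = TRUE, only.values = TRUE)$values), 0)
  ## off-diagonal coupling present and weaker than self-mobility
  expect_gt(max(abs(Dh[1:3, 4:6])), 0)
  expect_lt(max(abs(Dh[1:3, 4:6])), Dh[1, 1])
})

test_that("random displacements realize covariance 2 D dt and are seeded", {
  D0 <- 0.002
  D <- diag(D0, 6)
  set.seed(11)
  draws <- t(replicate(30000, as.numeric(t(random_displacements(D, 5)))))
  S <- cov(draws)
  target <- 2 * D0 * 5
  se <- target * sqrt(2 / nrow(draws))
  expect_true(all(abs(diag(S) - target) < 3 * se))
  expect_lt(max(abs(S[upper.tri(S)])), 3 * target / sqrt(nrow(draws)))
  set.seed(21); x1 <- random_displacements(D, 5)
  set.seed(21); x2 <- random_displacements(D, 5)
  expect_identical(x1, x2)
})

test_that("wall penalty clamps per coordinate and never touches z", {
  g <- channel_geometry(Hh = 6, Hw = 10)
  pos <- rbind(c(0, 0, 5), c(6, 0, -3), c(6.5, -4.2, 7))
  chi <- wall_penalty(pos, g)
  expect_equal(chi[1, ], c(0, 0, 0))
  expect_equal(chi[2, ], c(-1, 0, 0))          # x = Hw/2 + 1 -> back to the plane
  expect_equal(chi[3, ], c(-1.5, 1.2, 0))      # corner: both coordinates clamped
  expect_true(all(chi[, 3] == 0))
  expect_true(all(wall_penalty(pos, NULL) == 0))
})

test_that("constraint projection restores rod lengths without drift", {
  ## already on the manifold: unchanged
  ch <- init_straight_chain(12, 3)
  out <- constraint_projection(ch$positions, ch$positions, 3)
  expect_lt(max(abs(out - ch$positions)), 1e-12)
  ## two beads stretched by 10%: restored, midpoint preserved
  two <- rbind(c(0, 0, 0), c(0, 0, 2.2))
  ref <- rbind(c(0, 0, 0), c(0, 0, 2))
  out <- constraint_projection(two, ref, 2)
  expect_equal(out[2, 3] - out[1, 3], 2, tolerance = 1e-10)
  expect_equal(colMeans(out), colMeans(two), tolerance = 1e-12)
  ## random perturbations across chain lengths
  set.seed(5)
  for (N in c(6, 40, 120)) {
    ch <- sample_equilibrium_wlc(wlc_sampler(N, 4, Lp = 50))
    pert <- ch$positions + matrix(rnorm(3 * N), N, 3) * 0.15
    out <- constraint_projection(pert, ch$positions, 4)
    len <- sqrt(rowSums(diff(out)^2))
    expect_lt(max(abs(len - 4)) / 4, 1e-10)
  }
})

test_that("stepping: near-zero mobility fixed point, determinism, stretch drift", {
  geo <- channel_geometry(20, 20)
  f0 <- force_state(f_hat = 0)
  ## vanishing diffusion (enormous viscosity): straight interior chain is a
  ## fixed point of the update
  ch <- init_straight_chain(9, 4)
  p_frozen <- integrator_params(dt = 10, steps = 1, viscosity = 1e30)
  set.seed(1)
  ch1 <- gbr_step(ch, geo, f0, p_frozen)
  expect_lt(max(abs(ch1$positions - ch$positions)), 1e-10)
  ## identical seeds give identical trajectories
  p <- integrator_params(dt = 10, steps = 50, seed = 123, thin = 1)
  t1 <- run_trajectory(init_straight_chain(11, 4), geo, f0, p)
  t2 <- run_trajectory(init_straight_chain(11, 4), geo, f0, p)
  expect_identical(t1$extension, t2$extension)
  expect_identical(t1$final_positions, t2$final_positions)
  ## a single compiled step reproduces the R step bitwise
  p1 <- integrator_params(dt = 10, steps = 1, seed = 42, thin = 1)
  tr <- run_trajectory(init_straight_chain(11, 4), geo, force_state(f_hat = 5), p1)
  set.seed(42)
  chR <- gbr_step(init_straight_chain(11, 4), geo, force_state(f_hat = 5), p1)
  expect_identical(tr$final_positions, chR$positions)
  ## strong stretching pulls a coiled free chain toward full extension
  set.seed(8)
  coil <- sample_equilibrium_wlc(wlc_sampler(21, 4, Lp = 50))
  ext0 <- coil$positions[21, 3] - coil$positions[1, 3]
  tr <- run_trajectory(coil, NULL, force_state(f_hat = 80),
                       integrator_params(dt = 10, steps = 4000, seed = 3, thin = 10))
  expect_gt(mean(tail(tr$extension, 50)), 0.85 * 20 * 4)
  expect_gt(mean(tail(tr$extension, 50)), ext0)
})

test_that("trajectories keep rods fixed and beads inside the channel", {
  geo <- channel_geometry(10, 15)
  p <- integrator_params(dt = 10, steps = 4000, seed = 31, thin = 10,
                         frame_every = 500)
  tr <- run_trajectory(init_straight_chain(26, 4), geo, force_state(f_hat = 2), p)
  expect_lte(tr$diagnostics$max_rod_err, 1e-10)
  expect_lte(tr$diagnostics$max_wall_violation, 1e-9)
  expect_true(all(abs(tr$frames[, 1, ]) <= 7.5 + 1e-9))
  expect_true(all(abs(tr$frames[, 2, ]) <= 5 + 1e-9))
  expect_true(all(tr$extension <= 25 * 4 + 1e-9))
  ## empty run is permitted
  p0 <- integrator_params(dt = 10, steps = 0)
  tr0 <- run_trajectory(init_straight_chain(5, 4), geo, force_state(f_hat = 0), p0)
  expect_length(tr0$extension, 0)
})

test_that("equilibrium means are insensitive to the hydrodynamics model", {
  ## short stretched chains, identical conditions, the two mobility models
  f <- force_state(f_hat = 15)
  mean_ext <- function(model, seed) {
    p <- integrator_params(dt = 20, steps = 4000, seed = seed, thin = 5,
                           hydrodynamics = model)
    tr <- run_trajectory(init_straight_chain(6, 5, a = 2), NULL, f, p)
    mean(tr$extension[200:800])
  }
  fd <- sapply(1:3, function(s) mean_ext("free_draining", 100 + s))
  hi <- sapply(1:3, function(s) mean_ext("pairwise_mobility", 200 + s))
  se <- sqrt(var(fd) / 3 + var(hi) / 3)
  expect_lt(abs(mean(fd) - mean(hi)), 3 * se + 1e-8)
})

test_that("adjacent-bond statistics relax to the discrete-WLC Boltzmann law", {
  ## free chain started from equilibrium stays at the exact mean cosine
  set.seed(14)
  p <- integrator_params(dt = 10, steps = 8000, thin = 10, frame_every = 1000)
  cosbar <- replicate(4, {
    ch0 <- sample_equilibrium_wlc(wlc_sampler(51, 4, Lp = 50, a = 1.85))
    tr <- run_trajectory(ch0, NULL, force_state(f_hat = 0), p)
    mean(apply(tr$frames, 3, function(pos) tangent_correlation(pos, 1)))
  })
  target <- discrete_wlc_mean_cos(50 / 4)
  expect_lt(abs(mean(cosbar) - target), 3 * sd(cosbar) / 2 + 0.004)
})
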