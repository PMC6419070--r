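## Closed-form deflection lengths, free energies and extension relations.
## Frozen values are direct evaluations of the printed formulas at the
## default prefactors A = 1.1032, alpha = 0.09143 (theta = 0.80692448).

test_that("constants object enforces its invariants", {
  k <- odijk_constants()
  expect_equal(k$theta, 8 * 1.1032 * 0.09143)
  expect_error(odijk_constants(A_box = -1), class = "wlctube_domain_error")
  expect_error(odijk_constants(alpha_box = 0), class = "wlctube_domain_error")
  ## alternative literature row selectable
  k2 <- odijk_constants(1.1038, 0.09137)
  expect_equal(k2$theta, 8 * 1.1038 * 0.09137)
})

test_that("geometry and chain constructors validate their domains", {
  expect_error(channel_geometry(-1, 5), class = "wlctube_domain_error")
  expect_error(channel_geometry(5, 0), class = "wlctube_domain_error")
  expect_error(channel_geometry(5, 6, kind = "square"), class = "wlctube_domain_error")
  expect_error(channel_geometry(5, 6, kind = "slit"), class = "wlctube_domain_error")
  expect_identical(channel_geometry(5, 5)$kind, "square")
  expect_identical(channel_geometry(5, 1000)$kind, "slit")
  expect_identical(slit_geometry(10, Lp = 50)$Hw, 50000)
  expect_error(chain_spec(-2), class = "wlctube_domain_error")
  expect_error(force_state(f_hat = -1), class = "wlctube_domain_error")
  expect_error(force_state(), class = "wlctube_config_error")
  expect_error(force_state(f_hat = 1, fs = 1), class = "wlctube_config_error")
})

test_that("classical deflection lengths reproduce direct evaluations", {
  ch <- chain_spec(200, Lp0)
  g <- sq_geom(0.2)
  expect_equal(classical_deflection_fe(g, ch, kk) / Lp0,
               1 / (1.1032 * 2 * 0.2^(-2 / 3)), tolerance = 1e-12)
  expect_equal(classical_deflection_fe(g, ch, kk) / Lp0, 0.1550014,
               tolerance = 1e-6)
  expect_equal(classical_deflection_ext(g, ch, kk) / Lp0,
               2 * 0.09143 * 2 * 0.2^(2 / 3), tolerance = 1e-12)
  ## symmetry under (Hh, Hw) swap
  g1 <- channel_geometry(10, 25)
  g2 <- channel_geometry(25, 10)
  expect_equal(classical_deflection_fe(g1, ch, kk),
               classical_deflection_fe(g2, ch, kk))
  expect_equal(classical_deflection_ext(g1, ch, kk),
               classical_deflection_ext(g2, ch, kk))
  ## slit limit: lambda_fe -> (1/A) Lp^(1/3) H^(2/3)
  gs <- channel_geometry(0.1 * Lp0, Inf)
  expect_equal(classical_deflection_fe(gs, ch, kk),
               Lp0 / 1.1032 * 0.1^(2 / 3), tolerance = 1e-12)
  ## lambda_ext has no slit limit: the wide-direction term dominates
  expect_error(classical_deflection_ext(gs, ch, kk), class = "wlctube_domain_error")
  g_wide <- channel_geometry(0.1 * Lp0, 1000 * Lp0)
  lam <- classical_deflection_ext(g_wide, ch, kk)
  expect_gt(2 * 0.09143 * Lp0 * 1000^(2 / 3) / lam, 0.99)
  ## lambda_ext -> 0 monotonically with the channel
  lams <- sapply(c(0.2, 0.1, 0.05, 0.02), function(h)
    classical_deflection_ext(sq_geom(h), ch, kk))
  expect_true(all(diff(lams) < 0))
})

test_that("modified deflection length: value, Taylor limit, domain boundary", {
  ch <- chain_spec(200, Lp0)
  g <- sq_geom(0.2)
  eps <- kk$theta / (1.1032 * 2 * 0.2^(-2 / 3))
  expect_equal(modified_deflection(g, ch, kk) / Lp0, -log(1 - eps) / kk$theta,
               tolerance = 1e-12)
  expect_equal(modified_deflection(g, ch, kk) / Lp0, 0.1655874, tolerance = 1e-6)
  ## always exceeds the classical length on the validity domain
  for (h in c(0.02, 0.1, 0.3, 1)) {
    gg <- sq_geom(h)
    expect_gt(modified_deflection(gg, ch, kk),
              classical_deflection_fe(gg, ch, kk))
  }
  ## Taylor reduction as the channel tightens
  ratio <- function(h) {
    gg <- sq_geom(h)
    modified_deflection(gg, ch, kk) / classical_deflection_fe(gg, ch, kk)
  }
  ## leading-order gap is eps/2 (~8.6e-3 at H = 0.01 Lp)
  eps01 <- kk$theta / (1.1032 * 2 * 0.01^(-2 / 3))
  expect_lt(abs(ratio(0.01) - 1), eps01)
  expect_equal(ratio(0.01) - 1, eps01 / 2, tolerance = 2e-2)
  expect_lt(abs(ratio(0.001) - 1), abs(ratio(0.01) - 1))
  ## outside the validity domain: typed error naming the bound
  g_wide <- sq_geom(5.6)
  expect_false(validity_check(g_wide, ch, kk)$ok)
  err <- tryCatch(modified_deflection(g_wide, ch, kk), condition = identity)
  expect_s3_class(err, "wlctube_validity_error")
  expect_match(conditionMessage(err), "theta/A")
})

test_that("validity check reports the documented margins", {
  ch <- chain_spec(200, Lp0)
  v <- validity_check(sq_geom(0.2), ch, kk)
  expect_true(v$ok)
  expect_equal(v$lhs, 2 * 0.2^(-2 / 3), tolerance = 1e-12)
  expect_equal(v$bound, kk$theta / kk$A_box, tolerance = 1e-12)
  expect_false(validity_check(sq_geom(5.6), ch, kk)$ok)
  expect_true(validity_check(channel_geometry(0.6 * Lp0, 1000 * Lp0), ch, kk)$ok)
})

test_that("free energies: consistency chain, extensivity, ordering", {
  ch <- chain_spec(200, Lp0)
  ## slit H = 0.1 Lp classical value
  gs <- channel_geometry(0.1 * Lp0, Inf)
  expect_equal(free_energy_classical(chain_spec(Lp0, Lp0), gs, kk),
               1.1032 * 0.1^(-2 / 3), tolerance = 1e-12)
  ## rectangular = sum of the two slit contributions
  g <- channel_geometry(10, 25)
  s1 <- channel_geometry(10, Inf)
  s2 <- channel_geometry(25, Inf)
  expect_equal(free_energy_classical(ch, g, kk),
               free_energy_classical(ch, s1, kk) + free_energy_classical(ch, s2, kk),
               tolerance = 1e-12)
  ## F_modified * lambda_m / L == kBT identically; linear in L
  for (h in c(0.05, 0.2, 0.5, 2)) {
    gg <- sq_geom(h)
    expect_equal(free_energy_modified(ch, gg, kk) *
                   modified_deflection(gg, ch, kk) / ch$L, 1, tolerance = 1e-12)
    expect_equal(free_energy_modified(chain_spec(400, Lp0), gg, kk),
                 2 * free_energy_modified(ch, gg, kk), tolerance = 1e-12)
    ## log inequality: the modified free energy is the smaller one
    expect_lt(free_energy_modified(ch, gg, kk), free_energy_classical(ch, gg, kk))
  }
  ## slit H = 0.1 Lp: modified within 9% of classical
  expect_lt(abs(free_energy_modified(chain_spec(Lp0, Lp0), gs, kk) /
                free_energy_classical(chain_spec(Lp0, Lp0), gs, kk) - 1), 0.09)
})

test_that("unstretched extension deficits and their square-channel agreement", {
  ch <- chain_spec(200, Lp0)
  g <- sq_geom(0.2)
  expect_equal(extension_deficit_classical(g, ch, kk),
               0.09143 * 2 * 0.2^(2 / 3), tolerance = 1e-12)
  eps <- kk$theta / (1.1032 * 2 * 0.2^(-2 / 3))
  expect_equal(extension_deficit_modified(g, ch, kk),
               1 - eps / (-log(1 - eps)), tolerance = 1e-12)
  expect_equal(extension_deficit_modified(g, ch, kk), 0.0639295, tolerance = 1e-6)
  ## monotone in each channel dimension
  d <- sapply(c(0.1, 0.2, 0.3), function(h)
    extension_deficit_classical(channel_geometry(h * Lp0, 0.2 * Lp0), ch, kk))
  expect_true(all(diff(d) > 0))
  ## square channels: classical/modified ratio -> 1 as H -> 0
  r_sq <- sapply(c(0.05, 0.01, 0.002), function(h)
    extension_deficit_classical(sq_geom(h), ch, kk) /
      extension_deficit_modified(sq_geom(h), ch, kk))
  expect_true(all(diff(abs(r_sq - 1)) < 0))
  expect_lt(abs(r_sq[3] - 1), 5e-3)
  ## rectangular beta != 1: ratio -> phi(beta)
  beta <- 4
  r_rect <- sapply(c(0.01, 0.002), function(h) {
    gg <- channel_geometry(h * Lp0, h * Lp0 / beta)
    extension_deficit_classical(gg, ch, kk) / extension_deficit_modified(gg, ch, kk)
  })
  expect_lt(abs(r_rect[2] - aspect_ratio_factor(beta)), 2e-2)
  ## classical form is for tubes only
  expect_error(extension_deficit_classical(channel_geometry(5, Inf), ch, kk),
               class = "wlctube_domain_error")
})

test_that("aspect-ratio factor: minimum, symmetry, divergence", {
  expect_identical(aspect_ratio_factor(1), 1)
  expect_equal(aspect_ratio_factor(8), 0.25 * (2 + 0.5)^2, tolerance = 1e-12)
  b <- c(0.03, 0.7, 2, 40)
  expect_equal(aspect_ratio_factor(b), aspect_ratio_factor(1 / b), tolerance = 1e-12)
  expect_true(all(aspect_ratio_factor(b[b != 1]) > 1))
  opt <- optimize(aspect_ratio_factor, c(1e-3, 1e3))
  expect_equal(opt$minimum, 1, tolerance = 1e-4)
  expect_gt(aspect_ratio_factor(1e8), 1e4)
  expect_error(aspect_ratio_factor(0), class = "wlctube_domain_error")
  expect_error(aspect_ratio_factor(-2), class = "wlctube_domain_error")
})

test_that("force-extension without confinement", {
  expect_equal(force_extension_unconfined(force_state(f_hat = 25)), 0.1)
  expect_equal(force_extension_unconfined(force_state(f_hat = 1)), 0.5)
  f <- c(2, 5, 20, 100)
  d <- sapply(f, function(x) force_extension_unconfined(force_state(f_hat = x)))
  expect_true(all(diff(d) < 0))
  expect_error(force_extension_unconfined(force_state(f_hat = 0)),
               class = "wlctube_domain_error")
})

test_that("force-confinement-extension relation and the effective force", {
  ch <- chain_spec(200, Lp0)
  g <- sq_geom(0.2)
  eps <- kk$theta / (1.1032 * 2 * 0.2^(-2 / 3))
  minus_log <- -log(1 - eps)
  ## zero-force value and the effective-force equivalences
  expect_equal(force_confinement_extension(g, ch, force_state(f_hat = 0), kk),
               0.5 * minus_log, tolerance = 1e-12)
  fc <- effective_confinement_force(g, ch, kk)
  expect_equal(fc$f_hat, minus_log^(-2), tolerance = 1e-12)
  expect_equal(fc$f_hat, 56.0118, tolerance = 1e-5)
  expect_equal(force_confinement_extension(g, ch, force_state(f_hat = 0), kk),
               force_extension_unconfined(fc), tolerance = 1e-12)
  ## the textual alternative normalization differs by theta^2
  fc2 <- effective_confinement_force(g, ch, kk, form = "from_deflection_length")
  expect_equal(fc2$f_hat, kk$theta^2 * fc$f_hat, tolerance = 1e-12)
  ## tight zero-force limit reduces to the unstretched modified deficit
  g_tight <- sq_geom(0.01)
  expect_equal(force_confinement_extension(g_tight, ch, force_state(f_hat = 0), kk),
               extension_deficit_modified(g_tight, ch, kk), tolerance = 1e-2)
  ## strong-force limit matches the unconfined relation to first order
  fbig <- force_state(f_hat = 1e5)
  expect_equal(force_confinement_extension(g, ch, fbig, kk) /
                 force_extension_unconfined(fbig), 1, tolerance = 1e-3)
  ## deficit decreases with force and with tightening confinement
  d_f <- sapply(c(0, 2, 10, 50), function(x)
    force_confinement_extension(g, ch, force_state(f_hat = x), kk))
  expect_true(all(diff(d_f) < 0))
  d_h <- sapply(c(0.3, 0.2, 0.1), function(h)
    force_confinement_extension(sq_geom(h), ch, force_state(f_hat = 5), kk))
  expect_true(all(diff(d_h) < 0))
  ## swap symmetry
  expect_equal(
    force_confinement_extension(channel_geometry(10, 25), ch, force_state(f_hat = 3), kk),
    force_confinement_extension(channel_geometry(25, 10), ch, force_state(f_hat = 3), kk))
  ## validity error propagates
  expect_error(force_confinement_extension(sq_geom(5.6), ch, force_state(f_hat = 1), kk),
               class = "wlctube_validity_error")
})

test_that("tangent-end projection of a free segment", {
  ch <- chain_spec(200, Lp0)
  expect_identical(wlc_tangent_projection(0, ch), 0)
  expect_equal(wlc_tangent_projection(1e9, ch), Lp0)
  expect_equal(wlc_tangent_projection(Lp0, ch), Lp0 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_error(wlc_tangent_projection(-1, ch), class = "wlctube_domain_error")
})
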