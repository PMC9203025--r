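test_that("noisy rate matches an independent high-resolution quadrature", {
  p <- default_lif
  cases <- list(c(0.25, 0, -65, 3), c(0.4, 0.5, -62, 2), c(0.1, 0.2, -75, 5))
  for (cs in cases) {
    got <- ricciardi_rate(p, synaptic_drive(cs[1], cs[2], cs[3]),
                          noise_constant(cs[4]))
    expect_equal(got, oracle_ricciardi(p, cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-6)
  }
})

test_that("noisy rate converges to the deterministic rate as sigma -> 0", {
  p <- default_lif
  # 20-point drive grid with E_eff comfortably above threshold
  set.seed(5)
  n_checked <- 0
  while (n_checked < 20) {
    d <- synaptic_drive(runif(1, 0.4, 2), runif(1, 0, 1), runif(1, -80, -55))
    if (effective_input(p, d)$E_eff < p$E_thr + 0.5) next
    det <- deterministic_rate(p, d)
    expect_equal(ricciardi_rate(p, d, noise_constant(1e-3)), det,
                 tolerance = 0.5 / det)
    n_checked <- n_checked + 1
  }
  # and within 0.1% already at sigma = 0.01 mV for a representative point
  d <- synaptic_drive(0.4, 0, -63)
  expect_equal(ricciardi_rate(p, d, noise_constant(0.01)),
               deterministic_rate(p, d), tolerance = 1e-3)
  # sigma = 0 dispatches exactly
  expect_identical(ricciardi_rate(p, d, noise_constant(0)),
                   deterministic_rate(p, d))
})

test_that("noisy rate is finite, positive and increasing in sigma for sub-threshold drive", {
  p <- default_lif
  d <- synaptic_drive(0.25, 0.1, -70)  # E_eff below threshold
  r <- vapply(c(0.5, 1, 2, 3, 5, 8), function(s)
    ricciardi_rate(p, d, noise_constant(s)), numeric(1))
  expect_true(all(is.finite(r)) && all(r > 0))
  expect_true(all(diff(r) > 0))
  # far sub-threshold, tiny noise: underflows gracefully to 0, no overflow
  expect_identical(ricciardi_rate(p, synaptic_drive(0, 0, -80),
                                  noise_constant(0.5)), 0)
})

test_that("noisy rate agrees with Euler-Maruyama Monte Carlo", {
  p <- default_lif
  set.seed(6)
  for (i in 1:5) {
    d <- synaptic_drive(runif(1, 0.2, 0.8), runif(1, 0, 0.8),
                        runif(1, -75, -58))
    sg <- runif(1, 1.5, 5)
    theo <- ricciardi_rate(p, d, noise_constant(sg))
    if (theo < 0.5) next
    sim <- simulate_lif(p, d, noise_constant(sg),
                        sim_config(dt = 0.02, duration = 100100,
                                   seed = 100 + i), record_v = FALSE)
    n <- max(sum(sim$times > 100), 1)
    se <- theo * sqrt(1 / n)  # conservative Poisson-count standard error
    expect_lt(abs(sim$rate - theo), 4 * se + 0.05 * theo)
  }
})

test_that("high-noise closed form behaves as the large-sigma limit", {
  p <- default_lif
  d <- synaptic_drive(0.01, 0.01, -61)
  # sigma = 0 gives 0
  expect_equal(high_noise_rate(p, d, noise_constant(0)), 0)
  # strictly increasing in g_GABA
  r <- high_noise_rate(p, synaptic_drive(0.01, seq(0, 2, 0.1), -61),
                       noise_constant(5))
  expect_true(all(diff(r) > 0))
  # approaches the full integral from above as sigma grows; within 5% once
  # the integration bounds are well inside the flat part of the integrand
  err <- vapply(c(50, 150, 500), function(s)
    high_noise_rate(p, d, noise_constant(s)) /
      ricciardi_rate(p, d, noise_constant(s)) - 1, numeric(1))
  expect_true(all(err > 0))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.05)
})

test_that("conductance-dependent noise amplitude follows the diffusion formula", {
  p <- default_lif
  # vanishes with strengths or with conductances
  expect_equal(conductance_noise_sigma(p, synaptic_drive(0.8, 0.5, -65), 0, 0), 0)
  expect_equal(conductance_noise_sigma(p, synaptic_drive(0, 0, -65), 0.1), 0)
  # hand evaluation at E_eff
  d <- synaptic_drive(0.8, 0.5, -65)
  E <- (p$E_L + 0.5 * (-65) + 0.8 * 0) / (1 + 0.5 + 0.8)
  byhand <- sqrt(0.1 * 0.8 * (E - 0)^2 + 0.1 * 0.5 * (E + 65)^2)
  expect_equal(conductance_noise_sigma(p, d, 0.1), byhand, tolerance = 1e-12)
  # matches the fluctuation amplitude of a simulated diffusive input:
  # an Ornstein-Uhlenbeck voltage (no threshold) driven with this sigma has
  # stationary SD sigma_eff/sqrt(2)
  sg <- conductance_noise_sigma(p, d, 0.1)
  g_eff <- 1 + 0.5 + 0.8
  pp <- lif_params(E_thr = 100, E_reset = -70, E_Glu = 150)  # never spikes
  dd <- synaptic_drive(0.8, 0.5, -65)
  sim <- simulate_lif(pp, dd, noise_constant(sg),
                      sim_config(dt = 0.02, duration = 60000, seed = 7),
                      v_stride = 50L)
  keep <- sim$v_times > 500
  expect_equal(sd(sim$v[keep]), (sg / sqrt(g_eff)) / sqrt(2), tolerance = 0.05)
})

test_that("the inhibitory/non-monotonic boundary recovers the deterministic limit and widens with noise", {
  p <- default_lif
  # sigma -> 0: boundary -> critical E_GABA
  b <- boundary_egaba(p, 0.4, noise_constant(0.01))
  expect_equal(b, critical_egaba(p, 0.4), tolerance = 0.05)
  # noise lowers the boundary (expands the non-monotonic region)
  b1 <- boundary_egaba(p, 0.4, noise_constant(1))
  b3 <- boundary_egaba(p, 0.4, noise_constant(3))
  expect_lt(b1, b)
  expect_lt(b3, b1)
  # conductance-kind noise keeps expanding the region at strong drive, where
  # the constant-noise expansion collapses (the noise amplitude grows with
  # g_Glu instead of being fixed)
  nz <- noise_conductance(0.1)
  exp_cond <- vapply(c(0.4, 1.5), function(g)
    critical_egaba(p, g) - boundary_egaba(p, g, nz), numeric(1))
  exp_const <- vapply(c(0.4, 1.5), function(g)
    critical_egaba(p, g) - boundary_egaba(p, g, noise_constant(3)),
    numeric(1))
  expect_true(all(exp_cond > 0) && all(exp_const > 0))
  expect_lt(exp_const[2] / exp_const[1], 0.2)     # collapses at high g_Glu
  expect_gt(exp_cond[2] / exp_cond[1], 0.5)       # persists at high g_Glu
  expect_gt(exp_cond[2], exp_const[2])
  # and the conductance-noise expansion grows with the unitary strength a
  b_a <- vapply(c(0.01, 0.05, 0.1), function(a)
    boundary_egaba(p, 0.8, noise_conductance(a)), numeric(1))
  expect_true(all(diff(b_a) < 0))
})

test_that("noisy phase diagrams lose the silent region and keep the threshold boundary", {
  p <- default_lif
  eg <- seq(-70, -56, 1)
  gg <- seq(0.1, 1.3, 0.2)
  pd1 <- build_phase_diagram(p, eg, gg, noise = noise_constant(1))
  pd3 <- build_phase_diagram(p, eg, gg, noise = noise_constant(3))
  expect_false(any(pd1$points$label %in% c("SILENT", "GABA_ACTIVATED")))
  # every point above threshold reversal is excitatory
  expect_true(all(pd1$points$label[pd1$points$E_GABA_mV > p$E_thr] ==
                    "EXCITATORY"))
  # the non-monotonic region grows with sigma, as a containment
  nm1 <- pd1$points$label == "NON_MONOTONIC"
  nm3 <- pd3$points$label == "NON_MONOTONIC"
  expect_true(all(nm3[nm1]))
  expect_gt(sum(nm3), sum(nm1))
  # and with the unitary strength of conductance noise
  pda <- build_phase_diagram(p, eg, gg, noise = noise_conductance(0.01))
  pdb <- build_phase_diagram(p, eg, gg, noise = noise_conductance(0.1))
  nma <- pda$points$label == "NON_MONOTONIC"
  nmb <- pdb$points$label == "NON_MONOTONIC"
  expect_true(all(nmb[nma]))
  expect_gt(sum(nmb), sum(nma))
})
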