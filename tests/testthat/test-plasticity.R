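test_that("postsynaptic waveforms follow the double-exponential forms", {
  p <- plasticity_params()
  expect_equal(bpap(0, p, bpap_max = 1), 1)          # proportions sum to 1
  expect_equal(epsp(0, p, epsp_max = 1), 1)
  expect_equal(bpap(1.2, p, bpap_max = 1),
               0.75 * exp(-1) + 0.25 * exp(-0.12), tolerance = 1e-10)
  expect_equal(epsp(20, p, epsp_max = 1),
               0.5 * exp(-10) + 0.5 * exp(-1), tolerance = 1e-10)
  expect_lt(bpap(500, p, bpap_max = 1), 1e-10)        # vanishing tail
  # EPSP tail outlasts the BPAP tail beyond 5 ms
  tt <- seq(5, 60, by = 1)
  expect_true(all(epsp(tt, p, epsp_max = 1) > bpap(tt, p, bpap_max = 1)))
  expect_error(bpap(-1), "non-negative")
})

test_that("calcium driving force has the right equilibrium and block", {
  # zero flux at the calcium reversal potential under any reading
  expect_equal(driving_force(130), 0)
  expect_equal(driving_force(130, v_shift = 0), 0)
  expect_equal(driving_force(130, product = TRUE), 0)
  # literal shifted-scale reading at rest
  expect_equal(driving_force(0, mg = 1, v_shift = 0),
               -0.42 * (-130) / (1 + 0.6 / 3.57), tolerance = 1e-6)
  # block strengthens with magnesium at fixed subthreshold voltage
  h_mg <- driving_force(rep(20, 3), mg = c(0.5, 1, 2))
  expect_true(all(diff(h_mg) < 0))
  # default reading: steep relief of the block toward the BPAP range
  expect_gt(driving_force(90) / driving_force(0), 5)
})

test_that("NMDA current gating follows presynaptic spike timing", {
  p <- plasticity_params()
  expect_equal(nmda_current(NA, 0, p), 0)       # no spike yet
  expect_equal(nmda_current(-5, 0, p), 0)
  expect_equal(nmda_current(10, 130, p), 0)     # zero driving force
  expect_gt(nmda_current(0, 20, p), 0)          # inward calcium flux
  # activation decays with time since the spike
  expect_gt(nmda_current(1, 10, p), nmda_current(60, 10, p))
})

test_that("calcium dynamics decay and saturate as the ODE dictates", {
  # free decay over one time constant
  ca <- 1
  for (i in 1:500) ca <- calcium_step(ca, 0, 1e-4, tau_ca = 0.05)
  expect_equal(ca, exp(-1), tolerance = 3e-3)
  # steady state tau_ca * I under constant drive
  ca <- 0
  for (i in 1:20000) ca <- calcium_step(ca, 10, 1e-4, tau_ca = 0.05)
  expect_equal(ca, 0.5, tolerance = 1e-3)
  expect_equal(calcium_step(0, 0, 1e-4), 0)
  expect_error(calcium_step(0, 0, 0), "dt")
  expect_error(calcium_step(-1, 0, 1e-4), "non-negative")
})

test_that("the Omega function has the calcium-control shape", {
  p <- plasticity_params()
  expect_equal(omega(0, p), -1.34e-4, tolerance = 0.05)
  expect_equal(omega(0.25, p), -0.4, tolerance = 0.01)    # depression plateau
  expect_equal(omega(1.0, p), 0.6, tolerance = 0.001)     # potentiation plateau
  # retuned thresholds of the BPAP-free variant
  pa <- plasticity_params("ltp_ltd_adjusted")
  expect_equal(pa$alpha1, 0.3)
  expect_equal(pa$omega_rate, 0.3)
  # just above the retuned depression threshold: sig(4) - sided plateau
  expect_equal(omega(0.35, pa),
               plogis((0.35 - 0.4) * 80) - 0.3 * plogis((0.35 - 0.3) * 80),
               tolerance = 1e-10)
  expect_error(omega(-0.1, p), "non-negative")
})

test_that("the weight update relaxes toward kappa*Omega within bounds", {
  p <- plasticity_params()
  kap <- p$omega_to_weight_scale
  # fixed point: W = kappa * Omega(Ca)
  ca <- 1.0
  w_star <- kap * omega(ca, p)
  st <- list(weight = w_star, calcium = ca)
  expect_equal(weight_update(st, 1e-3, p)$weight,
               min(p$weight_max, w_star), tolerance = 1e-9)
  # sustained high calcium drives any weight up toward the plateau
  st <- list(weight = 1e-8, calcium = 1.0)
  for (i in 1:10000) st <- weight_update(st, 0.01, p)
  expect_equal(st$weight, min(kap * 0.6, p$weight_max), tolerance = 0.01)
  # the ceiling holds under continued potentiation drive
  st <- list(weight = 6.5e-8, calcium = 1.5)
  st <- weight_update(st, 1e-3, p)
  expect_equal(st$weight, 6.5e-8)
  # the floor holds under depression drive
  st <- list(weight = 1e-9, calcium = 0.25)
  st <- weight_update(st, 1e-3, p)
  expect_equal(st$weight, 1e-9)
})

test_that("the learning rate increases monotonically with calcium", {
  p <- plasticity_params()
  eta <- eta_ca(seq(0, 2, by = 0.05), p)
  expect_true(all(diff(eta) > 0))
  expect_lt(eta_ca(0, p), 1e-3)
})

test_that("pair-based STDP has the exponential window structure", {
  p <- plasticity_params("stdp_only")
  w <- 3e-8
  expect_gt(stdp_pair_update(w, 10, p), w)    # pre-post potentiates
  expect_lt(stdp_pair_update(w, -10, p), w)   # post-pre depresses
  expect_equal(stdp_pair_update(w, 1e5, p), w, tolerance = 1e-12)
  expect_equal(stdp_pair_update(w, -1e5, p), w, tolerance = 1e-12)
  expect_equal(stdp_pair_update(w, 0, p), w)
  # bounds
  expect_equal(stdp_pair_update(6.5e-8, 1, p), 6.5e-8)
})

test_that("calcium transients carry the spike-timing asymmetry", {
  # pre-post exceeds post-pre at equal |dt|
  for (dtms in c(5, 15)) {
    expect_gt(measure_calcium_response(3e-8, "pairing", dtms, cap = Inf),
              measure_calcium_response(3e-8, "pairing", -dtms, cap = Inf))
  }
  # removing BPAPs abolishes the asymmetry exactly
  pnb <- plasticity_params("ltp_ltd_only")
  expect_equal(
    measure_calcium_response(3e-8, "pairing", 15, cap = Inf, params = pnb),
    measure_calcium_response(3e-8, "pairing", -15, cap = Inf, params = pnb),
    tolerance = 1e-10)
})

test_that("single-synapse simulation keeps calcium non-negative and weights bounded", {
  p <- plasticity_params()
  pre <- seq(0.05, 3, by = 1 / 50)
  post <- seq(0.06, 3, by = 1 / 20)
  tr <- simulate_synapse(pre, post, 3e-8, 3.2, plasticity = "full", params = p)
  expect_true(all(tr$calcium >= 0))
  expect_true(all(tr$weight >= p$weight_min - 1e-15))
  expect_true(all(tr$weight <= p$weight_max + 1e-15))
})

test_that("plasticity parameter validation enforces invariants", {
  expect_error(plasticity_params(alpha1 = 0.5, alpha2 = 0.4))
  expect_error(plasticity_params(tau_ca = -1))
  expect_error(plasticity_params(nonsense = 1), "unknown")
  expect_true(plasticity_params("ltp_ltd_only")$no_bpap)
})
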