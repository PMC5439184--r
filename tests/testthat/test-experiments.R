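test_that("tetanus protocols move EPSP amplitudes bidirectionally", {
  t50 <- run_tetanus_protocol(50)
  t20 <- run_tetanus_protocol(20)
  t0 <- run_tetanus_protocol(0)
  expect_gt(t50$ratio, 1.05)            # lasting increase after 50 Hz
  expect_lt(t20$ratio, 0.95)            # lasting decrease after 20 Hz
  expect_equal(t0$ratio, 1, tolerance = 0.15)  # probes alone change little
  expect_gt(t50$final_weight, 3e-8)
  expect_lt(t20$final_weight, 3e-8)
  expect_gt(t50$baseline, 0)
})

test_that("pairing protocols potentiate pre-post and depress post-pre", {
  pp <- run_pairing_protocol(15, 15)
  pm <- run_pairing_protocol(-75, 30)
  p0 <- run_pairing_protocol(15, 0)
  expect_gt(pp$final_weight, 3e-8)
  expect_lt(pm$final_weight, 3e-8)
  expect_gt(pp$ratio, pm$ratio)
  expect_equal(p0$ratio, 1, tolerance = 0.15)  # zero pairings: no change

  # the pair-based STDP synapse variant shows the same directions
  ps <- run_pairing_protocol(10, 30, plasticity = "stdp_only")
  ms <- run_pairing_protocol(-10, 30, plasticity = "stdp_only")
  expect_gt(ps$final_weight, 3e-8)
  expect_lt(ms$final_weight, 3e-8)
})

test_that("calcium-response readout caps at saturation and respects modes", {
  ca <- measure_calcium_response(1e-8, "frequency", 100)
  expect_equal(ca, 1.0)
  expect_gt(measure_calcium_response(1e-8, "frequency", 100, cap = Inf), 1.0)
  expect_gt(measure_calcium_response(3e-8, "pairing", 5),
            measure_calcium_response(3e-8, "pairing", -5))
})

test_that("a zero-length learning phase reproduces baseline exactly", {
  fx <- fam_setup(11)
  res <- run_familiarity_experiment(fx$net, fx$images, learn_ids = 1,
                                    exposure = 0, n_probes = 2)
  expect_identical(res$baseline, res$test)
  expect_identical(res$weights_before, res$weights_after)
  expect_equal(sort(res$ranks), 1:30)
})

test_that("testing never changes weights and learning stays within bounds", {
  fx <- fam_setup(11)
  res <- run_familiarity_experiment(fx$net, fx$images, learn_ids = 5,
                                    exposure = 2, n_probes = 2)
  # weights_after were produced by learning; re-probing with them must not
  # change them (probe phases run with plasticity off)
  res2 <- run_familiarity_experiment(fx$net, fx$images, learn_ids = 5,
                                     exposure = 0, n_probes = 2,
                                     weights = res$weights_after)
  expect_identical(res2$weights_after, res$weights_after)
  plastic <- fx$net$synapses$kind == "nmdar_plastic"
  expect_true(all(res$weights_after[plastic] >= 1e-9 - 1e-15))
  expect_true(all(res$weights_after[plastic] <= 6.5e-8 + 1e-15))
  # static weights are untouched by learning
  expect_identical(res$weights_after[!plastic], res$weights_before[!plastic])
})

test_that("learning raises the learned image's response above baseline", {
  fx <- fam_setup(11)
  res <- run_familiarity_experiment(fx$net, fx$images, learn_ids = 7,
                                    exposure = 15, n_probes = 3)
  expect_gt(res$test[7], res$baseline[7])
  # familiarity effect direction: the learned image's gain exceeds the
  # average gain of the novel images
  expect_gt(res$test[7] - res$baseline[7],
            mean((res$test - res$baseline)[-7]))
  expect_error(run_familiarity_experiment(fx$net, fx$images, learn_ids = 31),
               "subset")
})

test_that("top-k accuracy implements the hypothetical-threshold readout", {
  expect_equal(accuracy_topk(c(1:9, 13), 10), 0.9)
  expect_equal(accuracy_topk(1:5, 10), 1.0)
  expect_error(accuracy_topk(1:3, 0), "k")

  # exchangeability: random ranks put half the familiar items in the top
  # half on average
  set.seed(31)
  acc <- vapply(1:2000, function(i) {
    r <- sample(20)
    accuracy_topk(r[1:10], 10)
  }, 0)
  expect_equal(mean(acc), 0.5, tolerance = 0.02)
})

test_that("robustness sweeps report ranks and a bursting indicator", {
  fx <- fam_setup(11)
  base <- list(network = fx$net, images = fx$images, learn_ids = 7,
               exposure = 1, n_probes = 2)
  sw <- robustness_sweep("noise_amplitude", c(0, 5), base)
  expect_equal(nrow(sw), 2)
  expect_true(all(c("rank", "accuracy", "silent_rate", "bursting") %in%
                  names(sw)))
  expect_false(sw$bursting[1])   # the down-state network is silent between
                                 # stimuli at zero noise
  expect_error(robustness_sweep("noise_amplitude", numeric(0), base), "empty")
})

test_that("tenfold weight scaling drives the reservoir into bursting", {
  cfg <- network_config(dims = c(10, 10, 5), lambda_ = 2,
                        input_mode = "one_to_one", wscale = 5, seed = 11)
  net <- build_network(cfg)
  net <- build_input_projection(net, c(10, 10))
  imgs <- generate_synthetic_faces(1, 1, size = 10, seed = 5)
  st <- encode_image(imgs[[1]], silence = 0.5, seed = 3)
  sim <- run_network(net, st, duration = 1, plasticity = "off", seed = 3)
  # spikes persist in the silent interval: the up-state signature
  expect_gt(firing_rate(sim$record, c(0.6, 1)), 1)
})
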