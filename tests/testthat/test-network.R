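test_that("grid construction places neurons and labels excitatory fraction", {
  g <- build_grid(c(10, 10, 5), seed = 1)
  expect_equal(nrow(g$positions), 500)
  expect_equal(sum(g$is_excitatory), ceiling(0.75 * 500))
  expect_true(all(g$positions >= 0))

  g1 <- build_grid(c(1, 1, 1))
  expect_equal(nrow(g1$positions), 1)

  expect_error(build_grid(c(0, 10, 5)), "dims")

  # Euclidean distances on the grid behave as expected (3-4-5 triangle)
  g2 <- build_grid(c(4, 5, 1), seed = 1)
  d <- sqrt(sum((g2$positions[1, ] - c(3, 4, 0))^2))
  expect_equal(d, 5)
})

test_that("connection probability follows the distance kernel", {
  expect_equal(connection_probability(c(0, 0, 0), c(0, 0, 0), "EE"), 0.3)
  expect_equal(connection_probability(c(0, 0, 0), c(7, 1, 2), "EE",
                                      lambda_ = Inf, cscale = 0.04), 0.012)
  # D = lambda gives C / e
  expect_equal(connection_probability(c(0, 0, 0), c(2, 0, 0), "EE",
                                      lambda_ = 2), 0.3 * exp(-1))
  expect_equal(connection_probability(c(0, 0, 0), c(0, 0, 0), "II"), 0.1)
  expect_error(connection_probability(c(0, 0, 0), c(1, 0, 0), "XX"), "unknown")
})

test_that("initial weights are gamma with the specified moments and signs", {
  w <- sample_weights("EE", wscale = 0.5, sh_w = 0.25, n = 1e5, seed = 42)
  expect_equal(mean(w), 1.5e-8, tolerance = 0.01)
  expect_equal(sd(w) / mean(w), 0.25, tolerance = 0.02)

  w2 <- sample_weights("EE", wscale = 2, sh_w = 0.7, n = 1e5, seed = 43)
  expect_equal(mean(w2), 6e-8, tolerance = 0.01)
  expect_equal(sd(w2) / mean(w2), 0.7, tolerance = 0.02)

  wi <- sample_weights("IE", wscale = 1, sh_w = 0.7, n = 1000, seed = 44)
  expect_true(all(wi < 0))
  expect_equal(mean(wi), -1.9e-8, tolerance = 0.1)

  expect_length(sample_weights("EE", 1, 0.7, n = 0), 0)
})

test_that("network construction is deterministic and well-formed", {
  cfg <- network_config(dims = c(6, 6, 3), lambda_ = 2, seed = 7)
  net1 <- build_network(cfg)
  net2 <- build_network(cfg)
  expect_identical(net1$synapses, net2$synapses)

  syn <- net1$synapses
  expect_false(any(syn$pre == syn$post))                 # no autapses
  expect_false(any(duplicated(syn[, c("pre", "post")]))) # no duplicate edges
  # plastic synapses come from excitatory neurons; inhibitory weights negative
  expect_true(all(net1$is_excitatory[syn$pre[syn$kind == "nmdar_plastic"]]))
  expect_true(all(syn$weight[syn$kind == "static_inhibitory"] < 0))
  expect_true(all(syn$weight[syn$kind == "nmdar_plastic"] >= 1e-9))
  expect_true(all(syn$weight[syn$kind == "nmdar_plastic"] <= 6.5e-8))
})

test_that("connection counts match the Bernoulli expectation", {
  cfg <- network_config(dims = c(8, 8, 3), lambda_ = 2, seed = 1)
  grid <- build_grid(cfg$dims, seed = derive_seed(1L, "grid"))
  exp_deg <- famlsm:::cpp_expected_degree(grid$positions + 0.0, grid$is_excitatory,
                                 2, 1, c(0.3, 0.2, 0.4, 0.1))
  counts <- vapply(1:5, function(s) {
    cfg$seed <- s * 1000L
    # same grid labels across seeds requires matching grid stream; rebuild
    # with the same label assignment by fixing the grid seed
    con <- withr::with_seed(s, famlsm:::cpp_sample_connections(
      grid$positions + 0.0, grid$is_excitatory, 2, 1, c(0.3, 0.2, 0.4, 0.1)))
    length(con$pre)
  }, 0)
  expect_lt(abs(mean(counts) - exp_deg$expected_total),
            3 * exp_deg$sd_total / sqrt(5))
})

test_that("input projections follow the stated wiring rules", {
  net <- build_network(network_config(dims = c(10, 10, 5), seed = 2))
  net <- build_input_projection(net, c(10, 10), mode = "one_to_one")
  expect_equal(nrow(net$input), 100)
  expect_true(all(net$input$weight == 2.7e-7))
  expect_equal(sort(unique(net$input$post)), 1:100)  # first layer only

  expect_error(build_input_projection(net, c(5, 5), mode = "one_to_one"),
               "one_to_one")
  expect_error(build_input_projection(net, c(0, 10)), "positive")

  netr <- build_input_projection(net, c(20, 20), mode = "random",
                                 input_cscale = 0.02, seed = 9)
  n_pairs <- 400 * 500
  expected <- n_pairs * 0.02
  expect_lt(abs(nrow(netr$input) - expected), 3 * sqrt(expected))
  expect_true(all(netr$input$weight > 0))
})

test_that("mean degree summaries count synapses per neuron", {
  net <- build_network(network_config(dims = c(6, 6, 3), seed = 7))
  m <- nrow(net$synapses); n <- nrow(net$positions)
  expect_equal(mean_degree(net, "out"), m / n)
  expect_equal(mean_degree(net, "total"), 2 * m / n)
})

test_that("configuration validation rejects bad values", {
  expect_error(network_config(dims = c(10, 10)), "three")
  expect_error(network_config(excitatory_fraction = 1.2), "excitatory_fraction")
  expect_error(network_config(lambda_ = -1), "lambda_")
  expect_silent(network_config(lambda_ = Inf))
})
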