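# Shared fixtures, built once per run and memoized. All fixtures are
# generated in code from fixed seeds; nothing is read from disk.
.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, force(expr), envir = .fix)
  get(key, envir = .fix)
}

# a small reservoir with one-to-one input and a normalized 30-image set;
# the workhorse for experiment-level tests
fam_setup <- function(seed, dims = c(10, 10, 5), size = dims[1],
                      n_probes = 3) {
  memo(paste0("fam", seed, "_", paste(dims, collapse = "x")), {
    imgs <- generate_synthetic_faces(3, 10, size = size, seed = 5)
    cfg <- network_config(dims = dims, lambda_ = 2,
                          input_mode = "one_to_one", seed = seed)
    net <- build_network(cfg)
    net <- build_input_projection(net, dims[1:2])
    nr <- normalize_image_set(imgs, net, max_iters = 12, n_probes = n_probes)
    list(net = net, images = nr$images, responses = nr$responses,
         converged = nr$converged)
  })
}

# tiny driven network for dynamics checks
tiny_net <- function(seed = 3) {
  memo(paste0("tiny", seed), {
    cfg <- network_config(dims = c(5, 5, 3), lambda_ = 2, seed = seed)
    net <- build_network(cfg)
    build_input_projection(net, c(5, 5))
  })
}
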