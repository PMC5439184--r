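#' Reservoir network configuration
#'
#' Parameters controlling network construction: neurons are placed on a 3-D
#' integer grid, 75% are excitatory, and directed connections between
#' neurons a and b are drawn with probability
#' \eqn{P(D) = C\,Cscale\,e^{-D^2(a,b)/\lambda^2}} where D is Euclidean
#' distance in grid units and C depends on the pre/post types
#' (EE 0.3, EI 0.2, IE 0.4, II 0.1). Initial weights are gamma distributed
#' with mean \code{W_base * wscale} and coefficient of variation
#' \code{sh_w}; weights of synapses from inhibitory neurons are negative.
#'
#' @param dims integer triple (nx, ny, nz)
#' @param excitatory_fraction fraction of excitatory neurons
#' @param lambda_ connectivity length scale in grid units; \code{Inf}
#'   removes the distance limitation
#' @param cscale connectivity multiplier
#' @param wscale weight multiplier
#' @param sh_w weight-distribution shape parameter (gamma CV)
#' @param input_mode \code{"one_to_one"} (input neurons map onto the first
#'   layer with fixed weight 2.7e-7) or \code{"random"} (Bernoulli
#'   projection with gamma weights)
#' @param input_cscale per-pair connection probability in random input mode
#' @param input_wscale,input_sh_w input weight distribution parameters
#'   (random mode)
#' @param seed RNG seed for construction
#' @return a list of class \code{network_config}
#' @export
network_config <- function(dims = c(10, 10, 5), excitatory_fraction = 0.75,
                           lambda_ = 2.0, cscale = 1.0,
                           wscale = 0.5, sh_w = 0.25,
                           input_mode = c("one_to_one", "random"),
                           input_cscale = 0.04, input_wscale = 3,
                           input_sh_w = 0.7, seed = 1L) {
  input_mode <- match.arg(input_mode)
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1)) stop("dims must be three integers >= 1")
  if (excitatory_fraction <= 0 || excitatory_fraction >= 1)
    stop("excitatory_fraction must be in (0, 1)")
  if (!(lambda_ > 0)) stop("lambda_ must be positive (possibly Inf)")
  stopifnot(cscale > 0, wscale > 0, sh_w > 0,
            input_cscale > 0, input_wscale > 0, input_sh_w > 0)
  structure(list(dims = dims, excitatory_fraction = excitatory_fraction,
                 lambda_ = lambda_, cscale = cscale, wscale = wscale,
                 sh_w = sh_w, input_mode = input_mode,
                 input_cscale = input_cscale, input_wscale = input_wscale,
                 input_sh_w = input_sh_w, seed = as.integer(seed)),
            class = "network_config")
}

# base connection probabilities and mean initial weights by (pre, post) type
.c_base <- c(EE = 0.3, EI = 0.2, IE = 0.4, II = 0.1)
.w_base <- c(EE = 3e-8, EI = 6e-8, IE = -1.9e-8, II = -1.9e-8)

#' Place neurons on a 3-D grid and assign excitatory/inhibitory labels
#'
#' Neurons occupy all integer coordinates of an nx-by-ny-by-nz grid
#' (0-based). \code{ceiling(fraction * N)} neurons are excitatory, chosen
#' by seeded sampling without replacement.
#'
#' @param dims integer triple (nx, ny, nz)
#' @param excitatory_fraction fraction of excitatory neurons
#' @param seed RNG seed
#' @return list with \code{positions} (N x 3 matrix) and
#'   \code{is_excitatory} (logical)
#' @export
build_grid <- function(dims, excitatory_fraction = 0.75, seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1)) stop("all dims must be >= 1")
  g <- expand.grid(x = seq_len(dims[1]) - 1L, y = seq_len(dims[2]) - 1L,
                   z = seq_len(dims[3]) - 1L)
  pos <- as.matrix(g)
  n <- nrow(pos)
  n_exc <- ceiling(excitatory_fraction * n)
  is_exc <- rep(FALSE, n)
  withr::with_seed(seed, {
    is_exc[sample.int(n, n_exc)] <- TRUE
  })
  list(positions = pos, is_excitatory = is_exc)
}

#' Distance-dependent connection probability
#'
#' \eqn{P(D) = C_{type}\,Cscale\,e^{-D^2/\lambda^2}}; with infinite lambda
#' the probability is distance independent.
#'
#' @param pos_a,pos_b coordinate triples
#' @param conn_type one of \code{"EE"}, \code{"EI"}, \code{"IE"}, \code{"II"}
#'   (pre type then post type)
#' @param lambda_ length scale (grid units), possibly \code{Inf}
#' @param cscale connectivity multiplier
#' @return connection probability
#' @export
connection_probability <- function(pos_a, pos_b, conn_type, lambda_ = 2,
                                   cscale = 1) {
  if (!conn_type %in% names(.c_base)) stop("unknown connection type: ", conn_type)
  if (!(lambda_ > 0)) stop("lambda_ must be positive")
  if (cscale <= 0) stop("cscale must be positive")
  d2 <- sum((as.numeric(pos_a) - as.numeric(pos_b))^2)
  decay <- if (is.finite(lambda_)) exp(-d2 / lambda_^2) else 1
  unname(.c_base[conn_type] * cscale * decay)
}

#' Sample initial synaptic weights from the gamma distribution
#'
#' Weights are drawn from a gamma distribution with shape
#' \eqn{a = 1/SH_W^2} and scale \eqn{b = W\,SH_W^2}, so the mean is
#' \code{W_base * wscale} and the coefficient of variation is \code{sh_w}.
#' Draws for synapses from inhibitory neurons (IE, II) are negative.
#'
#' @param conn_type connection type (pre, post)
#' @param wscale weight multiplier
#' @param sh_w shape parameter (CV)
#' @param n number of draws
#' @param seed optional RNG seed (draws use the current RNG state when NULL)
#' @return numeric vector of weights
#' @export
sample_weights <- function(conn_type, wscale = 1, sh_w = 0.7, n, seed = NULL) {
  if (!conn_type %in% names(.w_base)) stop("unknown connection type: ", conn_type)
  stopifnot(n >= 0, wscale > 0, sh_w > 0)
  if (n == 0) return(numeric(0))
  w_mean <- abs(.w_base[conn_type]) * wscale
  shape <- 1 / sh_w^2
  scale <- w_mean * sh_w^2
  draw <- function() stats::rgamma(n, shape = shape, scale = scale)
  w <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (conn_type %in% c("IE", "II")) w <- -w
  unname(w)
}

#' Build a randomized reservoir network
#'
#' Samples one Bernoulli draw per ordered neuron pair using
#' \code{\link{connection_probability}}, then assigns gamma-distributed
#' initial weights. Synapses from excitatory neurons are NMDAR-plastic
#' (their initial weights are clipped into the plasticity bounds); synapses
#' from inhibitory neurons are static with negative weights. The result is
#' deterministic given \code{config$seed}.
#'
#' @param config \code{\link{network_config}}
#' @return object of class \code{lsm_network}: positions, labels, a synapse
#'   table (pre, post, kind, weight) and the configuration
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  grid <- build_grid(config$dims, config$excitatory_fraction,
                     seed = derive_seed(config$seed, "grid"))
  pos <- grid$positions
  is_exc <- grid$is_excitatory
  con <- withr::with_seed(derive_seed(config$seed, "connect"), {
    cpp_sample_connections(pos + 0.0, is_exc, config$lambda_, config$cscale,
                           unname(.c_base))
  })
  pre <- con$pre; post <- con$post
  type <- paste0(ifelse(is_exc[pre], "E", "I"), ifelse(is_exc[post], "E", "I"))
  w <- numeric(length(pre))
  withr::with_seed(derive_seed(config$seed, "weights"), {
    for (tt in c("EE", "EI", "IE", "II")) {
      idx <- which(type == tt)
      if (length(idx))
        w[idx] <- sample_weights(tt, config$wscale, config$sh_w, length(idx))
    }
  })
  kind <- ifelse(is_exc[pre], "nmdar_plastic", "static_inhibitory")
  plastic <- kind == "nmdar_plastic"
  w[plastic] <- pmin(6.5e-8, pmax(1.0e-9, w[plastic]))
  net <- structure(list(
    positions = pos, is_excitatory = is_exc,
    synapses = data.frame(pre = pre, post = post, kind = kind, weight = w,
                          stringsAsFactors = FALSE),
    input = NULL, input_dims = NULL,
    config = config), class = "lsm_network")
  net
}

#' Build the input projection
#'
#' In \code{one_to_one} mode every input neuron of an nx-by-ny input layer
#' forms one synapse with the matching neuron of the first reservoir layer
#' (z = 0), with fixed weight 2.7e-7. In \code{random} mode each
#' (input, reservoir) pair is connected with probability
#' \code{input_cscale} and gamma-distributed weights (EE base weight,
#' \code{input_wscale}, \code{input_sh_w}). Input synapses are static.
#'
#' @param network \code{lsm_network}
#' @param input_dims integer pair (nx, ny) of the input layer
#' @param mode \code{"one_to_one"} or \code{"random"}
#' @param input_cscale,input_wscale,input_sh_w random-mode parameters
#' @param seed RNG seed (defaults to a stream derived from the network seed)
#' @return the network with an input synapse table (channel, post, weight)
#' @export
build_input_projection <- function(network, input_dims,
                                   mode = network$config$input_mode,
                                   input_cscale = network$config$input_cscale,
                                   input_wscale = network$config$input_wscale,
                                   input_sh_w = network$config$input_sh_w,
                                   seed = derive_seed(network$config$seed, "input")) {
  stopifnot(inherits(network, "lsm_network"))
  input_dims <- as.integer(input_dims)
  if (length(input_dims) != 2 || any(input_dims < 1))
    stop("input layer must have two positive dimensions")
  n_in <- prod(input_dims)
  dims <- network$config$dims
  if (mode == "one_to_one") {
    if (!all(input_dims == dims[1:2]))
      stop("one_to_one input requires input_dims equal to the first-layer dims")
    # channel (x, y) maps to reservoir neuron at (x, y, z = 0); the grid is
    # built with x fastest, matching column-major channel order
    post <- seq_len(n_in)
    tab <- data.frame(channel = seq_len(n_in), post = post,
                      weight = 2.7e-7)
  } else {
    n <- nrow(network$positions)
    tab <- withr::with_seed(seed, {
      hit <- which(stats::runif(n_in * n) < input_cscale)
      ch <- ((hit - 1L) %% n_in) + 1L
      po <- ((hit - 1L) %/% n_in) + 1L
      w <- sample_weights("EE", input_wscale, input_sh_w, length(hit))
      data.frame(channel = ch, post = po, weight = w)
    })
  }
  network$input <- tab
  network$input_dims <- input_dims
  network
}

#' @export
print.lsm_network <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("LSM reservoir: %d neurons (%s grid), %.0f%% excitatory\n",
              n, paste(x$config$dims, collapse = "x"),
              100 * mean(x$is_excitatory)))
  cat(sprintf("  %d recurrent synapses (%.1f per neuron), lambda=%s, Cscale=%g\n",
              nrow(x$synapses), nrow(x$synapses) / n,
              format(x$config$lambda_), x$config$cscale))
  if (!is.null(x$input))
    cat(sprintf("  input: %s layer (%s), %d synapses\n",
                paste(x$input_dims, collapse = "x"), x$config$input_mode,
                nrow(x$input)))
  invisible(x)
}

#' Mean number of synapses per neuron
#'
#' Counts the recurrent synapses each neuron participates in.
#'
#' @param network \code{lsm_network}
#' @param count \code{"total"} counts both incoming and outgoing synapses,
#'   \code{"out"} outgoing only
#' @return mean synapses per neuron
#' @export
mean_degree <- function(network, count = c("total", "out")) {
  count <- match.arg(count)
  n <- nrow(network$positions)
  m <- nrow(network$synapses)
  if (count == "out") m / n else 2 * m / n
}
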