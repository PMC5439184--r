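#' One membrane update step of a leaky integrate-and-fire neuron
#'
#' Exponential-Euler update toward the steady state
#' \eqn{V_\infty = V_{rest} + R_m I}: the synaptic/injected current is held
#' constant over the step and the membrane equation is solved exactly,
#' \eqn{V(t+dt) = V_\infty + (V - V_\infty) e^{-dt/\tau_m}}. This is the
#' update rule used by the simulation engine (fixed; documented here).
#'
#' @param v membrane potential (mV)
#' @param i_total total current (nA)
#' @param dt timestep (s)
#' @param params \code{\link{neuron_params}}
#' @return updated membrane potential (mV)
#' @export
membrane_step <- function(v, i_total, dt, params = neuron_params()) {
  if (dt <= 0) stop("dt must be positive")
  v_inf <- params$v_resting + params$r_m * i_total
  v_inf + (v - v_inf) * exp(-dt / params$tau_m)
}

#' Simulate the reservoir network
#'
#' Integrates all neurons with a fixed timestep (default 0.2 ms), delivers
#' spikes with a one-step transmission delay, enforces absolute refractory
#' periods, and (optionally) runs the NMDAR plasticity machinery on every
#' synapse with an excitatory presynaptic neuron. Initial membrane
#' potentials and post-spike resets are drawn uniformly from [-1, 1] mV
#' using a dynamics RNG stream derived from \code{seed}, separate from the
#' construction and stimulus streams.
#'
#' @param network \code{lsm_network} (with an input projection if a
#'   stimulus is given)
#' @param stimulus a \code{\link{encode_image}} stimulus, a list of
#'   stimuli with \code{offsets} (seconds), or \code{NULL}
#' @param duration simulated time (s)
#' @param plasticity \code{"off"}, \code{"full"}, \code{"ltp_ltd_only"},
#'   \code{"ltp_ltd_adjusted"} or \code{"stdp_only"}
#' @param noise_amplitude standard deviation of the zero-mean Gaussian
#'   noise current added per step (nA)
#' @param seed seed of the dynamics stream
#' @param params \code{\link{plasticity_params}}; its variant is
#'   overridden by \code{plasticity} unless plasticity is "off"
#' @param neuron \code{\link{neuron_params}}
#' @param dt timestep (s)
#' @param weights optional weight vector overriding the stored synapse
#'   weights (e.g. weights after learning)
#' @param calcium optional initial per-synapse calcium vector
#' @return list of class \code{sim_result}: \code{record} (a
#'   \code{spike_record}), \code{weights}, \code{calcium}
#' @export
run_network <- function(network, stimulus = NULL, duration,
                        plasticity = "off", noise_amplitude = 0,
                        seed = 1L, params = NULL,
                        neuron = neuron_params(), dt = 2e-4,
                        weights = NULL, calcium = NULL) {
  stopifnot(inherits(network, "lsm_network"), duration > 0, dt > 0)
  if (is.null(params)) {
    params <- if (plasticity %in% c("off", "full")) plasticity_params("full")
              else plasticity_params(plasticity)
  }
  syn <- network$synapses
  w <- if (is.null(weights)) syn$weight else weights
  if (length(w) != nrow(syn)) stop("weight vector does not match synapse table")
  ca0 <- if (is.null(calcium)) numeric(0) else calcium

  if (is.null(stimulus)) {
    ev_t <- numeric(0); ev_c <- integer(0); n_ch <- 0L
    in_ch <- integer(0); in_post <- integer(0); in_w <- numeric(0)
  } else {
    if (is.null(network$input)) stop("network has no input projection")
    ev <- stimulus_events(stimulus)
    n_ch <- prod(network$input_dims)
    if (ev$n_channels != n_ch)
      stop(sprintf("stimulus has %d channels but the input layer has %d",
                   ev$n_channels, n_ch))
    ev_t <- ev$time; ev_c <- ev$channel
    in_ch <- network$input$channel; in_post <- network$input$post
    in_w <- network$input$weight
  }

  res <- withr::with_seed(derive_seed(seed, "dynamics"), {
    cpp_simulate_network(syn$pre, syn$post, w, syn$kind == "nmdar_plastic",
                         network$is_excitatory,
                         in_ch, in_post, in_w, as.integer(n_ch),
                         ev_t, ev_c, duration, dt,
                         variant_code(plasticity), noise_amplitude,
                         unclass(neuron), unclass(params), ca0)
  })
  if (anyNA(res$weights) || anyNA(res$spike_time))
    stop("numerical failure: NaN state encountered during simulation")
  rec <- spike_record(res$spike_neuron, res$spike_time,
                      n_neurons = nrow(network$positions),
                      duration = duration, dt = dt)
  structure(list(record = rec, weights = res$weights, calcium = res$calcium),
            class = "sim_result")
}

#' Spike record container
#'
#' Per-neuron spike times over one simulation interval.
#'
#' @param neuron integer vector of neuron ids (1-based)
#' @param time spike times (s), non-decreasing
#' @param n_neurons number of neurons
#' @param duration simulation interval length (s)
#' @param dt timestep used (s)
#' @return object of class \code{spike_record}
#' @export
spike_record <- function(neuron, time, n_neurons, duration, dt) {
  structure(list(neuron = as.integer(neuron), time = as.numeric(time),
                 n_neurons = as.integer(n_neurons),
                 duration = duration, dt = dt),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("spike record: %d spikes, %d neurons, %.3g s (dt = %.2g ms)\n",
              length(x$time), x$n_neurons, x$duration, x$dt * 1000))
  invisible(x)
}

#' Spike times of one neuron
#' @param record \code{spike_record}
#' @param neuron neuron id
#' @return numeric vector of spike times (s)
#' @export
spike_times <- function(record, neuron) {
  record$time[record$neuron == neuron]
}

#' Population firing rate in a time window
#'
#' Mean over the population of (spike count in window / window length),
#' in spikes per second.
#'
#' @param record \code{spike_record}
#' @param window numeric pair (start, end) in seconds; defaults to the
#'   whole interval
#' @param population neuron subset (default all)
#' @return firing rate (1/s)
#' @export
firing_rate <- function(record, window = c(0, record$duration),
                        population = seq_len(record$n_neurons)) {
  if (diff(window) <= 0) stop("empty window")
  if (window[1] < 0 || window[2] > record$duration + 1e-9)
    stop("window outside the simulation interval")
  sel <- record$time >= window[1] & record$time < window[2] &
    record$neuron %in% population
  sum(sel) / diff(window) / length(population)
}

#' Per-neuron spike counts in a window
#' @inheritParams firing_rate
#' @return integer vector of counts (length \code{n_neurons})
#' @export
spike_counts <- function(record, window = c(0, record$duration)) {
  sel <- record$time >= window[1] & record$time < window[2]
  tabulate(record$neuron[sel], nbins = record$n_neurons)
}

#' Binned population spike counts
#' @param record \code{spike_record}
#' @param bin bin width (s)
#' @return numeric vector of total network spike counts per bin
#' @export
binned_counts <- function(record, bin = 0.010) {
  if (bin > record$duration) stop("bin larger than the record")
  breaks <- seq(0, record$duration, by = bin)
  if (breaks[length(breaks)] < record$duration - 1e-12)
    breaks <- c(breaks, record$duration)
  as.numeric(table(cut(record$time, breaks = breaks, right = FALSE,
                       include.lowest = TRUE)))
}

#' Export a spike record as two-column text
#' @param record \code{spike_record}
#' @param path output file
#' @return invisibly, the path
#' @export
export_spikes <- function(record, path) {
  utils::write.table(data.frame(neuron_id = record$neuron,
                                time_s = record$time),
                     path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
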