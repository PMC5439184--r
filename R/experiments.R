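#' Simulate a single NMDAR synapse with controlled spike trains
#'
#' Low-level driver for the single-synapse protocols: a presynaptic input
#' terminal connected to a postsynaptic neuron whose firing is controlled
#' externally (its membrane is integrated without a threshold, as when
#' action potentials are pharmacologically prevented or evoked by current
#' injection). Returns dense traces of calcium, weight and postsynaptic
#' potential.
#'
#' @param pre_times presynaptic spike times (s)
#' @param post_times forced postsynaptic spike (BPAP) times (s)
#' @param weight initial synaptic weight
#' @param duration simulated time (s)
#' @param plasticity \code{"off"} (calcium computed, weight frozen),
#'   \code{"full"}, \code{"ltp_ltd_only"} or \code{"stdp_only"}
#' @param params \code{\link{plasticity_params}}
#' @param neuron \code{\link{neuron_params}} (background current is not
#'   applied in this preparation)
#' @param dt timestep (s)
#' @param record_every record every n-th step
#' @return list with vectors \code{time}, \code{calcium}, \code{weight},
#'   \code{v_post}
#' @export
simulate_synapse <- function(pre_times, post_times = numeric(0), weight,
                             duration, plasticity = "full",
                             params = NULL, neuron = neuron_params(),
                             dt = 2e-4, record_every = 1L) {
  if (is.null(params)) {
    params <- if (plasticity %in% c("off", "full")) plasticity_params("full")
              else plasticity_params(plasticity)
  }
  cpp_simulate_synapse(as.numeric(sort(pre_times)), as.numeric(sort(post_times)),
                       weight, duration, dt, variant_code(plasticity),
                       unclass(neuron), unclass(params),
                       as.integer(record_every))
}

# EPSP amplitude readout: peak postsynaptic depolarization within `win`
# seconds after each probe spike, relative to the pre-probe baseline.
epsp_amplitudes <- function(trace, probe_times, win = 0.030) {
  vapply(probe_times, function(tp) {
    i0 <- findInterval(tp, trace$time)
    i1 <- findInterval(tp + win, trace$time)
    if (i0 < 1 || i1 <= i0) return(NA_real_)
    max(trace$v_post[i0:i1]) - trace$v_post[i0]
  }, 0)
}

#' Tetanus protocol on a single synapse
#'
#' Baseline EPSP amplitudes are probed with low-frequency presynaptic
#' spikes (0.2 Hz); a tetanus of the given frequency and duration is then
#' applied, and probing continues. The postsynaptic neuron never fires
#' (no BPAPs), so plasticity is driven purely by the presynaptic rate.
#' High-frequency tetani (50 Hz) produce a lasting increase of the EPSP
#' amplitude (LTP); low-frequency tetani (20 Hz) a lasting decrease (LTD).
#'
#' @param freq tetanus frequency (Hz); 0 runs probes only
#' @param tetanus_duration tetanus length (s)
#' @param probe_rate probe frequency (Hz)
#' @param initial_weight starting weight
#' @param n_baseline,n_after number of probe spikes before/after
#' @param params,dt see \code{\link{simulate_synapse}}
#' @return list: \code{probe_times}, \code{amplitudes} (mV),
#'   \code{baseline} (mean baseline amplitude), \code{ratio} (mean
#'   post-tetanus amplitude / baseline), \code{trace}
#' @export
run_tetanus_protocol <- function(freq, tetanus_duration = 2,
                                 probe_rate = 0.2, initial_weight = 3e-8,
                                 n_baseline = 4, n_after = 12,
                                 params = NULL, dt = 2e-4) {
  probe_gap <- 1 / probe_rate
  t_baseline <- seq_len(n_baseline) * probe_gap
  t_tet_start <- max(t_baseline) + probe_gap / 2
  tet <- if (freq > 0) t_tet_start + seq(0, tetanus_duration - 1e-9, by = 1 / freq)
         else numeric(0)
  t_after <- t_tet_start + tetanus_duration + seq_len(n_after) * probe_gap
  pre <- sort(c(t_baseline, tet, t_after))
  duration <- max(pre) + probe_gap / 2
  tr <- simulate_synapse(pre, numeric(0), initial_weight, duration,
                         plasticity = "full", params = params, dt = dt,
                         record_every = 5L)
  amp_base <- epsp_amplitudes(tr, t_baseline)
  amp_after <- epsp_amplitudes(tr, t_after)
  list(probe_times = c(t_baseline, t_after),
       amplitudes = c(amp_base, amp_after),
       baseline = mean(amp_base),
       ratio = mean(amp_after[(length(amp_after) %/% 2):length(amp_after)]) /
         mean(amp_base),
       final_weight = tr$weight[length(tr$weight)],
       trace = tr)
}

#' Spike-pairing (dual patch clamp) protocol on a single synapse
#'
#' Pre- and postsynaptic spikes are paired at interval \code{delta_t}
#' (positive = pre before post) at 1 Hz repetition. EPSP amplitudes are
#' probed before and after the pairing block with low-frequency
#' presynaptic spikes. Pre-post pairing (+15 ms) potentiates; post-pre
#' pairing (-75 ms) depresses.
#'
#' @param delta_t pairing interval (ms), post minus pre
#' @param n_pairings number of pairings
#' @param probe_rate probe frequency (Hz)
#' @param initial_weight starting weight
#' @param pairing_rate repetition rate of the pairing cycles (Hz)
#' @param n_baseline,n_after probe counts
#' @param params,dt see \code{\link{simulate_synapse}}
#' @param plasticity plasticity variant (\code{"stdp_only"} uses the
#'   pair-based synapse model)
#' @return list as in \code{\link{run_tetanus_protocol}}
#' @export
run_pairing_protocol <- function(delta_t, n_pairings, probe_rate = 0.125,
                                 initial_weight = 3e-8, pairing_rate = 1,
                                 n_baseline = 3, n_after = 8,
                                 params = NULL, dt = 2e-4,
                                 plasticity = "full") {
  probe_gap <- 1 / probe_rate
  t_baseline <- seq_len(n_baseline) * probe_gap
  t0 <- max(t_baseline) + probe_gap / 2
  cyc <- if (n_pairings > 0) t0 + (seq_len(n_pairings) - 1) / pairing_rate
         else numeric(0)
  dts <- delta_t / 1000
  pre_pair <- if (dts >= 0) cyc else cyc - dts
  post_pair <- pre_pair + dts
  t1 <- if (n_pairings > 0) max(c(pre_pair, post_pair)) + probe_gap / 2 else t0
  t_after <- t1 + seq_len(n_after) * probe_gap
  pre <- sort(c(t_baseline, pre_pair, t_after))
  duration <- max(pre, post_pair + 0) + probe_gap / 2
  tr <- simulate_synapse(pre, post_pair, initial_weight, duration,
                         plasticity = plasticity, params = params, dt = dt,
                         record_every = 5L)
  amp_base <- epsp_amplitudes(tr, t_baseline)
  amp_after <- epsp_amplitudes(tr, t_after)
  list(probe_times = c(t_baseline, t_after),
       amplitudes = c(amp_base, amp_after),
       baseline = mean(amp_base),
       ratio = mean(amp_after[(length(amp_after) %/% 2):length(amp_after)]) /
         mean(amp_base),
       final_weight = tr$weight[length(tr$weight)],
       trace = tr)
}

#' Peak synaptic calcium under a standard stimulation protocol
#'
#' Reproduces the calcium-response readout of the single-synapse
#' characterization: in \code{"frequency"} mode the presynaptic terminal
#' fires a regular train of the given frequency (Hz) and the postsynaptic
#' neuron is silent; in \code{"pairing"} mode pre/post spike pairs at the
#' given interval (ms) are repeated at 1 Hz. The readout is the
#' steady-state peak calcium (final second of sustained stimulation, or
#' maximum over a late pairing cycle), saturating at 1.0 uM.
#'
#' @param initial_weight synaptic weight (held fixed)
#' @param mode \code{"frequency"} or \code{"pairing"}
#' @param value frequency (Hz) or pairing interval (ms)
#' @param duration total stimulation time (s)
#' @param cap readout saturation level (uM); \code{Inf} disables
#' @param params,dt see \code{\link{simulate_synapse}}
#' @return peak calcium (uM)
#' @export
measure_calcium_response <- function(initial_weight,
                                     mode = c("frequency", "pairing"),
                                     value, duration = 4, cap = 1.0,
                                     params = NULL, dt = 2e-4) {
  mode <- match.arg(mode)
  if (mode == "frequency") {
    pre <- seq(0.05, duration - 1e-9, by = 1 / value)
    post <- numeric(0)
  } else {
    cyc <- seq(0.05, duration - 0.5, by = 1)
    dts <- value / 1000
    pre <- if (dts >= 0) cyc else cyc - dts
    post <- pre + dts
  }
  tr <- simulate_synapse(pre, post, initial_weight, duration,
                         plasticity = "off", params = params, dt = dt)
  sel <- tr$time >= duration - 1
  min(cap, max(tr$calcium[sel]))
}

#' Three-phase familiarity experiment
#'
#' Runs the standard protocol: (1) baseline - network responses to all
#' stimuli are recorded with plasticity disabled; (2) learning -
#' plasticity is enabled and the selected stimuli are presented (0.5 s
#' active + 0.5 s silence per presentation cycle, spike trains regenerated
#' with fresh seeds each cycle) for \code{exposure} seconds each, either
#' as sequential blocks or looping across images; (3) testing - plasticity
#' is disabled and responses to all stimuli are recorded with the same
#' probe seeds as the baseline, so that response changes isolate the
#' weight changes. Responses are population firing rates over the active
#' window.
#'
#' @param network \code{lsm_network} with input projection
#' @param images list of image matrices (normalized)
#' @param learn_ids indices of the images presented during learning
#' @param exposure learning exposure per image (s)
#' @param order \code{"blocks"} (each image presented for its full
#'   exposure, then the next) or \code{"looping"} (cycle through images)
#' @param plasticity plasticity variant used during learning
#' @param f_max peak encoding rate (Hz)
#' @param probe_seed base seed for baseline/test probe encoding
#' @param learn_seed base seed for learning-phase encoding
#' @param noise_amplitude background noise (nA)
#' @param params \code{\link{plasticity_params}}
#' @param dt timestep (s)
#' @param weights optional initial weights (e.g. permuted)
#' @param n_probes probe encodings averaged per response measurement
#' @return object of class \code{experiment_result}: baseline/test
#'   responses, ranks (1 = largest test response), accuracy of the learned
#'   set in the top-k (k = number of learned images), weight snapshots
#' @export
run_familiarity_experiment <- function(network, images, learn_ids,
                                       exposure = 15,
                                       order = c("blocks", "looping"),
                                       plasticity = "full", f_max = 50,
                                       probe_seed = 1000L,
                                       learn_seed = 5000L,
                                       noise_amplitude = 0,
                                       params = NULL, dt = 2e-4,
                                       weights = NULL, n_probes = 3L) {
  order <- match.arg(order)
  n <- length(images)
  if (!all(learn_ids %in% seq_len(n))) stop("learn_ids not a subset of stimuli")
  w0 <- if (is.null(weights)) network$synapses$weight else weights

  probe <- function(w) {
    vapply(seq_len(n), function(i) {
      mean(vapply(seq_len(n_probes), function(k) {
        st <- encode_image(images[[i]], f_max = f_max, silence = 0,
                           seed = probe_seed + i + 1000L * (k - 1L))
        sim <- run_network(network, st, duration = st$active,
                           plasticity = "off", seed = probe_seed + i,
                           noise_amplitude = noise_amplitude, dt = dt,
                           weights = w)
        firing_rate(sim$record, c(0, st$active))
      }, 0))
    }, 0)
  }
  baseline <- probe(w0)

  w <- w0
  if (exposure > 0 && length(learn_ids) > 0) {
    cycles_per_img <- max(1L, round(exposure / 1.0))
    sched <- if (order == "blocks") rep(learn_ids, each = cycles_per_img)
             else rep(learn_ids, times = cycles_per_img)
    stims <- lapply(seq_along(sched), function(k) {
      encode_image(images[[sched[k]]], f_max = f_max, silence = 0.5,
                   seed = learn_seed + k)
    })
    sim <- run_network(network, stims, duration = length(sched) * 1.0,
                       plasticity = plasticity, seed = learn_seed,
                       noise_amplitude = noise_amplitude,
                       params = params, dt = dt, weights = w)
    w <- sim$weights
  }
  test <- probe(w)
  ranks <- rank(-test, ties.method = "first")
  structure(list(baseline = baseline, test = test, ranks = ranks,
                 learn_ids = learn_ids,
                 accuracy = accuracy_topk(ranks[learn_ids],
                                          k = length(learn_ids)),
                 weights_before = w0, weights_after = w,
                 order = order, exposure = exposure),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("familiarity experiment: %d stimuli, learned %s (%.0f s each)\n",
              length(x$baseline), paste(x$learn_ids, collapse = ","),
              x$exposure))
  cat(sprintf("  learned-image rank(s): %s; top-k accuracy %.3f\n",
              paste(x$ranks[x$learn_ids], collapse = ","), x$accuracy))
  invisible(x)
}

#' Fraction of familiar items ranked in the top k
#'
#' The hypothetical-threshold accuracy: the share of learned stimuli whose
#' test responses rank at or above k among all stimuli. Rank ties are
#' broken by stimulus index.
#'
#' @param familiar_ranks ranks of the familiar items (1 = strongest)
#' @param k threshold rank
#' @return fraction in the top k
#' @export
accuracy_topk <- function(familiar_ranks, k) {
  if (k < 1) stop("k must be >= 1")
  mean(familiar_ranks <= k)
}

#' Parameter robustness sweep
#'
#' Repeats a base familiarity protocol while sweeping background noise,
#' a weight-scale multiplier, or a lambda multiplier, and reports the
#' learned-image rank plus a bursting indicator (population-synchronous
#' spiking during the silent interval of a probe presentation).
#'
#' @param parameter \code{"noise_amplitude"}, \code{"wscale_mult"} or
#'   \code{"lambda_mult"}
#' @param values parameter values to sweep
#' @param base_protocol list of arguments for
#'   \code{\link{run_familiarity_experiment}} (network, images, learn_ids,
#'   ...); for \code{wscale_mult}/\code{lambda_mult} the network is rebuilt
#'   from its config with the scaled parameter
#' @return data frame with one row per value: rank of the learned image,
#'   accuracy, bursting indicator
#' @export
robustness_sweep <- function(parameter = c("noise_amplitude", "wscale_mult",
                                           "lambda_mult"),
                             values, base_protocol) {
  parameter <- match.arg(parameter)
  if (length(values) == 0) stop("empty value list")
  rows <- lapply(values, function(v) {
    args <- base_protocol
    net <- args$network
    if (parameter == "noise_amplitude") {
      args$noise_amplitude <- v
    } else {
      cfg <- net$config
      if (parameter == "wscale_mult") cfg$wscale <- cfg$wscale * v
      if (parameter == "lambda_mult") cfg$lambda_ <- cfg$lambda_ * v
      net2 <- build_network(cfg)
      net2 <- build_input_projection(net2, net$input_dims,
                                     mode = cfg$input_mode)
      args$network <- net2
      net <- net2
    }
    res <- do.call(run_familiarity_experiment, args)
    # bursting probe: present one stimulus with its silent interval and
    # look for spikes after stimulus offset
    img <- args$images[[args$learn_ids[1]]]
    st <- encode_image(img, silence = 0.5, seed = 42L)
    sim <- run_network(net, st, duration = st$duration, plasticity = "off",
                       seed = 42L,
                       noise_amplitude = if (parameter == "noise_amplitude") v else 0,
                       weights = res$weights_after)
    silent_rate <- firing_rate(sim$record, c(st$active + 0.1, st$duration))
    data.frame(value = v, rank = res$ranks[res$learn_ids[1]],
               accuracy = res$accuracy, silent_rate = silent_rate,
               bursting = silent_rate > 1)
  })
  do.call(rbind, rows)
}
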