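#' Create a fresh set of spike-trace detectors
#'
#' Each neuron carries four exponentially decaying detectors acting as
#' running estimates of its firing rate: `r1`, `r2` (presynaptic role,
#' decaying with `tau_plus` and `tau_x`) and `o1`, `o2` (postsynaptic role,
#' decaying with `tau_minus` and `tau_y`). All start at zero and each is
#' incremented by one unit whenever the neuron fires.
#'
#' @param n number of neurons
#' @return list of four numeric vectors, class `trace_state`
#' @export
trace_state <- function(n) {
  z <- numeric(n)
  structure(list(r1 = z, r2 = z, o1 = z, o2 = z), class = "trace_state")
}

#' Exponentially decay all spike-trace detectors
#'
#' @param traces a [trace_state()] object
#' @param dt elapsed time (ms)
#' @param params a [triplet_params()] object supplying the four decay times
#' @return the decayed `trace_state`
#' @export
decay_traces <- function(traces, dt, params) {
  if (dt <= 0) stop("dt must be > 0")
  traces$r1 <- traces$r1 * exp(-dt / params$tau_plus)
  traces$r2 <- traces$r2 * exp(-dt / params$tau_x)
  traces$o1 <- traces$o1 * exp(-dt / params$tau_minus)
  traces$o2 <- traces$o2 * exp(-dt / params$tau_y)
  traces
}

#' Apply the plasticity rule triggered by one neuron's spike
#'
#' The spiking neuron is presynaptic to every outgoing synapse and
#' postsynaptic to every incoming one, so a single spike triggers the
#' depression-side update on row `neuron_id` of `w` and the
#' potentiation-side update on column `neuron_id`, in that order (which
#' makes coincident pre/post spikes deterministic). The second-order
#' detectors of the spiking neuron (`r2`, `o2`) enter with their values
#' just before the spike; the four detectors are incremented afterwards.
#' Every modified weight is clipped to `[0, w_max]`.
#'
#' @param neuron_id index of the spiking neuron
#' @param traces a [trace_state()] decayed to the current time
#' @param w scaling-factor matrix, `w[i, j]` for the synapse i -> j
#' @param wiring binary wiring matrix, same orientation
#' @param params a [triplet_params()] object
#' @return list with updated `traces` and `w`
#' @export
on_spike <- function(neuron_id, traces, w, wiring, params) {
  stopifnot(neuron_id >= 1, neuron_id <= nrow(w),
            all(dim(w) == dim(wiring)))
  lam <- params$lambda
  out <- wiring[neuron_id, ] > 0
  if (any(out)) {
    dw <- params$sign_pre * lam * traces$o1[out] *
      (params$A2_minus + params$A3_minus * traces$r2[neuron_id])
    w[neuron_id, out] <- pmin(pmax(w[neuron_id, out] + dw, 0), params$w_max)
  }
  inc <- wiring[, neuron_id] > 0
  if (any(inc)) {
    dw <- params$sign_post * lam * traces$r1[inc] *
      (params$A2_plus + params$A3_plus * traces$o2[neuron_id])
    w[inc, neuron_id] <- pmin(pmax(w[inc, neuron_id] + dw, 0), params$w_max)
  }
  for (f in c("r1", "r2", "o1", "o2"))
    traces[[f]][neuron_id] <- traces[[f]][neuron_id] + 1
  list(traces = traces, w = w)
}

#' Apply a plasticity rule to two prescribed spike trains
#'
#' Event-driven and exact for the given spike times: detectors decay
#' analytically between events, coincident events are processed
#' pre-triggered-update first. This is the engine behind the pairing
#' protocols.
#'
#' @param pre,post presynaptic and postsynaptic spike times (ms, sorted)
#' @param rule a [triplet_params()] object
#' @param w0 initial scaling factor
#' @return final scaling factor (clipped to `[0, w_max]` throughout)
#' @export
stdp_apply_trains <- function(pre, post, rule, w0 = 0.5) {
  stopifnot(inherits(rule, "triplet_params"),
            !is.unsorted(pre), !is.unsorted(post))
  cpp_stdp_trains(as.numeric(pre), as.numeric(post), rule_vector(rule), w0,
                  rule$w_max)
}

#' Standard spike-timing pairing protocol
#'
#' `n_pairs` pre/post pairs with fixed offset `delta_t = t_post - t_pre`
#' are delivered at `pairing_rate`; the relative change of the scaling
#' factor is returned. Positive `delta_t` is the causal (pre-before-post)
#' ordering.
#'
#' @param delta_t spike-timing offset (ms); `0` is handled by the
#'   pre-first coincidence rule
#' @param n_pairs number of pairing events
#' @param pairing_rate repetition rate of the pairs (Hz)
#' @param rule a [triplet_params()] object
#' @param w0 initial scaling factor
#' @return relative weight change `(w_final - w0) / w0`
#' @export
run_timing_protocol <- function(delta_t, n_pairs = 60, pairing_rate = 1,
                                rule = triplet_params(), w0 = 0.5) {
  if (n_pairs == 0) return(0)
  period <- 1000 / pairing_rate
  if (period <= abs(delta_t))
    stop("pairing_rate too high: inter-pair interval must exceed |delta_t|")
  base <- seq_len(n_pairs) * period
  pre <- base
  post <- base + delta_t
  shift <- abs(min(c(pre, post))) + 1
  wf <- stdp_apply_trains(pre + shift, post + shift, rule, w0)
  (wf - w0) / w0
}

#' Frequency dependence of the pairing protocol
#'
#' Runs the timing protocol at a fixed offset for each pairing rate. For
#' the triplet rule with post-before-pre pairs this exhibits the
#' experimentally observed reversal: depression at low rates, potentiation
#' above a critical frequency.
#'
#' @param delta_t spike-timing offset (ms)
#' @param rule a [triplet_params()] object
#' @param rates pairing rates (Hz)
#' @param n_pairs number of pairing events per rate
#' @param w0 initial scaling factor
#' @return numeric vector of relative weight changes, one per rate
#' @export
run_frequency_protocol <- function(delta_t, rule = triplet_params(),
                                   rates = c(1, 5, 10, 20, 30, 40, 50),
                                   n_pairs = 60, w0 = 0.5) {
  if (any(rates <= 0)) stop("rates must be positive")
  if (any(1000 / rates < abs(delta_t)))
    stop("pairing period shorter than |delta_t|: protocol degenerates")
  vapply(rates, function(r) {
    run_timing_protocol(delta_t, n_pairs, r, rule, w0)
  }, numeric(1))
}

#' LTD-to-LTP crossover frequency of the frequency protocol
#'
#' Bisects the pairing rate to the zero crossing of the net weight change.
#' If the change does not switch sign over the bracket (as for the
#' pair-based control), `NA` is returned with a message attribute.
#'
#' @param rule a [triplet_params()] object
#' @param delta_t spike-timing offset (ms); the canonical choice is the
#'   post-before-pre offset `-10`
#' @param bracket search interval (Hz)
#' @param tol bisection tolerance (Hz)
#' @param n_pairs pairing events per protocol run
#' @return crossover frequency (Hz), or `NA` if there is no sign change
#' @export
ltd_ltp_crossover <- function(rule = triplet_params(), delta_t = -10,
                              bracket = c(0.5, 60), tol = 0.1,
                              n_pairs = 60) {
  f <- function(r) run_timing_protocol(delta_t, n_pairs, r, rule)
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi) || flo == 0 && fhi == 0)
    return(structure(NA_real_, reason = "no crossover in bracket"))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Weight change over a grid of pre- and postsynaptic rates
#'
#' Regular spike trains at each rate combination, with the postsynaptic
#' train offset by `delta_t`, are applied to an isolated synapse over
#' `duration`. The resulting map is Hebbian: dominated by the postsynaptic
#' rate, with timing-dependent ridges where the two rates are
#' commensurate.
#'
#' @param pre_rates,post_rates rate grids (Hz); a zero rate means no spikes
#' @param delta_t offset of the postsynaptic train (ms)
#' @param rule a [triplet_params()] object
#' @param duration train duration (ms)
#' @param w0 initial scaling factor
#' @return matrix of relative weight changes, rows indexed by `pre_rates`
#' @export
rate_pair_map <- function(pre_rates, post_rates, delta_t = 10,
                          rule = triplet_params(), duration = 2000,
                          w0 = 0.5) {
  m <- matrix(0, length(pre_rates), length(post_rates),
              dimnames = list(pre_rates, post_rates))
  for (i in seq_along(pre_rates)) {
    rx <- pre_rates[i]
    pre <- if (rx > 0) seq(0, duration, by = 1000 / rx) else numeric()
    for (j in seq_along(post_rates)) {
      ry <- post_rates[j]
      if (rx == 0) next # no synaptic events at all
      post <- if (ry > 0) seq(0, duration, by = 1000 / ry) + delta_t
              else numeric()
      post <- post[post >= 0 & post <= duration]
      wf <- stdp_apply_trains(pre + 1, post + 1, rule, w0)
      m[i, j] <- (wf - w0) / w0
    }
  }
  m
}
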