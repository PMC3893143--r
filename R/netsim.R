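#' Build a randomly pruned recurrent wiring
#'
#' Starts from all-to-all connectivity without autapses and retains each
#' directed edge independently with probability `1 - prune_fraction`. The
#' maximal synaptic efficacy defaults to `72000 / (N - 1)` pA, which keeps
#' the expected recurrent drive per neuron independent of network size.
#' Short-term dynamics kinds are assigned per presynaptic neuron
#' (homogeneous or two-population layouts) or per synapse (`"overlapping"`).
#'
#' @param N number of neurons (>= 2)
#' @param prune_fraction fraction of possible edges removed, in `[0, 1)`
#' @param seed RNG seed; identical seeds give identical wirings
#' @param kind `"depressing"`, `"facilitating"`, `"mixed_populations"`
#'   (first half depressing, second half facilitating) or `"overlapping"`
#'   (per-synapse kind, depressing with probability `p_depressing`)
#' @param p_depressing per-synapse probability of a depressing kind when
#'   `kind = "overlapping"`
#' @param A maximal synaptic efficacy (pA), scalar or `N x N` matrix;
#'   `NULL` for the size-scaled default
#' @return object of class `wiring`: list with the binary matrix `C`
#'   (`C[i, j] = 1` when neuron i projects to neuron j), efficacy matrix
#'   `A`, character kind matrix (`"D"`/`"F"`), population labels, and
#'   bookkeeping fields
#' @export
build_wiring <- function(N, prune_fraction = 0.2, seed = 1,
                         kind = c("depressing", "facilitating",
                                  "mixed_populations", "overlapping"),
                         p_depressing = 0.5, A = NULL) {
  if (N < 2) stop("N must be >= 2")
  if (prune_fraction < 0 || prune_fraction >= 1)
    stop("prune_fraction must be in [0, 1)")
  kind <- match.arg(kind)
  set.seed(seed)
  C <- matrix(rbinom(N * N, 1, 1 - prune_fraction), N, N)
  diag(C) <- 0L
  if (is.null(A)) A <- 72000 / (N - 1)
  if (length(A) == 1) A <- matrix(A, N, N)
  labels <- switch(kind,
    depressing = rep("D", N),
    facilitating = rep("F", N),
    mixed_populations = rep(c("D", "F"), c(ceiling(N / 2), floor(N / 2))),
    overlapping = rep("M", N))
  K <- if (kind == "overlapping") {
    matrix(ifelse(runif(N * N) < p_depressing, "D", "F"), N, N)
  } else {
    matrix(rep(ifelse(labels == "D", "D", "F"), N), N, N)
  }
  K[C == 0] <- NA_character_
  structure(list(C = C, A = A, kind = K, labels = labels, N = N,
                 prune_fraction = prune_fraction, seed = seed,
                 layout = kind),
            class = "wiring")
}

#' Stimulus protocol description
#'
#' The toy drive is a travelling wave: on top of a weak constant baseline,
#' a depolarising pulse with a narrow bell-shaped spatial profile (unit
#' peak, standard deviation `sigma` in neuron-index units) is centred on
#' one unit and moves to the neighbouring unit every `dwell_time` ms,
#' wrapping around the index ring. Large networks add per-neuron coloured
#' (Ornstein-Uhlenbeck) background currents with means drawn once per
#' neuron at unit coefficient of variation. `"strong_drive_subset"` adds a
#' constant suprathreshold current to selected units.
#'
#' @param mode `"toy_wave"`, `"wave_plus_noise"` or `"strong_drive_subset"`
#' @param baseline constant current (nA)
#' @param pulse_amplitude wave pulse amplitude (nA)
#' @param dwell_time time the wave spends on each unit (ms)
#' @param sigma spatial width of the pulse (neuron-index units)
#' @param wrap does the wave wrap around the index ring?
#' @param noise_mean grand mean of the per-neuron noise means (pA)
#' @param noise_std noise standard deviation (pA)
#' @param noise_tau noise autocorrelation time (ms)
#' @param drive_units indices receiving the strong constant drive
#' @param drive_current strong drive amplitude (pA)
#' @return object of class `stimulus_protocol`
#' @export
stimulus_protocol <- function(mode = c("toy_wave", "wave_plus_noise",
                                       "strong_drive_subset"),
                              baseline = 0.2, pulse_amplitude = 1.0,
                              dwell_time = 20, sigma = 0.5, wrap = TRUE,
                              noise_mean = 100, noise_std = 150,
                              noise_tau = 5, drive_units = integer(),
                              drive_current = 1100) {
  mode <- match.arg(mode)
  if (dwell_time <= 0 || sigma <= 0) stop("dwell_time and sigma must be > 0")
  if (noise_std < 0 || noise_tau <= 0) stop("invalid noise parameters")
  structure(list(mode = mode, baseline = baseline,
                 pulse_amplitude = pulse_amplitude, dwell_time = dwell_time,
                 sigma = sigma, wrap = wrap, noise_mean = noise_mean,
                 noise_std = noise_std, noise_tau = noise_tau,
                 drive_units = drive_units, drive_current = drive_current),
            class = "stimulus_protocol")
}

#' Travelling-wave input current
#'
#' @param t time (ms)
#' @param neuron_index 1-based neuron index (vectorised)
#' @param protocol a [stimulus_protocol()] object
#' @param N network size
#' @return input current (nA)
#' @export
traveling_wave_current <- function(t, neuron_index, protocol, N) {
  stopifnot(t >= 0, all(neuron_index >= 1), all(neuron_index <= N))
  centre <- floor(t / protocol$dwell_time) %% N # 0-based position
  d <- abs((neuron_index - 1) - centre)
  if (protocol$wrap) d <- pmin(d, N - d)
  protocol$baseline +
    protocol$pulse_amplitude * exp(-0.5 * d^2 / protocol$sigma^2)
}

#' Per-neuron coloured background noise streams
#'
#' Ornstein-Uhlenbeck currents with exact discretisation, so the
#' stationary mean, variance and autocorrelation do not depend on `dt`.
#' Each neuron's mean is drawn once from a normal distribution with mean
#' `noise_mean` and unit coefficient of variation.
#'
#' @param N number of neurons
#' @param protocol a [stimulus_protocol()] object
#' @param dt sampling step (ms), must be below `noise_tau`
#' @param duration stream length (ms)
#' @param seed RNG seed
#' @return list with `current` (steps x N matrix, pA) and `mu` (per-neuron
#'   means, pA)
#' @export
background_noise_current <- function(N, protocol, dt, duration, seed = 1) {
  if (dt >= protocol$noise_tau)
    stop("dt must be smaller than the noise autocorrelation time")
  set.seed(seed)
  mu <- rnorm(N, protocol$noise_mean, abs(protocol$noise_mean))
  steps <- floor(duration / dt)
  rho <- exp(-dt / protocol$noise_tau)
  s1 <- protocol$noise_std * sqrt(1 - rho^2)
  eps <- matrix(rnorm(steps * N, 0, s1), steps, N)
  cur <- matrix(0, steps, N)
  for (i in seq_len(N))
    cur[, i] <- mu[i] + stats::filter(eps[, i], rho, method = "recursive",
                                      init = 0)
  list(current = cur, mu = mu)
}

#' Simulate a plastic recurrent network
#'
#' Couples the adaptive exponential neurons, PSC kinetics, per-synapse
#' short-term dynamics and the triplet STDP rule in one forward-Euler
#' loop (compiled). Within a step: states decay, external plus synaptic
#' currents are applied, thresholds are tested, and spike-triggered
#' updates run (depression-side weight updates, potentiation-side weight
#' updates, detector increments, synaptic release); spikes reach their
#' targets at the next step. Fully reproducible given `seed`, which drives
#' independent draws for initial weights and noise.
#'
#' @param wiring a [build_wiring()] object
#' @param protocol a [stimulus_protocol()] object
#' @param duration simulated time (ms)
#' @param dt integration step (ms)
#' @param seed master seed for initial weights and noise
#' @param neuron a [neuron_params()] object
#' @param sd_dep,sd_fac [sd_params()] objects for the two synapse kinds
#' @param rule a [triplet_params()] object; set `lambda = 0` to freeze
#'   long-term plasticity
#' @param w_init initial scaling matrix; `NULL` draws uniform `[0, w_max]`
#' @param w_cross_scale multiplier applied to initial cross-population
#'   weights in two-population layouts (weaker-than-intra initialisation)
#' @param snapshot_every cadence of scaling-matrix snapshots (ms); the
#'   final snapshot is always taken
#' @param record_spikes keep the spike record?
#' @return object of class `spikesim`: spike record, final and snapshot
#'   scaling matrices, and the inputs needed to reproduce the run
#' @export
simulate_network <- function(wiring, protocol, duration, dt = 0.1, seed = 1,
                             neuron = neuron_params(),
                             sd_dep = sd_params("depressing"),
                             sd_fac = sd_params("facilitating"),
                             rule = triplet_params(), w_init = NULL,
                             w_cross_scale = 1, snapshot_every = 1000,
                             record_spikes = TRUE) {
  stopifnot(inherits(wiring, "wiring"), inherits(protocol, "stimulus_protocol"),
            duration > dt)
  N <- wiring$N
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 2)
  if (is.null(w_init)) {
    set.seed(sub[1])
    w_init <- matrix(runif(N * N, 0, rule$w_max), N, N)
  }
  stopifnot(all(dim(w_init) == N))
  w <- w_init
  if (w_cross_scale != 1) {
    cross <- outer(wiring$labels, wiring$labels, FUN = `!=`)
    w[cross] <- w[cross] * w_cross_scale
  }
  w[wiring$C == 0] <- 0
  kindF <- wiring$kind == "F"
  kindF[is.na(kindF)] <- FALSE
  baseline <- rep(protocol$baseline * 1000, N) # nA -> pA
  extra <- rep(0, N)
  if (protocol$mode == "strong_drive_subset" &&
      length(protocol$drive_units) > 0)
    extra[protocol$drive_units] <- protocol$drive_current
  noise_on <- protocol$mode %in% c("wave_plus_noise", "strong_drive_subset")
  set.seed(sub[2])
  noise_mu <- if (noise_on)
    rnorm(N, protocol$noise_mean, abs(protocol$noise_mean)) else rep(0, N)
  sdvec <- c(U_D = sd_dep$U, taurec_D = sd_dep$tau_rec,
             taufac_D = sd_dep$tau_facil, U_F = sd_fac$U,
             taurec_F = sd_fac$tau_rec, taufac_F = sd_fac$tau_facil,
             tausyn = sd_dep$tau_syn)
  res <- cpp_simulate_network(
    wiring$C, wiring$A, w, kindF, neuron_vector(neuron), rule_vector(rule),
    sdvec, baseline, extra,
    wave_on = TRUE, wave_amp = protocol$pulse_amplitude * 1000,
    wave_dwell = protocol$dwell_time, wave_sigma = protocol$sigma,
    wave_wrap = protocol$wrap, noise_on = noise_on, noise_mu = noise_mu,
    noise_sd = protocol$noise_std, noise_tau = protocol$noise_tau,
    duration = duration, dt = dt, snapshot_every = snapshot_every,
    record_spikes = record_spikes)
  snaps <- res$snapshots
  times <- res$snapshot_times
  if (length(times) == 0 || times[length(times)] < duration) {
    snaps <- c(snaps, list(res$w_final))
    times <- c(times, duration)
  }
  structure(list(
    spikes = data.frame(time = res$spike_time, neuron = res$spike_id),
    w_final = res$w_final, w_init = w, snapshots = snaps,
    snapshot_times = times, duration = duration, dt = dt, seed = seed,
    wiring = wiring, protocol = protocol, rule = rule,
    sd_dep = sd_dep, sd_fac = sd_fac, neuron = neuron),
    class = "spikesim")
}

#' Per-neuron firing rates over a trailing window
#'
#' @param sim a [simulate_network()] result (or a data frame with `time`
#'   and `neuron` columns plus attributes `duration` and `N`)
#' @param window length of the trailing window (ms); `NULL` for the whole run
#' @param breaks histogram breaks (Hz), passed to [graphics::hist()]
#'   semantics via [base::cut()]; `NULL` for Sturges-style defaults
#' @return list with `rates` (Hz, per neuron), `histogram` (counts and
#'   mids) and the window used
#' @export
rate_summary <- function(sim, window = NULL, breaks = NULL) {
  spikes <- sim$spikes
  duration <- sim$duration
  N <- sim$wiring$N
  if (is.null(window)) window <- duration
  if (window > duration) stop("window must not exceed the run duration")
  keep <- spikes$time >= duration - window
  tab <- tabulate(spikes$neuron[keep], nbins = N)
  rates <- tab / (window / 1000)
  if (is.null(breaks)) breaks <- seq(0, max(rates, 1) + 5, length.out = 16)
  h <- hist(rates, breaks = breaks, plot = FALSE)
  list(rates = rates, histogram = list(counts = h$counts, mids = h$mids,
                                       breaks = h$breaks),
       window = window)
}

#' @importFrom graphics hist
NULL
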