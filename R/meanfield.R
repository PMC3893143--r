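#' Mean-field configuration
#'
#' Wilson-Cowan-style rate description of one or two recurrently coupled
#' populations with threshold-linear gain, short-term synaptic dynamics in
#' the mean efficacies, and a rate-dependent plasticity drift on the
#' scaling factors. Rate-model parameters live in their own block (they
#' are not meant to match the spiking simulations quantitatively; input is
#' expressed in rate units so the gain has unit slope by default).
#'
#' @param populations character vector of population kinds, `"D"` or `"F"`
#'   (length 1 or 2)
#' @param tau rate relaxation time constant (ms)
#' @param nu_thr threshold of the frequency-current response (input units)
#' @param gain_slope slope of the threshold-linear response
#' @param h average external input; 0 is the balanced case
#' @param A maximal synaptic efficacy, scalar or `P x P` matrix with
#'   `A[l, k]` the block from presynaptic population l to postsynaptic k
#' @param w initial scaling factors, same layout; default 0.7 within
#'   populations and `0.7 * w_cross_scale` across
#' @param w_cross_scale cross-population initial weakening ratio
#' @param sd_dep,sd_fac [sd_params()] objects for the two synapse kinds
#' @param rule [triplet_params()] supplying the drift coefficients
#' @param lambda_w mean-field plasticity rate (scales the drift)
#' @param w_max scaling-factor bound
#' @param p_depressing for a single population with overlapping kinds: the
#'   per-synapse probability of a depressing synapse (`NULL` = homogeneous)
#' @param inhibition optional recurrent inhibitory population with fixed,
#'   non-plastic couplings: a list with `J_ie` (excitatory drive onto the
#'   interneurons, per excitatory population), `J_ei` (inhibitory feedback
#'   strength) and optionally `h_i` (external input to the interneurons,
#'   default 0). The interneuron rate follows the same threshold-linear
#'   gain and is assumed fast (steady state within a rate step). `NULL`
#'   (default) disables it.
#' @return object of class `mf_config`
#' @export
mf_config <- function(populations = c("D", "F"), tau = 10, nu_thr = 2,
                      gain_slope = 1, h = 0, A = 10, w = NULL,
                      w_cross_scale = 0.1,
                      sd_dep = sd_params("depressing"),
                      sd_fac = sd_params("facilitating"),
                      rule = triplet_params(), lambda_w = 2, w_max = 1,
                      p_depressing = NULL, inhibition = NULL) {
  stopifnot(all(populations %in% c("D", "F")),
            length(populations) %in% 1:2, tau > 0)
  P <- length(populations)
  if (length(A) == 1) A <- matrix(A, P, P)
  if (is.null(w)) {
    w <- matrix(0.7, P, P)
    if (P == 2) w[cbind(c(1, 2), c(2, 1))] <- 0.7 * w_cross_scale
  }
  if (!is.null(p_depressing) &&
      (P != 1 || p_depressing < 0 || p_depressing > 1))
    stop("p_depressing needs a single population and a value in [0, 1]")
  if (!is.null(inhibition)) {
    stopifnot(is.list(inhibition), !is.null(inhibition$J_ie),
              !is.null(inhibition$J_ei))
    if (is.null(inhibition$h_i)) inhibition$h_i <- 0
  }
  structure(list(populations = populations, P = P, tau = tau,
                 nu_thr = nu_thr, gain_slope = gain_slope, h = h, A = A,
                 w = w, sd_dep = sd_dep, sd_fac = sd_fac, rule = rule,
                 lambda_w = lambda_w, w_max = w_max,
                 p_depressing = p_depressing, inhibition = inhibition,
                 nu_theta = critical_frequency(rule)),
            class = "mf_config")
}

#' Threshold-linear population gain
#'
#' @param input average input (rate units)
#' @param config an [mf_config()] object
#' @return output rate (Hz); zero at and below threshold, linear above
#' @export
mf_gain <- function(input, config) {
  config$gain_slope * pmax(0, input - config$nu_thr)
}

# stationary u*x of the presynaptic block, honouring an overlapping mix
mf_ux <- function(rate, config, pre) {
  sd <- if (config$populations[pre] == "D") config$sd_dep else config$sd_fac
  if (!is.null(config$p_depressing)) {
    p <- config$p_depressing
    uxd <- sd_stationary(rate, config$sd_dep)
    uxf <- sd_stationary(rate, config$sd_fac)
    return(p * uxd$u_inf * uxd$x_inf + (1 - p) * uxf$u_inf * uxf$x_inf)
  }
  st <- sd_stationary(rate, sd)
  st$u_inf * st$x_inf
}

#' Mean synaptic efficacy of a block at a presynaptic rate
#'
#' `J = A * w * u_inf(rate) * x_inf(rate)`: the maximal efficacy scaled by
#' the plasticity factor and the stationary short-term dynamics of the
#' presynaptic population.
#'
#' @param rate_pre presynaptic population rate (Hz)
#' @param config an [mf_config()] object
#' @param pre,post population indices of the block
#' @param w scaling factors to use (defaults to the configured initial ones)
#' @return mean efficacy `J`
#' @export
mean_efficacy <- function(rate_pre, config, pre = 1, post = 1,
                          w = config$w) {
  config$A[pre, post] * w[pre, post] * mf_ux(rate_pre, config, pre)
}

#' Right-hand side of the population rate dynamics
#'
#' `tau * dnu_k/dt = -nu_k + gain(sum_l J_lk(nu_l) nu_l + h)`.
#'
#' @param nu rate vector (Hz), one entry per population
#' @param config an [mf_config()] object
#' @param w scaling factors to use
#' @return `dnu/dt` (Hz per ms)
#' @export
rate_field <- function(nu, config, w = config$w) {
  if (length(nu) != config$P) stop("rate vector has the wrong length")
  drive <- vapply(seq_len(config$P), function(k) {
    sum(vapply(seq_len(config$P), function(l) {
      mean_efficacy(nu[l], config, l, k, w) * nu[l]
    }, numeric(1))) + config$h
  }, numeric(1))
  inh <- config$inhibition
  if (!is.null(inh)) {
    # fast interneurons with fixed couplings, at their steady state
    nu_i <- mf_gain(sum(inh$J_ie * nu) + inh$h_i, config)
    drive <- drive - inh$J_ei * nu_i
  }
  (-nu + mf_gain(drive, config)) / config$tau
}

#' Firing-rate equilibria and their stability
#'
#' Roots of the self-consistency equation are bracketed on a dense rate
#' grid and refined by bisection; stability comes from the sign of the
#' field derivative (one population) or the eigenvalues of a numerical
#' Jacobian (two populations, with a damped-Newton polish from a coarse
#' grid of starting points).
#'
#' @param config an [mf_config()] object
#' @param w scaling factors to use
#' @param scan_max upper end of the rate scan (Hz)
#' @param n_grid grid resolution for bracketing
#' @return list of equilibria, each a list with `rate` (vector, Hz),
#'   `stable` (logical) and `residual`
#' @export
equilibria <- function(config, w = config$w, scan_max = 200,
                       n_grid = 2000) {
  P <- config$P
  eps <- 1e-6
  if (P == 1) {
    f <- function(nu) rate_field(nu, config, w)
    grid <- seq(0, scan_max, length.out = n_grid)
    fv <- vapply(grid, f, numeric(1))
    roots <- numeric()
    if (abs(fv[1]) < 1e-12) roots <- c(roots, 0)
    for (i in seq_len(n_grid - 1)) {
      if (fv[i] == 0 && grid[i] > 0) roots <- c(roots, grid[i])
      if (fv[i] * fv[i + 1] < 0) {
        r <- uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
        roots <- c(roots, r)
      }
    }
    roots <- unique(round(roots, 8))
    return(lapply(roots, function(r) {
      d <- (f(r + eps) - f(max(r - eps, 0))) /
        (r + eps - max(r - eps, 0))
      list(rate = r, stable = d < 0, residual = abs(f(r)))
    }))
  }
  # two populations: damped Newton from a coarse grid of starting points
  f2 <- function(nu) rate_field(nu, config, w)
  starts <- as.matrix(expand.grid(seq(0, scan_max, length.out = 25),
                                  seq(0, scan_max, length.out = 25)))
  sols <- list()
  for (k in seq_len(nrow(starts))) {
    nu <- pmax(starts[k, ], 0)
    ok <- FALSE
    for (it in 1:60) {
      fv <- f2(nu)
      if (max(abs(fv)) < 1e-10) { ok <- TRUE; break }
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        dn <- nu; dn[j] <- dn[j] + eps
        J[, j] <- (f2(dn) - fv) / eps
      }
      step <- tryCatch(solve(J, fv), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      nu <- pmax(nu - 0.8 * step, 0)
      if (any(nu > 10 * scan_max)) break
    }
    if (ok) sols[[length(sols) + 1]] <- nu
  }
  if (length(sols) == 0) return(list())
  key <- unique(round(do.call(rbind, sols), 6))
  lapply(seq_len(nrow(key)), function(i) {
    nu <- key[i, ]
    fv <- f2(nu)
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      dn <- nu; dn[j] <- dn[j] + eps
      J[, j] <- (f2(dn) - fv) / eps
    }
    list(rate = unname(nu), stable = all(Re(eigen(J)$values) < 0),
         residual = max(abs(fv)))
  })
}

#' Mean plasticity drift under independent Poisson firing
#'
#' All-to-all triplet interactions with Poisson pre/post trains give the
#' average drift
#' \deqn{\dot w = \lambda \nu_x \nu_y [\tau_+ (A_2^+ + A_3^+ \tau_y \nu_y)
#'   - \tau_- (A_2^- + A_3^- \tau_x \nu_x)]}
#' which for the minimal rule reduces to
#' `lambda * k * nu_pre * nu_post * (nu_post - nu_theta)` with
#' `k = A3_plus * tau_plus * tau_y`: depression below the critical
#' frequency, potentiation above it.
#'
#' @param w current scaling factor (only used to suppress drift outside
#'   `[0, w_max]`)
#' @param nu_pre,nu_post firing rates (Hz)
#' @param rule a [triplet_params()] object
#' @param lambda plasticity rate multiplier
#' @param w_max scaling-factor bound
#' @return drift `dw/dt` in units of 1/s
#' @export
stdp_drift <- function(w, nu_pre, nu_post, rule = triplet_params(),
                       lambda = 1, w_max = rule$w_max) {
  if (any(nu_pre < 0) || any(nu_post < 0)) stop("rates must be >= 0")
  tp <- rule$tau_plus / 1000; tm <- rule$tau_minus / 1000
  tx <- rule$tau_x / 1000; ty <- rule$tau_y / 1000
  d <- lambda * nu_pre * nu_post *
    (rule$sign_post * tp * (rule$A2_plus + rule$A3_plus * ty * nu_post) +
       rule$sign_pre * tm * (rule$A2_minus + rule$A3_minus * tx * nu_pre))
  d[(w <= 0 & d < 0) | (w >= w_max & d > 0)] <- 0
  d
}

#' Integrate the coupled rate and plasticity dynamics
#'
#' Forward-Euler integration of the population rates together with the
#' slow drift of the scaling factors (clipped to `[0, w_max]`). With the
#' heterogeneous two-population setup and weak initial cross couplings,
#' the D-to-F coupling grows to its bound while the F-to-D coupling decays
#' to zero, and the final rates straddle the critical frequency.
#'
#' @param config an [mf_config()] object
#' @param duration simulated time (ms)
#' @param dt integration step (ms)
#' @param nu0 initial rates; default is a small positive kick
#' @param record_every cadence of recorded samples (ms)
#' @return list with `time` (ms), `nu` (samples x P), and `w`
#'   (samples x P^2, columns in column-major block order)
#' @export
integrate_meanfield <- function(config, duration = 15000, dt = 0.5,
                                nu0 = NULL, record_every = 10) {
  P <- config$P
  nu <- if (is.null(nu0)) rep(5, P) else nu0
  w <- config$w
  steps <- floor(duration / dt)
  every <- max(1, round(record_every / dt))
  idx <- seq(every, steps, by = every)
  out_nu <- matrix(NA_real_, length(idx), P)
  out_w <- matrix(NA_real_, length(idx), P * P)
  row <- 1
  for (s in seq_len(steps)) {
    dnu <- rate_field(nu, config, w)
    dw <- matrix(0, P, P)
    for (l in seq_len(P)) for (k in seq_len(P)) {
      dw[l, k] <- stdp_drift(w[l, k], nu[l], nu[k], config$rule,
                             config$lambda_w, config$w_max)
    }
    nu <- pmax(nu + dt * dnu, 0)
    w <- pmin(pmax(w + dt * dw / 1000, 0), config$w_max)
    if (any(!is.finite(nu)))
      stop("mean-field integration diverged at t = ", s * dt, " ms")
    if (s == idx[row]) {
      out_nu[row, ] <- nu
      out_w[row, ] <- as.vector(w)
      if (row < length(idx)) row <- row + 1
    }
  }
  list(time = idx * dt, nu = out_nu, w = out_w, w_final = w,
       nu_final = nu)
}

#' Equilibria of a mixed-kind population as a function of p
#'
#' A single population whose synapses are depressing with probability `p`
#' and facilitating otherwise: the effective efficacy is the mixture of
#' the two stationary short-term profiles. Stable equilibria interpolate
#' between the pure-facilitating (`p = 0`) and pure-depressing (`p = 1`)
#' cases.
#'
#' @param p_grid values of the depressing probability in `[0, 1]`
#' @param config a single-population [mf_config()] object
#' @param scan_max rate-scan bound (Hz)
#' @return data frame with columns `p`, `rate`, `stable`
#' @export
mixed_equilibria <- function(p_grid, config = mf_config(populations = "F"),
                             scan_max = 200) {
  stopifnot(config$P == 1, all(p_grid >= 0), all(p_grid <= 1))
  out <- lapply(p_grid, function(p) {
    cfg <- config
    cfg$p_depressing <- p
    eq <- equilibria(cfg, scan_max = scan_max)
    if (length(eq) == 0)
      return(data.frame(p = p, rate = NA_real_, stable = NA))
    data.frame(p = p, rate = vapply(eq, `[[`, numeric(1), "rate"),
               stable = vapply(eq, `[[`, logical(1), "stable"))
  })
  do.call(rbind, out)
}

#' Upper bound on reverberating rates from short-term depression
#'
#' For any Tsodyks-Markram synapse `u * x * nu <= 1 / tau_rec`, so a
#' self-consistent population rate cannot exceed
#' `gain_slope * (coupling / tau_rec + h - nu_thr)` (floored at zero),
#' with `coupling = A * w`. The bound is inversely proportional to the
#' recovery time from depression: slowly recovering (depressing) networks
#' are rate-limited, quickly recovering (facilitating) ones are not.
#'
#' @param params an [sd_params()] object (depressing-type)
#' @param coupling product of maximal efficacy and scaling factor
#' @param h external input
#' @param nu_thr gain threshold
#' @param gain_slope gain slope
#' @return bound on the stable population rate (Hz)
#' @export
rate_upper_bound <- function(params, coupling = 1, h = 0, nu_thr = 0,
                             gain_slope = 1) {
  stopifnot(inherits(params, "sd_params"))
  max(0, gain_slope * (coupling / (params$tau_rec / 1000) + h - nu_thr))
}
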