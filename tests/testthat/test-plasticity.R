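rule <- triplet_params()

test_that("trace decay: closed form and semigroup property", {
  tr <- trace_state(3)
  expect_equal(decay_traces(tr, 5, rule), tr) # zeros stay zero
  tr$r1 <- c(1, 0.5, 2)
  one <- decay_traces(tr, rule$tau_plus, rule)
  expect_equal(one$r1, tr$r1 * exp(-1))
  half <- decay_traces(decay_traces(tr, 3.7, rule), 3.7, rule)
  full <- decay_traces(tr, 7.4, rule)
  for (f in c("r1", "r2", "o1", "o2"))
    expect_equal(half[[f]], full[[f]], tolerance = 1e-12)
})

test_that("an isolated spike with zero traces changes no weight", {
  C <- matrix(1, 3, 3); diag(C) <- 0
  w <- matrix(0.5, 3, 3)
  out <- on_spike(2, trace_state(3), w, C, rule)
  expect_equal(out$w, w)
  expect_equal(out$traces$r1[2], 1)
  expect_equal(out$traces$o2[2], 1)
  expect_equal(out$traces$r1[1], 0)
})

test_that("compiled two-train engine matches the event-driven R oracle", {
  set.seed(11)
  for (k in 1:5) {
    pre <- poisson_train(15, 3000)
    post <- poisson_train(25, 3000)
    for (variant in c("triplet", "anti")) {
      rl <- configure_rule(variant, rule)
      expect_equal(stdp_apply_trains(pre, post, rl, 0.5),
                   oracle_triplet_trains(pre, post, rl, 0.5),
                   tolerance = 1e-12)
    }
  }
  # exact-coincidence handling follows the pre-increment convention
  expect_equal(stdp_apply_trains(c(10, 50), c(10, 50), rule, 0.5),
               oracle_triplet_trains(c(10, 50), c(10, 50), rule, 0.5),
               tolerance = 1e-12)
})

test_that("triplet rule with zeroed triplet terms equals pair-based STDP", {
  zeroed <- triplet_params(A2_plus = 4.6e-3, A2_minus = 3e-3, A3_plus = 0,
                           A3_minus = 0)
  set.seed(13)
  for (k in 1:5) {
    pre <- poisson_train(20, 4000)
    post <- poisson_train(20, 4000)
    expect_equal(stdp_apply_trains(pre, post, zeroed, 0.5),
                 oracle_pair_trains(pre, post, 4.6e-3, 3e-3,
                                    zeroed$tau_plus, zeroed$tau_minus),
                 tolerance = 1e-12)
  }
})

test_that("timing protocol reproduces the STDP window", {
  expect_equal(run_timing_protocol(10, 0, 1, rule), 0)
  expect_gt(run_timing_protocol(10, 60, 1, rule), 0)  # causal: LTP
  expect_lt(run_timing_protocol(-10, 60, 1, rule), 0) # anti-causal: LTD
  expect_error(run_timing_protocol(10, 60, 200, rule), "pairing_rate")
})

test_that("variant controls: identity, exact pair match, anti mirror", {
  expect_identical(configure_rule("triplet", rule), rule)
  expect_error(configure_rule("bogus", rule))
  expect_error(triplet_params(variant = "pair", A3_plus = 1e-3), "pair")

  pair <- configure_rule("pair", rule)
  anti <- configure_rule("anti", rule)
  grid <- seq(-100, 100, by = 10)
  w_tri <- vapply(grid, function(d) run_timing_protocol(d, 60, 1, rule),
                  numeric(1))
  w_pair <- vapply(grid, function(d) run_timing_protocol(d, 60, 1, pair),
                   numeric(1))
  w_anti <- vapply(grid, function(d) run_timing_protocol(d, 60, 1, anti),
                   numeric(1))
  # pair variant tuned at 1 Hz matches the triplet window at 1 Hz, up to
  # the first-pair transient of the slow detector (relative size 1/n_pairs)
  expect_equal(w_pair, w_tri, tolerance = 2 / 60)
  # anti variant flips the window about delta_t = 0 (pre/post role mirror):
  # an exact identity, so post-before-pre now potentiates
  expect_equal(w_anti, rev(w_tri), tolerance = 1e-10)
  expect_gt(run_timing_protocol(-10, 60, 1, anti), 0)
})

test_that("frequency protocol: reversal for triplet, none for pair", {
  rates <- c(1, 10, 20, 30, 40, 50)
  tri <- run_frequency_protocol(-10, rule, rates)
  expect_lt(tri[1], 0)
  expect_gt(tri[6], 0)
  pair <- run_frequency_protocol(-10, configure_rule("pair", rule), rates)
  expect_true(all(pair < 0))
  anti <- run_frequency_protocol(10, configure_rule("anti", rule), rates)
  expect_lt(anti[1], 0)
  expect_gt(anti[6], 0)
  expect_error(run_frequency_protocol(-30, rule, c(1, 40)), "degenerates")
})

test_that("crossover bisection: location, absence, pure LTD", {
  cross <- ltd_ltp_crossover(rule, -10)
  expect_gt(cross, 30)
  expect_lt(cross, 40)
  # bracketing to the stated tolerance: the change switches sign there
  expect_lt(run_timing_protocol(-10, 60, cross - 0.2, rule), 0)
  expect_gt(run_timing_protocol(-10, 60, cross + 0.2, rule), 0)
  expect_true(is.na(ltd_ltp_crossover(configure_rule("pair", rule), -10)))
  ltd_only <- triplet_params(A2_plus = 0, A3_plus = 0)
  expect_true(is.na(ltd_ltp_crossover(ltd_only, -10)))
})

test_that("rate-pair map is Hebbian in the postsynaptic rate", {
  m <- rate_pair_map(c(0, 10, 23), c(0, 10, 50), delta_t = 10, rule,
                     duration = 2000)
  expect_true(all(m[1, ] == 0))       # no presynaptic events at all
  expect_true(all(m[, 1] <= 0))       # no post spikes: no LTP terms
  expect_true(all(m[2:3, 3] > 0))     # post above crossover: LTP
})

test_that("weights stay bounded under violent updates", {
  big <- triplet_params(lambda = 50)
  set.seed(17)
  w <- stdp_apply_trains(poisson_train(40, 2000), poisson_train(40, 2000),
                         big, 0.5)
  expect_true(w >= 0 && w <= big$w_max)
})

test_that("Poisson drift sign matches the mean-field reduction", {
  set.seed(19)
  nu_th <- critical_frequency(rule)
  for (nu_post in c(10, 30)) {
    mc <- replicate(40, {
      pre <- poisson_train(20, 5000)
      post <- poisson_train(nu_post, 5000)
      stdp_apply_trains(pre, post, rule, 0.5) - 0.5
    })
    expect_equal(sign(mean(mc)),
                 sign(stdp_drift(0.5, 20, nu_post, rule)))
    expect_equal(sign(nu_post - nu_th),
                 sign(stdp_drift(0.5, 20, nu_post, rule)))
  }
})
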