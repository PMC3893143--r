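cfgF <- mf_config(populations = "F", h = 0)
cfgD <- mf_config(populations = "D", h = 0)

test_that("threshold-linear gain", {
  expect_equal(mf_gain(cfgF$nu_thr - 1, cfgF), 0)
  expect_equal(mf_gain(cfgF$nu_thr, cfgF), 0)
  x <- seq(cfgF$nu_thr + 1, cfgF$nu_thr + 20, by = 1)
  expect_equal(unique(round(diff(mf_gain(x, cfgF)), 10)),
               cfgF$gain_slope)
})

test_that("mean efficacy: resting value, depression bound, F vs D", {
  expect_equal(mean_efficacy(0, cfgD), cfgD$A[1] * cfgD$w[1] * cfgD$sd_dep$U)
  rates <- c(1, 5, 20, 50, 100, 500)
  jd <- vapply(rates, function(r) mean_efficacy(r, cfgD) * r, numeric(1))
  expect_true(all(jd <= cfgD$A[1] * cfgD$w[1] * 1000 / cfgD$sd_dep$tau_rec))
  jf <- vapply(rates, function(r) mean_efficacy(r, cfgF) * r, numeric(1))
  expect_true(all(jf[3:6] > jd[3:6])) # facilitating wins at moderate rates
})

test_that("rate field: quiescence, relaxation, equilibrium consistency", {
  expect_equal(rate_field(0, cfgF), 0) # balanced input: quiescent
  # zero coupling: linear relaxation to gain(h)
  cfg0 <- mf_config(populations = "F", A = 0, h = 10)
  nu <- 0
  for (k in 1:4000) nu <- nu + 0.5 * rate_field(nu, cfg0)
  expect_equal(nu, mf_gain(10, cfg0), tolerance = 1e-6)
  for (e in equilibria(cfgF))
    expect_lt(abs(rate_field(e$rate, cfgF)), 1e-8)
})

test_that("equilibria: balanced uncoupled case and grid-refinement oracle", {
  eq0 <- equilibria(mf_config(populations = "F", A = 0, h = 0))
  expect_equal(length(eq0), 1)
  expect_equal(eq0[[1]]$rate, 0)
  expect_true(eq0[[1]]$stable)
  for (cfg in list(cfgF, cfgD, mf_config(populations = "F", h = 5))) {
    a <- vapply(equilibria(cfg, n_grid = 2000), `[[`, numeric(1), "rate")
    b <- vapply(equilibria(cfg, n_grid = 20000), `[[`, numeric(1), "rate")
    expect_equal(sort(a), sort(b), tolerance = 1e-6)
  }
})

test_that("facilitating equilibria exceed depressing ones; bound respected", {
  for (h in c(0, 5)) {
    eF <- equilibria(mf_config(populations = "F", h = h))
    eD <- equilibria(mf_config(populations = "D", h = h))
    topF <- max(vapply(eF[vapply(eF, `[[`, logical(1), "stable")],
                       `[[`, numeric(1), "rate"))
    topD <- max(vapply(eD[vapply(eD, `[[`, logical(1), "stable")],
                       `[[`, numeric(1), "rate"))
    expect_gt(topF, topD)
    cfg <- mf_config(populations = "D", h = h)
    bound <- rate_upper_bound(cfg$sd_dep, coupling = cfg$A[1] * cfg$w[1],
                              h = h, nu_thr = cfg$nu_thr)
    for (e in eD) expect_lte(e$rate, bound + 1e-6)
  }
})

test_that("depressing equilibria respect the bound over random configs", {
  set.seed(23)
  for (k in 1:20) {
    sd_d <- sd_params("depressing", U = runif(1, 0.2, 0.9),
                      tau_rec = runif(1, 200, 1500),
                      tau_facil = runif(1, 5, 50))
    cfg <- mf_config(populations = "D", A = runif(1, 2, 25),
                     h = runif(1, 0, 8), sd_dep = sd_d)
    bound <- rate_upper_bound(sd_d, coupling = cfg$A[1] * cfg$w[1],
                              h = cfg$h, nu_thr = cfg$nu_thr)
    for (e in equilibria(cfg)) expect_lte(e$rate, bound + 1e-6)
  }
})

test_that("plasticity drift: zeros, signs, critical frequency", {
  expect_equal(stdp_drift(0.5, 0, 30), 0)
  nu_th <- critical_frequency()
  expect_lt(stdp_drift(0.5, 10, nu_th - 5), 0)
  expect_gt(stdp_drift(0.5, 10, nu_th + 5), 0)
  expect_equal(stdp_drift(0.5, 10, nu_th), 0, tolerance = 1e-12)
  # drift suppressed at the bounds
  expect_equal(stdp_drift(0, 10, 5), 0)
  expect_equal(stdp_drift(1, 10, 40), 0)
  expect_error(stdp_drift(0.5, -1, 10), "rates")
})

test_that("mean-field integration: fixed-rate consistency and symmetry", {
  cfg <- mf_config(populations = "F", h = 5, lambda_w = 0)
  tr <- integrate_meanfield(cfg, duration = 4000, dt = 0.5)
  eq <- equilibria(cfg)
  stables <- vapply(eq[vapply(eq, `[[`, logical(1), "stable")], `[[`,
                    numeric(1), "rate")
  expect_lt(min(abs(tr$nu_final - stables)), 1e-3)
  # two identical facilitating populations evolve identically
  cfg2 <- mf_config(populations = c("F", "F"), h = 5, w = matrix(0.7, 2, 2))
  tr2 <- integrate_meanfield(cfg2, duration = 2000, dt = 0.5)
  expect_equal(tr2$nu[, 1], tr2$nu[, 2], tolerance = 1e-10)
  expect_equal(tr2$w_final[1, 1], tr2$w_final[2, 2], tolerance = 1e-10)
})

test_that("mixed-kind equilibria interpolate monotonically", {
  cfg <- mf_config(populations = "F", h = 5)
  eq <- mixed_equilibria(seq(0, 1, by = 0.25), cfg)
  top <- vapply(split(eq, eq$p), function(d) max(d$rate[d$stable]),
                numeric(1))
  expect_true(all(diff(top) <= 1e-8)) # non-increasing in p
  pureF <- equilibria(cfg)
  pureD <- equilibria(mf_config(populations = "D", h = 5))
  expect_equal(sort(eq$rate[eq$p == 0]),
               sort(vapply(pureF, `[[`, numeric(1), "rate")),
               tolerance = 1e-6)
  expect_equal(sort(eq$rate[eq$p == 1]),
               sort(vapply(pureD, `[[`, numeric(1), "rate")),
               tolerance = 1e-6)
})

test_that("recurrent inhibition preserves the F-above-D ordering", {
  top_stable <- function(cfg) {
    eq <- equilibria(cfg)
    st <- vapply(eq, `[[`, logical(1), "stable")
    if (!any(st)) return(NA_real_)
    max(vapply(eq[st], `[[`, numeric(1), "rate"))
  }
  for (jei in c(0.05, 0.1, 0.2)) for (h in c(3, 5, 8)) {
    inh <- list(J_ie = 0.5, J_ei = jei)
    tF <- top_stable(mf_config(populations = "F", h = h, inhibition = inh))
    tD <- top_stable(mf_config(populations = "D", h = h, inhibition = inh))
    expect_gt(tF, tD)
    # inhibition lowers (or keeps) the top facilitating equilibrium
    t0 <- top_stable(mf_config(populations = "F", h = h))
    expect_lte(tF, t0 + 1e-8)
  }
})

test_that("rate bound scales inversely with the recovery time", {
  sd1 <- sd_params("depressing", tau_rec = 800)
  sd2 <- sd_params("depressing", tau_rec = 400)
  expect_equal(rate_upper_bound(sd2), 2 * rate_upper_bound(sd1))
  expect_lt(rate_upper_bound(sd_params("depressing", tau_rec = 1e9)), 1e-5)
})
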