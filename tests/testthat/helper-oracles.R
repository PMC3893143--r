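# Independent reference implementations used as oracles. These are written
# against the model definitions directly (plain R, per-event loops) and
# deliberately share no code with the library path they check.

# event-driven triplet rule on two spike trains; coincident events apply
# both weight updates from pre-increment trace values
oracle_triplet_trains <- function(pre, post, rule, w0 = 0.5) {
  ev <- rbind(data.frame(t = pre, is_pre = TRUE),
              data.frame(t = post, is_pre = FALSE))
  ev <- ev[order(ev$t, -ev$is_pre), ]
  r1 <- r2 <- o1 <- o2 <- 0
  t_last <- 0
  w <- w0
  i <- 1
  n <- nrow(ev)
  while (i <= n) {
    t <- ev$t[i]
    r1 <- r1 * exp(-(t - t_last) / rule$tau_plus)
    r2 <- r2 * exp(-(t - t_last) / rule$tau_x)
    o1 <- o1 * exp(-(t - t_last) / rule$tau_minus)
    o2 <- o2 * exp(-(t - t_last) / rule$tau_y)
    t_last <- t
    coincident <- i < n && ev$t[i + 1] == t
    here <- if (coincident) c(i, i + 1) else i
    for (k in here) {
      if (ev$is_pre[k]) {
        w <- w + rule$sign_pre * rule$lambda * o1 *
          (rule$A2_minus + rule$A3_minus * r2)
      } else {
        w <- w + rule$sign_post * rule$lambda * r1 *
          (rule$A2_plus + rule$A3_plus * o2)
      }
    }
    for (k in here) {
      if (ev$is_pre[k]) {
        r1 <- r1 + 1
        r2 <- r2 + 1
      } else {
        o1 <- o1 + 1
        o2 <- o2 + 1
      }
    }
    w <- min(max(w, 0), rule$w_max)
    i <- i + length(here)
  }
  w
}

# classic pair-based STDP accumulator (one trace per neuron), used for the
# zeroed-triplet equivalence check
oracle_pair_trains <- function(pre, post, A2_plus, A2_minus, tau_plus,
                               tau_minus, lambda = 1, w0 = 0.5, wmax = 1) {
  ev <- rbind(data.frame(t = pre, is_pre = TRUE),
              data.frame(t = post, is_pre = FALSE))
  ev <- ev[order(ev$t, -ev$is_pre), ]
  rp <- om <- 0
  t_last <- 0
  w <- w0
  i <- 1
  n <- nrow(ev)
  while (i <= n) {
    t <- ev$t[i]
    rp <- rp * exp(-(t - t_last) / tau_plus)
    om <- om * exp(-(t - t_last) / tau_minus)
    t_last <- t
    coincident <- i < n && ev$t[i + 1] == t
    here <- if (coincident) c(i, i + 1) else i
    for (k in here) {
      if (ev$is_pre[k]) w <- w - lambda * A2_minus * om
      else w <- w + lambda * A2_plus * rp
    }
    for (k in here) {
      if (ev$is_pre[k]) rp <- rp + 1 else om <- om + 1
    }
    w <- min(max(w, 0), wmax)
    i <- i + length(here)
  }
  w
}

# brute-force symmetry index straight from its definition
oracle_symmetry <- function(w) {
  N <- nrow(w)
  vals <- c()
  n0 <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    a <- w[i, j]
    b <- w[j, i]
    if (a == 0 && b == 0) n0 <- n0 + 1
    else vals <- c(vals, 1 - abs(a - b) / (a + b))
  }
  if (length(vals) == 0) return(list(s = NA_real_, N0 = n0))
  list(s = mean(vals), N0 = n0)
}

# Poisson spike train on [0, duration] ms at `rate` Hz
poisson_train <- function(rate, duration) {
  n <- rpois(1, rate * duration / 1000)
  sort(runif(n, 0, duration))
}
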