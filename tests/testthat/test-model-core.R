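# pointwise maps: sigmoid response, slope, synaptic kernel, gains

test_that("sigmoid response has the correct midpoint, limits, and values", {
  m <- ctbg_model()
  # midpoint: V = theta gives Qmax/2 for every population
  for (a in c("e", "r", "s", "d1", "d2", "p1", "p2", "z")) {
    p <- m$populations[m$populations$label == a, ]
    expect_equal(firing_rate(p$theta, a, m), p$Qmax / 2)
  }
  # saturation limits
  expect_lt(firing_rate(-1e4, "e", m), 1e-10)
  expect_equal(firing_rate(1e4, "e", m), 300)
  # direct evaluation: STN at 13 mV (Qmax 500, theta 10, sigma 3.3)
  expect_equal(firing_rate(13, "z", m), 356.407049309, tolerance = 1e-9)
  # strictly increasing
  v <- seq(-30, 50, 0.5)
  expect_true(all(diff(firing_rate(v, "z", m)) > 0))
  expect_error(firing_rate(NaN, "e", m), "non-finite")
  # inverse consistency
  expect_equal(potential_at_rate(firing_rate(7.3, "s", m), "s", m), 7.3)
})

test_that("rate slope equals the analytic derivative of the firing rate", {
  m <- ctbg_model()
  # logistic maximum and boundary
  expect_equal(rate_slope(250, "z", m), 500 / (4 * 3.3))
  expect_equal(rate_slope(0, "z", m), 0)
  # frozen evaluation at the STN example rate
  expect_equal(rate_slope(356.407049309, "z", m), 31.0166908227,
               tolerance = 1e-9)
  # centered finite differences of firing_rate across the operating range
  h <- 1e-5
  for (a in c("e", "d1", "p1", "z")) {
    V <- seq(-10, 40, length.out = 23)
    fd <- (firing_rate(V + h, a, m) - firing_rate(V - h, a, m)) / (2 * h)
    expect_equal(rate_slope(firing_rate(V, a, m), a, m), fd,
                 tolerance = 1e-6)
  }
  expect_error(rate_slope(501, "z", m), "outside")
})

test_that("synaptic kernel: unit integral, peak location, equal-rate limit", {
  tt <- seq(0, 0.5, 1e-5)
  k <- synaptic_kernel(tt, 50, 200)
  expect_true(all(k >= 0))
  # unit time-integral (DC gain 1 of the inverse dendritic operator)
  integral <- sum((k[-1] + k[-length(k)]) / 2) * 1e-5
  expect_equal(integral, 1, tolerance = 1e-6)
  # closed-form extremum of the biexponential: ln(beta/alpha)/(beta-alpha)
  expect_equal(tt[which.max(k)], 0.00924196240747, tolerance = 1e-3)
  # alpha = beta limit recovered continuously
  k_eq <- synaptic_kernel(tt[-1], 80, 80)
  k_near <- synaptic_kernel(tt[-1], 80, 80 * (1 + 1e-7))
  expect_equal(k_near, k_eq, tolerance = 1e-6)
  expect_error(synaptic_kernel(-0.1, 50, 200), "causal")
})

test_that("synaptic kernel equals the numerically integrated impulse response", {
  # independent oracle: RK4 on V'' = -alpha*beta*V - (alpha+beta)*V' with
  # impulse initial condition V(0) = 0, V'(0) = alpha*beta
  alpha <- 50; beta <- 200; dt <- 1e-5
  n <- round(0.2 / dt)
  x <- c(0, alpha * beta)
  deriv <- function(x) c(x[2], -alpha * beta * x[1] - (alpha + beta) * x[2])
  out <- numeric(n + 1)
  for (i in seq_len(n)) {
    k1 <- deriv(x); k2 <- deriv(x + dt / 2 * k1)
    k3 <- deriv(x + dt / 2 * k2); k4 <- deriv(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1] <- x[1]
  }
  tt <- (0:n) * dt
  ref <- synaptic_kernel(tt, alpha, beta)
  keep <- ref > 1e-3 * max(ref)
  expect_equal(out[keep], ref[keep], tolerance = 1e-4)
})

test_that("gains have neurotransmitter-class signs and compose into loop gains", {
  m <- ctbg_model()
  op <- parkinsonian_operating_state()
  g <- gains(op, m)
  expect_true(all(g$rho >= 0))
  gg <- g$G[!is.na(g$G$G), ]
  # sign(G_ab) = sign(nu_ab) since rho_a >= 0: glutamatergic sources
  # positive, GABAergic negative
  expect_true(all(sign(gg$G) == sign(gg$nu)))
  inhib <- c("i", "r", "d1", "d2", "p1", "p2")
  expect_true(all(gg$G[gg$source %in% inhib] < 0))
  expect_true(all(gg$G[!gg$source %in% inhib] > 0))
  # G_ze = rho_z * nu_ze with rho from rate_slope at the fixed point
  expect_equal(gg$G[gg$target == "z" & gg$source == "e"],
               rate_slope(op$phi0[["z"]], "z", m) * 1.3)
  # zero coupling gives zero gain
  m0 <- ctbg_model(nu = c(sr = 0))
  st0 <- select_operating_state(solve_steady_states(m0))
  g0 <- gains(st0, m0)
  expect_equal(g0$G$G[g0$G$target == "s" & g0$G$source == "r"], 0)

  # loop gains
  expect_identical(loop_gain(g, character(0)), 1)
  expect_lt(loop_gain(g, c("d1", "d1")), 0)    # inhibitory self-loop
  stn_gpe <- loop_gain(g, c("z", "p2", "z"))
  expect_lt(stn_gpe, 0)                        # one excitatory, one inhibitory leg
  expect_equal(stn_gpe,
               gg$G[gg$target == "p2" & gg$source == "z"] *
                 gg$G[gg$target == "z" & gg$source == "p2"])
  expect_error(loop_gain(g, c("z", "d1", "z")), "no such connection")
  expect_error(loop_gain(g, c("z", "p2")), "closed cycle")
})

test_that("model constructor validates parameters and serializes to YAML", {
  expect_error(ctbg_model(alpha = 300), "alpha < beta")
  expect_error(ctbg_model(sigma = -1), "sigma")
  expect_error(ctbg_model(nu = c(zq = 1)), "unknown connection")
  expect_error(ctbg_model(nu = c(sr = +0.5)), "sign")
  # packaged default reproduces the nominal parameters field for field
  packaged <- read_model_yaml(system.file("extdata", "parkinsonian.yaml",
                                          package = "ctbgsim"))
  expect_equal(packaged, ctbg_model())
  # round trip through a fresh file
  tmp <- tempfile(fileext = ".yaml")
  m2 <- ctbg_model(nu = c(p2z = 1.8), tau = c(es = 0.04))
  write_model_yaml(m2, tmp)
  expect_equal(read_model_yaml(tmp), m2)
  expect_error(read_model_yaml({
    bad <- tempfile(fileext = ".yaml")
    writeLines("sigma: 3.3\nnot_a_key: 1", bad)
    bad
  }), "unknown configuration key")
})
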