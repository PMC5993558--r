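# shared fixtures, built in code

# a model with every internal coupling and the external drive switched off:
# each population relaxes to S_a(0) independently
decoupled_model <- function(phi_n = 0) {
  cc <- ctbgsim:::ctbg_default_connections()
  zeros <- stats::setNames(rep(0, nrow(cc)), paste0(cc$target, cc$source))
  ctbg_model(nu = zeros, phi_n = phi_n)
}

# a model in which only the external drive to the relay nuclei is active
relay_only_model <- function() {
  cc <- ctbgsim:::ctbg_default_connections()
  zeros <- stats::setNames(rep(0, nrow(cc)), paste0(cc$target, cc$source))
  zeros["sn"] <- 0.5
  ctbg_model(nu = zeros, phi_n = 1)
}

# cache expensive shared objects across test files
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

parkinsonian_model <- function() cached("model", ctbg_model())

parkinsonian_operating_state <- function() {
  cached("op", select_operating_state(solve_steady_states(parkinsonian_model())))
}

# the unstimulated parkinsonian reference run shared by the acceptance tests
parkinsonian_run <- function() {
  cached("run40", {
    simulate_ctbg(parkinsonian_model(), duration = 40, dt = 1e-4,
                  init = parkinsonian_operating_state(),
                  noise = study_conditions(seed = 1)$noise)
  })
}

# calibrated default protocol (6% share at 150 Hz)
calibrated_protocol <- function() {
  cached("protocol", {
    calibrate_amplitude(parkinsonian_model(), stim_protocol(f_stim = 150),
                        target_share = 0.06,
                        init = parkinsonian_operating_state())
  })
}

# vectorized independent reimplementation of the reduced residual field,
# used by the brute-force steady-state oracle
residual_field <- function(E, S, D1, D2, P2, model) {
  p <- model$populations
  q <- stats::setNames(p$Qmax, p$label)
  th <- stats::setNames(p$theta, p$label)
  sg <- model$sigma
  cc <- model$connections
  nu <- stats::setNames(cc$nu, paste0(cc$target, cc$source))
  sig <- function(V, a) q[[a]] / (1 + exp(-(V - th[[a]]) / sg))
  Z <- sig(nu[["ze"]] * E + nu[["zp2"]] * P2, "z")
  P1 <- sig(nu[["p1z"]] * Z + nu[["p1d1"]] * D1 + nu[["p1p2"]] * P2, "p1")
  R <- sig(nu[["re"]] * E + nu[["rs"]] * S, "r")
  list(
    e = E - sig((nu[["ee"]] + nu[["ei"]]) * E + nu[["es"]] * S, "e"),
    s = S - sig(nu[["se"]] * E + nu[["sr"]] * R + nu[["sp1"]] * P1 +
                  nu[["sn"]] * model$phi_n, "s"),
    d1 = D1 - sig(nu[["d1e"]] * E + nu[["d1s"]] * S + nu[["d1d1"]] * D1, "d1"),
    d2 = D2 - sig(nu[["d2e"]] * E + nu[["d2s"]] * S + nu[["d2d2"]] * D2, "d2"),
    p2 = P2 - sig(nu[["p2d2"]] * D2 + nu[["p2p2"]] * P2 + nu[["p2z"]] * Z, "p2")
  )
}
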