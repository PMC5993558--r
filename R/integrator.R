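# Front end to the compiled RK4 delay-differential integrator.

# map source labels to the integrator's source codes
source_code <- function(source) {
  codes <- c(e = 8, i = 0, r = 1, s = 2, d1 = 3, d2 = 4, p1 = 5, p2 = 6,
             z = 7, n = 9, x = 10)
  # source e refers to the propagating wave field phi_e; the implicit
  # interneurons fire at the cortical rate Q_e = S_e(V_e)
  unname(codes[source])
}

compile_connections <- function(model, protocol, dt) {
  cc <- model$connections
  conn <- cbind(
    target = match(cc$target, CTBG_STATE_POPS) - 1,
    src = source_code(cc$source),
    delay = cc$tau / dt,
    nu = cc$nu
  )
  frac <- abs(conn[, "delay"] - round(conn[, "delay"]))
  if (any(frac > 1e-9 & conn[, "delay"] > 0))
    warning("delay(s) not integer multiples of dt; using linear interpolation",
            call. = FALSE)
  conn[, "delay"] <- ifelse(frac <= 1e-9, round(conn[, "delay"]),
                            conn[, "delay"])
  if (any(conn[, "delay"] > 0 & conn[, "delay"] < 1))
    stop("delays must be zero or at least one time step")
  if (!is.null(protocol) && !is.na(protocol$amp) && protocol$amp > 0) {
    conn <- rbind(conn,
      c(match("z", CTBG_STATE_POPS) - 1, 10, 0, protocol$couplings[["zx"]]),
      c(match("p1", CTBG_STATE_POPS) - 1, 10, 0, protocol$couplings[["p1x"]]),
      c(match("p2", CTBG_STATE_POPS) - 1, 10, 0, protocol$couplings[["p2x"]]))
  }
  conn
}

state_from_init <- function(init, model) {
  if (inherits(init, "ctbg_steady")) {
    V0 <- init$V0[CTBG_STATE_POPS]
    phie0 <- init$phi0[["e"]]
  } else if (is.list(init) && !is.null(init$V0)) {
    V0 <- init$V0[CTBG_STATE_POPS]
    if (any(is.na(V0))) stop("init$V0 must name all of: ",
                             paste(CTBG_STATE_POPS, collapse = ", "))
    phie0 <- if (!is.null(init$phi0) && !is.na(init$phi0["e"]))
      init$phi0[["e"]] else firing_rate(V0[["e"]], "e", model)
  } else stop("init must be a ctbg_steady or a list with element V0")
  c(unname(V0), rep(0, 8), phie0, 0)
}

#' Simulate the CTBG delay differential system
#'
#' Integrates, for each population, the second-order dendritic response
#' driven by the connection-weighted (and possibly delayed) afferent rate
#' fields, with the cortical axonal field obeying the damped-wave equation
#' in its spatially uniform form, using classical fixed-step RK4.  History
#' before t = 0 is held at the initial state.
#'
#' @param model a [ctbg_model()].
#' @param protocol optional [stim_protocol()] with a numeric amplitude; adds
#'   the three DBS drive channels.
#' @param duration simulated time (s).
#' @param dt integration step (s); delays should be integer multiples
#'   (fractional lags are interpolated linearly, with a warning).
#' @param init initial state: a `ctbg_steady` (default: the low-firing
#'   operating state of `model`) or a list with named vectors `V0` (mV) and
#'   optionally `phi0`.
#' @param perturbation optional named vector of constant soma-drive addends
#'   (mV) per population, e.g. `c(z = -1, p1 = 1, p2 = 1)`.
#' @param noise optional white-noise excitation of the external drive
#'   channel: a list with `psd` (one-sided power spectral density of the
#'   rate noise, s^-2 Hz^-1) and `seed`.  The per-step standard deviation is
#'   `sqrt(psd / (2 dt))`, making the forcing spectrum independent of `dt`.
#'   Off by default: the nominal external drive is the constant `phi_n`.
#' @param seed_offset one-off offset (mV) added to the cortical soma
#'   potential at t = 0.  Breaks exact equilibrium reproducibly so that an
#'   unstable fixed point leaves equilibrium at a defined time instead of on
#'   round-off; negligible (and decaying) at a stable fixed point.  Set to 0
#'   for equilibrium-preservation checks.
#' @param thin keep every `thin`-th sample in the output (default 1: full
#'   resolution).
#' @return An object of class `ctbg_sim`: list with `time` (s), `phi`
#'   (matrix of axonal rate fields, columns e, r, s, d1, d2, p1, p2, z,
#'   where column e is the wave field), `Q` (firing rates, with `Q[, "e"]`
#'   the instantaneous cortical rate), `V` (soma potentials, mV), `phix`
#'   (stimulus trace), and `meta` (resolved settings).
#' @export
simulate_ctbg <- function(model, protocol = NULL, duration, dt = 1e-4,
                          init = NULL, perturbation = NULL, noise = NULL,
                          seed_offset = 1e-6, thin = 1) {
  stopifnot(inherits(model, "ctbg_model"))
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "ctbg_protocol"))
    if (is.na(protocol$amp))
      stop("protocol amplitude not set; run calibrate_amplitude() first")
    if (protocol$t_width >= 1 / protocol$f_stim)
      stop("pulses overlap: need t_width < 1/f_stim")
  }
  if (is.null(init))
    init <- select_operating_state(solve_steady_states(model))
  y0 <- state_from_init(init, model)
  y0[1] <- y0[1] + seed_offset

  dV <- rep(0, 8)
  if (!is.null(perturbation)) {
    bad <- setdiff(names(perturbation), CTBG_STATE_POPS)
    if (length(bad)) stop("unknown population(s) in perturbation: ",
                          paste(bad, collapse = ", "))
    dV[match(names(perturbation), CTBG_STATE_POPS)] <- unname(perturbation)
  }

  noise_sd <- 0
  if (!is.null(noise)) {
    if (is.numeric(noise)) noise <- list(psd = noise)
    if (is.null(noise$psd) || noise$psd < 0) stop("noise$psd must be >= 0")
    noise_sd <- sqrt(noise$psd / (2 * dt))
    if (!is.null(noise$seed)) set.seed(noise$seed)
  }

  conn <- compile_connections(model, protocol, dt)
  nsteps <- round(duration / dt)
  p <- model$populations
  q8 <- stats::setNames(p$Qmax, p$label)[CTBG_STATE_POPS]
  th8 <- stats::setNames(p$theta, p$label)[CTBG_STATE_POPS]

  stim <- if (!is.null(protocol) && !is.na(protocol$amp) && protocol$amp > 0)
    protocol else NULL
  out <- ctbg_integrate_core(
    y0, dt, nsteps, conn, unname(q8), unname(th8),
    model$sigma, model$alpha, model$beta, model$gamma_e, model$phi_n,
    if (is.null(stim)) 0 else stim$amp,
    if (is.null(stim)) 0 else stim$f_stim,
    if (is.null(stim)) 0 else stim$t_width,
    if (is.null(stim)) 0 else stim$onset,
    dV, noise_sd, as.integer(thin)
  )

  V <- out$V
  colnames(V) <- CTBG_STATE_POPS
  Q <- vapply(CTBG_STATE_POPS, function(a)
    firing_rate(V[, a], a, model), numeric(nrow(V)))
  phi <- Q
  phi[, "e"] <- out$phie
  time <- seq(0, by = dt * thin, length.out = nrow(V))

  structure(
    list(time = time, phi = phi, Q = Q, V = V, phix = out$phix,
         meta = list(duration = duration, dt = dt, thin = thin,
                     seed_offset = seed_offset,
                     noise = if (noise_sd > 0) noise else NULL,
                     protocol = protocol,
                     perturbation = perturbation,
                     init_phi0 = if (inherits(init, "ctbg_steady"))
                       init$phi0 else NULL)),
    class = "ctbg_sim"
  )
}

#' @export
print.ctbg_sim <- function(x, ...) {
  cat(sprintf("CTBG simulation: %g s at dt = %g s (%d samples kept)\n",
              x$meta$duration, x$meta$dt, length(x$time)))
  if (!is.null(x$meta$protocol) && !is.na(x$meta$protocol$amp) &&
      x$meta$protocol$amp > 0)
    cat(sprintf("  DBS: %g Hz, amplitude %.4g s^-1, onset %g s\n",
                x$meta$protocol$f_stim, x$meta$protocol$amp,
                x$meta$protocol$onset))
  if (!is.null(x$meta$noise))
    cat(sprintf("  noise on phi_n: PSD %g s^-2/Hz\n", x$meta$noise$psd))
  rng <- range(x$phi[, "z"])
  cat(sprintf("  STN rate range: %.3f - %.3f s^-1\n", rng[1], rng[2]))
  invisible(x)
}

#' Simulate with a direct constant soma-potential perturbation
#'
#' Applies constant addends of magnitude `dV` to the summed soma drive of
#' the stimulation targets instead of an oscillating pulse train: the
#' time-averaged equivalent of DBS.  Two sign conventions are provided:
#' `"dbs"` mirrors the DBS coupling signs (STN inhibited, both pallidal
#' segments excited); `"reversed"` applies the opposite pattern (STN
#' excited, pallidum inhibited).
#'
#' @param model a [ctbg_model()].
#' @param init operating state (see [simulate_ctbg()]).
#' @param dV perturbation magnitude (mV), non-negative.
#' @param duration,dt,... passed to [simulate_ctbg()].
#' @param convention `"dbs"` (default) or `"reversed"`.
#' @return A `ctbg_sim`.
#' @export
apply_direct_perturbation <- function(model, init = NULL, dV, duration,
                                      dt = 1e-4,
                                      convention = c("dbs", "reversed"), ...) {
  if (dV < 0) stop("dV must be non-negative")
  convention <- match.arg(convention)
  pert <- if (convention == "dbs") c(z = -dV, p1 = dV, p2 = dV)
          else c(z = dV, p1 = -dV, p2 = -dV)
  simulate_ctbg(model, protocol = NULL, duration = duration, dt = dt,
                init = init, perturbation = pert, ...)
}

#' Export a simulated trajectory as a delimited table
#'
#' @param sim a `ctbg_sim`.
#' @param path output file.
#' @param thin keep every `thin`-th sample (applied on top of any thinning
#'   done at simulation time; default 10, i.e. 1 kHz at the default dt).
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(sim, path, thin = 10, sep = "\t") {
  stopifnot(inherits(sim, "ctbg_sim"))
  keep <- seq(1, length(sim$time), by = thin)
  df <- data.frame(time = sim$time[keep],
                   sim$phi[keep, , drop = FALSE],
                   stats::setNames(as.data.frame(sim$V[keep, , drop = FALSE]),
                                   paste0("V_", colnames(sim$V))),
                   phix = sim$phix[keep], check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
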