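# Model definition: populations, connections, and the pointwise maps
# (sigmoid firing response, synaptodendritic kernel, linearized gains).

# population order used throughout the dynamical state
CTBG_STATE_POPS <- c("e", "r", "s", "d1", "d2", "p1", "p2", "z")
CTBG_ALL_POPS <- c("e", "i", "r", "s", "d1", "d2", "p1", "p2", "z")

ctbg_default_populations <- function() {
  data.frame(
    label = CTBG_ALL_POPS,
    Qmax = c(300, 300, 300, 300, 65, 65, 250, 300, 500),
    theta = c(14, 14, 13, 13, 19, 19, 10, 9, 10),
    excitatory = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    local = c(FALSE, rep(TRUE, 8)),
    implicit = c(FALSE, TRUE, rep(FALSE, 7)),
    stringsAsFactors = FALSE
  )
}

ctbg_default_connections <- function() {
  conn <- rbind(
    c("e", "e", 1.2, 0), c("e", "i", -1.5, 0), c("e", "s", 1.1, 0.035),
    c("r", "e", 0.1, 0.045), c("r", "s", 0.1, 0),
    c("s", "e", 1.5, 0.045), c("s", "r", -0.1, 0), c("s", "p1", -0.2, 0),
    c("s", "n", 0.5, 0),
    c("d1", "e", 0.1, 0), c("d1", "s", 1.0, 0), c("d1", "d1", -0.02, 0),
    c("d2", "e", 0.1, 0), c("d2", "s", 0.1, 0), c("d2", "d2", -0.02, 0),
    c("p1", "d1", -0.2, 0), c("p1", "p2", -0.02, 0), c("p1", "z", 1.0, 0),
    c("p2", "d2", -0.8, 0), c("p2", "p2", -0.2, 0), c("p2", "z", 2.4, 0),
    c("z", "e", 1.3, 0), c("z", "p2", -0.2, 0)
  )
  data.frame(
    target = conn[, 1], source = conn[, 2],
    nu = as.numeric(conn[, 3]), tau = as.numeric(conn[, 4]),
    stringsAsFactors = FALSE
  )
}

conn_key <- function(target, source) paste0(target, source)

#' Construct a corticothalamic-basal ganglia model specification
#'
#' Builds the nine-population neural field model of the corticothalamic-basal
#' ganglia (CTBG) system with its nominal parkinsonian parameter set.  The
#' populations are cortical pyramidal neurons (`e`), cortical inhibitory
#' interneurons (`i`, represented implicitly: random intracortical
#' connectivity makes `V_i = V_e` and `Q_i = Q_e`, so `i` carries no
#' independent state), thalamic relay (`s`) and reticular (`r`) nuclei,
#' striatal D1/D2 populations (`d1`, `d2`), internal and external pallidal
#' segments (`p1`, `p2`), and the subthalamic nucleus (`z`).
#'
#' Each population maps its mean soma potential to a mean firing rate through
#' a sigmoid with maximum `Qmax`, threshold `theta` and common spread
#' `sigma`.  Only the cortical excitatory population carries damped-wave
#' axonal dynamics (damping rate `gamma_e`); all other populations use the
#' local-interaction approximation `phi_a = Q_a`.  Postsynaptic potentials
#' follow a second-order response with decay rate `alpha` and rise rate
#' `beta`, shared by all connections.
#'
#' @param nu named numeric vector of connection-strength overrides in mV s;
#'   names concatenate target then source, e.g. `c(p2z = 1.8)` for the
#'   STN -> GPe coupling.
#' @param tau named numeric vector of axonal delay overrides in seconds,
#'   same naming convention.
#' @param Qmax,theta named numeric vectors of per-population overrides
#'   (s^-1 and mV).
#' @param sigma sigmoid threshold spread (mV), shared by all populations.
#' @param alpha,beta synaptodendritic decay and rise rates (s^-1); requires
#'   `0 < alpha < beta`.
#' @param gamma_e cortical axonal damping rate (s^-1).
#' @param r_e cortical axonal range (mm); retained for completeness, it does
#'   not enter the spatially uniform dynamics.
#' @param phi_n constant external drive rate to the thalamic relay nuclei
#'   (s^-1).
#' @return An object of class `ctbg_model`: a list with elements
#'   `populations` (data frame), `connections` (data frame with columns
#'   `target`, `source`, `nu`, `tau`) and the scalar parameters above.
#' @examples
#' m <- ctbg_model()                  # nominal parkinsonian parameters
#' m_weak <- ctbg_model(nu = c(p2z = 1.8))  # weaker STN -> GPe coupling
#' @export
ctbg_model <- function(nu = NULL, tau = NULL, Qmax = NULL, theta = NULL,
                       sigma = 3.3, alpha = 50, beta = 200,
                       gamma_e = 116, r_e = 80, phi_n = 1) {
  pops <- ctbg_default_populations()
  conns <- ctbg_default_connections()

  apply_pop_override <- function(df, col, ov) {
    if (is.null(ov)) return(df)
    bad <- setdiff(names(ov), df$label)
    if (length(bad))
      stop("unknown population(s) in override: ", paste(bad, collapse = ", "))
    df[[col]][match(names(ov), df$label)] <- unname(ov)
    # i mirrors e
    df[[col]][df$label == "i"] <- df[[col]][df$label == "e"]
    df
  }
  pops <- apply_pop_override(pops, "Qmax", Qmax)
  pops <- apply_pop_override(pops, "theta", theta)

  apply_conn_override <- function(df, col, ov) {
    if (is.null(ov)) return(df)
    keys <- conn_key(df$target, df$source)
    bad <- setdiff(names(ov), keys)
    if (length(bad))
      stop("unknown connection(s) in override: ", paste(bad, collapse = ", "))
    df[[col]][match(names(ov), keys)] <- unname(ov)
    df
  }
  conns <- apply_conn_override(conns, "nu", nu)
  conns <- apply_conn_override(conns, "tau", tau)

  if (!(alpha > 0 && beta > 0 && alpha < beta))
    stop("require 0 < alpha < beta")
  if (sigma <= 0) stop("sigma must be positive")
  if (gamma_e <= 0) stop("gamma_e must be positive")
  if (any(pops$Qmax <= 0) || any(!is.finite(pops$theta)))
    stop("invalid population parameters")
  if (any(conns$tau < 0)) stop("delays must be non-negative")

  # efferent sign convention: inhibitory sources carry nu <= 0,
  # excitatory sources (and the external channel n) nu >= 0
  inhib <- pops$label[!pops$excitatory]
  bad_sign <- (conns$source %in% inhib & conns$nu > 0) |
    (!(conns$source %in% inhib) & conns$nu < 0)
  if (any(bad_sign))
    stop("connection sign violates source neurotransmitter class: ",
         paste(conn_key(conns$target, conns$source)[bad_sign], collapse = ", "))

  structure(
    list(populations = pops, connections = conns,
         sigma = sigma, alpha = alpha, beta = beta,
         gamma_e = gamma_e, r_e = r_e, phi_n = phi_n),
    class = "ctbg_model"
  )
}

#' @export
print.ctbg_model <- function(x, ...) {
  cat("CTBG neural field model\n")
  cat(sprintf("  populations: %d (+ implicit cortical interneurons)\n",
              sum(!x$populations$implicit)))
  cat(sprintf("  connections: %d\n", nrow(x$connections)))
  cat(sprintf("  sigma = %g mV, alpha = %g s^-1, beta = %g s^-1, gamma_e = %g s^-1\n",
              x$sigma, x$alpha, x$beta, x$gamma_e))
  cat(sprintf("  external drive phi_n = %g s^-1\n", x$phi_n))
  delayed <- x$connections[x$connections$tau > 0, ]
  if (nrow(delayed))
    cat("  delays:", paste(sprintf("%s = %g ms",
                                   conn_key(delayed$target, delayed$source),
                                   1e3 * delayed$tau), collapse = ", "), "\n")
  invisible(x)
}

pop_params <- function(model, pop) {
  i <- match(pop, model$populations$label)
  if (is.na(i)) stop("unknown population: ", pop)
  model$populations[i, ]
}

#' Sigmoid firing-rate response
#'
#' Maps a mean soma potential to a mean firing rate through the population's
#' sigmoid, `Q = Qmax / (1 + exp(-(V - theta) / sigma))`.
#'
#' @param V soma potential (mV); may be a vector.
#' @param pop population label (one of e, i, r, s, d1, d2, p1, p2, z).
#' @param model a [ctbg_model()].
#' @return Firing rate(s) in s^-1, strictly inside `(0, Qmax)` for finite `V`.
#' @export
firing_rate <- function(V, pop, model = ctbg_model()) {
  if (any(!is.finite(V))) stop("non-finite soma potential")
  p <- pop_params(model, pop)
  p$Qmax / (1 + exp(-(V - p$theta) / model$sigma))
}

#' Inverse of the sigmoid firing-rate response
#'
#' @param phi firing rate (s^-1), strictly inside `(0, Qmax)`.
#' @inheritParams firing_rate
#' @return Soma potential (mV).
#' @export
potential_at_rate <- function(phi, pop, model = ctbg_model()) {
  p <- pop_params(model, pop)
  if (any(phi <= 0 | phi >= p$Qmax))
    stop("rate outside (0, Qmax) has no finite potential")
  p$theta - model$sigma * log(p$Qmax / phi - 1)
}

#' Slope of the firing-rate response at an operating rate
#'
#' Returns `rho = dQ/dV` evaluated at the potential where the population
#' fires at `phi`: `rho = phi (1 - phi / Qmax) / sigma`.
#'
#' @param phi steady firing rate (s^-1), in `[0, Qmax]`.
#' @inheritParams firing_rate
#' @return Slope in s^-1 mV^-1; zero only at the boundaries.
#' @export
rate_slope <- function(phi, pop, model = ctbg_model()) {
  p <- pop_params(model, pop)
  if (any(phi < 0 | phi > p$Qmax)) stop("rate outside [0, Qmax]")
  phi * (1 - phi / p$Qmax) / model$sigma
}

#' Synaptodendritic impulse response
#'
#' Impulse response of the second-order dendritic operator with decay rate
#' `alpha` and rise rate `beta`:
#' `alpha beta / (beta - alpha) (exp(-alpha t) - exp(-beta t))` for
#' `alpha != beta`, and `alpha^2 t exp(-alpha t)` in the equal-rate limit.
#' The kernel is non-negative and integrates to one (unit DC gain).
#'
#' @param t time (s), non-negative; may be a vector.
#' @param alpha decay rate (s^-1).
#' @param beta rise rate (s^-1).
#' @return Kernel values (s^-1).
#' @export
synaptic_kernel <- function(t, alpha, beta) {
  if (any(t < 0)) stop("kernel is causal: t must be >= 0")
  if (alpha <= 0 || beta <= 0) stop("rates must be positive")
  if (isTRUE(all.equal(alpha, beta, tolerance = 1e-12))) {
    alpha^2 * t * exp(-alpha * t)
  } else {
    alpha * beta / (beta - alpha) * (exp(-alpha * t) - exp(-beta * t))
  }
}

#' Linearized connection gains at a fixed point
#'
#' Computes the sigmoid slope `rho_a` of every population at the fixed-point
#' rates and the dimensionless gain `G_ab = rho_a nu_ab` of every
#' connection: the additional output activity of `a` per additional unit
#' input activity from `b` at the operating point.
#'
#' @param steady a `ctbg_steady` fixed point from [solve_steady_states()].
#' @param model the [ctbg_model()] the fixed point belongs to.
#' @return An object of class `ctbg_gains`: list with `rho` (named vector,
#'   s^-1 mV^-1) and `G` (data frame `target`, `source`, `nu`, `G`).
#' @export
gains <- function(steady, model) {
  stopifnot(inherits(steady, "ctbg_steady"))
  rho <- vapply(CTBG_ALL_POPS, function(a) {
    phi <- if (a == "i") steady$phi0[["e"]] else steady$phi0[[a]]
    rate_slope(phi, a, model)
  }, numeric(1))
  G <- model$connections
  G$G <- ifelse(G$source == "n", NA_real_, rho[G$target] * G$nu)
  structure(list(rho = rho, G = G), class = "ctbg_gains")
}

#' @export
print.ctbg_gains <- function(x, ...) {
  cat("CTBG connection gains at fixed point\n")
  cat("  rho (s^-1 mV^-1):\n")
  print(round(x$rho, 4))
  g <- x$G[!is.na(x$G$G), ]
  cat("  gains G_ab:\n")
  print(data.frame(connection = conn_key(g$target, g$source),
                   G = round(g$G, 4)), row.names = FALSE)
  invisible(x)
}

#' Gain product along a closed loop
#'
#' Multiplies connection gains along a closed path of populations, e.g. the
#' STN-GPe loop `c("z", "p2", "z")` or the hyperdirect chain
#' `c("e", "z", "p1", "s", "e")`.  Consecutive labels `b, a` refer to the
#' connection `a <- b`.
#'
#' @param g a `ctbg_gains` object from [gains()].
#' @param path character vector of population labels; the first and last
#'   must coincide.  A path of length <= 1 returns the empty product, 1.
#' @return Dimensionless loop gain.
#' @export
loop_gain <- function(g, path) {
  stopifnot(inherits(g, "ctbg_gains"))
  if (length(path) <= 1) return(1)
  if (path[1] != path[length(path)]) stop("path must be a closed cycle")
  keys <- conn_key(g$G$target, g$G$source)
  prod(vapply(seq_len(length(path) - 1), function(k) {
    key <- conn_key(path[k + 1], path[k])
    i <- match(key, keys)
    if (is.na(i)) stop("no such connection: ", key)
    g$G$G[i]
  }, numeric(1)))
}

#' Write a model specification to a YAML file
#'
#' @param model a [ctbg_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_model_yaml()]; a packaged default with the nominal
#'   parkinsonian parameters ships as
#'   `system.file("extdata", "parkinsonian.yaml", package = "ctbgsim")`.
#' @export
write_model_yaml <- function(model, path) {
  stopifnot(inherits(model, "ctbg_model"))
  pops <- model$populations[!model$populations$implicit, ]
  obj <- list(
    populations = stats::setNames(
      lapply(seq_len(nrow(pops)), function(i)
        list(Qmax = pops$Qmax[i], theta = pops$theta[i],
             excitatory = pops$excitatory[i])),
      pops$label),
    connections = stats::setNames(
      lapply(seq_len(nrow(model$connections)), function(i) {
        cc <- model$connections[i, ]
        if (cc$tau > 0) list(nu = cc$nu, tau = cc$tau) else list(nu = cc$nu)
      }),
      conn_key(model$connections$target, model$connections$source)),
    sigma = model$sigma, alpha = model$alpha, beta = model$beta,
    gamma_e = model$gamma_e, r_e = model$r_e, phi_n = model$phi_n
  )
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' Read a model specification from a YAML file
#'
#' The file must describe the fixed CTBG topology; population and connection
#' entries override the packaged defaults, and unknown keys are rejected.
#'
#' @param path YAML file written by [write_model_yaml()] (or hand-edited).
#' @return A [ctbg_model()].
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- c("populations", "connections", "sigma", "alpha", "beta",
             "gamma_e", "r_e", "phi_n")
  bad <- setdiff(names(obj), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)
  Qmax <- theta <- NULL
  if (!is.null(obj$populations)) {
    Qmax <- vapply(obj$populations, function(p) as.numeric(p$Qmax), numeric(1))
    theta <- vapply(obj$populations, function(p) as.numeric(p$theta), numeric(1))
  }
  nu <- tau <- NULL
  if (!is.null(obj$connections)) {
    nu <- vapply(obj$connections, function(p) as.numeric(p$nu), numeric(1))
    tau <- vapply(obj$connections, function(p) num_or(p$tau, 0), numeric(1))
  }
  ctbg_model(nu = nu, tau = tau, Qmax = Qmax, theta = theta,
             sigma = num_or(obj$sigma, 3.3),
             alpha = num_or(obj$alpha, 50), beta = num_or(obj$beta, 200),
             gamma_e = num_or(obj$gamma_e, 116),
             r_e = num_or(obj$r_e, 80), phi_n = num_or(obj$phi_n, 1))
}
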