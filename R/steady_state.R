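# Time-independent states of the CTBG system.
#
# With all time derivatives set to zero the system reduces to five
# simultaneous equations in the rates (phi_e, phi_s, phi_d1, phi_d2, phi_p2);
# the remaining rates follow by direct substitution: phi_z from (phi_e,
# phi_p2), then phi_p1, then phi_r.  Roots are found by damped multi-start
# Newton iteration from deterministic low-discrepancy initial points.

steady_nu <- function(model) {
  cc <- model$connections
  stats::setNames(cc$nu, conn_key(cc$target, cc$source))
}

sig_ <- function(V, Qmax, theta, sigma) Qmax / (1 + exp(-(V - theta) / sigma))

# substitution chain for the dependent rates, given the five free rates
steady_dependent <- function(x, model) {
  nu <- steady_nu(model)
  p <- model$populations
  q <- stats::setNames(p$Qmax, p$label)
  th <- stats::setNames(p$theta, p$label)
  sg <- model$sigma
  phi_z <- sig_(nu["ze"] * x[["e"]] + nu["zp2"] * x[["p2"]], q["z"], th["z"], sg)
  phi_p1 <- sig_(nu["p1z"] * phi_z + nu["p1d1"] * x[["d1"]] +
                   nu["p1p2"] * x[["p2"]], q["p1"], th["p1"], sg)
  phi_r <- sig_(nu["re"] * x[["e"]] + nu["rs"] * x[["s"]], q["r"], th["r"], sg)
  c(z = unname(phi_z), p1 = unname(phi_p1), r = unname(phi_r))
}

#' Residuals of the reduced steady-state system
#'
#' Evaluates the five fixed-point residuals `F(phi_a) = phi_a - S_a(V_a)`
#' for the free rates `a` in `(e, s, d1, d2, p2)`, with the dependent rates
#' `phi_z`, `phi_p1`, `phi_r` obtained by direct substitution.
#'
#' @param x numeric 5-vector of candidate rates, named or in the order
#'   `e, s, d1, d2, p2`; each component must lie in `[0, Qmax)` of its
#'   population.
#' @param model a [ctbg_model()].
#' @return Named numeric 5-vector of residuals (s^-1); all zero exactly at
#'   a fixed point.
#' @export
reduced_residuals <- function(x, model = ctbg_model()) {
  free <- c("e", "s", "d1", "d2", "p2")
  if (is.null(names(x))) names(x) <- free
  stopifnot(setequal(names(x), free))
  p <- model$populations
  q <- stats::setNames(p$Qmax, p$label)
  th <- stats::setNames(p$theta, p$label)
  if (any(x < 0) || any(x >= q[free]))
    stop("candidate rates outside [0, Qmax)")
  sg <- model$sigma
  nu <- steady_nu(model)
  dep <- steady_dependent(x, model)
  c(
    e = unname(x[["e"]] - sig_((nu["ee"] + nu["ei"]) * x[["e"]] +
                                 nu["es"] * x[["s"]], q["e"], th["e"], sg)),
    s = unname(x[["s"]] - sig_(nu["se"] * x[["e"]] + nu["sr"] * dep[["r"]] +
                                 nu["sp1"] * dep[["p1"]] +
                                 nu["sn"] * model$phi_n, q["s"], th["s"], sg)),
    d1 = unname(x[["d1"]] - sig_(nu["d1e"] * x[["e"]] + nu["d1s"] * x[["s"]] +
                                   nu["d1d1"] * x[["d1"]], q["d1"], th["d1"], sg)),
    d2 = unname(x[["d2"]] - sig_(nu["d2e"] * x[["e"]] + nu["d2s"] * x[["s"]] +
                                   nu["d2d2"] * x[["d2"]], q["d2"], th["d2"], sg)),
    p2 = unname(x[["p2"]] - sig_(nu["p2d2"] * x[["d2"]] + nu["p2p2"] * x[["p2"]] +
                                   nu["p2z"] * dep[["z"]], q["p2"], th["p2"], sg))
  )
}

# Halton low-discrepancy sequence in [0,1]^dim (deterministic)
halton_seq <- function(n, dim, skip = 0) {
  primes <- c(2, 3, 5, 7, 11, 13, 17)
  stopifnot(dim <= length(primes))
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    b <- primes[d]
    for (k in seq_len(n)) {
      i <- k + skip
      f <- 1; r <- 0
      while (i > 0) {
        f <- f / b
        r <- r + f * (i %% b)
        i <- i %/% b
      }
      out[k, d] <- r
    }
  }
  out
}

# damped Newton with forward-difference Jacobian on the reduced residuals
newton_refine <- function(x0, model, qfree, max_iter = 200) {
  x <- pmin(pmax(x0, 1e-10), qfree * (1 - 1e-10))
  f <- reduced_residuals(x, model)
  for (it in seq_len(max_iter)) {
    nf <- max(abs(f))
    if (nf < 1e-15) break
    J <- matrix(0, 5, 5)
    for (j in 1:5) {
      h <- 1e-7 * max(1, abs(x[j]))
      xp <- x
      xp[j] <- min(x[j] + h, qfree[j] * (1 - 1e-12))
      J[, j] <- (reduced_residuals(xp, model) - f) / (xp[j] - x[j])
    }
    dx <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    lambda <- 1
    improved <- FALSE
    while (lambda >= 1e-8) {
      xn <- pmin(pmax(x + lambda * dx, 1e-10), qfree * (1 - 1e-10))
      fn <- tryCatch(reduced_residuals(xn, model), error = function(e) NULL)
      if (!is.null(fn) && max(abs(fn)) < nf) { improved <- TRUE; break }
      lambda <- lambda / 2
    }
    # at the round-off floor no step improves; accept if already converged
    if (!improved) {
      if (nf < 1e-9) break
      return(NULL)
    }
    x <- xn; f <- fn
  }
  if (max(abs(f)) > 1e-9) return(NULL)
  x
}

build_steady <- function(x, model, tol) {
  free <- c("e", "s", "d1", "d2", "p2")
  names(x) <- free
  dep <- steady_dependent(x, model)
  phi0 <- c(x, dep)[c("e", "s", "d1", "d2", "p2", "z", "p1", "r")]
  phi0 <- phi0[c("e", "r", "s", "d1", "d2", "p1", "p2", "z")]
  phi0 <- c(phi0, i = unname(phi0[["e"]]))[CTBG_ALL_POPS]
  V0 <- vapply(CTBG_ALL_POPS, function(a)
    potential_at_rate(phi0[[a]], a, model), numeric(1))
  f <- reduced_residuals(x, model)
  rho <- vapply(free, function(a) rate_slope(x[[a]], a, model), numeric(1))
  # potential-equivalent residual, with a rate-space cap where rho ~ 0
  res_pot <- max(abs(f) / pmax(rho, 1e-12))
  res_rate <- max(abs(f))
  structure(
    list(phi0 = phi0, V0 = V0,
         residual_norm = res_pot,
         residual_rate = res_rate, residual_potential = res_pot,
         converged = (res_pot < tol) || (res_rate < 1e-9)),
    class = "ctbg_steady"
  )
}

# structured enumeration: walk phi_e over a grid; at each point the cortical
# equation fixes phi_s (monotone), the striatal equations fix phi_d1, phi_d2
# (contraction via weak self-inhibition), and the pallidal equation may have
# several phi_p2 branches; sign changes of the remaining relay residual along
# each branch bracket candidate roots.
continuation_starts <- function(model, qfree) {
  p <- model$populations
  q <- stats::setNames(p$Qmax, p$label)
  th <- stats::setNames(p$theta, p$label)
  sg <- model$sigma
  nu <- steady_nu(model)
  ps_of <- function(pe) {
    g <- function(ps) pe - sig_((nu[["ee"]] + nu[["ei"]]) * pe +
                                  nu[["es"]] * ps, q[["e"]], th[["e"]], sg)
    if (nu[["es"]] == 0)
      return(if (abs(g(0)) < 1e-12) 0.5 * q[["s"]] else NA_real_)
    if (g(0) * g(q[["s"]] * (1 - 1e-12)) > 0) return(NA_real_)
    stats::uniroot(g, c(0, q[["s"]] * (1 - 1e-12)), tol = 1e-13)$root
  }
  pd_of <- function(pe, ps, lab) {
    nue <- nu[[paste0(lab, "e")]]; nus <- nu[[paste0(lab, "s")]]
    nud <- nu[[paste0(lab, lab)]]
    g <- function(x) x - sig_(nue * pe + nus * ps + nud * x,
                              q[[lab]], th[[lab]], sg)
    stats::uniroot(g, c(0, q[[lab]]), tol = 1e-13)$root
  }
  p2_branches <- function(pe, pd2) {
    g <- function(x) x - sig_(nu[["p2z"]] * sig_(nu[["ze"]] * pe +
                                                   nu[["zp2"]] * x,
                                                 q[["z"]], th[["z"]], sg) +
                               nu[["p2d2"]] * pd2 + nu[["p2p2"]] * x,
                              q[["p2"]], th[["p2"]], sg)
    xs <- seq(0, q[["p2"]] * (1 - 1e-9), length.out = 241)
    gv <- vapply(xs, g, numeric(1))
    idx <- which(gv[-1] * gv[-length(gv)] < 0)
    vapply(idx, function(k)
      stats::uniroot(g, c(xs[k], xs[k + 1]), tol = 1e-13)$root, numeric(1))
  }
  pes <- c(seq(1e-3, 0.2, length.out = 8),
           seq(0.25, 0.995, length.out = 120)) * q[["e"]]
  pts <- list()
  for (pe in pes) {
    ps <- ps_of(pe)
    if (is.na(ps)) next
    pd1 <- pd_of(pe, ps, "d1")
    pd2 <- pd_of(pe, ps, "d2")
    for (pp2 in p2_branches(pe, pd2))
      pts[[length(pts) + 1]] <- c(pe, ps, pd1, pd2, pp2)
  }
  if (!length(pts)) return(NULL)
  P <- do.call(rbind, pts)
  # relay-equation residual along the scan; keep points flanking sign changes
  fs <- apply(P, 1, function(z) reduced_residuals(z, model)[["s"]])
  keep <- unique(c(which(fs[-1] * fs[-length(fs)] < 0),
                   which(fs[-1] * fs[-length(fs)] < 0) + 1))
  P[keep, , drop = FALSE]
}

#' Find the fixed points of the CTBG system
#'
#' Multi-start damped Newton iteration on the reduced five-equation system,
#' started from deterministic Halton low-discrepancy points over the box of
#' admissible rates (plus the box centre and near-origin corners).  Distinct
#' refined roots are deduplicated and returned with the full nine-population
#' steady potentials and rates reconstructed by substitution.
#'
#' Residuals are naturally in rate units (s^-1); convergence is declared when
#' the potential-equivalent residual (rate residual divided by the local
#' sigmoid slope) falls below `tol`, with a rate-space cap of 1e-9 s^-1
#' guarding points where the slope vanishes.
#'
#' @param model a [ctbg_model()].
#' @param tol convergence tolerance on the potential-equivalent residual
#'   (mV); the default corresponds to 1e-15 V.
#' @param n_starts number of Halton initial points.
#' @param seed integer recorded in the output metadata (the start set is
#'   deterministic; the seed offsets the Halton sequence).
#' @return A list of `ctbg_steady` objects, sorted by increasing cortical
#'   rate `phi0["e"]`.  Each has fields `phi0` (named rates, s^-1), `V0`
#'   (named potentials, mV), `residual_norm`, and metadata attributes.
#' @export
solve_steady_states <- function(model = ctbg_model(), tol = 1e-12,
                                n_starts = 60, seed = 1) {
  if (tol <= 0) stop("tol must be positive")
  free <- c("e", "s", "d1", "d2", "p2")
  p <- model$populations
  qfree <- stats::setNames(p$Qmax, p$label)[free]

  # coarse deterministic pre-scan: keep the lowest-residual points as extra
  # Newton starts, so that narrow basins (e.g. the low-firing root) are hit
  scan <- sweep(halton_seq(40 * n_starts, 5, skip = as.integer(seed) %% 1000),
                2, qfree * (1 - 1e-6), "*")
  scan_norm <- apply(scan, 1, function(z)
    max(abs(reduced_residuals(z, model))))
  best <- scan[order(scan_norm)[seq_len(min(20, nrow(scan)))], , drop = FALSE]
  starts <- rbind(qfree * 0.5, qfree * 0.02, qfree * 0.98, best,
                  continuation_starts(model, qfree),
                  sweep(halton_seq(n_starts, 5,
                                   skip = as.integer(seed) %% 1000 + 7),
                        2, qfree * (1 - 1e-6), "*"))

  roots <- list()
  for (k in seq_len(nrow(starts))) {
    x <- newton_refine(starts[k, ], model, qfree)
    if (is.null(x)) next
    dup <- FALSE
    for (r in roots)
      if (max(abs(r - x)) < max(1e3 * tol * 20, 1e-6)) { dup <- TRUE; break }
    if (!dup) roots[[length(roots) + 1]] <- x
  }
  if (!length(roots))
    stop("no steady state found for this model (", n_starts, " starts)")

  states <- lapply(roots, build_steady, model = model, tol = tol)
  states <- states[order(vapply(states, function(s) s$phi0[["e"]], numeric(1)))]
  attr(states, "tol") <- tol
  attr(states, "n_starts") <- n_starts
  attr(states, "seed") <- seed
  states
}

#' @export
print.ctbg_steady <- function(x, ...) {
  cat("CTBG steady state\n")
  df <- data.frame(population = names(x$phi0),
                   V0_mV = round(unname(x$V0[names(x$phi0)]), 6),
                   phi0_s1 = round(unname(x$phi0), 6))
  print(df, row.names = FALSE)
  cat(sprintf("  residual: %.3g s^-1 (%.3g mV potential-equivalent)\n",
              x$residual_rate, x$residual_potential))
  invisible(x)
}

#' Select the low-firing operating state
#'
#' Among the fixed points of the system, returns the one with the smallest
#' cortical rate `phi0["e"]`, breaking ties by the smallest relay rate
#' `phi0["s"]`.  This is the state simulations are initialized to.
#'
#' @param states list of `ctbg_steady` objects from [solve_steady_states()].
#' @return A single `ctbg_steady`.
#' @export
select_operating_state <- function(states) {
  if (!length(states)) stop("empty list of steady states")
  pe <- vapply(states, function(s) s$phi0[["e"]], numeric(1))
  ps <- vapply(states, function(s) s$phi0[["s"]], numeric(1))
  states[[order(pe, ps)[1]]]
}
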