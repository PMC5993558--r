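# fixed points of the full system

test_that("decoupled systems have closed-form steady states", {
  # all couplings and external drive zero: unique root V0 = 0, phi0 = S(0)
  m0 <- decoupled_model(phi_n = 0)
  st <- solve_steady_states(m0)
  expect_length(st, 1)
  s <- st[[1]]
  expect_equal(unname(s$V0), rep(0, 9), tolerance = 1e-8)
  for (a in names(s$phi0))
    expect_equal(s$phi0[[a]], firing_rate(0, a, m0), tolerance = 1e-8)

  # only the external drive on the relay nuclei: V_s = nu_sn * phi_n = 0.5 mV
  mr <- relay_only_model()
  sr <- select_operating_state(solve_steady_states(mr))
  expect_equal(sr$V0[["s"]], 0.5, tolerance = 1e-8)
  expect_equal(sr$phi0[["s"]], firing_rate(0.5, "s", mr), tolerance = 1e-8)
})

test_that("residuals vanish at roots and bracket over the admissible range", {
  m <- parkinsonian_model()
  st <- solve_steady_states(m)
  for (s in st) {
    x <- s$phi0[c("e", "s", "d1", "d2", "p2")]
    expect_lt(max(abs(reduced_residuals(x, m))), 1e-9)
    expect_true(s$converged)
    expect_lt(s$residual_norm, 1e-12)
  }
  # sign bracketing of the cortical residual with the others held at a root
  x <- st[[1]]$phi0[c("e", "s", "d1", "d2", "p2")]
  lo <- x; lo["e"] <- 1e-9
  hi <- x; hi["e"] <- 300 * (1 - 1e-12)
  expect_lte(reduced_residuals(lo, m)[["e"]], 0)
  expect_gte(reduced_residuals(hi, m)[["e"]], 0)
  expect_error(reduced_residuals(c(e = -1, s = 1, d1 = 1, d2 = 1, p2 = 1), m),
               "outside")
})

test_that("solver finds both interior parkinsonian roots, refinement is idempotent", {
  st <- solve_steady_states(parkinsonian_model())
  expect_length(st, 2)
  pe <- vapply(st, function(s) s$phi0[["e"]], numeric(1))
  # independent cross-check of the root locations with pracma's solver
  m <- parkinsonian_model()
  f <- function(x) unname(reduced_residuals(
    stats::setNames(x, c("e", "s", "d1", "d2", "p2")), m))
  for (s in st) {
    x0 <- unname(s$phi0[c("e", "s", "d1", "d2", "p2")])
    ref <- suppressWarnings(pracma::fsolve(f, x0 * (1 + 1e-4), tol = 1e-13)$x)
    expect_equal(x0, ref, tolerance = 1e-7)
  }
  # idempotence: re-solving and re-selecting returns the same operating root
  st2 <- solve_steady_states(parkinsonian_model())
  expect_equal(select_operating_state(st2)$phi0,
               select_operating_state(st)$phi0, tolerance = 1e-12)
})

test_that("brute-force grid oracle: sign-change cells match reported roots", {
  m <- parkinsonian_model()
  st <- solve_steady_states(m)
  roots <- t(vapply(st, function(s)
    unname(s$phi0[c("e", "s", "d1", "d2", "p2")]), numeric(5)))

  # non-uniform grid fractions, denser at low rates where the roots live
  fr <- c(1e-4, 0.01, 0.02, 0.045, 0.06, 0.1, 0.15, 0.3, 0.45, 0.65, 0.95)
  q <- c(300, 300, 65, 65, 300)
  axes <- lapply(q, function(qm) fr * qm)
  grid <- expand.grid(e = axes[[1]], s = axes[[2]], d1 = axes[[3]],
                      d2 = axes[[4]], p2 = axes[[5]])
  R <- residual_field(grid$e, grid$s, grid$d1, grid$d2, grid$p2, m)
  n <- length(fr)
  dims <- rep(n, 5)
  signs <- lapply(R, function(v) array(sign(v), dims))

  # a cell varies in a component if its 32 corners carry both signs
  corner_sets <- expand.grid(rep(list(0:1), 5))
  cell_lo <- lapply(signs, function(S) {
    acc <- NULL
    idx_base <- lapply(seq_len(5), function(d) 1:(n - 1))
    for (r in seq_len(nrow(corner_sets))) {
      off <- unlist(corner_sets[r, ])
      idx <- lapply(seq_len(5), function(d) idx_base[[d]] + off[d])
      sub <- S[idx[[1]], idx[[2]], idx[[3]], idx[[4]], idx[[5]]]
      acc <- if (is.null(acc)) list(mn = sub, mx = sub)
             else list(mn = pmin(acc$mn, sub), mx = pmax(acc$mx, sub))
    }
    acc
  })
  varies <- Reduce(`&`, lapply(cell_lo, function(a) a$mn < 0 & a$mx > 0))
  cells <- which(varies, arr.ind = TRUE)

  # every reported root lies inside a sign-change cell
  locate <- function(val, ax) findInterval(val, ax, all.inside = TRUE)
  for (r in seq_len(nrow(roots))) {
    cell <- vapply(1:5, function(d) locate(roots[r, d], axes[[d]]), integer(1))
    expect_true(any(apply(cells, 1, function(cc) all(cc == cell))),
                info = sprintf("root %d not enclosed by a sign-change cell", r))
  }
  # and every sign-change cell refines onto a reported root (no extras)
  f <- function(x) unname(reduced_residuals(
    stats::setNames(pmin(pmax(x, 1e-9), q * (1 - 1e-9)),
                    c("e", "s", "d1", "d2", "p2")), m))
  for (r in seq_len(nrow(cells))) {
    centre <- vapply(1:5, function(d)
      mean(axes[[d]][cells[r, d] + 0:1]), numeric(1))
    sol <- tryCatch(suppressWarnings(pracma::fsolve(f, centre, tol = 1e-12)$x),
                    error = function(e) NULL)
    if (is.null(sol) || max(abs(f(sol))) > 1e-8) next
    dist <- apply(roots, 1, function(rt) max(abs(rt - sol)))
    expect_lt(min(dist), 1e-4)
  }
})

test_that("operating-state selection follows the low-firing rule", {
  mk <- function(pe, ps) structure(
    list(phi0 = c(e = pe, s = ps), V0 = c(e = 0, s = 0)),
    class = "ctbg_steady")
  expect_equal(select_operating_state(list(mk(20, 1), mk(5, 9)))$phi0[["e"]], 5)
  # tie on phi_e broken by the smaller phi_s
  expect_equal(select_operating_state(list(mk(5, 9), mk(5, 2)))$phi0[["s"]], 2)
  expect_error(select_operating_state(list()), "empty")
  # the Table-set operating root is dynamically admissible
  op <- parkinsonian_operating_state()
  q <- stats::setNames(parkinsonian_model()$populations$Qmax,
                       parkinsonian_model()$populations$label)
  expect_true(all(op$phi0 > 0 & op$phi0 < q[names(op$phi0)]))
})
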