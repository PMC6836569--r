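test_that("compound parameter transform matches the study arithmetic exactly", {
  # true simulation rates: psi/(mu+psi) = 0.143 (3 s.f.) at psi=0.01, mu=0.06
  drs <- rates_to_drs(0.12, 0.06, 0.01)
  expect_equal(drs$d, 0.06)
  expect_equal(drs$r, 0.5)
  expect_equal(signif(drs$s, 3), 0.143)
  back <- convert_parameterization(drs$d, drs$r, drs$s)
  expect_equal(back$lambda, 0.12, tolerance = 1e-12)
  expect_equal(back$mu, 0.06, tolerance = 1e-12)
  expect_equal(back$psi, 0.01, tolerance = 1e-12)
  # half-truth estimates imply mu = 0.01 and lambda = 0.04
  half <- convert_parameterization(0.03, 0.25, 0.143)
  expect_equal(half$lambda, 0.04, tolerance = 1e-12)
  expect_equal(half$mu, 0.01, tolerance = 1e-12)
  # with s fixed at 0.143 the implied fossil-sampling rate drops to 0.00167
  expect_equal(signif(half$psi, 3), 0.00167)
  # degenerate cases and errors
  expect_equal(convert_parameterization(0.05, 0, 0), list(lambda = 0.05, mu = 0, psi = 0))
  expect_error(convert_parameterization(0.05, 1, 0), "r")
  expect_error(convert_parameterization(0.05, 0.5, 1), "s")
  expect_error(convert_parameterization(-0.1, 0.5, 0.1), "d")
})

test_that("round-trip between canonical and compound parameters is exact", {
  set.seed(31)
  for (i in 1:50) {
    la <- runif(1, 0.01, 2)
    mu <- runif(1, 0, la * 0.99)
    psi <- runif(1, 0, 1)
    drs <- rates_to_drs(la, mu, psi)
    back <- convert_parameterization(drs$d, drs$r, drs$s)
    expect_equal(back$lambda, la, tolerance = 1e-12)
    expect_equal(back$mu, mu, tolerance = 1e-12)
    expect_equal(back$psi, psi, tolerance = 1e-12)
  }
  expect_error(fbd_params(0.1, 0.2, 0.01, 2), "rho")
})

test_that("FBD kernel functions solve their defining ODEs", {
  skip_if_not_installed("deSolve")
  la <- 0.25
  mu <- 0.1
  psi <- 0.05
  rho <- 0.6
  ts <- seq(0, 12, 0.5)
  sol <- deSolve::ode(
    c(p0 = 1 - rho, q = 1),
    ts,
    function(t, y, p) {
      list(c(
        -(la + mu + psi) * y[1] + mu + la * y[1]^2,
        -(la + mu + psi) * y[2] + 2 * la * y[1] * y[2]
      ))
    },
    NULL,
    rtol = 1e-10, atol = 1e-12
  )
  expect_lt(max(abs(sol[, 2] - fbdselect:::.fbd_p0(ts, la, mu, psi, rho))), 1e-8)
  expect_lt(max(abs(sol[, 3] - exp(fbdselect:::.fbd_log_q(ts, la, mu, psi, rho)))), 1e-8)
})

test_that("FBD density reduces to the birth-death density at psi = 0", {
  # two independent closed forms (c1/c2 kernels vs rho-sampled Nee et al.
  # expressions) must agree on arbitrary extant trees
  set.seed(32)
  for (i in 1:100) {
    tr <- simulate_bd_tree(0.4, 0.15,
      root_age = 6, n_min = 3, n_max = 30,
      require_both_sides = (i %% 2 == 0)
    )
    rec <- reconstruct_extant(tr)$tree
    la <- runif(1, 0.1, 0.8)
    mu <- runif(1, 0, la * 0.9)
    rho <- runif(1, 0.2, 1)
    a <- fbd_log_density(rec, fbd_params(la, mu, 0, rho))
    b <- bd_log_density(rec, la, mu, rho)
    expect_lt(abs(a - b), 1e-8)
  }
})

test_that("FBD density matches the Yule closed form at mu = psi = 0, rho = 1", {
  set.seed(33)
  tr <- simulate_bd_tree(0.5, 0, root_age = 5, n_min = 4, n_max = 30)
  rec <- reconstruct_extant(tr)$tree
  la <- 0.37
  # Yule: each non-root divergence contributes lambda e^(-lambda x); the two
  # root lineages contribute e^(-lambda x1) each
  x1 <- root_age(rec)
  xs <- divergence_ages(rec, drop_root = TRUE)
  yule <- -2 * la * x1 + sum(log(la) - la * xs)
  expect_equal(fbd_log_density(rec, fbd_params(la, 0, 0, 1)), yule,
    tolerance = 1e-10
  )
})

test_that("two-tip birth-death density matches the hand computation", {
  tr <- fbd_tree(parent = c(0L, 1L, 1L), age = c(7, 0, 0))
  la <- 0.3
  mu <- 0.1
  # conditioned on the root age and both sides surviving, a two-tip tree is
  # the whole event: density = p1(x1)^2 / (1 - p0(x1))^2 with rho = 1
  d <- la - mu
  p0 <- function(t) mu * (1 - exp(-d * t)) / (la - mu * exp(-d * t))
  p1 <- function(t) d^2 * exp(-d * t) / (la - mu * exp(-d * t))^2
  hand <- 2 * log(p1(7)) - 2 * log(1 - p0(7))
  expect_equal(bd_log_density(tr, la, mu, 1), hand, tolerance = 1e-10)
})

test_that("density is exchangeable and rejects inverted attachments", {
  # relabeling tips (permuting children) leaves the density unchanged
  tr1 <- fbd_tree(
    parent = c(0L, 1L, 1L, 2L, 2L, 5L, 5L),
    age = c(10, 6, 0, 0, 4, 0, 2)
  )
  tr2 <- fbd_tree(
    parent = c(0L, 1L, 1L, 2L, 2L, 5L, 5L),
    age = c(10, 6, 0, 0, 4, 2, 0)
  )
  p <- fbd_params(0.2, 0.05, 0.02, 0.8)
  expect_equal(fbd_log_density(tr1, p), fbd_log_density(tr2, p))
  # a fossil tip older than its attachment is not constructible as a tree,
  # and the vector core returns -Inf for inverted configurations
  expect_identical(
    fbdselect:::.fbd_log_density_core(10, c(6, 11), numeric(0), 4,
      0.2, 0.05, 0.02, 0.8),
    -Inf
  )
  expect_error(
    fbd_tree(parent = c(0L, 1L, 1L, 2L, 2L), age = c(10, 4, 0, 5, 0)),
    "child ages"
  )
})

test_that("C++ prior fast path agrees with the R density path", {
  d <- make_mini_data(seed = 34, k = 8)
  fa <- select_fossils(d$samp$fossils, "oldest")
  tree <- d$samp$tree
  par <- tree$parent
  tip <- is_tip(tree)
  nonroot_int <- setdiff(which(!tip), 1L)
  m <- nrow(fa)
  att <- (fa$age + tree$age[par[fa$current_branch]]) / 2
  drs <- d$truth
  cpp <- fbdselect:::.fbd_prior_cpp(
    tree$age, par, nonroot_int, sum(tip), att, fa$age,
    par[fa$current_branch], integer(0), integer(0),
    drs$d, drs$r, drs$s, d$rho
  )
  rates <- convert_parameterization(drs$d, drs$r, drs$s)
  r_core <- fbdselect:::.fbd_log_density_core(
    root_age(tree), c(tree$age[nonroot_int], att), fa$age, sum(tip),
    rates$lambda, rates$mu, rates$psi, d$rho
  )
  expect_equal(cpp, r_core, tolerance = 1e-10)
})
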