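trapz_cdf <- function(x, y) c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(x)))

test_that("calibration density validates inputs", {
  expect_error(
    estimate_first_occurrence_density(c(0.1, 0.05), 0.2, 0.01),
    "degenerate interval"
  )
  expect_error(estimate_first_occurrence_density(0.06, 1.2, 0.01), "r")
  expect_error(estimate_first_occurrence_density(0.06, 0.5, 0), "psi")
  expect_error(
    estimate_first_occurrence_density(0.06, 0.5, 0.01, n_sims = 100),
    "n_sims"
  )
})

test_that("immortal single lineage gives the Exponential(psi) limit", {
  set.seed(41)
  psi <- 0.05
  gmax <- 200
  cal <- estimate_first_occurrence_density(1e-9, 0, psi,
    grid_max = gmax, n_sims = 1e5
  )
  cdf <- trapz_cdf(cal$grid, cal$density)
  truth <- (1 - exp(-psi * cal$grid)) / (1 - exp(-psi * gmax))
  expect_lt(max(abs(cdf - truth)), 0.01)
  # log density at delta = 0 approaches log(psi) (modulo truncation mass)
  expect_equal(
    calibration_log_density(cal, 50, 50),
    log(psi / (1 - exp(-psi * gmax))),
    tolerance = 0.05
  )
})

test_that("study-value density agrees with the quadrature oracle", {
  set.seed(42)
  cal <- estimate_first_occurrence_density(0.06, 0.5, 0.01,
    grid_max = 250, n_sims = 1e5
  )
  ora <- first_occurrence_density_ode(0.06, 0.5, 0.01, grid_max = 250)
  tv <- 0.5 * sum(abs(cal$density - ora$density)) * diff(cal$grid[1:2])
  expect_lt(tv, 0.02)
})

test_that("estimated densities are normalized and start at delta = 0", {
  set.seed(43)
  for (psi in c(0.005, 0.05)) {
    cal <- estimate_first_occurrence_density(0.06, 0.5, psi,
      grid_max = 250, n_sims = 1e4
    )
    integral <- sum((cal$density[-1] + cal$density[-length(cal$density)]) / 2) *
      diff(cal$grid[1:2])
    expect_lt(abs(integral - 1), 0.01)
    expect_identical(cal$grid[1], 0)
    expect_true(all(cal$density >= 0))
  }
})

test_that("larger psi makes first occurrences stochastically earlier", {
  set.seed(44)
  lo <- estimate_first_occurrence_density(0.06, 0.5, 0.005,
    grid_max = 250, n_sims = 3e4
  )
  hi <- estimate_first_occurrence_density(0.06, 0.5, 0.05,
    grid_max = 250, n_sims = 3e4
  )
  cdf_lo <- trapz_cdf(lo$grid, lo$density)
  cdf_hi <- trapz_cdf(hi$grid, hi$density)
  # first-order stochastic dominance up to Monte-Carlo noise, with a
  # strictly positive average gap
  expect_true(all(cdf_hi >= cdf_lo - 0.02))
  expect_gt(mean(cdf_hi - cdf_lo), 0.02)
  # very large psi concentrates mass near zero
  conc <- estimate_first_occurrence_density(0.06, 0.5, 1,
    grid_max = 50, n_sims = 1e4
  )
  mean_delta <- sum(conc$grid * conc$density) * diff(conc$grid[1:2])
  expect_lt(mean_delta, 2 / 1)
})

test_that("parameter uncertainty intervals widen the calibration density", {
  set.seed(45)
  exact <- estimate_first_occurrence_density(0.06, 0.5, 0.01,
    grid_max = 250, n_sims = 5e4
  )
  wide <- estimate_first_occurrence_density(
    c(0.03, 0.09), c(0.25, 0.75), c(0.005, 0.015),
    grid_max = 250, n_sims = 5e4
  )
  mom <- function(cal, k) {
    sum(cal$grid^k * cal$density) * diff(cal$grid[1:2])
  }
  var_exact <- mom(exact, 2) - mom(exact, 1)^2
  var_wide <- mom(wide, 2) - mom(wide, 1)^2
  expect_gte(var_wide, var_exact)
})

test_that("calibration lookup interpolates and rejects impossible ages", {
  set.seed(46)
  cal <- estimate_first_occurrence_density(0.06, 0.5, 0.01,
    grid_max = 250, n_sims = 1e4
  )
  # clade younger than its own fossil has zero density
  expect_identical(calibration_log_density(cal, 10, 20), -Inf)
  # interpolated values are bounded by the neighboring grid densities
  set.seed(47)
  for (i in 1:50) {
    delta <- runif(1, 0, 250)
    j <- findInterval(delta, cal$grid)
    lo <- min(cal$density[j], cal$density[j + 1])
    hi <- max(cal$density[j], cal$density[j + 1])
    v <- exp(calibration_log_density(cal, delta + 5, 5))
    expect_gte(v, lo - 1e-12)
    expect_lte(v, hi + 1e-12)
  }
})
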