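test_that("HPD intervals match analytic quantiles", {
  expect_error(hpd_interval(numeric(0)), "empty")
  expect_error(hpd_interval(1:5), "at least 10")
  expect_error(hpd_interval(1:20, 1.2), "credibility")
  # constant series: zero width
  expect_equal(diff(hpd_interval(rep(2, 50))), 0)
  set.seed(61)
  z <- rnorm(4e6)
  h <- hpd_interval(z, 0.95)
  expect_lt(max(abs(h - c(-1.96, 1.96))), 0.02)
  u <- runif(1e6)
  hu <- hpd_interval(u, 0.95)
  expect_lt(abs(diff(hu) - 0.95), 0.01)
})

test_that("effective sample size tracks autocorrelation time", {
  set.seed(62)
  x <- rnorm(5000)
  expect_lt(abs(effective_sample_size(x) / 5000 - 1), 0.1)
  # AR(1): ESS/n = (1 - phi) / (1 + phi)
  phi <- 0.9
  y <- as.numeric(arima.sim(list(ar = phi), 20000))
  expect_lt(
    abs(effective_sample_size(y) / (20000 * (1 - phi) / (1 + phi)) - 1),
    0.2
  )
  expect_warning(ess0 <- effective_sample_size(rep(1, 200)), "constant")
  expect_identical(ess0, 0)
  expect_error(effective_sample_size(rnorm(50)), "at least 100")
  expect_lte(effective_sample_size(rnorm(500)), 500)
})

test_that("a run is flagged stationary only when all gate ESS exceed the threshold", {
  d <- make_mini_data(seed = 63, k = 6, len = 100)
  pri <- prior_spec(
    par_uniform_about(d$truth$d), par_uniform_about(d$truth$r),
    par_uniform_about(d$truth$s)
  )
  fit <- fbd_dating(d$samp$tree,
    priors = pri, rho = d$rho,
    target = "parameters_only",
    settings = mcmc_settings(n_iter = 40000, thin = 10, ess_threshold = 200)
  )
  s <- summary(fit)
  gate <- s$ess[s$parameter %in% c("d", "r", "s", "clock_rate", "age_1")]
  expect_identical(attr(s, "stationary"), all(gate > 200))
  # an absurd threshold can never be met
  fit$settings$ess_threshold <- 1e9
  expect_false(attr(summary(fit), "stationary"))
})

test_that("prior-only runs recover the parameter priors (move-kernel check)", {
  d <- make_mini_data(seed = 64, k = 6, len = 100)
  pri <- prior_spec(
    par_uniform(0.03, 0.09), par_uniform(0.25, 0.75),
    par_uniform(0.05, 0.25)
  )
  fit <- fbd_dating(d$samp$tree,
    priors = pri, rho = d$rho,
    target = "parameters_only",
    settings = mcmc_settings(n_iter = 450000, thin = 150, burnin = 0.1)
  )
  tr <- fit$trace[-(1:300), ]
  expect_gt(stats::ks.test(tr$d, "punif", 0.03, 0.09)$p.value, 0.01)
  expect_gt(stats::ks.test(tr$r, "punif", 0.25, 0.75)$p.value, 0.01)
  expect_gt(stats::ks.test(tr$s, "punif", 0.05, 0.25)$p.value, 0.01)
  # the clock mean is log-uniform over its support in the prior
  lv <- log(tr$clock_rate)
  expect_gt(
    stats::ks.test(lv, "punif", log(3e-3) - log(100), log(3e-3) + log(100))$p.value,
    0.01
  )
})

test_that("identical seeds reproduce identical traces", {
  d <- make_mini_data(seed = 65, k = 6, len = 120)
  pri <- prior_spec(
    par_fixed(d$truth$d), par_fixed(d$truth$r), par_fixed(d$truth$s)
  )
  fa <- select_fossils(d$samp$fossils, "oldest")
  run <- function() {
    fbd_dating(d$samp$tree, d$aln, fa,
      method = "fbd", priors = pri,
      rho = d$rho,
      settings = mcmc_settings(n_iter = 5000, thin = 50, seed = 99)
    )
  }
  expect_identical(run()$trace, run()$trace)
})

test_that("the sampler reports informative failures for invalid setups", {
  d <- make_mini_data(seed = 66, k = 6, len = 100)
  pri <- prior_spec(par_fixed(0.06), par_fixed(0.5), par_fixed(0.143))
  expect_error(
    fbd_dating(d$samp$tree,
      priors = pri, rho = d$rho, target = "posterior"
    ),
    "alignment required"
  )
  expect_error(
    fbd_dating(d$samp$tree, d$aln,
      method = "cladeage", priors = pri,
      rho = d$rho
    ),
    "calibration"
  )
  # a fossil assignment violating its own age support is reported
  bad <- select_fossils(d$samp$fossils, "oldest")
  bad$age <- bad$age + 1000
  expect_error(
    fbd_dating(d$samp$tree, d$aln, bad,
      method = "fbd", priors = pri,
      rho = d$rho
    ),
    "non-finite initial posterior"
  )
})

test_that("parameters are recovered on randomly sampled trees with all fossils", {
  # complete-information analog: random taxon sampling, all fossils used,
  # d/r/s estimated; truth should fall inside the 95% credible intervals at
  # roughly the nominal rate (pooled over replicates and parameters). The
  # generating harness imposes no richness conditioning beyond k <= N, so
  # that the trees carry no acceptance information the model cannot see.
  truth <- rates_to_drs(0.12, 0.06, 0.01)
  hits <- 0L
  total <- 0L
  for (rep in 1:12) {
    set.seed(770 + rep)
    tree <- simulate_bd_tree(0.12, 0.06,
      root_age = 50, n_min = 12,
      n_max = 10^9
    )
    fossils <- overlay_fossils(tree, 0.01)
    rec <- reconstruct_extant(tree, fossils)
    samp <- random_sample(rec$tree, 12, rec$fossils)
    rates <- draw_branch_rates(samp$tree, clock_model())
    aln <- simulate_alignment(samp$tree, rates, 500)
    fa <- select_fossils(samp$fossils, "all")
    pri <- prior_spec(
      par_uniform_about(truth$d), par_uniform_about(truth$r),
      par_uniform_about(truth$s)
    )
    fit <- fbd_dating(samp$tree, aln, fa,
      method = "fbd", priors = pri,
      rho = 12 / n_extant(tree),
      settings = mcmc_settings(n_iter = 120000, thin = 120)
    )
    s <- summary(fit)
    for (nm in c("d", "r", "s")) {
      row <- s[s$parameter == nm, ]
      hits <- hits + (truth[[nm]] >= row$hpd_lower && truth[[nm]] <= row$hpd_upper)
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})
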