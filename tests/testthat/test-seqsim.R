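test_that("lognormal clock recovers nominal mean and variance by moment matching", {
  cl <- clock_model(3e-3, 9e-6)
  # closed-form moments of the matched lognormal
  m <- exp(cl$meanlog + cl$sdlog^2 / 2)
  v <- (exp(cl$sdlog^2) - 1) * exp(2 * cl$meanlog + cl$sdlog^2)
  expect_equal(m, 3e-3, tolerance = 1e-12)
  expect_equal(v, 9e-6, tolerance = 1e-12)
  # large-sample convergence of draws
  set.seed(21)
  x <- stats::rlnorm(1e5, cl$meanlog, cl$sdlog)
  expect_lt(abs(mean(x) - 3e-3) / 3e-3, 0.02)
  expect_lt(abs(var(x) - 9e-6) / 9e-6, 0.1)
  # degenerate variance gives a strict clock
  strict <- clock_model(3e-3, 0)
  tr <- worked_tree()
  set.seed(1)
  expect_true(all(draw_branch_rates(tr, strict)[-1] == 3e-3))
  expect_error(clock_model(3e-3, -1), "rate_variance")
})

test_that("HKY transition probabilities match a dense eigendecomposition", {
  q_matrix <- function(kappa, pi) {
    M <- matrix(0, 4, 4)
    for (i in 1:4) {
      for (j in 1:4) {
        if (i != j) {
          ts <- (i == 1 && j == 3) || (i == 3 && j == 1) ||
            (i == 2 && j == 4) || (i == 4 && j == 2)
          M[i, j] <- if (ts) kappa * pi[j] else pi[j]
        }
      }
    }
    diag(M) <- -rowSums(M)
    M / -sum(pi * diag(M))
  }
  for (case in list(
    list(t = 0.3, kappa = 2, pi = c(.25, .25, .25, .25)),
    list(t = 1.7, kappa = 5, pi = c(.1, .4, .2, .3)),
    list(t = 0.01, kappa = 0.5, pi = c(.3, .2, .3, .2))
  )) {
    e <- eigen(q_matrix(case$kappa, case$pi))
    P_oracle <- e$vectors %*% diag(exp(case$t * e$values)) %*% solve(e$vectors)
    P <- hky_transition_matrix(case$t, case$kappa, case$pi)
    expect_lt(max(abs(P - P_oracle)), 1e-10)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
  }
})

test_that("alignment simulation honors branch lengths and rates", {
  tr <- fbd_tree(parent = c(0L, 1L, 1L), age = c(50, 0, 0))
  set.seed(22)
  # zero rate: all sequences identical to the root draw
  aln0 <- simulate_alignment(tr, 0, length = 200)
  expect_identical(aln0[1, ], aln0[2, ])
  expect_identical(dim(aln0), c(2L, 200L))
  expect_error(simulate_alignment(tr, 1e-3, length = 0), "length")
  # study dimensions
  d <- make_mini_data(seed = 23, k = 10, len = 300)
  expect_identical(dim(d$aln), c(10L, 300L))
  expect_true(all(d$aln %in% 1:4))
})

test_that("site pattern counts follow the exhaustive column classification", {
  # toy alignment with known classification per column
  aln <- rbind(
    c(1L, 1L, 1L, 2L),
    c(1L, 1L, 1L, 2L),
    c(1L, 2L, 3L, 2L),
    c(3L, 2L, 4L, 2L)
  )
  class(aln) <- c("fbd_alignment", class(aln))
  # col1 {A,A,A,G}: variable, not informative; col2 {A,A,C,C}: informative
  # col3 {A,A,G,T}: variable only; col4 {C,C,C,C}: constant
  cnt <- count_site_patterns(aln)
  expect_identical(unname(cnt["variable"]), 3L)
  expect_identical(unname(cnt["parsimony_informative"]), 1L)
  # brute-force check on a simulated alignment
  d <- make_mini_data(seed = 24, k = 8, len = 150)
  cnt2 <- count_site_patterns(d$aln)
  brute_var <- sum(apply(d$aln, 2, function(col) length(unique(col)) > 1))
  brute_pi <- sum(apply(d$aln, 2, function(col) {
    tb <- table(col)
    sum(tb >= 2) >= 2
  }))
  expect_identical(unname(cnt2["variable"]), as.integer(brute_var))
  expect_identical(unname(cnt2["parsimony_informative"]), as.integer(brute_pi))
})

test_that("longer trees produce stochastically more variable sites", {
  base <- fbd_tree(
    parent = c(0L, 1L, 1L, 3L, 3L),
    age = c(40, 0, 20, 0, 0)
  )
  scaled <- fbd_tree(base$parent, base$age * 4)
  set.seed(25)
  v1 <- replicate(40, count_site_patterns(
    simulate_alignment(base, 3e-3, 300)
  )["variable"])
  v2 <- replicate(40, count_site_patterns(
    simulate_alignment(scaled, 3e-3, 300)
  )["variable"])
  expect_gt(mean(v2), mean(v1))
})
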