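test_that("fossil transfer on the worked fixture matches hand enumeration", {
  tr <- worked_tree()
  # fossil 1 sits on extinct tip 7, whose stem diverged from the surviving
  # lineage at node 5 (age 4); fossil 2 sits on branch 5 itself, which is
  # suppressed in the reconstruction
  fs <- worked_fossils(ages = c(1.5, 3.5), branches = c(7L, 5L))
  out <- reconstruct_extant(tr, fs)
  rec <- out$tree
  # extant tips 4 and 6 survive; node 3 (extinct) drops the root side, so
  # the reconstructed root is node 2 (age 6); node 5 is degree-2 suppressed
  expect_identical(n_extant(rec), 2L)
  expect_identical(sort(rec$orig_id), c(2L, 4L, 6L))
  expect_identical(root_age(rec), 6)
  # fossil on branch 7 diverged at node 5 (age 4), which is suppressed;
  # the covering retained edge is the one subtending tip 6
  f1 <- out$fossils[1, ]
  expect_identical(rec$orig_id[f1$current_branch], 6L)
  expect_equal(f1$divergence_age, 4)
  # fossil on retained branch 5 stays on the edge covering that branch
  f2 <- out$fossils[2, ]
  expect_identical(rec$orig_id[f2$current_branch], 6L)
  expect_equal(f2$divergence_age, 3.5)
  # ages never change; count conserved
  expect_identical(out$fossils$age, fs$age)
})

test_that("pruning a tree with no extinct lineages is the identity", {
  tr <- fbd_tree(
    parent = c(0L, 1L, 1L, 3L, 3L),
    age = c(10, 0, 6, 0, 0)
  )
  fs <- worked_fossils(ages = 2, branches = 5L)
  out <- reconstruct_extant(tr, fs)
  expect_identical(out$tree$parent, tr$parent)
  expect_identical(out$tree$age, tr$age)
  expect_identical(out$fossils$current_branch, 5L)
})

test_that("fossil counts are conserved through the whole sampling cascade", {
  d <- make_mini_data(seed = 3)
  expect_identical(nrow(d$rec$fossils), nrow(d$fossils))
  expect_identical(nrow(d$samp$fossils), nrow(d$fossils))
  rs <- random_sample(d$rec$tree, 10, d$rec$fossils)
  expect_identical(nrow(rs$fossils), nrow(d$fossils))
})

test_that("diversified sampling retains exactly the k-1 oldest divergences", {
  for (seed in 1:4) {
    d <- make_mini_data(seed = seed, k = 12)
    src <- sort(divergence_ages(d$rec$tree), decreasing = TRUE)
    got <- sort(divergence_ages(d$samp$tree), decreasing = TRUE)
    expect_equal(got, src[1:11])
  }
  # k equal to the tip count returns the tree itself
  d <- make_mini_data(seed = 5, n_min = 20, n_max = 60, k = 10)
  full <- diversified_sample(d$rec$tree, n_extant(d$rec$tree), d$rec$fossils)
  expect_identical(full$tree$age, d$rec$tree$age)
  expect_error(diversified_sample(d$rec$tree, n_extant(d$rec$tree) + 1), "k")
})

test_that("random sampling is uniform over tips and respects root sides", {
  set.seed(14)
  tr <- simulate_bd_tree(0.2, 0, root_age = 15, n_min = 12, n_max = 40)
  rec <- reconstruct_extant(tr)$tree
  rec <- fbd_tree(rec$parent, rec$age) # re-key orig_id to this tree
  ntip <- n_extant(rec)
  k <- 5L
  counts <- integer(n_nodes(rec))
  ndraw <- 3000L
  side <- integer(n_nodes(rec))
  kids <- which(rec$parent == 1L)
  side[kids] <- kids
  for (i in 2:n_nodes(rec)) if (side[i] == 0L) side[i] <- side[rec$parent[i]]
  for (j in seq_len(ndraw)) {
    s <- random_sample(rec, k)
    tips <- s$tree$orig_id[is_tip(s$tree)]
    counts[tips] <- counts[tips] + 1L
    expect_identical(length(unique(side[tips])), 2L)
  }
  counts <- counts[counts > 0]
  expect_identical(length(counts), as.integer(ntip))
  # chi-square goodness of fit against equal inclusion probabilities
  p <- stats::chisq.test(counts, p = rep(1 / ntip, ntip))$p.value
  expect_gt(p, 0.01)
})

test_that("oldest-per-branch reduction keeps the single oldest fossil", {
  fs <- worked_fossils(
    ages = c(10, 20, 15, 4),
    branches = c(3L, 3L, 3L, 5L)
  )
  red <- select_fossils(fs, "oldest")
  expect_identical(nrow(red), 2L)
  expect_setequal(red$age, c(20, 4))
  expect_identical(attr(red, "mode"), "oldest")
  all_mode <- select_fossils(fs, "all")
  expect_identical(nrow(all_mode), 4L)
})

test_that("random sampling leaves more fossil-bearing branches than diversified", {
  # diversified trees concentrate fossils on fewer (older) branches; the
  # contrast grows with tree size, so test at a scale where it is reliable
  set.seed(15)
  diffs <- numeric(8)
  for (i in 1:8) {
    tr <- simulate_bd_tree(0.12, 0.06, n_min = 400, n_max = 900)
    fs <- overlay_fossils(tr, 0.01)
    rec <- reconstruct_extant(tr, fs)
    ds <- diversified_sample(rec$tree, 25, rec$fossils)
    rs <- random_sample(rec$tree, 25, rec$fossils)
    diffs[i] <- nrow(select_fossils(rs$fossils, "oldest")) -
      nrow(select_fossils(ds$fossils, "oldest"))
  }
  expect_gt(mean(diffs), 0)
})

test_that("CladeAge constraints obey own-fossil precedence and reuse", {
  # chain: root(1, age 10) -> node 2 (age 6) -> tips; fossils below
  tr <- fbd_tree(
    parent = c(0L, 1L, 1L, 2L, 2L, 5L, 5L),
    age = c(10, 8, 0, 0, 5, 0, 0)
  )
  # edge 5 has no own fossils; children edges 6, 7 have oldest 1.2 and 3.0
  fs <- worked_fossils(ages = c(1.2, 3.0, 2.0), branches = c(6L, 7L, 7L))
  cons <- cladeage_constraints(tr, fs)
  expect_identical(cons$node, c(2L, 5L, 6L, 7L))
  # parent edge without own record inherits the oldest in its clade
  expect_equal(cons$fossil_age[cons$node == 5L], 3.0)
  expect_equal(cons$fossil_age[cons$node == 2L], 3.0)
  expect_true(all(cons$inherited[cons$node %in% c(2L, 5L)]))
  # an edge with own fossils uses its own oldest regardless of descendants
  fs2 <- worked_fossils(ages = c(1.2, 3.0, 0.5), branches = c(6L, 7L, 5L))
  cons2 <- cladeage_constraints(tr, fs2)
  expect_equal(cons2$fossil_age[cons2$node == 5L], 0.5)
  expect_false(cons2$inherited[cons2$node == 5L])
  # no fossils -> no constraints
  empty <- cladeage_constraints(tr, worked_fossils(numeric(0), integer(0)))
  expect_identical(nrow(empty), 0L)
})
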