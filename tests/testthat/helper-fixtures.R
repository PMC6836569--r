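# Shared fixtures and small generators used across the test files.

# Hand-built 4-tip tree: root (1, age 10) with children A (2, internal age 6)
# and B (3, extinct tip age 3); A has children: extant tip 4 and internal
# node 5 (age 4) whose children are extant tip 6 and extinct tip 7 (age 2).
worked_tree <- function() {
  fbd_tree(
    parent = c(0L, 1L, 1L, 2L, 2L, 5L, 5L),
    age = c(10, 6, 3, 0, 4, 0, 2)
  )
}

worked_fossils <- function(ages, branches) {
  rec <- data.frame(
    fossil_id = seq_along(ages),
    age = ages,
    original_branch = branches,
    current_branch = branches,
    divergence_age = ages
  )
  class(rec) <- c("fossil_record", "data.frame")
  rec
}

# a small end-to-end dataset: simulated tree, fossils, sampled tree and
# alignment, at a scale that keeps unit tests fast
make_mini_data <- function(seed = 1, n_min = 80, n_max = 160, k = 10,
                           len = 400, psi = 0.01, scheme = "diversified") {
  set.seed(seed)
  tree <- simulate_bd_tree(0.12, 0.06, n_min = n_min, n_max = n_max)
  fossils <- overlay_fossils(tree, psi)
  rec <- reconstruct_extant(tree, fossils)
  samp <- if (scheme == "diversified") {
    diversified_sample(rec$tree, k, rec$fossils)
  } else {
    random_sample(rec$tree, k, rec$fossils)
  }
  rates <- draw_branch_rates(samp$tree, clock_model())
  aln <- simulate_alignment(samp$tree, rates, len)
  list(
    tree = tree, fossils = fossils, rec = rec, samp = samp,
    aln = aln, rho = k / n_extant(tree),
    truth = rates_to_drs(0.12, 0.06, psi)
  )
}

# forward draw from the FBD process started at a root divergence of age x1,
# with rho-sampling of extant tips; returns NULL unless the observed
# configuration matches n_keep sampled extant tips (on both root sides)
# and the requested number of fossils, none of which may have sampled
# descendants (no sampled-ancestor configurations)
forward_fbd_draw <- function(x1, lambda, mu, psi, rho, n_keep, m_keep) {
  tr <- try(
    simulate_bd_tree(lambda, mu,
      root_age = x1, n_min = 2, n_max = 10^9,
      max_attempts = 1000L
    ),
    silent = TRUE
  )
  if (inherits(tr, "try-error")) {
    return(NULL)
  }
  fossils <- overlay_fossils(tr, psi)
  if (nrow(fossils) != m_keep) {
    return(NULL)
  }
  ext <- which(is_extant_tip(tr))
  kept <- ext[stats::runif(length(ext)) < rho]
  if (length(kept) != n_keep) {
    return(NULL)
  }
  # both root sides sampled (the tree density conditions on this)
  side <- integer(n_nodes(tr))
  kids <- which(tr$parent == 1L)
  side[kids] <- kids
  for (i in 2:n_nodes(tr)) if (side[i] == 0L) side[i] <- side[tr$parent[i]]
  if (length(unique(side[kept])) != 2L) {
    return(NULL)
  }
  # exclude sampled-ancestor configurations: a fossil whose lineage carries
  # a sampled extant descendant
  if (m_keep > 0) {
    desc_kept <- logical(n_nodes(tr))
    desc_kept[kept] <- TRUE
    for (i in n_nodes(tr):2) {
      if (desc_kept[i]) desc_kept[tr$parent[i]] <- TRUE
    }
    if (any(desc_kept[fossils$current_branch])) {
      return(NULL)
    }
  }
  prune_to_tips(tr, kept, fossils)
}

# uniformized SBC rank: number of posterior draws below the truth, jittered
# to a continuous U(0,1) variate under the null
sbc_rank <- function(draws, truth) {
  (sum(draws < truth) + stats::runif(1)) / (length(draws) + 1)
}
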