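#' Simulate a constant-rate birth-death tree conditioned on extant richness
#'
#' Forward (Gillespie) simulation of a binary birth-death tree started from
#' a single divergence at `root_age` (two lineages), with per-lineage
#' speciation rate `lambda` and extinction rate `mu`. Waiting times between
#' events are exponential with rate `N (lambda + mu)` for `N` live lineages;
#' each event is a speciation with probability `lambda / (lambda + mu)` and
#' affects a uniformly chosen lineage. Attempts whose extant richness at the
#' present falls outside `[n_min, n_max]` (including extinction of the whole
#' tree) are discarded and re-drawn, so the returned tree is an exact draw
#' from the process conditioned on the richness window.
#'
#' The trajectory of lineage counts is simulated first (types and waiting
#' times only), and the tree topology is laid down only for accepted
#' trajectories; the two-stage scheme is distributionally identical to the
#' plain event loop because lineage choices are exchangeable.
#'
#' @param lambda speciation rate per lineage per time unit (> 0).
#' @param mu extinction rate per lineage per time unit (>= 0).
#' @param root_age age of the first divergence (time units before present).
#' @param n_min,n_max acceptance window for the number of extant species.
#' @param max_attempts maximum number of rejection-sampling attempts.
#' @param max_lineages hard cap on simultaneous lineages; trajectories that
#'   exceed it are treated as rejected (guards against runaway growth).
#' @param require_both_sides if `TRUE` (default), additionally require that
#'   both lineages of the first divergence have extant descendants, so that
#'   the reconstructed extant tree has its root at exactly `root_age`. This
#'   matches a sampling scheme that draws species from both sides of the
#'   root, which would be unsatisfiable on one-sided trees.
#' @return An `fbd_tree` with attributes `attempts` (number of trajectories
#'   drawn, including the accepted one) and `n_extant`.
#' @examples
#' set.seed(1)
#' tr <- simulate_bd_tree(0.12, 0.06, root_age = 100, n_min = 50, n_max = 200)
#' n_extant(tr)
#' @export
simulate_bd_tree <- function(lambda, mu, root_age = 100, n_min = 4000,
                             n_max = 5000, max_attempts = 100000L,
                             max_lineages = 50000L,
                             require_both_sides = TRUE) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (!is.finite(mu) || mu < 0) stop("mu must be >= 0")
  if (root_age <= 0) stop("root_age must be > 0")
  if (n_min < 2 || n_min > n_max) stop("need 2 <= n_min <= n_max")
  total <- lambda + mu
  pbirth <- lambda / total
  for (attempt in seq_len(max_attempts)) {
    res <- .bd_trajectory(pbirth, total, root_age, max_lineages)
    if (is.null(res)) next
    n_ext <- res$n_final
    if (n_ext < n_min || n_ext > n_max) next
    tr <- .bd_build_tree(res$types, res$times, root_age)
    if (require_both_sides && !.both_sides_extant(tr)) next
    attr(tr, "attempts") <- attempt
    attr(tr, "n_extant") <- n_ext
    return(tr)
  }
  stop(sprintf(
    "no tree with %g-%g extant species found in %d attempts",
    n_min, n_max, max_attempts
  ))
}

# One trajectory of the lineage-count process. Returns NULL on extinction or
# cap overflow, otherwise list(types, times, n_final) with the events that
# happened strictly before root_age was reached.
.bd_trajectory <- function(pbirth, total, root_age, max_lineages,
                           chunk = 4096L) {
  n_cur <- 2L
  t_cur <- 0
  types <- vector("list", 8L)
  times <- vector("list", 8L)
  nchunks <- 0L
  repeat {
    b <- stats::runif(chunk) < pbirth
    delta <- 2L * b - 1L
    n_pre <- n_cur + c(0L, cumsum(delta)[-chunk])
    n_post <- n_pre + delta
    # waiting time before event i depends on the pre-event count
    dt <- stats::rexp(chunk) / (pmax(n_pre, 1L) * total)
    tt <- t_cur + cumsum(dt)
    i_done <- which(tt > root_age)[1L] # present reached before event i_done
    i_ext <- which(n_post == 0L)[1L]
    i_cap <- which(n_post > max_lineages)[1L]
    stop_at <- suppressWarnings(min(i_done, i_ext, i_cap, na.rm = TRUE))
    if (is.finite(stop_at)) {
      if (!is.na(i_done) && i_done == stop_at) {
        keep <- seq_len(i_done - 1L)
        nchunks <- nchunks + 1L
        types[[nchunks]] <- b[keep]
        times[[nchunks]] <- tt[keep]
        return(list(
          types = unlist(types[seq_len(nchunks)]),
          times = unlist(times[seq_len(nchunks)]),
          n_final = n_pre[i_done]
        ))
      }
      return(NULL) # extinct or over cap
    }
    nchunks <- nchunks + 1L
    if (nchunks > length(types)) {
      length(types) <- 2L * nchunks
      length(times) <- 2L * nchunks
    }
    types[[nchunks]] <- b
    times[[nchunks]] <- tt
    n_cur <- n_post[chunk]
    t_cur <- tt[chunk]
  }
}

# Lay the topology over an accepted trajectory: each event picks a live
# lineage uniformly at random.
.bd_build_tree <- function(types, times, root_age) {
  nb <- sum(types)
  n_nodes_total <- 3L + 2L * nb
  parent <- integer(n_nodes_total)
  age <- numeric(n_nodes_total)
  parent[1L] <- 0L
  age[1L] <- root_age
  parent[2L] <- parent[3L] <- 1L
  act <- integer(n_nodes_total)
  act[1L] <- 2L
  act[2L] <- 3L
  nact <- 2L
  nn <- 3L
  picks <- stats::runif(length(types))
  for (k in seq_along(types)) {
    j <- 1L + as.integer(picks[k] * nact)
    if (j > nact) j <- nact
    v <- act[j]
    age[v] <- root_age - times[k]
    if (types[k]) {
      parent[nn + 1L] <- v
      parent[nn + 2L] <- v
      act[j] <- nn + 1L
      nact <- nact + 1L
      act[nact] <- nn + 2L
      nn <- nn + 2L
    } else {
      act[j] <- act[nact]
      nact <- nact - 1L
    }
  }
  # lineages alive at the present become extant tips with age 0 (default)
  fbd_tree(parent[seq_len(nn)], age[seq_len(nn)])
}

.both_sides_extant <- function(tr) {
  n <- n_nodes(tr)
  side <- integer(n)
  kids <- which(tr$parent == 1L)
  side[kids] <- kids
  for (i in 2:n) if (side[i] == 0L) side[i] <- side[tr$parent[i]]
  ext <- is_extant_tip(tr)
  length(unique(side[ext])) == 2L
}

#' Overlay a Poisson fossil record on a tree
#'
#' Each branch of length `l` receives `Poisson(psi * l)` fossil occurrences
#' with ages uniform over the branch's time span; fossil ages are recorded
#' without error. The root has no subtending branch and receives no fossils.
#'
#' @param tree an `fbd_tree`.
#' @param psi fossil-sampling rate per lineage per time unit (>= 0).
#' @return A `fossil_record`: a data frame with columns `fossil_id`, `age`,
#'   `original_branch` (stable id of the generating branch's child node),
#'   `current_branch` (node index in `tree`; updated by pruning operations),
#'   and `divergence_age` (age at which the fossil's lineage diverges from
#'   the current tree; equals the fossil's own age while it sits on its
#'   original branch).
#' @export
overlay_fossils <- function(tree, psi) {
  if (!is.finite(psi) || psi < 0) stop("psi must be >= 0")
  stopifnot(inherits(tree, "fbd_tree"))
  len <- branch_lengths(tree)
  counts <- stats::rpois(length(len), psi * len)
  counts[1L] <- 0L
  node <- rep.int(seq_along(counts), counts)
  lo <- tree$age[node]
  hi <- tree$age[tree$parent[node]]
  ages <- stats::runif(length(node), lo, hi)
  rec <- data.frame(
    fossil_id = seq_along(node),
    age = ages,
    original_branch = tree$orig_id[node],
    current_branch = node,
    divergence_age = ages
  )
  class(rec) <- c("fossil_record", "data.frame")
  rec
}

#' @export
print.fossil_record <- function(x, ...) {
  cat(sprintf(
    "fossil_record: %d occurrences on %d branches\n",
    nrow(x), length(unique(x$current_branch))
  ))
  if (nrow(x)) {
    cat(sprintf(
      "  age range %.3g-%.3g\n", min(x$age), max(x$age)
    ))
  }
  invisible(x)
}

#' Simulate replicate trees with fossil records
#'
#' Draws `n_trees` accepted birth-death trees and overlays a Poisson fossil
#' record on each. Each replicate runs under its own RNG seed derived from
#' the current RNG state, and the per-replicate seeds are recorded in the
#' result so any single replicate can be regenerated independently.
#'
#' @param n_trees number of replicates.
#' @param lambda,mu,root_age,n_min,n_max,max_attempts passed to
#'   [simulate_bd_tree()].
#' @param psi fossil-sampling rate, passed to [overlay_fossils()].
#' @return A list of `n_trees` elements, each `list(tree =, fossils =)`,
#'   with attribute `seeds` (integer vector of per-replicate seeds).
#' @export
simulate_replicates <- function(n_trees, lambda = 0.12, mu = 0.06,
                                psi = 0.01, root_age = 100, n_min = 4000,
                                n_max = 5000, max_attempts = 100000L) {
  stopifnot(n_trees >= 0)
  if (n_trees == 0L) {
    out <- list()
    attr(out, "seeds") <- integer(0)
    return(out)
  }
  seeds <- sample.int(.Machine$integer.max - 1L, n_trees)
  out <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    set.seed(seeds[i])
    tree <- simulate_bd_tree(lambda, mu,
      root_age = root_age, n_min = n_min,
      n_max = n_max, max_attempts = max_attempts
    )
    fossils <- overlay_fossils(tree, psi)
    out[[i]] <- list(tree = tree, fossils = fossils)
  }
  attr(out, "seeds") <- seeds
  out
}

#' Read and write fossil records as tab-separated tables
#'
#' @param rec a `fossil_record`.
#' @param file path to a TSV file.
#' @param tree_id identifier written alongside each occurrence.
#' @return `read_fossil_file` returns a `fossil_record`; `write_fossil_file`
#'   returns the path invisibly.
#' @export
write_fossil_file <- function(rec, file, tree_id = "tree1") {
  df <- cbind(tree_id = tree_id, as.data.frame(rec))
  utils::write.table(df, file,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(file)
}

#' @rdname write_fossil_file
#' @export
read_fossil_file <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  df$tree_id <- NULL
  class(df) <- c("fossil_record", "data.frame")
  df
}
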