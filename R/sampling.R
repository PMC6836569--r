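#' Prune a tree to a set of tips, transferring fossils to retained edges
#'
#' Core pruning engine shared by [reconstruct_extant()], [diversified_sample()]
#' and [random_sample()]. All tips not in `keep` are removed together with
#' their exclusive ancestry, degree-2 nodes are suppressed, and every fossil
#' whose branch is pruned is re-assigned to the retained edge subtending the
#' point where the pruned subtree's stem diverged from the retained tree.
#' Fossil ages are never changed and no fossil is ever dropped, so the
#' occurrence count is conserved.
#'
#' For each transferred fossil, `divergence_age` is updated to the age of
#' the divergence point, i.e. the age at which the fossil's lineage split
#' from the lineages of the pruned tree. Fossils that diverge above the new
#' root (possible when one side of the original root has no retained tips)
#' are assigned to the root node itself.
#'
#' @param tree an `fbd_tree`.
#' @param keep integer vector of node indices (tips) to retain.
#' @param fossils a `fossil_record` aligned to `tree`, or `NULL`.
#' @return `list(tree =, fossils =)`; the new tree carries an attribute
#'   `node_map` (old node index -> new index, `NA` for removed nodes).
#' @export
prune_to_tips <- function(tree, keep, fossils = NULL) {
  stopifnot(inherits(tree, "fbd_tree"))
  n <- n_nodes(tree)
  tip <- is_tip(tree)
  keep <- as.integer(keep)
  if (any(!tip[keep])) stop("keep must index tips")
  if (length(keep) < 2L) stop("need at least 2 tips to retain")
  par <- tree$parent
  has_kept <- logical(n)
  has_kept[keep] <- TRUE
  for (i in n:2) if (has_kept[i]) has_kept[par[i]] <- TRUE
  kept_ids <- which(has_kept)
  kept_ids <- kept_ids[kept_ids > 1L]
  kept_children <- tabulate(par[kept_ids], nbins = n)
  retained <- logical(n)
  retained[keep] <- TRUE
  retained <- retained | kept_children >= 2L
  # nearest retained proper ancestor
  ret_anc <- integer(n)
  for (i in 2:n) {
    ret_anc[i] <- if (retained[par[i]]) par[i] else ret_anc[par[i]]
  }
  # covering retained node: for every node on a kept path, the retained node
  # whose subtending edge in the pruned tree contains that node's position
  cov <- integer(n)
  covup <- integer(n)
  for (i in n:1) {
    if (retained[i]) {
      cov[i] <- i
    } else if (has_kept[i]) {
      cov[i] <- covup[i]
    }
    if (i > 1L && has_kept[i]) covup[par[i]] <- cov[i]
  }
  ids <- which(retained) # ascending => topological order preserved
  new_id <- integer(n)
  new_id[ids] <- seq_along(ids)
  ra <- ret_anc[ids]
  new_parent <- integer(length(ids))
  new_parent[ra > 0L] <- new_id[ra[ra > 0L]]
  # exactly one retained node without retained ancestor: the new root
  if (sum(new_parent == 0L) != 1L || new_parent[1L] != 0L) {
    stop("pruning produced an invalid root")
  }
  out <- fbd_tree(new_parent, tree$age[ids], orig_id = tree$orig_id[ids])
  attr(out, "node_map") <- replace(rep(NA_integer_, n), ids, new_id[ids])
  new_fossils <- NULL
  if (!is.null(fossils)) {
    new_fossils <- fossils
    if (nrow(fossils)) {
      cb <- fossils$current_branch
      div <- fossils$divergence_age
      for (f in seq_len(nrow(fossils))) {
        v <- cb[f]
        if (has_kept[v]) {
          cb[f] <- new_id[cov[v]]
        } else {
          a <- v
          while (!has_kept[a]) a <- par[a]
          div[f] <- tree$age[a]
          cb[f] <- if (retained[a]) new_id[a] else new_id[cov[a]]
        }
      }
      new_fossils$current_branch <- cb
      new_fossils$divergence_age <- div
    }
    class(new_fossils) <- c("fossil_record", "data.frame")
  }
  list(tree = out, fossils = new_fossils)
}

#' Reconstructed (extant-only) tree with transferred fossil records
#'
#' Prunes all extinct lineages from a simulated tree and transfers the
#' fossils of pruned branches to the ancestral branch in the reconstructed
#' phylogeny from which they diverged. Internal node ages of the result are
#' exactly the corresponding divergence ages of the full tree, and the
#' fossil occurrence count is conserved. Transferred fossil ages may
#' postdate the end of the branch they are assigned to, as is the case for
#' stem-group fossils that are younger than the origin of a crown group.
#'
#' @param tree an `fbd_tree` with at least two extant tips.
#' @param fossils a `fossil_record` for `tree`, or `NULL`.
#' @return `list(tree =, fossils =)` as in [prune_to_tips()].
#' @export
reconstruct_extant <- function(tree, fossils = NULL) {
  keep <- which(is_extant_tip(tree))
  if (length(keep) < 2L) stop("tree has fewer than 2 extant tips")
  prune_to_tips(tree, keep, fossils)
}

#' Strict diversified sampling of extant species
#'
#' Implements the strict diversified sampling scheme: the time point at
#' which exactly `k` branches with extant descendants existed is identified
#' on the extant-only tree, and one extant descendant of each of these `k`
#' branches is sampled uniformly at random. The resulting `k`-tip tree is
#' guaranteed to retain exactly the `k - 1` oldest divergences of the source
#' tree and none younger. Fossils are re-transferred to the retained edges.
#'
#' @param rtree an ultrametric extant-only `fbd_tree` (see
#'   [reconstruct_extant()]).
#' @param k number of species to sample (2 <= k <= number of tips).
#' @param fossils a `fossil_record` for `rtree`, or `NULL`.
#' @return `list(tree =, fossils =)`; the tree carries attribute
#'   `scheme = "diversified"`.
#' @export
diversified_sample <- function(rtree, k, fossils = NULL) {
  stopifnot(inherits(rtree, "fbd_tree"))
  tip <- is_tip(rtree)
  ntip <- sum(tip)
  if (any(rtree$age[tip] != 0)) stop("rtree must be extant-only (ultrametric)")
  if (k < 2 || k > ntip) stop("need 2 <= k <= number of tips")
  n <- n_nodes(rtree)
  int_ages <- rtree$age[!tip]
  thr <- sort(int_ages, decreasing = TRUE)[k - 1L]
  # lineages crossing the time point just after the (k-1)-th divergence
  idx <- 2:n
  cross <- idx[rtree$age[idx] < thr & rtree$age[rtree$parent[idx]] >= thr]
  if (rtree$age[1L] < thr) stop("threshold above root") # cannot happen
  if (length(cross) != k) stop("internal error: crossing count != k")
  # propagate subtree membership top-down
  grp <- integer(n)
  grp[cross] <- cross
  for (i in idx) if (grp[i] == 0L) grp[i] <- grp[rtree$parent[i]]
  chosen <- integer(k)
  tips_by_grp <- split(which(tip), grp[tip])
  for (j in seq_along(cross)) {
    cand <- tips_by_grp[[as.character(cross[j])]]
    chosen[j] <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  }
  out <- prune_to_tips(rtree, chosen, fossils)
  attr(out$tree, "scheme") <- "diversified"
  out
}

#' Uniform random sampling of extant species
#'
#' Samples `k` tips uniformly at random without replacement, subject to the
#' requirement that at least one tip is sampled from each side of the root;
#' draws violating the requirement are rejected and redrawn wholesale, which
#' preserves uniformity conditional on the constraint.
#'
#' @param rtree an ultrametric extant-only `fbd_tree`.
#' @param k number of species to sample.
#' @param fossils a `fossil_record` for `rtree`, or `NULL`.
#' @param max_draws maximum number of rejection draws.
#' @return `list(tree =, fossils =)`; the tree carries attribute
#'   `scheme = "random"`.
#' @export
random_sample <- function(rtree, k, fossils = NULL, max_draws = 10000L) {
  stopifnot(inherits(rtree, "fbd_tree"))
  tip <- is_tip(rtree)
  ntip <- sum(tip)
  if (any(rtree$age[tip] != 0)) stop("rtree must be extant-only (ultrametric)")
  if (k < 2 || k > ntip) stop("need 2 <= k <= number of tips")
  n <- n_nodes(rtree)
  side <- integer(n)
  kids <- which(rtree$parent == 1L)
  side[kids] <- kids
  for (i in 2:n) if (side[i] == 0L) side[i] <- side[rtree$parent[i]]
  tips <- which(tip)
  for (d in seq_len(max_draws)) {
    chosen <- tips[sample.int(ntip, k)]
    if (length(unique(side[chosen])) == 2L) {
      out <- prune_to_tips(rtree, chosen, fossils)
      attr(out$tree, "scheme") <- "random"
      return(out)
    }
  }
  stop("could not sample both root sides in max_draws attempts")
}

#' Reduce a fossil record for inference
#'
#' In `"oldest"` mode the record is reduced to the single oldest fossil per
#' fossil-bearing branch, as done before fossilized birth-death inference in
#' the study design; `"all"` keeps the complete record.
#'
#' @param fossils a `fossil_record` aligned to a sampled tree.
#' @param mode `"oldest"` or `"all"`.
#' @return A `fossil_record` subset with attribute `mode`.
#' @export
select_fossils <- function(fossils, mode = c("oldest", "all")) {
  mode <- match.arg(mode)
  out <- fossils
  if (mode == "oldest" && nrow(fossils)) {
    keep <- unlist(lapply(
      split(seq_len(nrow(fossils)), fossils$current_branch),
      function(i) i[which.max(fossils$age[i])]
    ), use.names = FALSE)
    out <- fossils[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("fossil_record", "data.frame")
  attr(out, "mode") <- mode
  out
}

#' CladeAge-style constraints: oldest fossil per clade with parental reuse
#'
#' Every branch whose own fossil record is non-empty is constrained by its
#' oldest fossil. A branch without own fossils inherits, as its constraint,
#' the oldest fossil found anywhere in its descendant clade (fossils are
#' reused for parental branches without a record of their own); branches
#' whose descendant clades contain no fossils are unconstrained. The root
#' has no subtending branch and never receives a constraint.
#'
#' @param stree a sampled `fbd_tree`.
#' @param fossils a `fossil_record` aligned to `stree`.
#' @return Data frame with columns `node` (child node of the constrained
#'   edge), `fossil_age` (age of the constraining fossil) and `inherited`
#'   (`TRUE` when reused from the descendant clade).
#' @export
cladeage_constraints <- function(stree, fossils) {
  stopifnot(inherits(stree, "fbd_tree"))
  n <- n_nodes(stree)
  own <- rep(-Inf, n)
  if (nrow(fossils)) {
    agg <- tapply(fossils$age, fossils$current_branch, max)
    own[as.integer(names(agg))] <- agg
  }
  clade_max <- own
  for (i in n:2) {
    p <- stree$parent[i]
    if (clade_max[i] > clade_max[p]) clade_max[p] <- clade_max[i]
  }
  # inherited candidate for edge i: oldest fossil strictly below i
  kids_max <- rep(-Inf, n)
  for (i in n:2) {
    p <- stree$parent[i]
    if (clade_max[i] > kids_max[p]) kids_max[p] <- clade_max[i]
  }
  node <- integer(0)
  fossil_age <- numeric(0)
  inherited <- logical(0)
  for (i in 2:n) {
    if (is.finite(own[i])) {
      node <- c(node, i)
      fossil_age <- c(fossil_age, own[i])
      inherited <- c(inherited, FALSE)
    } else if (is.finite(kids_max[i])) {
      node <- c(node, i)
      fossil_age <- c(fossil_age, kids_max[i])
      inherited <- c(inherited, TRUE)
    }
  }
  data.frame(node = node, fossil_age = fossil_age, inherited = inherited)
}
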