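#' Time-calibrated tree with extinct and extant lineages
#'
#' `fbd_tree` is the package's internal tree representation: a flat node
#' table in topological order (every node's parent precedes it), with node
#' ages measured in time units before the present. It is designed so that
#' node identities stay traceable through pruning and taxon sampling, which
#' `ape::phylo` does not support directly.
#'
#' @param parent integer vector; `parent[i]` is the row index of node `i`'s
#'   parent, 0 for the root (which must be node 1).
#' @param age numeric vector of node ages (time before present); extant tips
#'   have age 0, extinct tips age > 0.
#' @param orig_id integer vector of stable node labels, carried unchanged
#'   through pruning so that branches can be traced back to the full tree.
#' @return An object of class `fbd_tree`: a list with elements `parent`,
#'   `age`, `orig_id` and attribute-like fields `root_age`, `n_extant`.
#' @export
fbd_tree <- function(parent, age, orig_id = seq_along(parent)) {
  parent <- as.integer(parent)
  n <- length(parent)
  stopifnot(length(age) == n, length(orig_id) == n)
  tr <- structure(
    list(parent = parent, age = as.numeric(age), orig_id = as.integer(orig_id)),
    class = "fbd_tree"
  )
  validate_fbd_tree(tr)
  tr
}

validate_fbd_tree <- function(tr) {
  n <- length(tr$parent)
  if (n < 1L) stop("empty tree")
  if (tr$parent[1L] != 0L) stop("root must be node 1 with parent 0")
  if (n > 1L && any(tr$parent[-1L] >= seq_len(n)[-1L] | tr$parent[-1L] < 1L)) {
    stop("nodes must be in topological order (parent index < child index)")
  }
  nch <- tabulate(tr$parent, nbins = n)
  if (any(nch != 0L & nch != 2L)) stop("tree must be binary (0 or 2 children per node)")
  if (n > 1L && any(tr$age[-1L] >= tr$age[tr$parent[-1L]])) {
    stop("child ages must be strictly smaller than parent ages")
  }
  if (any(tr$age < 0)) stop("negative node age")
  invisible(tr)
}

#' @export
print.fbd_tree <- function(x, ...) {
  cat(sprintf(
    "fbd_tree: %d nodes, %d tips (%d extant, %d extinct), root age %.4g\n",
    n_nodes(x), sum(is_tip(x)), n_extant(x),
    sum(is_tip(x)) - n_extant(x), root_age(x)
  ))
  invisible(x)
}

#' Tip and node predicates for `fbd_tree` objects
#'
#' `is_tip` flags childless nodes, `is_extant_tip` flags tips with age 0,
#' `n_extant` counts them, `root_age` returns the age of node 1, and
#' `branch_lengths` returns the parent-to-child time spans (0 for the root,
#' which has no subtending branch).
#'
#' @param tr an `fbd_tree`.
#' @return logical or numeric vectors over nodes, or a scalar count/age.
#' @export
n_nodes <- function(tr) length(tr$parent)

#' @rdname n_nodes
#' @export
is_tip <- function(tr) tabulate(tr$parent, nbins = n_nodes(tr)) == 0L

#' @rdname n_nodes
#' @export
is_extant_tip <- function(tr) is_tip(tr) & tr$age == 0

#' @rdname n_nodes
#' @export
n_extant <- function(tr) sum(is_extant_tip(tr))

#' @rdname n_nodes
#' @export
root_age <- function(tr) tr$age[1L]

#' @rdname n_nodes
#' @export
branch_lengths <- function(tr) {
  len <- numeric(n_nodes(tr))
  if (n_nodes(tr) > 1L) {
    idx <- 2:n_nodes(tr)
    len[idx] <- tr$age[tr$parent[idx]] - tr$age[idx]
  }
  len
}

internal_nodes <- function(tr) which(!is_tip(tr))

#' Node ages of divergences (internal nodes)
#'
#' @param tr an `fbd_tree`.
#' @param drop_root if `TRUE`, exclude the root age.
#' @return numeric vector of internal node ages.
#' @export
divergence_ages <- function(tr, drop_root = FALSE) {
  idx <- internal_nodes(tr)
  if (drop_root) idx <- setdiff(idx, 1L)
  tr$age[idx]
}

node_labels <- function(tr) {
  tip <- is_tip(tr)
  lab <- character(n_nodes(tr))
  lab[tip & tr$age == 0] <- paste0("t", tr$orig_id[tip & tr$age == 0])
  lab[tip & tr$age > 0] <- paste0("x", tr$orig_id[tip & tr$age > 0])
  lab[!tip] <- paste0("n", tr$orig_id[!tip])
  lab
}

#' Convert an `fbd_tree` to an `ape::phylo` object
#'
#' Branch lengths are time spans; tip labels are `t<id>` for extant and
#' `x<id>` for extinct tips, node labels `n<id>`, where `<id>` is the stable
#' `orig_id` of the node.
#'
#' @param x an `fbd_tree`.
#' @param ... unused.
#' @return an object of class `phylo`.
#' @export
as.phylo.fbd_tree <- function(x, ...) {
  n <- n_nodes(x)
  tip <- is_tip(x)
  ntip <- sum(tip)
  if (ntip < 2L) stop("need at least 2 tips for a phylo object")
  lab <- node_labels(x)
  num <- integer(n)
  num[tip] <- seq_len(ntip)
  num[!tip] <- ntip + seq_len(n - ntip) # root (node 1) -> ntip + 1
  idx <- 2:n
  edge <- cbind(num[x$parent[idx]], num[idx])
  phy <- list(
    edge = edge,
    edge.length = x$age[x$parent[idx]] - x$age[idx],
    Nnode = n - ntip,
    tip.label = lab[tip][order(num[tip])],
    node.label = lab[!tip][order(num[!tip])]
  )
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

#' Convert an `ape::phylo` object to an `fbd_tree`
#'
#' The tree must be rooted and binary with branch lengths in time units.
#' Tip ages are derived from root-to-tip path lengths; tips whose depth is
#' within `tol` of the maximum are treated as extant (age exactly 0).
#'
#' @param phy a rooted binary `phylo` object with edge lengths.
#' @param tol relative tolerance for flattening near-zero tip ages.
#' @return an `fbd_tree`.
#' @export
as_fbd_tree <- function(phy, tol = 1e-8) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) stop("tree must be binary")
  n <- ape::Ntip(phy) + phy$Nnode
  depth <- numeric(n) # time from root
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    depth[ord$edge[i, 2L]] <- depth[ord$edge[i, 1L]] + ord$edge.length[i]
  }
  h <- max(depth)
  age <- h - depth
  age[abs(age) < tol * h] <- 0
  # map ape numbering -> topological order
  ord_nodes <- integer(n)
  root <- ape::Ntip(phy) + 1L
  ord_nodes[1L] <- root
  parent_ape <- integer(n)
  parent_ape[phy$edge[, 2L]] <- phy$edge[, 1L]
  # BFS to get topological order
  queue <- root
  pos <- 1L
  filled <- 1L
  children <- split(phy$edge[, 2L], phy$edge[, 1L])
  while (pos <= filled) {
    v <- queue[pos]
    ch <- children[[as.character(v)]]
    if (!is.null(ch)) {
      queue <- c(queue, ch)
      filled <- filled + length(ch)
    }
    pos <- pos + 1L
  }
  new_id <- integer(n)
  new_id[queue] <- seq_len(n)
  parent_new <- integer(n)
  parent_new[new_id[queue[-1L]]] <- new_id[parent_ape[queue[-1L]]]
  fbd_tree(parent_new, age[queue], orig_id = seq_len(n))
}

#' Read and write trees in Newick format
#'
#' Thin wrappers over [ape::write.tree()] and [ape::read.tree()] operating on
#' `fbd_tree` objects, with branch lengths in time units.
#'
#' @param tr an `fbd_tree`.
#' @param file path to a Newick file.
#' @return `read_tree_file` returns an `fbd_tree`; `write_tree_file` returns
#'   the file path invisibly.
#' @export
write_tree_file <- function(tr, file) {
  ape::write.tree(as.phylo.fbd_tree(tr), file = file)
  invisible(file)
}

#' @rdname write_tree_file
#' @export
read_tree_file <- function(file) {
  as_fbd_tree(ape::read.tree(file))
}
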