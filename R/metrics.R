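#' Pybus-Harvey gamma statistic of an ultrametric tree
#'
#' Computes the constant-rates test statistic from the internode intervals
#' of the lineage-through-time sequence. Under a constant-rate pure-birth
#' process the statistic is asymptotically standard normal; strongly
#' negative values indicate divergences concentrated toward the root, as
#' produced by diversified taxon sampling. The computation is delegated to
#' [ape::gammaStat()] after conversion.
#'
#' @param tree an ultrametric `fbd_tree` (or `phylo`) with >= 3 tips.
#' @param tol relative tolerance for the ultrametricity check.
#' @return the gamma statistic (numeric scalar).
#' @export
gamma_statistic <- function(tree, tol = 1e-8) {
  phy <- if (inherits(tree, "fbd_tree")) as.phylo.fbd_tree(tree) else tree
  if (!inherits(phy, "phylo")) stop("need an fbd_tree or phylo object")
  if (ape::Ntip(phy) < 3L) stop("need at least 3 tips")
  if (!ape::is.ultrametric(phy, tol = tol * max(ape::node.depth.edgelength(phy)))) {
    stop("tree is not ultrametric")
  }
  ape::gammaStat(phy)
}

#' Pooled coverage accuracy of highest-posterior-density intervals
#'
#' Fraction of nodes whose HPD interval contains the true age, pooled over
#' all nodes of all replicate analyses sharing a setting (one pooled
#' proportion, not a mean of per-replicate proportions).
#'
#' @param reports data frame with columns `true`, `lower`, `upper` (one row
#'   per node per replicate).
#' @return pooled accuracy in `[0, 1]`.
#' @export
coverage_accuracy <- function(reports) {
  stopifnot(all(c("true", "lower", "upper") %in% names(reports)))
  if (!nrow(reports)) stop("empty report set")
  mean(reports$true >= reports$lower & reports$true <= reports$upper)
}

#' Root-mean-square deviation between true and estimated node ages
#'
#' @param true_ages numeric vector of true node ages.
#' @param mean_estimates numeric vector of posterior mean ages, same length.
#' @return RMSD in time units.
#' @export
rmsd <- function(true_ages, mean_estimates) {
  if (length(true_ages) != length(mean_estimates)) {
    stop("length mismatch between true ages and estimates")
  }
  sqrt(mean((true_ages - mean_estimates)^2))
}
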