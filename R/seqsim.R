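#' Uncorrelated lognormal relaxed clock
#'
#' Branch substitution rates are independent lognormal draws whose
#' real-scale mean and variance equal `mean_rate` and `rate_variance`; the
#' lognormal's log-scale parameters are obtained by moment matching:
#' `sdlog^2 = log(1 + V / M^2)`, `meanlog = log(M) - sdlog^2 / 2`.
#'
#' @param mean_rate mean substitution rate per site per time unit.
#' @param rate_variance real-scale variance of branch rates (0 gives a
#'   strict clock).
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(mean_rate = 3e-3, rate_variance = 9e-6) {
  if (!is.finite(mean_rate) || mean_rate <= 0) stop("mean_rate must be > 0")
  if (!is.finite(rate_variance) || rate_variance < 0) {
    stop("rate_variance must be >= 0")
  }
  sdlog2 <- log(1 + rate_variance / mean_rate^2)
  structure(
    list(
      mean_rate = mean_rate, rate_variance = rate_variance,
      meanlog = log(mean_rate) - sdlog2 / 2, sdlog = sqrt(sdlog2)
    ),
    class = "clock_model"
  )
}

#' Draw branch rates under an uncorrelated lognormal clock
#'
#' @param tree an `fbd_tree`; one rate is drawn for every branch (every
#'   non-root node).
#' @param clock a [clock_model()].
#' @return numeric vector of length `n_nodes(tree)`; element `i` is the rate
#'   of the branch above node `i` (`NA` for the root).
#' @export
draw_branch_rates <- function(tree, clock) {
  stopifnot(inherits(tree, "fbd_tree"), inherits(clock, "clock_model"))
  n <- n_nodes(tree)
  if (clock$sdlog == 0) {
    return(c(NA_real_, rep(clock$mean_rate, n - 1L))) # exact strict clock
  }
  c(NA_real_, stats::rlnorm(n - 1L, clock$meanlog, clock$sdlog))
}

#' HKY transition probability matrix
#'
#' Closed-form transition probabilities for the HKY substitution model with
#' transition/transversion ratio `kappa` and stationary frequencies
#' `freqs` (order A, C, G, T), for a branch of `t` expected substitutions
#' per site (the generator is normalized to unit mean rate).
#'
#' @param t branch length in expected substitutions per site.
#' @param kappa transition/transversion rate ratio.
#' @param freqs stationary base frequencies, summing to 1.
#' @return 4x4 row-stochastic matrix, rows/cols ordered A, C, G, T.
#' @export
hky_transition_matrix <- function(t, kappa = 2, freqs = rep(0.25, 4)) {
  stopifnot(t >= 0, kappa > 0, length(freqs) == 4, all(freqs > 0))
  freqs <- freqs / sum(freqs)
  P <- .hky_pmat_cpp(t, kappa, freqs)
  dimnames(P) <- list(c("a", "c", "g", "t"), c("a", "c", "g", "t"))
  P
}

#' Simulate a nucleotide alignment along a tree
#'
#' Evolves sites independently down the tree under the HKY model, with the
#' expected number of substitutions on each branch equal to the branch's
#' time span multiplied by its rate.
#'
#' @param tree an `fbd_tree` (typically a sampled, extant-only tree).
#' @param rates per-node branch rates as returned by [draw_branch_rates()];
#'   a single number is recycled to all branches.
#' @param length number of sites (>= 1).
#' @param kappa,freqs HKY parameters, see [hky_transition_matrix()].
#' @return An integer matrix (class `fbd_alignment`) of states 1..4
#'   (A, C, G, T), one row per tip, rownames set to tip labels.
#' @export
simulate_alignment <- function(tree, rates, length = 3000, kappa = 2,
                               freqs = rep(0.25, 4)) {
  stopifnot(inherits(tree, "fbd_tree"))
  if (length < 1) stop("alignment length must be >= 1")
  n <- n_nodes(tree)
  if (base::length(rates) == 1L) rates <- c(NA_real_, rep(rates, n - 1L))
  if (base::length(rates) != n) stop("need one rate per node")
  if (any(rates[-1L] < 0, na.rm = TRUE)) stop("rates must be >= 0")
  freqs <- freqs / sum(freqs)
  states <- matrix(0L, nrow = n, ncol = length)
  states[1L, ] <- sample.int(4L, length, replace = TRUE, prob = freqs)
  blen <- branch_lengths(tree)
  for (v in 2:n) {
    P <- .hky_pmat_cpp(blen[v] * rates[v], kappa, freqs)
    ps <- states[tree$parent[v], ]
    out <- integer(length)
    for (s in 1:4) {
      idx <- which(ps == s)
      if (base::length(idx)) {
        out[idx] <- sample.int(4L, base::length(idx), replace = TRUE, prob = P[s, ])
      }
    }
    states[v, ] <- out
  }
  tip <- is_tip(tree)
  aln <- states[tip, , drop = FALSE]
  rownames(aln) <- node_labels(tree)[tip]
  class(aln) <- c("fbd_alignment", class(aln))
  aln
}

#' @export
print.fbd_alignment <- function(x, ...) {
  cat(sprintf("fbd_alignment: %d taxa x %d sites\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Count variable and parsimony-informative sites
#'
#' A column is variable if it holds at least two distinct states, and
#' parsimony-informative if at least two distinct states each occur in at
#' least two taxa.
#'
#' @param aln an `fbd_alignment` (integer state matrix, taxa in rows).
#' @return named numeric vector `c(variable =, parsimony_informative =)`.
#' @export
count_site_patterns <- function(aln) {
  if (!nrow(aln) || !ncol(aln)) stop("empty alignment")
  variable <- 0L
  informative <- 0L
  for (j in seq_len(ncol(aln))) {
    tb <- tabulate(aln[, j], nbins = 4L)
    k <- sum(tb > 0L)
    if (k >= 2L) {
      variable <- variable + 1L
      if (sum(tb >= 2L) >= 2L) informative <- informative + 1L
    }
  }
  c(variable = variable, parsimony_informative = informative)
}

#' Write an alignment to a FASTA file
#'
#' @param aln an `fbd_alignment`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(aln, file) {
  chars <- c("A", "C", "G", "T")
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(chars[aln[i, ]], collapse = ""), con)
  }
  invisible(file)
}
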