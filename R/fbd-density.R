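#' Parameters of the fossilized birth-death process
#'
#' Bundles the canonical rates (speciation `lambda`, extinction `mu`,
#' fossil-sampling `psi`, extant-sampling probability `rho`) together with
#' the compound parameterization used for inference: net diversification
#' `d = lambda - mu`, turnover `r = mu / lambda`, and fossil-sampling
#' proportion `s = psi / (mu + psi)`.
#'
#' @param lambda speciation rate (> 0).
#' @param mu extinction rate (>= 0).
#' @param psi fossil-sampling rate (>= 0).
#' @param rho extant-species sampling probability in (0, 1].
#' @return An object of class `fbd_params`.
#' @examples
#' p <- fbd_params(0.12, 0.06, 0.01, 1)
#' p$s # 0.143: probability of fossilization before extinction
#' @export
fbd_params <- function(lambda, mu, psi = 0, rho = 1) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (!is.finite(mu) || mu < 0) stop("mu must be >= 0")
  if (!is.finite(psi) || psi < 0) stop("psi must be >= 0")
  if (!is.finite(rho) || rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  structure(
    list(
      lambda = lambda, mu = mu, psi = psi, rho = rho,
      d = lambda - mu,
      r = mu / lambda,
      s = if (mu + psi > 0) psi / (mu + psi) else 0
    ),
    class = "fbd_params"
  )
}

#' @export
print.fbd_params <- function(x, ...) {
  cat(sprintf(
    "fbd_params: lambda=%.4g mu=%.4g psi=%.4g rho=%.4g | d=%.4g r=%.4g s=%.4g\n",
    x$lambda, x$mu, x$psi, x$rho, x$d, x$r, x$s
  ))
  invisible(x)
}

#' Convert between compound and canonical diversification parameters
#'
#' `convert_parameterization` maps net diversification `d`, turnover `r`
#' and fossil-sampling proportion `s` to the canonical rates:
#' `lambda = d / (1 - r)`, `mu = d r / (1 - r)`, `psi = s mu / (1 - s)`.
#' `rates_to_drs` is the exact inverse.
#'
#' @param d net diversification rate `lambda - mu` (> 0).
#' @param r turnover `mu / lambda` in `[0, 1)`.
#' @param s fossil-sampling proportion `psi / (mu + psi)` in `[0, 1)`.
#' @return `convert_parameterization`: list with `lambda`, `mu`, `psi`;
#'   `rates_to_drs`: list with `d`, `r`, `s`.
#' @examples
#' convert_parameterization(0.06, 0.5, 0.143) # lambda=0.12 mu=0.06 psi~0.01
#' @export
convert_parameterization <- function(d, r, s) {
  if (any(d <= 0)) stop("d must be > 0")
  if (any(r < 0 | r >= 1)) stop("r must be in [0, 1)")
  if (any(s < 0 | s >= 1)) stop("s must be in [0, 1)")
  lambda <- d / (1 - r)
  mu <- d * r / (1 - r)
  list(lambda = lambda, mu = mu, psi = s * mu / (1 - s))
}

#' @rdname convert_parameterization
#' @param lambda,mu,psi canonical rates.
#' @export
rates_to_drs <- function(lambda, mu, psi) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  list(
    d = lambda - mu,
    r = mu / lambda,
    s = ifelse(mu + psi > 0, psi / (mu + psi), 0)
  )
}

# ---- constant-rate FBD kernel functions -----------------------------------
# p0(t): probability that a lineage alive at age t leaves no sampled
# descendants (neither rho-sampled extant nor psi-sampled fossils).
# q(t): propagator for a lineage with exactly one sampled-descendant
# lineage, normalized so q(0) = 1. Both follow the standard constant-rate
# sampled-tree calculus; they are verified against direct ODE integration
# in the test suite.
.fbd_c1c2 <- function(lambda, mu, psi, rho) {
  c1 <- sqrt((lambda - mu - psi)^2 + 4 * lambda * psi)
  if (c1 <= 0) stop("degenerate parameters: lambda = mu and psi = 0")
  c2 <- -(lambda - mu - 2 * lambda * rho - psi) / c1
  list(c1 = c1, c2 = c2)
}

.fbd_log_q <- function(t, lambda, mu, psi, rho) {
  cc <- .fbd_c1c2(lambda, mu, psi, rho)
  log(4) - cc$c1 * t -
    2 * log(exp(-cc$c1 * t) * (1 - cc$c2) + (1 + cc$c2))
}

.fbd_p0 <- function(t, lambda, mu, psi, rho) {
  cc <- .fbd_c1c2(lambda, mu, psi, rho)
  e <- exp(-cc$c1 * t)
  w <- (e * (1 - cc$c2) - (1 + cc$c2)) / (e * (1 - cc$c2) + (1 + cc$c2))
  (lambda + mu + psi + cc$c1 * w) / (2 * lambda)
}

# Vectorized core used by both the exported density and the MCMC sampler.
# int_ages: ages of all non-root internal nodes (divergences among sampled
# lineages and fossil attachment points); fossil_ages: ages of the fossil
# tips; n_extant: number of rho-sampled extant tips.
.fbd_log_density_core <- function(root_age, int_ages, fossil_ages, n_extant,
                                  lambda, mu, psi, rho) {
  m <- length(fossil_ages)
  if (length(int_ages) != n_extant + m - 2L) {
    stop("inconsistent node counts: need n_extant + m - 2 non-root internal ages")
  }
  if (any(int_ages <= 0) || any(int_ages >= root_age)) {
    return(-Inf)
  }
  if (m > 0 && psi <= 0) {
    return(-Inf)
  }
  lq1 <- .fbd_log_q(root_age, lambda, mu, psi, rho)
  p01 <- .fbd_p0(root_age, lambda, mu, psi, rho)
  ll <- 2 * lq1 - 2 * log1p(-p01) + n_extant * log(rho)
  if (length(int_ages)) {
    ll <- ll + sum(log(lambda) + .fbd_log_q(int_ages, lambda, mu, psi, rho))
  }
  if (m > 0) {
    ll <- ll + sum(
      log(psi) + log(.fbd_p0(fossil_ages, lambda, mu, psi, rho)) -
        .fbd_log_q(fossil_ages, lambda, mu, psi, rho)
    )
  }
  ll
}

#' Log density of a sampled tree under the fossilized birth-death model
#'
#' Probability density of a sampled tree with `rho`-sampled extant tips and
#' fossil tips (extinct tips whose ages are `psi`-sampling times), under the
#' constant-rate fossilized birth-death process, conditioned on the age of
#' the root divergence and on both root children having at least one sampled
#' descendant. Sampled-ancestor configurations (a fossil lying exactly on a
#' lineage with sampled descendants) are outside the support; fossils enter
#' only as tips attached below a free attachment point. The density depends
#' on node ages only, not on tip labels, reflecting the exchangeability of
#' the process.
#'
#' @param tree an `fbd_tree`; extinct tips (age > 0) are interpreted as
#'   fossil tips, their parent nodes as attachment points.
#' @param params an `fbd_params` object.
#' @return log density (finite for admissible configurations; `-Inf` when
#'   an age ordering is violated).
#' @export
fbd_log_density <- function(tree, params) {
  stopifnot(inherits(tree, "fbd_tree"), inherits(params, "fbd_params"))
  tip <- is_tip(tree)
  fossil_ages <- tree$age[tip & tree$age > 0]
  int_ages <- tree$age[!tip][-1L] # drop root; node 1 is always root
  .fbd_log_density_core(
    root_age(tree), int_ages, fossil_ages, sum(tip & tree$age == 0),
    params$lambda, params$mu, params$psi, params$rho
  )
}

# ---- rho-sampled birth-death density (CladeAge tree prior) ----------------
.bd_p0 <- function(t, lambda, mu, rho) {
  d <- lambda - mu
  1 - rho * d / (rho * lambda + (lambda * (1 - rho) - mu) * exp(-d * t))
}

.bd_log_p1 <- function(t, lambda, mu, rho) {
  d <- lambda - mu
  log(rho) + 2 * log(d) - d * t -
    2 * log(rho * lambda + (lambda * (1 - rho) - mu) * exp(-d * t))
}

.bd_log_density_core <- function(root_age, int_ages, lambda, mu, rho) {
  if (any(int_ages <= 0) || any(int_ages >= root_age)) {
    return(-Inf)
  }
  ll <- 2 * .bd_log_p1(root_age, lambda, mu, rho) -
    2 * log1p(-.bd_p0(root_age, lambda, mu, rho))
  if (length(int_ages)) {
    ll <- ll + sum(log(lambda) + .bd_log_p1(int_ages, lambda, mu, rho))
  }
  ll
}

#' Log density of an extant ultrametric tree under the birth-death process
#'
#' Reconstructed-tree density for a binary ultrametric tree whose tips were
#' sampled with probability `rho`, conditioned on the root age and on both
#' root children having at least one sampled descendant. This is the tree
#' prior used in CladeAge-style analyses; it coincides with
#' [fbd_log_density()] at `psi = 0` (the two use independent closed forms,
#' which the test suite exploits as a cross-check).
#'
#' @param tree an ultrametric extant-only `fbd_tree`.
#' @param lambda speciation rate (> `mu`).
#' @param mu extinction rate (>= 0).
#' @param rho sampling probability in (0, 1].
#' @return log density.
#' @export
bd_log_density <- function(tree, lambda, mu, rho = 1) {
  stopifnot(inherits(tree, "fbd_tree"))
  if (lambda <= mu) stop("supercritical process required (lambda > mu)")
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  tip <- is_tip(tree)
  if (any(tree$age[tip] != 0)) stop("tree must be extant-only (ultrametric)")
  .bd_log_density_core(
    root_age(tree), tree$age[!tip][-1L], lambda, mu, rho
  )
}
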