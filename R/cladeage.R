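#' Monte-Carlo calibration density of a clade age given its oldest fossil
#'
#' Estimates, by forward simulation, the density of the waiting time
#' `delta >= 0` between the origin of a clade (a single stem lineage) and
#' its first fossil, under time-homogeneous diversification (`d`, `r`) and
#' Poisson fossil sampling (`psi`), conditional on at least one fossil
#' occurring before `grid_max`. Inverted in time, this is the density of a
#' clade's origin age given the age of its oldest fossil, and is used as a
#' node-calibration prior on the stem age of fossil-constrained clades.
#'
#' Parameters may be given either exactly (a single number) or as an
#' uncertainty interval `c(lower, upper)`; interval-valued parameters are
#' integrated over by drawing fresh uniform values for every simulation.
#'
#' @param d net diversification rate, value or interval.
#' @param r turnover, value or interval (each in `[0, 1)`).
#' @param psi fossil-sampling rate, value or interval (> 0).
#' @param grid_max largest offset covered by the density grid (time units).
#' @param n_grid number of grid points.
#' @param n_sims number of Monte-Carlo simulations (>= 1e4).
#' @param max_lineages cap on simultaneous lineages per simulated clade.
#' @return An object of class `calibration_density`: list with `grid`
#'   (offsets), `density` (values integrating to 1 over the grid),
#'   `params`, `n_sims`, `n_kept` (simulations that produced a fossil).
#' @export
estimate_first_occurrence_density <- function(d, r, psi, grid_max = 250,
                                              n_grid = 1000L,
                                              n_sims = 100000L,
                                              max_lineages = 100000L) {
  check_iv <- function(x, name, lo_ok = 0) {
    if (!length(x) %in% 1:2 || any(!is.finite(x))) {
      stop(sprintf("%s must be a value or an interval", name))
    }
    if (length(x) == 2L && x[1] > x[2]) {
      stop(sprintf("degenerate interval for %s (lower > upper)", name))
    }
    x
  }
  d <- check_iv(d, "d")
  r <- check_iv(r, "r")
  psi <- check_iv(psi, "psi")
  if (any(r < 0 | r >= 1)) stop("r must be in [0, 1)")
  if (any(d < 0)) stop("d must be >= 0")
  if (any(psi <= 0)) stop("psi must be > 0")
  if (n_sims < 1e4) stop("n_sims must be at least 1e4")
  if (grid_max <= 0) stop("grid_max must be > 0")
  draw <- function(x) if (length(x) == 2L) stats::runif(n_sims, x[1], x[2]) else rep(x, n_sims)
  dv <- draw(d)
  rv <- draw(r)
  psiv <- draw(psi)
  lambdav <- dv / (1 - rv)
  muv <- dv * rv / (1 - rv)
  times <- .first_fossil_times_cpp(
    as.integer(n_sims), lambdav, muv, psiv,
    grid_max, as.integer(max_lineages)
  )
  times <- times[!is.na(times)]
  if (length(times) < 100L) {
    stop("fewer than 100 simulated clades produced a fossil; increase n_sims")
  }
  grid <- seq(0, grid_max, length.out = n_grid)
  # gaussian kernel estimate with reflection at the delta = 0 boundary
  # (support starts at 0); bandwidth follows Silverman's rule
  h <- max(diff(grid)[1], stats::bw.nrd0(times) / 2)
  dens <- stats::density(c(times, -times),
    bw = h, from = 0, to = grid_max,
    n = n_grid, cut = 0
  )
  dy <- 2 * dens$y
  # renormalize over the grid (mass beyond grid_max is conditioned away);
  # trapezoid rule avoids a half-bin bias at the boundaries
  dy <- dy / .trapz(grid, dy)
  structure(
    list(
      grid = grid, density = dy,
      params = list(d = d, r = r, psi = psi),
      n_sims = n_sims, n_kept = length(times), grid_max = grid_max
    ),
    class = "calibration_density"
  )
}

#' @export
print.calibration_density <- function(x, ...) {
  cat(sprintf(
    "calibration_density: %d grid points to %.4g, %d/%d simulations kept\n",
    length(x$grid), x$grid_max, x$n_kept, x$n_sims
  ))
  invisible(x)
}

#' Log calibration density of a clade age given its oldest fossil
#'
#' Evaluates the density at offset `delta = clade_age - fossil_age` with
#' linear interpolation on the grid; `-Inf` for `clade_age < fossil_age`
#' or offsets beyond the grid.
#'
#' @param cal a `calibration_density`.
#' @param clade_age age of the clade's origin (stem age), time units.
#' @param fossil_age age of the clade's oldest fossil.
#' @return log density (vectorized over `clade_age`/`fossil_age`).
#' @export
calibration_log_density <- function(cal, clade_age, fossil_age) {
  stopifnot(inherits(cal, "calibration_density"))
  delta <- clade_age - fossil_age
  out <- rep(-Inf, length(delta))
  ok <- delta >= 0 & delta <= cal$grid_max & fossil_age >= 0
  if (any(ok)) {
    y <- stats::approx(cal$grid, cal$density, xout = delta[ok], rule = 2)$y
    out[ok] <- ifelse(y > 0, log(y), -Inf)
  }
  out
}

#' Quadrature estimate of the first-occurrence density (oracle)
#'
#' Independent check of [estimate_first_occurrence_density()]: the
#' probability that a clade of age `t` carries no fossil, `w(t)`, obeys
#' `w' = -(lambda + mu + psi) w + mu + lambda w^2`, `w(0) = 1`; the
#' first-occurrence density conditional on a fossil before `grid_max` is
#' `-w'(delta) / (1 - w(grid_max))`. Solved here by fixed-step RK4
#' integration of the ODE (exact parameters only).
#'
#' @param d,r,psi exact parameter values.
#' @param grid_max,n_grid as in [estimate_first_occurrence_density()].
#' @return list with `grid` and `density`.
#' @export
first_occurrence_density_ode <- function(d, r, psi, grid_max = 250,
                                         n_grid = 1000L) {
  stopifnot(length(d) == 1L, length(r) == 1L, length(psi) == 1L)
  lambda <- d / (1 - r)
  mu <- d * r / (1 - r)
  grid <- seq(0, grid_max, length.out = n_grid)
  f <- function(w) -(lambda + mu + psi) * w + mu + lambda * w^2
  w <- numeric(n_grid)
  w[1] <- 1
  hstep <- grid[2] - grid[1]
  nsub <- 20L
  h <- hstep / nsub
  cur <- 1
  for (i in 2:n_grid) {
    for (j in seq_len(nsub)) {
      k1 <- f(cur)
      k2 <- f(cur + h / 2 * k1)
      k3 <- f(cur + h / 2 * k2)
      k4 <- f(cur + h * k3)
      cur <- cur + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    w[i] <- cur
  }
  dens <- -f(w) / (1 - w[n_grid])
  dens <- dens / .trapz(grid, dens)
  list(grid = grid, density = dens)
}

# trapezoid-rule integral of y over x
.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
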