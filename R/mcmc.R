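#' Prior specifications for diversification parameters
#'
#' `par_fixed(value)` pins a parameter; `par_uniform(lower, upper)` gives it
#' a uniform prior. The study design uses uniform intervals spanning 50% to
#' 150% of the true value, built by `par_uniform_about(truth)`.
#'
#' @param value,lower,upper,truth,frac numeric scalars.
#' @return a `par_spec` list.
#' @export
par_fixed <- function(value) {
  structure(list(type = "fixed", value = value), class = "par_spec")
}

#' @rdname par_fixed
#' @export
par_uniform <- function(lower, upper) {
  if (!(lower < upper)) stop("need lower < upper")
  structure(list(type = "uniform", lower = lower, upper = upper),
    class = "par_spec"
  )
}

#' @rdname par_fixed
#' @export
par_uniform_about <- function(truth, frac = 0.5) {
  par_uniform((1 - frac) * truth, (1 + frac) * truth)
}

#' @rdname par_fixed
#' @param d,r,s `par_spec` objects for net diversification, turnover and
#'   fossil-sampling proportion (the latter ignored by the CladeAge tree
#'   prior).
#' @export
prior_spec <- function(d, r, s = par_fixed(0)) {
  stopifnot(inherits(d, "par_spec"), inherits(r, "par_spec"), inherits(s, "par_spec"))
  structure(list(d = d, r = r, s = s), class = "prior_spec")
}

#' MCMC run settings
#'
#' @param n_iter total number of Metropolis-Hastings iterations.
#' @param thin store every `thin`-th state.
#' @param burnin fraction of stored states discarded by summaries.
#' @param ess_threshold a run is flagged stationary only when the effective
#'   sample sizes of all scalar model parameters exceed this value.
#' @param root_max upper bound of the uniform root-age prior (time units).
#' @param seed optional RNG seed applied at the start of the run.
#' @return a `mcmc_settings` list.
#' @export
mcmc_settings <- function(n_iter = 250000L, thin = 250L, burnin = 0.1,
                          ess_threshold = 200, root_max = 1000,
                          seed = NULL) {
  stopifnot(n_iter > 0, thin > 0, burnin >= 0, burnin < 1)
  structure(
    list(
      n_iter = as.integer(n_iter), thin = as.integer(thin),
      burnin = burnin, ess_threshold = ess_threshold,
      root_max = root_max, seed = seed
    ),
    class = "mcmc_settings"
  )
}

# collapse alignment columns to site patterns
.site_patterns <- function(aln) {
  key <- apply(aln, 2L, paste, collapse = "\r")
  tb <- table(key)
  first <- match(names(tb), key)
  list(
    patterns = aln[, first, drop = FALSE],
    weights = as.numeric(tb)
  )
}

#' Bayesian divergence-time estimation on a fixed extant topology
#'
#' Metropolis-Hastings sampler over internal node ages, fossil attachment
#' ages, diversification parameters and relaxed-clock rates, with the
#' extant-species topology fixed. Two tree priors are available:
#' \describe{
#'   \item{`method = "fbd"`}{the fossilized birth-death density
#'     ([fbd_log_density()]); each fossil is a dated tip attached to its
#'     assigned clade at a free attachment age, allowed on the stem or
#'     anywhere in the crown of the clade (the number of candidate
#'     lineages at the proposed age enters the target, marginalizing the
#'     lineage choice).}
#'   \item{`method = "cladeage"`}{a birth-death prior on the extant tree
#'     ([bd_log_density()]) combined with calibration densities on the stem
#'     ages of fossil-constrained clades ([calibration_log_density()]).}
#' }
#' Branch-rate variation uses an uncorrelated lognormal clock with
#' estimated mean rate and fixed coefficient of variation.
#'
#' @param tree sampled extant-only `fbd_tree` (node ages are used as the
#'   starting state and recorded as the true ages in summaries).
#' @param alignment `fbd_alignment` with rownames matching the tree's tip
#'   labels; required when `target = "posterior"`.
#' @param fossils `fossil_record` of fossils used for inference (FBD mode):
#'   `current_branch` gives the assigned clade, `age` the fossil age.
#' @param method `"fbd"` or `"cladeage"`.
#' @param priors a [prior_spec()] for (d, r, s); under `"cladeage"` d and r
#'   parameterize the tree-generating process only.
#' @param rho fixed extant-species sampling probability.
#' @param calibration a `calibration_density` (CladeAge mode).
#' @param constraints data frame from [cladeage_constraints()] (CladeAge
#'   mode).
#' @param clock a [clock_model()]; its coefficient of variation is fixed in
#'   the inference, its mean is estimated on a broad log-uniform prior.
#' @param kappa,freqs HKY likelihood parameters (`freqs = NULL` uses
#'   empirical frequencies).
#' @param target `"posterior"` (default), `"tree_prior"` (sequence
#'   likelihood off; used for simulation-based calibration of the tree
#'   density), or `"parameters_only"` (all data-dependent terms and the
#'   tree-process density off, leaving the bare parameter priors; used to
#'   validate that the move kernels preserve their target).
#' @param settings an [mcmc_settings()].
#' @param fix_root if `TRUE`, the root age is held at its starting value
#'   (no root or whole-tree scale moves); used when the target conditions
#'   on a known root age, e.g. in simulation-based calibration checks.
#' @return An object of class `fbd_dating` with elements `trace` (data
#'   frame of sampled states), `acceptance` (per-move rates), `true_ages`,
#'   `settings` and model metadata. See [summary.fbd_dating()],
#'   [node_ages()].
#' @export
fbd_dating <- function(tree, alignment = NULL, fossils = NULL,
                       method = c("fbd", "cladeage"),
                       priors, rho = 1,
                       calibration = NULL, constraints = NULL,
                       clock = clock_model(), kappa = 2, freqs = NULL,
                       target = c("posterior", "tree_prior", "parameters_only"),
                       settings = mcmc_settings(), fix_root = FALSE) {
  method <- match.arg(method)
  target <- match.arg(target)
  stopifnot(inherits(tree, "fbd_tree"), inherits(priors, "prior_spec"))
  if (!is.null(settings$seed)) set.seed(settings$seed)
  n <- n_nodes(tree)
  par <- tree$parent
  tip <- is_tip(tree)
  if (any(tree$age[tip] != 0)) stop("tree must be extant-only")
  int_idx <- which(!tip)
  nonroot_int <- setdiff(int_idx, 1L)
  k <- sum(tip)
  ch1 <- integer(n)
  ch2 <- integer(n)
  for (i in 2:n) {
    p <- par[i]
    if (ch1[p] == 0L) ch1[p] <- i else ch2[p] <- i
  }
  # chain of internal nodes from each internal node up to the root; the
  # partial likelihoods of exactly these nodes change when the node's age
  # (or a subtending branch) changes
  path_int <- vector("list", n)
  path_int[[1L]] <- 1L
  for (i in nonroot_int) path_int[[i]] <- c(i, path_int[[par[i]]])

  use_lik <- target == "posterior"
  use_tree <- target != "parameters_only"

  # ---- likelihood setup ----
  lik <- NULL
  if (use_lik) {
    if (is.null(alignment)) stop("alignment required for target = 'posterior'")
    labs <- node_labels(tree)
    tip_row <- integer(n)
    tip_row[tip] <- match(labs[tip], rownames(alignment))
    if (anyNA(tip_row[tip])) stop("alignment rownames do not match tree tips")
    sp <- .site_patterns(alignment)
    if (is.null(freqs)) {
      freqs <- tabulate(alignment, nbins = 4L) + 1
      freqs <- freqs / sum(freqs)
    }
    postorder <- rev(int_idx) # children always have larger index
    lik <- .lik_init_cpp(
      par, postorder, ch1, ch2, sp$patterns, tip_row,
      sp$weights, kappa, freqs
    )
  }

  # ---- fossil setup (fbd) ----
  m <- 0L
  f_y <- numeric(0)
  f_par <- integer(0)
  desc_all <- integer(0)
  desc_fidx <- integer(0)
  if (method == "fbd" && !is.null(fossils) && nrow(fossils)) {
    m <- nrow(fossils)
    f_y <- fossils$age
    f_c <- fossils$current_branch
    if (any(f_c == 1L)) stop("fossils assigned to the root clade are not supported")
    f_par <- par[f_c]
    # internal nodes of each fossil's assigned clade (including its root),
    # flattened for fast lineage counting at proposed attachment ages
    desc_int <- vector("list", m)
    for (j in seq_len(m)) {
      sub <- f_c[j]
      stack <- f_c[j]
      while (length(stack)) {
        v <- stack[[1L]]
        stack <- stack[-1L]
        if (!tip[v]) {
          ch <- c(ch1[v], ch2[v])
          stack <- c(stack, ch)
          sub <- c(sub, ch)
        }
      }
      desc_int[[j]] <- sub[!tip[sub]]
    }
    desc_all <- unlist(desc_int)
    desc_fidx <- rep.int(seq_len(m), lengths(desc_int))
  }

  # ---- cladeage setup ----
  ca_par <- integer(0)
  ca_y <- numeric(0)
  cal_dens <- numeric(2)
  cal_max <- 1
  if (method == "cladeage") {
    if (use_tree && (is.null(calibration) || is.null(constraints))) {
      stop("cladeage method needs a calibration density and constraints")
    }
    if (!is.null(constraints) && nrow(constraints)) {
      ca_par <- par[constraints$node]
      ca_y <- constraints$fossil_age
    }
    if (!is.null(calibration)) {
      cal_dens <- calibration$density
      cal_max <- calibration$grid_max
    }
  }

  # ---- parameter bookkeeping ----
  pdef <- list(d = priors$d, r = priors$r, s = priors$s)
  th <- vapply(pdef, function(p) {
    if (p$type == "fixed") p$value else (p$lower + p$upper) / 2
  }, numeric(1))
  est <- names(pdef)[vapply(pdef, function(p) p$type == "uniform", logical(1))]
  lv_bounds <- log(clock$mean_rate) + c(-log(100), log(100))
  sdlog <- clock$sdlog

  state <- list(
    age = tree$age,
    att = numeric(m),
    th = th,
    logv = log(clock$mean_rate),
    logm = numeric(n) # log rate multipliers per branch (node), root unused
  )
  if (m) {
    init_att <- fossils$divergence_age
    lo <- f_y
    hi <- state$age[f_par]
    bad <- is.na(init_att) | init_att <= lo | init_att >= hi
    init_att[bad] <- lo[bad] + 0.5 * (hi[bad] - lo[bad])
    state$att <- init_att
  }

  # ---- target components ----
  # constant-support parameter prior (uniform densities + bounds checks);
  # the lognormal branch-rate prior is tracked incrementally
  param_logprior <- function(st) {
    lp <- 0
    for (nm in est) {
      p <- pdef[[nm]]
      if (st$th[[nm]] < p$lower || st$th[[nm]] > p$upper) return(-Inf)
      lp <- lp - log(p$upper - p$lower)
    }
    if (st$logv < lv_bounds[1] || st$logv > lv_bounds[2]) return(-Inf)
    if (st$age[1L] > settings$root_max) return(-Inf)
    if (!use_tree &&
      (any(st$age[nonroot_int] >= st$age[par[nonroot_int]]) ||
        any(st$age[nonroot_int] <= 0))) {
      return(-Inf)
    }
    lp
  }

  logm_prior <- function(lm) {
    if (sdlog == 0) return(0)
    sum(stats::dnorm(lm[-1L], -sdlog^2 / 2, sdlog, log = TRUE))
  }

  logm_delta <- function(new, old, idx) {
    sum(stats::dnorm(new[idx], -sdlog^2 / 2, sdlog, log = TRUE)) -
      sum(stats::dnorm(old[idx], -sdlog^2 / 2, sdlog, log = TRUE))
  }

  tree_logprior <- function(st) {
    if (!use_tree) {
      return(0)
    }
    if (method == "fbd") {
      .fbd_prior_cpp(
        st$age, par, nonroot_int, k, st$att, f_y, f_par,
        desc_all, desc_fidx,
        st$th[["d"]], st$th[["r"]], st$th[["s"]], rho
      )
    } else {
      .bd_cladeage_prior_cpp(
        st$age, par, nonroot_int, st$th[["d"]], st$th[["r"]], rho,
        ca_par, ca_y, cal_dens, cal_max
      )
    }
  }

  edge_lens <- function(st) {
    c(0, (st$age[par[2:n]] - st$age[2:n]) * exp(st$logv + st$logm[2:n]))
  }

  cur_lp <- param_logprior(state)
  cur_lpm <- logm_prior(state$logm)
  cur_tp <- tree_logprior(state)
  cur_ll <- if (use_lik) .lik_set_cpp(lik, edge_lens(state)) else 0
  if (!is.finite(cur_lp + cur_lpm + cur_tp + cur_ll)) {
    stop(sprintf(
      "non-finite initial posterior (param prior %.3g, tree prior %.3g, likelihood %.3g)",
      cur_lp + cur_lpm, cur_tp, cur_ll
    ))
  }

  # ---- move schedule ----
  moves <- c(
    age = length(nonroot_int),
    age_const = if (use_lik && sdlog > 0) length(nonroot_int) else 0,
    root = if (fix_root) 0 else 2,
    root_const = if (fix_root || !use_lik || sdlog == 0) 0 else 2,
    treescale = if (fix_root) 0 else 3,
    attach = if (m) max(2, m / 2) else 0,
    theta = 3 * length(est),
    clockmean = if (use_lik || target == "parameters_only") 3 else 0,
    branchrate = if (use_lik || target == "parameters_only") (n - 1) / 2 else 0,
    rateshift = if (use_lik && sdlog > 0) 3 else 0
  )
  moves <- moves[moves > 0]
  mnames <- names(moves)
  mcum <- cumsum(moves / sum(moves))
  n_try <- stats::setNames(numeric(length(moves)), mnames)
  n_acc <- n_try

  reflect <- function(x, lo, hi) {
    width <- hi - lo
    x <- (x - lo) %% (2 * width)
    lo + if (x > width) 2 * width - x else x
  }

  # the clock-mean window is tuned for data-informed runs; prior-only runs
  # need steps wide enough to traverse the whole log-uniform support
  w_lv <- if (use_lik) 0.1 else 2.0

  n_keep <- settings$n_iter %/% settings$thin
  trace <- matrix(NA_real_, n_keep,
    ncol = 6 + length(int_idx) + m,
    dimnames = list(NULL, c(
      "iter", "logpost", "loglik", c("d", "r", "s"),
      paste0("age_", int_idx),
      if (m) paste0("att_", seq_len(m))
    ))
  )
  trace_clock <- numeric(n_keep)
  row <- 0L
  runif <- stats::runif
  n_nonroot <- length(nonroot_int)
  all_int_postorder <- rev(int_idx)

  for (it in seq_len(settings$n_iter)) {
    u_mv <- runif(1L)
    mv <- mnames[sum(u_mv > mcum) + 1L]
    n_try[mv] <- n_try[mv] + 1
    prop <- state
    log_hastings <- 0
    lik_nodes <- NULL # internal nodes whose partials must be recomputed
    tree_affected <- TRUE
    valid <- TRUE
    p_lpm <- cur_lpm
    if (mv == "age") {
      i <- nonroot_int[sample.int(n_nonroot, 1L)]
      lo <- max(state$age[ch1[i]], state$age[ch2[i]])
      hi <- state$age[par[i]]
      prop$age[i] <- runif(1L, lo, hi) # bounds unchanged by move: MH ratio 1
      lik_nodes <- path_int[[i]]
    } else if (mv == "age_const") {
      # slide a node age while rescaling the rates of the three adjacent
      # branches so substitution lengths (hence the likelihood) are
      # unchanged; volume-preserving in (age, log rates), MH ratio 1
      i <- nonroot_int[sample.int(n_nonroot, 1L)]
      c1i <- ch1[i]
      c2i <- ch2[i]
      lo <- max(state$age[c1i], state$age[c2i])
      hi <- state$age[par[i]]
      u <- runif(1L, lo, hi)
      prop$age[i] <- u
      prop$logm[i] <- state$logm[i] + log((hi - state$age[i]) / (hi - u))
      prop$logm[c1i] <- state$logm[c1i] +
        log((state$age[i] - state$age[c1i]) / (u - state$age[c1i]))
      prop$logm[c2i] <- state$logm[c2i] +
        log((state$age[i] - state$age[c2i]) / (u - state$age[c2i]))
      p_lpm <- cur_lpm + logm_delta(prop$logm, state$logm, c(i, c1i, c2i))
    } else if (mv == "root") {
      # symmetric random walk; out-of-support values rejected via the prior
      prop$age[1L] <- state$age[1L] + runif(1L, -5, 5)
      lik_nodes <- 1L
    } else if (mv == "root_const") {
      c1i <- ch1[1L]
      c2i <- ch2[1L]
      u <- state$age[1L] + runif(1L, -8, 8)
      if (u <= max(state$age[c1i], state$age[c2i]) || u > settings$root_max) {
        valid <- FALSE
      } else {
        prop$age[1L] <- u
        prop$logm[c1i] <- state$logm[c1i] +
          log((state$age[1L] - state$age[c1i]) / (u - state$age[c1i]))
        prop$logm[c2i] <- state$logm[c2i] +
          log((state$age[1L] - state$age[c2i]) / (u - state$age[c2i]))
        p_lpm <- cur_lpm + logm_delta(prop$logm, state$logm, c(c1i, c2i))
      }
    } else if (mv == "treescale") {
      # scales all ages and divides the clock mean by the same factor, so
      # substitution lengths are unchanged and the likelihood need not be
      # re-evaluated
      cs <- exp(runif(1L, -0.04, 0.04))
      prop$age[int_idx] <- state$age[int_idx] * cs
      if (m) prop$att <- state$att * cs
      prop$logv <- state$logv - log(cs)
      log_hastings <- (length(int_idx) + m) * log(cs)
    } else if (mv == "attach") {
      j <- sample.int(m, 1L)
      prop$att[j] <- runif(1L, f_y[j], state$age[f_par[j]])
    } else if (mv == "theta") {
      nm <- est[sample.int(length(est), 1L)]
      p <- pdef[[nm]]
      # without data the target over the parameter is its uniform prior, so
      # a full-width reflected window mixes in one step
      w <- (if (use_lik) 0.2 else 1) * (p$upper - p$lower)
      prop$th[[nm]] <- reflect(
        state$th[[nm]] + runif(1L, -w, w),
        p$lower, p$upper
      )
    } else if (mv == "clockmean") {
      prop$logv <- state$logv + runif(1L, -w_lv, w_lv)
      tree_affected <- FALSE
      lik_nodes <- all_int_postorder
    } else if (mv == "rateshift") {
      # move mass between the clock mean and the branch-rate multipliers
      # without changing any substitution length (likelihood-invariant)
      delta <- runif(1L, -0.2, 0.2)
      prop$logv <- state$logv + delta
      prop$logm[2:n] <- state$logm[2:n] - delta
      p_lpm <- logm_prior(prop$logm)
      tree_affected <- FALSE
    } else { # branchrate
      i <- 1L + sample.int(n - 1L, 1L)
      delta <- runif(1L, -0.6, 0.6)
      prop$logm[i] <- state$logm[i] + delta
      if (sdlog > 0) {
        p_lpm <- cur_lpm +
          stats::dnorm(prop$logm[i], -sdlog^2 / 2, sdlog, log = TRUE) -
          stats::dnorm(state$logm[i], -sdlog^2 / 2, sdlog, log = TRUE)
      }
      tree_affected <- FALSE
      lik_nodes <- path_int[[par[i]]]
    }
    p_lp <- if (valid) param_logprior(prop) else -Inf
    ok <- is.finite(p_lp)
    p_tp <- cur_tp
    if (ok && tree_affected) {
      p_tp <- tree_logprior(prop)
      ok <- is.finite(p_tp)
    }
    p_ll <- cur_ll
    lik_pending <- FALSE
    if (ok && use_lik && !is.null(lik_nodes)) {
      p_ll <- .lik_propose_cpp(lik, lik_nodes, edge_lens(prop))
      lik_pending <- TRUE
      ok <- is.finite(p_ll)
    }
    if (ok) {
      lacc <- (p_lp + p_lpm + p_tp + p_ll) -
        (cur_lp + cur_lpm + cur_tp + cur_ll) + log_hastings
      if (log(runif(1L)) < lacc) {
        state <- prop
        cur_lp <- p_lp
        cur_lpm <- p_lpm
        cur_tp <- p_tp
        cur_ll <- p_ll
        n_acc[mv] <- n_acc[mv] + 1
        if (lik_pending) {
          .lik_accept_cpp(lik)
          lik_pending <- FALSE
        }
      }
    }
    if (lik_pending) .lik_reject_cpp(lik)
    if (it %% settings$thin == 0L) {
      row <- row + 1L
      trace[row, ] <- c(
        it, cur_lp + cur_lpm + cur_tp + cur_ll, cur_ll,
        state$th[["d"]], state$th[["r"]], state$th[["s"]],
        state$age[int_idx], state$att
      )
      trace_clock[row] <- exp(state$logv)
    }
  }

  tr <- as.data.frame(trace[seq_len(row), , drop = FALSE])
  tr$clock_rate <- trace_clock[seq_len(row)]
  structure(
    list(
      trace = tr,
      acceptance = ifelse(n_try > 0, n_acc / n_try, NA_real_),
      true_ages = stats::setNames(tree$age[int_idx], paste0("age_", int_idx)),
      int_nodes = int_idx,
      estimated = est,
      method = method, target = target,
      priors = priors, rho = rho, clock = clock,
      settings = settings, n_fossils = m
    ),
    class = "fbd_dating"
  )
}


#' Run the divergence-time MCMC engine
#'
#' Alias of [fbd_dating()] under the generic engine name.
#'
#' @inheritParams fbd_dating
#' @param ... passed to [fbd_dating()].
#' @return see [fbd_dating()].
#' @export
run_mcmc <- function(tree, ..., settings = mcmc_settings()) {
  fbd_dating(tree, ..., settings = settings)
}

.post_burnin <- function(fit) {
  tr <- fit$trace
  drop <- floor(fit$settings$burnin * nrow(tr))
  if (drop > 0) tr <- tr[-seq_len(drop), , drop = FALSE]
  tr
}

#' @export
print.fbd_dating <- function(x, ...) {
  cat(sprintf(
    "fbd_dating fit (%s, target %s): %d iterations, %d stored states\n",
    x$method, x$target, x$settings$n_iter, nrow(x$trace)
  ))
  cat(
    "acceptance:",
    paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance), collapse = ", "),
    "\n"
  )
  if (length(x$estimated)) {
    cat("estimated parameters:", paste(x$estimated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Posterior summaries of an `fbd_dating` fit
#'
#' @param object an `fbd_dating` object.
#' @param credibility HPD mass.
#' @param ... unused.
#' @return data frame with posterior mean, median, HPD bounds and effective
#'   sample size per scalar parameter and node age; attribute `stationary`
#'   flags whether all scalar-parameter ESS values exceed the threshold.
#' @export
summary.fbd_dating <- function(object, credibility = 0.95, ...) {
  tr <- .post_burnin(object)
  scalars <- c(object$estimated, "clock_rate", "age_1")
  cols <- c(
    intersect(c("d", "r", "s"), object$estimated), "clock_rate",
    grep("^age_", names(tr), value = TRUE)
  )
  out <- do.call(rbind, lapply(cols, function(cn) {
    x <- tr[[cn]]
    h <- hpd_interval(x, credibility)
    data.frame(
      parameter = cn, mean = mean(x), median = stats::median(x),
      hpd_lower = h[1], hpd_upper = h[2],
      ess = if (length(x) >= 100L && stats::var(x) > 0) {
        effective_sample_size(x)
      } else {
        NA_real_ # too few stored states (or a fixed quantity) to estimate
      }
    )
  }))
  gate_cols <- intersect(c(object$estimated, "clock_rate", "age_1"), out$parameter)
  gate_ess <- out$ess[out$parameter %in% gate_cols]
  attr(out, "stationary") <-
    !anyNA(gate_ess) && all(gate_ess > object$settings$ess_threshold)
  out
}

#' @export
coef.fbd_dating <- function(object, ...) {
  tr <- .post_burnin(object)
  c(
    vapply(object$estimated, function(nm) mean(tr[[nm]]), numeric(1)),
    clock_rate = mean(tr$clock_rate), root_age = mean(tr$age_1)
  )
}

#' @export
plot.fbd_dating <- function(x, ...) {
  tr <- x$trace
  cols <- c("logpost", intersect(c("d", "r", "s"), x$estimated), "age_1")
  op <- graphics::par(mfrow = c(length(cols), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (cn in cols) {
    graphics::plot(tr$iter, tr[[cn]],
      type = "l", xlab = "", ylab = cn, ...
    )
  }
  invisible(x)
}

#' Per-node age estimates against the truth
#'
#' @param fit an `fbd_dating` object.
#' @param credibility HPD mass.
#' @return data frame with one row per internal node: `node`, `true`,
#'   `mean`, `lower`, `upper`, `contained`.
#' @export
node_ages <- function(fit, credibility = 0.95) {
  tr <- .post_burnin(fit)
  cols <- grep("^age_", names(tr), value = TRUE)
  out <- do.call(rbind, lapply(cols, function(cn) {
    x <- tr[[cn]]
    h <- hpd_interval(x, credibility)
    data.frame(
      node = as.integer(sub("age_", "", cn)),
      true = unname(fit$true_ages[cn]),
      mean = mean(x), lower = h[1], upper = h[2]
    )
  }))
  out$contained <- out$true >= out$lower & out$true <= out$upper
  out
}

#' Shortest interval containing a given posterior mass
#'
#' @param samples numeric vector (>= 10 values).
#' @param credibility fraction of mass in (0, 1).
#' @return numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, credibility = 0.95) {
  if (!length(samples)) stop("empty sample series")
  if (length(samples) < 10L) stop("need at least 10 samples")
  if (credibility <= 0 || credibility >= 1) stop("credibility must be in (0,1)")
  x <- sort(samples)
  n <- length(x)
  nin <- max(1L, ceiling(credibility * n))
  if (nin >= n) {
    return(c(x[1L], x[n]))
  }
  starts <- seq_len(n - nin + 1L)
  widths <- x[starts + nin - 1L] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + nin - 1L])
}

#' Effective sample size of an MCMC trace
#'
#' Autocorrelation-time based estimate: the spectral density of the series
#' at frequency zero is estimated from an AIC-selected autoregressive fit,
#' and `ESS = n * var(x) / spec0`, capped at `n`. A constant series has an
#' ESS of 0 (with a warning).
#'
#' @param samples numeric vector (>= 100 values).
#' @return effective sample size (numeric scalar, `<= length(samples)`).
#' @export
effective_sample_size <- function(samples) {
  n <- length(samples)
  if (n < 100L) stop("need at least 100 samples")
  v <- stats::var(samples)
  if (v == 0) {
    warning("constant series: ESS is 0")
    return(0)
  }
  fit <- try(stats::ar(samples, aic = TRUE), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(n)
  }
  spec0 <- fit$var.pred / (1 - sum(fit$ar))^2
  min(n, n * v / spec0)
}
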