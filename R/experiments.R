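#' Configuration of a replicated simulation-inference experiment
#'
#' Bundles the generating process, the taxon-sampling scheme, the inference
#' setting and the problem-size knobs of one experimental cell. Settings
#' follow the study design:
#' \tabular{llll}{
#'   setting \tab tree prior \tab diversification/sampling parameters \tab fossils \cr
#'   set1 \tab FBD \tab all fixed to truth \tab oldest per branch \cr
#'   set2 \tab FBD \tab d, r, s estimated (uniform, 50-150% of truth) \tab oldest \cr
#'   set3 \tab FBD \tab d, r estimated; s fixed \tab oldest \cr
#'   set4 \tab FBD \tab d, r, s estimated \tab all fossils \cr
#'   set5 \tab CladeAge \tab calibration parameters exact \tab oldest (with reuse) \cr
#'   set6 \tab CladeAge \tab calibration parameters as 50-150% intervals \tab oldest (with reuse)
#' }
#' `set4` is only defined for diversified sampling. The CladeAge tree prior
#' estimates the tree-process net diversification and turnover under broad
#' uniform priors (`[1e-6, 1000]` and `[0, 1)`).
#'
#' The default scale (`"reduced"`) runs the full pipeline at desk scale:
#' 10 trees with 200-400 extant species, 20 sampled species, 1,000-bp
#' alignments and 250,000 MCMC iterations. `scale = "paper"` switches to
#' the study scale (20 trees, 4,000-5,000 species, 50 species, 3,000 bp,
#' 2,000,000 iterations); any field can be overridden explicitly.
#'
#' @param setting one of `"set1"`..`"set6"`.
#' @param sampling `"diversified"` or `"random"` taxon sampling.
#' @param scale `"reduced"` or `"paper"` preset.
#' @param n_trees,n_min,n_max,k,seq_length,n_iter,thin,burnin problem-size
#'   overrides.
#' @param lambda,mu,psi,root_age generating process (study values).
#' @param clock generating clock model.
#' @param kappa HKY transition/transversion ratio for simulation and
#'   inference.
#' @param cal_n_sims,cal_grid_max Monte-Carlo settings of the CladeAge
#'   calibration density.
#' @param seed master seed of the experiment.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(setting = c("set1", "set2", "set3", "set4", "set5", "set6"),
                              sampling = c("diversified", "random"),
                              scale = c("reduced", "paper"),
                              n_trees = NULL, n_min = NULL, n_max = NULL,
                              k = NULL, seq_length = NULL, n_iter = NULL,
                              thin = NULL, burnin = 0.1,
                              lambda = 0.12, mu = 0.06, psi = 0.01,
                              root_age = 100, clock = clock_model(),
                              kappa = 2, cal_n_sims = 100000L,
                              cal_grid_max = 250, seed = 1L) {
  setting <- match.arg(setting)
  sampling <- match.arg(sampling)
  scale <- match.arg(scale)
  if (setting == "set4" && sampling != "diversified") {
    stop("set4 (all fossils) is only defined for diversified sampling")
  }
  preset <- if (scale == "paper") {
    list(
      n_trees = 20L, n_min = 4000L, n_max = 5000L, k = 50L,
      seq_length = 3000L, n_iter = 2000000L, thin = 1000L
    )
  } else {
    list(
      n_trees = 10L, n_min = 200L, n_max = 400L, k = 20L,
      seq_length = 1000L, n_iter = 250000L, thin = 250L
    )
  }
  cfg <- list(
    setting = setting,
    method = if (setting %in% c("set5", "set6")) "cladeage" else "fbd",
    fossil_mode = if (setting == "set4") "all" else "oldest",
    sampling = sampling, scale = scale,
    n_trees = n_trees %||% preset$n_trees,
    n_min = n_min %||% preset$n_min,
    n_max = n_max %||% preset$n_max,
    k = k %||% preset$k,
    seq_length = seq_length %||% preset$seq_length,
    n_iter = n_iter %||% preset$n_iter,
    thin = thin %||% preset$thin,
    burnin = burnin,
    lambda = lambda, mu = mu, psi = psi, root_age = root_age,
    clock = clock, kappa = kappa,
    cal_n_sims = cal_n_sims, cal_grid_max = cal_grid_max,
    seed = as.integer(seed)
  )
  structure(cfg, class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# prior specification of one inference setting, given the true parameters
.setting_priors <- function(setting, truth) {
  switch(setting,
    set1 = prior_spec(
      par_fixed(truth$d), par_fixed(truth$r), par_fixed(truth$s)
    ),
    set2 = ,
    set4 = prior_spec(
      par_uniform_about(truth$d), par_uniform_about(truth$r),
      par_uniform_about(truth$s)
    ),
    set3 = prior_spec(
      par_uniform_about(truth$d), par_uniform_about(truth$r),
      par_fixed(truth$s)
    ),
    set5 = ,
    set6 = prior_spec(par_uniform(1e-6, 1000), par_uniform(0, 1 - 1e-9))
  )
}

#' Run one experimental cell end to end
#'
#' Executes the full pipeline for every replicate: birth-death simulation
#' conditioned on the richness window, Poisson fossilization, pruning with
#' fossil transfer, taxon sampling, fossil reduction, relaxed-clock
#' sequence simulation, Bayesian inference under the configured tree prior,
#' and pooled accuracy/RMSD reporting. All randomness derives from the
#' config's master seed via recorded per-replicate seeds, so identical
#' configurations reproduce identical reports.
#'
#' @param config an [experiment_config()].
#' @param keep_fits keep the full `fbd_dating` objects (memory-heavy).
#' @return An `experiment_report`: list with `nodes` (pooled per-node true
#'   ages, posterior means and HPD bounds across replicates), `accuracy`
#'   (pooled coverage), `rmsd` (pooled root-mean-square deviation),
#'   `params` (pooled post-burnin posterior samples of estimated
#'   parameters), `stationary` (per-replicate all-ESS gate), `seeds`, and
#'   the config.
#' @export
run_experiment <- function(config, keep_fits = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_trees + 1L)
  truth <- rates_to_drs(config$lambda, config$mu, config$psi)
  priors <- .setting_priors(config$setting, truth)
  calibration <- NULL
  if (config$method == "cladeage") {
    set.seed(seeds[config$n_trees + 1L])
    cal_args <- if (config$setting == "set6") {
      list(
        d = c(0.5, 1.5) * truth$d, r = c(0.5, 1.5) * truth$r,
        psi = c(0.5, 1.5) * config$psi
      )
    } else {
      list(d = truth$d, r = truth$r, psi = config$psi)
    }
    calibration <- estimate_first_occurrence_density(
      cal_args$d, cal_args$r, cal_args$psi,
      grid_max = config$cal_grid_max, n_sims = config$cal_n_sims
    )
  }
  nodes <- list()
  params <- list()
  stationary <- logical(config$n_trees)
  fits <- if (keep_fits) vector("list", config$n_trees) else NULL
  for (i in seq_len(config$n_trees)) {
    set.seed(seeds[i])
    tree <- simulate_bd_tree(
      config$lambda, config$mu,
      root_age = config$root_age,
      n_min = config$n_min, n_max = config$n_max
    )
    fossils <- overlay_fossils(tree, config$psi)
    rec <- reconstruct_extant(tree, fossils)
    samp <- if (config$sampling == "diversified") {
      diversified_sample(rec$tree, config$k, rec$fossils)
    } else {
      random_sample(rec$tree, config$k, rec$fossils)
    }
    rho <- config$k / n_extant(tree)
    rates <- draw_branch_rates(samp$tree, config$clock)
    aln <- simulate_alignment(
      samp$tree, rates, config$seq_length,
      kappa = config$kappa
    )
    fa <- select_fossils(samp$fossils, config$fossil_mode)
    settings <- mcmc_settings(
      n_iter = config$n_iter, thin = config$thin, burnin = config$burnin
    )
    fit <- if (config$method == "fbd") {
      fbd_dating(samp$tree, aln, fa,
        method = "fbd", priors = priors,
        rho = rho, clock = config$clock, kappa = config$kappa,
        settings = settings
      )
    } else {
      cons <- cladeage_constraints(samp$tree, fa)
      fbd_dating(samp$tree, aln,
        method = "cladeage", priors = priors,
        rho = rho, calibration = calibration, constraints = cons,
        clock = config$clock, kappa = config$kappa, settings = settings
      )
    }
    na <- node_ages(fit)
    na$tree <- i
    nodes[[i]] <- na
    tr <- .post_burnin(fit)
    params[[i]] <- tr[, c("d", "r", "s"), drop = FALSE]
    stationary[i] <- isTRUE(attr(summary(fit), "stationary"))
    if (keep_fits) fits[[i]] <- fit
  }
  nodes <- do.call(rbind, nodes)
  params <- do.call(rbind, params)
  report <- list(
    config = config,
    nodes = nodes,
    accuracy = coverage_accuracy(nodes),
    rmsd = rmsd(nodes$true, nodes$mean),
    params = params,
    estimated = setdiff(
      c("d", "r", "s")[vapply(priors, function(p) p$type == "uniform", logical(1))],
      character(0)
    ),
    priors = priors,
    truth = truth,
    stationary = stationary,
    seeds = seeds,
    fits = fits
  )
  class(report) <- "experiment_report"
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf(
    "experiment_report: %s / %s sampling (%s scale)\n",
    x$config$setting, x$config$sampling, x$config$scale
  ))
  cat(sprintf(
    "  %d replicates, pooled accuracy %.1f%%, RMSD %.2f time units\n",
    x$config$n_trees, 100 * x$accuracy, x$rmsd
  ))
  if (length(x$estimated)) {
    for (nm in x$estimated) {
      cat(sprintf(
        "  %s: posterior mean %.4g (truth %.4g)\n",
        nm, mean(x$params[[nm]]), x$truth[[nm]]
      ))
    }
  }
  cat(sprintf(
    "  stationarity gate passed in %d/%d replicates\n",
    sum(x$stationary), length(x$stationary)
  ))
  invisible(x)
}

#' Implied canonical rates from a posterior trace
#'
#' Applies the compound-to-canonical transformation sample by sample and
#' summarizes the implied speciation, extinction and fossil-sampling rates.
#' Useful for reading the indirect consequences of estimates of net
#' diversification, turnover and fossil-sampling proportion: e.g. with
#' `d = 0.03` and `r = 0.25`, the implied rates are `mu = 0.01` and
#' `lambda = 0.04`, and fixing `s = 0.143` then implies `psi = 0.00167`.
#'
#' @param trace a data frame with columns `d`, `r`, `s` (e.g. the `trace`
#'   of an [fbd_dating()] fit or the pooled `params` of a report).
#' @return data frame with mean, median and central 95% interval of the
#'   implied `lambda`, `mu`, `psi`.
#' @export
implied_rates_report <- function(trace) {
  stopifnot(all(c("d", "r", "s") %in% names(trace)))
  rates <- convert_parameterization(trace$d, trace$r, trace$s)
  do.call(rbind, lapply(names(rates), function(nm) {
    x <- rates[[nm]]
    data.frame(
      rate = nm, mean = mean(x), median = stats::median(x),
      q2.5 = unname(stats::quantile(x, 0.025)),
      q97.5 = unname(stats::quantile(x, 0.975))
    )
  }))
}
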