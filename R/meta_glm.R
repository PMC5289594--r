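# Bayesian binomial-logit network meta-analysis (fixed and random effects).

#' MCMC configuration for the Bayesian network models
#'
#' Defaults follow the study schedule: 2 chains, 5,000 burn-in iterations and
#' 10,000 retained draws in total. Convergence is assumed for a fixed
#' schedule; no diagnostics gate the result. Priors are fixed by the model:
#' Beta(0.5, 0.5) on each trial's baseline transition probability, N(0, 1e8)
#' on treatment effects, sigma ~ U(0.001, 10) for the random-effects
#' between-trial standard deviation (common across contrasts).
#'
#' @param n_chains number of chains.
#' @param n_burn burn-in iterations per chain.
#' @param n_keep total retained draws across chains (>= 1,000).
#' @param thin thinning interval.
#' @param seed integer seed.
#' @return object of class `glm_config`.
#' @export
glm_config <- function(n_chains = 2, n_burn = 5000, n_keep = 10000,
                       thin = 1, seed = 1L) {
  stopifnot(n_chains >= 1, n_burn >= 0, thin >= 1)
  if (n_keep < 1000) stop("retained draws must be >= 1,000")
  structure(list(n_chains = n_chains, n_burn = n_burn, n_keep = n_keep,
                 thin = thin, seed = seed),
            class = "glm_config")
}

# Run the sampler on arm-level data for one parameter; returns pooled draws
# across chains.
run_nma_sampler <- function(dat, random_effects, config) {
  treatments <- intersect(INTERVENTIONS, unique(dat$treatment))
  trial_ids <- sort(unique(dat$trial))
  S <- length(trial_ids)
  K <- length(treatments)
  trial_idx <- match(dat$trial, trial_ids) - 1L
  treat_idx <- match(dat$treatment, treatments) - 1L
  # baseline arm of each trial = the arm with the lower treatment index
  base_flag <- integer(nrow(dat))
  for (s in seq_len(S)) {
    rows <- which(trial_idx == s - 1L)
    base_flag[rows[which.min(treat_idx[rows])]] <- 1L
  }
  keep_per_chain <- ceiling(config$n_keep / config$n_chains)
  draws <- lapply(seq_len(config$n_chains), function(ch) {
    with_seed(derive_seed(config$seed, "chain", ch), {
      .nma_mcmc_cpp(trial_idx, treat_idx, base_flag, dat$r, dat$n,
                    S, K, random_effects, config$n_burn, keep_per_chain,
                    config$thin)
    })
  })
  d <- do.call(rbind, lapply(draws, `[[`, "d"))
  colnames(d) <- treatments[-1]
  list(treatments = treatments,
       d = d,
       mu = do.call(rbind, lapply(draws, `[[`, "mu")),
       sigma = unlist(lapply(draws, `[[`, "sigma")))
}

#' Bayesian GLM network meta-analysis
#'
#' Fits the binomial-logit network model by Markov chain Monte Carlo for one
#' effect-bearing parameter and returns the pooled contrast on the ln(RR)
#' scale: log odds-ratio draws are converted draw by draw via [or_to_rr()]
#' using the DerSimonian-Laird-pooled comparator risk, the point estimate is
#' the posterior mean and the interval the 2.5/97.5 posterior percentiles.
#' The random-effects specification places a common between-trial variance
#' on the trial-level effects and reports the posterior *predictive* effect
#' `N(d, sigma^2)` — the effect operating in a new (model) population — so
#' between-trial heterogeneity propagates into the downstream
#' cost-effectiveness model.
#'
#' @inheritParams pool_direct
#' @param config a [glm_config()].
#' @param random_effects logical; `FALSE` fits the fixed-effect model.
#' @return an `effect_estimate`; for the random-effects model `sigma2` holds
#'   the posterior median of the between-trial variance, and attribute
#'   `sigma_draws` the posterior draws of sigma.
#' @export
glm_fit <- function(network, contrast, parameter, config = glm_config(),
                    random_effects = FALSE) {
  stopifnot(inherits(config, "glm_config"))
  method <- if (random_effects) "GLMRE" else "GLMFE"
  dat <- network_param_data(network, parameter)
  if (!network_connects(dat, contrast)) {
    return(not_estimable(method, contrast))
  }
  fit <- run_nma_sampler(dat, random_effects, config)
  dcol <- function(iv) {
    if (iv == fit$treatments[1]) 0 else fit$d[, iv]
  }
  lnor <- dcol(contrast[1]) - dcol(contrast[2])
  if (random_effects) {
    # predictive uncertainty: the effect operating in a model population is
    # a trial-level effect N(d, sigma^2), so between-trial heterogeneity
    # propagates into the pooled estimate fed to the CE model
    lnor <- lnor + fit$sigma *
      with_seed(derive_seed(config$seed, "pred"),
                stats::rnorm(length(lnor)))
  }
  if (any(!is.finite(lnor))) {
    stop("glm_fit: sampler produced non-finite draws for contrast ",
         paste(contrast, collapse = " vs "))
  }
  p0 <- pooled_baseline_risk(network, contrast[2], parameter)
  lnrr <- or_to_rr(lnor, NULL, p0)$lnrr
  est <- new_effect_estimate(
    point = mean(lnrr),
    variance = stats::var(lnrr),
    ci = unname(stats::quantile(lnrr, c(0.025, 0.975))),
    method = method, contrast = contrast,
    sigma2 = if (random_effects) stats::median(fit$sigma)^2 else NA_real_,
    corrected = isTRUE(attr(dat, "corrected")))
  if (random_effects) attr(est, "sigma_draws") <- fit$sigma
  est
}
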