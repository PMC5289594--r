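# Decision-analytic Markov cohort model with probabilistic sensitivity
# analysis and cost-effectiveness acceptability curves.

ABSOLUTE_QUANTITIES <- c("maint_Moderate", "maint_Severe", "maint_VerySevere",
                         "event_cost", "util_Moderate", "util_Severe",
                         "util_VerySevere", "event_decrement")

# DL-pooled mean and SE of one intervention's arm-level per-cycle risk.
pooled_baseline <- function(network, intervention, parameter) {
  est <- list()
  for (tr in network$trials) {
    for (a in 1:2) {
      if (tr$contrast[a] != intervention) next
      r <- tr$counts[[a]]$r[[parameter]]
      n <- tr$counts[[a]]$n[[parameter]]
      if (n <= 0) next
      if (r == 0 || r == n) { r <- r + 0.5; n <- n + 1 }
      p <- r / n
      est[[length(est) + 1L]] <- c(p = p, v = p * (1 - p) / n)
    }
  }
  if (!length(est)) return(c(mean = NA_real_, se = NA_real_))
  m <- do.call(rbind, est)
  d <- dersimonian_laird(m[, "p"], m[, "v"])
  c(mean = min(max(d$point, 1e-6), 1 - 1e-6), se = sqrt(d$variance))
}

#' Assemble the full Markov model parameter set from pooled evidence
#'
#' Everything the cost-effectiveness model needs for one treatment-versus-
#' comparator analysis: the 12 comparator baseline probabilities
#' (DerSimonian-Laird pooled over the comparator arms in the network), the 12
#' relative effects on the ln(RR) scale estimated with the chosen
#' meta-analysis method, pooled costs and utilities with their uncertainty,
#' and the fixed intervention costs.
#'
#' @param network an [build_evidence_network()] result.
#' @param method one of `r toString(METHODS)`.
#' @param contrast character(2): (treatment, comparator); default
#'   `c("New", "Usual")`.
#' @param intervention_costs list as in [disease_spec()]; defaults to the
#'   standard price schedule of the four interventions.
#' @param glm_cfg a [glm_config()] (used by the Bayesian methods).
#' @return object of class `model_parameter_set`.
#' @export
model_parameter_set <- function(network, method, contrast = c("New", "Usual"),
                                intervention_costs = NULL,
                                glm_cfg = glm_config()) {
  method <- match.arg(method, METHODS)
  if (is.null(intervention_costs)) {
    intervention_costs <- default_disease_spec()$intervention_costs
  }
  baseline <- t(vapply(TRANSITIONS, function(par) {
    pooled_baseline(network, contrast[2], par)
  }, c(mean = 0.0, se = 0.0)))
  effects <- lapply(TRANSITIONS, function(par) {
    switch(method,
      DIRECT = pool_direct(network, contrast, par),
      SONG = song_mixed(network, contrast, par),
      PUHAN = puhan_logistic(network, contrast, par),
      GLMFE = glm_fit(network, contrast, par, glm_cfg, random_effects = FALSE),
      GLMRE = glm_fit(network, contrast, par, glm_cfg, random_effects = TRUE))
  })
  names(effects) <- TRANSITIONS
  abs_df <- network_absolutes_df(network)
  absolutes <- t(vapply(ABSOLUTE_QUANTITIES, function(q) {
    rows <- abs_df[abs_df$quantity == q & abs_df$n > 0, ]
    p <- pool_absolute(rows$mean, rows$se)
    c(mean = p$mean, se = p$se)
  }, c(mean = 0.0, se = 0.0)))
  structure(list(method = method, contrast = contrast, baseline = baseline,
                 effects = effects, absolutes = absolutes,
                 intervention_costs = intervention_costs),
            class = "model_parameter_set")
}

#' @export
print.model_parameter_set <- function(x, ...) {
  cat("Model parameter set:", x$method, "for", x$contrast[1], "vs",
      x$contrast[2], "\n")
  invisible(x)
}

#' Run the deterministic Markov cohort model for one arm
#'
#' Evolves the cohort from the population starting vector (5/8 Moderate, 2/8
#' Severe, 1/8 Very Severe) over 12 monthly cycles under the supplied
#' realized probabilities, accumulating life years, QALYs, expected events
#' and costs. The stage occupancy at cycle 1 is the starting vector (death
#' is counted from the cycle in which it is entered; no half-cycle
#' correction), matching the accounting of the microsimulation.
#'
#' @param probs named numeric vector over the 12 parameter codes with the
#'   realized per-cycle probabilities of this arm (values are clamped to
#'   \[0, 1\] and competing exits renormalized).
#' @param costs list with `maintenance` (length 3), `event`, `oneoff`,
#'   `per_cycle`.
#' @param utilities list with `stage` (length 3) and `event_decrement`.
#' @param cycles number of monthly cycles.
#' @param start starting occupancy over the four stages.
#' @return list with `ly`, `qaly`, `events`, cost components, `total_cost`,
#'   `cycles` (expected cycle counts per stage) and `prop_surviving`.
#' @export
run_markov <- function(probs, costs, utilities, cycles = 12,
                       start = c(5, 2, 1, 0) / 8) {
  probs <- probs[TRANSITIONS]
  if (anyNA(probs)) stop("run_markov: probabilities missing for some parameters")
  probs[probs < 0] <- 0
  probs[probs > 1] <- 1
  for (cols in list(c("MS", "MVS", "MD"), c("SVS", "SM", "SD"),
                    c("VSS", "VSM", "VSD"))) {
    tot <- sum(probs[cols])
    if (tot > 1) probs[cols] <- probs[cols] / tot
  }
  M <- transition_matrix_from_probs(probs)
  ev_p <- c(probs[["evM"]], probs[["evS"]], probs[["evVS"]], 0)
  occ <- start
  occupancy <- numeric(4)
  events <- 0
  maint <- 0
  qaly <- 0
  ustage <- pmin(1, pmax(0, utilities$stage))
  for (cyc in seq_len(cycles)) {
    occupancy <- occupancy + occ
    events <- events + sum(occ * ev_p)
    maint <- maint + sum(occ[1:3] * costs$maintenance)
    qaly <- qaly + sum(occ[1:3] * ustage) / 12
    if (cyc < cycles) occ <- drop(occ %*% M)
  }
  ly <- sum(occupancy[1:3]) / 12
  qaly <- qaly - events * max(0, utilities$event_decrement)
  iv_cost <- costs$oneoff + costs$per_cycle * sum(occupancy[1:3])
  list(ly = ly, qaly = qaly, events = events,
       maintenance_cost = maint, event_cost = events * costs$event,
       intervention_cost = iv_cost,
       total_cost = maint + events * costs$event + iv_cost,
       cycles = stats::setNames(occupancy, STAGES),
       prop_surviving = 1 - occ[4])
}

# Moment-matched distribution draws ------------------------------------------

draw_beta_matched <- function(n, mean, se) {
  if (se <= 0) return(rep(mean, n))
  v <- se^2
  if (v >= mean * (1 - mean)) {
    # infeasible for a Beta: fall back to a clamped normal
    return(pmin(1, pmax(0, stats::rnorm(n, mean, se))))
  }
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

draw_gamma_matched <- function(n, mean, se) {
  if (se <= 0 || mean <= 0) return(rep(max(mean, 0), n))
  shape <- mean^2 / se^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Draw one probabilistic-sensitivity-analysis parameter realization
#'
#' Relative effects are drawn from Normal(point, variance) on the ln(RR)
#' scale; baseline probabilities and utilities from moment-matched Beta
#' distributions; costs from moment-matched Gamma distributions. Fixed
#' intervention costs are not drawn. When Beta moment matching is infeasible
#' (SE too large for the mean) a clamped normal is used.
#'
#' @param params a [model_parameter_set()].
#' @param n number of draws.
#' @return list of matrices: `baseline` (n x 12), `lnrr` (n x 12),
#'   `absolutes` (n x 8).
#' @export
draw_psa <- function(params, n = 1) {
  stopifnot(inherits(params, "model_parameter_set"))
  baseline <- vapply(TRANSITIONS, function(par) {
    draw_beta_matched(n, params$baseline[par, "mean"],
                      params$baseline[par, "se"])
  }, numeric(n))
  lnrr <- vapply(TRANSITIONS, function(par) {
    e <- params$effects[[par]]
    if (!e$estimable || !is.finite(e$point)) return(rep(NA_real_, n))
    if (e$variance <= 0) rep(e$point, n)
    else stats::rnorm(n, e$point, sqrt(e$variance))
  }, numeric(n))
  absolutes <- vapply(ABSOLUTE_QUANTITIES, function(q) {
    m <- params$absolutes[q, "mean"]; s <- params$absolutes[q, "se"]
    if (startsWith(q, "util_") || q == "event_decrement") {
      draw_beta_matched(n, m, s)
    } else {
      draw_gamma_matched(n, m, s)
    }
  }, numeric(n))
  if (n == 1) {
    baseline <- matrix(baseline, 1, dimnames = list(NULL, TRANSITIONS))
    lnrr <- matrix(lnrr, 1, dimnames = list(NULL, TRANSITIONS))
    absolutes <- matrix(absolutes, 1, dimnames = list(NULL, ABSOLUTE_QUANTITIES))
  }
  list(baseline = baseline, lnrr = lnrr, absolutes = absolutes)
}

#' Probabilistic sensitivity analysis
#'
#' Runs the Markov cohort model `n_iter` times under random parameter draws.
#' Within an iteration the comparator and treatment arms share the same
#' baseline, cost and utility draws; the treatment arm applies the drawn
#' relative risks multiplicatively to the drawn baseline probabilities
#' (clamped at 1, competing exits renormalized). Incremental outcomes are
#' treatment minus comparator.
#'
#' @param params a [model_parameter_set()].
#' @param n_iter iterations (study default 1,100; must be >= 2).
#' @param seed integer seed.
#' @return object of class `psa_result`: `iterations` data.frame (one row per
#'   iteration: delta_qaly, delta_ly, delta_events, delta_total_cost),
#'   `means`, `ci` (2.5/97.5 percentiles), `method`, `contrast`.
#' @export
run_psa <- function(params, n_iter = 1100, seed = 1L) {
  stopifnot(inherits(params, "model_parameter_set"), n_iter >= 2)
  draws <- with_seed(derive_seed(seed, "psa", params$contrast[1],
                                 params$contrast[2]),
                     draw_psa(params, n_iter))
  ivc_t <- params$intervention_costs[[params$contrast[1]]]
  ivc_c <- params$intervention_costs[[params$contrast[2]]]
  p0 <- draws$baseline
  p1 <- p0 * exp(draws$lnrr)
  na1 <- is.na(p1)
  p1[na1] <- p0[na1]  # unestimable effect: assume no effect
  p1[p1 > 1] <- 1
  comp <- run_markov_vec(p0, draws$absolutes, ivc_c)
  trt <- run_markov_vec(p1, draws$absolutes, ivc_t)
  out <- cbind(delta_qaly = trt$qaly - comp$qaly,
               delta_ly = trt$ly - comp$ly,
               delta_events = trt$events - comp$events,
               delta_total_cost = trt$total_cost - comp$total_cost)
  iterations <- as.data.frame(out)
  means <- colMeans(out)
  ci <- apply(out, 2, stats::quantile, probs = c(0.025, 0.975))
  structure(list(iterations = iterations, means = means, ci = ci,
                 n_iter = n_iter, method = params$method,
                 contrast = params$contrast),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA (%s, %d iterations): dQALY %.4f [%.4f, %.4f], dCost %.0f\n",
              x$method, x$n_iter, x$means["delta_qaly"],
              x$ci[1, "delta_qaly"], x$ci[2, "delta_qaly"],
              x$means["delta_total_cost"]))
  invisible(x)
}

# Vectorized cohort model: one row per PSA iteration. Same accounting as
# run_markov (verified against it in the test suite), evaluated for all
# draws simultaneously.
run_markov_vec <- function(probs, absolutes, ivc, cycles = 12,
                           start = c(5, 2, 1, 0) / 8) {
  P <- probs[, TRANSITIONS, drop = FALSE]
  P[P < 0] <- 0
  P[P > 1] <- 1
  for (cols in list(c("MS", "MVS", "MD"), c("SVS", "SM", "SD"),
                    c("VSS", "VSM", "VSD"))) {
    tot <- rowSums(P[, cols, drop = FALSE])
    over <- tot > 1
    if (any(over)) P[over, cols] <- P[over, cols, drop = FALSE] / tot[over]
  }
  n <- nrow(P)
  occ <- matrix(rep(start, each = n), n, 4)
  cyc_tot <- matrix(0, n, 4)
  events <- numeric(n)
  maint_draw <- absolutes[, c("maint_Moderate", "maint_Severe",
                              "maint_VerySevere"), drop = FALSE]
  util_draw <- absolutes[, c("util_Moderate", "util_Severe",
                             "util_VerySevere"), drop = FALSE]
  util_draw[util_draw < 0] <- 0
  util_draw[util_draw > 1] <- 1
  maint <- numeric(n)
  qaly <- numeric(n)
  for (cyc in seq_len(cycles)) {
    cyc_tot <- cyc_tot + occ
    events <- events + occ[, 1] * P[, "evM"] + occ[, 2] * P[, "evS"] +
      occ[, 3] * P[, "evVS"]
    maint <- maint + rowSums(occ[, 1:3, drop = FALSE] * maint_draw)
    qaly <- qaly + rowSums(occ[, 1:3, drop = FALSE] * util_draw) / 12
    if (cyc < cycles) {
      o1 <- occ[, 1] * (1 - P[, "MS"] - P[, "MVS"] - P[, "MD"]) +
        occ[, 2] * P[, "SM"] + occ[, 3] * P[, "VSM"]
      o2 <- occ[, 1] * P[, "MS"] +
        occ[, 2] * (1 - P[, "SVS"] - P[, "SM"] - P[, "SD"]) +
        occ[, 3] * P[, "VSS"]
      o3 <- occ[, 1] * P[, "MVS"] + occ[, 2] * P[, "SVS"] +
        occ[, 3] * (1 - P[, "VSS"] - P[, "VSM"] - P[, "VSD"])
      o4 <- occ[, 4] + occ[, 1] * P[, "MD"] + occ[, 2] * P[, "SD"] +
        occ[, 3] * P[, "VSD"]
      occ <- cbind(o1, o2, o3, o4)
    }
  }
  alive <- rowSums(cyc_tot[, 1:3, drop = FALSE])
  dec <- absolutes[, "event_decrement"]
  dec[dec < 0] <- 0
  qaly <- qaly - events * dec
  ev_cost <- events * absolutes[, "event_cost"]
  iv_cost <- ivc$oneoff + ivc$per_cycle * alive
  list(ly = alive / 12, qaly = qaly, events = events,
       total_cost = maint + ev_cost + iv_cost)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the treatment is
#' cost-effective: the fraction of PSA iterations with positive net monetary
#' benefit `wtp * dQALY - dCost`.
#'
#' @param psa a [run_psa()] result.
#' @param wtp_grid willingness-to-pay values (euro per QALY).
#' @return data.frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 2500)) {
  stopifnot(inherits(psa, "psa_result"))
  dq <- psa$iterations$delta_qaly
  dc <- psa$iterations$delta_total_cost
  prob <- vapply(wtp_grid, function(l) mean(l * dq - dc > 0), 0.0)
  data.frame(wtp = wtp_grid, probability = prob)
}
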