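# Evidence pooling: DerSimonian-Laird direct pooling, adjusted indirect
# comparison via common comparators, fixed-effect logistic regression on
# reconstructed records, and helpers shared with the Bayesian models.

METHODS <- c("DIRECT", "SONG", "PUHAN", "GLMFE", "GLMRE")

new_effect_estimate <- function(point, variance, ci, method, contrast,
                                tau2 = NA_real_, sigma2 = NA_real_,
                                corrected = FALSE, estimable = TRUE,
                                draws = NULL) {
  structure(list(point = point, variance = variance, ci = ci,
                 method = method, contrast = contrast, tau2 = tau2,
                 sigma2 = sigma2, corrected = corrected,
                 estimable = estimable, draws = draws),
            class = "effect_estimate")
}

not_estimable <- function(method, contrast) {
  new_effect_estimate(NA_real_, NA_real_, c(NA_real_, NA_real_), method,
                      contrast, estimable = FALSE)
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("<%s %s vs %s: not estimable>\n", x$method,
                x$contrast[1], x$contrast[2]))
    return(invisible(x))
  }
  cat(sprintf("%s %s vs %s: %.4f (95%% CI %.4f to %.4f), var %.5f\n",
              x$method, x$contrast[1], x$contrast[2], x$point,
              x$ci[1], x$ci[2], x$variance))
  invisible(x)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment-based random-effects meta-analysis. The between-study variance is
#' `tau2 = max(0, (Q - (S-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' `Q = sum(w * (delta - delta_FE)^2)` and fixed-effect weights `w = 1/v`;
#' the pooled estimate uses weights `1/(v + tau2)` and its variance is the
#' reciprocal of their sum. A single study is returned as-is with `tau2 = 0`.
#'
#' @param delta study-level estimates.
#' @param v within-study variances (> 0).
#' @param method tag stored on the result.
#' @param contrast optional contrast labels.
#' @param conf_z normal quantile for the CI half-width (1.96 for 95%).
#' @return an `effect_estimate` with fields `point`, `variance`, `ci`,
#'   `tau2`.
#' @export
dersimonian_laird <- function(delta, v, method = "DIRECT",
                              contrast = c(NA, NA), conf_z = qnorm(0.975)) {
  keep <- is.finite(delta) & is.finite(v)
  delta <- as.numeric(delta[keep])
  v <- as.numeric(v[keep])
  if (length(delta) == 0) stop("dersimonian_laird: no estimates supplied")
  if (any(v <= 0)) stop("dersimonian_laird: within-study variances must be > 0")
  S <- length(delta)
  if (S == 1) {
    return(new_effect_estimate(delta, v, delta + c(-1, 1) * conf_z * sqrt(v),
                               method, contrast, tau2 = 0))
  }
  w <- 1 / v
  fe <- sum(w * delta) / sum(w)
  Q <- sum(w * (delta - fe)^2)
  tau2 <- if (Q >= S - 1) (Q - (S - 1)) / (sum(w) - sum(w^2) / sum(w)) else 0
  ws <- 1 / (v + tau2)
  point <- sum(ws * delta) / sum(ws)
  variance <- 1 / sum(ws)
  new_effect_estimate(point, variance,
                      point + c(-1, 1) * conf_z * sqrt(variance),
                      method, contrast, tau2 = tau2)
}

# Trial-level (delta, v) rows for a parameter on a given contrast,
# sign-adjusted so delta measures contrast[1] vs contrast[2]. Only trials
# whose two arms are exactly this pair qualify as direct evidence.
direct_rows <- function(network, contrast, parameter) {
  out <- list()
  for (tr in network$trials) {
    if (setequal(tr$contrast, contrast)) {
      row <- tr$lnrr[tr$lnrr$parameter == parameter, ]
      if (!row$estimable) next
      sgn <- if (identical(tr$contrast[1], contrast[1])) 1 else -1
      out[[length(out) + 1L]] <- c(delta = sgn * row$delta, v = row$v)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Pool direct evidence only
#'
#' DerSimonian-Laird pooling of the trials that compare the two interventions
#' head-to-head, for one effect-bearing parameter.
#'
#' @param network an [build_evidence_network()] result.
#' @param contrast character(2): (treatment, comparator).
#' @param parameter one of the 12 parameter codes (see `TRANSITIONS`).
#' @return an `effect_estimate` (`estimable = FALSE` if no direct trial).
#' @export
pool_direct <- function(network, contrast, parameter) {
  rows <- direct_rows(network, contrast, parameter)
  if (is.null(rows)) return(not_estimable("DIRECT", contrast))
  dersimonian_laird(rows[, "delta"], rows[, "v"], "DIRECT", contrast)
}

#' Adjusted indirect comparison combined with direct evidence
#'
#' For every intermediate intervention `j` with direct evidence on both legs,
#' forms the indirect estimate `delta_tc = delta_tj - delta_cj` with variance
#' `v_tj + v_cj` (each leg DerSimonian-Laird pooled), then pools the direct
#' estimate (if any) and all indirect estimates with DerSimonian-Laird,
#' treating each as a single study.
#'
#' @inheritParams pool_direct
#' @return an `effect_estimate`.
#' @export
song_mixed <- function(network, contrast, parameter) {
  pieces <- list()
  rows <- direct_rows(network, contrast, parameter)
  if (!is.null(rows)) {
    d <- dersimonian_laird(rows[, "delta"], rows[, "v"])
    pieces[[length(pieces) + 1L]] <- c(d$point, d$variance)
  }
  intermediates <- setdiff(INTERVENTIONS, contrast)
  for (j in intermediates) {
    leg1 <- direct_rows(network, c(contrast[1], j), parameter)
    leg2 <- direct_rows(network, c(contrast[2], j), parameter)
    if (is.null(leg1) || is.null(leg2)) next
    d1 <- dersimonian_laird(leg1[, "delta"], leg1[, "v"])
    d2 <- dersimonian_laird(leg2[, "delta"], leg2[, "v"])
    pieces[[length(pieces) + 1L]] <- c(d1$point - d2$point,
                                       d1$variance + d2$variance)
  }
  if (!length(pieces)) return(not_estimable("SONG", contrast))
  m <- do.call(rbind, pieces)
  dersimonian_laird(m[, 1], m[, 2], "SONG", contrast)
}

#' Convert a log odds ratio to a log relative risk
#'
#' `RR = OR / (1 - p0 + p0 * OR)` where `p0` is the comparator's baseline
#' risk. Vectorized over `lnor` (posterior draws are converted draw by
#' draw). For a frequentist point estimate the variance is propagated by the
#' delta method: `var_lnrr = ((1 - p0) / (1 - p0 + p0 * OR))^2 * var_lnor`.
#'
#' @param lnor log odds ratio (scalar or vector of draws).
#' @param var_lnor variance of `lnor`, or `NULL` for draw-wise conversion.
#' @param p0 comparator baseline risk, in (0, 1).
#' @return list with `lnrr` and `var_lnrr` (`NA` when `var_lnor` is `NULL`).
#' @export
or_to_rr <- function(lnor, var_lnor = NULL, p0) {
  if (length(p0) != 1 || !is.finite(p0) || p0 <= 0 || p0 >= 1) {
    stop("`p0` must lie strictly inside (0, 1)")
  }
  or <- exp(lnor)
  lnrr <- lnor - log(1 - p0 + p0 * or)
  if (is.null(var_lnor)) {
    return(list(lnrr = lnrr, var_lnrr = NA_real_))
  }
  grad <- (1 - p0) / (1 - p0 + p0 * or)
  list(lnrr = lnrr, var_lnrr = grad^2 * var_lnor)
}

# DL-pooled per-cycle risk of an intervention's arms for one parameter.
pooled_baseline_risk <- function(network, intervention, parameter) {
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
  if (!length(est)) return(NA_real_)
  m <- do.call(rbind, est)
  d <- dersimonian_laird(m[, "p"], m[, "v"])
  min(max(d$point, 1e-6), 1 - 1e-6)
}

# Arm-level rows (trial, treatment, r, n) usable for the regression-based
# and Bayesian methods, for one parameter. Arms with zero exposure drop the
# whole trial for this parameter; zero/complete cells get the 0.5
# continuity correction (flagged).
network_param_data <- function(network, parameter) {
  rows <- list()
  corrected <- FALSE
  for (tr in network$trials) {
    n1 <- tr$counts[[1]]$n[[parameter]]
    n2 <- tr$counts[[2]]$n[[parameter]]
    if (n1 <= 0 || n2 <= 0) next
    for (a in 1:2) {
      r <- tr$counts[[a]]$r[[parameter]]
      n <- tr$counts[[a]]$n[[parameter]]
      if (r == 0 || r == n) {
        r <- r + 0.5; n <- n + 1
        corrected <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tr$trial, treatment = tr$contrast[a], r = r, n = n,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  attr(out, "corrected") <- corrected
  out
}

# TRUE if the trials connect contrast[1] and contrast[2] through shared
# interventions.
network_connects <- function(dat, contrast) {
  if (is.null(dat)) return(FALSE)
  edges <- unique(t(vapply(split(dat$treatment, dat$trial), sort,
                           character(2))))
  nodes <- unique(as.vector(edges))
  if (!all(contrast %in% nodes)) return(FALSE)
  reach <- contrast[1]
  repeat {
    hit <- apply(edges, 1, function(e) any(e %in% reach))
    newr <- unique(c(reach, as.vector(edges[hit, ])))
    if (setequal(newr, reach)) break
    reach <- newr
  }
  contrast[2] %in% reach
}

#' Fixed-effect logistic regression pooling
#'
#' Maximum-likelihood logistic regression on the records reconstructed from
#' the arm-level summary tables (one Bernoulli unit per at-risk
#' patient-cycle, fitted equivalently through the aggregated binomial
#' counts), with treatment dummies and study dummies. The treatment contrast
#' is read off as a log odds ratio and converted to a log relative risk via
#' [or_to_rr()] using the DerSimonian-Laird-pooled comparator risk.
#'
#' @inheritParams pool_direct
#' @return an `effect_estimate` on the ln(RR) scale.
#' @export
puhan_logistic <- function(network, contrast, parameter) {
  dat <- network_param_data(network, parameter)
  if (!network_connects(dat, contrast)) {
    return(not_estimable("PUHAN", contrast))
  }
  dat$treatment <- factor(dat$treatment,
                          levels = intersect(INTERVENTIONS, dat$treatment))
  dat$trial <- factor(dat$trial)
  form <- if (nlevels(dat$trial) > 1) {
    cbind(r, n - r) ~ treatment + trial
  } else {
    cbind(r, n - r) ~ treatment
  }
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = dat))
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  term <- function(iv) {
    nm <- paste0("treatment", iv)
    if (iv == levels(dat$treatment)[1]) list(est = 0, idx = NA_integer_)
    else list(est = cf[[nm]], idx = which(names(cf) == nm))
  }
  t1 <- term(contrast[1]); t2 <- term(contrast[2])
  lnor <- t1$est - t2$est
  var_lnor <- 0
  if (!is.na(t1$idx)) var_lnor <- var_lnor + V[t1$idx, t1$idx]
  if (!is.na(t2$idx)) var_lnor <- var_lnor + V[t2$idx, t2$idx]
  if (!is.na(t1$idx) && !is.na(t2$idx)) {
    var_lnor <- var_lnor - 2 * V[t1$idx, t2$idx]
  }
  p0 <- pooled_baseline_risk(network, contrast[2], parameter)
  conv <- or_to_rr(lnor, var_lnor, p0)
  z <- stats::qnorm(0.975)
  new_effect_estimate(conv$lnrr, conv$var_lnrr,
                      conv$lnrr + c(-1, 1) * z * sqrt(conv$var_lnrr),
                      "PUHAN", contrast,
                      corrected = isTRUE(attr(dat, "corrected")))
}

#' Pool absolute (non-relative) quantities
#'
#' DerSimonian-Laird pooling of arm-level means (costs, utilities, baseline
#' probabilities) using the squared standard errors as within-trial
#' variances.
#'
#' @param means arm-level means.
#' @param ses arm-level standard errors.
#' @param floor_se lower bound applied to the standard errors; arm-level SEs
#'   of essentially homogeneous quantities can be numerically zero.
#' @return list with `mean`, `se`, `tau2`.
#' @export
pool_absolute <- function(means, ses, floor_se = NULL) {
  keep <- is.finite(means) & is.finite(ses)
  means <- means[keep]; ses <- ses[keep]
  if (!length(means)) stop("pool_absolute: no estimates supplied")
  if (all(ses == 0)) stop("pool_absolute: all standard errors are zero")
  if (is.null(floor_se)) floor_se <- 0.001 * max(abs(means), 1e-12)
  ses <- pmax(ses, floor_se)
  d <- dersimonian_laird(means, ses^2)
  list(mean = d$point, se = sqrt(d$variance), tau2 = d$tau2)
}
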